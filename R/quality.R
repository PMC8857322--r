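.tiers <- c("Complete", "HQ", "MQ", "LQ", "ND")

#' Assign a MIUViG-style quality tier
#'
#' Closed genomes (direct or inverted terminal repeats) are `Complete`
#' regardless of estimated completeness. Otherwise: completeness >= 90
#' is `HQ` (high quality), >= 50 is `MQ` (medium), below 50 is `LQ`;
#' a missing completeness estimate gives `ND` (not determined).
#'
#' @param completeness Numeric percent (NA = not determined). Vectorized.
#' @param closed Logical: terminal repeats present.
#' @return Character vector of tiers.
#' @export
assign_tier <- function(completeness, closed) {
  stopifnot(length(completeness) == length(closed))
  if (any(!is.na(completeness) & completeness < 0)) {
    stop("negative completeness")
  }
  out <- rep("ND", length(completeness))
  known <- !is.na(completeness)
  out[known & completeness < 50] <- "LQ"
  out[known & completeness >= 50] <- "MQ"
  out[known & completeness >= 90] <- "HQ"
  out[closed] <- "Complete"
  out
}

#' Remove concatemer and overcomplete bins
#'
#' Partitions quality records into kept and removed: bins with genome
#' copy number at least 1.25 are removed as concatemers (inclusive), and
#' bins with estimated completeness strictly above 120% are removed as
#' overcomplete. A bin failing both checks carries both tags.
#'
#' @param quality data.frame with `bin_id`, `completeness`,
#'   `copy_number` (as from [read_quality_summary()]).
#' @param copy_number_min Removal bound for copy number (default 1.25,
#'   inclusive).
#' @param completeness_max Removal bound for completeness (default 120,
#'   strict).
#' @return List with `kept` and `removed` data.frames; `removed` gains a
#'   `reason` column (`"concatemer"`, `"overcomplete"` or both,
#'   comma-separated). `rbind(kept, removed[names(kept)])` restores the
#'   input rows.
#' @export
filter_bins <- function(quality, copy_number_min = 1.25,
                        completeness_max = 120) {
  concat <- quality$copy_number >= copy_number_min
  overc <- !is.na(quality$completeness) & quality$completeness > completeness_max
  reason <- character(nrow(quality))
  reason[concat] <- "concatemer"
  reason[overc] <- ifelse(concat[overc], "concatemer,overcomplete",
                          "overcomplete")
  drop <- concat | overc
  removed <- quality[drop, , drop = FALSE]
  removed$reason <- reason[drop]
  rownames(removed) <- NULL
  kept <- quality[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Define viral populations from clusters of quality-tiered bins
#'
#' Every cluster of predicted-viral bins is a viral population. A
#' population is `HQ_ref` when at least one member bin is `HQ` or
#' `Complete`, `MQ_ref` when its best member is `MQ`, and `dark_matter`
#' when no member reaches `MQ`.
#'
#' @param bin_tiers data.frame with `bin_id`, `cluster_id`, `tier`.
#' @return data.frame: `cluster_id`, `n_bins`, `status` in
#'   `{"HQ_ref", "MQ_ref", "dark_matter"}`.
#' @export
define_populations <- function(bin_tiers) {
  stopifnot(all(c("bin_id", "cluster_id", "tier") %in% names(bin_tiers)))
  pieces <- split(bin_tiers, bin_tiers$cluster_id)
  rows <- lapply(pieces, function(p) {
    status <- if (any(p$tier %in% c("Complete", "HQ"))) "HQ_ref"
              else if (any(p$tier == "MQ")) "MQ_ref"
              else "dark_matter"
    data.frame(cluster_id = p$cluster_id[1L], n_bins = nrow(p),
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratify dark-matter populations into putative and viral-like
#'
#' Among dark-matter populations, a population is a putative virus when
#' its viral prediction score is strictly above 0.75 AND it carries at
#' least one viral hallmark gene AND its size is at least 10 kbp
#' (summed contig length). Putative viruses additionally targeted by a
#' CRISPR spacer from a MAG are upgraded to `viral_like`.
#'
#' @param populations Result of [define_populations()].
#' @param evidence data.frame with `cluster_id`, `score` (viral
#'   prediction score), `n_hallmark` (viral hallmark gene count),
#'   `size_bp`, `spacer_targeted` (logical).
#' @param min_score,min_hallmark,min_size Rule bounds: score strict
#'   `> 0.75`, hallmark `>= 1`, size `>= 10000` bp.
#' @return `populations` with added logical `putative_virus` column and
#'   `status` upgraded to `"viral_like"` where the full rule holds.
#' @export
stratify_dark_matter <- function(populations, evidence, min_score = 0.75,
                                 min_hallmark = 1, min_size = 10000) {
  i <- match(populations$cluster_id, evidence$cluster_id)
  put <- populations$status == "dark_matter" & !is.na(i) &
    evidence$score[i] > min_score &
    evidence$n_hallmark[i] >= min_hallmark &
    evidence$size_bp[i] >= min_size
  populations$putative_virus <- put
  upgrade <- put & evidence$spacer_targeted[i]
  populations$status[upgrade] <- "viral_like"
  populations
}
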