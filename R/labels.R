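#' Label viral bins from gold-standard alignments
#'
#' A contig "matches" the gold-standard reference set when any of its
#' alignments reaches at least `min_identity` percent identity and
#' `min_coverage` percent query coverage. A bin is labelled viral when
#' the fraction of its contigs that match is at least `min_fraction`
#' (inclusive); otherwise it stays unlabelled.
#'
#' @param assignments Cluster assignments (`cluster_id`, `contig_id`,
#'   `sample_id`).
#' @param hits Contig-vs-gold-standard alignments with columns
#'   `query_id`, `pct_identity` and either `query_coverage` or both
#'   `aln_length` and `query_length` (coverage is then computed as
#'   `aln_length / query_length * 100`).
#' @param min_identity,min_coverage,min_fraction Thresholds; defaults
#'   95, 50 and 0.95, all inclusive.
#' @return data.frame: `bin_id`, `cluster_id`, `label`
#'   (`"viral"`/`"unlabelled"`), `evidence` (matching-contig fraction).
#' @export
label_viral_bins <- function(assignments, hits, min_identity = 95,
                             min_coverage = 50, min_fraction = 0.95) {
  if (!"query_coverage" %in% names(hits)) {
    if (!all(c("aln_length", "query_length") %in% names(hits))) {
      stop("hits need query_coverage, or aln_length and query_length")
    }
    hits$query_coverage <- hits$aln_length / hits$query_length * 100
  }
  ok <- hits$pct_identity >= min_identity & hits$query_coverage >= min_coverage
  matching <- unique(hits$query_id[ok])
  a <- assignments
  a$bin_id <- .bin_id(a$sample_id, a$cluster_id)
  a$match <- a$contig_id %in% matching
  agg <- stats::aggregate(match ~ bin_id + cluster_id, data = a, FUN = mean)
  data.frame(bin_id = agg$bin_id, cluster_id = agg$cluster_id,
             label = ifelse(agg$match >= min_fraction, "viral", "unlabelled"),
             evidence = agg$match, stringsAsFactors = FALSE)
}

#' Label bacterial bins from a CheckM-style table
#'
#' A bin is labelled bacterial when its estimated completeness is at
#' least `min_completeness` percent and its contamination at most
#' `max_contamination` percent (both bounds inclusive).
#'
#' @param checkm data.frame with `bin_id`, `completeness`,
#'   `contamination` (percent).
#' @param min_completeness,max_contamination Thresholds; defaults 10
#'   and 30.
#' @return data.frame: `bin_id`, `label`
#'   (`"bacterial"`/`"unlabelled"`), `evidence`.
#' @export
label_bacterial_bins <- function(checkm, min_completeness = 10,
                                 max_contamination = 30) {
  ok <- checkm$completeness >= min_completeness &
    checkm$contamination <= max_contamination
  data.frame(bin_id = checkm$bin_id,
             label = ifelse(ok, "bacterial", "unlabelled"),
             evidence = sprintf("completeness=%.1f;contamination=%.1f",
                                checkm$completeness, checkm$contamination),
             stringsAsFactors = FALSE)
}

#' Combine viral and bacterial labels into a training label set
#'
#' Bins carrying both a viral and a bacterial label are conflicting
#' evidence; they are excluded from training (set back to unlabelled)
#' with a warning, since only confidently labelled bins should train the
#' classifier.
#'
#' @param viral Result of [label_viral_bins()].
#' @param bacterial Result of [label_bacterial_bins()].
#' @return data.frame: `bin_id`, `label` in
#'   `{"viral", "bacterial", "unlabelled"}`.
#' @export
combine_labels <- function(viral, bacterial) {
  ids <- union(viral$bin_id, bacterial$bin_id)
  v <- viral$label[match(ids, viral$bin_id)]
  b <- bacterial$label[match(ids, bacterial$bin_id)]
  is_v <- !is.na(v) & v == "viral"
  is_b <- !is.na(b) & b == "bacterial"
  conflict <- is_v & is_b
  if (any(conflict)) {
    warning(sprintf("%d bin(s) labelled both viral and bacterial; excluded: %s",
                    sum(conflict),
                    paste(utils::head(ids[conflict], 5L), collapse = ", ")))
  }
  label <- rep("unlabelled", length(ids))
  label[is_v & !conflict] <- "viral"
  label[is_b & !conflict] <- "bacterial"
  data.frame(bin_id = ids, label = label, stringsAsFactors = FALSE)
}
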