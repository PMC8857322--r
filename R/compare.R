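# Truncate (not round) a percentage to one decimal, the display
# convention used for contamination/purity.
.trunc1 <- function(x) trunc(x * 10) / 10

#' Call metavirome-genome recovery from ANI records
#'
#' A query genome is recovered by a bin at ANI level L when the aligned
#' fraction (bidirectional fragments / total fragments) is at least
#' `min_af` and the ANI is strictly above L. Records with ANI below
#' `min_ani` (weak hits) are dropped before calling. Levels are nested
#' by construction: recovery at 97.5 implies 95 implies 90.
#'
#' @param ani_records data.frame as from [read_fastani()]
#'   (`query_genome`, `ref_genome`, `ani`, `bidir_fragments`,
#'   `total_fragments`).
#' @param levels ANI levels in percent (default `c(90, 95, 97.5)`).
#' @param min_af Minimum aligned fraction (default 0.75).
#' @param min_ani Records below this ANI are discarded (default 80).
#' @return data.frame of the retained records with `aligned_fraction`
#'   and one logical column `recovered_<level>` per level.
#' @export
call_recovery <- function(ani_records, levels = c(90, 95, 97.5),
                          min_af = 0.75, min_ani = 80) {
  if (any(ani_records$total_fragments == 0L)) {
    stop("total_fragments must be >= 1")
  }
  x <- ani_records[ani_records$ani >= min_ani, , drop = FALSE]
  x$aligned_fraction <- x$bidir_fragments / x$total_fragments
  for (L in levels) {
    x[[sprintf("recovered_%g", L)]] <- x$aligned_fraction >= min_af & x$ani > L
  }
  rownames(x) <- NULL
  x
}

# Merge 1-based closed intervals and return total covered bp.
.covered_bp <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0L; cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ce + 1L) {
      ce <- max(ce, end[i])
    } else {
      tot <- tot + (ce - cs + 1L)
      cs <- start[i]; ce <- end[i]
    }
  }
  tot + (ce - cs + 1L)
}

#' Compute bin purity and contamination against a matched reference
#'
#' Alignment intervals of each contig to the bin's matched reference are
#' merged (overlaps counted once, strand ignored); contamination is the
#' unaligned fraction of the bin in base pairs,
#' `unaligned_bp / total_bp * 100`, and purity is `100 - contamination`.
#' Both the exact percentages and the one-decimal truncated display
#' values are returned (a bin of 90,000 bp with 8,000 bp unaligned has
#' exact contamination 8.888...%, displayed 8.8%, purity displayed
#' 91.2%).
#'
#' @param contigs data.frame with `contig_id`, `length` for the bin.
#' @param alignments data.frame with `contig_id`, `start`, `end`
#'   (1-based closed coordinates on the contig) of alignments to the
#'   matched reference. Contigs without alignments count entirely as
#'   unaligned.
#' @return List of class `bin_purity`: `total_bp`, `aligned_bp`,
#'   `unaligned_bp`, `contamination`, `purity` (exact percents),
#'   `contamination_1dp`, `purity_1dp` (one-decimal display:
#'   contamination truncated, purity = 100 - truncated contamination).
#' @export
compute_purity <- function(contigs, alignments) {
  stopifnot(all(c("contig_id", "length") %in% names(contigs)),
            all(c("contig_id", "start", "end") %in% names(alignments)))
  if (nrow(alignments) > 0L) {
    len <- contigs$length[match(alignments$contig_id, contigs$contig_id)]
    if (anyNA(len)) stop("alignment refers to a contig not in the bin")
    if (any(alignments$start < 1L) || any(alignments$end > len) ||
        any(alignments$start > alignments$end)) {
      stop("alignment coordinates must satisfy 1 <= start <= end <= contig length")
    }
  }
  aligned <- sum(vapply(split(alignments, alignments$contig_id), function(a) {
    .covered_bp(as.integer(a$start), as.integer(a$end))
  }, integer(1)))
  total <- sum(contigs$length)
  contamination <- (total - aligned) / total * 100
  structure(list(total_bp = total, aligned_bp = aligned,
                 unaligned_bp = total - aligned,
                 contamination = contamination, purity = 100 - contamination,
                 contamination_1dp = .trunc1(contamination),
                 purity_1dp = 100 - .trunc1(contamination)),
            class = "bin_purity")
}

#' @export
print.bin_purity <- function(x, ...) {
  cat(sprintf("bin of %d bp: %d bp unaligned -> contamination %.1f%% (exact %.4f%%), purity %.1f%%\n",
              x$total_bp, x$unaligned_bp, x$contamination_1dp,
              x$contamination, x$purity_1dp))
  invisible(x)
}

#' Purity of many bins, with cohort summary
#'
#' @param contigs data.frame with `bin_id`, `contig_id`, `length`.
#' @param alignments data.frame with `contig_id`, `start`, `end`.
#' @return List: `per_bin` data.frame (one row per bin with the
#'   [compute_purity()] fields) and `summary` (mean and median purity).
#' @export
bin_purity_table <- function(contigs, alignments) {
  per_bin <- do.call(rbind, lapply(split(contigs, contigs$bin_id), function(b) {
    a <- alignments[alignments$contig_id %in% b$contig_id, , drop = FALSE]
    p <- compute_purity(b, a)
    data.frame(bin_id = b$bin_id[1L], total_bp = p$total_bp,
               unaligned_bp = p$unaligned_bp,
               contamination = p$contamination, purity = p$purity,
               contamination_1dp = p$contamination_1dp,
               purity_1dp = p$purity_1dp, stringsAsFactors = FALSE)
  }))
  rownames(per_bin) <- NULL
  list(per_bin = per_bin,
       summary = c(mean_purity = mean(per_bin$purity),
                   median_purity = stats::median(per_bin$purity)))
}

#' Intra- and inter-cluster ANI summaries
#'
#' For every cluster with at least two members, the median of pairwise
#' ANI values between its member bins; clusters with a single member are
#' reported as NA. Pairs spanning two clusters form the inter-cluster
#' ANI distribution.
#'
#' @param ani data.frame with `query_genome`, `ref_genome`, `ani`
#'   (pairwise bin-vs-bin measurements; self pairs are ignored).
#' @param membership data.frame with `bin_id`, `cluster_id`.
#' @return List: `intra` data.frame (`cluster_id`, `n_pairs`,
#'   `median_ani`) and `inter` numeric vector of between-cluster ANIs.
#' @export
cluster_ani_summary <- function(ani, membership) {
  cl <- function(id) membership$cluster_id[match(id, membership$bin_id)]
  x <- ani[ani$query_genome != ani$ref_genome, , drop = FALSE]
  qc <- cl(x$query_genome); rc <- cl(x$ref_genome)
  known <- !is.na(qc) & !is.na(rc)
  x <- x[known, , drop = FALSE]; qc <- qc[known]; rc <- rc[known]
  intra_vals <- split(x$ani[qc == rc], qc[qc == rc])
  clusters <- unique(membership$cluster_id)
  intra <- data.frame(cluster_id = clusters,
                      n_pairs = vapply(clusters, function(c)
                        length(intra_vals[[c]]) %||% 0L, integer(1)),
                      median_ani = vapply(clusters, function(c) {
                        v <- intra_vals[[c]]
                        if (is.null(v)) NA_real_ else stats::median(v)
                      }, numeric(1)),
                      stringsAsFactors = FALSE)
  rownames(intra) <- NULL
  list(intra = intra, inter = x$ani[qc != rc])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
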