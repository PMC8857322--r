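#' RPKM abundance profiles of viral populations
#'
#' Per contig and sample, RPKM = reads / ((length/1e3) x
#' (sample_total_reads/1e6)). The abundance of a population (cluster)
#' in a sample is the mean RPKM over its member contigs whose breadth
#' of coverage — the fraction of contig positions covered at least
#' once — reaches `min_breadth`; populations with no qualifying contig
#' in a sample get 0.
#'
#' @param counts Numeric matrix of read counts, contigs x samples
#'   (rownames = contig ids).
#' @param lengths Named numeric vector of contig lengths in bp.
#' @param breadth Numeric matrix in `[0, 1]`, same shape as `counts`.
#' @param clusters data.frame with `contig_id`, `cluster_id`.
#' @param sample_totals Total reads per sample (default
#'   `colSums(counts)`); a sample with zero total reads is an error.
#' @param min_breadth Detection-breadth bound (default 0.75, inclusive).
#' @return List of class `population_profile`: `abundance` (populations
#'   x samples RPKM matrix), `prevalence` (fraction of samples with
#'   abundance > 0, per population).
#' @export
compute_population_rpkm <- function(counts, lengths, breadth, clusters,
                                    sample_totals = colSums(counts),
                                    min_breadth = 0.75) {
  stopifnot(identical(dim(counts), dim(breadth)))
  if (any(sample_totals <= 0)) {
    stop("every sample needs a positive total read count")
  }
  len <- lengths[rownames(counts)]
  if (anyNA(len)) stop("missing length for some contigs")
  rpkm <- counts / ((len / 1e3) %o% (sample_totals / 1e6))
  qualifies <- breadth >= min_breadth
  cl <- clusters$cluster_id[match(rownames(counts), clusters$contig_id)]
  pops <- sort(unique(cl[!is.na(cl)]))
  ab <- matrix(0, length(pops), ncol(counts),
               dimnames = list(pops, colnames(counts)))
  for (p in pops) {
    rows <- which(cl == p)
    for (s in seq_len(ncol(counts))) {
      q <- rows[qualifies[rows, s]]
      if (length(q)) ab[p, s] <- mean(rpkm[q, s])
    }
  }
  structure(list(abundance = ab, prevalence = rowMeans(ab > 0)),
            class = "population_profile")
}

#' @export
print.population_profile <- function(x, ...) {
  cat(sprintf("population abundance profile: %d populations x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  cat(sprintf("  detected (abundance > 0) entries: %.1f%%\n",
              100 * mean(x$abundance > 0)))
  invisible(x)
}

#' Community summaries of a population abundance matrix
#'
#' Richness (populations detected at abundance > 0), Shannon diversity
#' on relative abundances (natural log, with 0 log 0 = 0), and the
#' Bray-Curtis dissimilarity matrix between samples. An all-zero sample
#' has richness 0, Shannon 0, distance 1 to any non-empty sample and 0
#' to another empty one. When `groups` maps samples to subjects, the
#' Bray-Curtis values are also stratified into within-subject and
#' between-subject distances.
#'
#' @param abundance Nonnegative matrix, populations x samples.
#' @param groups Optional named vector: sample id -> subject/group.
#' @return List: `richness`, `shannon` (per sample), `bray_curtis`
#'   (`dist` object), and with `groups` also `intra_group` /
#'   `inter_group` distance vectors.
#' @export
community_summaries <- function(abundance, groups = NULL) {
  if (any(abundance < 0)) stop("abundances must be nonnegative")
  samples <- t(abundance)
  richness <- rowSums(samples > 0)
  # vegan collapses a one-species matrix to a single community; a single
  # population always has Shannon 0
  shannon <- if (ncol(samples) == 1L) {
    stats::setNames(rep(0, nrow(samples)), rownames(samples))
  } else {
    vegan::diversity(samples, index = "shannon")
  }
  empty <- rowSums(samples) == 0
  shannon[empty] <- 0
  bc <- matrix(0, nrow(samples), nrow(samples),
               dimnames = list(rownames(samples), rownames(samples)))
  if (any(!empty)) {
    sub <- vegan::vegdist(samples[!empty, , drop = FALSE], method = "bray")
    bc[!empty, !empty] <- as.matrix(sub)
  }
  bc[empty, !empty] <- 1
  bc[!empty, empty] <- 1
  d <- stats::as.dist(bc)
  out <- list(richness = richness, shannon = shannon, bray_curtis = d)
  if (!is.null(groups)) {
    g <- groups[rownames(samples)]
    m <- as.matrix(d)
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    same <- g[pairs[, 1L]] == g[pairs[, 2L]]
    out$intra_group <- m[pairs[same, , drop = FALSE]]
    out$inter_group <- m[pairs[!same, , drop = FALSE]]
  }
  out
}
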