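# Median DVF score over the contigs of a bin that actually carry a score;
# a bin with no scored contig gets 0. Even counts use the mean of the two
# middle values (stats::median's convention).
.median_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) return(0)
  stats::median(scores)
}

#' Compute the bin-level feature vector for one bin
#'
#' Aggregates per-contig annotations into the four features the random
#' forest consumes: total bin size in bp, the number of distinct
#' bacterial hallmark genes across the bin, the number of distinct viral
#' orthologous groups (VOGs) divided by the number of contigs, and the
#' median per-contig viral prediction score.
#'
#' @param contigs data.frame for the bin's contigs with columns
#'   `contig_id` and `length`.
#' @param scores data.frame with `contig_id` and `score`; contigs absent
#'   from it are treated as unscored and excluded from the median (a bin
#'   with no scored contig gets `median_dvf = 0`).
#' @param hmm data.frame of HMM hits with `contig_id`, `hmm_name`,
#'   `database` (`"vog"` / `"bacterial_hallmark"`) and `bitscore`.
#' @param bitscore_min Hits below this bitscore are ignored (hmmsearch
#'   working threshold; default 30).
#' @return A one-row data.frame: `bin_size`, `n_contigs`,
#'   `n_distinct_hallmark`, `vog_ratio`, `median_dvf`.
#' @examples
#' ctg <- data.frame(contig_id = c("a", "b", "c"), length = c(4e3, 3e3, 5e3))
#' sc <- data.frame(contig_id = c("a", "b", "c"), score = c(0.2, 0.6, 1.0))
#' hm <- data.frame(contig_id = c("a", "b", "c"),
#'                  hmm_name = c("VOG1", "VOG2", "VOG1"),
#'                  database = "vog", bitscore = 100)
#' compute_bin_features(ctg, sc, hm)   # vog_ratio 2/3, median_dvf 0.6
#' @export
compute_bin_features <- function(contigs, scores, hmm, bitscore_min = 30) {
  if (nrow(contigs) == 0L) stop("bin has zero contigs")
  if (anyNA(contigs$length)) stop("every contig in a bin needs a length")
  hmm <- hmm[hmm$bitscore >= bitscore_min & hmm$contig_id %in% contigs$contig_id,
             , drop = FALSE]
  sc <- scores$score[match(contigs$contig_id, scores$contig_id)]
  data.frame(
    bin_size = sum(contigs$length),
    n_contigs = nrow(contigs),
    n_distinct_hallmark = length(unique(
      hmm$hmm_name[hmm$database == "bacterial_hallmark"])),
    vog_ratio = length(unique(hmm$hmm_name[hmm$database == "vog"])) /
      nrow(contigs),
    median_dvf = .median_score(sc))
}

#' Compute the feature table over every sample-specific bin
#'
#' One row per (cluster, sample) bin, with the cluster id carried along
#' so that downstream steps (the classifier's grouped split, population
#' definition) can group bins by cluster.
#'
#' @param assignments Cluster assignments as returned by
#'   [read_cluster_table()] (`cluster_id`, `contig_id`, `sample_id`).
#' @param contig_lengths data.frame with `contig_id` and `length` for
#'   every assigned contig.
#' @param scores,hmm,bitscore_min As in [compute_bin_features()].
#'   Scores or hits for contigs not present in `assignments` raise a
#'   warning and are ignored.
#' @return data.frame with columns `bin_id`, `cluster_id`, `sample_id`
#'   and the five feature columns of [compute_bin_features()].
#' @export
compute_cluster_feature_table <- function(assignments, contig_lengths,
                                          scores, hmm, bitscore_min = 30) {
  known <- assignments$contig_id
  stray <- setdiff(unique(c(scores$contig_id, hmm$contig_id)), known)
  if (length(stray) > 0L) {
    warning(sprintf("%d annotated contig(s) have no cluster assignment; ignored",
                    length(stray)))
  }
  len <- contig_lengths$length[match(known, contig_lengths$contig_id)]
  if (anyNA(len)) {
    stop(sprintf("no length for contig '%s'", known[is.na(len)][1L]))
  }
  a <- data.frame(assignments, length = len, stringsAsFactors = FALSE)
  a$bin_id <- .bin_id(a$sample_id, a$cluster_id)
  pieces <- split(a, a$bin_id)
  rows <- lapply(pieces, function(b) {
    cbind(data.frame(bin_id = b$bin_id[1L], cluster_id = b$cluster_id[1L],
                     sample_id = b$sample_id[1L], stringsAsFactors = FALSE),
          compute_bin_features(b[c("contig_id", "length")], scores, hmm,
                               bitscore_min = bitscore_min))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
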