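# Tools whose per-contig score is a probability on [0, 1]; viralVerify reports
# a log-odds-like score on its native (unbounded) scale.
.unit_score_tools <- c("dvf", "virfinder", "virsorter2", "seeker")
.score_tools <- c(.unit_score_tools, "viralverify")

.io_stop <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Read a VAMB-style cluster table
#'
#' Parses the two-column tab-separated `clusters.tsv` dialect written by
#' VAMB-like binners: first column the cluster id, second the contig id.
#' The sample a contig came from is recovered from its id: the substring
#' before the first occurrence of `separator_token` (VAMB's `--o C`
#' convention produces ids like `S1C42`, sample `S1`).
#'
#' @param path Path to the cluster TSV.
#' @param separator_token Token separating the sample prefix from the contig
#'   counter inside contig ids. Default `"C"`.
#' @return A `data.frame` with columns `cluster_id`, `contig_id`,
#'   `sample_id`, in file order.
#' @details A contig listed under two clusters, a line without exactly two
#'   tab-separated fields, or a contig id lacking the separator token are
#'   hard errors (the offending contig or line number is named).
#' @seealso [write_cluster_table()]
#' @export
read_cluster_table <- function(path, separator_token = "C") {
  stopifnot(file.exists(path), nzchar(separator_token))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(cluster_id = character(), contig_id = character(),
                      sample_id = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    .io_stop(path, which(nf != 2L)[1L], "expected exactly 2 tab-separated fields")
  }
  cluster_id <- vapply(parts, `[[`, character(1), 1L)
  contig_id <- vapply(parts, `[[`, character(1), 2L)
  dup <- duplicated(contig_id)
  if (any(dup)) {
    stop(sprintf("duplicate contig '%s': a contig may belong to only one cluster",
                 contig_id[dup][1L]), call. = FALSE)
  }
  pos <- regexpr(separator_token, contig_id, fixed = TRUE)
  if (any(pos <= 1L)) {
    bad <- contig_id[pos <= 1L][1L]
    stop(sprintf("contig id '%s' has no sample prefix before separator token '%s'",
                 bad, separator_token), call. = FALSE)
  }
  sample_id <- substr(contig_id, 1L, pos - 1L)
  data.frame(cluster_id = cluster_id, contig_id = contig_id,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Write a cluster table
#'
#' @param x A data.frame with columns `cluster_id` and `contig_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(x, path) {
  stopifnot(all(c("cluster_id", "contig_id") %in% names(x)))
  writeLines(paste(x$cluster_id, x$contig_id, sep = "\t"), path)
  invisible(path)
}

#' Read per-contig viral prediction scores
#'
#' Reads the DeepVirFinder-style TSV dialect: a header line, then columns
#' `name`, `len`, `score` and (optionally) `pvalue`. The same dialect is
#' accepted for the other single-contig predictors; scores are
#' range-checked against the tool's declared scale.
#'
#' @param path Path to the score TSV.
#' @param tool One of `"dvf"`, `"virfinder"`, `"virsorter2"`, `"seeker"`
#'   (scores on `[0, 1]`) or `"viralverify"` (native unbounded scale).
#' @return A `data.frame` with columns `contig_id`, `length`, `score`,
#'   `pvalue` (NA when absent) and `tool`.
#' @export
read_contig_scores <- function(path, tool = "dvf") {
  tool <- match.arg(tool, .score_tools)
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop("score table needs at least 3 columns (name, len, score)")
  out <- data.frame(contig_id = as.character(x[[1L]]),
                    length = as.integer(x[[2L]]),
                    score = as.numeric(x[[3L]]),
                    pvalue = if (ncol(x) >= 4L) as.numeric(x[[4L]]) else NA_real_,
                    tool = tool, stringsAsFactors = FALSE)
  if (anyNA(out$length) || any(out$length < 1L)) {
    stop("contig lengths must be integers >= 1")
  }
  if (tool %in% .unit_score_tools &&
      (anyNA(out$score) || any(out$score < 0 | out$score > 1))) {
    stop(sprintf("scores for tool '%s' must lie in [0, 1]", tool))
  }
  bad_p <- !is.na(out$pvalue) & (out$pvalue < 0 | out$pvalue > 1)
  if (any(bad_p)) stop("p-values must lie in [0, 1]")
  out
}

#' Write per-contig viral prediction scores
#'
#' @param x A data.frame with columns `contig_id`, `length`, `score` and
#'   optionally `pvalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contig_scores <- function(x, path) {
  stopifnot(all(c("contig_id", "length", "score") %in% names(x)))
  out <- data.frame(name = x$contig_id, len = x$length, score = x$score,
                    pvalue = if ("pvalue" %in% names(x)) x$pvalue else NA_real_)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read hmmsearch tblout hits
#'
#' Parses the whitespace-delimited `--tblout` format of hmmsearch: `#`
#' comment lines are skipped; the target name (contig or protein), query
#' HMM name, full-sequence e-value and bitscore are captured.
#'
#' @param path Path to a tblout file.
#' @param database Which HMM collection the search was run against:
#'   `"vog"` (viral orthologous groups) or `"bacterial_hallmark"`
#'   (single-copy bacterial marker HMMs).
#' @return A `data.frame` with columns `contig_id`, `hmm_name`, `evalue`,
#'   `bitscore`, `database`.
#' @export
read_hmm_tblout <- function(path, database = c("vog", "bacterial_hallmark")) {
  database <- match.arg(database)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(contig_id = character(), hmm_name = character(),
                      evalue = numeric(), bitscore = numeric(),
                      database = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines[idx]), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 6L)) {
    .io_stop(path, idx[nf < 6L][1L], "expected at least 6 whitespace-delimited fields")
  }
  ev <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 5L)))
  if (anyNA(ev)) .io_stop(path, idx[is.na(ev)][1L], "non-numeric e-value")
  if (any(ev < 0)) .io_stop(path, idx[ev < 0][1L], "negative e-value")
  bs <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 6L)))
  if (anyNA(bs)) .io_stop(path, idx[is.na(bs)][1L], "non-numeric bitscore")
  data.frame(contig_id = vapply(parts, `[[`, character(1), 1L),
             hmm_name = vapply(parts, `[[`, character(1), 3L),
             evalue = ev, bitscore = bs, database = database,
             stringsAsFactors = FALSE)
}

#' Write hits in hmmsearch tblout format
#'
#' Emits a minimal, re-readable tblout: comment header, then the standard
#' field order with `-` for accessions and zeros for the per-domain
#' statistics this package does not track.
#'
#' @param x A data.frame with columns `contig_id`, `hmm_name`, `evalue`,
#'   `bitscore`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm_tblout <- function(x, path) {
  stopifnot(all(c("contig_id", "hmm_name", "evalue", "bitscore") %in% names(x)))
  hdr <- c("# target name  accession  query name  accession  E-value  score  bias",
           "#")
  rows <- sprintf("%s - %s - %.3g %.1f 0.0 %.3g %.1f 0.0 1 1 0 1 1 1 1 1 -",
                  x$contig_id, x$hmm_name, x$evalue, x$bitscore,
                  x$evalue, x$bitscore)
  writeLines(c(hdr, rows, "# [ok]"), path)
  invisible(path)
}

#' Read a CheckV-style quality summary
#'
#' Reads the per-bin quality dialect used throughout the package: a TSV
#' with header `bin_id`, `completeness` (percent, empty or `NA` when the
#' estimator could not determine it), `copy_number` and `terminal_repeat`
#' (`DTR`, `ITR` or `None`).
#'
#' @param path Path to the quality TSV.
#' @return A `data.frame` with columns `bin_id`, `completeness` (NA when
#'   not determined), `copy_number`, `closed` (logical: terminal repeats
#'   present), `terminal_repeat`.
#' @export
read_quality_summary <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("bin_id", "completeness", "copy_number", "terminal_repeat")
  if (!all(need %in% names(x))) {
    stop("quality summary must have columns: ", paste(need, collapse = ", "))
  }
  comp <- suppressWarnings(as.numeric(x$completeness))
  if (any(!is.na(comp) & comp < 0)) stop("negative completeness")
  cn <- as.numeric(x$copy_number)
  if (anyNA(cn) || any(cn < 0)) stop("copy_number must be a number >= 0")
  tr <- ifelse(is.na(x$terminal_repeat), "None", x$terminal_repeat)
  data.frame(bin_id = as.character(x$bin_id), completeness = comp,
             copy_number = cn, closed = tr %in% c("DTR", "ITR"),
             terminal_repeat = tr, stringsAsFactors = FALSE)
}

#' Write a quality summary
#'
#' @param x A data.frame as returned by [read_quality_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quality_summary <- function(x, path) {
  tr <- if ("terminal_repeat" %in% names(x)) x$terminal_repeat
        else ifelse(x$closed, "DTR", "None")
  out <- data.frame(bin_id = x$bin_id,
                    completeness = x$completeness,
                    copy_number = x$copy_number,
                    terminal_repeat = tr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a CheckM-style completeness/contamination table
#'
#' @param path TSV with header columns `bin_id`, `completeness`,
#'   `contamination` (both percent on 0-100).
#' @return A `data.frame` with those three columns.
#' @export
read_checkm_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("bin_id", "completeness", "contamination")
  if (!all(need %in% names(x))) {
    stop("CheckM table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(x$completeness < 0 | x$contamination < 0)) {
    stop("completeness and contamination must be >= 0")
  }
  x[need]
}

#' Read blastn outfmt-6 style alignment hits
#'
#' Parses the standard 12-column tabular BLAST output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), optionally followed by a 13th column `qlen`. When
#' `qlen` is present, `query_coverage` is computed as
#' `aln_length / query_length * 100`.
#'
#' @param path Path to the tabular BLAST file (no header).
#' @return A `data.frame` with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gapopen`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`, and when available
#'   `query_length` and `query_coverage`. Coordinates are 1-based closed.
#' @export
read_blast_table <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 12L) stop("expected >= 12 tab-separated columns (outfmt 6)")
  out <- data.frame(query_id = as.character(x[[1L]]),
                    subject_id = as.character(x[[2L]]),
                    pct_identity = as.numeric(x[[3L]]),
                    aln_length = as.integer(x[[4L]]),
                    mismatches = as.integer(x[[5L]]),
                    gapopen = as.integer(x[[6L]]),
                    qstart = as.integer(x[[7L]]), qend = as.integer(x[[8L]]),
                    sstart = as.integer(x[[9L]]), send = as.integer(x[[10L]]),
                    evalue = as.numeric(x[[11L]]),
                    bitscore = as.numeric(x[[12L]]),
                    stringsAsFactors = FALSE)
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("percent identity must lie in [0, 100]")
  }
  if (any(out$mismatches < 0) || any(out$mismatches > out$aln_length)) {
    stop("mismatches must lie in [0, aln_length]")
  }
  if (ncol(x) >= 13L) {
    out$query_length <- as.integer(x[[13L]])
    if (any(out$aln_length > out$query_length)) {
      stop("alignment length exceeds query length")
    }
    out$query_coverage <- out$aln_length / out$query_length * 100
  }
  out
}

#' Write alignment hits in outfmt-6 layout
#'
#' @param x A data.frame as returned by [read_blast_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_table <- function(x, path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  stopifnot(all(cols %in% names(x)))
  out <- x[cols]
  if ("query_length" %in% names(x)) out$query_length <- x$query_length
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read FastANI 5-column output
#'
#' Columns: query genome, reference genome, ANI (percent), count of
#' bidirectional fragment mappings, total query fragments. The aligned
#' fraction `bidir_fragments / total_fragments` is added.
#'
#' @param path Path to the FastANI output (no header).
#' @return A `data.frame` with columns `query_genome`, `ref_genome`,
#'   `ani`, `bidir_fragments`, `total_fragments`, `aligned_fraction`.
#' @export
read_fastani <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 5L) stop("expected 5 tab-separated columns (FastANI output)")
  out <- data.frame(query_genome = as.character(x[[1L]]),
                    ref_genome = as.character(x[[2L]]),
                    ani = as.numeric(x[[3L]]),
                    bidir_fragments = as.integer(x[[4L]]),
                    total_fragments = as.integer(x[[5L]]),
                    stringsAsFactors = FALSE)
  if (any(out$ani < 0 | out$ani > 100)) stop("ANI must lie in [0, 100]")
  if (any(out$total_fragments < 1L)) stop("total_fragments must be >= 1")
  if (any(out$bidir_fragments < 0L) ||
      any(out$bidir_fragments > out$total_fragments)) {
    stop("bidir_fragments must lie in [0, total_fragments]")
  }
  out$aligned_fraction <- out$bidir_fragments / out$total_fragments
  out
}

#' Write FastANI-style records
#'
#' @param x A data.frame with the five FastANI columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastani <- function(x, path) {
  cols <- c("query_genome", "ref_genome", "ani", "bidir_fragments",
            "total_fragments")
  stopifnot(all(cols %in% names(x)))
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-contig per-sample depth table
#'
#' TSV with header: `contig_id`, `length`, then one numeric column per
#' sample (read counts or depths, depending on what was summarised).
#'
#' @param path Path to the depth TSV.
#' @return A list with `contig_id` (character), `length` (integer vector
#'   named by contig) and `values` (numeric matrix, contigs x samples).
#' @export
read_depth_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (ncol(x) < 3L) stop("depth table needs contig_id, length and >= 1 sample column")
  if (!identical(names(x)[1:2], c("contig_id", "length"))) {
    stop("depth table must start with columns contig_id, length")
  }
  m <- as.matrix(x[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0)) stop("depth values must be numbers >= 0")
  rownames(m) <- x$contig_id
  len <- as.integer(x$length)
  names(len) <- x$contig_id
  list(contig_id = x$contig_id, length = len, values = m)
}

#' Write a per-contig per-sample depth table
#'
#' @param contig_id,length,values Components as returned by
#'   [read_depth_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(contig_id, length, values, path) {
  out <- data.frame(contig_id = contig_id, length = length,
                    as.data.frame(values), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
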