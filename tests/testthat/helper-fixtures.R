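# Shared synthetic-study fixtures, built once per test run.

.study_cache <- new.env(parent = emptyenv())

# Default-condition study (seed 7), reused by many tests.
demo_study <- function(seed = 7, ...) {
  key <- paste0("s", seed, "_", paste(deparse(substitute(list(...))),
                                      collapse = ""))
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  spec <- fixture_spec(seed = seed, ...)
  comm <- generate_community(spec)
  ann <- generate_annotations(comm, spec)
  out <- list(spec = spec, comm = comm, ann = ann)
  .study_cache[[key]] <- out
  out
}

# A small community for fast structural checks.
small_spec <- function(seed = 3, ...) {
  fixture_spec(n_samples = 3, n_viral_clusters = 10,
               n_bacterial_clusters = 6, seed = seed, ...)
}

# Independent brute-force confusion-matrix metrics (textbook formulas,
# no shared code with the package).
oracle_metrics <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(precision = prec, recall = rec, f1 = f1, mcc = mcc)
}

# Brute-force AUC: probability a random positive outranks a random
# negative, ties counted half.
oracle_auc <- function(prob, positive) {
  pos <- prob[positive]; neg <- prob[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
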