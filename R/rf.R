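.rf_features <- c("bin_size", "n_distinct_hallmark", "vog_ratio", "median_dvf")

#' Default per-tool viral decision thresholds
#'
#' Single-contig predictors call a sequence (or an aggregated bin score)
#' viral when the score is strictly above the tool's threshold:
#' viralVerify 7, Seeker 0.5, VirFinder 0.9, DeepVirFinder 0.9,
#' Virsorter2 0.9.
#'
#' @return Named numeric vector of thresholds.
#' @export
tool_thresholds <- function() {
  c(viralverify = 7, seeker = 0.5, virfinder = 0.9, dvf = 0.9,
    virsorter2 = 0.9)
}

#' Fit the random-forest viral-bin classifier
#'
#' Trains a random forest (300 trees, `sqrt(p)` candidate features per
#' split) on bin-level features to separate viral from bacterial bins,
#' using a stratified split with `train_fraction` of the observations
#' for training and the rest held out for evaluation. By default the
#' split is grouped by cluster — all sample-specific bins of a cluster
#' fall on the same side — so near-identical bins of one population
#' cannot leak between training and validation; set
#' `group_by_cluster = FALSE` for a plain per-bin split.
#'
#' @param features Feature table from [compute_cluster_feature_table()]
#'   (needs `bin_id`, `cluster_id` and the four feature columns
#'   `bin_size`, `n_distinct_hallmark`, `vog_ratio`, `median_dvf`).
#' @param labels data.frame with `bin_id` and `label`
#'   (`"viral"`/`"bacterial"`; `"unlabelled"` bins are dropped).
#' @param ntree Number of trees (default 300).
#' @param train_fraction Fraction of observations used for training
#'   (default 0.40), the rest evaluate the fit.
#' @param threshold Probability cutoff for calling a bin viral at
#'   prediction time (default 0.5).
#' @param group_by_cluster Keep all bins of a cluster on one side of the
#'   split (default TRUE).
#' @param seed Seed controlling the split and the forest.
#' @return An object of class `viral_rf` with components `forest` (the
#'   underlying [randomForest::randomForest]), `features` (column
#'   schema), `eval` (held-out [evaluate_bins()] report), `split`
#'   (train/test bin ids), `config`.
#' @seealso [predict.viral_rf()], [evaluate_bins()]
#' @export
viral_rf <- function(features, labels, ntree = 300, train_fraction = 0.4,
                     threshold = 0.5, group_by_cluster = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  miss <- setdiff(.rf_features, names(features))
  if (length(miss)) stop("missing feature column: ", paste(miss, collapse = ", "))
  lab <- labels$label[match(features$bin_id, labels$bin_id)]
  keep <- !is.na(lab) & lab %in% c("viral", "bacterial")
  x <- features[keep, , drop = FALSE]
  y <- factor(lab[keep], levels = c("bacterial", "viral"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training requires both viral and bacterial bins")
  }
  with_seed(seed, {
    if (group_by_cluster) {
      cl <- unique(x[c("cluster_id")])
      cl$label <- y[match(cl$cluster_id, x$cluster_id)]
      train_cl <- unlist(lapply(split(cl$cluster_id, cl$label), function(ids) {
        n <- max(1L, round(train_fraction * length(ids)))
        sample(ids, n)
      }), use.names = FALSE)
      train <- x$cluster_id %in% train_cl
    } else {
      train <- rep(FALSE, nrow(x))
      for (lv in levels(y)) {
        i <- which(y == lv)
        train[sample(i, max(1L, round(train_fraction * length(i))))] <- TRUE
      }
    }
    if (!any(train) || all(train)) stop("degenerate train/test split")
    xm <- as.matrix(x[.rf_features])
    forest <- randomForest::randomForest(
      x = xm[train, , drop = FALSE], y = droplevels(y[train]),
      ntree = ntree, mtry = floor(sqrt(length(.rf_features))))
    prob <- stats::predict(forest, xm[!train, , drop = FALSE],
                           type = "prob")[, "viral"]
    pred <- data.frame(bin_id = x$bin_id[!train], prob_viral = prob,
                       label = ifelse(prob >= threshold, "viral", "bacterial"),
                       stringsAsFactors = FALSE)
    truth <- data.frame(bin_id = x$bin_id[!train],
                        label = as.character(y[!train]),
                        stringsAsFactors = FALSE)
    structure(list(forest = forest, features = .rf_features,
                   threshold = threshold,
                   eval = evaluate_bins(pred, truth),
                   split = list(train = x$bin_id[train],
                                test = x$bin_id[!train]),
                   config = list(ntree = ntree,
                                 train_fraction = train_fraction,
                                 group_by_cluster = group_by_cluster,
                                 seed = seed)),
              class = "viral_rf")
  })
}

#' Predict viral probability and label for bins
#'
#' @param object A fitted [viral_rf()] model.
#' @param newdata Feature table with the model's feature columns and a
#'   `bin_id` column; a missing feature column is an error (the schema
#'   is checked, never imputed).
#' @param threshold Probability cutoff; a bin is called viral when its
#'   viral probability is at least this (default: the model's).
#' @param ... Ignored.
#' @return data.frame: `bin_id`, `prob_viral`, `label`.
#' @export
predict.viral_rf <- function(object, newdata, threshold = object$threshold,
                             ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop("missing feature column: ", paste(miss, collapse = ", "))
  }
  xm <- as.matrix(newdata[object$features])
  prob <- stats::predict(object$forest, xm, type = "prob")[, "viral"]
  data.frame(bin_id = newdata$bin_id, prob_viral = unname(prob),
             label = ifelse(prob >= threshold, "viral", "bacterial"),
             stringsAsFactors = FALSE)
}

#' @export
print.viral_rf <- function(x, ...) {
  cat("Viral-bin random forest\n")
  cat(sprintf("  %d trees, mtry %d, features: %s\n", x$config$ntree,
              x$forest$mtry, paste(x$features, collapse = ", ")))
  cat(sprintf("  split: %d train / %d held-out bins (%s)\n",
              length(x$split$train), length(x$split$test),
              if (x$config$group_by_cluster) "grouped by cluster"
              else "per bin"))
  cat(sprintf("  held-out AUC %.3f, F1 %.3f, MCC %.3f\n",
              x$eval$auc, x$eval$f1, x$eval$mcc))
  invisible(x)
}

#' @export
summary.viral_rf <- function(object, ...) {
  print(object)
  cat("\nVariable importance (mean decrease in Gini):\n")
  imp <- randomForest::importance(object$forest)
  print(imp[order(-imp[, 1L]), , drop = FALSE])
  cat("\nHeld-out confusion matrix:\n")
  print(object$eval$confusion)
  invisible(object)
}

#' Aggregate per-contig scores into a bin score
#'
#' The three aggregation rules used when lifting single-contig predictor
#' scores to bin level: the contig-length weighted mean
#' `sum(l_i s_i) / sum(l_i)`, the plain mean, and the median.
#'
#' @param scores Numeric vector of per-contig scores (>= 1 required).
#' @param lengths Contig lengths in bp (required for `weighted_mean`).
#' @param method One of `"weighted_mean"`, `"mean"`, `"median"`.
#' @return A single aggregated score.
#' @examples
#' aggregate_bin_score(c(0.2, 0.8), c(1000, 3000), "weighted_mean")  # 0.65
#' @export
aggregate_bin_score <- function(scores, lengths = NULL,
                                method = c("weighted_mean", "mean", "median")) {
  method <- match.arg(method)
  if (length(scores) == 0L) stop("no scores to aggregate")
  switch(method,
         weighted_mean = {
           if (is.null(lengths) || length(lengths) != length(scores)) {
             stop("weighted_mean needs one length per score")
           }
           sum(lengths * scores) / sum(lengths)
         },
         mean = mean(scores),
         median = stats::median(scores))
}

#' Call a bin viral from an aggregated tool score
#'
#' A bin is viral when its (aggregated) score is strictly above the
#' tool's threshold.
#'
#' @param score Numeric score(s).
#' @param tool Tool name, one of `names(tool_thresholds())`.
#' @param thresholds Named threshold vector (default [tool_thresholds()]).
#' @return Character vector: `"viral"` or `"bacterial"`.
#' @export
classify_bin_by_tool <- function(score, tool, thresholds = tool_thresholds()) {
  if (!tool %in% names(thresholds)) stop("unknown tool: ", tool)
  ifelse(score > thresholds[[tool]], "viral", "bacterial")
}

#' Evaluate binary bin predictions against truth
#'
#' Computes the held-out evaluation report: AUC (rank statistic over
#' probabilities with midranks for ties), F1, Matthews correlation
#' coefficient (0 when its denominator vanishes), precision, recall and
#' the 2x2 confusion matrix. The positive class is `"viral"`.
#'
#' @param predictions data.frame with `bin_id`, `label` and (for AUC)
#'   `prob_viral`.
#' @param truth data.frame with `bin_id` and `label`.
#' @return List of class `bin_eval`: `auc`, `f1`, `mcc`, `precision`,
#'   `recall`, `confusion`, `n`.
#' @export
evaluate_bins <- function(predictions, truth) {
  ids <- intersect(predictions$bin_id, truth$bin_id)
  if (length(ids) == 0L) stop("predictions and truth share no bin ids")
  pl <- predictions$label[match(ids, predictions$bin_id)]
  tl <- truth$label[match(ids, truth$bin_id)]
  tp <- sum(pl == "viral" & tl == "viral")
  fp <- sum(pl == "viral" & tl != "viral")
  fn <- sum(pl != "viral" & tl == "viral")
  tn <- sum(pl != "viral" & tl != "viral")
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  auc <- NA_real_
  if ("prob_viral" %in% names(predictions)) {
    p <- predictions$prob_viral[match(ids, predictions$bin_id)]
    pos <- tl == "viral"
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 > 0L && n0 > 0L) {
      r <- rank(p, ties.method = "average")
      auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  confusion <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                      dimnames = list(truth = c("viral", "bacterial"),
                                      predicted = c("viral", "bacterial")))
  structure(list(auc = auc, f1 = f1, mcc = mcc, precision = precision,
                 recall = recall, confusion = confusion, n = length(ids)),
            class = "bin_eval")
}

#' @export
print.bin_eval <- function(x, ...) {
  cat(sprintf("n = %d bins | AUC %.3f  F1 %.3f  MCC %.3f  precision %.3f  recall %.3f\n",
              x$n, x$auc, x$f1, x$mcc, x$precision, x$recall))
  print(x$confusion)
  invisible(x)
}

#' Benchmark single-contig aggregation baselines against truth
#'
#' For each aggregation method, lifts per-contig scores to bin level
#' with [aggregate_bin_score()], calls bins with
#' [classify_bin_by_tool()], and evaluates against truth — the
#' single-contig baseline the bin-level random forest is compared with.
#'
#' @param assignments Cluster assignments.
#' @param scores Per-contig score table (`contig_id`, `length`, `score`).
#' @param truth data.frame with `bin_id`, `label`.
#' @param tool Tool whose threshold applies (default `"dvf"`).
#' @param methods Aggregation methods to benchmark.
#' @param thresholds Threshold set (default [tool_thresholds()]).
#' @return data.frame: one row per method with `mcc`, `f1`, `auc`.
#' @export
benchmark_baselines <- function(assignments, scores, truth, tool = "dvf",
                                methods = c("weighted_mean", "mean", "median"),
                                thresholds = tool_thresholds()) {
  a <- assignments
  a$bin_id <- .bin_id(a$sample_id, a$cluster_id)
  a$score <- scores$score[match(a$contig_id, scores$contig_id)]
  a$length <- scores$length[match(a$contig_id, scores$contig_id)]
  a <- a[!is.na(a$score), , drop = FALSE]
  out <- lapply(methods, function(m) {
    agg <- vapply(split(a, a$bin_id), function(b) {
      aggregate_bin_score(b$score, b$length, method = m)
    }, numeric(1))
    pred <- data.frame(bin_id = names(agg), prob_viral = unname(agg),
                       label = classify_bin_by_tool(unname(agg), tool,
                                                    thresholds),
                       stringsAsFactors = FALSE)
    ev <- evaluate_bins(pred, truth)
    data.frame(method = m, mcc = ev$mcc, f1 = ev$f1, auc = ev$auc)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
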