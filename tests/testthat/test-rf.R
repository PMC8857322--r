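# Shared fitted model on the default-condition study.
fit_demo_rf <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    st <- demo_study()
    ft <- compute_cluster_feature_table(
      st$comm$clusters, st$comm$contigs[c("contig_id", "length")],
      st$ann$scores, st$ann$hmm)
    lab <- combine_labels(label_viral_bins(st$comm$clusters, st$ann$gold_hits),
                          label_bacterial_bins(st$ann$checkm))
    cache <<- list(st = st, ft = ft, lab = lab,
                   fit = viral_rf(ft, lab, seed = 7))
    cache
  }
})

test_that("training is deterministic and separates a well-separated fixture", {
  d <- fit_demo_rf()
  expect_gte(d$fit$eval$auc, 0.95)
  refit <- viral_rf(d$ft, d$lab, seed = 7)
  expect_identical(predict(refit, d$ft), predict(d$fit, d$ft))
  # on a noiseless fixture the held-out MCC is perfect
  expect_equal(d$fit$eval$mcc, 1)
})

test_that("randomly permuted labels give near-zero MCC at n = 500 bins", {
  d <- fit_demo_rf()
  lab <- d$lab
  set.seed(99)
  lab$label <- sample(lab$label)
  keep <- lab$label != "unlabelled"
  expect_gte(sum(keep), 500)
  fit <- viral_rf(d$ft, lab, seed = 99)
  expect_lt(abs(fit$eval$mcc), 0.2)
})

test_that("degenerate inputs are refused", {
  d <- fit_demo_rf()
  onlyv <- d$lab
  onlyv$label[onlyv$label == "bacterial"] <- "unlabelled"
  expect_error(viral_rf(d$ft, onlyv), "both viral and bacterial")
  expect_error(viral_rf(d$ft[setdiff(names(d$ft), "median_dvf")], d$lab),
               "missing feature column: median_dvf")
})

test_that("prediction checks the feature schema and is row-order invariant", {
  d <- fit_demo_rf()
  expect_error(predict(d$fit, d$ft[setdiff(names(d$ft), "vog_ratio")]),
               "missing feature column")
  p1 <- predict(d$fit, d$ft)
  shuffled <- d$ft[rev(seq_len(nrow(d$ft))), ]
  p2 <- predict(d$fit, shuffled)
  p2 <- p2[match(p1$bin_id, p2$bin_id), ]
  expect_equal(p1$prob_viral, p2$prob_viral)
  # probabilities are probabilities
  expect_true(all(p1$prob_viral >= 0 & p1$prob_viral <= 1))
})

test_that("an archetypal bacterial bin scores below the viral threshold", {
  d <- fit_demo_rf()
  bac <- data.frame(bin_id = "bac_archetype", bin_size = 3e6, n_contigs = 30,
                    n_distinct_hallmark = 40, vog_ratio = 0, median_dvf = 0.05)
  p <- predict(d$fit, bac)
  expect_lt(p$prob_viral, d$fit$threshold)
  expect_equal(p$label, "bacterial")
})

test_that("the grouped split keeps all bins of a cluster on one side", {
  d <- fit_demo_rf()
  side <- ifelse(d$ft$bin_id %in% d$fit$split$train, "train", "test")
  expect_true(all(tapply(side, d$ft$cluster_id,
                         function(s) length(unique(s))) == 1))
  # per-bin splitting is available and may split clusters
  fit2 <- viral_rf(d$ft, d$lab, group_by_cluster = FALSE, seed = 7)
  expect_s3_class(fit2, "viral_rf")
  expect_gte(fit2$eval$auc, 0.95)
})

test_that("bin-score aggregation follows the three stated rules", {
  expect_equal(aggregate_bin_score(c(0.2, 0.8), c(1000, 3000),
                                   "weighted_mean"), 0.65)
  # a single contig returns its score under every method
  for (m in c("weighted_mean", "mean", "median")) {
    expect_equal(aggregate_bin_score(0.7, 1234, m), 0.7)
  }
  # equal lengths collapse the weighted mean onto the mean
  s <- c(0.1, 0.5, 0.9)
  expect_equal(aggregate_bin_score(s, rep(2000, 3), "weighted_mean"),
               aggregate_bin_score(s, rep(2000, 3), "mean"))
  expect_error(aggregate_bin_score(numeric(0)), "no scores")
})

test_that("tool thresholds are strict (score must exceed the cutoff)", {
  expect_equal(classify_bin_by_tool(0.9, "dvf"), "bacterial")
  expect_equal(classify_bin_by_tool(0.9 + 1e-9, "dvf"), "viral")
  expect_equal(classify_bin_by_tool(7.1, "viralverify"), "viral")
  expect_equal(classify_bin_by_tool(7, "viralverify"), "bacterial")
  expect_error(classify_bin_by_tool(1, "unknown_tool"), "unknown tool")
})

test_that("evaluation handles perfect, degenerate and random cases", {
  perfect <- data.frame(bin_id = letters[1:6],
                        prob_viral = c(1, 1, 1, 0, 0, 0),
                        label = rep(c("viral", "bacterial"), each = 3))
  truth <- data.frame(bin_id = letters[1:6],
                      label = rep(c("viral", "bacterial"), each = 3))
  ev <- evaluate_bins(perfect, truth)
  expect_equal(c(ev$auc, ev$f1, ev$mcc), c(1, 1, 1))

  # all-positive predictor on balanced truth: MCC defined as 0
  allpos <- perfect
  allpos$label <- "viral"
  expect_equal(evaluate_bins(allpos, truth)$mcc, 0)

  expect_error(evaluate_bins(data.frame(bin_id = "zzz", label = "viral"),
                             truth), "share no bin ids")
})

test_that("AUC uses midranks for ties and is invariant under monotone transforms", {
  set.seed(5)
  prob <- round(runif(60), 1)   # force ties
  truth <- data.frame(bin_id = sprintf("b%d", 1:60),
                      label = sample(c("viral", "bacterial"), 60, TRUE))
  pred <- data.frame(bin_id = truth$bin_id, prob_viral = prob,
                     label = ifelse(prob >= 0.5, "viral", "bacterial"))
  a0 <- evaluate_bins(pred, truth)$auc
  expect_equal(a0, oracle_auc(prob, truth$label == "viral"))
  for (f in list(function(p) p^3, function(p) exp(2 * p), plogis)) {
    pred2 <- pred
    pred2$prob_viral <- f(prob)
    expect_equal(evaluate_bins(pred2, truth)$auc, a0)
  }
})

test_that("metrics match textbook formulas on 100 random confusion settings", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    tl <- sample(c("viral", "bacterial"), n, TRUE)
    pl <- sample(c("viral", "bacterial"), n, TRUE)
    pred <- data.frame(bin_id = sprintf("b%d", 1:n), label = pl,
                       prob_viral = runif(n))
    ev <- evaluate_bins(pred, data.frame(bin_id = pred$bin_id, label = tl))
    o <- oracle_metrics(tp = sum(pl == "viral" & tl == "viral"),
                        fp = sum(pl == "viral" & tl == "bacterial"),
                        fn = sum(pl == "bacterial" & tl == "viral"),
                        tn = sum(pl == "bacterial" & tl == "bacterial"))
    expect_equal(ev$mcc, o$mcc)
    expect_equal(ev$f1, o$f1)
    expect_equal(ev$precision, o$precision)
    expect_equal(ev$recall, o$recall)
    expect_equal(sum(ev$confusion), n)
  }
})

test_that("under heavy per-contig score noise the RF beats every aggregation baseline", {
  spec <- fixture_spec(viral_score_beta = c(1.6, 1.4),
                       bacterial_score_beta = c(1.4, 1.6), seed = 13)
  comm <- generate_community(spec)
  ann <- generate_annotations(comm, spec)
  ft <- compute_cluster_feature_table(
    comm$clusters, comm$contigs[c("contig_id", "length")], ann$scores,
    ann$hmm)
  truth <- comm$bins[c("bin_id", "label")]
  fit <- viral_rf(ft, truth, seed = 13)
  held <- truth[truth$bin_id %in% fit$split$test, ]
  base <- benchmark_baselines(comm$clusters, ann$scores, held)
  expect_gt(fit$eval$mcc, max(base$mcc))
})

test_that("print and summary methods describe the fit", {
  d <- fit_demo_rf()
  expect_output(print(d$fit), "Viral-bin random forest")
  expect_output(summary(d$fit), "importance")
  expect_output(print(d$fit$eval), "MCC")
})
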