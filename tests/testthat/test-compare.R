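test_that("recovery calls apply AF >= 0.75 with strict ANI levels and the 80% floor", {
  ani <- data.frame(query_genome = sprintf("q%d", 1:4), ref_genome = "bin",
                    ani = c(96, 99, 79.9, 95),
                    bidir_fragments = c(40, 37, 50, 38),
                    total_fragments = c(50, 50, 50, 50))
  rc <- call_recovery(ani)
  # ani 96, AF 0.80: recovered at 90 and 95, not 97.5
  expect_true(rc$recovered_90[rc$query_genome == "q1"])
  expect_true(rc$recovered_95[rc$query_genome == "q1"])
  expect_false(rc$recovered_97.5[rc$query_genome == "q1"])
  # ani 99 but AF 0.74: not recovered anywhere
  expect_false(any(unlist(rc[rc$query_genome == "q2",
                             c("recovered_90", "recovered_95",
                               "recovered_97.5")])))
  # ani < 80 dropped entirely
  expect_false("q3" %in% rc$query_genome)
  # ani exactly at a level is not recovered there (strict >)
  expect_false(rc$recovered_95[rc$query_genome == "q4"])
  expect_true(rc$recovered_90[rc$query_genome == "q4"])
})

test_that("recovery levels are nested and monotone over 1000 random records", {
  set.seed(23)
  ani <- data.frame(query_genome = sprintf("q%d", 1:1000), ref_genome = "b",
                    ani = runif(1000, 80, 100),
                    bidir_fragments = sample(0:50, 1000, TRUE),
                    total_fragments = 50)
  rc <- call_recovery(ani)
  expect_true(all(rc$recovered_97.5 <= rc$recovered_95))
  expect_true(all(rc$recovered_95 <= rc$recovered_90))
  # monotone: raising ANI or AF never loses recovery
  rc2 <- call_recovery(transform(ani, ani = pmin(100, ani + 2)))
  expect_true(all(rc$recovered_95 <= rc2$recovered_95))
})

test_that("purity reproduces the 90 kb / 8 kb worked example", {
  contigs <- data.frame(contig_id = "ctg1", length = 90000)
  aln <- data.frame(contig_id = "ctg1", start = 1, end = 82000)
  p <- compute_purity(contigs, aln)
  expect_equal(p$unaligned_bp, 8000)
  expect_equal(p$contamination, 8000 / 90000 * 100)
  expect_equal(p$contamination_1dp, 8.8)   # one-decimal truncation
  expect_equal(p$purity_1dp, 91.2)
  expect_equal(p$purity + p$contamination, 100)
})

test_that("overlapping alignment intervals are merged, never double counted", {
  contigs <- data.frame(contig_id = "c", length = 1000)
  aln <- data.frame(contig_id = "c",
                    start = c(1, 101, 50, 900), end = c(200, 300, 250, 1000))
  p <- compute_purity(contigs, aln)
  expect_equal(p$aligned_bp, 300 + 101)    # [1,300] merged + [900,1000]
  # fully aligned bin
  full <- compute_purity(contigs, data.frame(contig_id = "c", start = 1,
                                             end = 1000))
  expect_equal(full$purity, 100)
  expect_equal(full$contamination, 0)
  # invalid coordinates rejected
  expect_error(compute_purity(contigs, data.frame(contig_id = "c",
                                                  start = 0, end = 10)),
               "coordinates")
  expect_error(compute_purity(contigs, data.frame(contig_id = "c",
                                                  start = 5, end = 2000)),
               "coordinates")
})

test_that("purity matches an interval-arithmetic oracle on 100 random bins", {
  set.seed(29)
  for (i in 1:100) {
    n_ctg <- sample(1:4, 1)
    contigs <- data.frame(contig_id = sprintf("c%d", seq_len(n_ctg)),
                          length = sample(1000:5000, n_ctg))
    aln <- do.call(rbind, lapply(seq_len(n_ctg), function(j) {
      k <- sample(0:5, 1)
      if (k == 0) return(NULL)
      s <- sample(contigs$length[j], k, replace = TRUE)
      e <- pmin(contigs$length[j], s + sample(0:800, k, replace = TRUE))
      data.frame(contig_id = contigs$contig_id[j], start = s, end = e)
    }))
    if (is.null(aln)) aln <- data.frame(contig_id = character(),
                                        start = integer(), end = integer())
    p <- compute_purity(contigs, aln)
    # oracle: per-base coverage masks
    aligned <- 0L
    for (j in seq_len(n_ctg)) {
      mask <- logical(contigs$length[j])
      a <- aln[aln$contig_id == contigs$contig_id[j], , drop = FALSE]
      for (r in seq_len(nrow(a))) mask[a$start[r]:a$end[r]] <- TRUE
      aligned <- aligned + sum(mask)
    }
    expect_equal(p$aligned_bp, aligned)
    expect_equal(p$contamination,
                 (sum(contigs$length) - aligned) / sum(contigs$length) * 100)
    expect_equal(p$purity + p$contamination, 100)
  }
})

test_that("planted foreign contigs are exactly the unaligned fraction of a bin", {
  spec <- small_spec(seed = 14, misbinning_rate = 0.1)
  comm <- generate_community(spec)
  ctg <- comm$contigs
  # alignments to the bin's own cluster genome: native contigs align fully
  corrupted <- unique(ctg$bin_id[ctg$foreign])
  for (b in head(corrupted, 10)) {
    bc <- ctg[ctg$bin_id == b, ]
    aln <- data.frame(contig_id = bc$contig_id[!bc$foreign], start = 1,
                      end = bc$length[!bc$foreign])
    p <- compute_purity(bc[c("contig_id", "length")], aln)
    expect_equal(p$unaligned_bp, sum(bc$length[bc$foreign]))
    expect_equal(p$contamination,
                 sum(bc$length[bc$foreign]) / sum(bc$length) * 100)
  }
})

test_that("bin purity tables summarise a cohort", {
  contigs <- data.frame(bin_id = c("b1", "b1", "b2"),
                        contig_id = c("c1", "c2", "c3"),
                        length = c(1000, 1000, 2000))
  aln <- data.frame(contig_id = c("c1", "c3"), start = c(1, 1),
                    end = c(1000, 1000))
  t <- bin_purity_table(contigs, aln)
  expect_equal(t$per_bin$purity, c(50, 50))
  expect_equal(unname(t$summary["mean_purity"]), 50)
})

test_that("cluster ANI medians separate planted within/between levels", {
  # hand example: 3 members, pairwise {97, 98, 99} -> median 98
  memb <- data.frame(bin_id = c("a", "b", "c"), cluster_id = "c1")
  ani <- data.frame(query_genome = c("a", "a", "b"),
                    ref_genome = c("b", "c", "c"), ani = c(97, 98, 99))
  s <- cluster_ani_summary(ani, memb)
  expect_equal(s$intra$median_ani, 98)
  # identical genomes -> median 100
  s2 <- cluster_ani_summary(transform(ani, ani = 100), memb)
  expect_equal(s2$intra$median_ani, 100)
  # singleton cluster reported as NA
  memb3 <- rbind(memb, data.frame(bin_id = "z", cluster_id = "c9"))
  s3 <- cluster_ani_summary(ani, memb3)
  expect_true(is.na(s3$intra$median_ani[s3$intra$cluster_id == "c9"]))

  # planted two-level structure: within 98, between 92
  set.seed(7)
  memb4 <- data.frame(bin_id = sprintf("m%d", 1:12),
                      cluster_id = rep(sprintf("k%d", 1:3), each = 4))
  pairs <- t(combn(memb4$bin_id, 2))
  same <- memb4$cluster_id[match(pairs[, 1], memb4$bin_id)] ==
    memb4$cluster_id[match(pairs[, 2], memb4$bin_id)]
  ani4 <- data.frame(query_genome = pairs[, 1], ref_genome = pairs[, 2],
                     ani = ifelse(same, rnorm(nrow(pairs), 98, 0.3),
                                  rnorm(nrow(pairs), 92, 0.3)))
  s4 <- cluster_ani_summary(ani4, memb4)
  expect_true(all(s4$intra$median_ani > max(s4$inter)))
})
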