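test_that("spacer filter enforces identity, length fraction and mismatch bounds", {
  hits <- data.frame(query_id = sprintf("sp%d", 1:5), subject_id = "v1",
                     mag_id = "m1",
                     pct_identity = c(100, 96, 95, 94.9, 100),
                     aln_length = c(32, 31, 31, 32, 29),
                     mismatches = c(0, 3, 2, 0, 0))
  sl <- setNames(rep(32, 5), hits$query_id)
  kept <- filter_spacer_hits(hits, sl)
  # sp1 perfect: kept; sp2 has 3 mismatches; sp3 boundary-inclusive kept;
  # sp4 identity below 95; sp5 covers 29/32 < 95% of the spacer
  expect_setequal(kept$query_id, c("sp1", "sp3"))
  expect_true(all(kept$kind == "spacer"))
  # unknown spacer length is skipped with a warning
  expect_warning(k2 <- filter_spacer_hits(hits, sl[-1]), "unknown spacer length")
  expect_false("sp1" %in% k2$query_id)
})

test_that("spacer filter agrees with a brute-force filter on 500 random hits", {
  set.seed(41)
  n <- 500
  hits <- data.frame(query_id = sprintf("s%d", 1:n), subject_id = "v",
                     mag_id = "m",
                     pct_identity = runif(n, 85, 100),
                     aln_length = sample(25:36, n, TRUE),
                     mismatches = sample(0:4, n, TRUE),
                     spacer_length = sample(28:36, n, TRUE))
  kept <- filter_spacer_hits(hits)
  manual <- hits[hits$pct_identity >= 95 &
                   hits$aln_length >= 0.95 * hits$spacer_length &
                   hits$mismatches <= 2, ]
  expect_setequal(kept$query_id, manual$query_id)
  # pure and order-independent
  shuffled <- filter_spacer_hits(hits[sample(n), ])
  expect_setequal(shuffled$query_id, kept$query_id)
})

test_that("prophage filters are inclusive at 90 and merge dual evidence to 'both'", {
  ani <- data.frame(query_genome = c("v1", "v2", "v3"),
                    ref_genome = c("m1", "m2", "m3"),
                    ani = c(90.0, 89.9, 95))
  blast <- data.frame(query_id = c("v1", "v4"), subject_id = c("m1", "m4"),
                      pct_identity = c(92, 90.0))
  ev <- filter_prophage_hits(ani, blast)
  expect_false(any(ev$virus_id == "v2"))
  expect_equal(ev$kind[ev$virus_id == "v1"], "both")
  expect_equal(ev$kind[ev$virus_id == "v3"], "prophage_ani")
  expect_equal(ev$kind[ev$virus_id == "v4"], "prophage_blast")
  # set logic: evidence is a subset of the input pairs
  expect_true(all(paste(ev$virus_id, ev$mag_id) %in%
                    c(paste(ani$query_genome, ani$ref_genome),
                      paste(blast$query_id, blast$subject_id))))
})

test_that("plurality voting follows the >= 50% unique-maximum rule per rank", {
  tax <- data.frame(mag_id = c("m1", "m2", "m3", "m4"),
                    domain = "Bacteria", phylum = "Bacteroidota",
                    class = "Bacteroidia", order = "Bacteroidales",
                    family = c("Bacteroidaceae", "Bacteroidaceae",
                               "Prevotellaceae", "Rikenellaceae"),
                    genus = c("Bacteroides", "Bacteroides", "Prevotella",
                              "Alistipes"),
                    species = c("Bacteroides intestinalis",
                                "Bacteroides intestinalis",
                                "Prevotella intestinalis",
                                "Alistipes intestinalis"))
  # 2/3 Bacteroides wins the genus
  ev <- data.frame(virus_id = "v1", mag_id = c("m1", "m2", "m3"))
  call <- plurality_host(ev, tax)
  expect_equal(call$genus, "Bacteroides")
  # exact 50/50 two-way tie is NA, and deeper ranks stay NA
  ev2 <- data.frame(virus_id = "v2", mag_id = c("m1", "m3"))
  call2 <- plurality_host(ev2, tax)
  expect_equal(call2$order, "Bacteroidales")
  expect_true(is.na(call2$family))
  expect_true(is.na(call2$genus))
  expect_true(is.na(call2$species))
  # single supporting MAG transfers the full lineage
  ev3 <- data.frame(virus_id = "v3", mag_id = "m4")
  call3 <- plurality_host(ev3, tax)
  expect_equal(call3$species, "Alistipes intestinalis")
  expect_equal(call3$n_mags, 1L)
  # 2/4 with the rest split is a unique maximum at exactly 50%: wins
  ev4 <- data.frame(virus_id = "v4", mag_id = c("m1", "m2", "m3", "m4"))
  expect_equal(plurality_host(ev4, tax)$genus, "Bacteroides")
})

test_that("plurality voting agrees with a brute-force counter over 1000 vote multisets", {
  taxa <- c("A", "B", "C", "D")
  tax <- data.frame(mag_id = sprintf("m%d", 1:40),
                    domain = "Bacteria", phylum = "P", class = "C",
                    order = "O", family = "F",
                    genus = rep(taxa, 10),
                    species = paste(rep(taxa, 10), "sp"))
  set.seed(43)
  for (i in 1:1000) {
    k <- sample(1:8, 1)
    mags <- sample(tax$mag_id, k)
    ev <- data.frame(virus_id = "v", mag_id = mags)
    call <- plurality_host(ev, tax)
    votes <- tax$genus[match(mags, tax$mag_id)]
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    want <- if (length(top) == 1 && max(tab) / length(votes) >= 0.5) top
            else NA_character_
    expect_identical(call$genus, want)
  }
})

test_that("host purity and consensus behave on hand-built and noiseless inputs", {
  # 3 of 4 member calls agree -> population purity 75%
  calls <- data.frame(virus_id = sprintf("v%d", 1:4), cluster_id = "p1",
                      kind = "spacer",
                      species = c("X", "X", "X", "Y"))
  hp <- host_prediction_purity(calls)
  expect_equal(hp$per_population$purity, 0.75)
  expect_equal(hp$cohort$purity_pct, 75)
  # all identical -> 100%
  calls$species <- "X"
  expect_equal(host_prediction_purity(calls)$cohort$purity_pct, 100)

  # noiseless fixture: species purity 100% and full consensus across methods
  spec <- small_spec(seed = 19)
  comm <- generate_community(spec)
  host <- generate_host_evidence(comm, spec)
  sp <- filter_spacer_hits(host$spacer_hits)
  sp_ev <- data.frame(virus_id = sp$subject_id, mag_id = sp$mag_id)
  sp_calls <- plurality_host(sp_ev, host$mag_taxonomy)
  pr <- filter_prophage_hits(ani_records = host$prophage_ani)
  pr_calls <- plurality_host(pr, host$mag_taxonomy)
  all_calls <- rbind(cbind(sp_calls, kind = "spacer"),
                     cbind(pr_calls, kind = "prophage"))
  all_calls$cluster_id <- comm$bins$cluster_id[
    match(all_calls$virus_id, comm$bins$bin_id)]
  hp2 <- host_prediction_purity(all_calls, rank = "species")
  expect_true(all(hp2$cohort$purity_pct == 100))
  expect_equal(hp2$consensus_pct, 100)
})

test_that("temperate calls need coverage >= 80 with ANI >= 90, or an integrase", {
  aln <- data.frame(virus_id = c("v1", "v2", "v3"),
                    query_coverage = c(80, 79, 85),
                    ani = c(90, 99, 89.9))
  ann <- data.frame(virus_id = "v4",
                    description = "Phage integrase family protein")
  out <- annotate_temperate(c("v1", "v2", "v3", "v4", "v5"), aln, ann)
  expect_equal(out$temperate, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$evidence[1], "integration")
  expect_equal(out$evidence[4], "integrase")
  # case-insensitive integrase match
  ann2 <- data.frame(virus_id = "v5", description = "Site-specific INTEGRASE")
  out2 <- annotate_temperate("v5", NULL, ann2)
  expect_true(out2$temperate)
})

test_that("viral taxonomy uses the two-protein vote with reference fallback", {
  lca <- read.delim(system.file("extdata", "vog_lca_synthetic.tsv",
                                package = "viralbins"),
                    stringsAsFactors = FALSE)
  # one VOG protein, no reference -> all NA
  one <- assign_viral_taxonomy(
    data.frame(virus_id = "v1", protein_id = "p1", vog = "VOG00001"), lca)
  expect_true(is.na(one$family))
  expect_equal(one$method, "none")
  # 4 proteins voting 3:1 Siphoviridae at family
  four <- assign_viral_taxonomy(
    data.frame(virus_id = "v2", protein_id = sprintf("p%d", 1:4),
               vog = c("VOG00001", "VOG00002", "VOG00003", "VOG00004")), lca)
  expect_equal(four$family, "Siphoviridae")
  expect_equal(four$method, "vote")
  # 2:2 split -> family NA but shared order survives
  split2 <- assign_viral_taxonomy(
    data.frame(virus_id = "v3", protein_id = sprintf("p%d", 1:4),
               vog = c("VOG00001", "VOG00002", "VOG00004", "VOG00005")), lca)
  expect_equal(split2$order, "Caudovirales")
  expect_true(is.na(split2$family))
  # single protein with a reference lineage: transferred
  ref <- data.frame(virus_id = "v1", order = "Caudovirales",
                    family = "Podoviridae")
  fb <- assign_viral_taxonomy(
    data.frame(virus_id = "v1", protein_id = "p1", vog = "VOG00001"), lca,
    reference = ref)
  expect_equal(fb$family, "Podoviridae")
  expect_equal(fb$method, "reference")
})

test_that("crAss-like annotation needs a passing hit to a reference protein", {
  hits <- data.frame(virus_id = c("v1", "v2", "v3", "v4"),
                     subject_id = c("YP_009052554.1", "other_protein",
                                    "YP_009052497.1", "YP_009052554.1"),
                     evalue = c(1e-50, 1e-60, 1e-6, 1e-3),
                     pct_identity = c(45, 80, 31, 60),
                     query_coverage = c(90, 95, 55, 80))
  out <- annotate_crass_like(hits)
  # v1 strong TerL hit; v2 hits a non-reference; v3 passes all defaults;
  # v4 fails the e-value cutoff
  expect_equal(out$crass_like[match(c("v1", "v2", "v3", "v4"),
                                    out$virus_id)],
               c(TRUE, FALSE, TRUE, FALSE))
  expect_false(annotate_crass_like(hits[0, ], virus_ids = "vx")$crass_like)
})
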