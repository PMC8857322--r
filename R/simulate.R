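# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic binning study
#'
#' Bundles every parameter of the synthetic-study generator: community
#' layout, class-conditional annotation distributions, corruption rates
#' and the master seed. The defaults describe the study conditions used
#' throughout the package's benchmarks: a small multi-sample cohort whose
#' bins separate into viral and bacterial classes the way annotated
#' binning output does, with viral genomes short (5-200 kbp), bacterial
#' genomes long (1-5 Mbp), and all contigs at least `min_contig_length`.
#'
#' @param n_samples Number of samples in the cohort.
#' @param n_viral_clusters,n_bacterial_clusters Number of viral and
#'   bacterial clusters (populations); each cluster yields one
#'   sample-specific bin per sample it is present in.
#' @param prevalence Probability a cluster is present in a given sample
#'   (each cluster is forced into at least one sample).
#' @param viral_contigs_lambda,bacterial_contigs_lambda Poisson means for
#'   the number of contigs per bin beyond the first.
#' @param viral_genome_range,bacterial_genome_range Source-genome length
#'   ranges in bp.
#' @param min_contig_length Minimum contig length in bp (assembly
#'   length filter).
#' @param viral_score_beta,bacterial_score_beta Beta shape pairs for the
#'   class-conditional per-contig viral prediction score.
#' @param hallmark_rate_viral,hallmark_rate_bacterial Poisson means for
#'   bacterial-hallmark HMM hits per contig, by class.
#' @param vog_rate_viral,vog_rate_bacterial Poisson means for viral
#'   orthologous group (VOG) hits per contig, by class.
#' @param score_missing_rate Fraction of contigs without a viral score
#'   (the predictor skips short or ambiguous contigs in practice).
#' @param misbinning_rate Probability that a contig is reassigned to a
#'   random foreign bin (exercises purity logic).
#' @param concatemer_fraction Fraction of viral bins given an inflated
#'   genome copy number (>= 1.25).
#' @param overcomplete_fraction Fraction of viral bins given an estimated
#'   completeness > 120%.
#' @param tier_fractions Named numeric vector summing to 1 over
#'   `Complete`, `HQ`, `MQ`, `LQ`: target mixture of quality tiers among
#'   ordinary viral bins.
#' @param spacer_noise,prophage_noise Probability that a CRISPR-spacer /
#'   prophage evidence record points to a wrong (non-host) MAG.
#' @param spacer_decoy_rate Fraction of additional spacer hits generated
#'   to fail the spacer filter (3 mismatches, low identity).
#' @param temperate_fraction Fraction of viral clusters that are
#'   temperate (integrated in a MAG and/or carrying an integrase).
#' @param label_noise Fraction of truly viral contigs lacking a
#'   gold-standard alignment (degrades truth labelling when > 0).
#' @param seed Master seed; together with the other fields it fully
#'   determines every generated table.
#' @return An object of class `fixture_spec` (a validated list).
#' @export
fixture_spec <- function(n_samples = 6,
                         n_viral_clusters = 60,
                         n_bacterial_clusters = 40,
                         prevalence = 0.9,
                         viral_contigs_lambda = 1.5,
                         bacterial_contigs_lambda = 12,
                         viral_genome_range = c(5e3, 2e5),
                         bacterial_genome_range = c(1e6, 5e6),
                         min_contig_length = 2000,
                         viral_score_beta = c(8, 2),
                         bacterial_score_beta = c(2, 8),
                         hallmark_rate_viral = 0.02,
                         hallmark_rate_bacterial = 1.2,
                         vog_rate_viral = 1.5,
                         vog_rate_bacterial = 0.05,
                         score_missing_rate = 0.05,
                         misbinning_rate = 0,
                         concatemer_fraction = 0.05,
                         overcomplete_fraction = 0.02,
                         tier_fractions = c(Complete = 0.05, HQ = 0.25,
                                            MQ = 0.30, LQ = 0.40),
                         spacer_noise = 0,
                         prophage_noise = 0,
                         spacer_decoy_rate = 0.2,
                         temperate_fraction = 0.3,
                         label_noise = 0,
                         seed = 1L) {
  spec <- as.list(environment())
  counts <- c(n_samples, n_viral_clusters, n_bacterial_clusters)
  if (any(counts < 1)) stop("sample and cluster counts must be >= 1")
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must lie in (0, 1]")
  rates <- c(viral_contigs_lambda, bacterial_contigs_lambda,
             hallmark_rate_viral, hallmark_rate_bacterial,
             vog_rate_viral, vog_rate_bacterial)
  if (any(rates < 0)) stop("rates must be >= 0")
  probs <- c(score_missing_rate, misbinning_rate, concatemer_fraction,
             overcomplete_fraction, spacer_noise, prophage_noise,
             spacer_decoy_rate, temperate_fraction, label_noise)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (viral_genome_range[1] < min_contig_length) {
    stop("viral genomes must be at least as long as the minimum contig length")
  }
  if (!setequal(names(tier_fractions), c("Complete", "HQ", "MQ", "LQ")) ||
      abs(sum(tier_fractions) - 1) > 1e-8) {
    stop("tier_fractions must be named Complete/HQ/MQ/LQ and sum to 1")
  }
  spec$tier_fractions <- tier_fractions[c("Complete", "HQ", "MQ", "LQ")]
  spec$seed <- as.integer(seed)
  structure(spec, class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("Synthetic study specification\n")
  cat(sprintf("  samples: %d; clusters: %d viral + %d bacterial; seed %d\n",
              x$n_samples, x$n_viral_clusters, x$n_bacterial_clusters, x$seed))
  cat(sprintf("  misbinning %.3g, concatemers %.3g, spacer noise %.3g\n",
              x$misbinning_rate, x$concatemer_fraction, x$spacer_noise))
  invisible(x)
}

.bin_id <- function(sample_id, cluster_id) paste(sample_id, cluster_id, sep = "_")

#' Generate a synthetic binned community
#'
#' Draws viral and bacterial source genomes, fragments them into contigs
#' of at least `spec$min_contig_length` bp, distributes clusters across
#' samples, and (optionally) corrupts bins by moving contigs into foreign
#' bins at `spec$misbinning_rate`. Output is fully determined by the spec
#' (including its seed).
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{contigs}{data.frame: `contig_id`, `sample_id`, `cluster_id`,
#'       `bin_id`, `length`, `source_genome`, `start`, `end` (1-based
#'       closed on the source genome), `source_class`, `foreign` (placed
#'       in a bin of a different cluster).}
#'     \item{clusters}{cluster-assignment data.frame (as
#'       [read_cluster_table()] returns).}
#'     \item{bins}{data.frame: `bin_id`, `cluster_id`, `sample_id`,
#'       `label` (ground-truth class of the bin's cluster).}
#'     \item{genomes}{data.frame: `genome_id`, `cluster_id`, `class`,
#'       `length`, `gc`.}
#'   }
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n_clu <- spec$n_viral_clusters + spec$n_bacterial_clusters
    class <- c(rep("viral", spec$n_viral_clusters),
               rep("bacterial", spec$n_bacterial_clusters))
    class <- sample(class)   # interleave classes across cluster ids
    cluster_id <- sprintf("cluster_%03d", seq_len(n_clu))
    glen <- ifelse(class == "viral",
                   round(stats::runif(n_clu, spec$viral_genome_range[1],
                                      spec$viral_genome_range[2])),
                   round(stats::runif(n_clu, spec$bacterial_genome_range[1],
                                      spec$bacterial_genome_range[2])))
    genome_id <- ifelse(class == "viral",
                        sprintf("VGENOME_%03d", seq_len(n_clu)),
                        sprintf("BGENOME_%03d", seq_len(n_clu)))
    genomes <- data.frame(genome_id = genome_id, cluster_id = cluster_id,
                          class = class, length = glen,
                          gc = stats::runif(n_clu, 0.3, 0.6),
                          stringsAsFactors = FALSE)

    # presence of each cluster in each sample
    pres <- matrix(stats::runif(n_clu * spec$n_samples) < spec$prevalence,
                   nrow = n_clu)
    none <- rowSums(pres) == 0L
    pres[cbind(which(none), sample.int(spec$n_samples, sum(none), replace = TRUE))] <- TRUE

    rows <- vector("list", n_clu * spec$n_samples)
    k <- 0L
    counter <- integer(spec$n_samples)
    for (s in seq_len(spec$n_samples)) {
      sample_id <- sprintf("S%d", s)
      for (i in seq_len(n_clu)) {
        if (!pres[i, s]) next
        lambda <- if (class[i] == "viral") spec$viral_contigs_lambda
                  else spec$bacterial_contigs_lambda
        n_ctg <- 1L + stats::rpois(1L, lambda)
        mx <- max(spec$min_contig_length,
                  min(glen[i], if (class[i] == "viral") glen[i] else 2e5))
        lens <- round(stats::runif(n_ctg, spec$min_contig_length, mx))
        # keep contigs inside the genome; viral bins cannot exceed genome length
        if (class[i] == "viral" && sum(lens) > glen[i]) {
          lens <- pmax(spec$min_contig_length,
                       floor(lens * glen[i] / sum(lens)))
          if (sum(lens) > glen[i]) lens <- lens[cumsum(lens) <= glen[i]]
          if (length(lens) == 0L) lens <- glen[i]
        }
        start <- vapply(lens, function(l) {
          sample.int(glen[i] - l + 1L, 1L)
        }, integer(1))
        idx <- counter[s] + seq_along(lens)
        counter[s] <- counter[s] + length(lens)
        k <- k + 1L
        rows[[k]] <- data.frame(
          contig_id = sprintf("S%dC%d", s, idx),
          sample_id = sample_id, cluster_id = cluster_id[i],
          bin_id = .bin_id(sample_id, cluster_id[i]),
          length = as.integer(lens), source_genome = genome_id[i],
          start = as.integer(start), end = as.integer(start + lens - 1L),
          source_class = class[i], stringsAsFactors = FALSE)
      }
    }
    contigs <- do.call(rbind, rows[seq_len(k)])

    contigs$foreign <- FALSE
    if (spec$misbinning_rate > 0) {
      move <- stats::runif(nrow(contigs)) < spec$misbinning_rate
      if (any(move)) {
        all_bins <- unique(contigs[c("bin_id", "cluster_id", "sample_id")])
        for (j in which(move)) {
          other <- all_bins[all_bins$bin_id != contigs$bin_id[j], , drop = FALSE]
          pick <- other[sample.int(nrow(other), 1L), ]
          contigs$bin_id[j] <- pick$bin_id
          contigs$cluster_id[j] <- pick$cluster_id
          contigs$foreign[j] <- TRUE
        }
      }
    }

    bins <- unique(contigs[c("bin_id", "cluster_id", "sample_id")])
    bins$label <- genomes$class[match(bins$cluster_id, genomes$cluster_id)]
    rownames(bins) <- NULL
    clusters <- data.frame(cluster_id = contigs$cluster_id,
                           contig_id = contigs$contig_id,
                           sample_id = contigs$sample_id,
                           stringsAsFactors = FALSE)
    list(contigs = contigs, clusters = clusters, bins = bins, genomes = genomes)
  })
}

#' Generate contig sequences for a synthetic community
#'
#' Sequences are i.i.d. draws over A/C/G/T with the per-genome GC bias
#' recorded in the community; no k-mer structure is attempted, since the
#' downstream classifier consumes annotation tables rather than sequence.
#'
#' @param community Result of [generate_community()].
#' @param spec The [fixture_spec()] that produced it.
#' @return A [Biostrings::DNAStringSet] named by contig id.
#' @export
generate_sequences <- function(community, spec) {
  with_seed(spec$seed + 7L, {
    gc <- community$genomes$gc[match(community$contigs$source_genome,
                                     community$genomes$genome_id)]
    seqs <- vapply(seq_len(nrow(community$contigs)), function(i) {
      p <- c(A = (1 - gc[i]) / 2, C = gc[i] / 2, G = gc[i] / 2,
             T = (1 - gc[i]) / 2)
      paste(sample(names(p), community$contigs$length[i],
                   replace = TRUE, prob = p), collapse = "")
    }, character(1))
    names(seqs) <- community$contigs$contig_id
    Biostrings::DNAStringSet(seqs)
  })
}

#' Generate per-contig and per-bin annotation tables
#'
#' Emulates the tabular outputs the classifier consumes: per-contig viral
#' prediction scores (class-conditional Beta draws), VOG and
#' bacterial-hallmark HMM hits (class-conditional Poisson counts, with a
#' sub-threshold decoy fraction below bitscore 30), a CheckV-style
#' quality summary (viral bins placed in MIUViG tiers per
#' `spec$tier_fractions`, with configurable concatemer and overcomplete
#' fractions), a CheckM-style table (bacterial bins complete, viral bins
#' nearly empty), gold-standard alignment hits for truth labelling, and
#' per-contig read counts plus breadth of coverage per sample.
#'
#' @param community Result of [generate_community()].
#' @param spec The [fixture_spec()] that produced it.
#' @return A list: `scores`, `hmm` (VOG + hallmark hits), `quality`,
#'   `checkm`, `gold_hits`, `counts` (contig x sample), `breadth`
#'   (contig x sample), and `truth` (bookkeeping: `n_concatemer`,
#'   `n_overcomplete`, `tier` per viral bin, `total_score_length`).
#' @export
generate_annotations <- function(community, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ctg <- community$contigs
  bins <- community$bins
  with_seed(spec$seed + 1L, {
    viral <- ctg$source_class == "viral"

    ## per-contig scores (some contigs unscored)
    scored <- stats::runif(nrow(ctg)) >= spec$score_missing_rate
    sc <- numeric(nrow(ctg))
    sc[viral] <- stats::rbeta(sum(viral), spec$viral_score_beta[1],
                              spec$viral_score_beta[2])
    sc[!viral] <- stats::rbeta(sum(!viral), spec$bacterial_score_beta[1],
                               spec$bacterial_score_beta[2])
    scores <- data.frame(contig_id = ctg$contig_id[scored],
                         length = ctg$length[scored],
                         score = sc[scored],
                         pvalue = stats::runif(sum(scored)),
                         tool = "dvf", stringsAsFactors = FALSE)

    ## HMM hits
    vog_pool <- sprintf("VOG%05d", seq_len(300))
    hall_pool <- sprintf("Hallmark_%03d", seq_len(105))
    draw_hits <- function(ids, n_hits, pool, database) {
      n <- rep(seq_along(ids), n_hits)
      if (length(n) == 0L) {
        return(data.frame(contig_id = character(), hmm_name = character(),
                          evalue = numeric(), bitscore = numeric(),
                          database = character(), stringsAsFactors = FALSE))
      }
      data.frame(contig_id = ids[n],
                 hmm_name = sample(pool, length(n), replace = TRUE),
                 evalue = 10^stats::runif(length(n), -30, -5),
                 bitscore = stats::runif(length(n), 35, 250),
                 database = database, stringsAsFactors = FALSE)
    }
    n_vog <- stats::rpois(nrow(ctg), ifelse(viral, spec$vog_rate_viral,
                                            spec$vog_rate_bacterial))
    n_hall <- stats::rpois(nrow(ctg), ifelse(viral, spec$hallmark_rate_viral,
                                             spec$hallmark_rate_bacterial))
    hmm <- rbind(draw_hits(ctg$contig_id, n_vog, vog_pool, "vog"),
                 draw_hits(ctg$contig_id, n_hall, hall_pool, "bacterial_hallmark"))
    ## decoy hits below the bitscore-30 working threshold
    n_decoy <- max(1L, round(0.1 * nrow(hmm)))
    decoy <- data.frame(contig_id = sample(ctg$contig_id, n_decoy, replace = TRUE),
                        hmm_name = sample(c(vog_pool, hall_pool), n_decoy,
                                          replace = TRUE),
                        evalue = 10^stats::runif(n_decoy, -4, 0),
                        bitscore = stats::runif(n_decoy, 5, 29.9),
                        database = sample(c("vog", "bacterial_hallmark"),
                                          n_decoy, replace = TRUE),
                        stringsAsFactors = FALSE)
    hmm <- rbind(hmm, decoy)

    ## quality summary, per bin
    is_viral_bin <- bins$label == "viral"
    nvb <- sum(is_viral_bin)
    tier <- character(nrow(bins))
    tier[!is_viral_bin] <- "LQ"
    tier[is_viral_bin] <- sample(names(spec$tier_fractions), nvb,
                                 replace = TRUE, prob = spec$tier_fractions)
    comp <- numeric(nrow(bins))
    comp[tier == "Complete"] <- 100
    comp[tier == "HQ"] <- stats::runif(sum(tier == "HQ"), 90, 110)
    comp[tier == "MQ"] <- stats::runif(sum(tier == "MQ"), 50, 89.9)
    comp[tier == "LQ"] <- stats::runif(sum(tier == "LQ"), 1, 49.9)
    closed <- tier == "Complete"
    copy_number <- 1 + abs(stats::rnorm(nrow(bins), 0, 0.04))
    concat <- is_viral_bin & stats::runif(nrow(bins)) < spec$concatemer_fraction
    copy_number[concat] <- stats::runif(sum(concat), 1.25, 2.5)
    overc <- is_viral_bin & !concat &
      stats::runif(nrow(bins)) < spec$overcomplete_fraction
    comp[overc] <- stats::runif(sum(overc), 120.05, 160)
    quality <- data.frame(bin_id = bins$bin_id, completeness = comp,
                          copy_number = copy_number, closed = closed,
                          terminal_repeat = ifelse(closed, "DTR", "None"),
                          stringsAsFactors = FALSE)

    ## CheckM-style table (bacterial completeness/contamination)
    checkm <- data.frame(
      bin_id = bins$bin_id,
      completeness = ifelse(is_viral_bin,
                            stats::runif(nrow(bins), 0, 5),
                            stats::runif(nrow(bins), 50, 100)),
      contamination = ifelse(is_viral_bin, 0,
                             stats::runif(nrow(bins), 0, 15)),
      stringsAsFactors = FALSE)

    ## gold-standard alignments: viral contigs match the reference set
    gold <- viral & stats::runif(nrow(ctg)) >= spec$label_noise
    gold_hits <- data.frame(
      query_id = ctg$contig_id[gold],
      subject_id = ctg$source_genome[gold],
      pct_identity = stats::runif(sum(gold), 96, 100),
      query_coverage = stats::runif(sum(gold), 60, 100),
      stringsAsFactors = FALSE)
    ## spurious weak hits from bacterial contigs (fail the 95/50 filter)
    spur <- which(!viral & stats::runif(nrow(ctg)) < 0.05)
    if (length(spur)) {
      gold_hits <- rbind(gold_hits, data.frame(
        query_id = ctg$contig_id[spur],
        subject_id = sample(community$genomes$genome_id[community$genomes$class == "viral"],
                            length(spur), replace = TRUE),
        pct_identity = stats::runif(length(spur), 80, 94.5),
        query_coverage = stats::runif(length(spur), 10, 100),
        stringsAsFactors = FALSE))
    }

    ## read counts and breadth per sample
    n_s <- spec$n_samples
    sample_ids <- sprintf("S%d", seq_len(n_s))
    base <- matrix(stats::rlnorm(nrow(community$genomes) * n_s, 2, 1),
                   ncol = n_s, dimnames = list(community$genomes$cluster_id,
                                               sample_ids))
    counts <- matrix(0, nrow(ctg), n_s,
                     dimnames = list(ctg$contig_id, sample_ids))
    breadth <- matrix(0, nrow(ctg), n_s,
                      dimnames = list(ctg$contig_id, sample_ids))
    home <- match(ctg$cluster_id, community$genomes$cluster_id)
    for (s in seq_len(n_s)) {
      present <- ctg$sample_id == sample_ids[s]
      lam <- base[cbind(home, s)] * ctg$length / 1e3
      counts[present, s] <- stats::rpois(sum(present), lam[present])
      ## shared clusters are detected across samples at lower depth
      cross <- !present & stats::runif(nrow(ctg)) < 0.3
      counts[cross, s] <- stats::rpois(sum(cross), 0.3 * lam[cross])
      got <- counts[, s] > 0
      breadth[got, s] <- stats::runif(sum(got), 0.55, 1)
    }

    list(scores = scores, hmm = hmm, quality = quality, checkm = checkm,
         gold_hits = gold_hits, counts = counts, breadth = breadth,
         truth = list(n_concatemer = sum(concat), n_overcomplete = sum(overc),
                      tier = stats::setNames(tier, bins$bin_id),
                      total_score_length = sum(scores$length)))
  })
}

.lineage_ranks <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

.host_lineages <- function() {
  g <- data.frame(
    genus  = c("Bacteroides", "Prevotella", "Alistipes", "Faecalibacterium",
               "Roseburia", "Blautia", "Bifidobacterium", "Escherichia",
               "Akkermansia", "Ruminococcus", "Streptococcus", "Veillonella"),
    family = c("Bacteroidaceae", "Prevotellaceae", "Rikenellaceae",
               "Ruminococcaceae", "Lachnospiraceae", "Lachnospiraceae",
               "Bifidobacteriaceae", "Enterobacteriaceae", "Akkermansiaceae",
               "Ruminococcaceae", "Streptococcaceae", "Veillonellaceae"),
    order  = c("Bacteroidales", "Bacteroidales", "Bacteroidales",
               "Eubacteriales", "Eubacteriales", "Eubacteriales",
               "Bifidobacteriales", "Enterobacterales", "Verrucomicrobiales",
               "Eubacteriales", "Lactobacillales", "Veillonellales"),
    class  = c("Bacteroidia", "Bacteroidia", "Bacteroidia", "Clostridia",
               "Clostridia", "Clostridia", "Actinomycetia",
               "Gammaproteobacteria", "Verrucomicrobiae", "Clostridia",
               "Bacilli", "Negativicutes"),
    phylum = c("Bacteroidota", "Bacteroidota", "Bacteroidota", "Bacillota",
               "Bacillota", "Bacillota", "Actinomycetota", "Pseudomonadota",
               "Verrucomicrobiota", "Bacillota", "Bacillota", "Bacillota"),
    stringsAsFactors = FALSE)
  g$domain <- "Bacteria"
  g$species <- paste(g$genus, "intestinalis")
  g[.lineage_ranks]
}

#' Generate synthetic host-interaction evidence
#'
#' Assigns every bacterial cluster a taxonomic lineage (its MAGs inherit
#' it) and every viral cluster a true host among them, then generates
#' CRISPR-spacer alignment hits and prophage ANI records pointing at the
#' true host's MAGs with probability `1 - noise` and at a random wrong
#' MAG otherwise. Decoy spacer hits that must fail the spacer filter
#' (3 mismatches) are added at `spec$spacer_decoy_rate`. Temperate viral
#' clusters additionally get a high-coverage integration alignment and an
#' integrase protein annotation.
#'
#' @param community Result of [generate_community()].
#' @param spec The [fixture_spec()] that produced it.
#' @return A list: `spacer_hits` (blastn-short-style with `mismatches`),
#'   `spacer_lengths` (named vector), `prophage_ani` (FastANI-style),
#'   `mag_taxonomy` (MAG bin lineage table), `integration` (virus-vs-MAG
#'   alignments with `query_coverage` and `ani`), `annotations` (protein
#'   descriptions), and `truth` (`host` per viral cluster, `temperate`
#'   per viral cluster).
#' @export
generate_host_evidence <- function(community, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 2L, {
    genomes <- community$genomes
    bins <- community$bins
    bac_cl <- genomes$cluster_id[genomes$class == "bacterial"]
    vir_cl <- genomes$cluster_id[genomes$class == "viral"]
    lin <- .host_lineages()
    cl_lin <- lin[sample.int(nrow(lin), length(bac_cl), replace = TRUE), ,
                  drop = FALSE]
    rownames(cl_lin) <- bac_cl
    mags <- bins[bins$label == "bacterial", , drop = FALSE]
    mag_taxonomy <- cbind(data.frame(mag_id = mags$bin_id,
                                     stringsAsFactors = FALSE),
                          cl_lin[mags$cluster_id, , drop = FALSE])
    rownames(mag_taxonomy) <- NULL

    true_host <- stats::setNames(sample(bac_cl, length(vir_cl), replace = TRUE),
                                 vir_cl)
    vbins <- bins[bins$label == "viral", , drop = FALSE]

    pick_mag <- function(host_cl, wrong) {
      pool <- if (wrong) mags$bin_id[mags$cluster_id != host_cl]
              else mags$bin_id[mags$cluster_id == host_cl]
      if (length(pool) == 0L) pool <- mags$bin_id
      pool[sample.int(length(pool), 1L)]
    }

    ## spacer evidence: >= 1 hit per viral bin
    sp_rows <- lapply(seq_len(nrow(vbins)), function(i) {
      host <- true_host[[vbins$cluster_id[i]]]
      k <- 1L + stats::rpois(1L, 1)
      wrong <- stats::runif(k) < spec$spacer_noise
      mag <- vapply(wrong, function(w) pick_mag(host, w), character(1))
      sp_len <- sample(28:36, k, replace = TRUE)
      mm <- sample(0:1, k, replace = TRUE, prob = c(0.8, 0.2))
      aln <- sp_len - sample(0:1, k, replace = TRUE)
      data.frame(query_id = sprintf("%s_sp%d", mag, seq_len(k)),
                 subject_id = vbins$bin_id[i],
                 mag_id = mag,
                 pct_identity = 100 * (1 - mm / aln),
                 aln_length = aln, mismatches = mm,
                 spacer_length = sp_len, stringsAsFactors = FALSE)
    })
    spacer_hits <- do.call(rbind, sp_rows)
    n_decoy <- round(spec$spacer_decoy_rate * nrow(spacer_hits))
    if (n_decoy > 0) {
      i <- sample.int(nrow(vbins), n_decoy, replace = TRUE)
      mag <- mags$bin_id[sample.int(nrow(mags), n_decoy, replace = TRUE)]
      sp_len <- sample(28:36, n_decoy, replace = TRUE)
      decoy <- data.frame(query_id = sprintf("%s_spX%d", mag, seq_len(n_decoy)),
                          subject_id = vbins$bin_id[i], mag_id = mag,
                          pct_identity = stats::runif(n_decoy, 85, 94.9),
                          aln_length = sp_len - 2L, mismatches = 3L,
                          spacer_length = sp_len, stringsAsFactors = FALSE)
      spacer_hits <- rbind(spacer_hits, decoy)
    }
    spacer_lengths <- stats::setNames(spacer_hits$spacer_length,
                                      spacer_hits$query_id)

    ## prophage (alignment) evidence
    pr_rows <- lapply(seq_len(nrow(vbins)), function(i) {
      host <- true_host[[vbins$cluster_id[i]]]
      wrong <- stats::runif(1) < spec$prophage_noise
      mag <- pick_mag(host, wrong)
      data.frame(query_genome = vbins$bin_id[i], ref_genome = mag,
                 ani = stats::runif(1, 92, 99.5),
                 bidir_fragments = sample(2:10, 1L),
                 total_fragments = sample(10:20, 1L),
                 stringsAsFactors = FALSE)
    })
    prophage_ani <- do.call(rbind, pr_rows)
    ## sub-threshold records that the >=90 ANI filter must drop
    n_lo <- max(1L, round(0.15 * nrow(prophage_ani)))
    lo <- prophage_ani[sample.int(nrow(prophage_ani), n_lo, replace = TRUE), ]
    lo$ani <- stats::runif(n_lo, 80, 89.9)
    lo$ref_genome <- mags$bin_id[sample.int(nrow(mags), n_lo, replace = TRUE)]
    prophage_ani <- rbind(prophage_ani, lo)

    ## temperate truth and integration evidence
    temperate <- stats::setNames(stats::runif(length(vir_cl)) <
                                   spec$temperate_fraction, vir_cl)
    integ <- data.frame(virus_id = vbins$bin_id,
                        mag_id = vapply(vbins$cluster_id, function(cl)
                          pick_mag(true_host[[cl]], FALSE), character(1)),
                        query_coverage = ifelse(temperate[vbins$cluster_id],
                                                stats::runif(nrow(vbins), 85, 100),
                                                stats::runif(nrow(vbins), 5, 60)),
                        ani = ifelse(temperate[vbins$cluster_id],
                                     stats::runif(nrow(vbins), 92, 99.5),
                                     stats::runif(nrow(vbins), 91, 99)),
                        stringsAsFactors = FALSE)
    ann_rows <- vbins[temperate[vbins$cluster_id], , drop = FALSE]
    annotations <- data.frame(
      virus_id = ann_rows$bin_id,
      protein_id = sprintf("%s_p1", ann_rows$bin_id),
      description = "Phage integrase family protein",
      stringsAsFactors = FALSE)

    list(spacer_hits = spacer_hits, spacer_lengths = spacer_lengths,
         prophage_ani = prophage_ani, mag_taxonomy = mag_taxonomy,
         integration = integ, annotations = annotations,
         truth = list(host = cl_lin[true_host, , drop = FALSE],
                      host_cluster = true_host, temperate = temperate))
  })
}

#' Generate and write a complete synthetic study to disk
#'
#' Runs [generate_community()], [generate_annotations()] and
#' [generate_host_evidence()] and writes every table through the
#' package's writers, plus contig FASTA, a ground-truth TSV and the spec
#' as a tab-separated config file, so that a full analysis can be driven
#' from files alone.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param sequences Write contig FASTA as well (slower). Default FALSE.
#' @return Invisibly, a named character vector of the files written.
#' @export
simulate_study <- function(spec, dir, sequences = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comm <- generate_community(spec)
  ann <- generate_annotations(comm, spec)
  host <- generate_host_evidence(comm, spec)
  p <- function(f) file.path(dir, f)

  write_cluster_table(comm$clusters, p("clusters.tsv"))
  write_contig_scores(ann$scores, p("dvf_scores.tsv"))
  write_hmm_tblout(ann$hmm[ann$hmm$database == "vog", ], p("vog.tblout"))
  write_hmm_tblout(ann$hmm[ann$hmm$database == "bacterial_hallmark", ],
                   p("hallmark.tblout"))
  write_quality_summary(ann$quality, p("quality_summary.tsv"))
  utils::write.table(ann$checkm, p("checkm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann$gold_hits, p("gold_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_depth_table(rownames(ann$counts),
                    comm$contigs$length[match(rownames(ann$counts),
                                              comm$contigs$contig_id)],
                    ann$counts, p("read_counts.tsv"))
  write_depth_table(rownames(ann$breadth),
                    comm$contigs$length[match(rownames(ann$breadth),
                                              comm$contigs$contig_id)],
                    ann$breadth, p("breadth.tsv"))
  utils::write.table(host$spacer_hits, p("spacer_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fastani(host$prophage_ani, p("prophage_ani.tsv"))
  utils::write.table(host$mag_taxonomy, p("mag_taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comm$contigs, p("ground_truth_contigs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comm$bins, p("ground_truth_bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- data.frame(key = names(unclass(spec)),
                    value = vapply(unclass(spec), function(v)
                      paste(v, collapse = ","), character(1)))
  utils::write.table(cfg, p("fixture_spec.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sequences) {
    Biostrings::writeXStringSet(generate_sequences(comm, spec),
                                p("contigs.fasta"))
  }
  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}
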