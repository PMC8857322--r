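#' Filter CRISPR-spacer alignment hits
#'
#' A spacer-vs-virus hit is retained as host evidence when the percent
#' identity is at least 95, the alignment covers at least 95% of the
#' spacer length, and there are at most two mismatches. Hits whose
#' spacer length is unknown are skipped with a warning.
#'
#' @param hits data.frame with `query_id` (spacer), `subject_id`
#'   (virus), `mag_id` (the MAG carrying the spacer), `pct_identity`,
#'   `aln_length`, `mismatches`.
#' @param spacer_lengths Named numeric vector: spacer id -> length (bp).
#'   May be omitted if `hits` has a `spacer_length` column.
#' @param min_identity,min_length_fraction,max_mismatches Rule bounds
#'   (defaults 95, 0.95, 2; identity and length inclusive, mismatches
#'   at most 2).
#' @return The retained rows with `kind = "spacer"`.
#' @export
filter_spacer_hits <- function(hits, spacer_lengths = NULL,
                               min_identity = 95, min_length_fraction = 0.95,
                               max_mismatches = 2) {
  if (is.null(spacer_lengths)) {
    if (!"spacer_length" %in% names(hits)) {
      stop("provide spacer_lengths or a spacer_length column")
    }
    sl <- hits$spacer_length
  } else {
    sl <- unname(spacer_lengths[hits$query_id])
  }
  unknown <- is.na(sl)
  if (any(unknown)) {
    warning(sprintf("%d hit(s) with unknown spacer length skipped",
                    sum(unknown)))
  }
  keep <- !unknown &
    hits$pct_identity >= min_identity &
    hits$aln_length >= min_length_fraction * sl &
    hits$mismatches <= max_mismatches
  out <- hits[keep, , drop = FALSE]
  out$kind <- if (nrow(out)) "spacer" else character(0)
  rownames(out) <- NULL
  out
}

#' Filter prophage-style virus-vs-MAG evidence
#'
#' Two alignment routes connect a virus to a MAG it may be integrated
#' in: genome-level ANI records are kept at ANI >= 90 (computed over at
#' least one 5 kbp fragment), and nucleotide alignment hits are kept at
#' percent identity >= 90. Both bounds are inclusive.
#'
#' @param ani_records data.frame with `query_genome` (virus),
#'   `ref_genome` (MAG), `ani`; or NULL.
#' @param blast_hits data.frame with `query_id` (virus), `subject_id`
#'   (MAG), `pct_identity`; or NULL.
#' @param min_ani,min_identity Inclusive bounds (defaults 90, 90).
#' @return data.frame of (virus_id, mag_id) evidence with `kind` set to
#'   `"prophage_ani"`, `"prophage_blast"`, or `"both"` when a pair
#'   passes both routes.
#' @export
filter_prophage_hits <- function(ani_records = NULL, blast_hits = NULL,
                                 min_ani = 90, min_identity = 90) {
  ev <- list()
  if (!is.null(ani_records) && nrow(ani_records)) {
    keep <- ani_records$ani >= min_ani
    ev$ani <- data.frame(virus_id = ani_records$query_genome[keep],
                         mag_id = ani_records$ref_genome[keep],
                         kind = rep("prophage_ani", sum(keep)),
                         stringsAsFactors = FALSE)
  }
  if (!is.null(blast_hits) && nrow(blast_hits)) {
    keep <- blast_hits$pct_identity >= min_identity
    ev$blast <- data.frame(virus_id = blast_hits$query_id[keep],
                           mag_id = blast_hits$subject_id[keep],
                           kind = rep("prophage_blast", sum(keep)),
                           stringsAsFactors = FALSE)
  }
  if (length(ev) == 0L) {
    return(data.frame(virus_id = character(), mag_id = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, ev))
  key <- paste(out$virus_id, out$mag_id, sep = "\r")
  both <- key %in% key[out$kind == "prophage_ani"] &
    key %in% key[out$kind == "prophage_blast"]
  out$kind[both] <- "both"
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Plurality host call per virus
#'
#' Each MAG supporting a virus casts one vote per taxonomic rank
#' (domain down to species). At each rank the most frequent taxon is
#' assigned when it is the unique maximum and holds at least 50% of the
#' votes; otherwise the rank is NA (an exact two-way 50/50 split is
#' NA). Ranks are evaluated top-down and the lineage is truncated at
#' the first NA, so calls stay internally consistent.
#'
#' @param evidence data.frame with `virus_id`, `mag_id` (one vote per
#'   distinct supporting MAG).
#' @param mag_taxonomy data.frame with `mag_id` and the rank columns
#'   `domain`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species`.
#' @param min_share Minimum vote share (default 0.5, inclusive).
#' @return data.frame: `virus_id`, `n_mags`, and one column per rank
#'   (NA where no plurality). Viruses with no evidence are absent.
#' @export
plurality_host <- function(evidence, mag_taxonomy, min_share = 0.5) {
  ev <- unique(evidence[c("virus_id", "mag_id")])
  ranks <- .lineage_ranks
  rows <- lapply(split(ev, ev$virus_id), function(e) {
    lin <- mag_taxonomy[match(e$mag_id, mag_taxonomy$mag_id), ranks,
                        drop = FALSE]
    call <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
    for (r in ranks) {
      votes <- lin[[r]][!is.na(lin[[r]])]
      if (length(votes) == 0L) break
      tab <- sort(table(votes), decreasing = TRUE)
      top_unique <- length(tab) == 1L || tab[1L] > tab[2L]
      if (top_unique && tab[1L] / length(votes) >= min_share) {
        call[r] <- names(tab)[1L]
      } else break   # truncate at first NA
    }
    cbind(data.frame(virus_id = e$virus_id[1L], n_mags = nrow(e),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(call), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Host-prediction purity and cross-method consensus
#'
#' For each viral population and evidence kind, purity at a rank is the
#' fraction of member-bin host calls that agree with the population's
#' most common host taxon at that rank; cohort purity is the mean over
#' populations, in percent. The consensus rate is the percentage of
#' viruses called by both evidence kinds whose taxa agree at the rank.
#'
#' @param calls data.frame with `virus_id`, `cluster_id`, `kind` and
#'   rank columns (as from [plurality_host()] joined to populations and
#'   evidence kinds). Calls with NA at the rank are excluded.
#' @param rank Taxonomic rank to evaluate (default `"species"`).
#' @return List: `per_population` (cluster, kind, n_calls, purity),
#'   `cohort` (kind, purity_pct), `consensus_pct` (NA when no virus has
#'   both kinds).
#' @export
host_prediction_purity <- function(calls, rank = "species") {
  stopifnot(rank %in% names(calls))
  x <- calls[!is.na(calls[[rank]]), , drop = FALSE]
  per <- do.call(rbind, lapply(split(x, x[c("cluster_id", "kind")], drop = TRUE),
    function(g) {
      tab <- sort(table(g[[rank]]), decreasing = TRUE)
      data.frame(cluster_id = g$cluster_id[1L], kind = g$kind[1L],
                 n_calls = nrow(g), top_host = names(tab)[1L],
                 purity = as.numeric(tab[1L]) / nrow(g),
                 stringsAsFactors = FALSE)
    }))
  rownames(per) <- NULL
  cohort <- stats::aggregate(purity ~ kind, data = per,
                             FUN = function(p) 100 * mean(p))
  names(cohort)[2L] <- "purity_pct"
  kinds <- unique(x$kind)
  consensus <- NA_real_
  if (length(kinds) >= 2L) {
    wide <- lapply(kinds[1:2], function(k) {
      g <- x[x$kind == k, c("virus_id", rank)]
      g[!duplicated(g$virus_id), ]
    })
    shared <- intersect(wide[[1L]]$virus_id, wide[[2L]]$virus_id)
    if (length(shared)) {
      t1 <- wide[[1L]][[rank]][match(shared, wide[[1L]]$virus_id)]
      t2 <- wide[[2L]][[rank]][match(shared, wide[[2L]]$virus_id)]
      consensus <- 100 * mean(t1 == t2)
    }
  }
  list(per_population = per, cohort = cohort, consensus_pct = consensus)
}

#' Flag temperate viruses
#'
#' A virus is temperate when it is found integrated into a MAG — an
#' alignment with query coverage >= 80% and ANI >= 90% (both
#' inclusive) — or when any of its protein annotations mentions an
#' integrase (case-insensitive substring match).
#'
#' @param virus_ids Character vector of viruses to flag.
#' @param alignments data.frame with `virus_id`, `query_coverage`,
#'   `ani`; or NULL.
#' @param annotations data.frame with `virus_id`, `description`; or
#'   NULL.
#' @param min_coverage,min_ani Inclusive bounds (defaults 80, 90).
#' @return data.frame: `virus_id`, `temperate` (logical), `evidence`
#'   (`"integration"`, `"integrase"`, both, or `""`).
#' @export
annotate_temperate <- function(virus_ids, alignments = NULL,
                               annotations = NULL, min_coverage = 80,
                               min_ani = 90) {
  integrated <- character(0)
  if (!is.null(alignments) && nrow(alignments)) {
    ok <- alignments$query_coverage >= min_coverage & alignments$ani >= min_ani
    integrated <- unique(alignments$virus_id[ok])
  }
  with_integrase <- character(0)
  if (!is.null(annotations) && nrow(annotations)) {
    hit <- grepl("integrase", annotations$description, ignore.case = TRUE)
    with_integrase <- unique(annotations$virus_id[hit])
  }
  ev <- vapply(virus_ids, function(v) {
    paste(c(if (v %in% integrated) "integration",
            if (v %in% with_integrase) "integrase"), collapse = ",")
  }, character(1))
  data.frame(virus_id = virus_ids, temperate = nzchar(ev), evidence = ev,
             stringsAsFactors = FALSE)
}

#' Assign viral taxonomy by plurality over VOG lineages
#'
#' Rule 1: a virus with at least two VOG-annotated proteins gets, at
#' each rank, the taxon holding at least 50% of the per-protein votes
#' taken from the VOG entries' last-common-ancestor lineages (unique
#' maximum required; ties and sub-majority give NA, and the lineage is
#' truncated at the first NA). Rule 2: otherwise the lineage of the
#' best reference-genome match is transferred when available. Otherwise
#' every rank is NA.
#'
#' @param protein_hits data.frame with `virus_id`, `protein_id`,
#'   `vog` (one VOG per protein; with several, the highest `bitscore`
#'   wins if present, else the first).
#' @param vog_lca data.frame: `vog` plus rank columns (any subset of
#'   domain...species); see
#'   `system.file("extdata", "vog_lca_synthetic.tsv", package =
#'   "viralbins")` for the packaged synthetic lookup.
#' @param reference Optional data.frame with `virus_id` plus rank
#'   columns: best-reference lineages for rule 2.
#' @param min_share Vote share bound (default 0.5, inclusive).
#' @return data.frame: `virus_id`, `n_proteins`, `method`
#'   (`"vote"`, `"reference"`, `"none"`), and the rank columns present
#'   in `vog_lca`.
#' @export
assign_viral_taxonomy <- function(protein_hits, vog_lca, reference = NULL,
                                  min_share = 0.5) {
  ranks <- intersect(.lineage_ranks, names(vog_lca))
  if (length(ranks) == 0L) stop("vog_lca has no taxonomic rank columns")
  na_call <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
  rows <- lapply(split(protein_hits, protein_hits$virus_id), function(h) {
    vid <- h$virus_id[1L]
    if ("bitscore" %in% names(h)) h <- h[order(-h$bitscore), , drop = FALSE]
    h <- h[!duplicated(h$protein_id), , drop = FALSE]
    h <- h[h$vog %in% vog_lca$vog, , drop = FALSE]
    call <- na_call
    method <- "none"
    if (nrow(h) >= 2L) {
      lin <- vog_lca[match(h$vog, vog_lca$vog), ranks, drop = FALSE]
      for (r in ranks) {
        votes <- lin[[r]][!is.na(lin[[r]])]
        if (length(votes) == 0L) break
        tab <- sort(table(votes), decreasing = TRUE)
        top_unique <- length(tab) == 1L || tab[1L] > tab[2L]
        if (top_unique && tab[1L] / nrow(h) >= min_share) {
          call[r] <- names(tab)[1L]
        } else break
      }
      method <- "vote"
    } else if (!is.null(reference) && vid %in% reference$virus_id) {
      i <- match(vid, reference$virus_id)
      for (r in intersect(ranks, names(reference))) {
        call[r] <- reference[[r]][i]
      }
      method <- "reference"
    }
    cbind(data.frame(virus_id = vid, n_proteins = nrow(h),
                     method = method, stringsAsFactors = FALSE),
          as.data.frame(as.list(call), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag crAss-like viruses from protein alignments
#'
#' A virus is crAss-like when any of its proteins aligns to the
#' reference large terminase subunit (TerL) or DNA polymerase of the
#' progenitor crAssphage (accessions YP_009052554.1 and
#' YP_009052497.1) passing the configured cutoffs. Default cutoffs
#' (e-value <= 1e-5, identity >= 30%, query coverage >= 50%) are this
#' package's choice and are configurable.
#'
#' @param hits data.frame with `virus_id`, `subject_id`, `evalue`,
#'   `pct_identity`, `query_coverage`.
#' @param virus_ids Viruses to report (default: those present in
#'   `hits`).
#' @param references Accessions counting as crAss-like anchors.
#' @param max_evalue,min_identity,min_coverage Cutoffs.
#' @return data.frame: `virus_id`, `crass_like` (logical).
#' @export
annotate_crass_like <- function(hits, virus_ids = unique(hits$virus_id),
                                references = c("YP_009052554.1",
                                               "YP_009052497.1"),
                                max_evalue = 1e-5, min_identity = 30,
                                min_coverage = 50) {
  ok <- hits$subject_id %in% references &
    hits$evalue <= max_evalue &
    hits$pct_identity >= min_identity &
    hits$query_coverage >= min_coverage
  pos <- unique(hits$virus_id[ok])
  data.frame(virus_id = virus_ids, crass_like = virus_ids %in% pos,
             stringsAsFactors = FALSE)
}
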