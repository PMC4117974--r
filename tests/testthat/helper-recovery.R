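# Parameter-recovery helpers: compare a pipeline run against a simulation's
# ground truth.

# truth slot state per (locus, species, chromosome copy): E retained member,
# N subfunctionalized, L gene lost but the chromosome copy still carries
# enough genes to be detectable as a block, B otherwise
truth_chrom_states <- function(sim, min_anchors = 5L) {
  surv <- sim$truth[!is.na(sim$truth$gene_id), ]
  gmap <- sim$genes
  rows <- list()
  for (sp in unique(gmap$species)) {
    sp_genes <- gmap$gene_id[gmap$species == sp]
    chroms <- unique(gmap$chromosome[gmap$species == sp])
    cn <- table(gmap$chromosome[gmap$species == sp])
    for (loc in unique(sim$truth$locus)) {
      for (ch in chroms) {
        g <- surv[surv$locus == loc & surv$chromosome == ch &
                    surv$gene_id %in% sp_genes, ]
        st <- if (nrow(g) > 0L) {
          if (any(g$fate == "retained_member")) "E" else "N"
        } else if (cn[[ch]] >= min_anchors) "L" else "B"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          locus = loc, species = sp, chromosome = ch, state = st
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# fraction of truth slots the pipeline's retention matrix reproduces;
# present slots are reduced per chromosome copy, absent copies are matched
# against the L/B fills as multisets
retention_agreement <- function(sim, run, min_anchors = 5L) {
  truth <- truth_chrom_states(sim, min_anchors)
  pl <- generics::tidy(run$retention)
  gene_chrom <- stats::setNames(sim$genes$chromosome, sim$genes$gene_id)
  gene_locus <- stats::setNames(sim$truth$locus, sim$truth$gene_id)
  pl$truth_locus <- gene_locus[pl$gene_id]
  maj <- pl[!is.na(pl$truth_locus), ] |>
    dplyr::count(.data$locus_id, .data$truth_locus) |>
    dplyr::group_by(.data$truth_locus) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  agree <- 0L
  total <- 0L
  lev <- c("E", "N", "L", "B")
  for (loc in unique(truth$locus)) {
    comp <- maj$locus_id[maj$truth_locus == loc]
    for (sp in unique(truth$species)) {
      tt <- truth[truth$locus == loc & truth$species == sp, ]
      prows <- pl[pl$locus_id %in% comp & pl$species == sp, ]
      pres <- prows[!is.na(prows$gene_id), ]
      pres$chrom <- gene_chrom[pres$gene_id]
      pstates <- vapply(tt$chromosome, function(ch) {
        pg <- pres[pres$chrom == ch, ]
        if (nrow(pg) > 0L) {
          if (any(pg$state == "E")) "E" else "N"
        } else NA_character_
      }, character(1))
      miss <- which(is.na(pstates))
      n_l <- sum(prows$state == "L")
      fill <- c(rep("L", min(n_l, length(miss))),
                rep("B", max(0L, length(miss) - n_l)))
      common <- sum(pmin(table(factor(tt$state[miss], levels = lev)),
                         table(factor(fill, levels = lev))))
      hit <- if (length(miss) > 0L) {
        sum(pstates[-miss] == tt$state[-miss])
      } else {
        sum(pstates == tt$state)
      }
      agree <- agree + hit + common
      total <- total + nrow(tt)
    }
  }
  agree / total
}

# fraction of truth-logged within-species duplicate pairs whose mechanism
# (SWGD / TD / OTHER) the pipeline reproduces; uncalled pairs count wrong
mechanism_accuracy <- function(sim, run) {
  tp <- sim$truth_pairs[sim$truth_pairs$species_a ==
                          sim$truth_pairs$species_b, ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  dc <- run$duplication_calls
  mech <- stats::setNames(dc$mechanism, key(dc$gene_a, dc$gene_b))
  got <- mech[key(tp$gene_a, tp$gene_b)]
  mean(!is.na(got) & got == tp$mechanism_true)
}

# within-species block median-Ks peaks, split at the midpoint between the
# two simulated events
block_ks_peaks <- function(run, split_at = 0.9) {
  bs <- run$block_stats[run$block_stats$species_a ==
                          run$block_stats$species_b, ]
  c(young = stats::median(bs$median_ks[bs$median_ks < split_at]),
    old = stats::median(bs$median_ks[bs$median_ks >= split_at]))
}

# sensitive nucleotide scoring used for the simulated-study analyses (deep
# homologs at Ks ~1.5 are near the positivity boundary of +1/-2 scoring)
sim_scoring <- function() {
  scoring_scheme(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
}

sim_calibration <- function() {
  wgd_calibration(tibble::tibble(
    species = rep(c("A", "B", "C"), each = 2),
    event = rep(c("WGD10", "WGD50"), 3),
    lo = rep(c(0.15, 1.2), 3),
    hi = rep(c(0.45, 1.8), 3)
  ))
}

sim_species_events <- function() {
  list(A = c("duplication", "duplication"), B = "duplication",
       C = "duplication")
}
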