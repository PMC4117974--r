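test_that("expected_pairwise_ks is the inverted dating clock", {
  expect_equal(expected_pairwise_ks(4e6), 0.12)
  expect_equal(expected_pairwise_ks(0), 0)
  expect_equal(expected_pairwise_ks(2e7), 2 * expected_pairwise_ks(1e7))
  expect_equal(date_duplication(expected_pairwise_ks(3.3e7)), 3.3e7)
  expect_error(expected_pairwise_ks(-1), "non-negative")
})

test_that("ancestral families carry the requested motif template", {
  fam <- generate_ancestral_family(5, n_codons = 120, motif_repeats = 3,
                                   seed = 4)
  expect_equal(nrow(fam$genes), 5L)
  counts <- vapply(fam$proteins$seq,
                   function(s) scan_sp_repeats(s)$repeat_count, integer(1))
  expect_equal(unname(counts), rep(3L, 5))
  # CDS and protein agree
  expect_equal(translate_cds(fam$cds$seq[1]), fam$proteins$seq[1])
  # genes are spaced and ranked on one chromosome
  expect_equal(fam$genes$rank, 0:4)
  expect_equal(diff(fam$genes$start), rep(20000, 4))
})

test_that("the family generator is deterministic under its seed", {
  f1 <- generate_ancestral_family(4, seed = 99)
  f2 <- generate_ancestral_family(4, seed = 99)
  expect_identical(f1, f2)
  f3 <- generate_ancestral_family(1, seed = 99)
  expect_equal(nrow(f3$genes), 1L)
  expect_warning(sim_config(motif_repeats = 1L), "not classify")
})

test_that("sim_config validates events against the lineage tree", {
  expect_error(sim_config(events = tibble::tibble(
    lineage = "A", type = "duplication", time = 70e6, label = "bad"
  )), "exceeds")
  expect_error(sim_config(events = tibble::tibble(
    lineage = "nope", type = "duplication", time = 10e6, label = "x"
  )), "unknown event lineage")
  expect_error(sim_config(events = tibble::tibble(
    lineage = "A", type = "pentaploidy", time = 10e6, label = "x"
  )), "unknown event type")
  # an event on the stem above the root split is legal
  expect_s3_class(sim_config(), "sim_config")
})

small_config <- function(...) {
  sim_config(
    tree = list(name = "AB", age = 10e6, children = list(
      list(name = "A", age = 0), list(name = "B", age = 0)
    )),
    root_age = 20e6,
    events = tibble::tibble(lineage = "A", type = "duplication",
                            time = 5e6, label = "WGD5"),
    n_ancestral = 6L, n_codons = 90L, motif_repeats = 2L,
    ...
  )
}

test_that("simulate_dataset is deterministic under the config seed", {
  s1 <- simulate_dataset(small_config(seed = 12))
  s2 <- simulate_dataset(small_config(seed = 12))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(small_config(seed = 13))
  expect_false(identical(s1$cds, s3$cds))
})

test_that("full retention with no loss gives the exact multiplicity ratio", {
  cfg <- sim_config(
    tree = list(name = "AB", age = 10e6, children = list(
      list(name = "A", age = 0), list(name = "B", age = 0)
    )),
    root_age = 40e6,
    events = tibble::tibble(lineage = "A", type = "duplication",
                            time = c(8e6, 3e6), label = c("W1", "W2")),
    n_ancestral = 5L, n_codons = 90L, motif_repeats = 2L,
    p_retain = 1, p_subfun = 0, td_rate = 0, loss_rate = 0, seed = 2
  )
  sim <- simulate_dataset(cfg)
  counts <- table(sim$genes$species)
  expect_equal(unname(counts[["A"]] / counts[["B"]]), 4) # two doublings
  expect_equal(unname(counts[["B"]]), 5L)
})

test_that("a triplication creates three ordered chromosome copies", {
  cfg <- sim_config(
    tree = list(name = "A", age = 0),
    root_age = 10e6,
    events = tibble::tibble(lineage = "A", type = "triplication",
                            time = 5e6, label = "T"),
    n_ancestral = 4L, n_codons = 90L, motif_repeats = 2L,
    p_retain = 1, p_subfun = 0, td_rate = 0, seed = 3
  )
  sim <- simulate_dataset(cfg)
  expect_equal(length(unique(sim$genes$chromosome)), 3L)
  expect_equal(nrow(sim$genes), 12L)
})

test_that("forced subfunctionalization leaves no member duplicates", {
  cfg <- small_config(p_retain = 0, p_subfun = 1, td_rate = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  dup <- sim$truth[sim$truth$birth_event == "WGD5", ]
  expect_true(nrow(dup) > 0)
  expect_true(all(dup$fate == "subfunctionalized"))
  prot <- sim$proteins[sim$proteins$gene_id %in% dup$gene_id, ]
  counts <- vapply(prot$seq, function(s) scan_sp_repeats(s)$repeat_count,
                   integer(1))
  expect_true(all(counts < 2))
})

test_that("gene bookkeeping balances births, losses and survivors", {
  sim <- simulate_dataset(small_config(seed = 31, p_retain = 0.5,
                                       p_subfun = 0.2, td_rate = 2e-9))
  for (sp in c("A", "B")) {
    ids <- sim$genes$gene_id[sim$genes$species == sp]
    expect_equal(sort(sim$truth$gene_id[!is.na(sim$truth$gene_id) &
                                          sim$truth$gene_id %in% ids]),
                 sort(ids))
  }
  # every surviving gene has exactly one truth row and one locus
  surv <- sim$truth[!is.na(sim$truth$gene_id), ]
  expect_equal(anyDuplicated(surv$gene_id), 0L)
  expect_true(all(surv$locus %in% sprintf("anc%03d", 1:6)))
  # anchors only pair genes of the same ancestral locus
  locus_of <- stats::setNames(surv$locus, surv$gene_id)
  expect_true(all(locus_of[sim$anchors$gene_a] ==
                    locus_of[sim$anchors$gene_b]))
})

test_that("true pairwise Ks equals the clock at known split times", {
  cfg <- small_config(p_retain = 1, p_subfun = 0, td_rate = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  tp <- sim$truth_pairs
  # cross-species pairs split at the 10 My speciation
  cross <- tp[tp$species_a != tp$species_b, ]
  expect_true(all(cross$divergence_time == 10e6))
  expect_true(all(cross$ks_true == 0.3))
  expect_true(all(cross$mechanism_true == "speciation"))
  # within-A pairs split at the 5 My duplication
  within <- tp[tp$species_a == "A" & tp$species_b == "A", ]
  expect_true(all(within$divergence_time == 5e6))
  expect_true(all(within$event_true == "WGD5"))
})

test_that("realized synonymous substitution counts are Poisson", {
  # with omega = 0 and four-fold founder codons, synonymous changes never
  # alter the per-codon synonymous-change count, so the realized event
  # count per branch is exactly Poisson(lambda * S * t)
  withr::local_seed(303)
  tabs <- paleofam:::sim_tables()
  fam <- generate_ancestral_family(1, n_codons = 100, motif_repeats = 2,
                                   seed = 6)
  codons <- match(substring(fam$cds$seq[1],
                            seq(1, nchar(fam$cds$seq[1]), 3),
                            seq(3, nchar(fam$cds$seq[1]), 3)),
                  tabs$codons)
  protected <- rep(FALSE, length(codons))
  lambda <- 1.5e-8
  t_years <- 1e7
  s_sites <- sum(tabs$n_syn[codons]) / 3
  mu <- lambda * s_sites * t_years
  n_rep <- 1000
  counts <- vapply(seq_len(n_rep), function(r) {
    paleofam:::evolve_seq(codons, protected, t_years, lambda, omega = 0,
                          count_events = TRUE)$n_syn_events
  }, integer(1))
  expect_equal(mean(counts), mu, tolerance = 0.1)
  # chi-square goodness of fit against the Poisson(mu) bin probabilities
  brks <- unique(c(-Inf, stats::qpois(seq(0.1, 0.9, 0.1), mu), Inf))
  obs <- table(cut(counts, brks))
  p <- diff(stats::ppois(brks, mu))
  gof <- suppressWarnings(stats::chisq.test(as.vector(obs), p = p,
                                            rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("with synonymous-only divergence dN estimates center on zero", {
  withr::local_seed(404)
  tabs <- paleofam:::sim_tables()
  fam <- generate_ancestral_family(40, n_codons = 100, motif_repeats = 2,
                                   seed = 14)
  dn <- numeric(0)
  for (i in seq_len(nrow(fam$cds))) {
    cds <- fam$cds$seq[i]
    codons <- match(substring(cds, seq(1, nchar(cds), 3),
                              seq(3, nchar(cds), 3)), tabs$codons)
    prot <- rep(FALSE, length(codons))
    for (rep in 1:5) {
      a <- paleofam:::evolve_seq(codons, prot, 1e7, 1.5e-8, omega = 0)
      b <- paleofam:::evolve_seq(codons, prot, 1e7, 1.5e-8, omega = 0)
      est <- ng86_estimate(tibble::tibble(codon_a = tabs$codons[a],
                                          codon_b = tabs$codons[b]))
      dn <- c(dn, est$dN)
    }
  }
  expect_equal(length(dn), 200L)
  expect_lt(abs(mean(dn)), 0.005)
})
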