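two_chrom_genes <- function(ranks_a, ranks_b, species_b = "sp") {
  # helper: genes at given ranks on two chromosomes (spacing 10 kb)
  dplyr::bind_rows(
    tibble::tibble(gene_id = sprintf("a%02d", ranks_a), species = "sp",
                   chromosome = "c1", start = ranks_a * 10000L,
                   end = ranks_a * 10000L + 1000L, strand = "+"),
    tibble::tibble(gene_id = sprintf("b%02d", ranks_b), species = species_b,
                   chromosome = "c2", start = ranks_b * 10000L,
                   end = ranks_b * 10000L + 1000L, strand = "+")
  ) |> assign_gene_ranks()
}

anchors_at <- function(pairs) {
  tibble::tibble(gene_a = sprintf("a%02d", pairs[, 1]),
                 gene_b = sprintf("b%02d", pairs[, 2]))
}

test_that("a perfect diagonal chains into one block", {
  genes <- two_chrom_genes(0:5, 0:5)
  blocks <- find_collinear_blocks(anchors_at(cbind(0:5, 0:5)), genes)
  expect_equal(length(unique(blocks$block_id)), 1L)
  expect_equal(nrow(blocks), 6L)
  expect_equal(blocks$orientation[1], "same")
  expect_equal(blocks$anchor_index, 1:6)
})

test_that("chains below min_anchors are discarded", {
  genes <- two_chrom_genes(0:3, 0:3)
  blocks <- find_collinear_blocks(anchors_at(cbind(0:3, 0:3)), genes)
  expect_equal(nrow(blocks), 0L)
  blocks4 <- find_collinear_blocks(anchors_at(cbind(0:3, 0:3)), genes,
                                   min_anchors = 4L)
  expect_equal(nrow(blocks4), 4L)
})

test_that("inverted blocks are detected", {
  genes <- two_chrom_genes(0:5, 0:5)
  blocks <- find_collinear_blocks(anchors_at(cbind(0:5, 5:0)), genes)
  expect_equal(nrow(blocks), 6L)
  expect_equal(blocks$orientation[1], "inverted")
})

test_that("rank gaps over the limit split chains", {
  genes <- two_chrom_genes(0:40, 0:40)
  pairs <- cbind(c(0:5, 20:25), c(0:5, 20:25))
  blocks <- find_collinear_blocks(anchors_at(pairs), genes,
                                  max_rank_gap = 10L)
  expect_equal(length(unique(blocks$block_id)), 2L)
})

test_that("anchors missing coordinates are an error", {
  genes <- two_chrom_genes(0:5, 0:5)
  bad <- rbind(anchors_at(cbind(0:5, 0:5)),
               tibble::tibble(gene_a = "zz", gene_b = "b01"))
  expect_error(find_collinear_blocks(bad, genes), "zz")
})

test_that("greedy chaining matches the exhaustive oracle on shuffled anchors", {
  withr::local_seed(47)
  for (rep in 1:8) {
    n <- sample(12:20, 1)
    ra <- sample(0:(n + 4), n)
    rb <- sample(0:(n + 4), n)
    genes <- two_chrom_genes(0:(n + 4), 0:(n + 4))
    blocks <- find_collinear_blocks(anchors_at(cbind(ra, rb)), genes,
                                    min_anchors = 3L, max_rank_gap = 6L)
    got <- lapply(split(blocks, blocks$block_id), function(b) {
      unname(cbind(b$rank_a, b$rank_b))
    })
    orc <- oracle_chain_partition(ra, rb, min_anchors = 3L, max_gap = 6L)
    expect_equal(length(got), length(orc))
    for (k in seq_along(orc)) {
      expect_equal(got[[k]], unname(orc[[k]]), info = paste("rep", rep))
    }
  }
})

test_that("block anchors are unique and strictly monotone", {
  withr::local_seed(59)
  n <- 20
  ra <- sample(0:24, n); rb <- sample(0:24, n)
  genes <- two_chrom_genes(0:24, 0:24)
  blocks <- find_collinear_blocks(anchors_at(cbind(ra, rb)), genes,
                                  min_anchors = 3L, max_rank_gap = 8L)
  expect_equal(anyDuplicated(paste(blocks$gene_a, blocks$gene_b)), 0L)
  for (b in split(blocks, blocks$block_id)) {
    expect_true(all(diff(b$rank_a) > 0))
    expect_true(all(diff(b$rank_b) > 0) || all(diff(b$rank_b) < 0))
  }
})

test_that("block median Ks follows the even/odd median rules", {
  genes <- two_chrom_genes(0:5, 0:5)
  blocks <- find_collinear_blocks(anchors_at(cbind(0:5, 0:5)), genes,
                                  min_anchors = 3L)
  ks3 <- tibble::tibble(gene_a = sprintf("a%02d", 0:5),
                        gene_b = sprintf("b%02d", 0:5),
                        dS = c(0.25, 0.27, 0.30, NA, Inf, NaN))
  bm <- block_median_ks(blocks, ks3)
  expect_equal(bm$median_ks, 0.27) # undefined entries excluded
  expect_equal(bm$n_ks, 3L)
  ks2 <- dplyr::mutate(ks3, dS = c(0.2, 0.4, NA, NA, NA, NA))
  expect_equal(block_median_ks(blocks, ks2)$median_ks, 0.3)
  ks1 <- dplyr::mutate(ks3, dS = c(1.5, NA, NA, NA, NA, NA))
  expect_equal(block_median_ks(blocks, ks1)$median_ks, 1.5)
  ks0 <- dplyr::mutate(ks3, dS = NA_real_)
  expect_error(block_median_ks(blocks, ks0), "B001")
})

test_that("published calibration ranges drive event assignment", {
  cal <- default_wgd_calibration()
  expect_equal(assign_wgd_event(0.27, cal, "Populus"), "P-WGD")
  expect_equal(assign_wgd_event(1.54, cal, "Populus"), "gamma")
  expect_true(is.na(assign_wgd_event(0.60, cal, "Populus")))
  expect_equal(assign_wgd_event(0.86, cal, "Arabidopsis"), "alpha")
  # saturated medians get the indistinguishable label
  expect_equal(assign_wgd_event(2.1, cal, "Arabidopsis"),
               "beta/gamma-indistinguishable")
  # interval edges are inclusive
  expect_equal(assign_wgd_event(c(0.2437, 0.3345), cal, "Populus"),
               c("P-WGD", "P-WGD"))
})

test_that("overlapping calibration intervals are rejected at load", {
  expect_error(wgd_calibration(tibble::tibble(
    species = "x", event = c("e1", "e2"), lo = c(0.1, 0.3), hi = c(0.4, 0.6)
  )), "overlapping")
  expect_error(wgd_calibration(tibble::tibble(
    species = "x", event = "e", lo = 0.5, hi = 0.2
  )), "lo > hi")
})

test_that("tandem calls need same chromosome, 100-kb window and tiny E", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    species = "sp",
    chromosome = c("c1", "c1", "c1", "c2"),
    start = c(0L, 50000L, 150000L, 10000L),
    end = c(1000L, 51000L, 151000L, 11000L),
    strand = "+"
  ) |> assign_gene_ranks()
  pairs <- tibble::tibble(
    gene_a = c("g1", "g1", "g1", "g1"),
    gene_b = c("g2", "g3", "g4", "g2"),
    evalue = c(1e-30, 1e-30, 1e-30, 1e-10)
  )
  td <- call_tandem(pairs, genes)
  expect_equal(td$tandem, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(call_tandem(tibble::tibble(gene_a = "g1", gene_b = "nope",
                                          evalue = 1e-30), genes),
               "unplaced")
})

test_that("classification is exhaustive, exclusive, and SWGD-first", {
  blocks <- tibble::tibble(gene_a = "p1", gene_b = "p2", block_id = "B001",
                           event = "P-WGD")
  pairs <- tibble::tibble(gene_a = c("p1", "p3", "p5"),
                          gene_b = c("p2", "p4", "p6"))
  td <- tibble::tibble(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                       tandem = c(TRUE, TRUE, FALSE))
  out <- classify_duplication(pairs, blocks, td)
  expect_equal(out$mechanism, c("SWGD", "TD", "OTHER")) # block beats tandem
  expect_equal(out$event, c("P-WGD", NA, NA))
  expect_true(all(out$mechanism %in% c("SWGD", "TD", "OTHER")))
})

test_that("expected multiplicity compounds duplications and triplications", {
  expect_equal(expected_multiplicity(c("duplication", "duplication")), 4L)
  expect_equal(expected_multiplicity("duplication"), 2L)
  expect_equal(expected_multiplicity(character()), 1L)
  expect_equal(expected_multiplicity("triplication"), 3L)
  expect_equal(expected_multiplicity(c("triplication", "duplication")), 6L)
  expect_error(expected_multiplicity("hexaploidy"), "duplication")
})
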