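test_that("self alignment is perfect and scores match * length", {
  seq <- paste(rep("ACGT", 100), collapse = "")
  al <- align_local_nt(seq, seq)
  expect_equal(al$identity, 1.0)
  expect_equal(al$aligned_length, 400L)
  expect_equal(al$score, 400) # match = +1, gap free
})

test_that("local alignment score is symmetric in its arguments", {
  withr::local_seed(5)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
               collapse = "")
    expect_equal(align_local_nt(a, b)$score, align_local_nt(b, a)$score)
  }
})

test_that("disjoint alphabets give the empty zero-score alignment", {
  al <- align_local_nt("AAAA", "CCCC")
  expect_equal(al$score, 0)
  expect_equal(al$aligned_length, 0L)
  expect_equal(al$q_start, 0L)
})

test_that("local alignment rejects non-nucleotide input", {
  expect_error(align_local_nt("ACGU", "ACGT"), "non-ACGTN")
  expect_error(align_local_nt("", "ACGT"), "empty")
})

test_that("local DP score matches the Gotoh oracle on the 8x8 instance", {
  sc <- scoring_scheme(match = 1, mismatch = -2, gap_open = -5,
                       gap_extend = -2)
  got <- align_local_nt("ACACACAC", "ACACTCAC", sc)$score
  expect_equal(got, oracle_local_score("ACACACAC", "ACACTCAC",
                                       1, -2, 5, 2))
})

test_that("local DP score matches the oracle on random short pairs", {
  withr::local_seed(17)
  sc <- scoring_scheme(match = 1, mismatch = -2, gap_open = -5,
                       gap_extend = -2)
  for (i in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1),
                      replace = TRUE), collapse = "")
    expect_equal(align_local_nt(a, b, sc)$score,
                 oracle_local_score(a, b, 1, -2, 5, 2),
                 info = paste(a, b))
  }
})

test_that("batched all-vs-all equals the single-pair path", {
  withr::local_seed(3)
  seqs <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5),
    seq = replicate(5, paste(sample(c("A", "C", "G", "T"), 40,
                                    replace = TRUE), collapse = ""))
  )
  hits <- align_all_pairs(seqs)
  expect_equal(nrow(hits), choose(5, 2)) # unordered pairs, no self hits
  for (r in seq_len(nrow(hits))) {
    single <- align_local_nt(seqs$seq[seqs$gene_id == hits$query_id[r]],
                             seqs$seq[seqs$gene_id == hits$subject_id[r]])
    expect_equal(hits$score[r], single$score)
    expect_equal(hits$identity[r], single$identity)
  }
})

test_that("global protein alignment matches BLOSUM62 oracle and handles gaps", {
  b62 <- paleofam:::get_substitution_matrix("BLOSUM62")
  al <- align_global_protein("MKV", "MV")
  # Biostrings holds gap penalties in single precision, hence the tolerance
  expect_equal(al$score, oracle_global_score("MKV", "MV", b62),
               tolerance = 1e-6)
  expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
  expect_equal(gsub("-", "", al$aligned_b), "MV")
  ident <- align_global_protein("MKVL", "MKVL")
  expect_false(grepl("-", ident$aligned_a)) # identical -> gap free
  empty <- align_global_protein("", "MV")
  expect_equal(empty$aligned_a, "--")
  expect_equal(empty$aligned_b, "MV")
  expect_error(align_global_protein("MK1", "MV"), "invalid")
})

test_that("global protein score matches the oracle on random short pairs", {
  withr::local_seed(23)
  b62 <- paleofam:::get_substitution_matrix("BLOSUM62")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    a <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:8, 1), replace = TRUE), collapse = "")
    # absolute tolerance: scores sit near zero and Biostrings carries
    # single-precision gap penalties
    expect_lt(abs(align_global_protein(a, b)$score -
                    oracle_global_score(a, b, b62)), 1e-5)
  }
})

make_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    query_id = vapply(rows, `[[`, character(1), 1),
    subject_id = vapply(rows, `[[`, character(1), 2),
    score = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    aligned_length = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    identity = vapply(rows, function(r) as.numeric(r[[5]]), numeric(1)),
    evalue = 1e-30
  )
}

test_that("call_paralogs applies the strict >300 bp / >=40% rule", {
  hits <- make_hits(
    list("a", "b", 200, 350L, 0.45),  # kept
    list("a", "c", 300, 300L, 0.90),  # 300 is not over 300 -> rejected
    list("b", "c", 150, 400L, 0.39)   # identity below threshold
  )
  p <- call_paralogs(hits)
  expect_equal(nrow(p), 1L)
  expect_equal(p$gene_a, "a")
  expect_equal(p$gene_b, "b")
  expect_equal(p$relation, "paralog")
})

test_that("paralog groups are connected components (union-find oracle)", {
  hits <- make_hits(
    list("a", "b", 200, 350L, 0.5),
    list("b", "c", 210, 360L, 0.5),
    list("d", "e", 220, 340L, 0.6)
  )
  p <- call_paralogs(hits)
  grp <- paralog_groups(p)
  expect_equal(sort(grp$gene_id[grp$group_id == 1]), c("a", "b", "c"))
  expect_equal(sort(grp$gene_id[grp$group_id == 2]), c("d", "e"))
  oracle <- oracle_components(hits$query_id, hits$subject_id)
  expect_equal(unname(lapply(oracle, sort)),
               unname(lapply(split(grp$gene_id, grp$group_id), sort)))
})

test_that("random paralog graphs agree with the union-find oracle", {
  withr::local_seed(31)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    genes <- sprintf("g%02d", 1:n)
    pairs <- t(utils::combn(genes, 2))
    keep <- sample(nrow(pairs), sample(2:min(10, nrow(pairs)), 1))
    hits <- tibble::tibble(
      query_id = pairs[keep, 1], subject_id = pairs[keep, 2],
      score = 100, aligned_length = 400L, identity = 0.8, evalue = 1e-40
    )
    grp <- paralog_groups(call_paralogs(hits))
    oracle <- oracle_components(hits$query_id, hits$subject_id)
    expect_equal(unname(lapply(split(grp$gene_id, grp$group_id), sort)),
                 unname(lapply(oracle, sort)))
  }
})

test_that("call_orthologs keeps reciprocal best hits over 300 bp", {
  ab <- make_hits(
    list("a1", "b1", 500, 350L, 0.9),
    list("a1", "b2", 400, 350L, 0.8),
    list("a2", "b1", 450, 350L, 0.8)
  )
  ba <- make_hits(
    list("b1", "a1", 500, 350L, 0.9),
    list("b2", "a1", 400, 350L, 0.8),
    list("b1", "a2", 450, 350L, 0.8)
  )
  o <- call_orthologs(ab, ba)
  expect_equal(nrow(o), 1L)
  expect_equal(c(o$gene_a, o$gene_b), c("a1", "b1"))
  # a1's best is b1 but b1's best is a2: no a1 pair (a2-b1 forms instead)
  ba2 <- make_hits(list("b1", "a2", 600, 350L, 0.9),
                   list("b2", "a1", 400, 350L, 0.8))
  o2 <- call_orthologs(ab, ba2)
  expect_false("a1" %in% o2$gene_a)
  expect_equal(o2$gene_a, "a2")
  # reciprocal but short
  ab3 <- make_hits(list("a1", "b1", 500, 250L, 0.9))
  ba3 <- make_hits(list("b1", "a1", 500, 250L, 0.9))
  expect_equal(nrow(call_orthologs(ab3, ba3)), 0L)
})

test_that("ortholog output is a one-to-one matching", {
  withr::local_seed(41)
  for (rep in 1:8) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    ga <- sprintf("a%d", 1:na); gb <- sprintf("b%d", 1:nb)
    ab <- expand.grid(query_id = ga, subject_id = gb,
                      stringsAsFactors = FALSE)
    ab$score <- runif(nrow(ab), 10, 100)
    ab$aligned_length <- 400L
    ab$identity <- runif(nrow(ab), 0.4, 1)
    ab$evalue <- 1e-20
    ba <- ab
    names(ba)[1:2] <- c("subject_id", "query_id")
    o <- call_orthologs(tibble::as_tibble(ab), tibble::as_tibble(ba))
    expect_equal(anyDuplicated(o$gene_a), 0L)
    expect_equal(anyDuplicated(o$gene_b), 0L)
  }
})

test_that("karlin lambda solves the ungapped characteristic equation", {
  l <- karlin_lambda_ungapped(1, -2)
  expect_equal(exp(l) / 4 + 3 * exp(-2 * l) / 4, 1, tolerance = 1e-8)
  expect_error(karlin_lambda_ungapped(3, -1), "negative")
})
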