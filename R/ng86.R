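# Nei-Gojobori (1986) counting estimator of dN/dS with Jukes-Cantor
# correction -- a deliberate, documented stand-in for ML codon models:
# well defined and dependency-free, but numerically different from
# codeml-style estimates.

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

all_codons <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

codon_neighbors <- function(codon) {
  # the 9 single-base mutants of a codon
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      out <- c(out, mut)
    }
  }
  out
}

ng86_tables <- function() {
  if (!is.null(.paleofam_env$ng86)) return(.paleofam_env$ng86)
  codons <- all_codons()
  aa <- codon_aa(codons)
  sense <- codons[!codons %in% STOP_CODONS]
  # per-codon synonymous site count: each of the 9 single-base changes
  # contributes 1/3 site; changes into stop codons count as nonsynonymous
  syn_sites <- vapply(sense, function(cd) {
    nb <- codon_neighbors(cd)
    syn <- !nb %in% STOP_CODONS & codon_aa(nb) == codon_aa(cd)
    sum(syn) / 3
  }, numeric(1))
  # pathway-averaged difference counts for every sense-codon pair
  n <- length(sense)
  sd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- codon_path_diffs(sense[i], sense[j])
        sd_mat[i, j] <- sd_mat[j, i] <- d[1]
        nd_mat[i, j] <- nd_mat[j, i] <- d[2]
      }
    }
  }
  .paleofam_env$ng86 <- list(sense = sense, syn_sites = syn_sites,
                             sd = sd_mat, nd = nd_mat)
  .paleofam_env$ng86
}

codon_path_diffs <- function(c1, c2) {
  # average synonymous/nonsynonymous step counts over all mutational
  # pathways between two codons; pathways passing through a stop codon are
  # excluded unless every pathway is blocked
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(0, 0))
  perms <- permutations_of(pos)
  paths <- lapply(perms, function(ord) {
    cur <- c1
    steps <- matrix(NA_character_, nrow = length(ord), ncol = 2)
    for (s in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[s], ord[s]) <- substr(c2, ord[s], ord[s])
      steps[s, ] <- c(cur, nxt)
      cur <- nxt
    }
    steps
  })
  blocked <- vapply(paths, function(st) any(st %in% STOP_CODONS), logical(1))
  use <- if (all(blocked)) paths else paths[!blocked]
  counts <- vapply(use, function(st) {
    syn <- codon_aa(st[, 1]) == codon_aa(st[, 2]) &
      !st[, 1] %in% STOP_CODONS & !st[, 2] %in% STOP_CODONS
    c(sum(syn), nrow(st) - sum(syn))
  }, numeric(2))
  rowMeans(counts)
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Each of the nine single-base changes contributes one third of a site;
#' changes creating a stop codon count as nonsynonymous. The two counts
#' always sum to 3.
#'
#' @param codon A sense codon (string over ACGT).
#' @return Named numeric vector `c(syn, nonsyn)`.
#' @export
ng86_sites <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L, nchar(codon) == 3L)
  if (grepl("[^ACGT]", codon)) abort("codon must be over ACGT")
  if (codon %in% STOP_CODONS) abort("stop codon has no site decomposition")
  s <- ng86_tables()$syn_sites[[codon]]
  c(syn = s, nonsyn = 3 - s)
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Maps each residue column of a pairwise protein alignment onto the
#' corresponding codons of the two CDSs; residue gaps become codon gaps
#' (`NA`). The CDSs must translate exactly to the aligned proteins (an `X`
#' residue matches any codon) and contain no internal stop codon.
#'
#' @param aligned_a,aligned_b Equal-length aligned protein strings with `-`
#'   gaps.
#' @param cds_a,cds_b In-frame CDS of each sequence (no terminal stop).
#' @return Tibble with `codon_a`, `codon_b` (3-letter strings or `NA`), one
#'   row per protein alignment column.
#' @export
backtranslate <- function(aligned_a, aligned_b, cds_a, cds_b) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  map_one <- function(aligned, cds, label) {
    res <- strsplit(aligned, "")[[1]]
    ungapped <- res[res != "-"]
    if (nchar(cds) %% 3L != 0L) {
      abort(paste0("CDS of ", label, " is not a whole number of codons"))
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    if (length(codons) != length(ungapped)) {
      abort(paste0("CDS length of ", label, " (", length(codons),
                   " codons) does not match protein length (",
                   length(ungapped), ")"))
    }
    stops <- which(codons %in% STOP_CODONS)
    if (length(stops) > 0L) {
      abort(paste0("internal stop codon in ", label, " at codon ", stops[1]))
    }
    trans <- codon_aa(codons)
    mism <- which(trans != ungapped & ungapped != "X")
    if (length(mism) > 0L) {
      abort(paste0("translation mismatch in ", label, " at residue ", mism[1],
                   ": codon ", codons[mism[1]], " is ", trans[mism[1]],
                   ", protein has ", ungapped[mism[1]]))
    }
    out <- rep(NA_character_, length(res))
    out[res != "-"] <- codons
    out
  }
  tibble(codon_a = map_one(aligned_a, cds_a, "sequence a"),
         codon_b = map_one(aligned_b, cds_b, "sequence b"))
}

#' Nei-Gojobori (1986) substitution estimate for a codon alignment
#'
#' Site counts are averaged over the two sequences; difference counts use
#' unweighted pathway averaging for multi-hit codons (pathways through stop
#' codons excluded; if all are blocked, all are included). Proportions are
#' corrected with the Jukes-Cantor formula `d = -(3/4) log(1 - (4/3) p)`;
#' `p >= 3/4` is flagged as infinite. omega is defined only when dS is
#' finite and positive.
#'
#' @param codon_alignment Tibble from [backtranslate()] (columns `codon_a`,
#'   `codon_b`; `NA` = codon gap).
#' @return One-row tibble: `n_codons` (ungapped columns), `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `dS_infinite`, `dN_infinite`,
#'   `omega_defined`.
#' @export
ng86_estimate <- function(codon_alignment) {
  tabs <- ng86_tables()
  keep <- !is.na(codon_alignment$codon_a) & !is.na(codon_alignment$codon_b)
  ca <- codon_alignment$codon_a[keep]
  cb <- codon_alignment$codon_b[keep]
  if (length(ca) == 0L) abort("no ungapped codon columns")
  if (any(!ca %in% tabs$sense) || any(!cb %in% tabs$sense)) {
    abort("codon alignment contains stop or non-ACGT codons")
  }
  S <- (sum(tabs$syn_sites[ca]) + sum(tabs$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(tabs$sd[cbind(ca, cb)])
  Nd <- sum(tabs$nd[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS)
  dN <- jc(pN)
  omega_defined <- is.finite(dS) && dS > 0 && is.finite(dN)
  tibble(
    n_codons = length(ca), S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = dS, dN = dN,
    omega = if (omega_defined) dN / dS else NA_real_,
    dS_infinite = is.infinite(dS), dN_infinite = is.infinite(dN),
    omega_defined = omega_defined
  )
}

#' Translate an in-frame CDS to protein
#'
#' @param cds CDS string over ACGT (no terminal stop; internal stops error).
#' @return Protein string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) abort("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  if (any(codons %in% STOP_CODONS)) abort("internal stop codon in CDS")
  paste(codon_aa(codons), collapse = "")
}

#' Estimate dN, dS and omega for homolog pairs
#'
#' For every pair the two proteins are aligned globally (BLOSUM62, gap open
#' 2.0, gap extend 0.2), the alignment is back-translated against the CDSs,
#' and the NG86 estimate is computed.
#'
#' @param pairs Tibble with `gene_a`, `gene_b` (extra columns carried
#'   through).
#' @param cds Tibble with `gene_id`, `seq` (in-frame CDS).
#' @return `pairs` with the [ng86_estimate()] columns bound on.
#' @export
pair_dnds <- function(pairs, cds) {
  seqs <- setNames(cds$seq, cds$gene_id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(seqs))
  if (length(missing) > 0L) {
    abort(paste0("missing CDS for gene(s): ", paste(missing, collapse = ", ")))
  }
  est <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- seqs[[pairs$gene_a[i]]]
    b <- seqs[[pairs$gene_b[i]]]
    aln <- align_global_protein(translate_cds(a), translate_cds(b))
    ng86_estimate(backtranslate(aln$aligned_a, aln$aligned_b, a, b))
  })
  dplyr::bind_cols(pairs, est)
}

#' Classify selection regime from omega
#'
#' omega < 1 indicates purifying selection, omega > 1 positive selection. A
#' symmetric band around 1 is treated as neutral; purifying calls with
#' omega > 0.9 carry a weak-evidence flag (purifying "not evident").
#'
#' @param omega Numeric vector of defined omega values.
#' @param neutral_band Half-width of the neutral band around 1 (default 0.1).
#' @return Tibble with `omega`, `selection` in
#'   `{"purifying","neutral","positive"}` and `weak_evidence`.
#' @export
classify_selection <- function(omega, neutral_band = 0.1) {
  if (any(is.na(omega))) abort("omega must be defined (no NA)")
  stopifnot(neutral_band >= 0)
  selection <- dplyr::case_when(
    omega < 1 - neutral_band ~ "purifying",
    omega > 1 + neutral_band ~ "positive",
    TRUE ~ "neutral"
  )
  tibble(omega = omega, selection = selection,
         weak_evidence = selection == "purifying" & omega > 0.9)
}

#' Summarise omega by relation and species
#'
#' Arithmetic mean over pairs with a defined omega; pairs with undefined
#' omega are counted and listed in the `"excluded"` attribute.
#'
#' @param pairs Tibble with an `omega` column and any of `relation`,
#'   `species` to group by.
#' @return Tibble with grouping columns, `n_pairs`, `n_excluded`,
#'   `mean_omega`.
#' @export
summarize_omega <- function(pairs) {
  grp <- intersect(c("relation", "species"), names(pairs))
  defined <- !is.na(pairs$omega) & is.finite(pairs$omega)
  out <- pairs |>
    mutate(.defined = defined) |>
    group_by(across(all_of(grp))) |>
    summarise(
      n_pairs = sum(.data$.defined),
      n_excluded = sum(!.data$.defined),
      mean_omega = mean(.data$omega[.data$.defined]),
      .groups = "drop"
    )
  attr(out, "excluded") <- pairs[!defined, , drop = FALSE]
  out
}
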