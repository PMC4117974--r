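#' Detect collinear (syntenic) blocks from homolog anchors
#'
#' Anchors are homologous gene pairs; within each chromosome pair they are
#' chained into blocks whose ranks are strictly monotone on both chromosomes
#' (same orientation: both increasing; inverted: increasing against
#' decreasing), with consecutive anchors at most `max_rank_gap` ranks apart
#' on either side. Chains are extracted greedily, longest first (ties broken
#' toward the same orientation, then the lexicographically smallest anchor
#' sequence), each anchor belongs to at most one block, and chains shorter
#' than `min_anchors` are discarded. This is an in-package stand-in for
#' block inventories retrieved from synteny databases; precomputed anchor
#' tables can be ingested with [read_anchor_table()].
#'
#' @param anchors Tibble with `gene_a`, `gene_b` (any extra columns are
#'   dropped).
#' @param genes Gene table with `gene_id`, `species`, `chromosome`, `rank`,
#'   `start` (see [read_gff3()]).
#' @param min_anchors Minimum anchors per block (default 5).
#' @param max_rank_gap Maximum rank gap between consecutive anchors
#'   (default 10).
#' @return Tibble of block anchors: `block_id`, `orientation`,
#'   `anchor_index`, `gene_a`, `species_a`, `chr_a`, `rank_a`, `gene_b`,
#'   `species_b`, `chr_b`, `rank_b`. Empty (zero rows) when nothing chains.
#' @export
find_collinear_blocks <- function(anchors, genes, min_anchors = 5L,
                                  max_rank_gap = 10L) {
  prepped <- prepare_anchors(anchors, genes)
  grp <- prepped |>
    group_by(.data$species_a, .data$chr_a, .data$species_b, .data$chr_b)
  keys <- dplyr::group_keys(grp)
  groups <- dplyr::group_split(grp)
  ord <- order(keys$species_a, keys$chr_a, keys$species_b, keys$chr_b)
  out <- list()
  block_n <- 0L
  for (gi in ord) {
    g <- groups[[gi]]
    remaining <- g
    repeat {
      chain <- best_chain(remaining$rank_a, remaining$rank_b, max_rank_gap)
      if (length(chain$idx) < min_anchors) break
      block_n <- block_n + 1L
      block <- remaining[chain$idx, , drop = FALSE]
      block$block_id <- sprintf("B%03d", block_n)
      block$orientation <- chain$orientation
      block$anchor_index <- seq_along(chain$idx)
      out[[length(out) + 1L]] <- block
      remaining <- remaining[-chain$idx, , drop = FALSE]
    }
  }
  if (length(out) == 0L) {
    return(tibble(block_id = character(), orientation = character(),
                  anchor_index = integer(), gene_a = character(),
                  species_a = character(), chr_a = character(),
                  rank_a = integer(), gene_b = character(),
                  species_b = character(), chr_b = character(),
                  rank_b = integer()))
  }
  bind_rows(out) |>
    select("block_id", "orientation", "anchor_index", "gene_a", "species_a",
           "chr_a", "rank_a", "gene_b", "species_b", "chr_b", "rank_b")
}

prepare_anchors <- function(anchors, genes) {
  coords <- select(genes, "gene_id", "species", "chromosome", "rank")
  a <- anchors |>
    filter(.data$gene_a != .data$gene_b) |>
    select("gene_a", "gene_b") |>
    left_join(rename(coords, gene_a = "gene_id", species_a = "species",
                     chr_a = "chromosome", rank_a = "rank"), by = "gene_a") |>
    left_join(rename(coords, gene_b = "gene_id", species_b = "species",
                     chr_b = "chromosome", rank_b = "rank"), by = "gene_b")
  missing <- unique(c(a$gene_a[is.na(a$rank_a)], a$gene_b[is.na(a$rank_b)]))
  if (length(missing) > 0L) {
    abort(paste0("anchor gene(s) without coordinates: ",
                 paste(missing, collapse = ", ")))
  }
  # canonical orientation of each pair so every anchor is stored once
  flip <- a$species_a > a$species_b |
    (a$species_a == a$species_b &
       (a$chr_a > a$chr_b |
          (a$chr_a == a$chr_b & a$rank_a > a$rank_b)))
  flipped <- a[flip, c("gene_b", "species_b", "chr_b", "rank_b",
                       "gene_a", "species_a", "chr_a", "rank_a")]
  names(flipped) <- c("gene_a", "species_a", "chr_a", "rank_a",
                      "gene_b", "species_b", "chr_b", "rank_b")
  bind_rows(a[!flip, names(flipped)], flipped) |>
    distinct() |>
    arrange(.data$species_a, .data$chr_a, .data$species_b, .data$chr_b,
            .data$rank_a, .data$rank_b)
}

# longest strictly monotone chain over anchors (rank_a, rank_b), trying both
# orientations; deterministic: among longest chains the lexicographically
# smallest index sequence (anchors pre-sorted by rank_a then rank_b) wins,
# and a tie between orientations goes to "same"
best_chain <- function(rank_a, rank_b, max_rank_gap) {
  same <- longest_chain(rank_a, rank_b, max_rank_gap, inverted = FALSE)
  inv <- longest_chain(rank_a, rank_b, max_rank_gap, inverted = TRUE)
  if (length(inv$idx) > length(same$idx)) {
    list(idx = inv$idx, orientation = "inverted")
  } else {
    list(idx = same$idx, orientation = "same")
  }
}

longest_chain <- function(rank_a, rank_b, max_rank_gap, inverted = FALSE) {
  n <- length(rank_a)
  if (n == 0L) return(list(idx = integer()))
  ok_step <- function(i, j) {
    da <- rank_a[j] - rank_a[i]
    db <- rank_b[j] - rank_b[i]
    if (inverted) db <- -db
    da >= 1L && da <= max_rank_gap && db >= 1L && db <= max_rank_gap
  }
  # anchors arrive sorted by (rank_a, rank_b), so successors always have a
  # larger index; f[i] = length of the longest valid chain starting at i
  f <- integer(n)
  for (i in rev(seq_len(n))) {
    f[i] <- 1L
    if (i < n) {
      for (j in seq(i + 1L, n)) {
        if (ok_step(i, j) && f[j] + 1L > f[i]) f[i] <- f[j] + 1L
      }
    }
  }
  # lexicographically smallest longest chain: smallest start index, then at
  # each step the smallest valid successor preserving maximal length
  L <- max(f)
  start <- which(f == L)[1]
  idx <- start
  cur <- start
  while (f[cur] > 1L) {
    cand <- which(vapply(seq_len(n), function(j) {
      j != cur && ok_step(cur, j) && f[j] == f[cur] - 1L
    }, logical(1)))
    cur <- cand[1]
    idx <- c(idx, cur)
  }
  list(idx = idx)
}

#' Median Ks of each collinear block
#'
#' Genes on a block pair duplicated simultaneously, so the median Ks over a
#' block's anchors dates the underlying duplication event.
#'
#' @param blocks Block-anchor tibble from [find_collinear_blocks()].
#' @param pairs Tibble with `gene_a`, `gene_b` and a Ks column (undirected).
#' @param value Name of the Ks column (default `"dS"`).
#' @return Tibble with one row per block: `block_id`, `species_a`, `chr_a`,
#'   `species_b`, `chr_b`, `orientation`, `n_anchors`, `n_ks`, `median_ks`.
#'   A block none of whose anchors has a defined Ks is an error.
#' @export
block_median_ks <- function(blocks, pairs, value = "dS") {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ks <- pairs[[value]]
  ks[!is.finite(ks)] <- NA_real_
  lookup <- setNames(ks, key(pairs$gene_a, pairs$gene_b))
  out <- blocks |>
    mutate(.ks = unname(lookup[key(.data$gene_a, .data$gene_b)])) |>
    group_by(.data$block_id, .data$species_a, .data$chr_a, .data$species_b,
             .data$chr_b, .data$orientation) |>
    summarise(
      n_anchors = n(),
      n_ks = sum(!is.na(.data$.ks)),
      median_ks = median(.data$.ks, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(out$n_ks == 0L)) {
    abort(paste0("no defined Ks for block(s): ",
                 paste(out$block_id[out$n_ks == 0L], collapse = ", ")))
  }
  arrange(out, .data$block_id)
}

#' Ks calibration intervals for whole-genome duplication events
#'
#' Validates that the closed intervals are non-overlapping within each
#' species.
#'
#' @param intervals Tibble with `species`, `event`, `lo`, `hi`.
#' @return The validated tibble, classed `wgd_calibration`.
#' @export
wgd_calibration <- function(intervals) {
  stopifnot(all(c("species", "event", "lo", "hi") %in% names(intervals)))
  if (any(intervals$lo > intervals$hi)) abort("calibration interval with lo > hi")
  for (sp in unique(intervals$species)) {
    iv <- intervals[intervals$species == sp, ]
    iv <- iv[order(iv$lo), ]
    if (nrow(iv) > 1L && any(iv$lo[-1] <= iv$hi[-nrow(iv)])) {
      abort(paste0("overlapping calibration intervals for species ", sp))
    }
  }
  structure(as_tibble(intervals), class = c("wgd_calibration", class(as_tibble(intervals))))
}

#' Default Ks calibration
#'
#' Ships the published block median-Ks ranges: the salicoid P duplication
#' (0.2437-0.3345) and the gamma triplication (1.2633-1.7896) for Populus,
#' and the alpha duplication (0.783-0.881) for Arabidopsis.
#'
#' @return A [wgd_calibration()] object.
#' @export
default_wgd_calibration <- function() {
  wgd_calibration(tibble(
    species = c("Populus", "Populus", "Arabidopsis"),
    event = c("P-WGD", "gamma", "alpha"),
    lo = c(0.2437, 1.2633, 0.783),
    hi = c(0.3345, 1.7896, 0.881)
  ))
}

#' Assign a block median Ks to a whole-genome duplication event
#'
#' Returns the label of the calibration interval containing the value.
#' Values above `saturation_ks` fall in the regime where ancient events can
#' no longer be separated on Ks and get `saturation_label`; values outside
#' all intervals and below saturation are unassigned (`NA`).
#'
#' @param median_ks Numeric vector of block median Ks values.
#' @param calibration A [wgd_calibration()] object.
#' @param species Species the blocks belong to (scalar or vector).
#' @param saturation_ks Ks saturation threshold (default 1.9).
#' @param saturation_label Label for saturated blocks.
#' @return Character vector of event labels (`NA` = unassigned).
#' @export
assign_wgd_event <- function(median_ks, calibration, species,
                             saturation_ks = 1.9,
                             saturation_label = "beta/gamma-indistinguishable") {
  if (!inherits(calibration, "wgd_calibration")) {
    calibration <- wgd_calibration(calibration)
  }
  species <- rep_len(species, length(median_ks))
  vapply(seq_along(median_ks), function(i) {
    iv <- calibration[calibration$species == species[i], ]
    hit <- which(median_ks[i] >= iv$lo & median_ks[i] <= iv$hi)
    if (length(hit) > 0L) return(iv$event[hit[1]])
    if (!is.na(median_ks[i]) && median_ks[i] >= saturation_ks) {
      return(saturation_label)
    }
    NA_character_
  }, character(1))
}

#' Call tandem duplicates
#'
#' A pair is a tandem duplication when both genes lie on the same chromosome
#' of the same species, their start positions are at most `window` bp apart,
#' and the supporting alignment E-value is at or below `max_evalue`.
#' Distance is start-to-start and strand-agnostic.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`, `evalue`.
#' @param genes Gene table with coordinates.
#' @param window Maximum start-to-start distance in bp (default 100 kb).
#' @param max_evalue Maximum alignment E-value (default 1e-25).
#' @return `pairs` with a logical `tandem` column.
#' @export
call_tandem <- function(pairs, genes, window = 1e5, max_evalue = 1e-25) {
  coords <- select(genes, "gene_id", "species", "chromosome", "start")
  out <- pairs |>
    left_join(rename(coords, gene_a = "gene_id", species_a = "species",
                     chr_a = "chromosome", start_a = "start"), by = "gene_a") |>
    left_join(rename(coords, gene_b = "gene_id", species_b = "species",
                     chr_b = "chromosome", start_b = "start"), by = "gene_b")
  missing <- unique(c(out$gene_a[is.na(out$start_a)],
                      out$gene_b[is.na(out$start_b)]))
  if (length(missing) > 0L) {
    abort(paste0("unplaced gene(s): ", paste(missing, collapse = ", ")))
  }
  out |>
    mutate(tandem = .data$species_a == .data$species_b &
             .data$chr_a == .data$chr_b &
             abs(.data$start_a - .data$start_b) <= window &
             .data$evalue <= max_evalue) |>
    select(-"species_a", -"chr_a", -"start_a", -"species_b", -"chr_b",
           -"start_b")
}

#' Classify the duplication mechanism of paralog pairs
#'
#' Precedence is segmental/whole-genome duplication (the pair is an anchor
#' in a collinear block; block membership is the stronger positional
#' evidence) over tandem duplication over "other".
#'
#' @param pairs Paralog-pair tibble (`gene_a`, `gene_b`).
#' @param blocks Block-anchor tibble from [find_collinear_blocks()],
#'   optionally carrying an `event` column from [assign_wgd_event()].
#' @param tandem_calls Result of [call_tandem()] on the same pairs.
#' @return `pairs` with `mechanism` in `{"SWGD","TD","OTHER"}`, `event`
#'   (SWGD only) and `block_id`.
#' @export
classify_duplication <- function(pairs, blocks, tandem_calls) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pk <- key(pairs$gene_a, pairs$gene_b)
  if (nrow(blocks) > 0L) {
    bk <- key(blocks$gene_a, blocks$gene_b)
    block_of <- setNames(blocks$block_id, bk)[!duplicated(bk)]
    event_of <- if ("event" %in% names(blocks)) {
      setNames(blocks$event, bk)[!duplicated(bk)]
    } else {
      setNames(rep(NA_character_, length(block_of)), names(block_of))
    }
  } else {
    block_of <- event_of <- setNames(character(), character())
  }
  td <- setNames(tandem_calls$tandem,
                 key(tandem_calls$gene_a, tandem_calls$gene_b))
  in_block <- pk %in% names(block_of)
  is_td <- !in_block & !is.na(td[pk]) & td[pk]
  pairs |>
    mutate(
      mechanism = dplyr::case_when(in_block ~ "SWGD", is_td ~ "TD",
                                   TRUE ~ "OTHER"),
      event = ifelse(in_block, unname(event_of[pk]), NA_character_),
      block_id = ifelse(in_block, unname(block_of[pk]), NA_character_)
    )
}

#' Expected copy-number multiplicity after a series of genome duplications
#'
#' Each whole-genome duplication doubles and each triplication triples the
#' expected copy number of an ancestral gene (e.g. two duplications after
#' the shared baseline give 4, one gives 2, none gives 1 - the 4:2:1:1
#' pattern across lineages).
#'
#' @param events Character vector over `{"duplication","triplication"}`
#'   (empty for none).
#' @return Integer multiplicity.
#' @export
expected_multiplicity <- function(events) {
  if (length(events) == 0L) return(1L)
  if (!all(events %in% c("duplication", "triplication"))) {
    abort("events must be 'duplication' or 'triplication'")
  }
  as.integer(prod(ifelse(events == "duplication", 2L, 3L)))
}
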