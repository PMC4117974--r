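#' Call paralog pairs and groups from within-species alignments
#'
#' A pair is a paralog when it aligned over more than `min_aligned`
#' nucleotide columns ("over 300 bp", read strictly) and showed at least
#' `min_identity` identity. Paralog groups are the connected components of
#' the kept pairs.
#'
#' @param alignments Within-species alignment tibble (see
#'   [align_all_pairs()]), one row per unordered pair.
#' @param min_aligned Pairs must align over strictly more than this many
#'   columns (default 300).
#' @param min_identity Minimum identity fraction (default 0.40).
#' @return Tibble with `gene_a`, `gene_b`, `relation = "paralog"`,
#'   `group_id`, `aligned_length`, `identity`, `score`, `evalue`. The
#'   gene-to-group membership table is attached as attribute `"groups"`
#'   (tibble `gene_id`, `group_id`).
#' @export
call_paralogs <- function(alignments, min_aligned = 300L, min_identity = 0.40) {
  kept <- alignments |>
    filter(.data$aligned_length > min_aligned,
           .data$identity >= min_identity,
           .data$query_id != .data$subject_id) |>
    mutate(
      gene_a = pmin(.data$query_id, .data$subject_id),
      gene_b = pmax(.data$query_id, .data$subject_id)
    ) |>
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)
  if (nrow(kept) == 0L) {
    out <- tibble(gene_a = character(), gene_b = character(),
                  relation = character(), group_id = integer(),
                  aligned_length = integer(), identity = double(),
                  score = double(), evalue = double())
    attr(out, "groups") <- tibble(gene_id = character(), group_id = integer())
    return(out)
  }
  g <- igraph::graph_from_data_frame(kept[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  # stable group ids: numbered by each component's lexicographically first gene
  membership <- tibble(gene_id = names(comp$membership),
                       comp = as.integer(comp$membership))
  first_gene <- membership |>
    group_by(.data$comp) |>
    summarise(first = min(.data$gene_id), .groups = "drop") |>
    arrange(.data$first) |>
    mutate(group_id = row_number())
  membership <- membership |>
    left_join(first_gene[, c("comp", "group_id")], by = "comp") |>
    select("gene_id", "group_id") |>
    arrange(.data$group_id, .data$gene_id)
  out <- kept |>
    left_join(rename(membership, gene_a = "gene_id", group_id = "group_id"),
              by = "gene_a") |>
    mutate(relation = "paralog") |>
    select("gene_a", "gene_b", "relation", "group_id", "aligned_length",
           "identity", "score", "evalue") |>
    arrange(.data$group_id, .data$gene_a, .data$gene_b)
  attr(out, "groups") <- membership
  out
}

#' Gene-to-group membership of called paralogs
#'
#' @param paralogs Result of [call_paralogs()].
#' @return Tibble with `gene_id`, `group_id`.
#' @export
paralog_groups <- function(paralogs) {
  attr(paralogs, "groups") %||%
    abort("paralogs must be the result of call_paralogs()")
}

best_hits <- function(hits) {
  # deterministic best hit per query: score, then identity, then aligned
  # length (all descending), then lexicographic subject id
  hits |>
    group_by(.data$query_id) |>
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
            dplyr::desc(.data$aligned_length), .data$subject_id,
            .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup()
}

#' Call orthologs by reciprocal best hit
#'
#' Genes a (species A) and b (species B) are orthologs when b is a's best
#' hit against B, a is b's best hit against A, and the supporting alignment
#' covers strictly more than `min_aligned` columns. The result is a partial
#' one-to-one matching.
#'
#' @param hits_ab Alignments of species-A queries against species B.
#' @param hits_ba Alignments of species-B queries against species A.
#' @param min_aligned Strict lower bound on aligned columns (default 300).
#' @return Tibble with `gene_a`, `gene_b`, `relation = "ortholog"`,
#'   `aligned_length`, `identity`, `score`, `evalue` (from the A-to-B hit).
#' @export
call_orthologs <- function(hits_ab, hits_ba, min_aligned = 300L) {
  empty <- tibble(gene_a = character(), gene_b = character(),
                  relation = character(), aligned_length = integer(),
                  identity = double(), score = double(), evalue = double())
  if (nrow(hits_ab) == 0L || nrow(hits_ba) == 0L) return(empty)
  ab <- best_hits(hits_ab)
  ba <- best_hits(hits_ba)
  ba_map <- setNames(ba$subject_id, ba$query_id)
  recip <- ab |>
    filter(!is.na(ba_map[.data$subject_id]),
           ba_map[.data$subject_id] == .data$query_id,
           .data$aligned_length > min_aligned)
  if (nrow(recip) == 0L) return(empty)
  recip |>
    mutate(gene_a = .data$query_id, gene_b = .data$subject_id,
           relation = "ortholog") |>
    select("gene_a", "gene_b", "relation", "aligned_length", "identity",
           "score", "evalue") |>
    arrange(.data$gene_a)
}
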