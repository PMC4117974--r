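#' Cross-species retention matrix of ancestral loci
#'
#' Reconstructs ancestral loci as the connected components of genes linked
#' by collinear-block anchors (within and between species) and scores, for
#' every locus and species, the per-copy slots:
#'
#' * `E` - a gene is present and passes the family classifier (retained
#'   member);
#' * `N` - a gene is present but fails the classifier (subfunctionalized
#'   into a non-member);
#' * `L` - a chromosome of the species is covered by a collinear block that
#'   spans the locus, but carries no gene of the locus (gene lost, block
#'   retained);
#' * `B` - no block evidence at all (block lost).
#'
#' Family members that sit in no block form singleton loci. The number of
#' slots per species is the expected copy-number multiplicity (see
#' [expected_multiplicity()]), extended when more genes are present (e.g.
#' tandem copies).
#'
#' @param blocks Block-anchor tibble from [find_collinear_blocks()]
#'   (within-species and cross-species blocks together).
#' @param genes Gene table.
#' @param family_calls Family-call tibble (`protein_id`, `is_member`), e.g.
#'   from [identify_extensins()]; must cover every gene appearing in a
#'   block.
#' @param multiplicities Tibble with `species` and `multiplicity` (expected
#'   copies per ancestral locus); species not listed default to 1.
#' @param span_slack Ranks by which a block's span is extended beyond its
#'   terminal anchors when scoring loss evidence: a slot within this
#'   distance of the block would have been chained had its gene survived.
#'   Use the `max_rank_gap` of the block search (default 10).
#' @return An object of class `retention_matrix`: long tibble with
#'   `locus_id`, `species`, `slot`, `state`, `gene_id` (`NA` for `L`/`B`
#'   slots). Use [tidy()] for the long table, [retention_wide()] for a
#'   locus-by-species view, [glance()] for summary fractions.
#' @export
build_retention_matrix <- function(blocks, genes, family_calls,
                                   multiplicities, span_slack = 10L) {
  member_of <- setNames(family_calls$is_member, family_calls$protein_id)
  block_genes <- unique(c(blocks$gene_a, blocks$gene_b))
  uncovered <- setdiff(block_genes, names(member_of))
  if (length(uncovered) > 0L) {
    abort(paste0("no family call for block gene(s): ",
                 paste(uncovered, collapse = ", ")))
  }
  members <- names(member_of)[member_of]
  members <- intersect(members, genes$gene_id)
  # ancestral loci: components of the anchor graph, plus singleton loci for
  # members outside every block
  nodes <- unique(c(block_genes, members))
  if (length(nodes) == 0L) {
    return(new_retention_matrix(tibble(
      locus_id = character(), species = character(), slot = integer(),
      state = character(), gene_id = character()
    )))
  }
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(length(nodes), name = nodes)
  if (nrow(blocks) > 0L) {
    g <- igraph::add_edges(g, rbind(match(blocks$gene_a, nodes),
                                    match(blocks$gene_b, nodes)))
  }
  comp <- igraph::components(g)
  membership <- tibble(gene_id = nodes, comp = as.integer(comp$membership))
  locus_ids <- membership |>
    group_by(.data$comp) |>
    summarise(first = min(.data$gene_id), .groups = "drop") |>
    arrange(.data$first) |>
    mutate(locus_id = sprintf("locus%03d", row_number()))
  membership <- left_join(membership, locus_ids[, c("comp", "locus_id")],
                          by = "comp")
  coords <- select(genes, "gene_id", "species", "chromosome", "rank")
  placed <- membership |>
    left_join(coords, by = "gene_id") |>
    filter(!is.na(.data$species))
  # present slots
  present <- placed |>
    mutate(state = ifelse(unname(member_of[.data$gene_id]), "E", "N"))
  # loss evidence: a block whose span on one side contains a gene of the
  # locus while its span on the other side contains none
  loss <- block_loss_evidence(blocks, placed, span_slack)
  all_species <- unique(genes$species)
  mult <- setNames(rep(1L, length(all_species)), all_species)
  if (!is.null(multiplicities)) {
    mult[multiplicities$species] <- as.integer(multiplicities$multiplicity)
  }
  rows <- list()
  for (loc in sort(unique(membership$locus_id))) {
    pres <- present[present$locus_id == loc, ]
    for (sp in all_species) {
      p <- pres[pres$species == sp, ]
      p <- arrange(p, dplyr::desc(.data$state == "E"), .data$gene_id)
      lost_chroms <- loss$chromosome[loss$locus_id == loc &
                                       loss$species == sp]
      lost_chroms <- setdiff(unique(lost_chroms), p$chromosome)
      n_slots <- max(mult[[sp]], nrow(p) + length(lost_chroms))
      n_b <- max(0L, n_slots - nrow(p) - length(lost_chroms))
      states <- c(p$state, rep("L", length(lost_chroms)), rep("B", n_b))
      rows[[length(rows) + 1L]] <- tibble(
        locus_id = loc, species = sp, slot = seq_along(states),
        state = states,
        gene_id = c(p$gene_id, rep(NA_character_,
                                   length(states) - nrow(p)))
      )
    }
  }
  new_retention_matrix(bind_rows(rows))
}

# for every (block, side) pair: loci with a gene inside the span on one
# side but absent from the span on the other side
block_loss_evidence <- function(blocks, placed, span_slack = 10L) {
  empty <- tibble(locus_id = character(), species = character(),
                  chromosome = character())
  if (nrow(blocks) == 0L) return(empty)
  spans <- blocks |>
    group_by(.data$block_id) |>
    summarise(
      species_a = .data$species_a[1], chr_a = .data$chr_a[1],
      lo_a = min(.data$rank_a) - span_slack,
      hi_a = max(.data$rank_a) + span_slack,
      species_b = .data$species_b[1], chr_b = .data$chr_b[1],
      lo_b = min(.data$rank_b) - span_slack,
      hi_b = max(.data$rank_b) + span_slack,
      .groups = "drop"
    )
  out <- list()
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    in_a <- placed$species == s$species_a & placed$chromosome == s$chr_a &
      placed$rank >= s$lo_a & placed$rank <= s$hi_a
    in_b <- placed$species == s$species_b & placed$chromosome == s$chr_b &
      placed$rank >= s$lo_b & placed$rank <= s$hi_b
    loci_a <- unique(placed$locus_id[in_a])
    loci_b <- unique(placed$locus_id[in_b])
    only_a <- setdiff(loci_a, loci_b)
    only_b <- setdiff(loci_b, loci_a)
    if (length(only_a) > 0L) {
      out[[length(out) + 1L]] <- tibble(locus_id = only_a,
                                        species = s$species_b,
                                        chromosome = s$chr_b)
    }
    if (length(only_b) > 0L) {
      out[[length(out) + 1L]] <- tibble(locus_id = only_b,
                                        species = s$species_a,
                                        chromosome = s$chr_a)
    }
  }
  if (length(out) == 0L) return(empty)
  distinct(bind_rows(out))
}

new_retention_matrix <- function(long) {
  structure(long, class = c("retention_matrix", class(long)))
}

#' @export
print.retention_matrix <- function(x, ...) {
  cat("Retention matrix:", length(unique(x$locus_id)), "ancestral loci x",
      length(unique(x$species)), "species\n")
  print(retention_wide(x), ...)
  invisible(x)
}

#' Locus-by-species view of a retention matrix
#'
#' @param x A `retention_matrix`.
#' @return Tibble with one row per locus and one column per species; cells
#'   concatenate the slot states (e.g. `"EENL"`).
#' @export
retention_wide <- function(x) {
  as_tibble(x) |>
    group_by(.data$locus_id, .data$species) |>
    summarise(states = paste(.data$state, collapse = ""), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "states")
}

#' @describeIn build_retention_matrix Long slot table of a
#'   `retention_matrix`.
#' @param x A `retention_matrix`.
#' @param ... Unused.
#' @export
tidy.retention_matrix <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @describeIn build_retention_matrix State counts and the fraction of
#'   paleopolyploidy-derived duplicate slots that were subfunctionalized
#'   (`N`) or lost (`L`/`B`).
#' @export
glance.retention_matrix <- function(x, ...) {
  n <- table(factor(x$state, levels = c("E", "N", "L", "B")))
  tibble(
    n_loci = length(unique(x$locus_id)),
    n_slots = nrow(x),
    n_E = as.integer(n[["E"]]), n_N = as.integer(n[["N"]]),
    n_L = as.integer(n[["L"]]), n_B = as.integer(n[["B"]]),
    frac_subfun_or_lost_gene = (n[["N"]] + n[["L"]]) /
      max(1L, n[["E"]] + n[["N"]] + n[["L"]]),
    frac_not_retained = (n[["N"]] + n[["L"]] + n[["B"]]) / max(1L, nrow(x))
  )
}

#' Tile plot of a retention matrix
#'
#' @param object A `retention_matrix`.
#' @param ... Unused.
#' @return A ggplot with loci on y, species/slot on x, coloured by state.
#' @export
autoplot.retention_matrix <- function(object, ...) {
  df <- as_tibble(unclass(object)) |>
    mutate(col = paste0(.data$species, ".", .data$slot))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$locus_id,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(E = "#1b9e77", N = "#d95f02",
                                          L = "#7570b3", B = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
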