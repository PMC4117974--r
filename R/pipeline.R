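#' Run the full retention/expansion pipeline
#'
#' Orchestrates every stage end-to-end: family identification (SP3/SP4
#' motif scan), within-species all-against-all alignment and paralog
#' calling, cross-species reciprocal-best-hit ortholog calling, NG86
#' dN/dS/Ks estimation for every homolog pair, median-Ks clustering and
#' dating of each paralog group, collinear-block detection with median-Ks
#' event assignment, tandem-duplication calling, duplication-mechanism
#' classification, and the cross-species retention matrix. The run is a
#' pure function of its inputs and settings: identical inputs give
#' byte-identical outputs.
#'
#' @param genes Gene table for all species (see [read_gff3()] /
#'   [assign_gene_ranks()]).
#' @param cds Tibble with `gene_id`, `seq` (in-frame CDS) covering every
#'   gene.
#' @param annotations Optional domain-annotation tibble.
#' @param min_repeats,require_domain Family-classifier settings (see
#'   [identify_extensins()]).
#' @param scoring Nucleotide [scoring_scheme()] for the all-against-all
#'   search.
#' @param min_aligned,min_identity Paralog thresholds (see
#'   [call_paralogs()]).
#' @param td_window,td_max_evalue Tandem-duplication rule (see
#'   [call_tandem()]).
#' @param min_anchors,max_rank_gap Collinearity settings (see
#'   [find_collinear_blocks()]).
#' @param calibration [wgd_calibration()] mapping block median Ks to
#'   events.
#' @param species_events Named list: for each species, a character vector
#'   over `{"duplication","triplication"}` of its paleopolyploidies since
#'   the common baseline (drives expected slot multiplicities).
#' @param lambda Neutral rate for dating.
#' @param baseline_species Optional species used as the denominator of the
#'   member-count ratio line.
#' @param anchors Optional precomputed anchor tibble (`gene_a`, `gene_b`,
#'   optional `ks`), e.g. from [read_anchor_table()]; when given it
#'   replaces the internally derived anchors (and its `ks` replaces NG86
#'   Ks for block medians when present).
#' @param out_dir Optional directory; when given, all report files are
#'   written there (membership, tallies, paralogs, orthologs, dN/dS,
#'   blocks, duplication calls, retention matrix, per-group Newick/node
#'   tables, and a JSON manifest of every threshold used).
#' @return Object of class `paleofam_run`: list with `membership`,
#'   `paralogs`, `orthologs`, `dnds`, `trees`, `blocks`, `block_stats`,
#'   `duplication_calls`, `retention`, `counts` (when `baseline_species`
#'   given) and `manifest`.
#' @export
run_pipeline <- function(genes, cds, annotations = NULL, min_repeats = 2L,
                         require_domain = FALSE,
                         scoring = scoring_scheme(),
                         min_aligned = 300L, min_identity = 0.40,
                         td_window = 1e5, td_max_evalue = 1e-25,
                         min_anchors = 5L, max_rank_gap = 10L,
                         calibration = default_wgd_calibration(),
                         species_events = NULL, lambda = 1.5e-8,
                         baseline_species = NULL, anchors = NULL,
                         out_dir = NULL) {
  missing_cds <- setdiff(genes$gene_id, cds$gene_id)
  if (length(missing_cds) > 0L) {
    abort(paste0("[identify] missing CDS for gene(s): ",
                 paste(missing_cds, collapse = ", ")))
  }
  cds <- cds |>
    filter(.data$gene_id %in% genes$gene_id) |>
    left_join(select(genes, "gene_id", "species"), by = "gene_id") |>
    arrange(.data$gene_id)

  # 1. family identification
  proteins <- cds |>
    mutate(seq = vapply(.data$seq, translate_cds, character(1),
                        USE.NAMES = FALSE))
  membership <- identify_extensins(proteins, min_repeats = min_repeats,
                                   annotations = annotations,
                                   require_domain = require_domain)
  tallies <- if (!is.null(annotations)) tally_by_domain(membership) else NULL

  # 2. homology within and between species
  species <- sort(unique(genes$species))
  by_sp <- split(cds[, c("gene_id", "seq")], cds$species)
  paralogs <- list()
  for (sp in species) {
    hits <- align_all_pairs(by_sp[[sp]], scoring = scoring)
    p <- call_paralogs(hits, min_aligned = min_aligned,
                       min_identity = min_identity)
    if (nrow(p) > 0L) {
      p$species <- sp
      p$group_id <- sprintf("%s_g%02d", sp, p$group_id)
      paralogs[[sp]] <- p
    }
  }
  paralogs <- bind_rows(paralogs)
  orthologs <- list()
  cross_hits <- list()
  if (length(species) > 1L) {
    combos <- utils::combn(species, 2L)
    for (k in seq_len(ncol(combos))) {
      sa <- combos[1, k]; sb <- combos[2, k]
      hits_ab <- align_all_pairs(by_sp[[sa]], by_sp[[sb]], scoring = scoring)
      o <- call_orthologs(hits_ab, swap_alignments(hits_ab),
                          min_aligned = min_aligned)
      if (nrow(o) > 0L) orthologs[[paste(sa, sb)]] <- o
      ch <- filter(hits_ab, .data$aligned_length > min_aligned,
                   .data$identity >= min_identity)
      if (nrow(ch) > 0L) {
        cross_hits[[paste(sa, sb)]] <- tibble(
          gene_a = ch$query_id, gene_b = ch$subject_id,
          relation = "cross_hit", aligned_length = ch$aligned_length,
          identity = ch$identity, score = ch$score, evalue = ch$evalue
        )
      }
    }
  }
  orthologs <- bind_rows(orthologs)
  cross_hits <- bind_rows(cross_hits)

  # 3. dN/dS for every homolog pair (paralogs, cross hits; orthologs are a
  # subset of the cross hits by construction of the thresholds)
  pair_cols <- c("gene_a", "gene_b", "relation")
  all_pairs <- bind_rows(
    if (nrow(paralogs) > 0L) paralogs[, c(pair_cols, "species", "evalue")],
    if (nrow(cross_hits) > 0L) cross_hits[, c(pair_cols, "evalue")]
  )
  if (nrow(orthologs) > 0L) {
    okey <- paste(orthologs$gene_a, orthologs$gene_b)
    is_orth <- paste(all_pairs$gene_a, all_pairs$gene_b) %in% okey |
      paste(all_pairs$gene_b, all_pairs$gene_a) %in% okey
    all_pairs$relation[is_orth & all_pairs$relation == "cross_hit"] <-
      "ortholog"
  }
  dnds <- if (!is.null(all_pairs) && nrow(all_pairs) > 0L) {
    pair_dnds(all_pairs, cds)
  } else {
    NULL
  }

  # 4. median-Ks tree per paralog group
  trees <- list()
  if (nrow(paralogs) > 0L) {
    grp <- paralog_groups(paralogs)
    for (gid in unique(grp$group_id)) {
      members <- grp$gene_id[grp$group_id == gid]
      if (length(members) < 2L) next
      sub <- dnds |>
        filter(.data$gene_a %in% members, .data$gene_b %in% members)
      tree <- tryCatch(median_ks_linkage(ks_matrix(sub)),
                       error = function(e) NULL)
      if (is.null(tree)) next
      trees[[gid]] <- list(
        tree = tree,
        newick = suppressWarnings(to_newick(tree)),
        nodes = tidy(tree, lambda = lambda)
      )
    }
  }

  # 5. collinear blocks and event assignment
  anchor_ks <- NULL
  if (is.null(anchors)) {
    anchors <- bind_rows(
      if (nrow(paralogs) > 0L) paralogs[, c("gene_a", "gene_b")],
      if (nrow(cross_hits) > 0L) cross_hits[, c("gene_a", "gene_b")]
    )
  } else if ("ks" %in% names(anchors) && any(is.finite(anchors$ks))) {
    anchor_ks <- select(anchors, "gene_a", "gene_b", dS = "ks")
  }
  blocks <- find_collinear_blocks(anchors, genes, min_anchors = min_anchors,
                                  max_rank_gap = max_rank_gap)
  block_stats <- NULL
  if (nrow(blocks) > 0L) {
    ks_src <- anchor_ks %||% dnds
    block_stats <- block_median_ks(blocks, ks_src)
    block_stats <- block_stats |>
      mutate(event = ifelse(
        .data$species_a == .data$species_b,
        assign_wgd_event(.data$median_ks, calibration, .data$species_a),
        NA_character_
      ))
    blocks <- left_join(blocks,
                        block_stats[, c("block_id", "median_ks", "event")],
                        by = "block_id")
  }

  # 6. duplication mechanism per paralog pair
  dup_calls <- NULL
  if (nrow(paralogs) > 0L) {
    td <- call_tandem(paralogs[, c("gene_a", "gene_b", "evalue")], genes,
                      window = td_window, max_evalue = td_max_evalue)
    dup_calls <- classify_duplication(
      paralogs[, c("gene_a", "gene_b", "species", "group_id")],
      if (nrow(blocks) > 0L) blocks else
        tibble(gene_a = character(), gene_b = character(),
               block_id = character()),
      td
    )
  }

  # 7. retention matrix
  multiplicities <- NULL
  if (!is.null(species_events)) {
    multiplicities <- tibble(
      species = names(species_events),
      multiplicity = vapply(species_events, expected_multiplicity, integer(1))
    )
  }
  retention <- build_retention_matrix(blocks, genes, membership,
                                      multiplicities,
                                      span_slack = max_rank_gap)

  counts <- if (!is.null(baseline_species)) {
    summarize_counts(membership, baseline_species)
  } else {
    NULL
  }

  settings <- list(
    min_repeats = min_repeats, require_domain = require_domain,
    match = scoring$match, mismatch = scoring$mismatch,
    gap_open = scoring$gap_open, gap_extend = scoring$gap_extend,
    karlin_lambda = scoring$karlin_lambda, karlin_k = scoring$karlin_k,
    min_aligned = min_aligned, min_identity = min_identity,
    td_window = td_window, td_max_evalue = td_max_evalue,
    min_anchors = min_anchors, max_rank_gap = max_rank_gap,
    lambda = lambda
  )
  manifest <- c(settings, list(
    calibration = as.data.frame(calibration),
    n_genes = nrow(genes), n_species = length(species),
    package_version = as.character(utils::packageVersion("paleofam")),
    config_hash = rlang::hash(settings)
  ))

  run <- structure(list(
    membership = membership, tallies = tallies, paralogs = paralogs,
    orthologs = orthologs, dnds = dnds, trees = trees, blocks = blocks,
    block_stats = block_stats, duplication_calls = dup_calls,
    retention = retention, counts = counts, manifest = manifest
  ), class = "paleofam_run")
  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name, key = NULL) {
    if (is.null(x) || nrow(x) == 0L) return(invisible(NULL))
    write_tsv_report(x, file.path(out_dir, name),
                     key = key %||% names(x)[1])
  }
  w(run$membership, "membership.tsv", "protein_id")
  w(run$tallies, "domain_tally.tsv", c("species", "domain_id"))
  w(run$paralogs, "paralogs.tsv", c("group_id", "gene_a", "gene_b"))
  w(run$orthologs, "orthologs.tsv", c("gene_a", "gene_b"))
  w(run$dnds, "omega_ks.tsv", c("gene_a", "gene_b"))
  w(run$blocks, "blocks.tsv", c("block_id", "anchor_index"))
  w(run$duplication_calls, "duplication_calls.tsv", c("gene_a", "gene_b"))
  w(tidy(run$retention), "retention_matrix.tsv",
    c("locus_id", "species", "slot"))
  if (length(run$trees) > 0L) {
    newicks <- vapply(run$trees, `[[`, character(1), "newick")
    writeLines(paste0(names(newicks), "\t", newicks),
               file.path(out_dir, "group_trees.newick.tsv"))
    nodes <- bind_rows(lapply(run$trees, `[[`, "nodes"), .id = "group_id")
    w(nodes, "group_tree_nodes.tsv", c("group_id", "node_id"))
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.paleofam_run <- function(x, ...) {
  cat("paleofam pipeline run\n")
  cat("  members:", sum(x$membership$is_member), "of",
      nrow(x$membership), "genes\n")
  cat("  paralog pairs:", if (is.null(x$paralogs)) 0 else nrow(x$paralogs),
      " ortholog pairs:", if (is.null(x$orthologs)) 0 else nrow(x$orthologs),
      "\n")
  cat("  blocks:",
      if (is.null(x$block_stats)) 0 else nrow(x$block_stats), "\n")
  invisible(x)
}

#' @describeIn run_pipeline One-row summary of a pipeline run.
#' @param x A `paleofam_run`.
#' @param ... Unused.
#' @export
glance.paleofam_run <- function(x, ...) {
  tibble(
    n_genes = x$manifest$n_genes,
    n_species = x$manifest$n_species,
    n_members = sum(x$membership$is_member),
    n_paralog_pairs = if (is.null(x$paralogs)) 0L else nrow(x$paralogs),
    n_ortholog_pairs = if (is.null(x$orthologs)) 0L else nrow(x$orthologs),
    n_blocks = if (is.null(x$block_stats)) 0L else nrow(x$block_stats),
    n_loci = length(unique(x$retention$locus_id))
  )
}

#' Member counts per species with a baseline ratio line
#'
#' Divides each species' family-member count by the count of the baseline
#' species, rounded to one decimal (the "9.2 : 7.4 : 3.6 : 1" style
#' comparison of observed versus expected multiplicity).
#'
#' @param membership Family-call tibble with `species` and `is_member`.
#' @param baseline_species Species used as denominator; must have at least
#'   one member.
#' @return Tibble with `species`, `n_members`, `ratio`, ordered by
#'   decreasing count; the formatted ratio line is in attribute
#'   `"ratio_line"`.
#' @export
summarize_counts <- function(membership, baseline_species) {
  counts <- membership |>
    group_by(.data$species) |>
    summarise(n_members = sum(.data$is_member), .groups = "drop")
  base <- counts$n_members[counts$species == baseline_species]
  if (length(base) == 0L) {
    abort(paste0("baseline species not present: ", baseline_species))
  }
  if (base == 0L) {
    abort(paste0("baseline species has zero members: ", baseline_species))
  }
  out <- counts |>
    mutate(ratio = round(.data$n_members / base, 1)) |>
    arrange(dplyr::desc(.data$n_members), .data$species)
  attr(out, "ratio_line") <- paste(
    sub("\\.?0+$", "", sprintf("%.1f", out$ratio)), collapse = " : "
  )
  out
}
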