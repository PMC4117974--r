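#' Expected pairwise Ks for a given divergence time
#'
#' Two sequences that split t years ago accumulate `2 * lambda * t`
#' synonymous substitutions per synonymous site (the same clock inverted by
#' [date_duplication()]).
#'
#' @param t Divergence time in years (>= 0).
#' @param lambda Neutral rate per site per year.
#' @return Expected Ks.
#' @export
expected_pairwise_ks <- function(t, lambda = 1.5e-8) {
  if (any(t < 0)) abort("t must be non-negative")
  2 * lambda * t
}

#' Simulation configuration
#'
#' Defines the study conditions for the forward simulator: a lineage tree
#' with split times, whole-genome duplication/triplication events placed on
#' branches, per-duplicate fate probabilities, tandem-duplication and loss
#' rates, and the sequence model (synonymous rate `lambda`, nonsynonymous
#' rate `omega * lambda`; the family-defining motif evolves only
#' synonymously in retained genes, so that subfunctionalization is the only
#' motif-destroying process).
#'
#' The default emulates three lineages with a shared whole-genome
#' duplication at 50 My on the common stem and a second, A-specific one at
#' 10 My (expected copy multiplicity 4:2:2), splits at 45 My (C) and 30 My
#' (A vs B), and a 60 My-old ancestral family of 24 loci.
#'
#' @param tree Nested list: a node is `list(name, age)` for tips
#'   (`age = 0`) or `list(name, age, children)` for splits; `age` is years
#'   before present.
#' @param root_age Start of the simulation (stem above the root node).
#' @param events Tibble with `lineage` (node name of the branch), `type`
#'   (`"duplication"` or `"triplication"`), `time` (years before present)
#'   and `label`.
#' @param n_ancestral Ancestral family size.
#' @param n_codons Codons per gene.
#' @param motif_repeats SP3/SP4 units per ancestral gene.
#' @param gene_spacing Distance between gene starts on a chromosome (bp).
#' @param p_retain,p_subfun Per-duplicate probabilities of being retained
#'   as a member / subfunctionalized (motif destroyed); the remainder is
#'   lost at the duplication.
#' @param loss_rate Ongoing per-gene loss rate per year.
#' @param td_rate Per-gene tandem-duplication rate per year.
#' @param td_offset Range (bp) of the start-to-start offset of a tandem
#'   copy.
#' @param lambda Synonymous substitution rate per site per year.
#' @param omega dN/dS governing the nonsynonymous rate.
#' @param seed RNG seed used by [simulate_dataset()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(tree = NULL, root_age = 60e6, events = NULL,
                       n_ancestral = 24L, n_codons = 300L,
                       motif_repeats = 4L, gene_spacing = 20000L,
                       p_retain = 0.55, p_subfun = 0.25, loss_rate = 0,
                       td_rate = 1e-9, td_offset = c(1000L, 19000L),
                       lambda = 1.5e-8, omega = 0.15, seed = 1L) {
  if (is.null(tree)) {
    tree <- list(name = "rosid", age = 45e6, children = list(
      list(name = "AB", age = 30e6, children = list(
        list(name = "A", age = 0),
        list(name = "B", age = 0)
      )),
      list(name = "C", age = 0)
    ))
  }
  if (is.null(events)) {
    events <- tibble(
      lineage = c("rosid", "A"),
      type = c("duplication", "duplication"),
      time = c(50e6, 10e6),
      label = c("WGD50", "WGD10")
    )
  }
  stopifnot(p_retain >= 0, p_subfun >= 0, p_retain + p_subfun <= 1,
            loss_rate >= 0, td_rate >= 0, lambda > 0, omega >= 0,
            root_age > 0, n_ancestral >= 1L)
  if (motif_repeats < 2L) {
    warn("motif_repeats < 2: ancestral genes will not classify as members")
  }
  cfg <- list(tree = tree, root_age = root_age, events = events,
              n_ancestral = as.integer(n_ancestral),
              n_codons = as.integer(n_codons),
              motif_repeats = as.integer(motif_repeats),
              gene_spacing = as.integer(gene_spacing),
              p_retain = p_retain, p_subfun = p_subfun,
              loss_rate = loss_rate, td_rate = td_rate,
              td_offset = as.integer(td_offset), lambda = lambda,
              omega = omega, seed = as.integer(seed))
  validate_sim_events(cfg)
  structure(cfg, class = "sim_config")
}

node_names <- function(node) {
  c(node$name, unlist(lapply(node$children %||% list(), node_names)))
}

validate_sim_events <- function(cfg) {
  branch_top <- function(node, parent_age) {
    out <- setNames(list(c(top = parent_age, bottom = node$age)), node$name)
    for (ch in node$children %||% list()) {
      out <- c(out, branch_top(ch, node$age))
    }
    out
  }
  branches <- branch_top(cfg$tree, cfg$root_age)
  ev <- cfg$events
  for (i in seq_len(nrow(ev))) {
    if (!ev$type[i] %in% c("duplication", "triplication")) {
      abort(paste0("unknown event type: ", ev$type[i]))
    }
    br <- branches[[ev$lineage[i]]]
    if (is.null(br)) abort(paste0("unknown event lineage: ", ev$lineage[i]))
    if (ev$time[i] >= br[["top"]] || ev$time[i] > cfg$root_age) {
      abort(paste0("event ", ev$label[i], " at ", ev$time[i],
                   " exceeds the age of its lineage branch"))
    }
    if (ev$time[i] < br[["bottom"]]) {
      abort(paste0("event ", ev$label[i], " postdates the end of branch ",
                   ev$lineage[i]))
    }
  }
  invisible(cfg)
}

## ---- codon-level mutation machinery ---------------------------------------

sim_tables <- function() {
  if (!is.null(.paleofam_env$sim)) return(.paleofam_env$sim)
  codons <- all_codons()
  aa <- codon_aa(codons)
  is_stop <- codons %in% STOP_CODONS
  idx_of <- setNames(seq_along(codons), codons)
  syn_targets <- vector("list", 64)
  nonsyn_targets <- vector("list", 64)
  for (i in seq_along(codons)) {
    if (is_stop[i]) {
      syn_targets[[i]] <- integer()
      nonsyn_targets[[i]] <- integer()
      next
    }
    nb <- codon_neighbors(codons[i])
    nb_idx <- idx_of[nb]
    viable <- !is_stop[nb_idx] # stop-creating changes are lethal
    syn <- viable & aa[nb_idx] == aa[i]
    syn_targets[[i]] <- unname(nb_idx[syn])
    nonsyn_targets[[i]] <- unname(nb_idx[viable & !syn])
  }
  aa_codons <- split(seq_along(codons)[!is_stop], aa[!is_stop])
  # four-fold degenerate codon boxes (third position free): founder codons
  # are drawn from these so synonymous sites follow the four-state site
  # model that the Jukes-Cantor correction assumes
  fourfold <- list()
  for (p in unique(substr(codons, 1, 2))) {
    box <- which(substr(codons, 1, 2) == p)
    if (length(unique(aa[box])) == 1L && !any(is_stop[box])) {
      fourfold[[aa[box][1]]] <- box
    }
  }
  .paleofam_env$sim <- list(
    codons = codons, aa = aa, idx_of = idx_of,
    syn_targets = syn_targets, nonsyn_targets = nonsyn_targets,
    n_syn = lengths(syn_targets), n_nonsyn = lengths(nonsyn_targets),
    aa_codons = aa_codons, fourfold = fourfold
  )
  .paleofam_env$sim
}

codons_to_string <- function(idx) {
  paste(sim_tables()$codons[idx], collapse = "")
}

protein_of <- function(idx) {
  paste(sim_tables()$aa[idx], collapse = "")
}

# continuous-time evolution of one coding sequence for t years; protected
# codons accept only synonymous changes; with count_events = TRUE the
# realized event tallies are returned alongside the sequence
evolve_seq <- function(codons, protected, t, lambda, omega,
                       count_events = FALSE) {
  tabs <- sim_tables()
  rs <- lambda * tabs$n_syn[codons] / 3
  rn <- (omega * lambda) * tabs$n_nonsyn[codons] / 3
  rn[protected] <- 0
  total <- sum(rs) + sum(rn)
  elapsed <- 0
  n_syn_events <- 0L
  n_nonsyn_events <- 0L
  repeat {
    if (total <= 0) break
    elapsed <- elapsed + rexp(1, total)
    if (elapsed > t) break
    rate_i <- rs + rn
    i <- sample.int(length(codons), 1L, prob = rate_i)
    syn <- runif(1) < rs[i] / rate_i[i]
    if (syn) n_syn_events <- n_syn_events + 1L else
      n_nonsyn_events <- n_nonsyn_events + 1L
    targets <- if (syn) tabs$syn_targets[[codons[i]]] else
      tabs$nonsyn_targets[[codons[i]]]
    codons[i] <- targets[sample.int(length(targets), 1L)]
    total <- total - rs[i] - rn[i]
    rs[i] <- lambda * tabs$n_syn[codons[i]] / 3
    rn[i] <- if (protected[i]) 0 else
      (omega * lambda) * tabs$n_nonsyn[codons[i]] / 3
    total <- total + rs[i] + rn[i]
  }
  if (count_events) {
    return(list(codons = codons, n_syn_events = n_syn_events,
                n_nonsyn_events = n_nonsyn_events))
  }
  codons
}

random_codon_for <- function(aa_vec) {
  tabs <- sim_tables()
  vapply(aa_vec, function(a) {
    ch <- tabs$fourfold[[a]] %||% tabs$aa_codons[[a]]
    ch[sample.int(length(ch), 1L)]
  }, integer(1), USE.NAMES = FALSE)
}

motif_codon_positions <- function(codons) {
  scan <- scan_sp_repeats(protein_of(codons))
  pos <- integer()
  if (scan$repeat_count > 0L) {
    for (i in seq_len(nrow(scan$spans))) {
      pos <- c(pos, seq(scan$spans$start[i] + 1L, scan$spans$end[i]))
    }
  }
  pos
}

destroy_motif <- function(codons) {
  # subfunctionalization: the serine anchoring each repeat unit is replaced
  # (S -> A), which takes the repeat count to zero
  scan <- scan_sp_repeats(protein_of(codons))
  if (scan$repeat_count == 0L) return(codons)
  ala <- sim_tables()$idx_of[["GCA"]]
  codons[scan$spans$start + 1L] <- ala
  codons
}

## ---- genome construction and branching ------------------------------------

new_sim_env <- function() {
  e <- new.env(parent = emptyenv())
  e$uid <- 0L
  e$truth <- list()
  e
}

next_uid <- function(env) {
  env$uid <- env$uid + 1L
  env$uid
}

record_truth <- function(env, gene, lineage, fate) {
  env$truth[[length(env$truth) + 1L]] <- list(
    uid = gene$uid, parent_uid = gene$parent_uid,
    birth_time = gene$birth_time, birth_event = gene$birth_event,
    lineage = lineage, locus = gene$locus, chromosome = gene$chrom,
    fate = fate
  )
}

ancestral_genome <- function(cfg, env) {
  tabs <- sim_tables()
  unit_len <- function(k) if (k %% 2L == 1L) 4L else 5L # alternate SP3/SP4
  lapply(seq_len(cfg$n_ancestral), function(i) {
    units <- vapply(seq_len(cfg$motif_repeats), unit_len, integer(1))
    n_fill <- cfg$n_codons - sum(units)
    if (n_fill < cfg$motif_repeats + 1L) {
      abort("n_codons too small for the motif template")
    }
    # filler residues exclude proline (no spurious SP3 runs) and are drawn
    # from amino acids with four-fold degenerate codon boxes, keeping the
    # synonymous site structure consistent with the Jukes-Cantor model
    fill_alpha <- setdiff(names(tabs$fourfold), "P")
    cuts <- sort(sample.int(n_fill - 1L, cfg$motif_repeats))
    seg_len <- diff(c(0L, cuts, n_fill))
    aa <- character()
    for (k in seq_along(seg_len)) {
      aa <- c(aa, sample(fill_alpha, seg_len[k], replace = TRUE))
      if (k <= length(units)) {
        aa <- c(aa, "S", rep("P", units[k] - 1L))
      }
    }
    codons <- random_codon_for(aa)
    gene <- list(
      uid = next_uid(env), chrom = "chr1",
      pos = as.numeric((i - 1L) * cfg$gene_spacing),
      locus = sprintf("anc%03d", i),
      codons = codons,
      protected = seq_along(codons) %in% motif_codon_positions(codons),
      intact = TRUE, birth_time = cfg$root_age, parent_uid = NA_integer_,
      birth_event = "ancestral"
    )
    record_truth(env, gene, "root", "alive")
    gene
  })
}

duplicate_gene <- function(gene, env, chrom, birth_event, birth_time,
                           pos = gene$pos) {
  g <- gene
  g$uid <- next_uid(env)
  g$parent_uid <- gene$uid
  g$chrom <- chrom
  g$pos <- pos
  g$birth_event <- birth_event
  g$birth_time <- birth_time
  g
}

draw_fate <- function(cfg) {
  u <- runif(1)
  if (u < cfg$p_retain) "retained"
  else if (u < cfg$p_retain + cfg$p_subfun) "subfunctionalized"
  else "lost"
}

apply_duplicate_fate <- function(gene, cfg, env, lineage) {
  fate <- draw_fate(cfg)
  if (fate == "lost") {
    record_truth(env, gene, lineage, "lost")
    return(NULL)
  }
  if (fate == "subfunctionalized") {
    gene$codons <- destroy_motif(gene$codons)
    gene$protected <- rep(FALSE, length(gene$codons))
    gene$intact <- FALSE
  }
  record_truth(env, gene, lineage, "alive")
  gene
}

apply_wgd <- function(genome, event, cfg, env, lineage) {
  n_copies <- if (event$type == "triplication") 2L else 1L
  new_genes <- list()
  for (d in seq_len(n_copies)) {
    suffix <- paste0("_", event$label, if (d == 2L) "b" else "")
    for (gene in genome) {
      copy <- duplicate_gene(gene, env, chrom = paste0(gene$chrom, suffix),
                             birth_event = event$label,
                             birth_time = event$time)
      copy <- apply_duplicate_fate(copy, cfg, env, lineage)
      if (!is.null(copy)) new_genes[[length(new_genes) + 1L]] <- copy
    }
  }
  c(genome, new_genes)
}

# evolve one gene from t_from down to t_to, spawning tandem copies and
# applying ongoing loss; returns a list of surviving gene records
evolve_gene <- function(gene, t_from, t_to, cfg, env, lineage) {
  jump_rate <- cfg$td_rate + cfg$loss_rate
  if (jump_rate > 0) {
    t_event <- t_from - rexp(1, jump_rate)
    if (t_event > t_to) {
      gene$codons <- evolve_seq(gene$codons, gene$protected,
                                t_from - t_event, cfg$lambda, cfg$omega)
      if (runif(1) < cfg$loss_rate / jump_rate) {
        record_truth(env, gene, lineage, "lost")
        return(list())
      }
      offset <- sample(seq(cfg$td_offset[1], cfg$td_offset[2]), 1L)
      copy <- duplicate_gene(gene, env, chrom = gene$chrom,
                             birth_event = "TD", birth_time = t_event,
                             pos = gene$pos + offset)
      copy <- apply_duplicate_fate(copy, cfg, env, lineage)
      out <- evolve_gene(gene, t_event, t_to, cfg, env, lineage)
      if (!is.null(copy)) {
        out <- c(out, evolve_gene(copy, t_event, t_to, cfg, env, lineage))
      }
      return(out)
    }
  }
  gene$codons <- evolve_seq(gene$codons, gene$protected, t_from - t_to,
                            cfg$lambda, cfg$omega)
  list(gene)
}

evolve_branch <- function(genome, node, t_top, cfg, env) {
  ev <- cfg$events[cfg$events$lineage == node$name, , drop = FALSE]
  ev <- ev[order(-ev$time), , drop = FALSE]
  t <- t_top
  apply_seg <- function(genome, t1, t2) {
    unlist(lapply(genome, evolve_gene, t_from = t1, t_to = t2, cfg = cfg,
                  env = env, lineage = node$name),
           recursive = FALSE)
  }
  for (i in seq_len(nrow(ev))) {
    genome <- apply_seg(genome, t, ev$time[i])
    genome <- apply_wgd(genome, ev[i, ], cfg, env, node$name)
    t <- ev$time[i]
  }
  genome <- apply_seg(genome, t, node$age)
  genome
}

copy_genome_for_child <- function(genome, child_name, split_time, env) {
  lapply(genome, function(gene) {
    g <- duplicate_gene(gene, env, chrom = gene$chrom,
                        birth_event = "speciation",
                        birth_time = split_time)
    record_truth(env, g, child_name, "alive")
    g
  })
}

## ---- top-level simulation --------------------------------------------------

#' Generate an ancestral gene family
#'
#' Builds `n_genes` coding sequences on a linear ancestral chromosome, each
#' encoding a protein with exactly `motif_repeats` SP3/SP4 units (units
#' alternate SP3 and SP4; filler residues exclude proline so no further
#' units can arise by chance), genes spaced `gene_spacing` bp apart.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_codons Codons per gene.
#' @param motif_repeats Repeat units per gene (< 2 triggers a warning since
#'   such genes would not classify as members).
#' @param gene_spacing Start-to-start spacing in bp.
#' @param seed RNG seed (deterministic output).
#' @return List with `genes` (gene table, species `"ancestor"`), `cds` and
#'   `proteins` (tibbles of `gene_id`, `seq`).
#' @export
generate_ancestral_family <- function(n_genes, n_codons = 150L,
                                      motif_repeats = 3L,
                                      gene_spacing = 20000L, seed = 1L) {
  cfg <- sim_config(n_ancestral = n_genes, n_codons = n_codons,
                    motif_repeats = motif_repeats,
                    gene_spacing = gene_spacing, seed = seed)
  env <- new_sim_env()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  genome <- ancestral_genome(cfg, env)
  ids <- sprintf("anc_%03d", seq_along(genome))
  genes <- assign_gene_ranks(tibble(
    gene_id = ids, species = "ancestor",
    chromosome = vapply(genome, `[[`, character(1), "chrom"),
    start = vapply(genome, `[[`, numeric(1), "pos"),
    end = vapply(genome, `[[`, numeric(1), "pos") + 3 * n_codons,
    strand = "+"
  ))
  list(
    genes = genes,
    cds = tibble(gene_id = ids,
                 seq = vapply(genome, function(g) codons_to_string(g$codons),
                              character(1))),
    proteins = tibble(gene_id = ids,
                      seq = vapply(genome, function(g) protein_of(g$codons),
                                   character(1)))
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Simulate a multi-lineage gene-family dataset with ground truth
#'
#' Evolves the ancestral family along the configured lineage tree. At every
#' whole-genome duplication/triplication each chromosome is copied wholesale
#' (so true collinear blocks exist by construction) and every new duplicate
#' is independently retained, subfunctionalized (motif destroyed) or lost;
#' tandem duplications insert copies next to their template; substitutions
#' run as a continuous-time process with synonymous rate `lambda` and
#' nonsynonymous rate `omega * lambda` per site (stop-creating changes are
#' lethal and the defining motif of retained genes evolves only
#' synonymously). Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `paleofam_sim`: list with `genes`, `cds`,
#'   `proteins` (per-tip tibbles), `anchors` (all surviving same-locus pairs
#'   with true Ks `2*lambda*t`), `truth` (one row per gene ever created:
#'   `uid`, `parent_uid`, `gene_id`, `lineage`, `locus`, `chromosome`,
#'   `birth_event`, `birth_time`, `fate`), `truth_pairs` (surviving pairs
#'   with divergence time and true mechanism) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  env <- new_sim_env()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tips <- list()
  recurse <- function(node, genome, t_top) {
    genome <- evolve_branch(genome, node, t_top, config, env)
    if (is.null(node$children)) {
      tips[[node$name]] <<- genome
    } else {
      for (ch in node$children) {
        child_genome <- copy_genome_for_child(genome, ch$name, node$age, env)
        recurse(ch, child_genome, node$age)
      }
    }
  }
  recurse(config$tree, ancestral_genome(config, env), config$root_age)
  finalize_sim(tips, env, config)
}

finalize_sim <- function(tips, env, cfg) {
  truth <- bind_rows(lapply(env$truth, as_tibble))
  gene_rows <- list()
  seq_rows <- list()
  surviving <- tibble(uid = integer(), gene_id = character(),
                      species = character(), locus = character(),
                      intact = logical())
  for (tip in names(tips)) {
    genome <- tips[[tip]]
    ord <- order(vapply(genome, `[[`, character(1), "chrom"),
                 vapply(genome, `[[`, numeric(1), "pos"),
                 vapply(genome, `[[`, integer(1), "uid"))
    genome <- genome[ord]
    ids <- sprintf("%s_%03d", tip, seq_along(genome))
    for (k in seq_along(genome)) {
      g <- genome[[k]]
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        gene_id = ids[k], species = tip, chromosome = g$chrom,
        start = g$pos, end = g$pos + 3 * length(g$codons), strand = "+"
      )
      seq_rows[[length(seq_rows) + 1L]] <- tibble(
        gene_id = ids[k], species = tip,
        cds = codons_to_string(g$codons), protein = protein_of(g$codons)
      )
      surviving <- bind_rows(surviving, tibble(
        uid = g$uid, gene_id = ids[k], species = tip, locus = g$locus,
        intact = g$intact
      ))
    }
  }
  genes <- assign_gene_ranks(bind_rows(gene_rows))
  seqs <- bind_rows(seq_rows)
  # close out fates: surviving genes by motif integrity, the rest were lost
  truth <- truth |>
    left_join(surviving[, c("uid", "gene_id", "intact")], by = "uid") |>
    mutate(fate = dplyr::case_when(
      .data$fate == "lost" ~ "lost",
      !is.na(.data$gene_id) & .data$intact ~ "retained_member",
      !is.na(.data$gene_id) & !.data$intact ~ "subfunctionalized",
      TRUE ~ "internal"
    )) |>
    select("uid", "parent_uid", "gene_id", "lineage", "locus", "chromosome",
           "birth_event", "birth_time", "fate")
  truth_pairs <- build_truth_pairs(surviving, truth, cfg)
  anchors <- truth_pairs |>
    mutate(ks = .data$ks_true) |>
    select("gene_a", "gene_b", "ks")
  structure(list(
    genes = genes,
    cds = select(seqs, "gene_id", seq = "cds"),
    proteins = select(seqs, "gene_id", "species", seq = "protein"),
    anchors = anchors,
    truth = truth,
    truth_pairs = truth_pairs,
    config = cfg
  ), class = "paleofam_sim")
}

build_truth_pairs <- function(surviving, truth, cfg) {
  parent_of <- setNames(truth$parent_uid, truth$uid)
  birth_of <- setNames(truth$birth_time, truth$uid)
  event_of <- setNames(truth$birth_event, truth$uid)
  chain <- function(uid) {
    out <- uid
    while (!is.na(parent_of[[as.character(uid)]])) {
      uid <- parent_of[[as.character(uid)]]
      out <- c(out, uid)
    }
    out
  }
  chains <- lapply(surviving$uid, chain)
  names(chains) <- surviving$uid
  rows <- list()
  for (loc in unique(surviving$locus)) {
    gs <- surviving[surviving$locus == loc, ]
    if (nrow(gs) < 2L) next
    for (i in seq_len(nrow(gs) - 1L)) {
      for (j in seq((i + 1L), nrow(gs))) {
        c1 <- chains[[as.character(gs$uid[i])]]
        c2 <- chains[[as.character(gs$uid[j])]]
        mrca_pos1 <- match(TRUE, c1 %in% c2)
        mrca <- c1[mrca_pos1]
        below1 <- if (mrca_pos1 > 1L) c1[mrca_pos1 - 1L] else NA_integer_
        mrca_pos2 <- match(mrca, c2)
        below2 <- if (mrca_pos2 > 1L) c2[mrca_pos2 - 1L] else NA_integer_
        bt <- c(
          if (!is.na(below1)) birth_of[[as.character(below1)]] else -Inf,
          if (!is.na(below2)) birth_of[[as.character(below2)]] else -Inf
        )
        t_div <- max(bt)
        split_uid <- c(below1, below2)[which.max(bt)]
        ev <- event_of[[as.character(split_uid)]]
        mech <- if (ev == "TD") "TD"
          else if (ev == "speciation") "speciation"
          else "SWGD"
        rows[[length(rows) + 1L]] <- tibble(
          gene_a = gs$gene_id[i], gene_b = gs$gene_id[j],
          species_a = gs$species[i], species_b = gs$species[j],
          locus = loc, divergence_time = t_div,
          ks_true = expected_pairwise_ks(t_div, cfg$lambda),
          mechanism_true = mech,
          event_true = if (mech == "SWGD") ev else NA_character_
        )
      }
    }
  }
  bind_rows(rows)
}

#' @export
print.paleofam_sim <- function(x, ...) {
  cat("Simulated gene-family dataset\n")
  counts <- table(x$genes$species)
  cat("  genes per species:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  cat("  ancestral loci:", length(unique(x$truth$locus)), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated dataset to pipeline input files
#'
#' Emits, per species, CDS and protein FASTA and a GFF3, plus an anchor TSV
#' and the truth log as JSON - byte-identical in format to real inputs.
#'
#' @param sim A `paleofam_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in unique(sim$genes$species)) {
    g <- filter(sim$genes, .data$species == sp)
    write_gff3(g, file.path(dir, paste0(sp, ".gff3")))
    ids <- g$gene_id
    write_fasta(filter(sim$cds, .data$gene_id %in% ids),
                file.path(dir, paste0(sp, ".cds.fasta")))
    prot <- filter(sim$proteins, .data$gene_id %in% ids)
    write_fasta(select(prot, "gene_id", "seq"),
                file.path(dir, paste0(sp, ".protein.fasta")))
  }
  write_tsv_report(sim$anchors, file.path(dir, "anchors.tsv"),
                   key = c("gene_a", "gene_b"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(dir)
}
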