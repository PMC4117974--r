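#' Read a FASTA file into a sequence table
#'
#' Sequences are keyed by the first whitespace-delimited token of each header
#' and uppercased. Protein sequences may contain the 20 standard amino acids
#' plus `X` (a terminal `*` is stripped); CDS sequences must consist of
#' `ACGTN` and, after trimming of a terminal stop codon, have length divisible
#' by three. One sequence per gene is assumed: callers must pre-select a
#' representative isoform per gene.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"protein"` or `"dna"`.
#' @return A tibble with columns `gene_id` and `seq`, and an `"alphabet"`
#'   attribute.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicated FASTA id(s): ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (alphabet == "protein") {
    seqs <- sub("\\*$", "", seqs)
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
    if (any(bad)) {
      abort(paste0("invalid protein residue(s) in: ",
                   paste(ids[bad], collapse = ", ")))
    }
  } else {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      abort(paste0("invalid nucleotide(s) in: ", paste(ids[bad], collapse = ", ")))
    }
    seqs <- trim_terminal_stop(seqs)
    if (any(nchar(seqs) %% 3L != 0L)) {
      abort(paste0("CDS length not divisible by 3 for: ",
                   paste(ids[nchar(seqs) %% 3L != 0L], collapse = ", ")))
    }
  }
  out <- tibble(gene_id = ids, seq = seqs)
  attr(out, "alphabet") <- alphabet
  out
}

trim_terminal_stop <- function(seqs) {
  ok <- nchar(seqs) %% 3L == 0L & nchar(seqs) >= 3L
  last <- substr(seqs, nchar(seqs) - 2L, nchar(seqs))
  stopc <- ok & last %in% c("TAA", "TAG", "TGA")
  seqs[stopc] <- substr(seqs[stopc], 1L, nchar(seqs[stopc]) - 3L)
  seqs
}

#' Write a sequence table to FASTA
#'
#' @param seqs Tibble with `gene_id` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("gene_id", "seq") %in% names(seqs)))
  lines <- as.vector(rbind(paste0(">", seqs$gene_id), seqs$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Only rows whose feature type is `gene` are kept; each must carry an `ID`
#' attribute. GFF3 1-based inclusive coordinates are converted to the
#' package-internal 0-based half-open convention, and genes are ranked along
#' each chromosome by ascending start (0-based ordinal; ties broken by
#' gene id). Strand is ignored for ranking so that collinearity chaining has
#' a single linear order per chromosome.
#'
#' @param path Path to a GFF3 file.
#' @param species Species label to attach to every gene.
#' @return A gene table: tibble with columns `gene_id`, `species`,
#'   `chromosome`, `start`, `end`, `strand`, `rank`.
#' @export
read_gff3 <- function(path, species) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(assign_gene_ranks(tibble(
      gene_id = character(), species = character(), chromosome = character(),
      start = integer(), end = integer(), strand = character()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    abort(paste0("malformed GFF3 line (expected 9 columns, got ", nf[nf != 9L][1],
                 "): ", lines[nf != 9L][1]))
  }
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) abort(paste0("no gene features in ", path))
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) abort("non-numeric start/end in GFF3")
  bad <- start1 > end1
  if (any(bad)) {
    abort(paste0("GFF3 start > end for line: ", lines[keep][bad][1]))
  }
  id <- stringr::str_match(m[, 9], "(?:^|;)\\s*ID=([^;]+)")[, 2]
  if (anyNA(id)) {
    abort(paste0("GFF3 gene feature missing ID attribute: ", lines[keep][is.na(id)][1]))
  }
  genes <- tibble(
    gene_id = id, species = species, chromosome = m[, 1],
    start = start1 - 1L, end = end1, strand = m[, 7]
  )
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicated gene ID(s) in GFF3: ", paste(unique(dup), collapse = ", ")))
  }
  assign_gene_ranks(genes)
}

#' Assign per-chromosome gene ranks
#'
#' Ranks are 0-based ordinals along each `(species, chromosome)` by ascending
#' start position (ties broken by `gene_id`).
#'
#' @param genes Gene table (see [read_gff3()]); any existing `rank` column is
#'   recomputed.
#' @return The gene table with a `rank` column, sorted by species,
#'   chromosome and start.
#' @export
assign_gene_ranks <- function(genes) {
  genes |>
    arrange(.data$species, .data$chromosome, .data$start, .data$gene_id) |>
    group_by(.data$species, .data$chromosome) |>
    mutate(rank = row_number() - 1L) |>
    ungroup() |>
    select("gene_id", "species", "chromosome", "start", "end", "strand", "rank")
}

#' Write a gene table as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3 1-based
#' inclusive coordinates.
#'
#' @param genes Gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  genes <- arrange(genes, .data$chromosome, .data$start, .data$gene_id)
  lines <- sprintf(
    "%s\tpaleofam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    genes$chromosome, genes$start + 1L, genes$end, genes$strand, genes$gene_id
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a domain-annotation table
#'
#' Expects a tab-separated file with at least three columns:
#' `protein_id`, `domain_id` (e.g. an InterPro accession such as IPR006706)
#' and `label`. Extra columns are ignored. A header line is detected by the
#' literal column name `protein_id` in the first field.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `protein_id`, `domain_id`, `label`.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) abort(paste0("domain table not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble(protein_id = character(), domain_id = character(),
                  label = character())
  if (length(lines) == 0L) return(empty)
  if (grepl("^protein_id\\b", lines[1])) lines <- lines[-1]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(paste0("domain table row has fewer than 3 columns: ", lines[nf < 3L][1]))
  }
  out <- tibble(
    protein_id = vapply(fields, `[[`, character(1), 1L),
    domain_id = vapply(fields, `[[`, character(1), 2L),
    label = vapply(fields, `[[`, character(1), 3L)
  )
  if (any(!nzchar(out$domain_id))) {
    abort(paste0("empty domain_id for protein: ",
                 out$protein_id[!nzchar(out$domain_id)][1]))
  }
  out
}

#' Read a precomputed homolog-anchor table
#'
#' Tab-separated with columns `gene_a`, `gene_b` and optionally `ks`, so that
#' anchor pairs from an external homology search (or the simulator) can be
#' fed straight into [find_collinear_blocks()].
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene_a`, `gene_b`, `ks` (NA when absent).
#' @export
read_anchor_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(out))) {
    abort("anchor table must have columns gene_a, gene_b")
  }
  if (!"ks" %in% names(out)) out$ks <- NA_real_
  select(out, "gene_a", "gene_b", "ks")
}

#' Write a deterministic TSV report
#'
#' Writes a header plus one row per record, sorted by the given key column(s)
#' so that re-runs on the same input are byte-identical. List columns are
#' collapsed with `,`.
#'
#' @param records A data frame of homogeneous records.
#' @param path Output path.
#' @param key Column name(s) to sort by; defaults to the first column.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(records, path, key = names(records)[1]) {
  records <- as_tibble(records)
  for (nm in names(records)) {
    if (is.list(records[[nm]])) {
      records[[nm]] <- vapply(
        records[[nm]],
        function(x) paste(sort(as.character(x)), collapse = ","),
        character(1)
      )
    }
  }
  if (nrow(records) > 0L && length(key) > 0L) {
    records <- arrange(records, across(all_of(key)))
  }
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}
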