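#' Scan a protein for Ser-Pro(3+) repeat units
#'
#' Extensins are operationally defined by repeats of Ser-Pro-Pro-Pro (SP3)
#' and/or Ser-Pro-Pro-Pro-Pro (SP4). Hydroxyproline is post-translational, so
#' genomic protein sequences carry plain proline. Each maximal run matching
#' `S` followed by three or more `P` counts as exactly one repeat unit
#' (`"SPPPPPP"` is one unit, not several overlapping ones); scanning is
#' left-to-right and units never overlap.
#'
#' @param protein A single amino-acid string (20 standard residues plus `X`).
#' @return A list with `repeat_count` and `spans`, a tibble of 0-based
#'   half-open `(start, end)` intervals, one per repeat unit.
#' @export
scan_sp_repeats <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) abort("empty protein sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", protein)) {
    abort("protein contains characters outside the amino-acid alphabet")
  }
  m <- gregexpr("SP{3,}", protein)[[1]]
  if (m[1] == -1L) {
    return(list(repeat_count = 0L,
                spans = tibble(start = integer(), end = integer())))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  list(repeat_count = length(start), spans = tibble(start = start, end = end))
}

#' Decide family membership from a repeat scan
#'
#' @param scan Result of [scan_sp_repeats()].
#' @param min_repeats Minimum number of SP3/SP4 units required (default 2).
#' @return Logical scalar.
#' @export
classify_member <- function(scan, min_repeats = 2L) {
  if (min_repeats < 1L) abort("min_repeats must be >= 1")
  scan$repeat_count >= min_repeats
}

#' Classify a protein table into family members
#'
#' Runs the SP3/SP4 repeat scan over every sequence and applies the
#' membership threshold. Domain annotations are metadata, not a membership
#' requirement, unless `require_domain = TRUE`.
#'
#' @param proteins Tibble with `gene_id` and `seq` columns (protein
#'   alphabet); an optional `species` column is carried through.
#' @param min_repeats Minimum number of repeat units for membership.
#' @param annotations Optional domain-annotation tibble (see
#'   [read_domain_table()]); when given, domain ids are attached via
#'   [attach_domains()].
#' @param require_domain When `TRUE`, membership additionally requires at
#'   least one annotated signature domain.
#' @return Tibble with columns `protein_id`, (`species`,) `repeat_count`,
#'   `is_member` and, when annotations are given, a `domain_ids` list-column.
#' @export
identify_extensins <- function(proteins, min_repeats = 2L, annotations = NULL,
                               require_domain = FALSE) {
  if (min_repeats < 1L) abort("min_repeats must be >= 1")
  counts <- vapply(proteins$seq,
                   function(s) scan_sp_repeats(s)$repeat_count,
                   integer(1), USE.NAMES = FALSE)
  calls <- tibble(
    protein_id = proteins$gene_id,
    repeat_count = counts,
    is_member = counts >= min_repeats
  )
  if ("species" %in% names(proteins)) {
    calls <- mutate(calls, species = proteins$species, .after = "protein_id")
  }
  if (!is.null(annotations)) {
    calls <- attach_domains(calls, annotations)
    if (require_domain) {
      calls <- mutate(calls,
                      is_member = .data$is_member & lengths(.data$domain_ids) > 0L)
    }
  }
  calls
}

#' Attach signature-domain ids to family calls
#'
#' @param calls Family-call tibble with a `protein_id` column.
#' @param annotations Domain-annotation tibble (`protein_id`, `domain_id`).
#' @return `calls` with a `domain_ids` list-column (sorted unique ids;
#'   proteins without annotations get an empty set). The membership decision
#'   is unchanged.
#' @export
attach_domains <- function(calls, annotations) {
  by_prot <- split(annotations$domain_id, annotations$protein_id)
  calls$domain_ids <- lapply(calls$protein_id, function(p) {
    sort(unique(by_prot[[p]] %||% character()))
  })
  calls
}

#' Tally family members by signature domain
#'
#' For each `(species, domain_id)` reports the member count and its
#' percentage of all members in that species, rounded to one decimal (e.g.
#' 18 of 46 members carrying IPR006706 gives 39.1).
#'
#' @param calls Family-call tibble with `species` and `domain_ids` columns
#'   (see [identify_extensins()]).
#' @return Tibble with `species`, `domain_id`, `n_members`, `total_members`,
#'   `percent` (NA, flagged, for species with zero members).
#' @export
tally_by_domain <- function(calls) {
  stopifnot(all(c("species", "domain_ids") %in% names(calls)))
  totals <- calls |>
    group_by(.data$species) |>
    summarise(total_members = sum(.data$is_member), .groups = "drop")
  members <- filter(calls, .data$is_member)
  long <- members |>
    select("species", "protein_id", "domain_ids") |>
    tidyr::unnest_longer("domain_ids", values_to = "domain_id") |>
    filter(!is.na(.data$domain_id))
  tallied <- long |>
    group_by(.data$species, .data$domain_id) |>
    summarise(n_members = dplyr::n_distinct(.data$protein_id), .groups = "drop") |>
    left_join(totals, by = "species") |>
    mutate(
      percent = ifelse(.data$total_members > 0L,
                       round(100 * .data$n_members / .data$total_members, 1),
                       NA_real_),
      undefined = .data$total_members == 0L
    )
  arrange(tallied, .data$species, .data$domain_id)
}
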