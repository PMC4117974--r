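#' Nucleotide scoring scheme with Karlin-Altschul parameters
#'
#' The default scheme (match +1, mismatch -2, gap open -5, gap extend -2)
#' emulates a stringent BLASTN-like search. An affine gap of length L costs
#' `gap_open + L * gap_extend` (as positive penalties). `karlin_lambda` is,
#' by default, the ungapped Karlin-Altschul lambda for the match/mismatch
#' scores at uniform base composition, obtained by solving
#' sum_ij p_i p_j exp(lambda s_ij) = 1; `karlin_k` defaults to 0.1. E-values
#' from this scheme are approximate and are used as a relative significance
#' cutoff (the tandem-duplication rule), not as calibrated search statistics.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening score (<= 0).
#' @param gap_extend Gap extension score per gap column (<= 0).
#' @param karlin_lambda Karlin-Altschul lambda; computed from
#'   `match`/`mismatch` when `NULL`.
#' @param karlin_k Karlin-Altschul K.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2, karlin_lambda = NULL,
                           karlin_k = 0.1) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  if (is.null(karlin_lambda)) karlin_lambda <- karlin_lambda_ungapped(match, mismatch)
  stopifnot(karlin_lambda > 0, karlin_k > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_k = karlin_k),
            class = "scoring_scheme")
}

#' Ungapped Karlin-Altschul lambda at uniform base composition
#'
#' Solves `(1/4) exp(lambda * match) + (3/4) exp(lambda * mismatch) = 1` for
#' lambda > 0.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0); expected score must be negative.
#' @return Positive lambda.
#' @export
karlin_lambda_ungapped <- function(match, mismatch) {
  stopifnot(match > 0, mismatch < 0)
  if (match / 4 + 3 * mismatch / 4 >= 0) {
    abort("expected score must be negative for lambda to exist")
  }
  f <- function(l) exp(l * match) / 4 + 3 * exp(l * mismatch) / 4 - 1
  stats::uniroot(f, c(1e-8, 10), tol = 1e-12)$root
}

nt_substitution_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

check_nt <- function(x, what = "sequence") {
  if (!nzchar(x)) abort(paste0("empty ", what))
  if (grepl("[^ACGTN]", x)) abort(paste0("non-ACGTN characters in ", what))
}

#' Optimal local nucleotide alignment (Smith-Waterman, affine gaps)
#'
#' Identity is computed over all alignment columns including gap columns
#' (identical columns / aligned_length), a conservative convention chosen so
#' that the 40% paralog threshold is reproducible. The E-value is
#' `K * m * n * exp(-lambda * score)` with `m`, `n` the full sequence
#' lengths. When no positive-scoring local alignment exists the empty
#' alignment (score 0, length 0) is returned.
#'
#' @param a,b Nucleotide sequences (strings over ACGTN).
#' @param scoring A [scoring_scheme()].
#' @param query_id,subject_id Optional ids recorded in the result.
#' @return One-row tibble: `query_id`, `subject_id`, `score`,
#'   `aligned_length`, `identity`, `evalue`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (1-based, 0/0 for the empty alignment).
#' @export
align_local_nt <- function(a, b, scoring = scoring_scheme(),
                           query_id = NA_character_,
                           subject_id = NA_character_) {
  check_nt(a, "query"); check_nt(b, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = nt_substitution_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  sc <- Biostrings::score(pa)
  m <- nchar(a); n <- nchar(b)
  if (sc <= 0) {
    return(tibble(query_id = query_id, subject_id = subject_id, score = 0,
                  aligned_length = 0L, identity = 0,
                  evalue = scoring$karlin_k * m * n,
                  q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L))
  }
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  len <- nchar(ap)
  ident <- Biostrings::nmatch(pa) / len
  pr <- pa@pattern@range
  sr <- pa@subject@range
  tibble(
    query_id = query_id, subject_id = subject_id, score = sc,
    aligned_length = len, identity = ident,
    evalue = scoring$karlin_k * m * n * exp(-scoring$karlin_lambda * sc),
    q_start = BiocGenerics::start(pr), q_end = BiocGenerics::end(pr),
    s_start = BiocGenerics::start(sr), s_end = BiocGenerics::end(sr)
  )
}

#' Optimal global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Defaults follow a BLOSUM62 scheme with gap opening penalty 2.0 and gap
#' extension penalty 0.2 per column (an affine gap of length L costs
#' `2.0 + 0.2 * L`).
#'
#' @param a,b Protein sequences (may be empty, giving an all-gap alignment).
#' @param substitution_matrix Matrix name or matrix; default `"BLOSUM62"`.
#' @param gap_open,gap_extend Positive penalties.
#' @return List with `score`, `aligned_a`, `aligned_b` (equal-length strings
#'   with `-` gaps).
#' @export
align_global_protein <- function(a, b, substitution_matrix = "BLOSUM62",
                                 gap_open = 2.0, gap_extend = 0.2) {
  for (x in c(a, b)) {
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", x)) abort("invalid protein residue")
  }
  if (!nzchar(a) && !nzchar(b)) {
    return(list(score = 0, aligned_a = "", aligned_b = ""))
  }
  if (!nzchar(a) || !nzchar(b)) {
    len <- max(nchar(a), nchar(b))
    gaps <- strrep("-", len)
    return(list(score = -(gap_open + gap_extend * len),
                aligned_a = if (nzchar(a)) a else gaps,
                aligned_b = if (nzchar(b)) b else gaps))
  }
  if (is.character(substitution_matrix)) {
    substitution_matrix <- get_substitution_matrix(substitution_matrix)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(score = Biostrings::score(pa),
       aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)))
}

get_substitution_matrix <- function(name) {
  key <- paste0("submat_", name)
  if (is.null(.paleofam_env[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .paleofam_env[[key]] <- get(name, envir = e)
  }
  .paleofam_env[[key]]
}

#' All-against-all local nucleotide alignments
#'
#' With one sequence set, every unordered within-set pair is aligned once and
#' self-hits are excluded; with two sets, every cross pair is aligned.
#'
#' @param seqs_a Tibble with `gene_id`, `seq` (CDS).
#' @param seqs_b Optional second tibble; `NULL` for within-set search.
#' @param scoring A [scoring_scheme()].
#' @return Tibble of [align_local_nt()] rows (query from `seqs_a`).
#' @export
align_all_pairs <- function(seqs_a, seqs_b = NULL, scoring = scoring_scheme()) {
  for (s in seqs_a$seq) check_nt(s)
  if (!is.null(seqs_b)) for (s in seqs_b$seq) check_nt(s)
  if (is.null(seqs_b)) {
    n <- nrow(seqs_a)
    if (n < 2L) return(empty_alignment_tbl())
    out <- purrr::map(seq(2L, n), function(j) {
      align_set_vs_one(seqs_a[seq_len(j - 1L), , drop = FALSE],
                       seqs_a$seq[j], seqs_a$gene_id[j], scoring)
    })
  } else {
    out <- purrr::map(seq_len(nrow(seqs_b)), function(j) {
      align_set_vs_one(seqs_a, seqs_b$seq[j], seqs_b$gene_id[j], scoring)
    })
  }
  bind_rows(out)
}

# batched local alignment of a query set against one subject; queries are
# the (vectorized) pattern side, matching the orientation of
# align_local_nt() so tied-score tracebacks agree with the single-pair path
align_set_vs_one <- function(set_tbl, subject_seq, subject_id, scoring) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(set_tbl$seq),
    Biostrings::DNAString(subject_seq),
    type = "local", substitutionMatrix = nt_substitution_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  sc <- Biostrings::score(pa)
  len <- Biostrings::nchar(pa)
  ident <- Biostrings::nmatch(pa) / pmax(len, 1L)
  pr <- pa@pattern@range # span on the query (set) sequence
  sr <- pa@subject@range # span on the subject
  m <- nchar(set_tbl$seq)
  n <- nchar(subject_seq)
  out <- tibble(
    query_id = set_tbl$gene_id, subject_id = subject_id, score = sc,
    aligned_length = len, identity = ident,
    evalue = scoring$karlin_k * m * n * exp(-scoring$karlin_lambda * sc),
    q_start = BiocGenerics::start(pr), q_end = BiocGenerics::end(pr),
    s_start = BiocGenerics::start(sr), s_end = BiocGenerics::end(sr)
  )
  none <- out$score <= 0
  if (any(none)) {
    out$score[none] <- 0
    out$aligned_length[none] <- 0L
    out$identity[none] <- 0
    out$evalue[none] <- scoring$karlin_k * m[none] * n
    out$q_start[none] <- 0L
    out$q_end[none] <- 0L
    out$s_start[none] <- 0L
    out$s_end[none] <- 0L
  }
  out
}

# flip query/subject roles of an alignment table (scores are symmetric)
swap_alignments <- function(hits) {
  hits |>
    rename(query_id = "subject_id", subject_id = "query_id",
           q_start = "s_start", q_end = "s_end",
           s_start = "q_start", s_end = "q_end") |>
    select("query_id", "subject_id", "score", "aligned_length", "identity",
           "evalue", "q_start", "q_end", "s_start", "s_end")
}

empty_alignment_tbl <- function() {
  tibble(query_id = character(), subject_id = character(), score = double(),
         aligned_length = integer(), identity = double(), evalue = double(),
         q_start = integer(), q_end = integer(), s_start = integer(),
         s_end = integer())
}
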