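# Sequence-based homolog search: exact Smith-Waterman local alignment with
# affine gaps (delegated to Biostrings' dynamic programming) and
# Karlin-Altschul E-values with the standard gapped BLOSUM62 constants.

#' Default substitution matrix (BLOSUM62, X scored 0 against everything)
#'
#' @return A 21 x 21 integer matrix over the 20 standard residues plus `X`.
#' @export
default_matrix <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  m <- data_env$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

#' Karlin-Altschul parameters
#'
#' The statistics behind local-alignment E-values:
#' `E = K * m * n * exp(-lambda * S)`. Defaults are the standard published
#' gapped constants for BLOSUM62 with gap open 11 / extend 1
#' (`lambda = 0.267`, `K = 0.041`).
#'
#' @param m Query length (residues).
#' @param n Database length (total residues).
#' @param lambda Nats per score unit (> 0).
#' @param K Dimensionless prefactor (> 0).
#' @return A `karlin_params` list.
#' @export
karlin_params <- function(m, n, lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0, m >= 1, n >= 1)
  structure(list(lambda = lambda, K = K, m = m, n = n), class = "karlin_params")
}

#' E-value of a raw local-alignment score
#'
#' @param S Raw score (substitution-matrix units).
#' @param p A [karlin_params()].
#' @return The expected number of chance alignments scoring >= S.
#' @export
evalue <- function(S, p) {
  stopifnot(inherits(p, "karlin_params"))
  p$K * p$m * p$n * exp(-p$lambda * S)
}

#' Bit score of a raw score
#'
#' @inheritParams evalue
#' @return `(lambda * S - ln K) / ln 2`.
#' @export
bit_score <- function(S, p) {
  (p$lambda * S - log(p$K)) / log(2)
}

#' Optimal Smith-Waterman local alignment
#'
#' Exact affine-gap local alignment: a gap of length L costs
#' `gap_open + L * gap_extend`. `X` (and any non-standard letter, which is
#' mapped to `X`) scores 0 against everything. Empty input yields score 0
#' with an empty alignment.
#'
#' @param query,target Amino-acid sequences (character scalars).
#' @param matrix Substitution matrix (default [default_matrix()]).
#' @param gap_open,gap_extend Nonnegative gap penalties,
#'   `gap_open >= gap_extend`.
#' @return An `sw_alignment`: list with `score`, `q_start`, `q_end`,
#'   `t_start`, `t_end` (1-based inclusive; 0 when empty) and the aligned
#'   strings `q_aln`, `t_aln`.
#' @export
smith_waterman <- function(query, target, matrix = default_matrix(),
                           gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  query <- sanitize_aa(query)
  target <- sanitize_aa(target)
  if (nchar(query) == 0 || nchar(target) == 0) {
    return(sw_result(0, 0L, 0L, 0L, 0L, "", ""))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- BiocGenerics::score(pa)
  if (s <= 0) return(sw_result(max(0, s), 0L, 0L, 0L, 0L, "", ""))
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  sw_result(
    s,
    BiocGenerics::start(pat), BiocGenerics::end(pat),
    BiocGenerics::start(sub), BiocGenerics::end(sub),
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa))
  )
}

sw_result <- function(score, qs, qe, ts, te, q_aln, t_aln) {
  structure(
    list(score = score, q_start = as.integer(qs), q_end = as.integer(qe),
         t_start = as.integer(ts), t_end = as.integer(te),
         q_aln = q_aln, t_aln = t_aln),
    class = "sw_alignment"
  )
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %.1f, query %d-%d, target %d-%d\n",
              x$score, x$q_start, x$q_end, x$t_start, x$t_end))
  invisible(x)
}

#' @export
glance.sw_alignment <- function(x, ...) {
  tibble::tibble(
    score = x$score, q_start = x$q_start, q_end = x$q_end,
    t_start = x$t_start, t_end = x$t_end,
    aln_length = nchar(x$q_aln)
  )
}

sanitize_aa <- function(seq) {
  seq <- toupper(seq)
  stringr::str_replace_all(seq, sprintf("[^%s]", paste(AA20, collapse = "")), "X")
}

#' Search a proteome with a query sequence
#'
#' Aligns the query against every target, converts raw scores to
#' Karlin-Altschul E-values (database length n = total residues searched) and
#' keeps hits with `E <= cutoff`, sorted by E then target id. Self-hits are
#' retained; triage handles exclusions.
#'
#' @param query Named character scalar (or plain scalar) query sequence.
#' @param proteome Tibble with columns `id` and `seq`, or a named character
#'   vector.
#' @param cutoff E-value cutoff (default the screen's 1e-5).
#' @param matrix,gap_open,gap_extend Passed to [smith_waterman()].
#' @param lambda,K Karlin-Altschul constants.
#' @return A tibble of hits: `query`, `target`, `score`, `bits`, `evalue`,
#'   `q_start`, `q_end`, `t_start`, `t_end`.
#' @export
search_proteome <- function(query, proteome, cutoff = 1e-5,
                            matrix = default_matrix(),
                            gap_open = 11, gap_extend = 1,
                            lambda = 0.267, K = 0.041) {
  stopifnot(cutoff > 0)
  proteome <- as_proteome_tbl(proteome)
  qid <- names(query) %||% "query"
  query <- unname(query)
  empty <- tibble::tibble(
    query = character(), target = character(), score = double(),
    bits = double(), evalue = double(),
    q_start = integer(), q_end = integer(), t_start = integer(), t_end = integer()
  )
  if (nrow(proteome) == 0) return(empty)
  n_db <- sum(nchar(proteome$seq))
  p <- karlin_params(m = max(1, nchar(query)), n = max(1, n_db),
                     lambda = lambda, K = K)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(setNames(
      vapply(proteome$seq, sanitize_aa, character(1)), proteome$id
    )),
    Biostrings::AAString(sanitize_aa(query)),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- pmax(0, BiocGenerics::score(pa))
  tgt <- Biostrings::pattern(pa) # targets were passed as pattern set
  qry <- Biostrings::subject(pa)
  hits <- tibble::tibble(
    query = qid, target = proteome$id, score = s,
    bits = bit_score(s, p), evalue = evalue(s, p),
    q_start = BiocGenerics::start(qry), q_end = BiocGenerics::end(qry),
    t_start = BiocGenerics::start(tgt), t_end = BiocGenerics::end(tgt)
  )
  dplyr::bind_rows(empty, hits) |>
    dplyr::filter(.data$evalue <= cutoff) |>
    dplyr::arrange(.data$evalue, .data$target)
}

as_proteome_tbl <- function(proteome) {
  if (is.character(proteome)) {
    proteome <- tibble::tibble(id = names(proteome), seq = unname(proteome))
  }
  tibble::as_tibble(proteome)
}

#' Write / read a sequence-hit table as TSV
#'
#' @param hits Hit tibble from [search_proteome()].
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_seq_hits <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname write_seq_hits
#' @export
read_seq_hits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
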