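# Candidate triage: union the three hit sets, drop proteins already
# annotated with the excluded CAZyme family, and report the tick matrix plus
# the structure-only and all-modes sets.

#' Combine the three search modes into a candidate matrix
#'
#' Rows are the union of hit ids minus the ids annotated with
#' `excluded_family` (the family the screen already knows about: AA9 for the
#' LPMO screen, AA1 for laccases, AA2 for peroxidases). Boolean columns
#' reflect hit membership exactly; annotation columns are pass-through
#' metadata, never logic.
#'
#' @param seq_hits,dom_hits,struct_hits Character vectors of protein ids, or
#'   hit tibbles with a `target` column (for `dom_hits` only rows with
#'   `included == TRUE` count if that column is present).
#' @param cazyme_annotations Tibble `protein_id`, `family` (one row per
#'   annotated domain), or `NULL`.
#' @param excluded_family Family label to exclude (e.g. `"AA9"`), or `NULL`.
#' @param proteome_ids Optional character vector of valid ids; hits outside
#'   it are an error.
#' @param annotations Optional tibble of per-candidate metadata keyed by
#'   `protein_id` (e.g. `accession`, `interpro`, `has_signal_peptide`,
#'   `cleavage_position`); joined onto the matrix.
#' @return A `candidate_matrix` tibble: `protein_id`, `hit_sequence`,
#'   `hit_domain`, `hit_structure`, `cazyme_families` plus any metadata
#'   columns, sorted by `protein_id`.
#' @export
combine_hits <- function(seq_hits, dom_hits, struct_hits,
                         cazyme_annotations = NULL, excluded_family = NULL,
                         proteome_ids = NULL, annotations = NULL) {
  seq_ids <- hit_ids(seq_hits)
  dom_ids <- hit_ids(dom_hits, included_only = TRUE)
  str_ids <- hit_ids(struct_hits)
  all_ids <- sort(unique(c(seq_ids, dom_ids, str_ids)))
  if (!is.null(proteome_ids)) {
    bad <- setdiff(all_ids, proteome_ids)
    if (length(bad)) stop("hit ids absent from proteome: ", paste(bad, collapse = ", "))
  }
  fam_of <- function(id) {
    if (is.null(cazyme_annotations) || nrow(cazyme_annotations) == 0) return(character(0))
    cazyme_annotations$family[cazyme_annotations$protein_id == id]
  }
  out <- tibble::tibble(
    protein_id = all_ids,
    hit_sequence = all_ids %in% seq_ids,
    hit_domain = all_ids %in% dom_ids,
    hit_structure = all_ids %in% str_ids,
    cazyme_families = purrr::map(all_ids, fam_of)
  )
  if (!is.null(excluded_family)) {
    out <- dplyr::filter(
      out, !purrr::map_lgl(.data$cazyme_families, ~ excluded_family %in% .x)
    )
  }
  if (!is.null(annotations)) {
    out <- dplyr::left_join(out, tibble::as_tibble(annotations), by = "protein_id")
  }
  attr(out, "excluded_family") <- excluded_family
  class(out) <- c("candidate_matrix", class(out))
  out
}

hit_ids <- function(x, included_only = FALSE) {
  if (is.null(x)) return(character(0))
  if (is.data.frame(x)) {
    if (included_only && "included" %in% names(x)) x <- x[x$included, , drop = FALSE]
    return(unique(x$target))
  }
  unique(as.character(x))
}

#' Structure-only candidates
#'
#' Ids hit by the structure mode and by neither the sequence nor the domain
#' mode -- the screen's headline output: divergent candidates invisible to
#' sequence-level searching.
#'
#' @param matrix A [combine_hits()] candidate matrix.
#' @return Sorted character vector of protein ids.
#' @export
structure_only <- function(matrix) {
  sort(matrix$protein_id[matrix$hit_structure & !matrix$hit_sequence & !matrix$hit_domain])
}

#' Candidates identified by all three modes
#'
#' @param matrix A [combine_hits()] candidate matrix.
#' @return Sorted character vector of protein ids.
#' @export
all_modes <- function(matrix) {
  sort(matrix$protein_id[matrix$hit_sequence & matrix$hit_domain & matrix$hit_structure])
}

#' N-terminal histidine check for LPMO candidates
#'
#' LPMOs carry a conserved histidine immediately after the signal-peptide
#' cleavage site. Returns `TRUE` iff the residue at `cleavage_position + 1`
#' is histidine; a missing cleavage position (no predicted signal peptide)
#' returns `FALSE`.
#'
#' @param sequence Amino-acid sequence.
#' @param cleavage_position Last residue of the signal peptide, or `NA`.
#' @return Logical scalar.
#' @export
lpmo_his_check <- function(sequence, cleavage_position) {
  if (is.null(cleavage_position) || is.na(cleavage_position)) return(FALSE)
  if (cleavage_position < 0 || cleavage_position >= nchar(sequence)) return(FALSE)
  substr(sequence, cleavage_position + 1, cleavage_position + 1) == "H"
}

#' Crude signal-peptide heuristic (non-authoritative)
#'
#' Signal peptides are input annotations from a dedicated predictor; this
#' fallback only flags an N-terminal hydrophobic window (>= 8 hydrophobic
#' residues among positions 1-25) and guesses the cleavage site at the end
#' of that window. Clearly labelled non-authoritative; never used by the
#' screen logic itself.
#'
#' @param sequence Amino-acid sequence.
#' @return A list `has_signal_peptide`, `cleavage_position` (NA when absent).
#' @export
crude_signal_peptide <- function(sequence) {
  hydrophobic <- c("A", "C", "F", "I", "L", "M", "V", "W")
  x <- strsplit(substr(sequence, 1, 25), "")[[1]]
  h <- x %in% hydrophobic
  if (sum(h) >= 8) {
    list(has_signal_peptide = TRUE, cleavage_position = max(which(h)))
  } else {
    list(has_signal_peptide = FALSE, cleavage_position = NA_integer_)
  }
}

#' Render a candidate matrix as a deterministic report
#'
#' Tick-mark table in the style of the screen's printed candidate tables,
#' sorted by protein id; byte-stable across runs.
#'
#' @param matrix A candidate matrix.
#' @param path Optional file to write the TSV to.
#' @param format `"tsv"` (tick marks as `yes`/empty) or `"markdown"`.
#' @return The rendered lines, invisibly if `path` given.
#' @export
render_candidate_table <- function(matrix, path = NULL, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  m <- dplyr::arrange(tibble::as_tibble(matrix), .data$protein_id)
  tick <- function(x) ifelse(x, "yes", "")
  body <- tibble::tibble(
    protein_id = m$protein_id,
    sequence = tick(m$hit_sequence),
    domain = tick(m$hit_domain),
    structure = tick(m$hit_structure)
  )
  if (format == "tsv") {
    lines <- c(
      paste(names(body), collapse = "\t"),
      purrr::map_chr(seq_len(nrow(body)), function(i) paste(unlist(body[i, ]), collapse = "\t"))
    )
  } else {
    lines <- c(
      paste0("| ", paste(names(body), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(body)), collapse = "|"), "|"),
      purrr::map_chr(seq_len(nrow(body)), function(i) {
        paste0("| ", paste(unlist(body[i, ]), collapse = " | "), " |")
      })
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a rendered candidate TSV back into a candidate matrix
#'
#' @param path TSV written by [render_candidate_table()].
#' @return A `candidate_matrix` tibble.
#' @export
parse_candidate_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  out <- tibble::tibble(
    protein_id = x$protein_id,
    hit_sequence = !is.na(x$sequence) & x$sequence == "yes",
    hit_domain = !is.na(x$domain) & x$domain == "yes",
    hit_structure = !is.na(x$structure) & x$structure == "yes",
    cazyme_families = purrr::map(x$protein_id, ~ character(0))
  )
  class(out) <- c("candidate_matrix", class(out))
  out
}

#' Load a packaged tick-matrix fixture
#'
#' The package ships the three published-style candidate tick matrices
#' (LPMO, laccase, peroxidase screens) as plain TSVs under `extdata/`.
#'
#' @param name One of `"lpmo"`, `"laccase"`, `"peroxidase"`.
#' @return A `candidate_matrix` tibble with metadata columns.
#' @export
read_candidate_fixture <- function(name = c("lpmo", "laccase", "peroxidase")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("candidates_", name, ".tsv"),
                      package = "triscreen", mustWork = TRUE)
  x <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tibble::tibble(
    protein_id = x$protein_id,
    hit_sequence = x$sequence == 1,
    hit_domain = x$domain == 1,
    hit_structure = x$structure == 1,
    cazyme_families = purrr::map(x$protein_id, ~ character(0)),
    coding_region = x$coding_region,
    accession = x$accession,
    interpro = x$interpro
  )
  class(out) <- c("candidate_matrix", class(out))
  out
}
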