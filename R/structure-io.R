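#' Read a C-alpha structure model from a PDB file
#'
#' Dialect rules: first model only; CA atoms with blank or `'A'` altLoc; the
#' first chain encountered unless `chain` is given; the B-factor column is
#' read as per-residue confidence. CA-only files (AlphaFold-style minimal
#' models) are accepted.
#'
#' @param path PDB file with ATOM records.
#' @param chain Optional chain id; default first encountered.
#' @param id Model id; defaults to the file name without extension.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, chain = NULL, id = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("malformed PDB file '", path, "': ", conditionMessage(e))
  )
  at <- pdb$atom
  ca <- at[at$elety == "CA" & (is.na(at$alt) | at$alt %in% c("", "A")), , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in '", path, "'")
  chain <- chain %||% ca$chain[1]
  ca <- ca[ca$chain == chain | is.na(ca$chain), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  structure_model(
    id = id %||% sub("\\.[^.]*$", "", basename(path)),
    xyz = as.matrix(ca[, c("x", "y", "z")]),
    confidence = ca$b,
    resno = ca$resno
  )
}

#' Load a structure database directory
#'
#' A structure database is a directory of PDB files plus a `manifest.tsv`
#' (columns `id`, `file`, `n_residues`); without a manifest every `.pdb`
#' file in the directory is read.
#'
#' @param dir Directory path.
#' @return Named list of [structure_model()]s, sorted by id.
#' @export
read_structure_db <- function(dir) {
  if (!dir.exists(dir)) stop("structure directory '", dir, "' does not exist")
  manifest <- file.path(dir, "manifest.tsv")
  files <- if (file.exists(manifest)) {
    m <- readr::read_tsv(manifest, show_col_types = FALSE)
    setNames(file.path(dir, m$file), m$id)
  } else {
    f <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
    setNames(f, sub("\\.pdb$", "", basename(f)))
  }
  files <- files[order(names(files))]
  purrr::imap(files, function(p, id) read_structure(p, id = id))
}
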