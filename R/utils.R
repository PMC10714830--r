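# Shared small helpers: alphabet, seeded substreams, FASTA I/O conveniences.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# CAZyme classes recognised by the repertoire profiler.
CAZY_CLASSES <- c("GH", "GT", "PL", "CE", "AA", "CBM")

#' Derive a named RNG substream seed from a master seed
#'
#' Every stochastic operation in the package draws its seed from the single
#' scenario/config seed plus a stream name, so that modules can be re-run in
#' isolation with reproducible results and adding a stage never perturbs the
#' randomness of another.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # Cheap string hash (polynomial rolling, mod a prime below 2^31).
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(seed) + h) %% 2147483629)
}

with_stream_seed <- function(seed, stream, code) {
  withr::with_seed(substream_seed(seed, stream), code)
}

# Random amino-acid sequence from a background composition.
random_aa <- function(n, background = rep(1 / 20, 20)) {
  paste(sample(AA20, n, replace = TRUE, prob = background), collapse = "")
}

# Read a FASTA file of protein sequences into a named character vector.
read_fasta_vec <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# Write a named character vector of sequences as FASTA.
write_fasta_vec <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), path, width = 60L
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
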