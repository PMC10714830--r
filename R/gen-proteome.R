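#' Generate the synthetic proteome of a scenario
#'
#' Emits one record per template, planted analog and decoy. Decoys are i.i.d.
#' draws from the scenario's background composition with lengths uniform over
#' `decoy_length_range`. Substitution counts for planted homologs are fixed
#' fractions of the length (not binomial draws) so identity guarantees hold
#' for every seed: `seq_homolog` 15% point substitutions, `dom_homolog` 50%
#' substitutions across the template embedded in random coil flanks,
#' `struct_only` a residue permutation of the template (composition kept,
#' order destroyed).
#'
#' @param spec A [scenario_spec()].
#' @return A tibble with columns `id`, `seq`, `role`
#'   (`template`/`seq_homolog`/`dom_homolog`/`struct_only`/`decoy`),
#'   `template` (source template id or `NA`) and `family` (template CAZyme
#'   family or `NA`).
#' @export
gen_proteome <- function(spec) {
  validate_scenario(spec)
  rows <- list()
  for (t in spec$templates) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = t$id, seq = t$seq, role = "template", template = t$id, family = t$family
    )
  }
  if (nrow(spec$planted) > 0) {
    for (i in seq_len(nrow(spec$planted))) {
      p <- spec$planted[i, ]
      t <- spec$templates[[p$template]]
      seq <- with_stream_seed(spec$seed, paste0("planted:", p$id), switch(p$kind,
        seq_homolog = substitute_fraction(t$seq, 0.15, spec$background),
        dom_homolog = embed_in_flanks(
          substitute_fraction(t$seq, 0.50, spec$background),
          spec$background
        ),
        struct_only = scramble_seq(t$seq)
      ))
      flanks <- attr(seq, "flanks") %||% c(NA_integer_, NA_integer_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = p$id, seq = as.character(seq), role = p$kind, template = p$template,
        family = NA_character_, flank_n = flanks[1], flank_c = flanks[2]
      )
    }
  }
  if (spec$n_decoys > 0) {
    decoys <- with_stream_seed(spec$seed, "decoys", {
      lens <- sample(
        seq(spec$decoy_length_range[1], spec$decoy_length_range[2]),
        spec$n_decoys,
        replace = TRUE
      )
      purrr::map_chr(lens, random_aa, background = spec$background)
    })
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("DEC_%03d", seq_len(spec$n_decoys)), seq = decoys,
      role = "decoy", template = NA_character_, family = NA_character_
    )
  }
  empty <- tibble::tibble(
    id = character(), seq = character(), role = character(),
    template = character(), family = character(),
    flank_n = integer(), flank_c = integer()
  )
  out <- dplyr::bind_rows(empty, rows)
  if (anyDuplicated(out$id)) stop("duplicate protein ids in scenario")
  out
}

# Replace an exact fraction of positions with a different residue.
substitute_fraction <- function(seq, fraction, background = rep(1 / 20, 20)) {
  x <- strsplit(seq, "")[[1]]
  n_sub <- floor(fraction * length(x))
  if (n_sub == 0) return(seq)
  pos <- sample(length(x), n_sub)
  for (i in pos) {
    x[i] <- sample(setdiff(AA20, x[i]), 1)
  }
  paste(x, collapse = "")
}

# Embed a sequence in random N- and C-terminal flanks (20-60 residues each).
embed_in_flanks <- function(seq, background = rep(1 / 20, 20),
                            flank_range = c(20L, 60L)) {
  n1 <- sample(seq(flank_range[1], flank_range[2]), 1)
  n2 <- sample(seq(flank_range[1], flank_range[2]), 1)
  out <- paste0(random_aa(n1, background), seq, random_aa(n2, background))
  attr(out, "flanks") <- c(n1, n2)
  out
}

# Random permutation of the residues of a sequence.
scramble_seq <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  paste(sample(x), collapse = "")
}

#' Percent identity of two equal-length sequences
#'
#' Position-wise identity, as used to verify planted-homolog divergence.
#'
#' @param a,b Character scalars of equal nchar.
#' @return Percent of positions identical.
#' @export
percent_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(NA_real_)
  100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}
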