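#' Scenario specification for synthetic screen data
#'
#' A scenario bundles everything the generators need to emit a miniature
#' proteome with planted ground truth: templates (the "known" enzymes with a
#' CAZyme family, a sequence and a secondary-structure plan), planted analogs
#' of three detectability kinds, decoys, a multi-clade taxonomy plan with
#' controlled auxiliary-activity (AA) proportions, and a
#' glucose-versus-substrate expression design.
#'
#' Planted kinds:
#' * `seq_homolog` — template with a fixed fraction of point substitutions
#'   (default 15%, so identity >= 80%); detectable by all three search modes.
#' * `dom_homolog` — template sequence at 40–60% substitution embedded in
#'   random coil flanks; reliably detectable by the domain model (and, at
#'   this identity, usually by the other modes too).
#' * `struct_only` — a fully scrambled (permuted) template sequence paired
#'   with the template fold; detectable by the structure mode only.
#'
#' @param seed Master integer seed; all generator randomness flows from it
#'   through named substreams (see [substream_seed()]).
#' @param n_decoys Number of decoy proteins (i.i.d. background residues).
#' @param templates Named list of templates as built by [make_template()].
#' @param planted Tibble with columns `id`, `kind`
#'   (`seq_homolog`/`dom_homolog`/`struct_only`) and `template` (template id).
#' @param taxonomy_plan Tibble with columns `clade` (semicolon path
#'   `phylum;class;order;family;genus`), `n_genomes`, `aa_mean`, `aa_sd`
#'   (AA proportion of total CAZyme domains, in percent).
#' @param expression_plan Tibble with columns `protein_id`, `timepoint`
#'   (`d2`/`d4`/`d10`) and `log2fc` (substrate vs glucose).
#' @param replicates Replicates per condition/timepoint.
#' @param decoy_length_range Decoy lengths are uniform over this range.
#' @param background Residue background composition (length 20, sums to 1);
#'   default uniform.
#' @return A `scenario_spec` object (a validated list).
#' @export
scenario_spec <- function(seed,
                          n_decoys = 0L,
                          templates = list(),
                          planted = empty_planted(),
                          taxonomy_plan = empty_taxonomy_plan(),
                          expression_plan = empty_expression_plan(),
                          replicates = 3L,
                          decoy_length_range = c(120L, 400L),
                          background = rep(1 / 20, 20)) {
  spec <- structure(
    list(
      seed = as.integer(seed),
      n_decoys = as.integer(n_decoys),
      templates = templates,
      planted = tibble::as_tibble(planted),
      taxonomy_plan = tibble::as_tibble(taxonomy_plan),
      expression_plan = tibble::as_tibble(expression_plan),
      replicates = as.integer(replicates),
      decoy_length_range = as.integer(decoy_length_range),
      background = background
    ),
    class = "scenario_spec"
  )
  validate_scenario(spec)
  spec
}

empty_planted <- function() {
  tibble::tibble(id = character(), kind = character(), template = character())
}
empty_taxonomy_plan <- function() {
  tibble::tibble(
    clade = character(), n_genomes = integer(),
    aa_mean = double(), aa_sd = double()
  )
}
empty_expression_plan <- function() {
  tibble::tibble(protein_id = character(), timepoint = character(), log2fc = double())
}

validate_scenario <- function(spec) {
  stopifnot(spec$n_decoys >= 0L, spec$replicates >= 1L)
  stopifnot(length(spec$background) == 20, abs(sum(spec$background) - 1) < 1e-8)
  if (nrow(spec$planted) > 0) {
    bad <- setdiff(spec$planted$kind, c("seq_homolog", "dom_homolog", "struct_only"))
    if (length(bad)) stop("unknown planted kind: ", paste(bad, collapse = ", "))
    miss <- setdiff(spec$planted$template, names(spec$templates))
    if (length(miss)) stop("planted rows reference unknown template: ", paste(miss, collapse = ", "))
    if (anyDuplicated(spec$planted$id)) stop("duplicate planted ids")
  }
  if (nrow(spec$taxonomy_plan) > 0) {
    with(spec$taxonomy_plan, stopifnot(all(n_genomes >= 1), all(aa_mean >= 0), all(aa_mean <= 100), all(aa_sd >= 0)))
  }
  invisible(spec)
}

#' Build a template enzyme for a scenario
#'
#' A template couples a CAZyme family label, a seeded random sequence whose
#' length matches its secondary-structure plan, and the plan itself (used to
#' generate the template structure and the folds of planted analogs).
#'
#' @param id Template protein id.
#' @param family CAZyme family label (e.g. `"AA9"`).
#' @param sse_plan Tibble with columns `type` (`"H"`, `"E"`, `"coil"`) and
#'   `length`; defaults to an LPMO-like beta-sandwich plan (7 strands + 1
#'   short helix joined by coils).
#' @param seed Seed for the template sequence.
#' @return A list with elements `id`, `family`, `sse_plan`, `seq`.
#' @export
make_template <- function(id, family, sse_plan = lpmo_like_plan(), seed = 1L) {
  stopifnot(all(sse_plan$type %in% c("H", "E", "coil")), all(sse_plan$length >= 1))
  len <- sum(sse_plan$length)
  seq <- with_stream_seed(seed, paste0("template:", id), random_aa(len))
  list(id = id, family = family, sse_plan = sse_plan, seq = seq)
}

#' An LPMO-like secondary-structure plan
#'
#' Eight secondary-structure elements (seven strands and one short helix)
#' joined by coils, emulating the immunoglobulin-like beta-sandwich core of
#' lytic polysaccharide monooxygenases at desk scale (~150 residues).
#'
#' @return A tibble with columns `type` and `length`.
#' @export
lpmo_like_plan <- function() {
  tibble::tribble(
    ~type, ~length,
    "coil", 6L, "E", 6L, "coil", 5L, "E", 7L, "coil", 8L, "H", 7L,
    "coil", 5L, "E", 5L, "coil", 6L, "E", 6L, "coil", 7L, "E", 6L,
    "coil", 5L, "E", 7L, "coil", 8L, "E", 5L, "coil", 6L
  )
}

#' A mostly-helical plan (laccase/peroxidase-style stand-in)
#'
#' @return A tibble with columns `type` and `length`.
#' @export
helical_plan <- function() {
  tibble::tribble(
    ~type, ~length,
    "coil", 6L, "H", 10L, "coil", 6L, "H", 8L, "coil", 7L, "E", 5L,
    "coil", 5L, "H", 9L, "coil", 6L, "H", 7L, "coil", 6L, "E", 5L, "coil", 5L
  )
}

#' The default planted-recovery scenario
#'
#' One AA9-family LPMO-like template plus one planted analog of each kind and
#' `n_decoys` random decoys; a five-clade taxonomy plan; expression design in
#' which the fold-only analog is up-regulated on the substrate at day 4.
#'
#' @param seed Master seed.
#' @param n_decoys Decoy count (default 50).
#' @return A `scenario_spec`.
#' @export
default_scenario <- function(seed = 101L, n_decoys = 50L) {
  tpl <- make_template("TPL_AA9", "AA9", lpmo_like_plan(), seed = seed)
  scenario_spec(
    seed = seed,
    n_decoys = n_decoys,
    templates = list(TPL_AA9 = tpl),
    planted = tibble::tribble(
      ~id, ~kind, ~template,
      "PLT_SEQ", "seq_homolog", "TPL_AA9",
      "PLT_DOM", "dom_homolog", "TPL_AA9",
      "PLT_STR", "struct_only", "TPL_AA9"
    ),
    taxonomy_plan = tibble::tribble(
      ~clade, ~n_genomes, ~aa_mean, ~aa_sd,
      "Ascomycota;Sordariomycetes;Microascales;Microascaceae;Parascedosporium", 3L, 20, 2,
      "Ascomycota;Sordariomycetes;Microascales;Microascaceae;Scedosporium", 5L, 19.5, 1.2,
      "Ascomycota;Sordariomycetes;Hypocreales;Hypocreaceae;Trichoderma", 8L, 14, 4,
      "Ascomycota;Sordariomycetes;Xylariales;Hypoxylaceae;Hypoxylon", 6L, 19.8, 1.8,
      "Ascomycota;Saccharomycetes;Saccharomycetales;Saccharomycetaceae;Saccharomyces", 8L, 9, 4.5
    ),
    expression_plan = tibble::tribble(
      ~protein_id, ~timepoint, ~log2fc,
      "PLT_STR", "d2", 2,
      "PLT_STR", "d4", 3
    )
  )
}

#' Read / write a scenario specification as YAML
#'
#' Templates are serialized with their sequence and plan so a round-tripped
#' file regenerates identical data.
#'
#' @param spec A `scenario_spec`.
#' @param path File path.
#' @return `read_scenario()` returns a `scenario_spec`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(spec, path) {
  x <- unclass(spec)
  x$templates <- purrr::map(x$templates, function(t) {
    list(
      id = t$id, family = t$family, seq = t$seq,
      sse_type = t$sse_plan$type, sse_length = t$sse_plan$length
    )
  })
  x$planted <- as.list(x$planted)
  x$taxonomy_plan <- as.list(x$taxonomy_plan)
  x$expression_plan <- as.list(x$expression_plan)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  templates <- purrr::map(x$templates, function(t) {
    list(
      id = t$id, family = t$family, seq = t$seq,
      sse_plan = tibble::tibble(type = t$sse_type, length = as.integer(t$sse_length))
    )
  })
  names(templates) <- purrr::map_chr(templates, "id")
  scenario_spec(
    seed = x$seed, n_decoys = x$n_decoys, templates = templates,
    planted = tibble::as_tibble(x$planted),
    taxonomy_plan = tibble::as_tibble(x$taxonomy_plan),
    expression_plan = tibble::as_tibble(x$expression_plan),
    replicates = x$replicates,
    decoy_length_range = x$decoy_length_range,
    background = x$background
  )
}
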