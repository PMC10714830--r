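# End-to-end orchestration from a config (YAML file or list): the tri-modal
# screen with triage and expression cross-reference, and the taxonomy
# density analysis. The package functions are the API; these runners are
# thin, reproducible glue with a manifest.

#' Default screen thresholds
#'
#' E-value cutoff 1e-5 (sequence), inclusion threshold 0.01 (domain) and
#' lowest acceptable SSE match 50% (structure; 30% is the relaxed setting
#' used for more divergent folds).
#'
#' @return Named list.
#' @export
default_thresholds <- function() {
  list(evalue_cutoff = 1e-5, inclusion = 0.01, lowest_match = 50)
}

#' Run the tri-modal screen from a config
#'
#' Config fields (YAML file or list): `proteome` (FASTA), `structure_dir`,
#' `query_fasta`, `query_pdb`, `msa` (aligned FASTA), `annotations` (TSV
#' `protein_id`, `family`), `excluded_family`, `expression` (TSV, optional),
#' `out_dir`, `seed`, and optional `thresholds` overriding
#' [default_thresholds()] plus `n_null`. Writes the three hit TSVs, the
#' candidate TSV, the expression report and `manifest.json` (config echo,
#' package version, seed, input checksums). Identical inputs and seed give
#' byte-identical candidate output; any stage error aborts with the stage
#' named and removes partial outputs.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @return Invisibly, a list with `candidates` (candidate matrix), the three
#'   hit tibbles, `expression_report` and `paths`.
#' @export
run_screen <- function(config) {
  cfg <- load_config(config)
  for (f in c("proteome", "structure_dir", "query_fasta", "query_pdb", "msa")) {
    if (is.null(cfg[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(cfg[[f]])) stop("config path '", f, "' does not exist: ", cfg[[f]])
  }
  thr <- utils::modifyList(default_thresholds(), cfg$thresholds %||% list())
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$out_dir %||% stop("config field 'out_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop("screen stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  proteome <- tryCatch(
    tibble::tibble(
      id = names(read_fasta_vec(cfg$proteome)),
      seq = unname(read_fasta_vec(cfg$proteome))
    ),
    error = function(e) fail("inputs", e)
  )
  annotations <- if (!is.null(cfg$annotations)) {
    readr::read_tsv(cfg$annotations, show_col_types = FALSE)
  } else {
    NULL
  }

  seq_hits <- tryCatch({
    q <- read_fasta_vec(cfg$query_fasta)
    search_proteome(setNames(q[1], names(q)[1]), proteome,
                    cutoff = thr$evalue_cutoff)
  }, error = function(e) fail("seq_search", e))

  dom_hits <- tryCatch({
    hmm <- build_hmm(cfg$msa)
    calibrate_and_search(hmm, proteome, inclusion = thr$inclusion,
                         n_null = as.integer(cfg$n_null %||% 200L),
                         seed = substream_seed(seed, "hmm_null"))
  }, error = function(e) fail("hmm_search", e))

  struct_hits <- tryCatch({
    query <- read_structure(cfg$query_pdb)
    db <- read_structure_db(cfg$structure_dir)
    db <- db[setdiff(names(db), query$id)]
    search_structure_db(query, db, lowest_match = thr$lowest_match)
  }, error = function(e) fail("struct_search", e))

  candidates <- tryCatch(
    combine_hits(
      seq_hits, dom_hits, struct_hits,
      cazyme_annotations = if (!is.null(annotations)) {
        dplyr::rename(annotations, protein_id = 1, family = 2)
      },
      excluded_family = cfg$excluded_family,
      proteome_ids = proteome$id
    ),
    error = function(e) fail("triage", e)
  )

  expression_report <- NULL
  if (!is.null(cfg$expression)) {
    expression_report <- tryCatch({
      expr <- readr::read_tsv(cfg$expression, show_col_types = FALSE)
      candidate_expression_report(candidates, expr)
    }, error = function(e) fail("expression_link", e))
  }

  paths <- list(
    seq_hits = file.path(out_dir, "seq_hits.tsv"),
    dom_hits = file.path(out_dir, "dom_hits.tsv"),
    struct_hits = file.path(out_dir, "struct_hits.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(seq_hits, paths$seq_hits)
  readr::write_tsv(dom_hits, paths$dom_hits)
  readr::write_tsv(struct_hits, paths$struct_hits)
  render_candidate_table(candidates, paths$candidates)
  written <- unlist(paths)
  if (!is.null(expression_report)) {
    paths$expression_report <- file.path(out_dir, "expression_report.tsv")
    readr::write_tsv(expression_report, paths$expression_report)
  }

  inputs <- unlist(cfg[c("proteome", "query_fasta", "query_pdb", "msa",
                         "annotations", "expression")])
  manifest <- list(
    package = "triscreen",
    version = as.character(utils::packageVersion("triscreen")),
    seed = seed,
    thresholds = thr,
    config = cfg[setdiff(names(cfg), "thresholds")],
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    candidates = candidates, seq_hits = seq_hits, dom_hits = dom_hits,
    struct_hits = struct_hits, expression_report = expression_report,
    paths = paths
  ))
}

#' Run the taxonomy density analysis from a config
#'
#' Config fields: `taxonomy` (TSV with ranked lineages),
#' `genome_annotations` (TSV `genome_id`, `protein_id`, `family`),
#' `out_dir`, optional `genus_min` (3), `family_min` (8), and
#' `focal_values` (named list of AA proportions to percentile-rank against
#' the full genome population). Writes the pruned Newick tree, the clade
#' report and the percentile table.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @return Invisibly: `tree` (pruned), `report`, `percentiles`, `profiles`,
#'   `paths`.
#' @export
run_density <- function(config) {
  cfg <- load_config(config)
  for (f in c("taxonomy", "genome_annotations")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop("config path '", f, "' missing")
    }
  }
  out_dir <- cfg$out_dir %||% stop("config field 'out_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  taxonomy <- readr::read_tsv(cfg$taxonomy, show_col_types = FALSE)
  ann <- readr::read_tsv(cfg$genome_annotations, show_col_types = FALSE)
  profiles <- ann |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::group_map(~ profile_genome(.x, genome_id = .y$genome_id)) |>
    (\(x) setNames(x, purrr::map_chr(x, "genome_id")))()
  full_tree <- build_tree(taxonomy, profiles)
  pruned <- prune(full_tree,
                  genus_min = cfg$genus_min %||% 3,
                  family_min = cfg$family_min %||% 8)
  report <- clade_report(pruned)
  population <- purrr::map_dbl(profiles, "aa_proportion")
  focal <- cfg$focal_values %||% list()
  percentiles <- tibble::tibble(
    id = names(focal),
    aa_proportion = as.numeric(unlist(focal)),
    percentile = unname(purrr::map_dbl(focal, ~ percentile_rank(.x, population)))
  )

  paths <- list(
    newick = file.path(out_dir, "tree.nwk"),
    report = file.path(out_dir, "clade_report.tsv"),
    percentiles = file.path(out_dir, "percentiles.tsv")
  )
  write_tree_newick(pruned, paths$newick)
  readr::write_tsv(report, paths$report)
  readr::write_tsv(percentiles, paths$percentiles)
  invisible(list(tree = pruned, report = report, percentiles = percentiles,
                 profiles = profiles, paths = paths))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file '", config, "' does not exist")
    yaml::read_yaml(config)
  } else {
    as.list(config)
  }
}
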