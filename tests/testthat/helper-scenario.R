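# Default scenario materialised once per test session (the screen stages all
# reuse it).

.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function() {
  if (is.null(.scenario_cache$sc)) {
    spec <- default_scenario(seed = 101L, n_decoys = 50L)
    dir <- file.path(tempdir(), "triscreen-default-scenario")
    .scenario_cache$sc <- gen_scenario(spec, dir)
  }
  .scenario_cache$sc
}

scenario_config <- function(sc, out_dir = tempfile("screen-out"),
                            excluded_family = "AA9", ...) {
  c(
    list(
      proteome = sc$paths$proteome,
      structure_dir = sc$paths$structure_dir,
      query_fasta = sc$paths$queries$TPL_AA9$fasta,
      query_pdb = sc$paths$queries$TPL_AA9$pdb,
      msa = sc$paths$queries$TPL_AA9$msa,
      annotations = sc$paths$annotations,
      excluded_family = excluded_family,
      expression = sc$paths$expression,
      out_dir = out_dir,
      seed = sc$spec$seed
    ),
    list(...)
  )
}

.screen_cache <- new.env(parent = emptyenv())

cached_screen <- function() {
  if (is.null(.screen_cache$res)) {
    .screen_cache$res <- run_screen(scenario_config(cached_scenario()))
  }
  .screen_cache$res
}
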