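test_that("empty scenario yields an empty proteome and empty FASTA", {
  spec <- scenario_spec(seed = 1L, n_decoys = 0L)
  p <- gen_proteome(spec)
  expect_equal(nrow(p), 0L)
  f <- tempfile(fileext = ".fasta")
  triscreen:::write_fasta_vec(setNames(p$seq, p$id), f)
  expect_true(file.exists(f))
  expect_equal(length(triscreen:::read_fasta_vec(f)), 0L)
})

test_that("proteome has planted records with the promised divergences", {
  tpl <- make_template("T1", "AA9", seed = 7L)
  spec <- scenario_spec(
    seed = 7L, n_decoys = 50L, templates = list(T1 = tpl),
    planted = tibble::tibble(
      id = c("S1", "D1", "X1"),
      kind = c("seq_homolog", "dom_homolog", "struct_only"),
      template = "T1"
    )
  )
  p <- gen_proteome(spec)
  expect_equal(nrow(p), 54L) # 1 template + 3 planted + 50 decoys
  expect_equal(anyDuplicated(p$id), 0L)

  # close homolog: identity >= 80%
  expect_gte(percent_identity(tpl$seq, p$seq[p$id == "S1"]), 80)
  # remote homolog: embedded core at 40-60% substitution
  dom <- p[p$id == "D1", ]
  core <- substr(dom$seq, dom$flank_n + 1, dom$flank_n + nchar(tpl$seq))
  ident <- percent_identity(tpl$seq, core)
  expect_gte(ident, 40)
  expect_lte(ident, 60)
  # fold-only analog: permutation (composition kept, order lost)
  x1 <- p$seq[p$id == "X1"]
  expect_equal(sort(strsplit(x1, "")[[1]]), sort(strsplit(tpl$seq, "")[[1]]))
  expect_lt(percent_identity(tpl$seq, x1), 20)
  # decoy lengths within the declared range
  dec <- p[p$role == "decoy", ]
  expect_true(all(nchar(dec$seq) >= 120 & nchar(dec$seq) <= 400))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- default_scenario(seed = 11L, n_decoys = 5L)
  d1 <- tempfile("s1")
  d2 <- tempfile("s2")
  gen_scenario(spec, d1)
  gen_scenario(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("ideal SSE geometry holds and survives a round trip through assignment", {
  helix <- gen_structure(tibble::tibble(type = "H", length = 12L), 0, seed = 1L)
  expect_equal(length(helix), 12L)
  d <- sqrt(rowSums(diff(helix$xyz)^2))
  expect_true(all(abs(d - 3.8) < 0.2))
  sse_h <- assign_sse(helix)
  expect_equal(sse_h$type, "helix")
  expect_gte(sse_h$length, 10)

  strand <- gen_structure(tibble::tibble(type = "E", length = 8L), 0, seed = 2L)
  sse_e <- assign_sse(strand)
  expect_equal(sse_e$type, "strand")

  mixed <- gen_structure(
    tibble::tibble(type = c("H", "coil", "E"), length = c(10L, 4L, 6L)),
    noise_sigma = 0.3, seed = 5L
  )
  expect_equal(length(mixed), 20L)
  sse_m <- assign_sse(mixed)
  expect_gte(sum(sse_m$type == "helix"), 1)
  expect_gte(sum(sse_m$type == "strand"), 1)
})

test_that("confidence mimics pLDDT: 90 on elements, 50 on coils", {
  m <- gen_structure(
    tibble::tibble(type = c("H", "coil"), length = c(6L, 5L)), 0, seed = 3L
  )
  expect_equal(m$confidence, c(rep(90, 6), rep(50, 5)))
})

test_that("noise lowers the self-alignment Q-score", {
  plan <- lpmo_like_plan()
  clean <- gen_structure(plan, 0, seed = 9L, id = "clean")
  noisy <- perturb_structure(clean, 2.0, seed = 10L, id = "noisy")
  mild <- perturb_structure(clean, 0.3, seed = 10L, id = "mild")
  q_noisy <- align_structures(clean, noisy)$q
  q_mild <- align_structures(clean, mild)$q
  expect_lt(q_noisy, q_mild)
  expect_lt(q_mild, 1)
})

test_that("random coils stay clear of the SSE windows", {
  counts <- purrr::map_int(1:100, function(s) {
    coil <- gen_structure(tibble::tibble(type = "coil", length = 30L), 0, seed = s)
    nrow(assign_sse(coil))
  })
  expect_lte(mean(counts), 1)
})

test_that("taxonomy plan is realised with the requested clade statistics", {
  spec <- scenario_spec(
    seed = 3L,
    taxonomy_plan = tibble::tibble(
      clade = "Ascomycota;Sordariomycetes;Microascales;Microascaceae;ParaG",
      n_genomes = 5L, aa_mean = 20, aa_sd = 2
    )
  )
  tb <- gen_tables(spec)
  expect_equal(nrow(tb$taxonomy), 5L)
  profs <- tb$genome_annotations |>
    dplyr::group_by(genome_id) |>
    dplyr::group_map(~ profile_genome(.x, .y$genome_id))
  aa <- purrr::map_dbl(profs, "aa_proportion")
  expect_lt(abs(mean(aa) - 20), 3 * 2 / sqrt(5))
})

test_that("expression plan produces the planted fold-change", {
  tpl <- make_template("T1", "AA9", seed = 2L)
  spec <- scenario_spec(
    seed = 21L, templates = list(T1 = tpl),
    expression_plan = tibble::tibble(protein_id = "T1", timepoint = "d4", log2fc = 3)
  )
  tb <- gen_tables(spec)
  x <- tb$expression
  m_glu <- mean(x$tpm[x$protein_id == "T1" & x$condition == "glucose"])
  m_d4 <- mean(x$tpm[x$protein_id == "T1" & x$timepoint == "d4"])
  expect_gte(m_d4 / m_glu, 4)
  expect_lte(m_d4 / m_glu, 16)
})

test_that("annotation table has template rows only", {
  spec <- default_scenario(seed = 4L, n_decoys = 3L)
  tb <- gen_tables(spec)
  expect_equal(tb$annotations$protein_id, "TPL_AA9")
  expect_equal(tb$annotations$family, "AA9")
  spec_empty <- scenario_spec(
    seed = 4L, templates = list(T1 = make_template("T1", "AA1", seed = 1L))
  )
  expect_equal(gen_tables(spec_empty)$annotations$protein_id, "T1")
})

test_that("scenario YAML round-trips", {
  spec <- default_scenario(seed = 31L, n_decoys = 2L)
  f <- tempfile(fileext = ".yaml")
  write_scenario(spec, f)
  spec2 <- read_scenario(f)
  expect_identical(gen_proteome(spec), gen_proteome(spec2))
})

test_that("duplicate planted ids are rejected", {
  tpl <- make_template("T1", "AA9", seed = 1L)
  expect_error(
    scenario_spec(
      seed = 1L, templates = list(T1 = tpl),
      planted = tibble::tibble(
        id = c("P", "P"), kind = c("seq_homolog", "struct_only"), template = "T1"
      )
    ),
    "duplicate"
  )
})
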