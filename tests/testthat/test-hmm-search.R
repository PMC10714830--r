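toy_msa <- c(a = "ACD", b = "ACD", c = "ACD")

test_that("single-sequence MSA concentrates emissions on its residues", {
  hmm <- build_hmm(c(s = "ACD"), pseudocount = 1e-9)
  expect_equal(hmm$M, 3L)
  expect_equal(unname(hmm$emissions[1, "A"]), 1, tolerance = 1e-6)
  expect_equal(unname(hmm$emissions[2, "C"]), 1, tolerance = 1e-6)
  expect_equal(unname(hmm$emissions[3, "D"]), 1, tolerance = 1e-6)
  expect_equal(hmm$consensus, "ACD")
})

test_that("duplicated rows leave the profile unchanged (equal weighting)", {
  h1 <- build_hmm(c(a = "AC-DF"))
  h4 <- build_hmm(c(a = "AC-DF", b = "AC-DF", c = "AC-DF", d = "AC-DF"))
  expect_equal(h1$emissions, h4$emissions)
  expect_equal(h1$tMM, h4$tMM)
  expect_equal(h1$tMD, h4$tMD)
})

test_that("occupancy boundary: a 50% column is a match state at match_fraction 0.5", {
  msa <- c(a = "AC", b = "A-")
  hmm <- build_hmm(msa, match_fraction = 0.5)
  expect_equal(hmm$M, 2L)
  expect_error(build_hmm(c(a = "--", b = "--")), "degenerate")
})

test_that("profiles are row-stochastic after smoothing", {
  sc <- cached_scenario()
  hmm <- build_hmm(sc$paths$queries$TPL_AA9$msa)
  expect_true(all(abs(rowSums(hmm$emissions) - 1) < 1e-9))
  for (j in seq_len(hmm$M - 1)) {
    expect_equal(hmm$tMM[j] + hmm$tMI[j] + hmm$tMD[j], 1, tolerance = 1e-9)
    expect_equal(hmm$tII[j] + hmm$tIM[j], 1, tolerance = 1e-9)
    expect_equal(hmm$tDD[j] + hmm$tDM[j], 1, tolerance = 1e-9)
  }
})

test_that("forward probability equals exhaustive path enumeration on tiny profiles", {
  set.seed(5)
  for (k in 1:12) {
    M <- sample(1:3, 1)
    rows <- sample(1:3, 1)
    msa <- purrr::map_chr(seq_len(rows), function(i) {
      paste(sample(c("A", "C", "D", "G"), M, TRUE), collapse = "")
    })
    hmm <- build_hmm(setNames(msa, paste0("s", seq_len(rows))))
    L <- sample(1:4, 1)
    seq <- paste(sample(c("A", "C", "D", "G", "K"), L, TRUE), collapse = "")
    expect_equal(
      forward_bits(hmm, seq),
      log2(oracle_forward_odds(hmm, seq)),
      tolerance = 1e-9,
      label = sprintf("case %d (M=%d, seq=%s)", k, hmm$M, seq)
    )
  }
})

test_that("forward bits dominate Viterbi bits everywhere", {
  sc <- cached_scenario()
  hmm <- build_hmm(sc$paths$queries$TPL_AA9$msa)
  seqs <- head(sc$proteome$seq, 10)
  for (s in seqs) {
    expect_gte(forward_bits(hmm, s), viterbi_bits(hmm, s))
  }
})

test_that("the consensus of a sharp profile scores positive bits", {
  sc <- cached_scenario()
  hmm <- build_hmm(sc$paths$queries$TPL_AA9$msa)
  expect_gt(forward_bits(hmm, hmm$consensus), 0)
})

test_that("calibration is self-consistent: ~1% of null scores get P <= 0.01", {
  sc <- cached_scenario()
  hmm <- build_hmm(sc$paths$queries$TPL_AA9$msa)
  prot <- sc$proteome[, c("id", "seq")]
  hits <- calibrate_and_search(hmm, prot, n_null = 400L, seed = 19L)
  # re-score a fresh batch of shuffles against the fitted null
  mu <- attr(hits, "mu")
  beta <- attr(hits, "beta")
  withr::with_seed(77L, {
    null_bits <- purrr::map_dbl(sample(nrow(prot), 300, TRUE), function(i) {
      forward_bits(hmm, triscreen:::scramble_seq(prot$seq[i]))
    })
  })
  frac <- mean(triscreen:::gumbel_upper_tail(null_bits, mu, beta) <= 0.01)
  # binomial tolerance around 1%
  expect_lte(frac, 0.04)
})

test_that("domain search includes the family members and excludes the scrambled analog", {
  sc <- cached_scenario()
  hmm <- build_hmm(sc$paths$queries$TPL_AA9$msa)
  prot <- sc$proteome[, c("id", "seq")]
  hits <- calibrate_and_search(hmm, prot, seed = 3L)
  inc <- hits$target[hits$included]
  expect_true(all(c("TPL_AA9", "PLT_SEQ", "PLT_DOM") %in% inc))
  expect_false("PLT_STR" %in% inc)
  # the proteome's own consensus-like template is the top hit
  expect_equal(hits$target[1], "TPL_AA9")
  expect_error(
    calibrate_and_search(hmm, tibble::tibble(id = "a", seq = "AAAAA"), n_null = 100L),
    "degenerate"
  )
})

test_that("profile serialization round-trips scores", {
  sc <- cached_scenario()
  hmm <- build_hmm(sc$paths$queries$TPL_AA9$msa)
  f <- tempfile(fileext = ".yaml")
  write_hmm(hmm, f)
  hmm2 <- read_hmm(f)
  s <- sc$proteome$seq[1]
  expect_equal(forward_bits(hmm2, s), forward_bits(hmm, s), tolerance = 1e-6)
})
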