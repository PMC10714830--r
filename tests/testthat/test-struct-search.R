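test_that("structure models round-trip through PDB files", {
  m <- gen_structure(lpmo_like_plan(), 0.2, seed = 4L, id = "rt")
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f, id = "rt")
  expect_equal(m2$xyz, m$xyz, tolerance = 1e-3)
  expect_equal(m2$confidence, round(m$confidence, 2))
  expect_equal(m2$resno, m$resno)
})

test_that("only model 1 is read from multi-model files, CA-only accepted", {
  m <- gen_structure(tibble::tibble(type = "H", length = 6L), 0, seed = 1L)
  f <- tempfile(fileext = ".pdb")
  atoms <- function(offset) {
    purrr::map_chr(1:6, function(i) {
      sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00 90.00           C",
              i, i, m$xyz[i, 1] + offset, m$xyz[i, 2], m$xyz[i, 3])
    })
  }
  writeLines(c("MODEL        1", atoms(0), "ENDMDL",
               "MODEL        2", atoms(99), "ENDMDL", "END"), f)
  m1 <- read_structure(f)
  expect_equal(nrow(m1$xyz), 6L)
  expect_equal(m1$xyz[, 1], m$xyz[, 1], tolerance = 1e-3)
  # no CA atoms -> error
  f2 <- tempfile(fileext = ".pdb")
  writeLines(sub("CA ", "CB ", atoms(0)), f2)
  expect_error(read_structure(f2), "no CA")
})

test_that("Kabsch superposition recovers rigid motions and keeps chirality", {
  set.seed(8)
  a <- matrix(rnorm(30), 10)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  b <- a %*% t(rot) + matrix(rep(c(1, -2, 3), each = 10), 10)
  fit <- superpose(a, b)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # mirrored copy cannot be superposed with a proper rotation
  b_mirror <- a %*% diag(c(-1, 1, 1))
  fit_m <- superpose(a, b_mirror)
  expect_gt(fit_m$rmsd, 0.1)
  expect_equal(det(fit_m$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(a[1:2, ], b[1:2, ]), "3 point")
})

test_that("superposition RMSD is a lower bound over random rigid motions", {
  set.seed(21)
  a <- matrix(rnorm(15), 5)
  b <- matrix(rnorm(15), 5)
  best <- superpose(a, b)$rmsd
  for (k in 1:1000) {
    rot <- triscreen:::random_rotation()
    tr <- rnorm(3)
    moved <- sweep(a %*% t(rot), 2, tr, "+")
    expect_gte(sqrt(mean(rowSums((moved - b)^2))) + 1e-12, best)
  }
})

test_that("superposition agrees with the bio3d reference fit", {
  set.seed(31)
  a <- matrix(rnorm(45), 15)
  b <- a + matrix(rnorm(45, sd = 0.5), 15)
  ours <- superpose(a, b)$rmsd
  ref <- bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("SSE matching equals exhaustive enumeration for small lists", {
  set.seed(12)
  for (k in 1:40) {
    q <- random_sse_list(sample(1:5, 1))
    t <- random_sse_list(sample(1:5, 1))
    m <- match_sse(q, t)
    expect_equal(m$total_score, oracle_sse_match_score(q, t), tolerance = 1e-9,
                 label = paste("case", k))
    # pairs must be valid: ordered, type-consistent
    if (nrow(m$pairs) > 1) {
      expect_true(all(diff(m$pairs$q_idx) > 0))
      expect_true(all(diff(m$pairs$t_idx) > 0))
    }
    if (nrow(m$pairs) > 0) {
      expect_true(all(q$type[m$pairs$q_idx] == t$type[m$pairs$t_idx]))
    }
  }
})

test_that("SSE match boundary cases follow the percent-match conventions", {
  q <- random_sse_list(4)
  expect_equal(match_sse(q, q)$percent_match, 100)
  expect_equal(match_sse(q, q)$pairs$q_idx, 1:4)
  # [H, E, H] vs [H, H]: the strand stays unmatched
  qh <- random_sse_list(3); qh$type <- c("helix", "strand", "helix")
  th <- random_sse_list(2); th$type <- c("helix", "helix")
  m <- match_sse(qh, th)
  expect_lte(m$n_matched, 2)
  expect_lte(m$percent_match, 200 / 3)
  # empty query convention
  expect_equal(match_sse(qh[0, ], th)$percent_match, 0)
  # denominator switch
  expect_equal(match_sse(qh, th, denominator = "min")$n_matched /
                 2 * 100, match_sse(qh, th, denominator = "min")$percent_match)
})

test_that("self-alignment is exact and the Q formula is honoured", {
  m <- gen_structure(lpmo_like_plan(), 0, seed = 13L, id = "self")
  aln <- align_structures(m, m)
  expect_equal(aln$nalign, length(m))
  expect_lt(aln$rmsd, 1e-6)
  expect_equal(aln$q, 1, tolerance = 1e-6)
  expect_equal(q_score(50, 3.0, 100, 100, r0 = 3.0), 0.125)
  expect_equal(q_score(0, 0, 100, 100), 0)
})

test_that("Q decreases strictly along a coordinate-noise ladder", {
  clean <- gen_structure(lpmo_like_plan(), 0, seed = 5L, id = "q")
  qs <- purrr::map_dbl(c(0, 0.5, 1.0, 2.0), function(s) {
    align_structures(clean, perturb_structure(clean, s, seed = 99L, id = "t"))$q
  })
  expect_equal(qs[1], 1, tolerance = 1e-6)
  expect_true(all(diff(qs) < 0))
})

test_that("Q is symmetric and bounded", {
  a <- gen_structure(lpmo_like_plan(), 0, seed = 1L, id = "a")
  b <- perturb_structure(a, 0.6, seed = 2L, id = "b")
  qab <- align_structures(a, b)$q
  qba <- align_structures(b, a)$q
  expect_equal(qab, qba, tolerance = 1e-6)
  expect_gte(qab, 0)
  expect_lte(qab, 1)
})

test_that("database search ranks the query first and filters monotonically", {
  sc <- cached_scenario()
  db <- read_structure_db(sc$paths$structure_dir)
  query <- read_structure(sc$paths$queries$TPL_AA9$pdb)
  hits50 <- search_structure_db(query, db, lowest_match = 50)
  # the template shares the query fold exactly
  expect_equal(hits50$target[1], "TPL_AA9")
  expect_gt(hits50$q[1], 0.99)
  hits100 <- search_structure_db(query, db, lowest_match = 100)
  hits30 <- search_structure_db(query, db, lowest_match = 30)
  expect_true(all(hits100$target %in% hits50$target))
  expect_true(all(hits50$target %in% hits30$target))
})

test_that("hit sets ignore the confidence column entirely", {
  sc <- cached_scenario()
  db <- read_structure_db(sc$paths$structure_dir)
  query <- read_structure(sc$paths$queries$TPL_AA9$pdb)
  db_hi <- purrr::map(db, function(m) {
    structure_model(m$id, m$xyz, rep(95, length(m)), m$resno)
  })
  db_lo <- purrr::map(db, function(m) {
    structure_model(m$id, m$xyz, rep(55, length(m)), m$resno)
  })
  h1 <- search_structure_db(query, db_hi, lowest_match = 50)
  h2 <- search_structure_db(query, db_lo, lowest_match = 50)
  expect_equal(h1, h2)
})

test_that("alignment degenerates gracefully without any correspondence", {
  coil_a <- gen_structure(tibble::tibble(type = "coil", length = 20L), 0, seed = 1L, id = "a")
  coil_b <- gen_structure(tibble::tibble(type = "coil", length = 21L), 0, seed = 2L, id = "b")
  aln <- align_structures(coil_a, coil_b)
  expect_equal(aln$nalign, 0L)
  expect_equal(aln$q, 0)
})
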