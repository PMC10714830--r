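# Residue-level structural alignment: Kabsch superposition, iterative
# mutually-nearest-neighbour refinement seeded from the SSE correspondence,
# and the Q-score of the final alignment.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Returns the proper rotation (determinant +1) and translation minimising
#' the RMSD of `a` onto `b`, and that minimal RMSD.
#'
#' @param a,b Numeric n x 3 matrices of paired points (n >= 3, not all
#'   collinear).
#' @return List `rotation` (3 x 3), `translation` (length 3; apply as
#'   `a %*% t(rotation) + translation`), `rmsd`.
#' @export
superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 3) stop("need at least 3 point pairs")
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(rotation = rot, translation = as.numeric(cb - ca %*% t(rot)), rmsd = rmsd)
}

#' Q-score of a structural alignment
#'
#' `Q = Nalign^2 / ((1 + (RMSD / R0)^2) * N1 * N2)`, in `[0, 1]`, equal to 1
#' only for a complete zero-RMSD alignment of equal-size models. `R0 = 3` A
#' is the established scale constant.
#'
#' @param nalign Number of aligned residue pairs.
#' @param rmsd RMSD (A) of the aligned pairs after optimal superposition.
#' @param n1,n2 Residue counts of the two models.
#' @param r0 Scale constant (A).
#' @return The Q-score.
#' @export
q_score <- function(nalign, rmsd, n1, n2, r0 = 3.0) {
  if (n1 == 0 || n2 == 0) return(0)
  nalign^2 / ((1 + (rmsd / r0)^2) * n1 * n2)
}

#' Align two structure models
#'
#' Seeds residue pairs from the SSE correspondence (elements matched by
#' [match_sse()], paired across their overlapping midsections), then
#' iterates: Kabsch-superpose on the current pairs, re-pair as mutually
#' nearest C-alpha neighbours within `cutoff` A, stop when the pair set is
#' unchanged (at most `max_iter` rounds). If no SSE correspondence and no
#' pairs within the cutoff exist, returns `Nalign = 0`, `Q = 0`.
#'
#' @param model_a,model_b [structure_model()]s with >= 3 residues.
#' @param r0 Q-score scale constant (A).
#' @param cutoff Nearest-neighbour pairing cutoff (A).
#' @param max_iter Maximum refinement rounds.
#' @return A `struct_alignment`: list with `pairs` (tibble `a_idx`,
#'   `b_idx`), `nalign`, `rmsd`, `n1`, `n2`, `r0`, `q`, `rotation`,
#'   `translation`, `iterations`.
#' @export
align_structures <- function(model_a, model_b, r0 = 3.0, cutoff = 4.5,
                             max_iter = 50L) {
  n1 <- nrow(model_a$xyz); n2 <- nrow(model_b$xyz)
  stopifnot(n1 >= 3, n2 >= 3)
  sse_a <- assign_sse(model_a)
  sse_b <- assign_sse(model_b)
  m <- match_sse(sse_a, sse_b)
  seeds <- list(sse = seed_pairs(sse_a, sse_b, m$pairs))
  if (n1 == n2) {
    # equal-size models: the sequential correspondence is a cheap extra
    # basin to start from (rescues noisy near-identical folds whose SSE
    # windows have degraded); a wrong fold simply refines to a low Q
    seeds$sequential <- tibble::tibble(a_idx = seq_len(n1), b_idx = seq_len(n2))
  }
  seeds <- purrr::keep(seeds, ~ nrow(.x) >= 3)
  if (!length(seeds)) {
    return(empty_alignment(model_a, model_b, r0, sse_percent = m$percent_match))
  }
  results <- purrr::map(seeds, function(p) {
    refine_alignment(model_a$xyz, model_b$xyz, p, cutoff, max_iter, r0)
  })
  qs <- purrr::map_dbl(results, "q")
  best <- results[[which.max(qs)]]
  if (best$nalign == 0) {
    return(empty_alignment(model_a, model_b, r0, sse_percent = m$percent_match))
  }
  structure(
    c(
      list(id_a = model_a$id, id_b = model_b$id),
      best,
      list(n1 = n1, n2 = n2, r0 = r0, sse_percent_match = m$percent_match)
    ),
    class = "struct_alignment"
  )
}

# Iterative closest-point style refinement: superpose on the current pairs,
# re-pair as mutual nearest neighbours (one opening round at a doubled
# cutoff enlarges the convergence basin), stop when the pair set repeats.
refine_alignment <- function(xa, xb, pairs, cutoff, max_iter, r0) {
  n1 <- nrow(xa); n2 <- nrow(xb)
  it <- 0L
  for (round in seq_len(max_iter)) {
    it <- round
    fit <- superpose(xa[pairs$a_idx, , drop = FALSE], xb[pairs$b_idx, , drop = FALSE])
    moved <- sweep(xa %*% t(fit$rotation), 2, fit$translation, "+")
    cut <- if (round == 1) 2 * cutoff else cutoff
    new_pairs <- mutual_nn_pairs(moved, xb, cut)
    if (nrow(new_pairs) < 3) break
    if (round > 1 && identical(new_pairs, pairs)) {
      pairs <- new_pairs
      break
    }
    pairs <- new_pairs
  }
  fit <- superpose(xa[pairs$a_idx, , drop = FALSE], xb[pairs$b_idx, , drop = FALSE])
  list(
    pairs = pairs, nalign = nrow(pairs), rmsd = fit$rmsd,
    q = q_score(nrow(pairs), fit$rmsd, n1, n2, r0),
    rotation = fit$rotation, translation = fit$translation, iterations = it
  )
}

empty_alignment <- function(model_a, model_b, r0, sse_percent = 0) {
  structure(
    list(
      id_a = model_a$id, id_b = model_b$id,
      pairs = tibble::tibble(a_idx = integer(), b_idx = integer()),
      nalign = 0L, rmsd = NA_real_, n1 = nrow(model_a$xyz), n2 = nrow(model_b$xyz),
      r0 = r0, q = 0, sse_percent_match = sse_percent,
      rotation = diag(3), translation = c(0, 0, 0), iterations = 0L
    ),
    class = "struct_alignment"
  )
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat(sprintf("<struct_alignment> %s vs %s: Nalign %d, RMSD %.2f A, Q %.3f\n",
              x$id_a, x$id_b, x$nalign, x$rmsd, x$q))
  invisible(x)
}

#' Tidy / summarise a structural alignment
#'
#' `tidy()` returns the residue pair list; `glance()` a one-row summary
#' (`nalign`, `rmsd`, `n1`, `n2`, `r0`, `q`, `sse_percent_match`).
#'
#' @param x A `struct_alignment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.struct_alignment <- function(x, ...) x$pairs

#' @rdname tidy.struct_alignment
#' @export
glance.struct_alignment <- function(x, ...) {
  tibble::tibble(
    id_a = x$id_a, id_b = x$id_b, nalign = x$nalign, rmsd = x$rmsd,
    n1 = x$n1, n2 = x$n2, r0 = x$r0, q = x$q,
    sse_percent_match = x$sse_percent_match, iterations = x$iterations
  )
}

# Seed residue pairs across the overlapping midsections of matched SSEs.
seed_pairs <- function(sse_a, sse_b, sse_pairs) {
  if (nrow(sse_pairs) == 0) {
    return(tibble::tibble(a_idx = integer(), b_idx = integer()))
  }
  purrr::map(seq_len(nrow(sse_pairs)), function(k) {
    ea <- sse_a[sse_pairs$q_idx[k], ]
    eb <- sse_b[sse_pairs$t_idx[k], ]
    len <- min(ea$length, eb$length)
    offa <- ea$start + (ea$length - len) %/% 2
    offb <- eb$start + (eb$length - len) %/% 2
    tibble::tibble(a_idx = offa + seq_len(len) - 1L, b_idx = offb + seq_len(len) - 1L)
  }) |> dplyr::bind_rows()
}

# Mutually nearest neighbours within a distance cutoff.
mutual_nn_pairs <- function(a, b, cutoff) {
  # pairwise squared distances
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  nn_ab <- max.col(-d2, ties.method = "first")
  nn_ba <- max.col(-t(d2), ties.method = "first")
  ia <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab] == ia
  dist_ok <- d2[cbind(ia, nn_ab)] <= cutoff^2
  keep <- which(mutual & dist_ok)
  tibble::tibble(a_idx = keep, b_idx = nn_ab[keep])
}

#' Search a structure database with a query model
#'
#' Stage 1 filters targets by the "lowest acceptable match": the percentage
#' of query SSEs with an order-preserving, type-consistent correspondence in
#' the target ([match_sse()]) must reach `lowest_match`. Survivors get a
#' residue-level alignment ([align_structures()]) and are ranked by Q-score
#' descending, ties broken by target id. Per-residue confidence is carried
#' but never filtered on.
#'
#' @param query A [structure_model()].
#' @param db Named list of [structure_model()]s (see [read_structure_db()]).
#' @param lowest_match Lowest acceptable SSE match, percent in `[0, 100]`.
#' @param r0,cutoff,max_iter Passed to [align_structures()].
#' @param denominator Percent-match convention, see [match_sse()].
#' @return A tibble of hits: `target`, `percent_match`, `nalign`, `rmsd`,
#'   `q`, `n1`, `n2`, sorted by `q` descending then `target`.
#' @export
search_structure_db <- function(query, db, lowest_match = 50,
                                r0 = 3.0, cutoff = 4.5, max_iter = 50L,
                                denominator = "query") {
  stopifnot(length(db) > 0, lowest_match >= 0, lowest_match <= 100)
  query_sses <- assign_sse(query)
  rows <- purrr::map(db, function(target) {
    m <- match_sse(query_sses, assign_sse(target), denominator = denominator)
    if (m$percent_match < lowest_match) return(NULL)
    aln <- align_structures(query, target, r0 = r0, cutoff = cutoff,
                            max_iter = max_iter)
    tibble::tibble(
      target = target$id, percent_match = m$percent_match,
      nalign = aln$nalign, rmsd = aln$rmsd, q = aln$q,
      n1 = aln$n1, n2 = aln$n2
    )
  })
  rows <- unname(purrr::compact(rows))
  empty <- tibble::tibble(
    target = character(), percent_match = double(), nalign = integer(),
    rmsd = double(), q = double(), n1 = integer(), n2 = integer()
  )
  dplyr::bind_rows(empty, rows) |>
    dplyr::arrange(dplyr::desc(.data$q), .data$target)
}
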