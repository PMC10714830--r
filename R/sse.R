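# Secondary-structure-element assignment from C-alpha geometry (P-SEA style
# short-range distance windows) and order-preserving SSE matching by dynamic
# programming -- the mechanism behind the "lowest acceptable match" filter.

# Geometric windows (Angstrom); config-exposed via arguments.
SSE_WINDOWS <- list(
  helix_d2 = c(5.1, 6.4), helix_d3 = c(4.6, 6.4), strand_d2 = c(6.4, 7.4)
)

#' Assign secondary-structure elements from C-alpha geometry
#'
#' A residue run is helical when `d(i, i+2)` and `d(i, i+3)` stay inside the
#' alpha-helix windows for at least 5 covered residues, and strand when
#' `d(i, i+2)` stays inside the extended window for at least 3 covered
#' residues (at least two consecutive window hits, which suppresses
#' single-residue artifacts at segment junctions). Helices take precedence
#' on overlaps. Each element's axis is the principal component of its
#' C-alpha coordinates, oriented N- to C-terminal.
#'
#' @param model A [structure_model()].
#' @param windows Geometric windows (named list like `SSE_WINDOWS`).
#' @return A tibble of SSEs: `type` (`"helix"`/`"strand"`), `start`, `end`
#'   (residue indices, inclusive), `length`, and axis components `ax`, `ay`,
#'   `az`.
#' @export
assign_sse <- function(model, windows = SSE_WINDOWS) {
  xyz <- model$xyz
  n <- nrow(xyz)
  empty <- tibble::tibble(
    type = character(), start = integer(), end = integer(),
    length = integer(), ax = double(), ay = double(), az = double()
  )
  if (n < 5) return(empty)
  d2 <- sqrt(rowSums((xyz[seq_len(n - 2) + 2, , drop = FALSE] -
                        xyz[seq_len(n - 2), , drop = FALSE])^2))
  d3 <- sqrt(rowSums((xyz[seq_len(n - 3) + 3, , drop = FALSE] -
                        xyz[seq_len(n - 3), , drop = FALSE])^2))
  in_win <- function(x, w) x >= w[1] & x <= w[2]
  h_ind <- in_win(d2[seq_along(d3)], windows$helix_d2) & in_win(d3, windows$helix_d3)
  e_ind <- in_win(d2, windows$strand_d2)

  helix <- runs_to_sse(h_ind, cover = 3L, min_run = 2L, min_len = 5L, "helix", n)
  taken <- rep(FALSE, n)
  for (i in seq_len(nrow(helix))) taken[helix$start[i]:helix$end[i]] <- TRUE
  # strands only where helices did not claim the residues
  e_ind[e_ind] <- vapply(which(e_ind), function(i) !any(taken[i:min(i + 2, n)]), logical(1))
  strand <- runs_to_sse(e_ind, cover = 2L, min_run = 2L, min_len = 3L, "strand", n)

  out <- dplyr::bind_rows(helix, strand) |> dplyr::arrange(.data$start)
  if (nrow(out) == 0) return(empty)
  axes <- purrr::map(seq_len(nrow(out)), function(i) {
    segment_axis(xyz[out$start[i]:out$end[i], , drop = FALSE])
  })
  out$ax <- purrr::map_dbl(axes, 1)
  out$ay <- purrr::map_dbl(axes, 2)
  out$az <- purrr::map_dbl(axes, 3)
  out
}

# Convert an indicator over window start positions into covered SSE segments.
runs_to_sse <- function(ind, cover, min_run, min_len, type, n) {
  r <- rle(ind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_run)
  if (!length(keep)) {
    return(tibble::tibble(type = character(), start = integer(), end = integer(),
                          length = integer()))
  }
  s <- starts[keep]
  e <- pmin(ends[keep] + cover, n)
  # merge covered intervals that overlap or touch (window-boundary jitter
  # can split one physical element into adjacent runs)
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(s)[-1]) {
    if (s[k] <= me + 1L) {
      me <- max(me, e[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[k]; me <- e[k]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  tibble::tibble(
    type = type,
    start = as.integer(out_s),
    end = as.integer(out_e)
  ) |>
    dplyr::mutate(length = .data$end - .data$start + 1L) |>
    dplyr::filter(.data$length >= min_len)
}

segment_axis <- function(xyz) {
  c0 <- scale(xyz, scale = FALSE)
  v <- svd(c0, nu = 0, nv = 1)$v[, 1]
  disp <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(v * disp) < 0) v <- -v
  v
}

#' Match two SSE sequences and compute the percent match
#'
#' Order-preserving correspondence by dynamic programming over the two SSE
#' lists. A pair is admissible only with equal type; its score rewards
#' similar length and similar inter-SSE axis angles:
#' `score = 2 - |dlen| / max(len) - |dangle| / pi`, where the angle feature
#' of element k is the angle between its axis and the previous element's
#' axis in the same structure. Skips cost nothing; the DP maximises total
#' score. `percent_match` is computed over query SSEs by default
#' (`denominator = "query"`), with `"min"` and `"target"` variants.
#'
#' @param query_sses,target_sses Tibbles from [assign_sse()] (may be empty).
#' @param denominator One of `"query"`, `"min"`, `"target"`.
#' @return A list: `pairs` (tibble `q_idx`, `t_idx`, `score`), `n_matched`,
#'   `percent_match`, `total_score`.
#' @export
match_sse <- function(query_sses, target_sses, denominator = c("query", "min", "target")) {
  denominator <- match.arg(denominator)
  nq <- nrow(query_sses)
  nt <- nrow(target_sses)
  empty_pairs <- tibble::tibble(q_idx = integer(), t_idx = integer(), score = double())
  denom <- switch(denominator,
    query = nq, target = nt, min = min(nq, nt)
  )
  if (nq == 0 || nt == 0) {
    return(list(pairs = empty_pairs, n_matched = 0L, percent_match = 0,
                total_score = 0))
  }
  qa <- inter_sse_angles(query_sses)
  ta <- inter_sse_angles(target_sses)
  s <- matrix(-Inf, nq, nt)
  for (i in seq_len(nq)) {
    for (j in seq_len(nt)) {
      if (query_sses$type[i] == target_sses$type[j]) {
        s[i, j] <- sse_pair_score(query_sses$length[i], target_sses$length[j],
                                  qa[i], ta[j])
      }
    }
  }
  dp <- matrix(0, nq + 1, nt + 1)
  for (i in seq_len(nq)) {
    for (j in seq_len(nt)) {
      dp[i + 1, j + 1] <- max(
        dp[i, j + 1], dp[i + 1, j],
        if (is.finite(s[i, j])) dp[i, j] + s[i, j] else -Inf
      )
    }
  }
  # traceback (prefer diagonal, then query-skip, for determinism)
  pairs <- list()
  i <- nq; j <- nt
  while (i > 0 && j > 0) {
    if (is.finite(s[i, j]) && abs(dp[i + 1, j + 1] - (dp[i, j] + s[i, j])) < 1e-12) {
      pairs[[length(pairs) + 1L]] <- tibble::tibble(q_idx = i, t_idx = j, score = s[i, j])
      i <- i - 1; j <- j - 1
    } else if (abs(dp[i + 1, j + 1] - dp[i, j + 1]) < 1e-12) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  pairs <- if (length(pairs)) dplyr::arrange(dplyr::bind_rows(pairs), .data$q_idx) else empty_pairs
  n_matched <- nrow(pairs)
  list(
    pairs = pairs, n_matched = n_matched,
    percent_match = if (denom > 0) 100 * n_matched / denom else 0,
    total_score = dp[nq + 1, nt + 1]
  )
}

sse_pair_score <- function(len_q, len_t, ang_q, ang_t) {
  2 - abs(len_q - len_t) / max(len_q, len_t) - abs(ang_q - ang_t) / pi
}

# Angle (radians) between each SSE axis and its predecessor's; first SSE -> 0.
inter_sse_angles <- function(sses) {
  n <- nrow(sses)
  if (n == 0) return(numeric(0))
  ax <- as.matrix(sses[, c("ax", "ay", "az")])
  out <- numeric(n)
  if (n > 1) {
    for (k in 2:n) {
      cosv <- sum(ax[k, ] * ax[k - 1, ])
      out[k] <- acos(pmin(1, pmax(-1, cosv)))
    }
  }
  out
}
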