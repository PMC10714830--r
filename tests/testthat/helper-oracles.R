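# Independent oracles used to validate the dynamic-programming routes.

# Smith-Waterman by direct quartic recurrence: H(i,j) = best local alignment
# ending with column (i,j), maximising over all predecessor pairs with
# closed-form affine gap costs (no three-state machinery).
oracle_sw_score <- function(query, target, matrix, gap_open, gap_extend) {
  qs <- strsplit(query, "")[[1]]
  ts <- strsplit(target, "")[[1]]
  n <- length(qs)
  m <- length(ts)
  if (n == 0 || m == 0) return(0)
  gap_cost <- function(L) ifelse(L <= 0, 0, gap_open + L * gap_extend)
  H <- matrix(0, n, m)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- matrix[qs[i], ts[j]]
      b <- s
      if (i > 1 && j > 1) {
        prev <- H[seq_len(i - 1), seq_len(j - 1), drop = FALSE]
        gq <- gap_cost(i - seq_len(i - 1) - 1)
        gt <- gap_cost(j - seq_len(j - 1) - 1)
        b <- max(b, max(prev - outer(gq, rep(0, j - 1), "+") -
                          outer(rep(0, i - 1), gt, "+")) + s)
      }
      H[i, j] <- max(0, b)
      best <- max(best, H[i, j])
    }
  }
  best
}

# Forward odds by exhaustive path enumeration over the local-wrapped profile
# (entry 1/M into any match state at any position, exit factor 1/M from any
# match state; insert emissions and flanks are background => odds 1).
oracle_forward_odds <- function(hmm, seq) {
  M <- hmm$M
  x <- match(strsplit(seq, "")[[1]], triscreen:::AA20)
  L <- length(x)
  eo <- sweep(hmm$emissions, 2, hmm$background, "/")
  emit <- function(j, i) if (is.na(x[i])) 1 else eo[j, x[i]]
  total <- 0
  recurse <- function(state, j, i, w) {
    # contribute on every match-state visit (possible exit point)
    if (state == "M") total <<- total + w / M
    if (j >= M && state != "D") {
      # from M_M / I_M nothing further (no transitions out of last node)
      return(invisible())
    }
    if (state == "M") {
      if (i < L) {
        recurse("M", j + 1, i + 1, w * hmm$tMM[j] * emit(j + 1, i + 1))
        recurse("I", j, i + 1, w * hmm$tMI[j])
      }
      recurse("D", j + 1, i, w * hmm$tMD[j])
    } else if (state == "I") {
      if (i < L) {
        recurse("I", j, i + 1, w * hmm$tII[j])
        recurse("M", j + 1, i + 1, w * hmm$tIM[j] * emit(j + 1, i + 1))
      }
    } else { # D
      if (j < M) {
        recurse("D", j + 1, i, w * hmm$tDD[j])
        if (i < L) recurse("M", j + 1, i + 1, w * hmm$tDM[j] * emit(j + 1, i + 1))
      }
    }
    invisible()
  }
  for (u in seq_len(L)) {
    for (j0 in seq_len(M)) {
      recurse("M", j0, u, (1 / M) * emit(j0, u))
    }
  }
  unname(total)
}

# SSE matching by exhaustive enumeration of all order-preserving,
# type-consistent matchings (both sides <= 5 elements).
oracle_sse_match_score <- function(query_sses, target_sses) {
  nq <- nrow(query_sses)
  nt <- nrow(target_sses)
  if (nq == 0 || nt == 0) return(0)
  qa <- triscreen:::inter_sse_angles(query_sses)
  ta <- triscreen:::inter_sse_angles(target_sses)
  best <- 0
  for (k in seq_len(min(nq, nt))) {
    qc <- utils::combn(nq, k, simplify = FALSE)
    tc <- utils::combn(nt, k, simplify = FALSE)
    for (qi in qc) {
      for (ti in tc) {
        if (all(query_sses$type[qi] == target_sses$type[ti])) {
          s <- sum(purrr::map_dbl(seq_len(k), function(z) {
            triscreen:::sse_pair_score(
              query_sses$length[qi[z]], target_sses$length[ti[z]],
              qa[qi[z]], ta[ti[z]]
            )
          }))
          best <- max(best, s)
        }
      }
    }
  }
  best
}

random_sse_list <- function(n) {
  d <- tibble::tibble(
    type = sample(c("helix", "strand"), n, replace = TRUE),
    start = cumsum(sample(5:12, n, replace = TRUE)),
    length = sample(3:12, n, replace = TRUE)
  )
  d$end <- d$start + d$length - 1L
  ax <- matrix(stats::rnorm(n * 3), n)
  nrm <- sqrt(rowSums(ax^2))
  d$ax <- ax[, 1] / nrm
  d$ay <- ax[, 2] / nrm
  d$az <- ax[, 3] / nrm
  d
}
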