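# Domain-based search: bespoke profile HMMs built from curated family MSAs,
# scored by the full forward algorithm in log-odds bits against an i.i.d.
# background null, with significance calibrated on shuffled decoys via a
# moment-matched Gumbel fit.

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns whose residue occupancy is at least `match_fraction` become match
#' states. Match emissions are smoothed residue counts
#' `(counts + pseudocount * background)` normalised per state; transition
#' probabilities come from the observed match/insert/delete paths of the
#' aligned rows with the same Laplace-style smoothing. Insert states emit the
#' background (so insertions are score-neutral).
#'
#' @param msa Named character vector of aligned sequences (equal length; `-`
#'   or `.` for gaps), or the path of an aligned FASTA file.
#' @param match_fraction Minimum column occupancy for a match state
#'   (boundary inclusive).
#' @param pseudocount Smoothing weight against the background.
#' @param background Residue background composition (length 20, sums to 1).
#' @return An `hmm_profile`: list with `M`, `emissions` (M x 20), the seven
#'   per-node transition vectors, `background`, `consensus` and
#'   `match_columns`.
#' @export
build_hmm <- function(msa, match_fraction = 0.5, pseudocount = 1.0,
                      background = rep(1 / 20, 20)) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    msa <- read_fasta_vec(msa)
  }
  stopifnot(length(msa) >= 1, length(background) == 20)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1) stop("aligned rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  is_gap <- mat == "-" | mat == "."
  occupancy <- colMeans(!is_gap)
  match_cols <- which(occupancy >= match_fraction)
  M <- length(match_cols)
  if (M == 0) stop("degenerate MSA: no match columns at match_fraction ", match_fraction)

  # emissions
  emissions <- matrix(0, M, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    res <- mat[, match_cols[k]]
    res <- res[res %in% AA20]
    cnt <- table(factor(res, levels = AA20)) / nrow(mat) # per-row weights 1/n
    e <- as.numeric(cnt) + pseudocount * background
    emissions[k, ] <- e / sum(e)
  }

  # transitions from observed paths
  nt <- max(M - 1, 0)
  cM <- matrix(0, max(nt, 1), 3, dimnames = list(NULL, c("MM", "MI", "MD")))
  cI <- matrix(0, max(nt, 1), 2, dimnames = list(NULL, c("II", "IM")))
  cD <- matrix(0, max(nt, 1), 2, dimnames = list(NULL, c("DD", "DM")))
  col_role <- rep("I", ncol(mat))
  col_role[match_cols] <- "M"
  node_of_col <- integer(ncol(mat))
  node_of_col[match_cols] <- seq_len(M)
  for (r in seq_len(nrow(mat))) {
    prev_state <- NULL # c(state, node)
    for (c in seq_len(ncol(mat))) {
      st <- if (col_role[c] == "M") {
        c(if (is_gap[r, c]) "D" else "M", node_of_col[c])
      } else if (!is_gap[r, c]) {
        # insert between match nodes: belongs to the preceding node
        node <- sum(match_cols < c)
        if (node == 0 || node >= M) NULL else c("I", node)
      } else {
        NULL
      }
      if (is.null(st)) next
      if (!is.null(prev_state)) {
        j <- as.integer(prev_state[2])
        key <- paste0(prev_state[1], st[1])
        if (j >= 1 && j <= nt) {
          if (prev_state[1] == "M" && key %in% colnames(cM)) cM[j, key] <- cM[j, key] + 1
          if (prev_state[1] == "I" && key %in% colnames(cI)) cI[j, key] <- cI[j, key] + 1
          if (prev_state[1] == "D" && key %in% colnames(cD)) cD[j, key] <- cD[j, key] + 1
        }
      }
      prev_state <- st
    }
  }
  # equal sequence weighting (1/n) so duplicated rows leave the profile
  # unchanged
  cM <- cM / nrow(mat)
  cI <- cI / nrow(mat)
  cD <- cD / nrow(mat)
  smooth <- function(counts) {
    k <- ncol(counts)
    p <- sweep(counts + pseudocount / k, 1, rowSums(counts) + pseudocount, "/")
    p
  }
  tM <- smooth(cM)
  tI <- smooth(cI)
  tD <- smooth(cD)

  consensus <- paste(AA20[apply(emissions, 1, which.max)], collapse = "")
  structure(
    list(
      M = M, emissions = emissions, background = background,
      tMM = tM[seq_len(nt), "MM"], tMI = tM[seq_len(nt), "MI"], tMD = tM[seq_len(nt), "MD"],
      tII = tI[seq_len(nt), "II"], tIM = tI[seq_len(nt), "IM"],
      tDD = tD[seq_len(nt), "DD"], tDM = tD[seq_len(nt), "DM"],
      consensus = consensus, match_columns = match_cols
    ),
    class = "hmm_profile"
  )
}

#' @export
print.hmm_profile <- function(x, ...) {
  cat(sprintf("<hmm_profile> %d match states, consensus %s...\n",
              x$M, substr(x$consensus, 1, 30)))
  invisible(x)
}

#' Forward (or Viterbi) log-odds score in bits
#'
#' Sum (forward) or maximum (Viterbi) over all alignments of the sequence to
#' the local-alignment-wrapped profile, in log2 odds against the i.i.d.
#' background null. The local wrapping is uniform: entry probability `1/M`
#' into any match state, exit factor `1/M` from any match state; residues
#' outside the aligned region and insert-state emissions score as background.
#' Residues outside the 20-letter alphabet are background-distributed
#' wildcards (log-odds 0).
#'
#' @param hmm An [build_hmm()] profile.
#' @param seq Amino-acid sequence (non-empty character scalar).
#' @param viterbi Use the best single path instead of the sum.
#' @return Log-odds score in bits (finite).
#' @export
forward_bits <- function(hmm, seq, viterbi = FALSE) {
  stopifnot(inherits(hmm, "hmm_profile"), nchar(seq) >= 1)
  idx <- match(strsplit(toupper(seq), "")[[1]], AA20) - 1L
  idx[is.na(idx)] <- 20L
  lo <- cbind(log(sweep(hmm$emissions, 2, hmm$background, "/")), 0)
  nats <- hmm_score_cpp(
    lo, idx,
    log(hmm$tMM), log(hmm$tMI), log(hmm$tMD),
    log(hmm$tIM), log(hmm$tII),
    log(hmm$tDM), log(hmm$tDD),
    viterbi
  )
  nats / log(2)
}

#' @rdname forward_bits
#' @export
viterbi_bits <- function(hmm, seq) forward_bits(hmm, seq, viterbi = TRUE)

#' Calibrate a profile on shuffled decoys and search a proteome
#'
#' Null scores come from `n_null` residue-shuffled sequences drawn (with
#' replacement) from the proteome itself, fitted with a Gumbel by moment
#' matching (`beta = sd * sqrt(6) / pi`, `mu = mean - gamma * beta`).
#' Per-sequence P-values are the Gumbel upper tail; E-values multiply by the
#' number of target sequences searched. A hit is `included` when
#' `E <= inclusion`.
#'
#' @param hmm An [build_hmm()] profile.
#' @param proteome Tibble with `id`, `seq` columns or named character vector.
#' @param inclusion Inclusion threshold on the E-value (default 0.01).
#' @param n_null Number of shuffled null sequences (>= 100).
#' @param seed Integer seed for the shuffles.
#' @return A tibble: `target`, `bits`, `pvalue`, `evalue`, `included`,
#'   sorted by `evalue` then target id, with the Gumbel location/scale as
#'   attributes `mu`, `beta`.
#' @export
calibrate_and_search <- function(hmm, proteome, inclusion = 0.01,
                                 n_null = 200L, seed = 1L) {
  stopifnot(n_null >= 100)
  proteome <- as_proteome_tbl(proteome)
  null_bits <- withr::with_seed(as.integer(seed), {
    src <- sample(nrow(proteome), n_null, replace = TRUE)
    purrr::map_dbl(src, function(i) forward_bits(hmm, scramble_seq(proteome$seq[i])))
  })
  if (sd(null_bits) < 1e-9) stop("degenerate null variance")
  fit <- gumbel_fit(null_bits)
  bits <- purrr::map_dbl(proteome$seq, function(s) forward_bits(hmm, s))
  pv <- gumbel_upper_tail(bits, fit$mu, fit$beta)
  out <- tibble::tibble(
    target = proteome$id, bits = bits, pvalue = pv,
    evalue = pv * nrow(proteome)
  ) |>
    dplyr::mutate(included = .data$evalue <= inclusion) |>
    dplyr::arrange(.data$evalue, .data$target)
  attr(out, "mu") <- fit$mu
  attr(out, "beta") <- fit$beta
  out
}

gumbel_fit <- function(x) {
  beta <- sd(x) * sqrt(6) / pi
  mu <- mean(x) - 0.5772156649 * beta
  list(mu = mu, beta = beta)
}

gumbel_upper_tail <- function(x, mu, beta) {
  # 1 - exp(-exp(-z)), computed stably for large z
  z <- (x - mu) / beta
  -expm1(-exp(-z))
}

#' Serialize / load a profile HMM as plain text (YAML)
#'
#' @param hmm An `hmm_profile`.
#' @param path File path.
#' @return `read_hmm()` returns the profile; `write_hmm()` the path,
#'   invisibly.
#' @export
write_hmm <- function(hmm, path) {
  x <- unclass(hmm)
  x$emissions <- as.vector(x$emissions)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  x <- yaml::read_yaml(path)
  x$emissions <- matrix(x$emissions, x$M, 20, dimnames = list(NULL, AA20))
  for (f in c("tMM", "tMI", "tMD", "tII", "tIM", "tDD", "tDM", "background")) {
    x[[f]] <- as.numeric(x[[f]])
  }
  structure(x, class = "hmm_profile")
}
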