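# Cross-reference candidates with a glucose-versus-substrate expression time
# course and flag up-regulation on at least one timepoint.

#' Up-regulation flags for one protein
#'
#' Per substrate timepoint the flag requires both an effect size --
#' `log2(mean substrate TPM / mean glucose TPM) >= min_log2fc` -- and
#' significance: Welch two-sample t-test on `log2(TPM + 0.5)`, with
#' Benjamini-Hochberg correction across whatever candidate x timepoint set
#' is tested together (here, this protein's timepoints; use
#' [candidate_expression_report()] to correct across a candidate set). The
#' pseudo-TPM of 0.5 guards against zeros. This operational test is the
#' package's own stand-in for upstream differential-expression calls;
#' precomputed flags can be ingested instead via the `flags` argument of
#' [candidate_expression_report()].
#'
#' @param table Expression tibble: `protein_id`, `condition`
#'   (`glucose`/`substrate`), `timepoint` (`none` for glucose, else
#'   `d2`/`d4`/`d10`), `replicate`, `tpm`.
#' @param protein Protein id (must be present in both conditions).
#' @param min_log2fc Minimum log2 fold-change (>= 0, default 1).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return Tibble with one row per timepoint (`timepoint`, `log2fc`,
#'   `pvalue`, `padj`, `flag`) plus attribute `any_timepoint`.
#' @export
upregulation_flags <- function(table, protein, min_log2fc = 1, alpha = 0.05) {
  stopifnot(min_log2fc >= 0, alpha > 0, alpha < 1)
  stats_tbl <- timepoint_stats(table, protein)
  stats_tbl$padj <- p.adjust(stats_tbl$pvalue, method = "BH")
  stats_tbl$flag <- stats_tbl$log2fc >= min_log2fc & stats_tbl$padj <= alpha
  attr(stats_tbl, "any_timepoint") <- any(stats_tbl$flag)
  stats_tbl
}

# Raw per-timepoint effect and P-value (no multiplicity correction).
timepoint_stats <- function(table, protein) {
  x <- dplyr::filter(table, .data$protein_id == protein)
  glu <- x$tpm[x$condition == "glucose"]
  if (nrow(x) == 0 || !length(glu) || !any(x$condition == "substrate")) {
    stop("protein '", protein, "' absent from one or both conditions")
  }
  tps <- intersect(c("d2", "d4", "d10"), unique(x$timepoint[x$condition == "substrate"]))
  purrr::map(tps, function(tp) {
    sub <- x$tpm[x$condition == "substrate" & x$timepoint == tp]
    lg <- log2(glu + 0.5)
    ls <- log2(sub + 0.5)
    p <- if (length(sub) > 1 && length(glu) > 1 &&
               (sd(lg) > 0 || sd(ls) > 0)) {
      t.test(ls, lg, alternative = "greater")$p.value
    } else {
      1
    }
    tibble::tibble(
      protein_id = protein, timepoint = tp,
      mean_glucose = mean(glu), mean_substrate = mean(sub),
      log2fc = log2(mean(sub + 0.5) / mean(glu + 0.5)),
      pvalue = p
    )
  }) |> dplyr::bind_rows()
}

#' Candidate x expression joined report
#'
#' For every candidate-matrix row: mean TPM per condition/timepoint, the
#' per-timepoint up-regulation flags (BH-corrected across the whole
#' candidate x timepoint set tested here) and the `any_timepoint` flag.
#' Candidates absent from the table are rendered with missing markers.
#'
#' @param matrix A [combine_hits()] candidate matrix (or tibble with a
#'   `protein_id` column).
#' @param table Expression tibble, see [upregulation_flags()].
#' @param min_log2fc,alpha As in [upregulation_flags()].
#' @param flags Optional precomputed tibble `protein_id`, `timepoint`,
#'   `flag` that replaces the built-in test.
#' @return An `expression_report` tibble: one row per candidate x timepoint
#'   (`log2fc`, `padj`, `flag`, means) plus `any_timepoint`; deterministic
#'   order (protein id, then d2/d4/d10).
#' @export
candidate_expression_report <- function(matrix, table, min_log2fc = 1,
                                        alpha = 0.05, flags = NULL) {
  ids <- sort(unique(matrix$protein_id))
  empty <- tibble::tibble(
    protein_id = character(), timepoint = character(),
    mean_glucose = double(), mean_substrate = double(),
    log2fc = double(), pvalue = double(), padj = double(),
    flag = logical(), any_timepoint = logical(), missing = logical()
  )
  rows <- purrr::map(ids, function(id) {
    if (!id %in% table$protein_id) {
      return(tibble::tibble(
        protein_id = id, timepoint = NA_character_,
        mean_glucose = NA_real_, mean_substrate = NA_real_,
        log2fc = NA_real_, pvalue = NA_real_, missing = TRUE
      ))
    }
    dplyr::mutate(timepoint_stats(table, id), missing = FALSE)
  }) |> dplyr::bind_rows()
  if (nrow(rows) > 0 && !all(rows$missing)) {
    if (is.null(flags)) {
      rows$padj <- NA_real_
      tested <- !rows$missing
      rows$padj[tested] <- p.adjust(rows$pvalue[tested], method = "BH")
      rows$flag <- !rows$missing & rows$log2fc >= min_log2fc & rows$padj <= alpha
    } else {
      rows <- dplyr::left_join(rows, flags, by = c("protein_id", "timepoint"))
      rows$padj <- NA_real_
      rows$flag[is.na(rows$flag)] <- FALSE
    }
    rows <- rows |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::mutate(any_timepoint = any(.data$flag)) |>
      dplyr::ungroup()
  }
  out <- dplyr::bind_rows(empty, rows) |>
    dplyr::arrange(.data$protein_id, match(.data$timepoint, c("d2", "d4", "d10")))
  class(out) <- c("expression_report", class(out))
  out
}

#' Bar-chart of candidate expression (glucose vs substrate timepoints)
#'
#' @param object An `expression_report`.
#' @param ... Unused.
#' @return A ggplot faceted per candidate.
#' @export
autoplot.expression_report <- function(object, ...) {
  dat <- object |>
    dplyr::filter(!.data$missing) |>
    tidyr::pivot_longer(c("mean_glucose", "mean_substrate"),
                        names_to = "condition", values_to = "tpm") |>
    dplyr::mutate(
      x = ifelse(.data$condition == "mean_glucose", "glucose", .data$timepoint)
    ) |>
    dplyr::distinct(.data$protein_id, .data$x, .data$tpm, .keep_all = TRUE)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$x, levels = c("glucose", "d2", "d4", "d10")),
    y = .data$tpm, fill = .data$x == "glucose"
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~protein_id, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "TPM") +
    ggplot2::theme_minimal()
}
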