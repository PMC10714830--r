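# CAZyme repertoire profiling: class and family counts per genome and the
# auxiliary-activity proportion aggregated over taxonomy.

#' Profile a genome's CAZyme repertoire
#'
#' Counts each annotated domain once (a protein may contribute several
#' domains), rolls families up to their class by label prefix
#' (GH/GT/PL/CE/AA/CBM; subfamilies like `AA3_2` stay distinct at family
#' level), and computes the AA proportion of total domains.
#'
#' @param annotations Tibble with a `family` column, one row per domain
#'   (any id columns are ignored), or a character vector of family labels.
#' @param genome_id Genome identifier stamped on the profile.
#' @return A `genome_profile`: list with `genome_id`, `class_counts` (named
#'   over GH, GT, PL, CE, AA, CBM), `family_counts` tibble, `total` and
#'   `aa_proportion` (percent of total; 0 with a warning for an empty
#'   annotation set).
#' @export
profile_genome <- function(annotations, genome_id = "genome") {
  labels <- if (is.data.frame(annotations)) annotations$family else as.character(annotations)
  cls <- family_class(labels)
  class_counts <- setNames(integer(length(CAZY_CLASSES)), CAZY_CLASSES)
  tab <- table(cls)
  class_counts[names(tab)] <- as.integer(tab)
  total <- sum(class_counts)
  aa_prop <- if (total == 0) {
    warning("empty annotation set: aa_proportion undefined, reported as 0")
    0
  } else {
    100 * class_counts[["AA"]] / total
  }
  fam <- tibble::tibble(family = labels, class = cls) |>
    dplyr::count(.data$class, .data$family, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$family)
  structure(
    list(genome_id = genome_id, class_counts = class_counts,
         family_counts = fam, total = total, aa_proportion = aa_prop),
    class = "genome_profile"
  )
}

# Map family labels to their class prefix; errors name the offender.
family_class <- function(labels) {
  cls <- stringr::str_extract(labels, "^(GH|GT|PL|CE|AA|CBM)(?=[0-9_]|$)")
  bad <- labels[is.na(cls)]
  if (length(bad)) stop("unparseable CAZyme family label: ", bad[1])
  cls
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf("<genome_profile> %s: %d domains, AA %.2f%%\n",
              x$genome_id, x$total, x$aa_proportion))
  print(x$class_counts)
  invisible(x)
}

#' Tidy / summarise a genome profile
#'
#' `tidy()` gives per-class counts and proportions; `glance()` a one-row
#' summary.
#'
#' @param x A `genome_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.genome_profile <- function(x, ...) {
  tibble::tibble(
    genome_id = x$genome_id,
    class = names(x$class_counts),
    count = as.integer(x$class_counts),
    proportion = if (x$total > 0) 100 * x$class_counts / x$total else 0
  )
}

#' @rdname tidy.genome_profile
#' @export
glance.genome_profile <- function(x, ...) {
  tibble::tibble(
    genome_id = x$genome_id, total = x$total, aa_proportion = x$aa_proportion
  )
}

#' Family distribution within a CAZyme class
#'
#' @param annotations As in [profile_genome()].
#' @param class One of `"GH"`, `"GT"`, `"PL"`, `"CE"`, `"AA"`, `"CBM"`.
#' @return Tibble `family`, `count`, sorted count-descending then family id.
#' @export
family_distribution <- function(annotations, class) {
  stopifnot(class %in% CAZY_CLASSES)
  labels <- if (is.data.frame(annotations)) annotations$family else as.character(annotations)
  cls <- family_class(labels)
  keep <- labels[cls == class]
  if (!length(keep)) return(tibble::tibble(family = character(), count = integer()))
  tibble::tibble(family = keep) |>
    dplyr::count(.data$family, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$family)
}

#' Published CAZyme repertoire of the focal genome
#'
#' The printed class counts of the focal soft-rot ascomycete genome
#' (290 GH, 162 AA, 113 GT, 51 CE, 18 PL, 161 CBM; 795 domains in total)
#' with the reported AA family breakdown (35 AA9, 29 AA3, 27 AA3_2, 12 AA7,
#' 12 AA1, 7 AA8, 6 AA4, 2 AA16; the remaining AA domains are pooled as
#' `AA_other`). Used as worked-example input for [profile_genome()].
#'
#' @return Tibble `family`, one row per domain.
#' @export
no1_repertoire <- function() {
  aa_known <- c(AA9 = 35, AA3 = 29, AA3_2 = 27, AA7 = 12, AA1 = 12,
                AA8 = 7, AA4 = 6, AA16 = 2)
  aa_rest <- 162 - sum(aa_known)
  fams <- c(
    rep("GH5", 290), rep("GT2", 113), rep("PL1", 18), rep("CE1", 51),
    rep("CBM1", 161),
    rep(names(aa_known), aa_known), rep("AA_other", aa_rest)
  )
  tibble::tibble(family = fams)
}

#' Stacked class-proportion plot of one or more genome profiles
#'
#' @param object A `genome_profile` or list of them.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genome_profile <- function(object, ...) {
  profiles <- if (inherits(object, "genome_profile")) list(object) else object
  dat <- purrr::map(profiles, tidy) |> dplyr::bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$genome_id, y = .data$proportion,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of CAZyme domains", fill = "Class") +
    ggplot2::theme_minimal()
}
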