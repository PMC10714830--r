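# Auxiliary-activity density over a taxonomy tree: build a node table from
# ranked lineages, prune thin clades, summarise mean +/- SD per clade and
# percentile-rank focal genomes.

TAX_RANKS <- c("phylum", "class", "order", "family", "genus", "species", "genome")

#' Build a taxonomy tree with per-clade AA density summaries
#'
#' The topology comes from ranked lineage strings (one row per genome); each
#' genome attaches under its species. Every node carries the number of
#' descendant genomes, distinct species, and the mean and sample SD (n-1) of
#' descendant genome AA proportions.
#'
#' @param taxonomy Tibble with columns `genome_id`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species`.
#' @param profiles Either a tibble `genome_id`, `aa_proportion`, or a list of
#'   [profile_genome()] objects named by genome id.
#' @return A `taxon_tree`: tibble of nodes with `node_id`, `name`, `rank`,
#'   `parent`, `n_genomes`, `n_species`, `mean`, `sd`.
#' @export
build_tree <- function(taxonomy, profiles) {
  taxonomy <- tibble::as_tibble(taxonomy)
  stopifnot(all(c("genome_id", TAX_RANKS[1:6]) %in% names(taxonomy)))
  if (anyDuplicated(taxonomy$genome_id)) stop("conflicting lineages: duplicated genome_id")
  if (!is.data.frame(profiles)) {
    profiles <- tibble::tibble(
      genome_id = purrr::map_chr(profiles, "genome_id"),
      aa_proportion = purrr::map_dbl(profiles, "aa_proportion")
    )
  }
  missing <- setdiff(taxonomy$genome_id, profiles$genome_id)
  if (length(missing)) stop("genome without profile: ", paste(missing, collapse = ", "))
  tax <- dplyr::left_join(taxonomy, profiles[, c("genome_id", "aa_proportion")],
                          by = "genome_id")

  # node id = rank-qualified path, so homonymous clades at different ranks
  # cannot collide
  paths <- purrr::map(seq_len(nrow(tax)), function(i) {
    lineage <- c(tax$phylum[i], tax$class[i], tax$order[i], tax$family[i],
                 tax$genus[i], tax$species[i], tax$genome_id[i])
    tibble::tibble(
      rank = TAX_RANKS,
      name = lineage,
      node_id = purrr::accumulate(lineage, ~ paste(.x, .y, sep = "/")),
      genome_id = tax$genome_id[i],
      species = tax$species[i],
      aa = tax$aa_proportion[i]
    ) |>
      dplyr::mutate(parent = dplyr::lag(.data$node_id, default = NA_character_))
  }) |> dplyr::bind_rows()

  nodes <- paths |>
    dplyr::group_by(.data$node_id, .data$name, .data$rank, .data$parent) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species),
      mean = mean(.data$aa),
      sd = if (dplyr::n() > 1) stats::sd(.data$aa) else 0,
      .groups = "drop"
    )
  dup <- nodes |> dplyr::count(.data$node_id) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) stop("conflicting lineages for node: ", dup$node_id[1])
  out <- dplyr::arrange(nodes,
                        match(.data$rank, TAX_RANKS), .data$node_id)
  class(out) <- c("taxon_tree", class(out))
  out
}

#' Prune thin clades and collapse below a rank floor
#'
#' Genera with fewer than `genus_min` species-level representatives are
#' removed; then families with fewer than `family_min` remaining species are
#' removed with their subtrees; finally all nodes below `rank_floor`
#' (species, genome) are collapsed into their genus, which keeps the
#' aggregated statistics. "Species-level representatives" counts distinct
#' species names; multiple assemblies of one species count once.
#'
#' @param tree A [build_tree()] node table.
#' @param genus_min,family_min Minimum species counts (boundaries: 3 kept /
#'   2 pruned, 8 kept / 7 pruned at the defaults).
#' @param rank_floor Rank below which nodes are collapsed (default genus).
#' @return A pruned `taxon_tree` with summaries recomputed on survivors.
#' @export
prune <- function(tree, genus_min = 3, family_min = 8, rank_floor = "genus") {
  stopifnot(genus_min >= 1, family_min >= 1)
  drop_genera <- tree$node_id[tree$rank == "genus" & tree$n_species < genus_min]
  kept <- drop_subtrees(tree, drop_genera)

  # family species counts recomputed over surviving genera
  fam_counts <- kept |>
    dplyr::filter(.data$rank == "genus") |>
    dplyr::group_by(.data$parent) |>
    dplyr::summarise(n_species = sum(.data$n_species), .groups = "drop")
  fam_keep <- setNames(fam_counts$n_species, fam_counts$parent)
  fam_n <- fam_keep[kept$node_id]
  fam_n[is.na(fam_n)] <- 0
  drop_fams <- kept$node_id[kept$rank == "family" & fam_n < family_min]
  kept <- drop_subtrees(kept, drop_fams)

  # recompute ancestors' summaries over surviving genomes
  floor_idx <- match(rank_floor, TAX_RANKS)
  genomes <- kept |> dplyr::filter(.data$rank == "genome")
  kept <- recompute_summaries(kept, genomes)
  out <- kept |> dplyr::filter(match(.data$rank, TAX_RANKS) <= floor_idx)
  class(out) <- c("taxon_tree", class(out))
  out
}

drop_subtrees <- function(tree, roots) {
  if (!length(roots)) return(tree)
  drop <- roots
  repeat {
    more <- tree$node_id[tree$parent %in% drop & !(tree$node_id %in% drop)]
    if (!length(more)) break
    drop <- c(drop, more)
  }
  tree[!(tree$node_id %in% drop), , drop = FALSE]
}

recompute_summaries <- function(tree, genomes) {
  # each genome's ancestors are prefixes of its node_id path
  stats <- purrr::map(seq_len(nrow(tree)), function(i) {
    node <- tree$node_id[i]
    desc <- genomes[startsWith(genomes$node_id, paste0(node, "/")) |
                      genomes$node_id == node, ]
    tibble::tibble(
      n_genomes = nrow(desc),
      n_species = dplyr::n_distinct(dirname(desc$node_id)),
      mean = if (nrow(desc)) mean(desc$mean) else NA_real_,
      sd = if (nrow(desc) > 1) stats::sd(desc$mean) else 0
    )
  }) |> dplyr::bind_rows()
  tree$n_genomes <- stats$n_genomes
  tree$n_species <- ifelse(tree$rank == "genome", 1L, stats$n_species)
  tree$mean <- stats$mean
  tree$sd <- stats$sd
  tree[tree$n_genomes > 0, , drop = FALSE]
}

#' Percentile rank of a value in a genome population
#'
#' Strict-below convention by default:
#' `100 * #(population < value) / #population`; the midpoint convention
#' credits half of the ties.
#'
#' @param value AA proportion (percent).
#' @param population Numeric vector of genome AA proportions (non-empty).
#' @param ties `"strict"` (default) or `"midpoint"`.
#' @return Percentile in `[0, 100]`.
#' @export
percentile_rank <- function(value, population, ties = c("strict", "midpoint")) {
  ties <- match.arg(ties)
  stopifnot(length(population) > 0)
  below <- sum(population < value)
  if (ties == "midpoint") below <- below + sum(population == value) / 2
  100 * below / length(population)
}

#' Clade report: mean +/- SD per surviving order/family/genus
#'
#' One row per node at ranks order, family and genus, depth-first and
#' name-sorted, mean and SD rounded to 2 decimals; regeneration is
#' byte-identical.
#'
#' @param tree A (typically pruned) `taxon_tree`.
#' @return Tibble `clade`, `rank`, `n`, `mean`, `sd`, `label`
#'   (`"mean +/- sd"`).
#' @export
clade_report <- function(tree) {
  tree |>
    dplyr::filter(.data$rank %in% c("order", "family", "genus")) |>
    dplyr::arrange(.data$node_id) |>
    dplyr::transmute(
      clade = .data$name, rank = .data$rank, n = .data$n_genomes,
      mean = round(.data$mean, 2), sd = round(.data$sd, 2),
      label = sprintf("%.2f ± %.2f", round(.data$mean, 2), round(.data$sd, 2))
    )
}

#' Serialize a taxonomy tree as Newick
#'
#' Internal node labels carry `name|n|mean|sd`.
#'
#' @param tree A `taxon_tree`.
#' @param path Optional output file.
#' @return The Newick string (invisibly if `path` given).
#' @export
write_tree_newick <- function(tree, path = NULL) {
  label <- function(i) {
    sprintf("%s|%d|%.2f|%.2f", tree$name[i], tree$n_genomes[i],
            tree$mean[i], tree$sd[i])
  }
  children_of <- split(seq_len(nrow(tree)), tree$parent)
  rec <- function(i) {
    kids <- children_of[[tree$node_id[i]]]
    if (is.null(kids)) return(label(i))
    kids <- kids[order(tree$node_id[kids])]
    paste0("(", paste(purrr::map_chr(kids, rec), collapse = ","), ")", label(i))
  }
  roots <- which(is.na(tree$parent))
  nwk <- paste0("(", paste(purrr::map_chr(roots, rec), collapse = ","), ");")
  if (length(roots) == 1) nwk <- paste0(purrr::map_chr(roots, rec), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' AA-density plot over clades
#'
#' @param object A `taxon_tree` (ideally pruned).
#' @param ... Unused.
#' @return A ggplot of genus means with SD error bars, coloured by order.
#' @export
autoplot.taxon_tree <- function(object, ...) {
  dat <- clade_report(object) |> dplyr::filter(.data$rank == "genus")
  ord <- object |> dplyr::filter(.data$rank == "genus")
  dat$order <- purrr::map_chr(strsplit(ord$node_id, "/"), 3)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$clade, .data$mean),
                                    y = .data$mean, colour = .data$order)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd), width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "AA proportion of CAZyme domains (%)",
                  colour = "Order") +
    ggplot2::theme_minimal()
}
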