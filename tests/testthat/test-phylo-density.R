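lineage_tbl <- function(genus, n, family = "FamA", order = "OrdA",
                        aa = rep(10, n)) {
  tibble::tibble(
    genome_id = sprintf("%s_g%02d", genus, seq_len(n)),
    phylum = "Ascomycota", class = "ClsA", order = order, family = family,
    genus = genus, species = sprintf("%s_sp%02d", genus, seq_len(n)),
    aa_proportion = aa
  )
}

profiles_of <- function(tax) tax[, c("genome_id", "aa_proportion")]

test_that("clade summaries follow hand arithmetic", {
  tax <- lineage_tbl("GenA", 3, aa = c(10, 20, 30))
  tree <- build_tree(tax[, -8], profiles_of(tax))
  genus <- tree[tree$rank == "genus", ]
  expect_equal(genus$mean, 20)
  expect_equal(genus$sd, 10) # sample SD
  expect_equal(genus$n_genomes, 3L)
  # single genome: ancestors carry its value with SD 0
  tax1 <- lineage_tbl("GenB", 1, aa = 42)
  t1 <- build_tree(tax1[, -8], profiles_of(tax1))
  expect_true(all(t1$mean == 42))
  expect_true(all(t1$sd == 0))
})

test_that("parents aggregate children counts and weighted means", {
  tax <- dplyr::bind_rows(
    lineage_tbl("GenA", 3, aa = c(10, 20, 30)),
    lineage_tbl("GenB", 5, aa = rep(8, 5))
  )
  tree <- build_tree(tax[, -8], profiles_of(tax))
  fam <- tree[tree$rank == "family", ]
  expect_equal(fam$n_genomes, 8L)
  expect_equal(fam$mean, (10 + 20 + 30 + 5 * 8) / 8)
  # weighted-mean consistency at every internal node
  genera <- tree[tree$rank == "genus", ]
  wmean <- sum(genera$mean * genera$n_genomes) / sum(genera$n_genomes)
  expect_equal(fam$mean, wmean, tolerance = 1e-9)
})

test_that("errors: missing profiles and conflicting lineages", {
  tax <- lineage_tbl("GenA", 2)
  expect_error(build_tree(tax[, -8], profiles_of(tax)[1, ]), "without profile")
  dup <- dplyr::bind_rows(tax, tax[1, ])
  expect_error(build_tree(dup[, -8], profiles_of(dup)), "duplicated genome_id")
})

test_that("pruning boundaries: 3 species kept vs 2 pruned; 8 vs 7 for families", {
  tax <- dplyr::bind_rows(
    lineage_tbl("Gen3", 3, family = "FamKeep"),
    lineage_tbl("Gen2", 2, family = "FamKeep"),
    lineage_tbl("Gen5", 5, family = "FamKeep"),
    lineage_tbl("Gen8", 8, family = "FamBig"),
    lineage_tbl("Gen7", 7, family = "FamSmall")
  )
  tree <- build_tree(tax[, -8], profiles_of(tax))
  pruned <- prune(tree, genus_min = 3, family_min = 8)
  genera <- pruned$name[pruned$rank == "genus"]
  expect_true(all(c("Gen3", "Gen5", "Gen8") %in% genera))
  expect_false("Gen2" %in% genera) # < 3 species
  expect_false("Gen7" %in% genera) # its family has 7 < 8 species
  fams <- pruned$name[pruned$rank == "family"]
  expect_true(all(c("FamKeep", "FamBig") %in% fams))
  expect_false("FamSmall" %in% fams)
  # nothing below genus survives
  expect_false(any(pruned$rank %in% c("species", "genome")))
  # multiple assemblies of one species count once
  tax_multi <- lineage_tbl("GenM", 3)
  tax_multi$species <- "GenM_sp01"
  tm <- prune(build_tree(tax_multi[, -8], profiles_of(tax_multi)), genus_min = 3)
  expect_false("GenM" %in% tm$name[tm$rank == "genus"])
})

test_that("raising genus_min never adds nodes", {
  sc <- cached_scenario()
  tax <- readr::read_tsv(sc$paths$taxonomy, show_col_types = FALSE)
  ann <- readr::read_tsv(sc$paths$genome_annotations, show_col_types = FALSE)
  profs <- ann |>
    dplyr::group_by(genome_id) |>
    dplyr::summarise(aa_proportion = 100 * mean(startsWith(family, "AA")))
  tree <- build_tree(tax, profs)
  for (gm in c(1, 3, 6)) {
    p_lo <- prune(tree, genus_min = gm, family_min = 1)
    p_hi <- prune(tree, genus_min = gm + 2, family_min = 1)
    expect_true(all(p_hi$node_id %in% p_lo$node_id))
  }
})

test_that("percentile rank follows the strict-below convention", {
  pop <- 1:100
  expect_equal(percentile_rank(1000, pop), 100)
  expect_equal(percentile_rank(0, pop), 0)
  # median of an odd population sits at 50 +/- one rank unit
  popo <- 1:99
  expect_lt(abs(percentile_rank(50, popo) - 50), 100 / 99 + 1e-9)
  # midpoint convention credits half the ties
  expect_equal(percentile_rank(5, c(1, 5, 5, 9), ties = "midpoint"), 50)
  # empirical CDF oracle on a synthetic population
  withr::with_seed(9L, {
    pop_n <- rnorm(1000, 15, 3)
  })
  expect_equal(percentile_rank(20.38, pop_n),
               100 * mean(pop_n < 20.38))
})

test_that("clade report is deterministic and excludes pruned clades", {
  tax <- dplyr::bind_rows(
    lineage_tbl("GenA", 3, aa = c(10, 20, 30)),
    lineage_tbl("GenB", 2, aa = c(5, 6))
  )
  tree <- build_tree(tax[, -8], profiles_of(tax))
  pruned <- prune(tree, genus_min = 3, family_min = 1)
  rep1 <- clade_report(pruned)
  rep2 <- clade_report(prune(build_tree(tax[, -8], profiles_of(tax)),
                             genus_min = 3, family_min = 1))
  expect_identical(rep1, rep2)
  expect_false("GenB" %in% rep1$clade)
  genrow <- rep1[rep1$clade == "GenA", ]
  expect_equal(genrow$n, 3L)
  expect_equal(genrow$label, "20.00 ± 10.00")
})

test_that("newick export carries labels and drops pruned genera", {
  tax <- dplyr::bind_rows(
    lineage_tbl("GenA", 3, aa = c(10, 20, 30)),
    lineage_tbl("GenB", 2)
  )
  pruned <- prune(build_tree(tax[, -8], profiles_of(tax)), genus_min = 3, family_min = 1)
  nwk <- write_tree_newick(pruned)
  expect_match(nwk, "GenA\\|3\\|20.00\\|10.00")
  expect_false(grepl("GenB", nwk))
  # parses as a valid tree
  tr <- ape::read.tree(text = nwk)
  expect_s3_class(tr, "phylo")
})

test_that("synthetic taxonomy plans are recovered within 3 SE", {
  plan <- tibble::tibble(
    clade = paste0("Asco;Cls;Ord", c("A", "A", "B", "C"), ";Fam", c("A", "A", "B", "C"),
                   ";Gen", c("A", "B", "C", "D")),
    n_genomes = c(60L, 50L, 50L, 40L),
    aa_mean = c(20, 16, 12, 9),
    aa_sd = c(2, 2.5, 3, 2)
  )
  spec <- scenario_spec(seed = 17L, taxonomy_plan = plan)
  tb <- gen_tables(spec)
  profs <- tb$genome_annotations |>
    dplyr::group_by(genome_id) |>
    dplyr::group_map(~ profile_genome(.x, .y$genome_id))
  tree <- build_tree(tb$taxonomy, profs)
  genera <- tree[tree$rank == "genus", ]
  for (i in seq_len(nrow(plan))) {
    g <- genera[genera$name == sub(".*;", "", plan$clade[i]), ]
    se <- plan$aa_sd[i] / sqrt(plan$n_genomes[i])
    expect_lt(abs(g$mean - plan$aa_mean[i]), 3 * se + 0.5,
              label = paste("genus", g$name))
  }
})
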