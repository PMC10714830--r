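# Synthetic annotation, taxonomy, expression tables and the family MSA.

#' Generate the tabular inputs of a scenario
#'
#' Produces, with ground truth controlled by the scenario plan:
#' * `annotations` — CAZyme family labels for the screened proteome: template
#'   proteins carry their family, planted analogs stay unlabeled (they are
#'   the "missed by annotation" candidates the screen exists to find).
#' * `taxonomy` — one row per genome of the taxonomy plan with a full ranked
#'   lineage; each genome is its own species by default.
#' * `genome_annotations` — per-genome CAZyme domain rows whose AA proportion
#'   is drawn from Normal(aa_mean, aa_sd), truncated to `[0, 100]`, realised
#'   over `domains_per_genome` domains.
#' * `expression` — TPM per protein x condition x timepoint x replicate;
#'   log-normal noise (s.d. 0.25 in log2) around a per-protein baseline, with
#'   the plan's log2 fold-changes applied to substrate timepoints.
#' * `msa` — an aligned (gap-free) family of 8 template variants at 25%
#'   point substitution, the input for bespoke profile-HMM construction.
#'
#' @param spec A [scenario_spec()].
#' @param domains_per_genome CAZyme domains realised per synthetic genome.
#' @return Named list of tibbles (`annotations`, `taxonomy`,
#'   `genome_annotations`, `expression`) plus `msa` (named character vector,
#'   one per template, each a named vector of aligned sequences).
#' @export
gen_tables <- function(spec, domains_per_genome = 300L) {
  validate_scenario(spec)
  proteome <- gen_proteome(spec)

  annotations <- proteome |>
    dplyr::filter(.data$role == "template") |>
    dplyr::transmute(protein_id = .data$id, family = .data$family)

  tax <- gen_taxonomy(spec)
  genome_ann <- gen_genome_annotations(spec, tax, domains_per_genome)
  expression <- gen_expression(spec, proteome)
  msa <- purrr::map(spec$templates, function(t) gen_family_msa(spec, t))

  list(
    annotations = annotations, taxonomy = tax$taxonomy,
    genome_annotations = genome_ann, expression = expression, msa = msa
  )
}

gen_taxonomy <- function(spec) {
  plan <- spec$taxonomy_plan
  if (nrow(plan) == 0) {
    return(list(
      taxonomy = tibble::tibble(
        genome_id = character(), phylum = character(), class = character(),
        order = character(), family = character(), genus = character(),
        species = character()
      ),
      aa_target = tibble::tibble(genome_id = character(), aa_target = double())
    ))
  }
  rows <- purrr::map(seq_len(nrow(plan)), function(i) {
    parts <- strsplit(plan$clade[i], ";", fixed = TRUE)[[1]]
    stopifnot(length(parts) == 5)
    k <- plan$n_genomes[i]
    tibble::tibble(
      genome_id = sprintf("%s_sp%02d_g1", parts[5], seq_len(k)),
      phylum = parts[1], class = parts[2], order = parts[3],
      family = parts[4], genus = parts[5],
      species = sprintf("%s_sp%02d", parts[5], seq_len(k)),
      aa_mean = plan$aa_mean[i], aa_sd = plan$aa_sd[i]
    )
  })
  tax <- dplyr::bind_rows(rows)
  aa <- with_stream_seed(spec$seed, "taxonomy_aa", {
    pmin(100, pmax(0, rnorm(nrow(tax), tax$aa_mean, tax$aa_sd)))
  })
  list(
    taxonomy = dplyr::select(tax, -"aa_mean", -"aa_sd"),
    aa_target = tibble::tibble(genome_id = tax$genome_id, aa_target = aa)
  )
}

gen_genome_annotations <- function(spec, tax, domains_per_genome) {
  if (nrow(tax$taxonomy) == 0) {
    return(tibble::tibble(genome_id = character(), protein_id = character(),
                          family = character()))
  }
  aa_families <- c("AA9", "AA3", "AA3_2", "AA1", "AA2", "AA7", "AA8")
  other_families <- c("GH5", "GH7", "GH10", "GT2", "CE1", "CE5", "CBM1", "PL1")
  with_stream_seed(spec$seed, "genome_annotations", {
    purrr::map2(tax$taxonomy$genome_id, tax$aa_target$aa_target, function(g, p) {
      n_aa <- round(p / 100 * domains_per_genome)
      fams <- c(
        sample(aa_families, n_aa, replace = TRUE),
        sample(other_families, domains_per_genome - n_aa, replace = TRUE)
      )
      tibble::tibble(
        genome_id = g,
        protein_id = sprintf("%s_p%04d", g, seq_along(fams)),
        family = fams
      )
    }) |> dplyr::bind_rows()
  })
}

gen_expression <- function(spec, proteome) {
  if (nrow(proteome) == 0) {
    return(tibble::tibble(
      protein_id = character(), condition = character(), timepoint = character(),
      replicate = integer(), tpm = double()
    ))
  }
  tps <- c("d2", "d4", "d10")
  reps <- spec$replicates
  with_stream_seed(spec$seed, "expression", {
    base <- setNames(rnorm(nrow(proteome), mean = 5, sd = 1), proteome$id)
    grid <- tidyr::expand_grid(
      protein_id = proteome$id,
      cond_tp = c("glucose:none", paste0("substrate:", tps)),
      replicate = seq_len(reps)
    ) |>
      tidyr::separate_wider_delim("cond_tp", ":", names = c("condition", "timepoint"))
    fc <- spec$expression_plan
    grid$log2fc <- 0
    if (nrow(fc) > 0) {
      key <- paste(grid$protein_id, grid$timepoint)
      fckey <- setNames(fc$log2fc, paste(fc$protein_id, fc$timepoint))
      hit <- key %in% names(fckey) & grid$condition == "substrate"
      grid$log2fc[hit] <- fckey[key[hit]]
    }
    grid |>
      dplyr::mutate(
        tpm = 2^(base[.data$protein_id] + .data$log2fc + rnorm(dplyr::n(), sd = 0.25))
      ) |>
      dplyr::select("protein_id", "condition", "timepoint", "replicate", "tpm")
  })
}

gen_family_msa <- function(spec, template, n_members = 8L, divergence = 0.25) {
  with_stream_seed(spec$seed, paste0("msa:", template$id), {
    seqs <- purrr::map_chr(seq_len(n_members), function(i) {
      substitute_fraction(template$seq, divergence, spec$background)
    })
    setNames(seqs, sprintf("%s_FAM%02d", template$id, seq_len(n_members)))
  })
}

#' Materialise a scenario on disk
#'
#' Writes every input the screen consumes: `proteome.fasta`, one PDB per
#' protein under `structures/` plus a `manifest.tsv`, per-template query
#' FASTA/PDB/MSA files, and the annotation, taxonomy, genome-annotation and
#' expression TSVs. Fixed seed implies byte-identical regeneration.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if missing).
#' @param domains_per_genome Passed to [gen_tables()].
#' @return Invisibly, a list with the ground-truth `proteome` tibble and all
#'   file `paths`.
#' @export
gen_scenario <- function(spec, dir, domains_per_genome = 300L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "structures"), showWarnings = FALSE)
  proteome <- gen_proteome(spec)
  tables <- gen_tables(spec, domains_per_genome)

  paths <- list(
    proteome = file.path(dir, "proteome.fasta"),
    structure_dir = file.path(dir, "structures"),
    annotations = file.path(dir, "annotations.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    genome_annotations = file.path(dir, "genome_annotations.tsv"),
    expression = file.path(dir, "expression.tsv")
  )
  write_fasta_vec(setNames(proteome$seq, proteome$id), paths$proteome)
  readr::write_tsv(tables$annotations, paths$annotations)
  readr::write_tsv(tables$taxonomy, paths$taxonomy)
  readr::write_tsv(tables$genome_annotations, paths$genome_annotations)
  readr::write_tsv(tables$expression, paths$expression)

  # structures for every proteome entry
  manifest <- purrr::map(seq_len(nrow(proteome)), function(i) {
    row <- proteome[i, ]
    model <- scenario_structure(spec, row)
    p <- file.path(dir, "structures", paste0(row$id, ".pdb"))
    write_structure(model, p)
    tibble::tibble(id = row$id, file = basename(p), n_residues = length(model))
  }) |> dplyr::bind_rows()
  paths$structure_manifest <- file.path(dir, "structures", "manifest.tsv")
  readr::write_tsv(manifest, paths$structure_manifest)

  # queries: one FASTA/PDB/MSA per template
  paths$queries <- purrr::map(spec$templates, function(t) {
    q <- list(
      fasta = file.path(dir, paste0("query_", t$id, ".fasta")),
      pdb = file.path(dir, paste0("query_", t$id, ".pdb")),
      msa = file.path(dir, paste0("msa_", t$id, ".afa"))
    )
    write_fasta_vec(setNames(t$seq, paste0("QRY_", t$id)), q$fasta)
    qmodel <- gen_structure(t$sse_plan, 0, substream_seed(spec$seed, paste0("struct:", t$id)),
                            id = paste0("QRY_", t$id))
    write_structure(qmodel, q$pdb)
    write_fasta_vec(tables$msa[[t$id]], q$msa)
    q
  })
  invisible(list(proteome = proteome, tables = tables, paths = paths, spec = spec))
}

# Structure for one proteome row, per its role.
scenario_structure <- function(spec, row) {
  seed <- substream_seed(spec$seed, paste0("struct:", row$id))
  if (row$role %in% c("template")) {
    t <- spec$templates[[row$template]]
    return(gen_structure(t$sse_plan, 0, seed, id = row$id))
  }
  if (row$role %in% c("seq_homolog", "struct_only")) {
    # same fold as the template (same builder stream), its own noise
    t <- spec$templates[[row$template]]
    base <- gen_structure(t$sse_plan, 0,
                          substream_seed(spec$seed, paste0("struct:", t$id)),
                          id = row$id)
    return(perturb_structure(base, 0.4, seed))
  }
  if (row$role == "dom_homolog") {
    t <- spec$templates[[row$template]]
    plan <- dplyr::bind_rows(
      tibble::tibble(type = "coil", length = as.integer(row$flank_n)),
      t$sse_plan,
      tibble::tibble(type = "coil", length = as.integer(row$flank_c))
    )
    return(gen_structure(plan, 0.4, seed, id = row$id))
  }
  # decoy: random sequences fold mostly to disorder -- 0-3 short elements in
  # long coils, so chance secondary-structure agreement with a query stays low
  gen_structure(decoy_plan(nchar(row$seq), seed), 0.2, seed, id = row$id)
}

decoy_plan <- function(len, seed) {
  withr::with_seed(seed + 1L, {
    k <- sample(0:2, 1)
    sse <- if (k > 0) {
      tibble::tibble(
        type = sample(c("H", "E"), k, replace = TRUE)
      ) |>
        dplyr::mutate(length = ifelse(.data$type == "H", sample(5:9, k, replace = TRUE),
                                      sample(4:7, k, replace = TRUE)))
    } else {
      tibble::tibble(type = character(), length = integer())
    }
    remaining <- len - sum(sse$length)
    # split remaining residues over k+1 coil segments, each >= 5
    n_coil <- k + 1
    base <- rep(remaining %/% n_coil, n_coil)
    base[1] <- base[1] + remaining %% n_coil
    plan <- tibble::tibble(type = "coil", length = base[1])
    for (i in seq_len(k)) {
      plan <- dplyr::bind_rows(
        plan, sse[i, ], tibble::tibble(type = "coil", length = base[i + 1])
      )
    }
    dplyr::filter(plan, .data$length > 0)
  })
}
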