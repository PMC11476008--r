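#' Run the full analysis pipeline
#'
#' Orchestrates the stages behind one entry point: obtain inputs (either by
#' simulation or from files), project intron positions onto the protein
#' alignment and call shared junctions, run region analyses (loop insertions,
#' residue-set correspondence, region conservation), extract features and
#' classify homologs, build the clade presence/absence profile, and — when a
#' duplication hypothesis is configured — compute duplication support. Every
#' report is a plain TSV with a `#`-prefixed parameter header; a
#' `manifest.json` with md5 checksums makes reruns diff-able.
#'
#' @param config A list or path to a YAML file. Keys: `seed`, `out_dir`;
#'   either `simulate` (a list of [simulation_config()] overrides, or `TRUE`
#'   for defaults) or `inputs` (paths: `alignment`, `genomes`, `gene_models`,
#'   `region_set`, `taxon_map`, optionally `transcripts`, `tree`); optional
#'   parameter blocks `junctions`, `regions`, `classify`, `dupsupport`
#'   (with `child_gene` / `parent_gene` / `outgroup_clade` for simulated
#'   input, or explicit id vectors `child_ids` / `parent_ids` /
#'   `outgroup_ids`).
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "splicetrace_run"
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(tbl, name, params) {
    path <- file.path(out_dir, name)
    write_report(tbl, path, params)
    written <<- c(written, path)
    path
  }
  results <- list()

  if (!is.null(config$simulate)) {
    overrides <- if (isTRUE(config$simulate)) list() else config$simulate
    cfg <- do.call(simulation_config, c(list(seed = seed), overrides))
    fam <- simulate_family(cfg)
    write_fixture_files(fam, file.path(out_dir, "fixtures"))
    msa <- fam$alignment
    models <- fam$gene_models
    genomes <- fam$genomes
    rs <- fam$region_set
    taxon_map <- fam$taxon_map
    tree <- fam$tree
    transcripts <- fam$transcripts
    proteins <- fam$proteins
    results$family <- fam
  } else {
    inp <- config$inputs
    if (is.null(inp) || is.null(inp$alignment)) {
      abort("config needs either 'simulate' or 'inputs' with an alignment",
            class = "splicetrace_config_error")
    }
    for (f in unlist(inp)) {
      if (!file.exists(f)) {
        abort(paste0("input file not found: ", f),
              class = "splicetrace_config_error")
      }
    }
    msa <- read_alignment(inp$alignment)
    genomes <- if (!is.null(inp$genomes)) read_fasta(inp$genomes) else NULL
    models <- if (!is.null(inp$gene_models)) read_gene_models(inp$gene_models, genomes) else NULL
    rs <- if (!is.null(inp$region_set)) read_region_set(inp$region_set) else default_region_set()
    taxon_map <- if (!is.null(inp$taxon_map)) {
      readr::read_tsv(inp$taxon_map, show_col_types = FALSE)
    } else NULL
    tree <- if (!is.null(inp$tree)) readLines(inp$tree, warn = FALSE) else NULL
    transcripts <- if (!is.null(inp$transcripts)) read_fasta(inp$transcripts) else NULL
    proteins <- tibble(id = msa$id, residues = ungap(msa$aligned))
  }

  # junctions stage
  introns <- NULL
  if (!is.null(models)) {
    jp <- config$junctions %||% list()
    introns <- intron_positions(models)
    splice <- classify_splice_sites(models, genomes)
    jm <- project_junctions(msa, introns,
                            eligible_ids = intersect(unique(models$gene_id[!models$partial]),
                                                     msa$id))
    shared <- call_shared_junctions(jm,
                                    shift_tolerance = jp$shift_tolerance %||% 0L,
                                    require_same_phase = jp$require_same_phase %||% TRUE)
    pars <- list(shift_tolerance = jp$shift_tolerance %||% 0L,
                 require_same_phase = jp$require_same_phase %||% TRUE)
    emit(splice, "splice_sites.tsv", pars)
    emit(jm, "junction_map.tsv", pars)
    emit(shared, "shared_junctions.tsv", pars)
    results$junctions <- list(map = jm, shared = shared, splice = splice)
  }

  # regions stage
  rp <- config$regions %||% list()
  min_ins <- rp$min_insertion %||% 10L
  gap_merge <- rp$gap_merge %||% 2L
  ins <- detect_insertions(msa, rs, min_insertion = min_ins, gap_merge = gap_merge)
  cons <- region_conservation(msa, rs)
  pars <- list(min_insertion = min_ins, gap_merge = gap_merge,
               reference = rs$reference_id)
  emit(ins, "insertions.tsv", pars)
  emit(cons, "region_conservation.tsv", pars)
  corr <- NULL
  if ("catalytic" %in% rs$residue_sets$set_name) {
    corr <- residue_correspondence(msa, rs, "catalytic")
    emit(corr, "catalytic_correspondence.tsv", pars)
  }
  results$regions <- list(insertions = ins, conservation = cons,
                          correspondence = corr)

  # leaders stage
  if (!is.null(transcripts) && "canonical_start" %in% names(transcripts)) {
    leaders <- detect_leader(transcripts)
    emit(leaders, "leaders.tsv", list())
    results$leaders <- leaders
  }

  # classify + profile
  cp <- config$classify %||% list()
  feats <- extract_features(msa, rs, introns = introns,
                            model_ids = if (!is.null(models))
                              unique(models$gene_id[!models$partial]) else NULL,
                            min_insertion = min_ins, gap_merge = gap_merge)
  classes <- classify_homologs(feats,
                               ins_min = cp$ins_min %||% 10L,
                               cat_low = cp$cat_low %||% 0.4,
                               cat_high = cp$cat_high %||% 0.8,
                               iface_low = cp$iface_low %||% 0.5)
  cpars <- list(ins_min = cp$ins_min %||% 10L, cat_low = cp$cat_low %||% 0.4,
                cat_high = cp$cat_high %||% 0.8, iface_low = cp$iface_low %||% 0.5)
  emit(feats, "features.tsv", cpars)
  emit(classes, "classes.tsv", cpars)
  results$features <- feats
  results$classes <- classes

  if (!is.null(taxon_map) && "taxon" %in% names(proteins)) {
    classified <- classes |>
      left_join(proteins[, c("id", "taxon")], by = "id")
    profile <- build_profile(classified, taxon_map, tree = tree)
    emit(profile, "profile.tsv", list())
    results$profile <- profile
  }

  if (!is.null(results$family)) {
    truth <- results$family$truth
    recov <- classes |>
      left_join(truth[, c("id", "class")], by = "id",
                suffix = c("_called", "_truth")) |>
      mutate(correct = .data$class_called == .data$class_truth)
    emit(recov, "class_recovery.tsv", cpars)
    results$recovery <- recov
  }

  # duplication support
  dp <- config$dupsupport
  if (!is.null(dp) || !is.null(results$family)) {
    dp <- dp %||% list()
    if (!is.null(results$family)) {
      fam <- results$family
      child_gene <- dp$child_gene %||% "prpsap1"
      parent_gene <- dp$parent_gene %||% "prpsap2"
      outgroup_clade <- dp$outgroup_clade %||% "Amoebozoa"
      pr <- fam$proteins
      child <- pr[pr$gene == child_gene, ]
      parents <- pr[pr$gene == parent_gene & !(pr$id %in% child$id), ]
      outg <- pr[pr$gene == fam$config$reference_gene &
                   fam$taxon_map$clade[match(pr$taxon, fam$taxon_map$taxon)] ==
                   outgroup_clade, ]
    } else {
      child <- tibble(id = dp$child_ids, residues = ungap(msa$aligned[match(dp$child_ids, msa$id)]))
      parents <- tibble(id = dp$parent_ids, residues = ungap(msa$aligned[match(dp$parent_ids, msa$id)]))
      outg <- tibble(id = dp$outgroup_ids, residues = ungap(msa$aligned[match(dp$outgroup_ids, msa$id)]))
    }
    if (nrow(child) && nrow(parents) && nrow(outg)) {
      ds <- duplication_support(child, parents, outg,
                                jm = results$junctions$map,
                                n_boot = dp$n_boot %||% 200L, seed = seed)
      emit(glance(ds), "duplication_support.tsv",
           list(n_boot = dp$n_boot %||% 200L, seed = seed))
      results$dupsupport <- ds
    }
  }

  sums <- tools::md5sum(written)
  manifest <- list(seed = seed,
                   reports = setNames(as.list(unname(sums)), basename(written)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
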