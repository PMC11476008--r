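#' Assemble per-sequence diagnostic feature vectors
#'
#' Combines loop-insertion calls, residue-set conservation and gene-structure
#' information into one row per sequence: insertion lengths in the catalytic
#' flexible and regulatory flexible loops, conservation fractions of the
#' catalytic, bent-interface, parallel-interface and allosteric residue sets
#' (NA when a set is not configured), and an `intronless` flag (NA when no
#' gene model was supplied).
#'
#' @inheritParams detect_insertions
#' @param introns Optional tibble from [intron_positions()] (ids matching
#'   alignment rows); sequences present in `model_ids` but absent here are
#'   intronless.
#' @param model_ids Ids for which gene models exist; controls whether
#'   `intronless` is known.
#' @param cf_region,reg_region Region names for the catalytic flexible and
#'   regulatory flexible loops.
#' @param catalytic_set,bent_set,parallel_set,allosteric_set Residue-set
#'   names looked up in `rs` (missing sets yield NA features).
#' @return Tibble of feature vectors, one row per alignment sequence.
#' @export
extract_features <- function(msa, rs, introns = NULL, model_ids = NULL,
                             min_insertion = 10L, gap_merge = 2L,
                             cf_region = "cf_loop",
                             reg_region = "regulatory_flexible_loop",
                             catalytic_set = "catalytic",
                             bent_set = "bent_dimer",
                             parallel_set = "parallel_dimer",
                             allosteric_set = "allosteric") {
  ids <- msa$id
  if (!is.null(introns)) {
    iid <- if ("gene_id" %in% names(introns)) introns$gene_id else introns$id
    bad <- setdiff(unique(iid), ids)
    if (length(bad)) {
      abort(paste0("intron ids absent from alignment: ", paste(bad, collapse = ", ")),
            class = "splicetrace_consistency_error")
    }
  }
  ins <- detect_insertions(msa, rs, min_insertion = min_insertion,
                           gap_merge = gap_merge, targets = setdiff(ids, rs$reference_id))
  ins_len <- function(id, region) {
    rows <- ins[ins$sequence_id == id & ins$region_name == region, ]
    if (nrow(rows)) max(rows$length) else 0L
  }
  set_cons <- function(set) {
    if (!set %in% rs$residue_sets$set_name) return(NULL)
    sc <- set_conservation(msa, rs, set, targets = ids)
    setNames(sc$conservation, sc$target_id)
  }
  cat_c <- set_cons(catalytic_set)
  bent_c <- set_cons(bent_set)
  par_c <- set_cons(parallel_set)
  allo_c <- set_cons(allosteric_set)
  lookup <- function(v, id) if (is.null(v) || !id %in% names(v)) NA_real_ else unname(v[id])
  purrr::map_dfr(ids, function(id) {
    intronless <- if (is.null(model_ids) || !id %in% model_ids) NA else {
      if (is.null(introns)) TRUE else {
        iid <- if ("gene_id" %in% names(introns)) introns$gene_id else introns$id
        !id %in% iid
      }
    }
    tibble(id = id,
           cf_loop_insertion_len = if (id == rs$reference_id) 0L else ins_len(id, cf_region),
           reg_loop_insertion_len = if (id == rs$reference_id) 0L else ins_len(id, reg_region),
           catalytic_conservation = if (id == rs$reference_id) 1 else lookup(cat_c, id),
           bent_interface_conservation = if (id == rs$reference_id && !is.null(bent_c)) 1 else lookup(bent_c, id),
           parallel_interface_conservation = if (id == rs$reference_id && !is.null(par_c)) 1 else lookup(par_c, id),
           allosteric_conservation = if (id == rs$reference_id && !is.null(allo_c)) 1 else lookup(allo_c, id),
           intronless = intronless)
  })
}

#' Rule-based homolog classification
#'
#' Applies an ordered rule cascade to feature vectors:
#' \enumerate{
#'   \item `PRS5_LIKE` — regulatory-loop insertion of at least `ins_min`
#'     residues (checked first: some Prs5-type proteins carry catalytic-loop
#'     insertions too);
#'   \item `PRPSAP_LIKE` — catalytic-loop insertion of at least `ins_min` and
#'     catalytic conservation at most `cat_low`;
#'   \item `CLASS_II_PRPS` — catalytic conservation at least `cat_high` but a
#'     poorly conserved dimer interface
#'     (`min(bent, parallel) <= iface_low`);
#'   \item `CLASS_I_PRPS` — catalytic conservation at least `cat_high`
#'     (`CLASS_I_RETROCOPY` when additionally intronless);
#'   \item otherwise `UNCLASSIFIED`.
#' }
#'
#' @param features Tibble from [extract_features()].
#' @param ins_min Minimum insertion length in residues (default 10).
#' @param cat_low,cat_high Catalytic-conservation cutoffs (defaults 0.4, 0.8).
#' @param iface_low Interface-conservation cutoff (default 0.5).
#' @return Tibble: `id`, `class`, `rationale` (semicolon-joined triggered
#'   rules; empty for `UNCLASSIFIED`).
#' @export
classify_homologs <- function(features, ins_min = 10L, cat_low = 0.4,
                              cat_high = 0.8, iface_low = 0.5) {
  purrr::map_dfr(seq_len(nrow(features)), function(k) {
    f <- features[k, ]
    rat <- character(0)
    iface_min <- suppressWarnings(min(f$bent_interface_conservation,
                                      f$parallel_interface_conservation,
                                      na.rm = TRUE))
    iface_known <- is.finite(iface_min)
    cls <- if (!is.na(f$reg_loop_insertion_len) && f$reg_loop_insertion_len >= ins_min) {
      rat <- c(rat, sprintf("regulatory-loop insertion %d >= %d",
                            f$reg_loop_insertion_len, ins_min))
      "PRS5_LIKE"
    } else if (!is.na(f$cf_loop_insertion_len) && f$cf_loop_insertion_len >= ins_min &&
               !is.na(f$catalytic_conservation) && f$catalytic_conservation <= cat_low) {
      rat <- c(rat, sprintf("CF-loop insertion %d >= %d", f$cf_loop_insertion_len, ins_min),
               sprintf("catalytic conservation %.2f <= %.2f",
                       f$catalytic_conservation, cat_low))
      "PRPSAP_LIKE"
    } else if (!is.na(f$catalytic_conservation) && f$catalytic_conservation >= cat_high &&
               iface_known && iface_min <= iface_low) {
      rat <- c(rat, sprintf("catalytic conservation %.2f >= %.2f",
                            f$catalytic_conservation, cat_high),
               sprintf("interface conservation %.2f <= %.2f", iface_min, iface_low))
      "CLASS_II_PRPS"
    } else if (!is.na(f$catalytic_conservation) && f$catalytic_conservation >= cat_high) {
      rat <- c(rat, sprintf("catalytic conservation %.2f >= %.2f",
                            f$catalytic_conservation, cat_high))
      if (isTRUE(f$intronless)) {
        rat <- c(rat, "intronless gene model")
        "CLASS_I_RETROCOPY"
      } else "CLASS_I_PRPS"
    } else "UNCLASSIFIED"
    tibble(id = f$id, class = cls, rationale = paste(rat, collapse = "; "))
  })
}

#' Clade-by-class presence/absence profile
#'
#' @param classified Tibble with `id`, `taxon`, `class` (join taxa onto
#'   [classify_homologs()] output).
#' @param taxon_map Tibble `taxon`, `clade` (every taxon must be mapped).
#' @param tree Optional `ape::phylo` or newick string used only to order
#'   clade rows by first tip occurrence.
#' @return A `profile_matrix` tibble: complete `clade` x `class` grid with
#'   `count` and `present`.
#' @export
build_profile <- function(classified, taxon_map, tree = NULL) {
  stopifnot(all(c("id", "taxon", "class") %in% names(classified)))
  unmapped <- setdiff(unique(classified$taxon), taxon_map$taxon)
  if (length(unmapped)) {
    abort(paste0("taxa missing from taxon map: ", paste(unmapped, collapse = ", ")),
          class = "splicetrace_mapping_error")
  }
  clade_levels <- unique(taxon_map$clade)
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    tip_clades <- taxon_map$clade[match(tree$tip.label, taxon_map$taxon)]
    ordered <- unique(tip_clades[!is.na(tip_clades)])
    clade_levels <- c(ordered, setdiff(clade_levels, ordered))
  }
  class_levels <- sort(unique(classified$class))
  counts <- classified |>
    left_join(taxon_map, by = "taxon") |>
    dplyr::count(.data$clade, .data$class, name = "count")
  grid <- tidyr::expand_grid(clade = clade_levels, class = class_levels) |>
    left_join(counts, by = c("clade", "class")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L),
           present = .data$count >= 1L,
           clade = factor(.data$clade, levels = clade_levels))
  class(grid) <- c("profile_matrix", class(grid))
  grid
}

#' Support for a duplication origin hypothesis
#'
#' Quantifies whether a putative duplicate ("child") set is closer to a
#' candidate parent set than to an outgroup: mean pairwise global identity to
#' each, their difference `delta`, the number of splice junctions shared
#' child-to-parent at zero tolerance and equal phase, and a seeded bootstrap
#' over resampled identity pairs giving the fraction of replicates with
#' `delta > 0`.
#'
#' @param child,parents,outgroup Protein sets: tibbles with `id`, `residues`
#'   or named character vectors.
#' @param jm Optional junction map from [project_junctions()] covering child
#'   and parent ids.
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed (required when `n_boot > 0`).
#' @param matrix,gap_open,gap_extend Passed to [align_global()].
#' @return A `duplication_support` object; see [tidy()] / [glance()].
#' @export
duplication_support <- function(child, parents, outgroup, jm = NULL,
                                n_boot = 200L, seed = 1L,
                                matrix = blosum62(), gap_open = 11,
                                gap_extend = 1) {
  ch <- normalize_seq_tbl(child); pa <- normalize_seq_tbl(parents)
  og <- normalize_seq_tbl(outgroup)
  if (!nrow(ch) || !nrow(pa) || !nrow(og)) abort("all three sets must be non-empty")
  pair_ids <- function(a, b) {
    tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  }
  ident <- function(a, b) {
    g <- pair_ids(a, b)
    g$identity <- purrr::map2_dbl(g$i, g$j, function(i, j) {
      overlap_identity(a$residues[i], b$residues[j], matrix, gap_open, gap_extend)
    })
    tibble(child_id = a$id[g$i], other_id = b$id[g$j], identity = g$identity)
  }
  pid <- ident(ch, pa); oid <- ident(ch, og)
  delta <- mean(pid$identity) - mean(oid$identity)
  shared <- 0L
  if (!is.null(jm) && nrow(jm)) {
    jms <- jm |> filter(.data$id %in% c(ch$id, pa$id))
    if (nrow(jms)) {
      sj <- call_shared_junctions(jms, shift_tolerance = 0L,
                                  require_same_phase = TRUE,
                                  eligible_ids = c(ch$id, pa$id))
      if (nrow(sj)) {
        shared <- sum(purrr::map_lgl(sj$supporters, function(s) {
          any(s %in% ch$id) && any(s %in% pa$id)
        }))
      }
    }
  }
  boot <- NULL
  if (n_boot > 0L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      mean(sample(pid$identity, replace = TRUE)) -
        mean(sample(oid$identity, replace = TRUE))
    }, double(1))
  }
  structure(list(
    child_ids = ch$id, parent_ids = pa$id, outgroup_ids = og$id,
    parent_identities = pid, outgroup_identities = oid,
    mean_parent_identity = mean(pid$identity),
    mean_outgroup_identity = mean(oid$identity),
    delta = delta, shared_junction_count = shared,
    bootstrap_deltas = boot,
    bootstrap_support = if (is.null(boot)) NA_real_ else mean(boot > 0),
    n_boot = n_boot, seed = seed
  ), class = "duplication_support")
}

#' @export
print.duplication_support <- function(x, ...) {
  cat(sprintf(paste0("<duplication_support> parent identity %.3f, outgroup ",
                     "%.3f, delta %+.3f\n  shared junctions %d, bootstrap ",
                     "support %s (n=%d)\n"),
              x$mean_parent_identity, x$mean_outgroup_identity, x$delta,
              x$shared_junction_count,
              ifelse(is.na(x$bootstrap_support), "NA",
                     sprintf("%.3f", x$bootstrap_support)), x$n_boot))
  invisible(x)
}

#' @rdname duplication_support
#' @param x A `duplication_support` object.
#' @param ... Unused.
#' @export
tidy.duplication_support <- function(x, ...) {
  bind_rows(mutate(x$parent_identities, set = "parent"),
            mutate(x$outgroup_identities, set = "outgroup"))
}

#' @rdname duplication_support
#' @export
glance.duplication_support <- function(x, ...) {
  tibble(mean_parent_identity = x$mean_parent_identity,
         mean_outgroup_identity = x$mean_outgroup_identity,
         delta = x$delta,
         shared_junction_count = x$shared_junction_count,
         bootstrap_support = x$bootstrap_support,
         n_boot = x$n_boot)
}
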