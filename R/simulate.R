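#' Configure a gene-family simulation
#'
#' Builds the configuration for [simulate_family()]: a clade tree whose branch
#' lengths are per-site substitution probabilities, taxa sampled per clade,
#' an ancestral protein with a fixed intron layout, named loop regions and
#' residue sets on ancestral coordinates, and a scripted list of evolutionary
#' events (duplications, loop-window insertions, residue-set degradation,
#' retrocopies, leader extensions) placed on named branches.
#'
#' The defaults emulate the history inferred for the PRPS family: an
#' opisthokont duplication producing a catalytically degraded paralog with a
#' 25-residue catalytic-flexible-loop insertion (PRPSAP2-like), a holomycotan
#' duplicate with a regulatory-loop insertion (Prs5-like), an amoebozoan
#' duplicate with degraded dimer interfaces (Class II-like), a jawed-vertebrate
#' double duplication (PRPS2-like and PRPSAP1-like), an intronless retrocopy,
#' and upstream leader extensions of 29 and 12 codons on the two
#' PRPSAP-like lineages.
#'
#' Residue-set positions are under purifying selection: background
#' substitutions never touch them, so only `degrade` events change their
#' conservation and the ground-truth class of every lineage is well defined.
#'
#' @param seed Integer seed driving every random choice.
#' @param clade_tree Newick string over clades; branch lengths are per-site
#'   substitution probabilities for those branches.
#' @param n_taxa_per_clade Taxa sampled per clade tip (default 3).
#' @param taxon_branch_length Per-site substitution probability on each
#'   terminal taxon branch (default 0.05).
#' @param ancestral_protein_length Ancestral protein length (default 320).
#' @param intron_set Tibble `codon_index`, `phase` of ancestral introns.
#' @param blosum_bias Probability a substitution picks a BLOSUM62-positive
#'   partner rather than a uniform different residue (default 0.5).
#' @param intron_gain_rate,intron_loss_rate Expected intron gain/loss events
#'   per gene per branch (defaults 0.02).
#' @param events Tibble of scripted events; see [default_events()].
#' @param regions Tibble `name`, `start`, `end` on ancestral coordinates.
#' @param residue_sets Tibble `set_name`, `position` (+ optional `residue`
#'   forced in the ancestor).
#' @param reference_gene Gene lineage used as analysis reference; it must not
#'   receive insertion events (default `"prps1"`).
#' @param intron_length Length-2 range of simulated intron lengths.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              clade_tree = default_clade_tree(),
                              n_taxa_per_clade = 3L,
                              taxon_branch_length = 0.05,
                              ancestral_protein_length = 320L,
                              intron_set = default_intron_set(),
                              blosum_bias = 0.5,
                              intron_gain_rate = 0.02,
                              intron_loss_rate = 0.02,
                              events = default_events(),
                              regions = default_sim_regions(),
                              residue_sets = default_sim_residue_sets(),
                              reference_gene = "prps1",
                              intron_length = c(60L, 90L)) {
  cfg <- list(seed = as.integer(seed), clade_tree = clade_tree,
              n_taxa_per_clade = as.integer(n_taxa_per_clade),
              taxon_branch_length = taxon_branch_length,
              ancestral_protein_length = as.integer(ancestral_protein_length),
              intron_set = as_tibble(intron_set), blosum_bias = blosum_bias,
              intron_gain_rate = intron_gain_rate,
              intron_loss_rate = intron_loss_rate,
              events = as_tibble(events), regions = as_tibble(regions),
              residue_sets = as_tibble(residue_sets),
              reference_gene = reference_gene,
              intron_length = as.integer(intron_length))
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  if (cfg$intron_gain_rate < 0 || cfg$intron_loss_rate < 0 ||
      cfg$taxon_branch_length < 0) {
    abort("rates must be >= 0", class = "splicetrace_config_error")
  }
  tree <- ape::read.tree(text = cfg$clade_tree)
  if (is.null(tree)) abort("invalid clade tree", class = "splicetrace_config_error")
  branches <- c(tree$tip.label, tree$node.label)
  bad <- setdiff(cfg$events$branch, branches)
  if (length(bad)) {
    abort(paste0("event branch not in tree: ", paste(bad, collapse = ", ")),
          class = "splicetrace_config_error")
  }
  L <- cfg$ancestral_protein_length
  if (nrow(cfg$regions) && any(cfg$regions$end > L | cfg$regions$start < 1)) {
    abort("region interval outside ancestral length",
          class = "splicetrace_config_error")
  }
  if (any(cfg$residue_sets$position > L)) {
    abort("residue-set position outside ancestral length",
          class = "splicetrace_config_error")
  }
  deg <- cfg$events[cfg$events$kind == "degrade", ]
  if (nrow(deg) && any(deg$fraction > 1 | deg$fraction < 0)) {
    abort("degrade fraction must lie in [0,1]", class = "splicetrace_config_error")
  }
  ins <- cfg$events[cfg$events$kind == "insertion", ]
  if (nrow(ins) && any(ins$gene == cfg$reference_gene)) {
    abort("insertion events may not target the reference gene lineage",
          class = "splicetrace_config_error")
  }
  if (any(cfg$intron_set$codon_index >= L)) {
    abort("ancestral intron beyond protein length",
          class = "splicetrace_config_error")
  }
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_clade_tree <- function() {
  paste0("(Amoebozoa:0.08,(Holomycota:0.1,(Cyclostomata:0.06,",
         "Gnathostomata:0.06)Vertebrata:0.05)Opisthokonta:0.05)Amorphea;")
}

#' @rdname simulation_config
#' @export
default_intron_set <- function() {
  tibble(codon_index = c(40L, 75L, 120L, 170L, 230L, 290L),
         phase = c(0L, 1L, 2L, 0L, 1L, 0L))
}

#' @rdname simulation_config
#' @export
default_sim_regions <- function() {
  tibble(name = c("flag_region", "regulatory_flexible_loop", "pp_loop",
                  "cf_loop", "r5p_loop"),
         start = c(29L, 88L, 165L, 190L, 218L),
         end = c(45L, 110L, 175L, 205L, 230L))
}

#' @rdname simulation_config
#' @export
default_sim_residue_sets <- function() {
  bind_rows(
    tibble(set_name = "catalytic", position = c(171L, 194L, 196L, 200L, 225L),
           residue = c("D", "K", "R", "N", "T")),
    tibble(set_name = "bent_dimer", position = c(60L, 62L, 64L, 66L, 68L),
           residue = NA_character_),
    tibble(set_name = "parallel_dimer", position = c(250L, 252L, 254L, 256L, 258L),
           residue = NA_character_),
    tibble(set_name = "allosteric", position = c(300L, 302L, 304L, 306L),
           residue = NA_character_)
  )
}

#' Default scripted event list
#'
#' @return Tibble with columns `branch`, `kind`, `gene`, `new_gene`,
#'   `region`, `length`, `residue_set`, `fraction`, `leader_aa`.
#' @export
default_events <- function() {
  ev <- function(branch, kind, gene, new_gene = NA, region = NA, length = NA,
                 residue_set = NA, fraction = NA, leader_aa = NA) {
    tibble(branch = branch, kind = kind, gene = gene,
           new_gene = as.character(new_gene), region = as.character(region),
           length = as.integer(length), residue_set = as.character(residue_set),
           fraction = as.numeric(fraction), leader_aa = as.integer(leader_aa))
  }
  bind_rows(
    ev("Opisthokonta", "duplication", "prps1", new_gene = "prpsap2"),
    ev("Opisthokonta", "insertion", "prpsap2", region = "cf_loop", length = 25),
    ev("Opisthokonta", "degrade", "prpsap2", residue_set = "catalytic", fraction = 0.8),
    ev("Holomycota", "duplication", "prps1", new_gene = "prs5"),
    ev("Holomycota", "insertion", "prs5", region = "regulatory_flexible_loop", length = 25),
    ev("Amoebozoa", "duplication", "prps1", new_gene = "prps_cII"),
    ev("Amoebozoa", "degrade", "prps_cII", residue_set = "bent_dimer", fraction = 0.6),
    ev("Amoebozoa", "degrade", "prps_cII", residue_set = "parallel_dimer", fraction = 0.6),
    ev("Gnathostomata", "duplication", "prps1", new_gene = "prps2"),
    ev("Gnathostomata", "duplication", "prpsap2", new_gene = "prpsap1"),
    ev("Gnathostomata", "retrocopy", "prps1", new_gene = "prps1l1"),
    ev("Gnathostomata", "leader", "prpsap1", leader_aa = 29),
    ev("Gnathostomata", "leader", "prpsap2", leader_aa = 12)
  )
}

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

codon_table_for <- function() {
  # aa -> candidate codons under the standard code (stops excluded)
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], unname(gc[gc != "*"]))
}

the_codons <- new.env(parent = emptyenv())
codon_for <- function(aa) {
  if (is.null(the_codons$tab)) the_codons$tab <- codon_table_for()
  tab <- the_codons$tab
  vapply(aa, function(a) sample(tab[[a]], 1L), character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

substitute_residue <- function(current, bias) {
  if (runif(1) < bias) {
    pool <- blosum_positive_partners(current)
    if (!length(pool)) pool <- setdiff(AA20, current)
  } else pool <- setdiff(AA20, current)
  sample(pool, 1L)
}

degrade_residue <- function(anc_res) {
  m <- blosum62()
  pool <- AA20[m[anc_res, AA20] <= 0 & AA20 != anc_res]
  sample(pool, 1L)
}

#' Simulate a gene family with a ground-truth event log
#'
#' Evolves an ancestral gene along the configured clade tree: per-site
#' substitutions on each branch, Poisson intron gain/loss, and the scripted
#' duplication/insertion/degrade/retrocopy/leader events, then emits mutually
#' consistent genomes, strand-aware gene models, transcripts, proteins, the
#' true protein alignment, and a truth table with the class, junctions and
#' leader of every sequence. Fully reproducible from the seed.
#'
#' @param cfg A `simulation_config`.
#' @return A `simulated_family` object: tibbles `genomes`, `gene_models`,
#'   `transcripts` (with `canonical_start`), `proteins`, an `alignment`
#'   (`msa`), `introns` (true junctions), `truth` (per-sequence classes and
#'   features), `events`, `calibration` (realized vs configured substitution
#'   fractions per branch), a `region_set` anchored on an un-indeled
#'   reference tip, `taxon_map`, and the expanded taxon `tree` (newick).
#' @export
simulate_family <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  L <- cfg$ancestral_protein_length
  protected <- sort(unique(cfg$residue_sets$position))

  # ancestral protein and codons; residue 1 is M, forced set residues applied
  aa <- c("M", sample(AA20, L - 1L, replace = TRUE))
  forced <- cfg$residue_sets[!is.na(cfg$residue_sets$residue), ]
  if (nrow(forced)) aa[forced$position] <- forced$residue
  codons <- codon_for(aa)
  codons[1] <- "ATG"

  reg <- new.env(parent = emptyenv())
  reg$order <- seq_len(L)
  reg$next_id <- L + 1L

  log <- new.env(parent = emptyenv())
  log$events <- list(); log$calib <- list()

  anc_state <- list(gene = cfg$reference_gene, aa = aa, codons = codons,
                    anc = seq_len(L), col = seq_len(L),
                    introns = as_tibble(cfg$intron_set),
                    stop_codon = sample(c("TAA", "TAG", "TGA"), 1L),
                    intronless = FALSE, leader_aa = 0L,
                    leader_codons = character(0),
                    ins_by_region = setNames(integer(length(cfg$regions$name)),
                                             cfg$regions$name),
                    degraded = integer(0))

  tree <- ape::read.tree(text = cfg$clade_tree)
  labels <- c(tree$tip.label, tree$node.label)
  root <- ape::Ntip(tree) + 1L

  tips <- list()  # per-taxon list of states

  evolve_branch <- function(states, branch_label, rate) {
    states <- lapply(states, function(st) {
      # the start methionine and all functional-set positions are invariant
      elig <- setdiff(which(!(st$anc %in% protected)), 1L)
      hit <- elig[runif(length(elig)) < rate]
      for (i in hit) {
        st$aa[i] <- substitute_residue(st$aa[i], cfg$blosum_bias)
        st$codons[i] <- codon_for(st$aa[i])
      }
      log$calib[[length(log$calib) + 1L]] <- tibble(
        branch = branch_label, gene = st$gene, rate = rate,
        n_eligible = length(elig), n_substituted = length(hit))
      # intron gain / loss
      n_gain <- rpois(1L, cfg$intron_gain_rate)
      for (g in seq_len(n_gain)) {
        ci <- sample(2:(length(st$aa) - 1L), 1L)
        ph <- sample(0:2, 1L)
        if (!any(st$introns$codon_index == ci & st$introns$phase == ph)) {
          st$introns <- arrange(bind_rows(st$introns,
                                          tibble(codon_index = ci, phase = ph)),
                                .data$codon_index, .data$phase)
          log$events[[length(log$events) + 1L]] <- tibble(
            branch = branch_label, gene = st$gene, kind = "intron_gain",
            detail = paste0("codon ", ci, " phase ", ph))
        }
      }
      if (cfg$intron_loss_rate > 0 && nrow(st$introns)) {
        n_loss <- min(rpois(1L, cfg$intron_loss_rate), nrow(st$introns))
        if (n_loss > 0) {
          drop <- sample(seq_len(nrow(st$introns)), n_loss)
          lost <- st$introns[drop, ]
          st$introns <- st$introns[-drop, ]
          log$events[[length(log$events) + 1L]] <- tibble(
            branch = branch_label, gene = st$gene, kind = "intron_loss",
            detail = paste0("codon ", lost$codon_index, " phase ", lost$phase))
        }
      }
      st
    })
    # scripted events for this branch, in listed order
    evs <- cfg$events[cfg$events$branch == branch_label, ]
    for (k in seq_len(nrow(evs))) {
      e <- evs[k, ]
      gi <- which(vapply(states, function(s) s$gene, character(1)) == e$gene)
      if (!length(gi)) {
        abort(paste0("event targets gene '", e$gene, "' absent on branch ",
                     branch_label), class = "splicetrace_config_error")
      }
      st <- states[[gi[1]]]
      if (e$kind == "duplication" || e$kind == "retrocopy") {
        dup <- st
        dup$gene <- e$new_gene
        if (e$kind == "retrocopy") {
          dup$introns <- dup$introns[0, ]
          dup$intronless <- TRUE
        }
        states[[length(states) + 1L]] <- dup
      } else if (e$kind == "insertion") {
        st <- apply_insertion(st, e$region, e$length, cfg, reg)
        states[[gi[1]]] <- st
      } else if (e$kind == "degrade") {
        st <- apply_degrade(st, e$residue_set, e$fraction, cfg)
        states[[gi[1]]] <- st
      } else if (e$kind == "leader") {
        st$leader_aa <- e$leader_aa
        body <- if (e$leader_aa > 1L) {
          codon_for(sample(setdiff(AA20, "M"), e$leader_aa - 1L, replace = TRUE))
        } else character(0)
        st$leader_codons <- c("ATG", body)
        states[[gi[1]]] <- st
      } else {
        abort(paste0("unknown event kind: ", e$kind),
              class = "splicetrace_config_error")
      }
      detail <- switch(e$kind,
        duplication = paste0("new_gene=", e$new_gene),
        retrocopy = paste0("new_gene=", e$new_gene),
        insertion = paste0(e$region, " +", e$length, "aa"),
        degrade = paste0(e$residue_set, " fraction=", e$fraction),
        leader = paste0("+", e$leader_aa, "aa"))
      log$events[[length(log$events) + 1L]] <- tibble(
        branch = e$branch, gene = e$gene, kind = e$kind, detail = detail)
    }
    states
  }

  descend <- function(node, states) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (i in seq_along(kids)) {
      child <- kids[i]
      len <- tree$edge.length[which(tree$edge[, 1] == node & tree$edge[, 2] == child)]
      lab <- labels[child]
      st2 <- evolve_branch(states, lab, len)
      if (child <= ape::Ntip(tree)) {
        for (t in seq_len(cfg$n_taxa_per_clade)) {
          taxon <- paste0(lab, "_t", t)
          tips[[taxon]] <<- evolve_branch(st2, taxon, cfg$taxon_branch_length)
        }
      } else {
        descend(child, st2)
      }
    }
  }
  descend(root, list(anc_state))

  assemble_family(cfg, tips, reg, log, tree)
}

apply_insertion <- function(st, region, len, cfg, reg) {
  r <- cfg$regions[cfg$regions$name == region, ]
  if (!nrow(r)) abort(paste0("unknown region: ", region),
                      class = "splicetrace_config_error")
  idx <- which(!is.na(st$anc) & st$anc >= r$start & st$anc <= r$end)
  if (length(idx) < 2) abort("region has fewer than 2 residues left",
                             class = "splicetrace_config_error")
  q <- sample(idx[-length(idx)], 1L)  # insert after residue q, inside region
  new_aa <- sample(AA20, len, replace = TRUE)
  new_codons <- codon_for(new_aa)
  new_ids <- seq(reg$next_id, length.out = len)
  reg$next_id <- reg$next_id + len
  pos <- match(st$col[q], reg$order)
  reg$order <- append(reg$order, new_ids, after = pos)
  st$aa <- append(st$aa, new_aa, after = q)
  st$codons <- append(st$codons, new_codons, after = q)
  st$anc <- append(st$anc, rep(NA_integer_, len), after = q)
  st$col <- append(st$col, new_ids, after = q)
  st$introns <- mutate(st$introns, codon_index = ifelse(
    .data$codon_index > q, .data$codon_index + len, .data$codon_index))
  st$ins_by_region[region] <- st$ins_by_region[region] + len
  st
}

apply_degrade <- function(st, set_name, fraction, cfg) {
  set <- cfg$residue_sets[cfg$residue_sets$set_name == set_name, ]
  if (!nrow(set)) abort(paste0("unknown residue set: ", set_name),
                        class = "splicetrace_config_error")
  n <- ceiling(fraction * nrow(set))
  chosen <- sample(set$position, n)
  for (p in chosen) {
    i <- which(st$anc == p)
    st$aa[i] <- degrade_residue(st$aa[i])
    st$codons[i] <- codon_for(st$aa[i])
  }
  st$degraded <- sort(unique(c(st$degraded, chosen)))
  st
}

truth_class <- function(st, cfg, thresholds = list(ins_min = 10L, cat_low = 0.4,
                                                   cat_high = 0.8, iface_low = 0.5)) {
  set_frac <- function(set_name) {
    pos <- cfg$residue_sets$position[cfg$residue_sets$set_name == set_name]
    if (!length(pos)) return(NA_real_)
    1 - sum(st$degraded %in% pos) / length(pos)
  }
  cat_c <- set_frac("catalytic")
  iface <- min(set_frac("bent_dimer"), set_frac("parallel_dimer"))
  cf <- unname(st$ins_by_region["cf_loop"])
  rg <- unname(st$ins_by_region["regulatory_flexible_loop"])
  if (!is.na(rg) && rg >= thresholds$ins_min) return("PRS5_LIKE")
  if (!is.na(cf) && cf >= thresholds$ins_min && cat_c <= thresholds$cat_low) {
    return("PRPSAP_LIKE")
  }
  if (cat_c >= thresholds$cat_high && !is.na(iface) && iface <= thresholds$iface_low) {
    return("CLASS_II_PRPS")
  }
  if (cat_c >= thresholds$cat_high) {
    if (st$intronless || nrow(st$introns) == 0L) return("CLASS_I_RETROCOPY")
    return("CLASS_I_PRPS")
  }
  "UNCLASSIFIED"
}

assemble_family <- function(cfg, tips, reg, log, clade_tree) {
  rows <- list(); genomes <- list(); models <- list(); txs <- list()
  prots <- list(); introns <- list(); truth <- list()
  taxa <- names(tips)
  for (taxon in taxa) {
    clade <- sub("_t\\d+$", "", taxon)
    for (st in tips[[taxon]]) {
      id <- paste0(taxon, ".", st$gene)
      cds <- paste(c(st$codons, st$stop_codon), collapse = "")
      # genome with introns (+ or - strand)
      cum <- with(st$introns, sort(3L * (codon_index - 1L) + phase))
      pieces <- substring(cds, c(1L, cum + 1L), c(cum, nchar(cds)))
      intr <- vapply(seq_len(length(pieces) - 1L), function(i) {
        n <- sample(seq(cfg$intron_length[1], cfg$intron_length[2]), 1L)
        paste0("GT", random_dna(n - 4L), "AG")
      }, character(1))
      flank5 <- random_dna(25L); flank3 <- random_dna(25L)
      body <- character(0)
      starts <- integer(length(pieces)); ends <- integer(length(pieces))
      off <- nchar(flank5)
      for (i in seq_along(pieces)) {
        starts[i] <- off
        ends[i] <- off + nchar(pieces[i])
        off <- ends[i]
        body <- c(body, pieces[i])
        if (i < length(pieces)) {
          body <- c(body, intr[i])
          off <- off + nchar(intr[i])
        }
      }
      gseq <- paste0(flank5, paste(body, collapse = ""), flank3)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        Lg <- nchar(gseq)
        gseq <- revcomp(gseq)
        tmp <- Lg - ends
        ends <- Lg - starts
        starts <- tmp
      }
      gid <- paste0("chr_", id)
      genomes[[gid]] <- tibble(id = gid, residues = gseq,
                               description = paste0("taxon=", taxon))
      models[[id]] <- tibble(gene_id = id, taxon = taxon, genome_id = gid,
                             strand = strand, exon_start = starts,
                             exon_end = ends, rank = seq_along(starts),
                             partial = FALSE)
      # transcript: 12-nt UTR ending in-frame TAA, optional leader, CDS, UTR3
      utr5 <- paste0(random_dna(9L), "TAA")
      leader <- paste(st$leader_codons, collapse = "")
      tx_seq <- paste0(utr5, leader, cds, random_dna(20L))
      txs[[id]] <- tibble(id = id, residues = tx_seq,
                          canonical_start = nchar(utr5) + nchar(leader),
                          taxon = taxon)
      prot <- paste(st$aa, collapse = "")
      prots[[id]] <- tibble(id = id, residues = prot, taxon = taxon,
                            gene = st$gene)
      if (nrow(st$introns)) {
        ord <- order(st$introns$codon_index, st$introns$phase)
        introns[[id]] <- tibble(id = id,
                                intron_rank = seq_along(ord),
                                codon_index = st$introns$codon_index[ord],
                                phase = st$introns$phase[ord])
      }
      rows[[id]] <- tibble(id = id, aligned = {
        r <- rep("-", length(reg$order))
        r[match(st$col, reg$order)] <- st$aa
        paste(r, collapse = "")
      })
      truth[[id]] <- tibble(id = id, gene = st$gene, taxon = taxon,
                            clade = clade, class = truth_class(st, cfg),
                            n_introns = nrow(st$introns),
                            intronless = nrow(st$introns) == 0L,
                            leader_aa = st$leader_aa,
                            cf_insertion_len = unname(st$ins_by_region["cf_loop"]),
                            reg_insertion_len = unname(st$ins_by_region["regulatory_flexible_loop"]),
                            strand = strand)
    }
  }
  ref_taxon <- taxa[[1]]
  reference_id <- paste0(ref_taxon, ".", cfg$reference_gene)
  ref_state <- tips[[ref_taxon]][[which(vapply(tips[[ref_taxon]],
                                               function(s) s$gene, character(1)) ==
                                          cfg$reference_gene)[1]]]
  rs <- new_region_set(
    reference_id, cfg$regions,
    cfg$residue_sets |>
      mutate(expected = ref_state$aa[.data$position]) |>
      select("set_name", "position", "expected"))
  # expanded taxon tree: replace each clade tip with its taxa
  tree_txt <- cfg$clade_tree
  for (cl in clade_tree$tip.label) {
    sub <- paste0("(", paste0(cl, "_t", seq_len(cfg$n_taxa_per_clade), ":",
                              cfg$taxon_branch_length, collapse = ","), ")", cl)
    tree_txt <- sub(paste0(cl, ":"), paste0(sub, ":"), tree_txt, fixed = TRUE)
  }
  structure(list(
    config = cfg,
    genomes = bind_rows(genomes),
    gene_models = {
      m <- bind_rows(models); class(m) <- c("gene_models", class(m)); m
    },
    transcripts = bind_rows(txs),
    proteins = bind_rows(prots),
    alignment = as_msa(bind_rows(rows)),
    introns = if (length(introns)) bind_rows(introns) else
      tibble(id = character(), intron_rank = integer(),
             codon_index = integer(), phase = integer()),
    truth = bind_rows(truth),
    events = if (length(log$events)) bind_rows(log$events) else
      tibble(branch = character(), gene = character(), kind = character(),
             detail = character()),
    calibration = bind_rows(log$calib),
    region_set = rs,
    taxon_map = tibble(taxon = taxa, clade = sub("_t\\d+$", "", taxa)),
    tree = tree_txt
  ), class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf(paste0("<simulated_family> seed %d: %d sequences, %d taxa, ",
                     "%d genes, alignment %d x %d\n"),
              x$config$seed, nrow(x$proteins),
              dplyr::n_distinct(x$proteins$taxon),
              dplyr::n_distinct(x$proteins$gene), nrow(x$alignment),
              attr(x$alignment, "ncol")))
  invisible(x)
}

#' @rdname simulate_family
#' @param x A `simulated_family`.
#' @param ... Unused.
#' @export
glance.simulated_family <- function(x, ...) {
  tibble(seed = x$config$seed, n_sequences = nrow(x$proteins),
         n_taxa = dplyr::n_distinct(x$proteins$taxon),
         n_genes = dplyr::n_distinct(x$proteins$gene),
         alignment_columns = attr(x$alignment, "ncol"),
         n_events = nrow(x$events))
}

#' Write a simulated family to fixture files
#'
#' Writes FASTA/TSV/newick fixtures plus a JSON manifest of md5 checksums and
#' a configuration hash; identical configurations reproduce byte-identical
#' files.
#'
#' @param fam A `simulated_family`.
#' @param dir Output directory (created if needed).
#' @return Manifest as a named list, invisibly; also written as
#'   `manifest.json`.
#' @export
write_fixture_files <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(fam$genomes, p("genomes.fasta"))
  write_fasta(fam$transcripts |> mutate(
    description = paste0("canonical_start=", .data$canonical_start)), p("transcripts.fasta"))
  write_fasta(fam$proteins, p("proteins.fasta"))
  write_fasta(tibble(id = fam$alignment$id, residues = fam$alignment$aligned),
              p("alignment.fasta"))
  readr::write_tsv(fam$gene_models[, c("gene_id", "taxon", "genome_id", "strand",
                                       "exon_start", "exon_end", "rank")],
                   p("gene_models.tsv"))
  readr::write_tsv(fam$truth, p("truth.tsv"))
  readr::write_tsv(fam$events, p("events.tsv"))
  readr::write_tsv(fam$taxon_map, p("taxon_map.tsv"))
  writeLines(fam$tree, p("tree.nwk"))
  rs <- fam$region_set
  rs_tbl <- bind_rows(
    tibble(kind = "reference", name = rs$reference_id, start = NA_integer_,
           end = NA_integer_, position = NA_integer_, expected = NA_character_),
    tibble(kind = "region", name = rs$regions$name, start = rs$regions$start,
           end = rs$regions$end, position = NA_integer_, expected = NA_character_),
    tibble(kind = "set", name = rs$residue_sets$set_name, start = NA_integer_,
           end = NA_integer_, position = rs$residue_sets$position,
           expected = rs$residue_sets$expected))
  readr::write_tsv(rs_tbl, p("region_set.tsv"))
  files <- c("genomes.fasta", "transcripts.fasta", "proteins.fasta",
             "alignment.fasta", "gene_models.tsv", "truth.tsv", "events.tsv",
             "taxon_map.tsv", "tree.nwk", "region_set.tsv")
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  cfg_txt <- paste(deparse(unclass(fam$config)), collapse = "\n")
  cfg_file <- tempfile()
  writeLines(cfg_txt, cfg_file)
  manifest <- list(seed = fam$config$seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   files = as.list(sums))
  unlink(cfg_file)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
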