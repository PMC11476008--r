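# In-code fixture builders shared across test files.

# Build a one-gene genome from CDS pieces and intron sequences:
# pieces = exon sequences (coding order), introns between them.
make_gene_fixture <- function(pieces, introns = character(0), strand = "+",
                              gene_id = "g1", genome_id = "chr1",
                              flank = "CCCCC") {
  stopifnot(length(introns) == length(pieces) - 1)
  body <- character(0)
  starts <- integer(length(pieces)); ends <- integer(length(pieces))
  off <- nchar(flank)
  for (i in seq_along(pieces)) {
    starts[i] <- off
    ends[i] <- off + nchar(pieces[i])
    off <- ends[i]
    body <- c(body, pieces[i])
    if (i < length(pieces)) {
      body <- c(body, introns[i])
      off <- off + nchar(introns[i])
    }
  }
  gseq <- paste0(flank, paste(body, collapse = ""), flank)
  if (strand == "-") {
    Lg <- nchar(gseq)
    gseq <- paste(rev(strsplit(chartr("ACGT", "TGCA", gseq), "")[[1]]),
                  collapse = "")
    tmp <- Lg - ends
    ends <- Lg - starts
    starts <- tmp
  }
  models <- tibble::tibble(gene_id = gene_id, taxon = "taxonA",
                           genome_id = genome_id, strand = strand,
                           exon_start = starts, exon_end = ends,
                           rank = seq_along(starts), partial = FALSE)
  list(models = models,
       genomes = stats::setNames(gseq, genome_id))
}

# canonical GT..AG intron of a given total length
gt_ag_intron <- function(n = 11) {
  paste0("GT", paste(rep("C", n - 4), collapse = ""), "AG")
}

# small msa builder from named gapped strings
make_msa <- function(...) {
  rows <- c(...)
  splicetrace::as_msa(tibble::tibble(id = names(rows), aligned = unname(rows)))
}

# region set with a single region / set on a given reference
make_region_set <- function(reference_id, regions = NULL, sets = NULL) {
  splicetrace:::new_region_set(
    reference_id,
    regions %||% tibble::tibble(name = character(), start = integer(),
                                end = integer()),
    sets %||% tibble::tibble(set_name = character(), position = integer(),
                             expected = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cache simulated families across test files (keyed by seed, default config)
the_family_cache <- new.env(parent = emptyenv())
get_family <- function(seed) {
  key <- as.character(seed)
  if (is.null(the_family_cache[[key]])) {
    the_family_cache[[key]] <- splicetrace::simulate_family(
      splicetrace::simulation_config(seed = seed))
  }
  the_family_cache[[key]]
}

# a compact simulation configuration used where full size is not needed
small_sim_config <- function(seed, ...) {
  splicetrace::simulation_config(
    seed = seed,
    n_taxa_per_clade = 2L,
    ancestral_protein_length = 320L,
    ...)
}

# zero-divergence variant: all branch rates, gain/loss zero
zero_rate_config <- function(seed, events = splicetrace::default_events(), ...) {
  tr <- ape::read.tree(text = splicetrace::default_clade_tree())
  tr$edge.length[] <- 0
  splicetrace::simulation_config(
    seed = seed,
    clade_tree = ape::write.tree(tr),
    taxon_branch_length = 0,
    intron_gain_rate = 0, intron_loss_rate = 0,
    n_taxa_per_clade = 2L,
    events = events, ...)
}
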