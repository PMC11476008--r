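#' Gene models: strand-aware exon tables
#'
#' A gene model is a set of ordered exon intervals on a genomic sequence, the
#' unit of all splice-structure analysis here. Models are held as a tibble with
#' one row per exon and columns `gene_id`, `taxon`, `genome_id`, `strand`
#' (`"+"`/`"-"`), `exon_start`, `exon_end` (0-based half-open genomic
#' coordinates), `rank` (1-based 5'->3' transcript order) and `partial`
#' (model fails CDS completeness checks and is excluded from junction analysis
#' by default).
#'
#' Two input dialects are supported: a TSV exon table with the columns above
#' (`rank` and `taxon` optional; missing ranks are assigned by transcript
#' order) and GFF3 (exon features carrying `gene_id` and optional `rank`
#' attributes, parsed via rtracklayer).
#'
#' @param path Path to an exon-table TSV or a GFF3 file.
#' @param genomes Genomic sequences: a tibble from [read_fasta()] or a named
#'   character vector keyed by `genome_id`.
#' @param format `"auto"` (by extension), `"exon_tsv"` or `"gff3"`.
#' @return A validated gene-model tibble (class `gene_models`).
#' @export
read_gene_models <- function(path, genomes, format = c("auto", "exon_tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "exon_tsv"
  }
  tbl <- if (format == "gff3") parse_gff3_exons(path) else parse_exon_tsv(path)
  validate_gene_models(tbl, genomes)
}

parse_exon_tsv <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("gene_id", "genome_id", "strand", "exon_start", "exon_end")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) abort(paste0("exon table ", path, " lacks columns: ",
                                 paste(miss, collapse = ", ")))
  tbl$exon_start <- as.integer(tbl$exon_start)
  tbl$exon_end <- as.integer(tbl$exon_end)
  if (!"taxon" %in% names(tbl)) tbl$taxon <- NA_character_
  if ("rank" %in% names(tbl)) tbl$rank <- as.integer(tbl$rank) else tbl$rank <- NA_integer_
  bad <- which(!is.na(tbl$exon_start) & !is.na(tbl$exon_end) &
                 tbl$exon_start >= tbl$exon_end)
  if (length(bad)) {
    abort(paste0("malformed interval (start >= end) in ", path,
                 " at data line ", bad[1]),
          class = "splicetrace_parse_error")
  }
  tbl[, c("gene_id", "taxon", "genome_id", "strand", "exon_start", "exon_end", "rank")]
}

parse_gff3_exons <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  md <- as.data.frame(gr)
  gene_id <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else as.character(md$Parent)
  tibble(
    gene_id = gene_id,
    taxon = if ("taxon" %in% names(md)) as.character(md$taxon) else NA_character_,
    genome_id = as.character(md$seqnames),
    strand = as.character(md$strand),
    # GFF3 is 1-based inclusive; internal convention is 0-based half-open
    exon_start = as.integer(md$start) - 1L,
    exon_end = as.integer(md$end),
    rank = if ("rank" %in% names(md)) as.integer(md$rank) else NA_integer_
  )
}

as_genome_index <- function(genomes) {
  if (is.character(genomes) && !is.null(names(genomes))) return(toupper(genomes))
  stopifnot(all(c("id", "residues") %in% names(genomes)))
  setNames(toupper(genomes$residues), genomes$id)
}

#' Validate a gene-model tibble
#'
#' Checks interval sanity, exon overlap, genome references and bounds, assigns
#' missing ranks by transcript order, and flags models whose spliced CDS is
#' not a complete start-to-stop open reading frame as `partial` (with a
#' warning) rather than failing.
#'
#' @param tbl Exon tibble (see [read_gene_models()] for columns).
#' @inheritParams read_gene_models
#' @return The tibble with `rank` filled and a logical `partial` column.
#' @export
validate_gene_models <- function(tbl, genomes) {
  gi <- as_genome_index(genomes)
  if (any(tbl$exon_start >= tbl$exon_end)) {
    abort("malformed interval (start >= end)", class = "splicetrace_parse_error")
  }
  if (!all(tbl$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  unknown <- setdiff(unique(tbl$genome_id), names(gi))
  if (length(unknown)) {
    abort(paste0("unknown genome_id: ", paste(unknown, collapse = ", ")),
          class = "splicetrace_reference_error")
  }
  out <- tbl |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      strand <- g$strand[1]
      if (!all(g$strand == strand)) abort(paste0("mixed strand in gene ", key$gene_id))
      if (all(is.na(g$rank))) {
        ord <- order(g$exon_start, decreasing = (strand == "-"))
        g$rank[ord] <- seq_len(nrow(g))
      }
      g <- arrange(g, .data$rank)
      if (!identical(g$rank, seq_len(nrow(g)))) {
        abort(paste0("ranks not consecutive from 1 in gene ", key$gene_id))
      }
      o <- order(g$exon_start)
      so <- g$exon_start[o]; eo <- g$exon_end[o]
      if (nrow(g) > 1 && any(so[-1] < eo[-nrow(g)])) {
        abort(paste0("overlapping exons in gene ", key$gene_id))
      }
      expect_ord <- if (strand == "+") order(g$exon_start) else order(-g$exon_start)
      if (!identical(expect_ord, seq_len(nrow(g)))) {
        abort(paste0("exon genomic order inconsistent with strand in gene ", key$gene_id))
      }
      glen <- nchar(gi[[g$genome_id[1]]])
      if (any(g$exon_end > glen) || any(g$exon_start < 0)) {
        abort(paste0("exon outside genome bounds in gene ", key$gene_id),
              class = "splicetrace_reference_error")
      }
      g
    }) |>
    ungroup()
  out <- out[, c("gene_id", "taxon", "genome_id", "strand", "exon_start", "exon_end", "rank")]
  # completeness check -> partial flag
  partial_genes <- character(0)
  for (g in unique(out$gene_id)) {
    rows <- out[out$gene_id == g, ]
    cds <- splice_cds(rows, gi)
    ok <- nchar(cds) %% 3L == 0L &&
      nchar(cds) >= 6L &&
      substr(cds, 1L, 3L) == "ATG" &&
      substr(cds, nchar(cds) - 2L, nchar(cds)) %in% c("TAA", "TAG", "TGA")
    if (!ok) partial_genes <- c(partial_genes, g)
  }
  if (length(partial_genes)) {
    warn(paste0("partial gene models (flagged, excluded from junction analysis ",
                "by default): ", paste(partial_genes, collapse = ", ")))
  }
  out$partial <- out$gene_id %in% partial_genes
  class(out) <- c("gene_models", class(out))
  out
}

# spliced coding sequence of one gene (rows = its exons), coding strand 5'->3'
splice_cds <- function(rows, genome_index) {
  rows <- rows[order(rows$rank), ]
  gseq <- genome_index[[rows$genome_id[1]]]
  pieces <- substring(gseq, rows$exon_start + 1L, rows$exon_end)
  if (rows$strand[1] == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

one_gene <- function(models, gene_id) {
  rows <- models[models$gene_id == gene_id, ]
  if (!nrow(rows)) abort(paste0("unknown gene_id: ", gene_id))
  rows
}

#' Extract and translate the spliced CDS of gene models
#'
#' @param models Gene-model tibble from [read_gene_models()] /
#'   [validate_gene_models()].
#' @inheritParams read_gene_models
#' @param gene_ids Genes to translate; defaults to all non-partial models.
#' @return Tibble of protein records: `id` (gene_id), `residues`,
#'   `source_gene`, `taxon`.
#' @export
spliced_protein <- function(models, genomes, gene_ids = NULL) {
  gi <- as_genome_index(genomes)
  if (is.null(gene_ids)) gene_ids <- unique(models$gene_id[!models$partial])
  purrr::map_dfr(gene_ids, function(g) {
    rows <- one_gene(models, g)
    if (rows$partial[1]) {
      abort(paste0("gene ", g, " is partial; spliced_protein requires a complete model"),
            class = "splicetrace_precondition_error")
    }
    cds <- splice_cds(rows, gi)
    aa <- translate_cds(cds, strip_stop = TRUE)
    if (grepl("\\*", aa)) {
      abort(paste0("internal stop codon in gene ", g, " (pseudogene?)"),
            class = "splicetrace_pseudogene_error")
    }
    tibble(id = g, residues = aa, source_gene = g, taxon = rows$taxon[1])
  })
}

#' Classify splice-site dinucleotides of every intron
#'
#' Donor/acceptor dinucleotides are read from the coding strand of each
#' intron. `GT/AG` is canonical, `GC/AG` non-canonical, everything else
#' (including `N`-containing sites, which draw a warning) is `other`.
#'
#' @inheritParams spliced_protein
#' @param include_partial Include models flagged partial (default `FALSE`).
#' @return Tibble: `gene_id`, `intron_rank`, `donor`, `acceptor`, `klass`.
#' @export
classify_splice_sites <- function(models, genomes, include_partial = FALSE) {
  gi <- as_genome_index(genomes)
  keep <- if (include_partial) unique(models$gene_id) else unique(models$gene_id[!models$partial])
  purrr::map_dfr(keep, function(g) {
    rows <- one_gene(models, g) |> arrange(.data$rank)
    if (nrow(rows) < 2) return(tibble())
    gseq <- gi[[rows$genome_id[1]]]
    purrr::map_dfr(seq_len(nrow(rows) - 1L), function(i) {
      if (rows$strand[1] == "+") {
        s <- rows$exon_end[i]; e <- rows$exon_start[i + 1]
      } else {
        s <- rows$exon_end[i + 1]; e <- rows$exon_start[i]
      }
      if (e - s < 4L) {
        abort(paste0("degenerate intron (<4 nt) in gene ", g, " after exon rank ", i),
              class = "splicetrace_degenerate_intron_error")
      }
      iseq <- substring(gseq, s + 1L, e)
      if (rows$strand[1] == "-") iseq <- revcomp(iseq)
      donor <- substr(iseq, 1L, 2L)
      acceptor <- substr(iseq, nchar(iseq) - 1L, nchar(iseq))
      if (grepl("N", paste0(donor, acceptor))) {
        warn(paste0("N in splice dinucleotide of gene ", g, ", intron ", i))
      }
      klass <- if (donor == "GT" && acceptor == "AG") "canonical"
      else if (donor == "GC" && acceptor == "AG") "noncanonical"
      else "other"
      tibble(gene_id = g, intron_rank = i, donor = donor,
             acceptor = acceptor, klass = klass)
    })
  })
}

#' Intron positions with codon phase
#'
#' For each intron, the number of coding nucleotides upstream of the junction
#' (`L`, the cumulative exon length) gives `phase = L mod 3` (nucleotides of
#' the split codon contributed by the upstream exon) and
#' `codon_index = floor(L/3) + 1`: the residue hosting the split codon for
#' phases 1 and 2, or the residue immediately following a codon-boundary
#' (phase 0) junction.
#'
#' @inheritParams spliced_protein
#' @param gene_ids Genes to report; defaults to all non-partial models.
#' @return Tibble: `gene_id`, `intron_rank`, `codon_index`, `phase`.
#' @export
intron_positions <- function(models, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- unique(models$gene_id[!models$partial])
  purrr::map_dfr(gene_ids, function(g) {
    rows <- one_gene(models, g) |> arrange(.data$rank)
    if (rows$partial[1]) {
      abort(paste0("gene ", g, " is partial; intron_positions requires a complete model"),
            class = "splicetrace_precondition_error")
    }
    if (nrow(rows) < 2) return(tibble())
    lens <- rows$exon_end - rows$exon_start
    cum <- cumsum(lens)[-nrow(rows)]
    tibble(gene_id = g,
           intron_rank = seq_along(cum),
           codon_index = as.integer(cum %/% 3L + 1L),
           phase = as.integer(cum %% 3L))
  })
}

#' Write a tibble as a TSV report with a parameter header
#'
#' Reports are plain TSV with `#`-prefixed header lines echoing the parameters
#' that produced them, so runs are diff-able.
#'
#' @param x Tibble.
#' @param path Output path.
#' @param params Named list echoed as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params)) {
    writeLines(paste0("# ", names(params), ": ",
                      vapply(params, function(v) paste(format(v), collapse = ","),
                             character(1))), con)
  }
  x <- as.data.frame(x)
  for (j in seq_along(x)) if (is.list(x[[j]])) {
    x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ","), character(1))
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
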