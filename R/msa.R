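#' Read a protein multiple alignment from aligned FASTA
#'
#' Alignments are consumed, never built, by this package. Rows must be equal
#' length and ids unique; ungapping a row reproduces the input protein.
#'
#' @param path Aligned FASTA path.
#' @return An `msa` tibble with columns `id`, `aligned` and attribute `ncol`.
#' @export
read_alignment <- function(path) {
  x <- read_fasta(path)
  as_msa(tibble(id = x$id, aligned = x$residues))
}

#' Coerce a tibble of gapped rows to an `msa`
#'
#' @param x Tibble with `id` and `aligned` (gap character `-`).
#' @return `msa` tibble.
#' @export
as_msa <- function(x) {
  stopifnot(all(c("id", "aligned") %in% names(x)))
  if (nrow(x) < 2) abort("an alignment needs at least 2 rows")
  if (anyDuplicated(x$id)) {
    abort("duplicate sequence ids in alignment", class = "splicetrace_id_error")
  }
  w <- unique(nchar(x$aligned))
  if (length(w) != 1) {
    abort("ragged alignment: rows differ in length",
          class = "splicetrace_alignment_format_error")
  }
  out <- as_tibble(x[, c("id", "aligned")])
  attr(out, "ncol") <- w
  class(out) <- c("msa", class(out))
  out
}

msa_row <- function(msa, id) {
  i <- match(id, msa$id)
  if (is.na(i)) abort(paste0("unknown alignment id: ", id),
                      class = "splicetrace_id_error")
  msa$aligned[i]
}

#' Map residue indices to alignment columns
#'
#' @param msa An `msa` tibble.
#' @param id Sequence id.
#' @return Strictly increasing integer vector: element `i` is the 1-based
#'   alignment column of residue `i`.
#' @export
residue_to_column <- function(msa, id) {
  row <- strsplit(msa_row(msa, id), "")[[1]]
  which(row != "-")
}

ungap <- function(aligned) unname(gsub("-", "", aligned))

#' Project intron positions onto alignment columns
#'
#' Each junction is mapped to the alignment column of its `codon_index`
#' residue (phase-0 junctions attach to the following residue, consistent with
#' [intron_positions()]); the phase is carried through unchanged.
#'
#' @param msa An `msa` tibble.
#' @param introns Tibble from [intron_positions()] (`gene_id` or `id`,
#'   `intron_rank`, `codon_index`, `phase`). Ids must match alignment rows.
#' @param eligible_ids Sequences eligible for junction sharing (used as the
#'   support denominator downstream); defaults to the ids present in
#'   `introns`. Pass all sequences with a usable gene model to count
#'   intronless genes in the denominator.
#' @return Junction-map tibble: `id`, `intron_rank`, `column`, `phase`, with
#'   attribute `eligible_ids`.
#' @export
project_junctions <- function(msa, introns, eligible_ids = NULL) {
  introns <- as_tibble(introns)
  if ("gene_id" %in% names(introns) && !"id" %in% names(introns)) {
    introns <- rename(introns, id = "gene_id")
  }
  ids <- unique(introns$id)
  missing <- setdiff(ids, msa$id)
  if (length(missing)) {
    abort(paste0("intron ids absent from alignment: ",
                 paste(missing, collapse = ", ")),
          class = "splicetrace_id_error")
  }
  out <- purrr::map_dfr(ids, function(i) {
    map <- residue_to_column(msa, i)
    rows <- introns[introns$id == i, ]
    if (any(rows$codon_index > length(map))) {
      abort(paste0("codon_index beyond ungapped length for ", i,
                   " (gene model and protein disagree)"),
            class = "splicetrace_consistency_error")
    }
    tibble(id = i, intron_rank = rows$intron_rank,
           column = map[rows$codon_index], phase = rows$phase)
  })
  out <- arrange(out, .data$id, .data$intron_rank)
  attr(out, "eligible_ids") <- unique(c(eligible_ids %||% character(0), ids))
  out
}

#' Call splice junctions shared across sequences
#'
#' Junctions from distinct sequences are grouped greedily left to right:
#' scanning columns in ascending order, a group collects junctions whose
#' column lies within `shift_tolerance` of the group's anchor (its minimum
#' member column), requiring equal phase by default; each junction joins at
#' most one group and a sequence contributes at most one junction per group.
#' Groups with at least two supporting sequences are reported. The defaults
#' (`shift_tolerance = 0`, `require_same_phase = TRUE`) encode exact junction
#' conservation; looser settings are opt-in.
#'
#' @param jm Junction map from [project_junctions()].
#' @param shift_tolerance Maximum column shift within a group (default 0).
#' @param require_same_phase Require equal phase within a group (default TRUE).
#' @param eligible_ids Denominator for `support`; defaults to the junction
#'   map's `eligible_ids` attribute, else the ids present in `jm`.
#' @return Tibble of shared junctions: `column` (anchor), `phase` (`NA` when
#'   mixed), `n_supporters`, `support`, `supporters` (list column).
#' @export
call_shared_junctions <- function(jm, shift_tolerance = 0L,
                                  require_same_phase = TRUE,
                                  eligible_ids = NULL) {
  stopifnot(shift_tolerance >= 0L)
  eligible <- eligible_ids %||% attr(jm, "eligible_ids") %||% unique(jm$id)
  n_elig <- length(eligible)
  if (!nrow(jm)) {
    return(tibble(column = integer(), phase = integer(),
                  n_supporters = integer(), support = double(),
                  supporters = list()))
  }
  j <- arrange(as_tibble(jm), .data$column, .data$phase, .data$id, .data$intron_rank)
  assigned <- rep(FALSE, nrow(j))
  groups <- list()
  for (k in seq_len(nrow(j))) {
    if (assigned[k]) next
    anchor_col <- j$column[k]
    anchor_phase <- j$phase[k]
    members <- k
    assigned[k] <- TRUE
    used <- j$id[k]
    for (l in seq_len(nrow(j))) {
      if (assigned[l] || j$id[l] %in% used) next
      if (abs(j$column[l] - anchor_col) > shift_tolerance) next
      if (require_same_phase && j$phase[l] != anchor_phase) next
      members <- c(members, l)
      assigned[l] <- TRUE
      used <- c(used, j$id[l])
    }
    groups[[length(groups) + 1L]] <- members
  }
  out <- purrr::map_dfr(groups, function(m) {
    if (length(m) < 2) return(tibble())
    ph <- unique(j$phase[m])
    tibble(column = min(j$column[m]),
           phase = if (length(ph) == 1) ph else NA_integer_,
           n_supporters = length(m),
           support = length(m) / n_elig,
           supporters = list(sort(j$id[m])))
  })
  if (!nrow(out)) {
    return(tibble(column = integer(), phase = integer(),
                  n_supporters = integer(), support = double(),
                  supporters = list()))
  }
  arrange(out, .data$column)
}
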