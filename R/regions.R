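#' Region and residue-set specifications
#'
#' A region set anchors analyses to a reference sequence: named residue-index
#' windows (e.g. the FLAG region and the PP, catalytic flexible, regulatory
#' flexible and R5P loops of human PRPS1) and named residue sets (e.g. the
#' catalytic set D171, K194, R196, N200, T225). Everything is 1-based
#' inclusive on reference residues and fully user-editable.
#'
#' The TSV dialect has columns `kind` (`reference`/`region`/`set`), `name`,
#' `start`, `end`, `position`, `expected`; `reference` rows carry the
#' reference id in `name`.
#'
#' @param path TSV path.
#' @return A `region_set`: list with `reference_id`, `regions` tibble
#'   (`name`, `start`, `end`) and `residue_sets` tibble (`set_name`,
#'   `position`, `expected`).
#' @export
read_region_set <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  ref <- tbl$name[tbl$kind == "reference"]
  if (length(ref) != 1) abort("region-set file needs exactly one 'reference' row")
  regions <- tbl |> filter(.data$kind == "region") |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    select("name", "start", "end")
  sets <- tbl |> filter(.data$kind == "set") |>
    mutate(position = as.integer(.data$position)) |>
    select(set_name = "name", "position", "expected")
  new_region_set(ref, regions, sets)
}

new_region_set <- function(reference_id, regions, residue_sets) {
  if (nrow(regions) && any(regions$start > regions$end)) abort("region start > end")
  dup <- residue_sets |> group_by(.data$set_name) |>
    summarise(d = anyDuplicated(.data$position), .groups = "drop")
  if (any(dup$d > 0)) abort("duplicate positions within a residue set")
  structure(list(reference_id = reference_id,
                 regions = as_tibble(regions),
                 residue_sets = as_tibble(residue_sets)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> reference %s: %d regions, %d residue sets\n",
              x$reference_id, nrow(x$regions),
              dplyr::n_distinct(x$residue_sets$set_name)))
  invisible(x)
}

#' Default region set for human PRPS1
#'
#' Approximate loop windows on human PRPS1 numbering (implementer-chosen,
#' editable; the catalytic residue set is the published one). Interface and
#' allosteric set membership is user-supplied and ships empty.
#'
#' @param reference_id Id the reference sequence carries in your alignment
#'   (default `"PRPS1_HUMAN"`).
#' @return A `region_set`.
#' @export
default_region_set <- function(reference_id = "PRPS1_HUMAN") {
  rs <- read_region_set(system.file("extdata", "prps1_human_regions.tsv",
                                    package = "splicetrace"))
  rs$reference_id <- reference_id
  rs
}

#' Project reference regions onto alignment columns
#'
#' @param msa An `msa` tibble containing the region set's reference sequence.
#' @param rs A `region_set`.
#' @return Tibble: `name`, `start_col`, `end_col` (columns of the first and
#'   last reference residue of each region).
#' @export
project_regions <- function(msa, rs) {
  map <- residue_to_column(msa, rs$reference_id)
  if (nrow(rs$regions) && any(rs$regions$end > length(map))) {
    abort("region exceeds reference length", class = "splicetrace_bounds_error")
  }
  tibble(name = rs$regions$name,
         start_col = map[rs$regions$start],
         end_col = map[rs$regions$end])
}

msa_chars <- function(msa, id) strsplit(msa_row(msa, id), "")[[1]]

#' Detect long insertions (non-homologous regions) within reference regions
#'
#' For each non-reference sequence and region, counts residues the sequence
#' holds in columns where the reference is gapped, merging insertion runs
#' separated by at most `gap_merge` columns, and reports merged runs of at
#' least `min_insertion` residues — the signature of lineage-specific
#' loop insertions such as the catalytic-flexible-loop NHRs of PRPSAP-type
#' proteins or the regulatory-loop insertions of Prs5-type proteins.
#'
#' @inheritParams project_regions
#' @param min_insertion Minimum inserted residues to report (default 10).
#' @param gap_merge Merge runs separated by up to this many columns (default 2).
#' @param flank_len Columns aligned (no gap in either row) required on both
#'   sides for `flank_anchored` (default 5).
#' @param targets Sequence ids to scan (default: everything but the reference).
#' @return Tibble: `sequence_id`, `region_name`, `length`, `col_start`,
#'   `col_end`, `flank_anchored`.
#' @export
detect_insertions <- function(msa, rs, min_insertion = 10L, gap_merge = 2L,
                              flank_len = 5L, targets = NULL) {
  stopifnot(min_insertion >= 1L)
  targets <- targets %||% setdiff(msa$id, rs$reference_id)
  spans <- project_regions(msa, rs)
  ref <- msa_chars(msa, rs$reference_id)
  purrr::map_dfr(targets, function(tid) {
    tgt <- msa_chars(msa, tid)
    purrr::map_dfr(seq_len(nrow(spans)), function(ri) {
      cols <- seq(spans$start_col[ri], spans$end_col[ri])
      ins <- cols[ref[cols] == "-" & tgt[cols] != "-"]
      if (!length(ins)) return(tibble())
      runs <- split(ins, cumsum(c(1L, diff(ins) > gap_merge + 1L)))
      merged <- purrr::map_dfr(runs, function(r) {
        tibble(col_start = min(r), col_end = max(r), length = length(r))
      })
      merged <- merged[merged$length >= min_insertion, , drop = FALSE]
      if (!nrow(merged)) return(tibble())
      merged |>
        mutate(sequence_id = tid, region_name = spans$name[ri],
               flank_anchored = purrr::map2_lgl(.data$col_start, .data$col_end,
                 function(a, b) {
                   left <- which(ref != "-" & tgt != "-" & seq_along(ref) < a)
                   right <- which(ref != "-" & tgt != "-" & seq_along(ref) > b)
                   length(left) >= flank_len && length(right) >= flank_len
                 })) |>
        select("sequence_id", "region_name", "length", "col_start",
               "col_end", "flank_anchored")
    })
  })
}

#' Residue correspondence between a reference residue set and targets
#'
#' For each (position, expected residue) of a named residue set, reports the
#' residue (and its own 1-based position) each target holds in the same
#' alignment column — e.g. mapping a catalytic aspartate of one paralog to
#' the serine a degenerate paralog carries at the corresponding position.
#'
#' @inheritParams project_regions
#' @param set_name Name of the residue set.
#' @param targets Target sequence ids (default: everything but the reference).
#' @param strict Error (rather than warn) if the reference residue at a
#'   position differs from the expected residue.
#' @return Tibble: `ref_position`, `ref_residue`, `target_id`,
#'   `target_position` (`NA` at a gap), `target_residue` (`-` at a gap),
#'   `conserved` (identical), `similar` (positive BLOSUM62 score).
#' @export
residue_correspondence <- function(msa, rs, set_name, targets = NULL,
                                   strict = FALSE) {
  set <- rs$residue_sets |> filter(.data$set_name == !!set_name)
  if (!nrow(set)) abort(paste0("unknown residue set: ", set_name))
  targets <- targets %||% setdiff(msa$id, rs$reference_id)
  map <- residue_to_column(msa, rs$reference_id)
  if (any(set$position > length(map))) {
    abort("residue-set position exceeds reference length",
          class = "splicetrace_bounds_error")
  }
  ref <- msa_chars(msa, rs$reference_id)
  m <- blosum62()
  purrr::map_dfr(targets, function(tid) {
    tgt <- msa_chars(msa, tid)
    tgt_cum <- cumsum(tgt != "-")
    purrr::map_dfr(seq_len(nrow(set)), function(i) {
      col <- map[set$position[i]]
      rres <- ref[col]
      if (!is.na(set$expected[i]) && rres != set$expected[i]) {
        msg <- paste0("reference residue at position ", set$position[i], " is ",
                      rres, ", expected ", set$expected[i])
        if (strict) abort(msg, class = "splicetrace_reference_mismatch") else warn(msg)
      }
      tres <- tgt[col]
      gap <- tres == "-"
      tibble(ref_position = set$position[i], ref_residue = rres,
             target_id = tid,
             target_position = if (gap) NA_integer_ else tgt_cum[col],
             target_residue = tres,
             conserved = !gap && tres == rres,
             similar = !gap && tres %in% rownames(m) && rres %in% rownames(m) &&
               m[rres, tres] > 0)
    })
  })
}

#' Conservation of each target within reference regions
#'
#' Identity vs the reference over region columns where the reference is not
#' gapped; a gap in the target counts as a mismatch.
#'
#' @inheritParams detect_insertions
#' @return Tibble: `region_name`, `target_id`, `identity`, plus the
#'   per-region mean over targets as attribute-free rows via
#'   `dplyr::summarise` by the caller if desired.
#' @export
region_conservation <- function(msa, rs, targets = NULL) {
  targets <- targets %||% setdiff(msa$id, rs$reference_id)
  spans <- project_regions(msa, rs)
  ref <- msa_chars(msa, rs$reference_id)
  purrr::map_dfr(seq_len(nrow(spans)), function(ri) {
    cols <- seq(spans$start_col[ri], spans$end_col[ri])
    cols <- cols[ref[cols] != "-"]
    purrr::map_dfr(targets, function(tid) {
      tgt <- msa_chars(msa, tid)
      tibble(region_name = spans$name[ri], target_id = tid,
             identity = mean(tgt[cols] == ref[cols]))
    })
  })
}

#' Fraction of a residue set conserved in each target
#'
#' Convenience summary of [residue_correspondence()]: the fraction of set
#' positions whose target residue is identical to the reference residue.
#'
#' @inheritParams residue_correspondence
#' @return Tibble: `set_name`, `target_id`, `conservation`.
#' @export
set_conservation <- function(msa, rs, set_name, targets = NULL) {
  ct <- residue_correspondence(msa, rs, set_name, targets)
  ct |> group_by(target_id = .data$target_id) |>
    summarise(conservation = mean(.data$conserved), .groups = "drop") |>
    mutate(set_name = !!set_name, .before = 1)
}

#' Concentration of pairwise differences in a sequence window
#'
#' Globally aligns two proteins (free end gaps), counts difference events —
#' mismatch columns plus each maximal indel run counted once — and reports
#' how many fall inside a window of the first sequence's coordinates. Masked
#' intervals (e.g. NHR loops, whose flexible residues would otherwise swamp
#' the count) are excluded. Indel runs are anchored to the nearest preceding
#' residue of `a` (runs before the first residue anchor to position 1).
#'
#' @param a,b Amino-acid strings; the window and mask are in `a` coordinates.
#' @param window Length-2 integer vector, 1-based inclusive on `a`
#'   (default `c(1, 95)`, the N-terminal window).
#' @param mask Optional tibble/data frame of intervals to exclude
#'   (`start`, `end`, 1-based inclusive on `a`).
#' @param matrix,gap_open,gap_extend Passed to [align_global()].
#' @return One-row tibble: `total_differences`, `in_window`, `fraction`,
#'   `n_masked`, `window_start`, `window_end`.
#' @export
difference_concentration <- function(a, b, window = c(1L, 95L), mask = NULL,
                                     matrix = blosum62(), gap_open = 11,
                                     gap_extend = 1) {
  stopifnot(length(window) == 2, window[1] >= 1, window[2] <= nchar(a),
            window[1] <= window[2])
  al <- align_global(a, b, matrix, gap_open, gap_extend)
  p <- al$pairs
  is_gap <- is.na(p$query_pos) | is.na(p$ref_pos)
  # anchor every column to an a-coordinate (nearest preceding residue of a)
  anchor <- cummax(ifelse(is.na(p$query_pos), 0L, p$query_pos))
  anchor[anchor == 0L] <- 1L
  # events: mismatches + one per maximal indel run
  mm <- which(!is_gap & !p$match)
  runs <- rle(is_gap)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  gap_runs <- run_start[runs$values]
  events <- tibble(pos = c(anchor[mm], anchor[gap_runs]),
                   kind = rep(c("mismatch", "indel"),
                              c(length(mm), length(gap_runs))))
  masked <- 0L
  if (!is.null(mask) && nrow(mask)) {
    in_mask <- purrr::map_lgl(events$pos, function(x) {
      any(x >= mask$start & x <= mask$end)
    })
    masked <- sum(in_mask)
    events <- events[!in_mask, , drop = FALSE]
  }
  total <- nrow(events)
  if (total == 0L) {
    abort("sequences have no differences; the window fraction is undefined",
          class = "splicetrace_undefined_fraction_error")
  }
  in_win <- sum(events$pos >= window[1] & events$pos <= window[2])
  tibble(total_differences = total, in_window = in_win,
         fraction = in_win / total, n_masked = masked,
         window_start = window[1], window_end = window[2])
}

#' Detect upstream in-frame alternative translation starts (leader peptides)
#'
#' Scans upstream of a transcript's canonical ATG for in-frame ATGs with no
#' intervening in-frame stop — the pattern behind N-terminal leader
#' extensions selected by alternative TSS usage. Only AUG starts are
#' considered.
#'
#' @param transcripts Tibble with `id`, `residues` and `canonical_start`
#'   (0-based ATG offset), or a single DNA string (then supply
#'   `canonical_start`).
#' @param canonical_start 0-based offset of the canonical ATG (used when
#'   `transcripts` is a bare string).
#' @return Tibble, furthest-upstream starts first: `transcript_id`,
#'   `canonical_start`, `alt_start`, `leader_aa`, `leader_sequence`.
#' @export
detect_leader <- function(transcripts, canonical_start = NULL) {
  if (is.character(transcripts)) {
    transcripts <- tibble(id = names(transcripts) %||% "tx",
                          residues = unname(transcripts),
                          canonical_start = canonical_start)
  }
  stopifnot(all(c("id", "residues", "canonical_start") %in% names(transcripts)))
  purrr::map_dfr(seq_len(nrow(transcripts)), function(k) {
    s <- check_dna(transcripts$residues[k], "transcript")
    cs <- transcripts$canonical_start[k]
    if (substr(s, cs + 1L, cs + 3L) != "ATG") {
      abort(paste0("canonical_start of ", transcripts$id[k],
                   " does not point at ATG"),
            class = "splicetrace_annotation_error")
    }
    alt <- integer(0)
    pos <- cs - 3L
    while (pos >= 0L) {
      codon <- substr(s, pos + 1L, pos + 3L)
      if (codon %in% STOP_CODONS) break
      if (codon == "ATG") alt <- c(alt, pos)
      pos <- pos - 3L
    }
    if (!length(alt)) return(tibble())
    alt <- sort(alt)  # furthest upstream first
    tibble(transcript_id = transcripts$id[k], canonical_start = cs,
           alt_start = alt,
           leader_aa = (cs - alt) %/% 3L,
           leader_sequence = vapply(alt, function(a) {
             translate_cds(substr(s, a + 1L, cs), strip_stop = FALSE)
           }, character(1)))
  })
}
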