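STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in transcripts
#'
#' Scans all six frames for ATG-initiated ORFs ending at a stop codon or at
#' the transcript end (flagged `partial3`). Within one stop-bounded segment of
#' a frame only the 5'-most ATG is reported unless `all_starts = TRUE`.
#' Frames `-1/-2/-3` are scanned on the reverse complement and their `start` /
#' `end` offsets refer to the reverse-complemented transcript.
#'
#' @param transcripts Tibble with `id` and `residues` (DNA), or a character
#'   vector of sequences (optionally named).
#' @param min_aa Minimum protein length (stop excluded) to report.
#' @param all_starts Report nested downstream ATGs too.
#' @return Tibble: `id`, `frame` (+1..+3, -1..-3), `start` (0-based ATG
#'   offset), `end` (0-based exclusive, past the stop), `protein`, `partial3`;
#'   longest proteins first.
#' @export
find_orfs <- function(transcripts, min_aa = 150L, all_starts = FALSE) {
  stopifnot(min_aa >= 1L)
  tx <- normalize_seq_tbl(transcripts)
  purrr::map_dfr(seq_len(nrow(tx)), function(k) {
    s <- check_dna(tx$residues[k], "transcript")
    out <- bind_rows(orfs_one_strand(s, 1L, all_starts),
                     orfs_one_strand(revcomp(s), -1L, all_starts))
    if (!nrow(out)) return(tibble())
    out$id <- tx$id[k]
    out[nchar(out$protein) >= min_aa,
        c("id", "frame", "start", "end", "protein", "partial3")]
  }) |>
    (\(d) if (nrow(d)) arrange(d, dplyr::desc(nchar(.data$protein)),
                               .data$frame, .data$start) else d)()
}

orfs_one_strand <- function(s, sign, all_starts) {
  n <- nchar(s)
  purrr::map_dfr(0:2, function(off) {
    if (n < off + 3L) return(tibble())
    starts <- seq(off + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    seg <- cumsum(dplyr::lag(is_stop, default = FALSE))
    purrr::map_dfr(split(seq_along(codons), seg), function(idx) {
      atgs <- idx[is_atg[idx]]
      if (!length(atgs)) return(tibble())
      if (!all_starts) atgs <- atgs[1]
      # a segment contains at most one stop, as its last codon
      term <- if (is_stop[max(idx)]) max(idx) else NA_integer_
      purrr::map_dfr(atgs, function(a) {
        last <- if (!is.na(term)) term else length(codons)
        prot <- translate_cds(paste(codons[a:last], collapse = ""), strip_stop = TRUE)
        tibble(frame = sign * (off + 1L),
               start = starts[a] - 1L,
               end = starts[last] + 2L,
               protein = prot,
               partial3 = is.na(term))
      })
    })
  })
}

normalize_seq_tbl <- function(x) {
  if (is.character(x)) {
    tibble(id = names(x) %||% paste0("seq", seq_along(x)), residues = unname(x))
  } else {
    stopifnot(all(c("id", "residues") %in% names(x)))
    as_tibble(x[, c("id", "residues")])
  }
}

#' Annotate transcripts by ORF extraction and homology to a reference panel
#'
#' Mirrors homology-based curation of candidate family members: every ORF of
#' each transcript is aligned locally against every panel protein; the
#' best-scoring ORF/panel pair is reported with an `accepted` call made from
#' score, identity and reference-coverage thresholds. No E-values are
#' computed (there is no database context here); score + identity + coverage
#' stand in for "significant match".
#'
#' @inheritParams find_orfs
#' @param panel Reference proteins: tibble with `id`, `residues` or a named
#'   character vector.
#' @param score_min,identity_min,coverage_min Acceptance thresholds
#'   (defaults 50, 0.30, 0.60); coverage is the aligned fraction of the
#'   reference.
#' @param matrix,gap_open,gap_extend Passed to [align_local()].
#' @return Tibble with one row per transcript that produced an ORF with a
#'   positive alignment score: `transcript_id`, `frame`, `orf_start`,
#'   `orf_end`, `protein`, `best_reference`, `score`, `identity`,
#'   `ref_coverage`, `accepted`. Transcripts with no such ORF yield no row.
#' @export
annotate_transcripts <- function(transcripts, panel, min_aa = 150L,
                                 score_min = 50, identity_min = 0.30,
                                 coverage_min = 0.60, matrix = blosum62(),
                                 gap_open = 11, gap_extend = 1) {
  tx <- normalize_seq_tbl(transcripts)
  pn <- normalize_seq_tbl(panel)
  if (!nrow(pn)) abort("reference panel is empty")
  purrr::map_dfr(seq_len(nrow(tx)), function(k) {
    orfs <- find_orfs(tx[k, ], min_aa = min_aa)
    if (!nrow(orfs)) return(tibble())
    best <- NULL
    for (i in seq_len(nrow(orfs))) {
      for (j in seq_len(nrow(pn))) {
        al <- align_local(orfs$protein[i], pn$residues[j], matrix, gap_open, gap_extend)
        if (al$score > 0 && (is.null(best) || al$score > best$al$score)) {
          best <- list(al = al, orf = orfs[i, ], ref = pn[j, ])
        }
      }
    }
    if (is.null(best)) return(tibble())
    cov <- (best$al$ref_span[2] - best$al$ref_span[1] + 1) / nchar(best$ref$residues)
    tibble(transcript_id = tx$id[k],
           frame = best$orf$frame, orf_start = best$orf$start,
           orf_end = best$orf$end, protein = best$orf$protein,
           best_reference = best$ref$id,
           score = best$al$score, identity = best$al$identity,
           ref_coverage = cov,
           accepted = best$al$score >= score_min &&
             best$al$identity >= identity_min && cov >= coverage_min)
  })
}
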