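#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a tibble, the
#' tabular currency of this package. The header is split at the first
#' whitespace into `id` and `description`.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A tibble with columns `id`, `residues`, `description`. DNA input is
#'   uppercased; the caller decides the alphabet.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence ids in ", path, ": ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  tibble(id = id, residues = toupper(as.character(ss)), description = desc)
}

#' Write a sequence tibble to FASTA
#'
#' @param x Tibble with columns `id`, `residues` and optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(all(c("id", "residues") %in% names(x)))
  hdr <- if ("description" %in% names(x) && any(nzchar(x$description))) {
    ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  } else x$id
  lines <- purrr::map2(hdr, x$residues, function(h, s) {
    c(paste0(">", h),
      substring(s, seq(1L, nchar(s), by = width),
                pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

# DNA helpers on plain strings ------------------------------------------------

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) abort(paste0(what, " contains characters outside {A,C,G,T,N}"))
  x
}

#' Translate a coding sequence
#'
#' Standard nuclear code; codons containing `N` that cannot be resolved
#' translate to `X`. The string must be a whole number of codons.
#'
#' @param cds Coding DNA string (no introns), 5' to 3'.
#' @param strip_stop Drop a single terminal stop, if present.
#' @return Amino-acid string; internal stops are retained (callers decide how
#'   to treat them).
#' @export
translate_cds <- function(cds, strip_stop = TRUE) {
  cds <- check_dna(cds, "CDS")
  if (nchar(cds) %% 3L != 0L) {
    abort("frame error: CDS length is not a multiple of 3",
          class = "splicetrace_frame_error")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "solve",
                                           no.init.codon = TRUE))
  if (strip_stop) aa <- sub("\\*$", "", aa)
  aa
}
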