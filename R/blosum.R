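the_blosum <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix (from Biostrings), with the ambiguity code `X`
#' rescored to 0 against every residue so that `N`-derived positions neither
#' reward nor penalise an alignment.
#'
#' @return Integer matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  if (is.null(the_blosum$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    the_blosum$m <- m
  }
  the_blosum$m
}

# BLOSUM62-positive partners (excluding self) per residue, for the simulator's
# similarity-biased substitutions and for "similar" calls.
blosum_positive_partners <- function(aa) {
  m <- blosum62()
  std <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  p <- std[m[aa, std] > 0 & std != aa]
  p
}
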