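# Independent oracles, kept structurally separate from the package code.

# Plain-matrix affine-gap DP for the optimal local alignment score.
# Same gap convention as the package (length-k gap costs open + k*extend).
oracle_local_score <- function(q, r, sub = blosum62(), gap_open = 11, gap_extend = 1) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  opn <- gap_open + gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[qs[i], rs[j]]
      M[i + 1, j + 1] <- s + max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - opn, X[i, j + 1] - gap_extend,
                             Y[i, j + 1] - opn)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - opn, Y[i + 1, j] - gap_extend,
                             X[i + 1, j] - opn)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Free-end-gap global score: best substitution-ending cell on last row/column.
oracle_overlap_score <- function(q, r, sub = blosum62(), gap_open = 11, gap_extend = 1) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  opn <- gap_open + gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      start <- if (i == 1 || j == 1) 0 else -Inf
      M[i + 1, j + 1] <- sub[qs[i], rs[j]] + max(start, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - opn, X[i, j + 1] - gap_extend,
                             Y[i, j + 1] - opn)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - opn, Y[i + 1, j] - gap_extend,
                             X[i + 1, j] - opn)
    }
  }
  max(M[n + 1, 2:(m + 1)], M[2:(n + 1), m + 1])
}

# Recompute an alignment's score from its column pairs.
rescore_pairs <- function(al, sub = blosum62(), gap_open = 11, gap_extend = 1) {
  p <- al$pairs
  gap <- is.na(p$query_pos) | is.na(p$ref_pos)
  if (al$mode == "overlap") {
    core <- which(!gap)
    if (!length(core)) return(0)
    p <- p[seq(min(core), max(core)), ]
    gap <- is.na(p$query_pos) | is.na(p$ref_pos)
  }
  s <- 0
  for (k in which(!gap)) s <- s + sub[p$query_res[k], p$ref_res[k]]
  runs <- rle(gap)
  n_gap_runs <- sum(runs$values)
  gap_cols <- sum(gap)
  s - n_gap_runs * gap_open - gap_cols * gap_extend
}

# Exhaustive six-frame ORF enumeration (5'-most ATG per stop-bounded segment).
oracle_orfs <- function(s, min_aa = 1L) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  out <- list()
  for (strand in c(1L, -1L)) {
    seqn <- if (strand == 1L) s else rc
    n <- nchar(seqn)
    for (off in 0:2) {
      if (n < off + 3) next
      starts <- seq(off + 1L, n - 2L, by = 3L)
      codons <- substring(seqn, starts, starts + 2L)
      stops <- codons %in% c("TAA", "TAG", "TGA")
      for (a in seq_along(codons)) {
        if (codons[a] != "ATG") next
        prev_stop <- if (any(stops[seq_len(a - 1)])) max(which(stops[seq_len(a - 1)])) else 0L
        seg_before <- setdiff(seq_len(a - 1), seq_len(prev_stop))
        if (any(codons[seg_before] == "ATG")) next  # not 5'-most in its segment
        nxt <- which(stops & seq_along(codons) > a)
        last <- if (length(nxt)) nxt[1] else length(codons)
        aa <- paste(vapply(codons[a:last], function(cd) {
          c(Biostrings::GENETIC_CODE[cd])
        }, character(1)), collapse = "")
        aa <- sub("\\*$", "", aa)
        if (nchar(aa) < min_aa) next
        out[[length(out) + 1L]] <- tibble::tibble(
          frame = strand * (off + 1L), start = starts[a] - 1L,
          end = starts[last] + 2L, protein = aa,
          partial3 = !length(nxt))
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(frame = integer(), start = integer(), end = integer(),
                   protein = character(), partial3 = logical())
}

# Transcript-nucleotide-to-codon map oracle for intron positions.
oracle_intron_positions <- function(exon_lengths) {
  cum <- cumsum(exon_lengths)
  cum <- cum[-length(cum)]
  tibble::tibble(
    intron_rank = seq_along(cum),
    codon_index = ifelse(cum %% 3L == 0L, cum %/% 3L + 1L,
                         (cum + 2L) %/% 3L),  # codon containing nt `cum`
    phase = as.integer(cum %% 3L))
}

# Exhaustive-pairing oracle for shared-junction grouping: scan junctions in
# (column, phase, id, rank) order; each unassigned junction seeds a group and
# absorbs every later unassigned junction within tolerance (one per id).
oracle_shared_junctions <- function(jm, tol = 0L, same_phase = TRUE,
                                    eligible = unique(jm$id)) {
  j <- jm[order(jm$column, jm$phase, jm$id, jm$intron_rank), ]
  taken <- rep(FALSE, nrow(j))
  res <- list()
  for (k in seq_len(nrow(j))) {
    if (taken[k]) next
    taken[k] <- TRUE
    ids <- j$id[k]; cols <- j$column[k]; phs <- j$phase[k]
    for (l in seq_len(nrow(j))) {
      if (taken[l] || j$id[l] %in% ids) next
      if (abs(j$column[l] - j$column[k]) > tol) next
      if (same_phase && j$phase[l] != j$phase[k]) next
      taken[l] <- TRUE
      ids <- c(ids, j$id[l]); cols <- c(cols, j$column[l]); phs <- c(phs, j$phase[l])
    }
    if (length(ids) >= 2) {
      res[[length(res) + 1L]] <- tibble::tibble(
        column = min(cols),
        phase = if (length(unique(phs)) == 1) phs[1] else NA_integer_,
        n_supporters = length(ids),
        support = length(ids) / length(eligible),
        supporters = list(sort(ids)))
    }
  }
  if (length(res)) {
    d <- dplyr::bind_rows(res)
    d[order(d$column), ]
  } else {
    tibble::tibble(column = integer(), phase = integer(),
                   n_supporters = integer(), support = double(),
                   supporters = list())
  }
}

random_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
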