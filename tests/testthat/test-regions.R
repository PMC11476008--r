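ref10 <- "MKLVEDRSTW"

test_that("region projection follows the reference's gap structure", {
  rs <- make_region_set("ref", regions = tibble::tibble(
    name = "loopA", start = 3L, end = 6L))
  m <- make_msa(ref = ref10, tgt = "MKLVEDRSTW")
  pr <- project_regions(m, rs)
  expect_equal(pr$start_col, 3L)
  expect_equal(pr$end_col, 6L)

  # gaps inside the reference widen the column span
  m2 <- make_msa(ref = "MKL--VEDRSTW", tgt = "MKLAAVEDRSTW")
  pr2 <- project_regions(m2, rs)
  expect_equal(pr2$start_col, 3L)
  expect_equal(pr2$end_col, 8L)

  rs_bad <- make_region_set("ref", regions = tibble::tibble(
    name = "x", start = 1L, end = 99L))
  expect_error(project_regions(m, rs_bad), class = "splicetrace_bounds_error")

  rs_empty <- make_region_set("ref")
  expect_equal(nrow(project_regions(m, rs_empty)), 0L)
})

test_that("insertion detection recovers length, region and flank anchoring", {
  rs <- make_region_set("ref", regions = tibble::tibble(
    name = "cf_loop", start = 11L, end = 20L))
  base <- paste(rep("MKLVEDRSTW", 3), collapse = "")  # 30 residues
  # identical target: nothing to report
  m0 <- make_msa(ref = base, tgt = base)
  expect_equal(nrow(detect_insertions(m0, rs, min_insertion = 1)), 0L)

  # 12-residue insertion inside the loop window
  ins <- paste(rep("A", 12), collapse = "")
  ref_row <- paste0(substr(base, 1, 15), strrep("-", 12), substr(base, 16, 30))
  tgt_row <- paste0(substr(base, 1, 15), ins, substr(base, 16, 30))
  m1 <- make_msa(ref = ref_row, tgt = tgt_row)
  call <- detect_insertions(m1, rs, min_insertion = 10)
  expect_equal(nrow(call), 1L)
  expect_equal(call$region_name, "cf_loop")
  expect_equal(call$length, 12L)
  expect_true(call$flank_anchored)

  # below min_insertion: silent
  expect_equal(nrow(detect_insertions(m1, rs, min_insertion = 13)), 0L)

  # runs separated by more than gap_merge stay separate and can each fail the cutoff
  ref_row2 <- paste0(substr(base, 1, 13), "----", substr(base, 14, 16),
                     "----", substr(base, 17, 30))
  tgt_row2 <- paste0(substr(base, 1, 13), "AAAA", substr(base, 14, 16),
                     "AAAA", substr(base, 17, 30))
  m2 <- make_msa(ref = ref_row2, tgt = tgt_row2)
  expect_equal(nrow(detect_insertions(m2, rs, min_insertion = 8, gap_merge = 2)), 0L)
  merged <- detect_insertions(m2, rs, min_insertion = 8, gap_merge = 3)
  expect_equal(merged$length, 8L)
})

test_that("residue correspondence reports target positions, gaps and similarity", {
  sets <- tibble::tibble(set_name = "catalytic", position = c(2L, 5L),
                         expected = c("K", "E"))
  rs <- make_region_set("ref", sets = sets)
  m <- make_msa(ref = ref10, tgt = ref10)
  ct <- residue_correspondence(m, rs, "catalytic")
  expect_true(all(ct$conserved))
  expect_equal(ct$target_position, c(2L, 5L))

  # a 6-residue N-terminal extension in the target offsets its numbering,
  # mirroring how an aspartate of one paralog maps to residue (pos+6) of another
  m2 <- make_msa(ref = paste0("------", ref10),
                 tgt = paste0("AAAAAA", "MSLVEDRSTW"))
  ct2 <- residue_correspondence(m2, rs, "catalytic")
  expect_equal(ct2$target_position, c(8L, 11L))
  expect_equal(ct2$target_residue, c("S", "E"))
  expect_equal(ct2$conserved, c(FALSE, TRUE))

  # gap in the target at a set column
  m3 <- make_msa(ref = ref10, tgt = "M-LVEDRSTW")
  ct3 <- residue_correspondence(m3, rs, "catalytic")
  expect_true(is.na(ct3$target_position[1]))
  expect_equal(ct3$target_residue[1], "-")
  expect_false(ct3$conserved[1])

  # reference residue differing from the expected annotation warns (or errors)
  sets_bad <- tibble::tibble(set_name = "catalytic", position = 2L, expected = "W")
  rs_bad <- make_region_set("ref", sets = sets_bad)
  expect_warning(residue_correspondence(m, rs_bad, "catalytic"), "expected")
  expect_error(suppressWarnings(
    residue_correspondence(m, rs_bad, "catalytic", strict = TRUE)),
    class = "splicetrace_reference_mismatch")
})

test_that("region conservation counts identity over reference columns", {
  rs <- make_region_set("ref", regions = tibble::tibble(
    name = "r", start = 1L, end = 10L))
  m <- make_msa(ref = ref10, tgt = ref10)
  expect_equal(region_conservation(m, rs)$identity, 1.0)

  m2 <- make_msa(ref = ref10, tgt = "----------")
  expect_equal(region_conservation(m2, rs)$identity, 0.0)

  # 3 substitutions in 10 residues
  m3 <- make_msa(ref = ref10, tgt = "MALVADRSTA")
  expect_equal(region_conservation(m3, rs)$identity, 0.7)
})

test_that("difference concentration counts events, windows, masks and indel runs", {
  a <- paste(rep("MKLVEDRSTW", 10), collapse = "")  # 100 residues
  chars <- strsplit(a, "")[[1]]
  # 4 substitutions: 3 inside [1,95], 1 outside
  b_chars <- chars
  b_chars[c(10, 20, 30, 99)] <- c("A", "A", "A", "A")
  b <- paste(b_chars, collapse = "")
  dc <- difference_concentration(a, b, window = c(1, 95))
  expect_equal(dc$total_differences, 4L)
  expect_equal(dc$in_window, 3L)
  expect_equal(dc$fraction, 0.75)

  # identical sequences: the fraction is undefined
  expect_error(difference_concentration(a, a),
               class = "splicetrace_undefined_fraction_error")

  # a 9-residue deletion counts as one event
  b2 <- paste0(substr(a, 1, 50), substr(a, 60, 100))
  dc2 <- difference_concentration(a, b2, window = c(1, 95))
  expect_equal(dc2$total_differences, 1L)
  expect_equal(dc2$in_window, 1L)

  # masking removes events inside the masked interval
  dc3 <- difference_concentration(a, b, window = c(1, 95),
                                  mask = tibble::tibble(start = 25L, end = 35L))
  expect_equal(dc3$total_differences, 3L)
  expect_equal(dc3$n_masked, 1L)

  # totals agree in both orientations
  dc_ab <- difference_concentration(a, b, window = c(1, 95))
  dc_ba <- difference_concentration(b, a, window = c(1, 95))
  expect_equal(dc_ab$total_differences, dc_ba$total_differences)
})

test_that("upstream in-frame starts are detected with clean leaders only", {
  # no upstream ATG
  tx0 <- paste0(strrep("C", 12), "ATGGCTGCTTAA")
  expect_equal(nrow(detect_leader(c(t0 = tx0), canonical_start = 12L)), 0L)

  # 29-codon clean leader (87 nt), murine-AP1-style synthetic construction
  leader <- paste0("ATG", strrep("GCT", 28))
  tx1 <- paste0("CCCCCCTAA", leader, "ATGGCTGCTTAA")
  res <- detect_leader(c(t1 = tx1), canonical_start = 9L + 87L)
  expect_equal(nrow(res), 1L)
  expect_equal(res$leader_aa, 29L)
  expect_equal(res$alt_start, 9L)
  expect_equal(nchar(res$leader_sequence), 29L)
  expect_equal(substr(res$leader_sequence, 1, 1), "M")

  # an in-frame stop between upstream ATG and canonical start excludes it
  tx2 <- paste0("ATGGCT", "TAA", "ATGGCTGCTTAA")
  expect_equal(nrow(detect_leader(c(t2 = tx2), canonical_start = 9L)), 0L)

  # canonical_start must point at ATG
  expect_error(detect_leader(c(t3 = "CCCATGTAA"), canonical_start = 0L),
               class = "splicetrace_annotation_error")

  # invariance: 5' extension behind a stop-containing prefix changes nothing
  tx3 <- paste0(strrep("GCC", 4), "TAG", tx1)
  res3 <- detect_leader(c(t4 = tx3), canonical_start = 15L + 9L + 87L)
  expect_equal(res3$leader_aa, res$leader_aa)
})

test_that("insertion and difference calls are gap-column invariant", {
  rs <- make_region_set("ref", regions = tibble::tibble(
    name = "cf_loop", start = 11L, end = 20L))
  base <- paste(rep("MKLVEDRSTW", 3), collapse = "")
  ins <- strrep("A", 12)
  ref_row <- paste0(substr(base, 1, 15), strrep("-", 12), substr(base, 16, 30))
  tgt_row <- paste0(substr(base, 1, 15), ins, substr(base, 16, 30))
  m1 <- make_msa(ref = ref_row, tgt = tgt_row)
  call1 <- detect_insertions(m1, rs, min_insertion = 10)
  # all-gap column after column 5
  gapify <- function(s) paste0(substr(s, 1, 5), "-", substr(s, 6, nchar(s)))
  m2 <- make_msa(ref = gapify(ref_row), tgt = gapify(tgt_row))
  call2 <- detect_insertions(m2, rs, min_insertion = 10)
  expect_equal(call2$length, call1$length)
  expect_equal(call2$region_name, call1$region_name)
  expect_equal(call2$col_start, call1$col_start + 1L)
})
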