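mk_features <- function(...) {
  defaults <- list(id = "x", cf_loop_insertion_len = 0L,
                   reg_loop_insertion_len = 0L, catalytic_conservation = 1,
                   bent_interface_conservation = 1,
                   parallel_interface_conservation = 1,
                   allosteric_conservation = 1, intronless = FALSE)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

test_that("the rule cascade assigns every archetype its class", {
  expect_equal(classify_homologs(mk_features())$class, "CLASS_I_PRPS")
  expect_equal(classify_homologs(mk_features(intronless = TRUE))$class,
               "CLASS_I_RETROCOPY")
  expect_equal(classify_homologs(mk_features(cf_loop_insertion_len = 25L,
                                             catalytic_conservation = 0.2))$class,
               "PRPSAP_LIKE")
  expect_equal(classify_homologs(mk_features(reg_loop_insertion_len = 25L))$class,
               "PRS5_LIKE")
  # regulatory-loop rule wins even with an additional CF-loop insertion
  expect_equal(classify_homologs(mk_features(reg_loop_insertion_len = 25L,
                                             cf_loop_insertion_len = 15L,
                                             catalytic_conservation = 0.2))$class,
               "PRS5_LIKE")
  expect_equal(classify_homologs(mk_features(bent_interface_conservation = 0.4))$class,
               "CLASS_II_PRPS")
  expect_equal(classify_homologs(mk_features(catalytic_conservation = 0.6))$class,
               "UNCLASSIFIED")
  # unknown interface sets cannot trigger the Class II rule
  expect_equal(classify_homologs(mk_features(bent_interface_conservation = NA,
                                             parallel_interface_conservation = NA))$class,
               "CLASS_I_PRPS")
})

test_that("classification is deterministic and order-invariant", {
  feats <- dplyr::bind_rows(
    mk_features(id = "a"),
    mk_features(id = "b", reg_loop_insertion_len = 12L),
    mk_features(id = "c", cf_loop_insertion_len = 30L, catalytic_conservation = 0.1),
    mk_features(id = "d", intronless = TRUE))
  c1 <- classify_homologs(feats)
  c2 <- classify_homologs(feats[c(3, 1, 4, 2), ])
  expect_equal(c1[order(c1$id), ]$class, c2[order(c2$id), ]$class)
  expect_true(all(nzchar(c1$rationale[c1$class != "UNCLASSIFIED"])))
})

test_that("feature extraction assembles insertions, conservation and intron status", {
  base <- paste(rep("MKLVEDRSTW", 3), collapse = "")
  rs <- make_region_set("ref",
    regions = tibble::tibble(name = c("cf_loop", "regulatory_flexible_loop"),
                             start = c(11L, 21L), end = c(20L, 30L)),
    sets = tibble::tibble(set_name = "catalytic", position = c(12L, 14L),
                          expected = c("K", "V")))
  ins <- strrep("A", 12)
  ref_row <- paste0(substr(base, 1, 15), strrep("-", 12), substr(base, 16, 30))
  tgt_row <- paste0(substr(base, 1, 15), ins, substr(base, 16, 30))
  m <- make_msa(ref = ref_row, tgt = tgt_row)
  introns <- tibble::tibble(id = "ref", intron_rank = 1L, codon_index = 5L,
                            phase = 0L)
  fv <- extract_features(m, rs, introns = introns, model_ids = c("ref", "tgt"))
  tgt <- fv[fv$id == "tgt", ]
  expect_equal(tgt$cf_loop_insertion_len, 12L)
  expect_equal(tgt$reg_loop_insertion_len, 0L)
  expect_equal(tgt$catalytic_conservation, 1)
  expect_true(is.na(tgt$bent_interface_conservation))
  expect_true(tgt$intronless)  # model known, no introns recorded
  refrow <- fv[fv$id == "ref", ]
  expect_equal(refrow$catalytic_conservation, 1)
  expect_equal(refrow$cf_loop_insertion_len, 0L)
  expect_false(refrow$intronless)

  # protein-only input: intron status unknown
  fv2 <- extract_features(m, rs)
  expect_true(all(is.na(fv2$intronless)))

  # id mismatch between introns and alignment is a consistency error
  bad <- tibble::tibble(id = "nope", intron_rank = 1L, codon_index = 2L, phase = 0L)
  expect_error(extract_features(m, rs, introns = bad, model_ids = "nope"),
               class = "splicetrace_consistency_error")
})

test_that("profiles count every classified sequence once per clade/class cell", {
  classified <- tibble::tibble(
    id = c("a1", "a2", "b1"),
    taxon = c("taxA", "taxA2", "taxB"),
    class = c("CLASS_I_PRPS", "CLASS_I_PRPS", "PRS5_LIKE"))
  tm <- tibble::tibble(taxon = c("taxA", "taxA2", "taxB"),
                       clade = c("CladeA", "CladeA", "CladeB"))
  pm <- build_profile(classified, tm)
  expect_s3_class(pm, "profile_matrix")
  expect_equal(sum(pm$count), nrow(classified))
  expect_equal(pm$count[pm$clade == "CladeA" & pm$class == "CLASS_I_PRPS"], 2L)
  expect_true(pm$present[pm$clade == "CladeB" & pm$class == "PRS5_LIKE"])
  expect_false(pm$present[pm$clade == "CladeB" & pm$class == "CLASS_I_PRPS"])

  expect_error(build_profile(classified, tm[1:2, ]),
               class = "splicetrace_mapping_error")

  # a tree orders clade rows
  pm2 <- build_profile(classified, tm, tree = "(taxB:1,(taxA:1,taxA2:1):1);")
  expect_equal(levels(pm2$clade), c("CladeB", "CladeA"))
})

test_that("duplication support behaves at its self-similarity limits", {
  withr::with_seed(61, {
    child <- c(c1 = random_protein(60), c2 = random_protein(60))
    far <- c(o1 = random_protein(60), o2 = random_protein(60))
    # parent set = child set: delta > 0 against a diverged outgroup
    ds <- duplication_support(child, child, far, n_boot = 50, seed = 2)
    expect_gt(ds$delta, 0)
    expect_gt(ds$bootstrap_support, 0.5)
    # outgroup = parent set: delta exactly 0
    ds2 <- duplication_support(child, far, far, n_boot = 0, seed = 2)
    expect_equal(ds2$delta, 0)
    expect_true(is.na(ds2$bootstrap_support))
    # tidiers
    expect_equal(nrow(tidy(ds)), 8L)  # 4 parent + 4 outgroup pairs
    expect_equal(glance(ds)$delta, ds$delta)
  })
})

test_that("duplication support is reproducible for a fixed seed", {
  withr::with_seed(62, {
    child <- c(c1 = random_protein(40))
    par <- c(p1 = random_protein(40), p2 = random_protein(40))
    out <- c(o1 = random_protein(40))
    a <- duplication_support(child, par, out, n_boot = 100, seed = 7)
    b <- duplication_support(child, par, out, n_boot = 100, seed = 7)
    expect_identical(a$bootstrap_deltas, b$bootstrap_deltas)
  })
})
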