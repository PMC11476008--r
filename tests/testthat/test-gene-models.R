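test_that("exon-table parsing builds validated models and flags errors", {
  tsv <- tempfile(fileext = ".tsv")
  genome <- c(chr1 = paste0("CCCCC", "ATGGCTTAA", "CCCCC"))
  writeLines(c("gene_id\ttaxon\tgenome_id\tstrand\texon_start\texon_end\trank",
               "g1\ttaxA\tchr1\t+\t5\t14\t1"), tsv)
  m <- read_gene_models(tsv, genome)
  expect_s3_class(m, "gene_models")
  expect_equal(nrow(m), 1L)
  expect_false(m$partial)
  expect_equal(nrow(intron_positions(m)), 0L)

  # two exons, hand-parsed oracle
  fix <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"), gt_ag_intron(11))
  writeLines(c("gene_id\ttaxon\tgenome_id\tstrand\texon_start\texon_end\trank",
               sprintf("g1\ttaxA\tchr1\t+\t%d\t%d\t%d",
                       fix$models$exon_start, fix$models$exon_end,
                       fix$models$rank)), tsv)
  m2 <- read_gene_models(tsv, fix$genomes)
  expect_equal(m2$rank, c(1L, 2L))
  expect_equal(m2$exon_start, fix$models$exon_start)

  # malformed interval names the line
  writeLines(c("gene_id\ttaxon\tgenome_id\tstrand\texon_start\texon_end\trank",
               "g1\ttaxA\tchr1\t+\t9\t5\t1"), tsv)
  expect_error(read_gene_models(tsv, genome), class = "splicetrace_parse_error")

  # unknown genome id
  writeLines(c("gene_id\ttaxon\tgenome_id\tstrand\texon_start\texon_end\trank",
               "g1\ttaxA\tchrX\t+\t5\t14\t1"), tsv)
  expect_error(read_gene_models(tsv, genome),
               class = "splicetrace_reference_error")
})

test_that("GFF3 exon features parse into the same models as the TSV dialect", {
  genome <- c(chr1 = paste0("CCCCC", "ATGGCTGCT", gt_ag_intron(11),
                            "GCTGCTTAA", "CCCCC"))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\texon\t6\t14\t.\t+\t.\tgene_id=g1;rank=1",
               "chr1\ttest\texon\t26\t34\t.\t+\t.\tgene_id=g1;rank=2"), gff)
  m <- read_gene_models(gff, genome)
  expect_equal(m$exon_start, c(5L, 25L))
  expect_equal(m$exon_end, c(14L, 34L))
  expect_equal(spliced_protein(m, genome)$residues, "MAAAA")
  expect_equal(intron_positions(m)$phase, 0L)
})

test_that("minus-strand models listed out of genomic order get transcript ranks", {
  fix <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"), gt_ag_intron(11),
                           strand = "-")
  tsv <- tempfile(fileext = ".tsv")
  # write rows in ascending genomic order (reverse of transcript order), no rank
  m <- fix$models[order(fix$models$exon_start), ]
  writeLines(c("gene_id\ttaxon\tgenome_id\tstrand\texon_start\texon_end",
               sprintf("g1\ttaxA\tchr1\t-\t%d\t%d", m$exon_start, m$exon_end)),
             tsv)
  parsed <- read_gene_models(tsv, fix$genomes)
  expect_equal(parsed$rank, c(1L, 2L))
  # rank 1 exon is the genomically-last one on the minus strand
  expect_true(parsed$exon_start[1] > parsed$exon_start[2])
  expect_equal(spliced_protein(parsed, fix$genomes)$residues, "MAAAA")
})

test_that("splice-site dinucleotides classify as canonical/noncanonical/other", {
  fix <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"),
                           paste0("GTAAG", "CCC", "TTCAG"))
  ss <- classify_splice_sites(fix$models, fix$genomes)
  expect_equal(ss$donor, "GT"); expect_equal(ss$acceptor, "AG")
  expect_equal(ss$klass, "canonical")

  fix2 <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"),
                            paste0("GCAAG", "CCC", "TTCAG"))
  expect_equal(classify_splice_sites(fix2$models, fix2$genomes)$klass,
               "noncanonical")

  fix3 <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"),
                            paste0("ATAAG", "CCC", "TTTAC"))
  expect_equal(classify_splice_sites(fix3$models, fix3$genomes)$klass, "other")

  # N in a dinucleotide warns and yields other
  fixN <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"),
                            paste0("NTAAG", "CCC", "TTCAG"))
  expect_warning(ssN <- classify_splice_sites(fixN$models, fixN$genomes),
                 "N in splice")
  expect_equal(ssN$klass, "other")

  # degenerate intron
  fixD <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"), "GTA")
  expect_error(classify_splice_sites(fixD$models, fixD$genomes),
               class = "splicetrace_degenerate_intron_error")
})

test_that("splice classification is strand-symmetric", {
  withr::with_seed(11, {
    for (k in 1:10) {
      n_ex <- sample(2:4, 1)
      pieces <- vapply(seq_len(n_ex), function(i) random_dna_str(3 * sample(2:6, 1)),
                       character(1))
      pieces[1] <- paste0("ATG", substr(pieces[1], 4, nchar(pieces[1])))
      pieces[n_ex] <- paste0(substr(pieces[n_ex], 1, nchar(pieces[n_ex]) - 3), "TAA")
      introns <- vapply(seq_len(n_ex - 1), function(i) gt_ag_intron(sample(8:20, 1)),
                        character(1))
      fp <- make_gene_fixture(pieces, introns, strand = "+")
      fm <- make_gene_fixture(pieces, introns, strand = "-")
      sp <- tryCatch(classify_splice_sites(fp$models, fp$genomes), error = function(e) NULL)
      if (is.null(sp)) next  # random CDS contained an internal stop; irrelevant here
      sm <- classify_splice_sites(fm$models, fm$genomes)
      expect_equal(sp$klass, sm$klass)
      expect_equal(sp$donor, sm$donor)
    }
  })
})

test_that("spliced translation handles strands, stops and frame errors", {
  fix <- make_gene_fixture("ATGGCTTAA")
  expect_equal(spliced_protein(fix$models, fix$genomes)$residues, "MA")

  # minus-strand model whose coding strand spells ATGTGGTGA -> frozen oracle "MW"
  fixm <- make_gene_fixture("ATGTGGTGA", strand = "-")
  expect_equal(spliced_protein(fixm$models, fixm$genomes)$residues, "MW")

  # internal stop -> pseudogene error (force a non-partial-looking model)
  fixs <- make_gene_fixture("ATGTAAGCTTAA")
  expect_error(spliced_protein(fixs$models, fixs$genomes),
               class = "splicetrace_pseudogene_error")
})

test_that("intron positions follow the cumulative-length/phase convention", {
  fix <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"), gt_ag_intron(11))
  ip <- intron_positions(fix$models)
  expect_equal(ip$codon_index, 4L)
  expect_equal(ip$phase, 0L)

  fix2 <- make_gene_fixture(c("ATGGCTGCTG", "CTGCTTAA"), gt_ag_intron(11))
  ip2 <- intron_positions(fix2$models)
  expect_equal(ip2$codon_index, 4L)
  expect_equal(ip2$phase, 1L)

  expect_equal(nrow(intron_positions(make_gene_fixture("ATGGCTTAA")$models)), 0L)
})

test_that("intron positions agree with the nucleotide-to-codon map oracle", {
  withr::with_seed(21, {
    for (k in 1:20) {
      n_ex <- sample(2:6, 1)
      lens <- sample(4:30, n_ex, replace = TRUE)
      lens[n_ex] <- lens[n_ex] + (3 - sum(lens) %% 3) %% 3  # total multiple of 3
      pieces <- vapply(lens, random_dna_str, character(1))
      pieces[1] <- paste0("ATG", substr(pieces[1], 4, nchar(pieces[1])))
      pieces[n_ex] <- paste0(substr(pieces[n_ex], 1, nchar(pieces[n_ex]) - 3), "TAA")
      introns <- vapply(seq_len(n_ex - 1), function(i) gt_ag_intron(10), character(1))
      fix <- make_gene_fixture(pieces, introns)
      got <- intron_positions(fix$models)
      exp <- oracle_intron_positions(nchar(pieces))
      expect_equal(got$codon_index, exp$codon_index)
      expect_equal(got$phase, exp$phase)
    }
  })
})

test_that("stop-terminated models translate to (exonic length)/3 - 1 residues", {
  fix <- make_gene_fixture(c("ATGGCTGCT", "GCTGCTTAA"), gt_ag_intron(11))
  pr <- spliced_protein(fix$models, fix$genomes)
  total <- sum(fix$models$exon_end - fix$models$exon_start)
  expect_equal(nchar(pr$residues), total / 3 - 1)
})

test_that("incomplete models are flagged partial and refused downstream", {
  fix <- make_gene_fixture("GCTGCTGCT")  # no start, no stop
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttaxon\tgenome_id\tstrand\texon_start\texon_end\trank",
               sprintf("g1\ttaxA\tchr1\t+\t%d\t%d\t1",
                       fix$models$exon_start, fix$models$exon_end)), tsv)
  expect_warning(m <- read_gene_models(tsv, fix$genomes), "partial")
  expect_true(all(m$partial))
  expect_error(intron_positions(m, gene_ids = "g1"),
               class = "splicetrace_precondition_error")
  expect_error(spliced_protein(m, fix$genomes, gene_ids = "g1"),
               class = "splicetrace_precondition_error")
})
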