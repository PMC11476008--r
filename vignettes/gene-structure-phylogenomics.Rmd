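---
title: "Tracing paralog origins from exon-intron gene structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing paralog origins from exon-intron gene structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicetrace)
library(dplyr)
```

## The problem

Eukaryotic genomes often carry several homologs of the same enzyme family.
The PRPS family is a canonical case: alongside the catalytic
phosphoribosyl-pyrophosphate synthetase isozymes (PRPS1/PRPS2 in mammals,
plus the testis-restricted intronless PRPS1L1), most opisthokonts encode
non-catalytic PRPS-associated proteins (PRPSAP1/2, yeast Prs1/Prs5) that are
ancient duplicates of the catalytic gene. Telling these apart, and working
out which duplicated from which, cannot rely on sequence similarity alone:
after a billion years the proteins have diverged heavily, while other
features — the position and phase of introns in the coding sequence, long
lineage-specific insertions confined to particular catalytic-loop windows,
and the erosion of specific active-site residues — remain diagnostic.

`splicetrace` implements that evidence chain as composable, tested pieces:

1. **Gene models** (`read_gene_models()`, `classify_splice_sites()`,
   `spliced_protein()`, `intron_positions()`): strand-aware exon tables or
   GFF3 in, validated coding structures out. An intron's position is encoded
   as the 1-based protein residue hosting the split codon together with the
   phase (0, 1 or 2 coding nucleotides contributed by the upstream exon);
   phase-0 junctions attach to the following residue. This convention is
   symmetric and makes positions comparable across genes.
2. **Junction projection** (`project_junctions()`,
   `call_shared_junctions()`): intron positions are mapped to the alignment
   column of their residue in a protein multiple alignment (the alignment is
   consumed as input, never built here). Junctions from different sequences
   that occupy the same column with the same phase are called *shared* — the
   classic evidence that two paralogs descend from one ancestral gene
   structure.
3. **Region analyses** (`detect_insertions()`, `residue_correspondence()`,
   `region_conservation()`, `difference_concentration()`,
   `detect_leader()`): everything anchored on a reference sequence's residue
   numbering through a `region_set`: named loop windows (FLAG region, PP
   loop, catalytic flexible loop, regulatory flexible loop, R5P loop) and
   residue sets (the catalytic set D171, K194, R196, N200, T225 of human
   PRPS1 ships as the default).
4. **Classification and profiles** (`extract_features()`,
   `classify_homologs()`, `build_profile()`, `duplication_support()`).
5. **Simulation** (`simulation_config()`, `simulate_family()`): gene
   families with a known event history, used as ground truth by every other
   module's tests.

## The classification rules

`classify_homologs()` applies an ordered cascade to per-sequence features:

* regulatory-flexible-loop insertion ≥ `ins_min` → **PRS5-like** (checked
  first because some Prs5-type proteins carry catalytic-loop insertions
  *as well*);
* catalytic-flexible-loop insertion ≥ `ins_min` and catalytic-set
  conservation ≤ `cat_low` → **PRPSAP-like**;
* catalytic conservation ≥ `cat_high` but a poorly conserved dimer
  interface (min of bent/parallel ≤ `iface_low`) → **Class II PRPS**;
* catalytic conservation ≥ `cat_high` → **Class I PRPS**, or **Class I
  retrocopy** when the gene model is intronless;
* otherwise unclassified.

Defaults are `ins_min = 10` residues, `cat_low = 0.4`, `cat_high = 0.8`
(at least 4 of the 5-residue catalytic set), `iface_low = 0.5`. The
literature describes these patterns qualitatively, not as cutoffs; the
values here are this package's own, they are echoed in every report header,
and they are all arguments. Interface and allosteric residue-set membership
is deliberately not hard-coded: it ships empty and must be supplied by the
user, so the Class II rule stays silent (reports `NA`) until real interface
annotations are provided.

## The aligner

Homology scoring is done by an in-package affine-gap aligner
(`align_local()`, Smith-Waterman; `align_global()`, global with free end
gaps) rather than an external search tool, so results are deterministic and
self-contained. Conventions that matter:

* a gap of length $k$ costs $\mathrm{open} + k\cdot\mathrm{extend}$
  (defaults 11 and 1, BLOSUM62);
* `identity` is the fraction of identical columns over the aligned block,
  terminal gap runs excluded;
* tie-breaks are deterministic (earliest best-scoring end cell;
  substitutions preferred over gaps during traceback);
* the ambiguity residue `X` (from `N`-containing codons) scores 0 against
  everything;
* no E-values are computed — there is no database context — so transcript
  annotation (`annotate_transcripts()`) accepts a hit on score, identity
  and reference coverage thresholds (defaults 50, 0.30, 0.60) instead.

The test suite holds the aligner to an independent pure-R
dynamic-programming oracle on all short sequence pairs, and the greedy
junction-grouping to an exhaustive-pairing oracle.

## Counting differences between paralogs

`difference_concentration()` asks how much of the divergence between two
paralogs sits in a window (by default the N-terminal residues 1–95, in the
first sequence's coordinates). Counting rules: one event per mismatch
column, one event per *maximal indel run* — a 25-residue loop insertion is
one evolutionary event, not 25 — and masked intervals (e.g. the
non-homologous loop insertions themselves) are excluded before counting.
Indel runs are anchored to the nearest preceding residue of the first
sequence; runs before its first residue anchor to position 1. The fraction
is undefined (an error, not `NaN`) for identical sequences.

## Upstream starts

`detect_leader()` scans upstream of a transcript's canonical ATG in steps
of three, collecting every in-frame ATG not separated from the canonical
start by an in-frame stop. Only AUG starts are considered; near-cognate
(non-AUG) starts are future work. The result mirrors leader-peptide
analyses of alternative translation start sites, e.g. N-terminal extensions
of 29 and 12 residues on the two PRPSAP paralogs.

## What the simulator emulates — and what it does not

`simulate_family()` evolves one ancestral gene (default 320 residues, six
introns) along a clade tree whose branch lengths are per-site substitution
probabilities, then samples taxa per clade. Scripted events place the
biology on named branches; the default script mirrors the inferred PRPS
history: an early opisthokont duplication producing a catalytically
degraded paralog with a 25-residue catalytic-loop insertion; a holomycotan
duplicate with a regulatory-loop insertion; an amoebozoan duplicate with
degraded dimer interfaces; a jawed-vertebrate double duplication; an
intronless retrocopy; and 29- and 12-codon leader extensions on the two
PRPSAP-like lineages.

Design choices worth knowing:

* **Purifying selection on functional sites.** Background substitution
  never touches the configured residue sets (or the start codon); only
  `degrade` events change them, by forcing residues with non-positive
  BLOSUM62 score against the ancestral residue. This makes every lineage's
  ground-truth class well defined and is the simulator's strongest
  idealisation.
* **Substitution model.** Per-site Bernoulli replacement with probability
  equal to the branch rate; half the replacements (configurable) draw from
  BLOSUM62-positive partners. No codon model, no rate heterogeneity, no
  dN/dS.
* **Indels only by script.** Insertions are codon-aligned, confined to
  their named loop window, and recorded in the truth log; there is no
  background indel process, so the *true* alignment is known exactly and is
  emitted alongside the sequences.
* **Intron dynamics.** Poisson gain/loss per gene per branch (default 0.02
  events each), gains at uniform random codons with random phase. Introns
  in emitted genomes are random 60–90 nt sequences with GT...AG boundaries;
  roughly half the simulated genes are placed on the minus strand to
  exercise strand-aware parsing.
* **Transcripts** carry a 12-nt 5' UTR ending in an in-frame stop directly
  upstream of the (leader-extended) start, so leader detection has a clean,
  known truth.

Consequently, passing recovery tests on simulated families shows the
machinery is correct under these idealised conditions; it does not show
robustness to alignment error, background indels, or relaxed selection on
active sites, which real data have and the simulator deliberately omits.

## Problem sizes and reproducibility

Test and acceptance runs use the default family (four clades, three taxa
per clade, about 36 sequences of ~320 residues): 50 seeded families for the
round-trip and class-recovery suites, 50 zero-rate families for the exact
junction-sharing property, 500 random pairs for the aligner oracle, and 200
bootstrap replicates for duplication support. All randomness flows from a
single integer seed (`simulation_config(seed = )`, the `seed` arguments of
`duplication_support()` and `run_pipeline()`); global RNG state is saved
and restored around every seeded computation.

## A worked run

```{r example, eval = FALSE}
fam <- simulate_family(simulation_config(seed = 1))

ip <- intron_positions(fam$gene_models)
jm <- project_junctions(fam$alignment, ip)
call_shared_junctions(jm)          # conserved junction columns + support

feats <- extract_features(fam$alignment, fam$region_set, introns = ip,
                          model_ids = unique(fam$gene_models$gene_id))
classify_homologs(feats) |> count(class)

res <- run_pipeline(list(seed = 1, out_dir = tempfile(), simulate = TRUE))
autoplot(res$profile)
```

## Known limitations

* Junction sharing is reported descriptively (support fractions); no
  significance test of co-occurrence is attempted.
* Alignments are inputs; a misaligned column misplaces a junction, and the
  default zero shift tolerance is the strict reading — widen
  `shift_tolerance` deliberately, not by default.
* Region windows for human PRPS1 are approximate spans chosen around the
  published catalytic residues and are meant to be edited.
* The transcript annotator approximates "significant match" curation with
  score/identity/coverage thresholds; it performs no spliced alignment of
  transcripts to genomes and no HMM domain scanning.
* Corroboration of splice predictions by transcriptome data is represented
  only as user-supplied metadata, not computed.
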