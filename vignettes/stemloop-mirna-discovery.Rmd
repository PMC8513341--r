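---
title: "Small RNA processing, stem-loop miRNA discovery and median-reference normalization"
author: "stemmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA processing, stem-loop miRNA discovery and median-reference normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemmiR)
```

# Scope and model

`stemmiR` implements the analysis chain used in plant small-RNA sequencing
studies of developing seeds: single-end 50 bp libraries are cleaned and
collapsed to unique 18–25 nt sequences, partitioned into non-coding
RNA/repeat classes, matched against a mature/precursor miRNA database, and
the remaining sequences are mapped to the genome where flanked windows are
folded and screened by an eleven-criterion stem-loop filter to call novel
miRNAs. Per-library copy numbers are normalized by a median-reference
regression, and differential expression is assessed by Student's t-tests
between lines and one-way ANOVA across developmental stages at raw
P < 0.05. Mature miRNAs are scanned against transcripts with the plant
complementarity penalty, and target sets are tested for GO/KEGG term
enrichment with the upper-tail hypergeometric distribution.

The motivating design is a two-line (high-oil "HO" vs low-oil "LO"
yellowhorn) by four-stage (40/54/68/81 days after anthesis) experiment with
two biological replicates, i.e. 16 libraries. The packaged synthetic-data
generator reproduces that design with planted ground truth so that every
stage of the pipeline is testable without the original sequencing archive.

# Read cleaning

Cleaning locates the first eight bases of the 3' adapter (exact or one
mismatch, leftmost match), trims it, and tallies reads into three disjoint
removal classes plus the retained class, so that

raw = (adapter dimers + length-filtered) + junk + clean

holds exactly per library. The published studies do not define their
"junk/low-complexity" rule, so the package fixes one and exposes it in
`cleaning_config()`: an insert is junk when one nucleotide makes up ≥ 80%
of it, or a mono-/di-nucleotide repeat covers ≥ 90%, or it contains
non-ACGT/U symbols. Adapter dimers (zero-length inserts) are tallied with
the length-filtered reads, matching the merged "adaptor and length" column
convention of sequencing summary tables. Sequences are canonicalized to RNA
letters (U) at ingest.

# Ungapped matching and the seed length

Database and genome matching follows Bowtie's `-v 1` semantics: every
end-to-end ungapped placement of the read, on either strand, with at most
one mismatch. The matcher finds candidates by exact k-mer seed lookup and
verifies them over the whole read. The package defaults to `k = 9` with
disjoint seed offsets: by the pigeonhole principle a read of length ≥ 2k
with at most one mismatch always contains one clean seed, so the procedure
is provably lossless for 18–25 nt reads. A 16-nt seed — the speed setting
commonly quoted with this class of aligners — cannot guarantee that for
reads shorter than 32 nt (a mismatch in the middle of a 20-mer intersects
every 16-nt window), which is why 16 is available but not the default.
Ambiguous symbols never match. A property-style test holds the matcher
equal to a brute-force scan of every window on both strands.

Precursor-to-genome localization uses Smith–Waterman local alignment
(Biostrings) and reports loci covering ≥ 90% of the query at ≥ 90%
identity.

# Folding and the eleven hairpin criteria

Secondary structure comes from an energy-minimizing dynamic program over
non-crossing pairings: pair energies G:C −3, A:U −2, G:U −1 (kcal/mol
scale), a −1 stacking bonus for directly nested pairs, and a minimum
hairpin loop of 3 nt. This is deliberately not a full nearest-neighbour
thermodynamic model — loop entropies are ignored — but it is deterministic,
dependency-free, and adequate for a screen whose decisions rest on stem
extent, pairing of the mature region and a coarse stability cutoff. The
ViennaRNA `RNAfold` executable can be selected as an alternative backend
when present (`fold_hairpin(..., backend = "rnafold")`); all packaged
checks use the built-in backend for determinism.

Windows are the aligned read plus 120 nt of genomic flank on each side, in
read-strand orientation. The structure parser anchors on the hairpin loop
nearest the mature, walks the enclosing ladder of pairs outwards until the
first branch point, and measures: ladder base pairs; the longest unpaired
run between consecutive ladder pairs (a bulge, "biased" when confined to
one arm); hairpin extent and terminal loop length; and the mature-region
quantities (unpaired positions = errors, longest unpaired run, biased
bulges and their mature-position counts, paired positions, and the share of
the mature inside the ladder span). Because the window is symmetric and the
mature's coordinates are known, a mature on either arm is handled by the
same anchoring rule without trying alternative placements. "Errors" and
"biased errors/bulges" have no published formal definition; the definitions
above (miRDeep-style) are fixed here and exercised against an independent
re-implementation on constructed structures.

A candidate is a novel miRNA precursor iff all eleven thresholds hold:
stem bulge ≤ 12 nt; stem ≥ 16 bp; free energy ≤ −15 kcal/mol; hairpin
≥ 50 nt; loop ≤ 200 nt; mature bulge ≤ 4 nt; ≤ 2 biased errors in one
mature bulge; ≤ 2 biased bulges in the mature; ≤ 4 mature errors; ≥ 12
mature base pairs; ≥ 80% of the mature in the stem. Accepted candidates are
deduplicated by mature sequence and named `Xso-miRn1..N` in (contig, start)
order, independent of discovery order.

Reads matching a database precursor but not overlapping its annotated
mature arm are reported as opposite-arm (p5/p3) species, labelled by which
side of the precursor's terminal loop they fall on.

# Median-reference regression normalization

For libraries i = 1..S with copy numbers on a common set (sequences
positive in every library):

1. reference r_s = median over libraries of copy#(s) (mean-of-central-pair
   for even S);
2. x = log2 r, y_i = log2 copy#_i;
3. subset: |y_i − x| < 2 (less than 4-fold off the reference);
4. OLS fit y_i = a_i x + b_i on the subset;
5. x_mid = (max(x) − min(x)) / 2; Δy_i = x_mid − (a_i x_mid + b_i);
6. f_i = 2^(Δy_i); every count in library i (all sequences, not only the
   common set) is multiplied by f_i.

Two numerical points are worth making explicit. First, the mid-value is
implemented exactly as the half-range (max − min)/2 — the form the
procedure was stated with — although the conventional midrange
(max + min)/2 is available via `midpoint = "midrange"`; on log2 count data
the two differ by min(x), which shifts every Δy_i equally and so changes
factors only when samples differ in slope. Second, the |Δlog2| < 2 subset
rule interacts with global rescaling: multiplying one library by c shifts
all its Δlog2 by log2 c, so for |log2 c| ≥ 2 the standard subset empties
and the fit is impossible by construction. The exact equivariance
f → f/c therefore holds whenever the subset is unchanged — guaranteed by
pinning the subset to the whole common set (`delta_cutoff = Inf`) or for
|log2 c| small relative to the cutoff — and the tests exercise both
regimes. Normalizing an already-normalized matrix returns factors of 1 on
constructions where the reference is reproduced exactly (e.g. a majority of
unscaled libraries); with arbitrary data the refit factors are 1 only up to
the movement of the row medians.

No pseudocounts are used: logs are only ever taken on the common set, which
is positive by construction.

# Differential expression

Tests run per miRNA on log2(normalized + 1) by default (variance
stabilization; `scale = "linear"` reproduces untransformed testing):
classical pooled-variance Student's t between two groups, one-way ANOVA
across the four stages, both at raw P < 0.05 with no multiple-testing
correction on the significance flag (a Benjamini–Hochberg column is emitted
for reference). Zero pooled variance with equal means reports P = 1; with
unequal means P = 0 and a flag. Fold changes are log2 of (mean + 1) ratios
on the normalized scale. The replicate-consistency view is a centered PCA
of libraries on log2(normalized + 1).

With two replicates per group the t-test has 2 degrees of freedom; the
calibration that matters is empirical: under a null negative-binomial
simulation (2000 miRNAs, dispersion 0.05, n = 2 per group) the type-I error
at α = 0.05 falls within [0.03, 0.07], and planted 4-fold effects at means
≥ 200 are detected with sensitivity above 0.70 and full direction
agreement. Those checks run in the test suite and the acceptance script.

# Target scoring and enrichment

The plant complementarity penalty (the scheme popularized by the
TargetFinder lineage of tools, re-implemented here; it is an external
scoring convention, not a contribution of the motivating study): mismatch
1, G:U wobble 0.5, gap 1, all doubled at miRNA positions 2–13, default
cutoff 4, at most one gap (so a site of the miRNA's length is scored
ungapped, and sites one base shorter/longer place a single gap optimally).
Scanning enumerates every transcript window of lengths L−1, L, L+1 without
merging overlaps, so the reported set equals exhaustive enumeration under
the same scorer. One symmetry note: the score is invariant to reading the
duplex from its other end (reversing both strands and swapping roles),
which preserves every base pair and its distance from the guide 5' end;
reverse-*complementing* both strands is not a symmetry, since it would turn
G:U wobbles into A:C mismatches.

Enrichment is the upper-tail hypergeometric probability of a term's overlap
with a query gene set against a universe defaulting to all annotated genes
(the original study does not state its universe), flagged at raw P < 0.05;
it is held equal to the one-sided Fisher exact test in the suite.

# The synthetic study and what it does (not) show

`sim_config()` defaults encode the study conditions: 16 libraries
(2 lines × 4 stages × 2 replicates) of 50,000 single-end 50 bp reads; 30
database ("known") miRNAs, 20 genome-only ("novel") loci and 20 decoy
windows planted with ≥ 120 nt flanks on a 200 kb four-contig genome; 10%
contaminant reads from 25 rRNA/tRNA/snRNA/snoRNA/repeat references, 5%
adapter dimers, 2% low-complexity junk; mature lengths dominated by 24 nt
with a 5'-U bias, as in plant embryo sRNA populations; per-miRNA abundances
log-normal (natural-log mean log 150, sd 1) with negative-binomial
dispersion 0.05 per library; 20% of miRNAs carry a planted |log2FC| = 2
between lines or between late and early stages (the DE subset is floored at
mean 400 so planted effects are detectable at this depth); star-arm reads
at low constant abundance exercise opposite-arm detection. Reads carry the
TruSeq small-RNA 3' adapter (the kit named in this class of protocols
defines no insert-specific adapter, so it is configuration, not a
constant) and constant Q35 qualities — the cleaning filters ignore
qualities, so quality realism is deliberately out of scope, as are
sequencing errors, UMIs and paired ends.

Planted hairpins are built stem-outward (extension + mature arm, an A/C
loop that cannot self-pair, and a star arm with a small bulge) and then
re-folded and re-measured through the package's own evaluator during
generation, with bounded retries, so criteria satisfaction is guaranteed by
construction and verified, not assumed. Decoys come in two classes: purine-only
windows in which no canonical or wobble pair can form (structurally
unpairable, fail with certainty), and random windows certified at build
time to violate at least one criterion. Library sizes are realized exactly;
class counts are multinomial; per-miRNA counts are gamma-weighted
multinomial draws, giving negative-binomial-like marginals around the
planted means.

Passing on these simulations demonstrates internal correctness — recovery
of planted signal under the stated noise model — not performance on real
tissue libraries, where expression is burstier, contaminant families are
homologous rather than random, isomiR end-variation is pervasive, and
genomes contain repeats and paralogous MIR families. The published
study-scale headline counts (hundreds of known miRNAs, dozens of novel
loci, thousands of targets) depend on the original sequencing archive,
genome assembly and database releases and are therefore out of reach of a
self-contained package; the simulation-based checks above are the packaged
substitute.

# Problem sizes and determinism

The test suite and the acceptance script run the full 16 × 50,000-read
design (three seeds in the suite), the 2000-miRNA null calibration and the
500-miRNA sensitivity simulation; smaller configurations (6 + 4 planted
loci, 3000 reads) cover unit-level behaviour. All generation is
deterministic given one integer seed: per-library and per-module streams
are derived from it, and identical seeds yield byte-identical FASTA/FASTQ
output.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- generate_reference(cfg)
libs <- simulate_libraries(sim, tempdir())
res <- run_srna_pipeline(libs, sim$genome, sim$mature_db, sim$precursor_db,
                         sim$precursor_info, sim$contaminants,
                         sim$contaminant_info)
print(res)
summary(res$norm)        # per-library regression fits and factors
head(res$de[["HO40_vs_LO40"]])
plot(res$pca)
```

# Known limitations

* The folding backend's energies are on a coarse kcal/mol-like scale; the
  −15 kcal/mol cutoff is meaningful for ranking stems under this model, and
  agreement with a thermodynamic backend's exact MFE values is not claimed.
* Known-miRNA matching requires end-to-end alignment; 5'/3' isomiR offsets
  are not credited to the database mature.
* The reported precursor for an accepted novel candidate is trimmed to the
  outermost ladder pair of its hairpin, which is narrower than the folded
  window and may differ from what other tools report.
* GO terms are flat labels; no ontology-graph propagation is applied.
* phasiRNA and NAT-siRNA classes are out of scope (their published
  identification relies on external tools whose algorithms are not defined
  in the protocol this package follows).
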