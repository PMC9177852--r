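---
title: "Methods: gamma/delta clonotype repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma/delta clonotype repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrgd)
library(dplyr)
```

This vignette documents the models, decision rules and numerical choices
behind `tcrgd`, and what the synthetic-data validation does and does not
establish about real data.

## The analysis problem

Tγδ LGL leukemia and hepatosplenic T-cell lymphoma are clonal expansions
of γδ T cells. Amplicon deep sequencing of the rearranged TRG and TRD
loci produces per-sample clonotype tables; the biological questions are
about clonal architecture, V-(D)-J usage, sharing of CDR3 sequences
across individuals, and the relation between somatic STAT3/STAT5B
mutations, the clone, the immunophenotype and the clinical course. The
package operates strictly downstream of clonotype assembly.

## Productive-repertoire filter

All frequency denominators are **productive reads of the same chain**. A
clonotype is productive when its CDR3 junction is in frame (length
divisible by 3), its translation contains no stop, and — when a segment
library is supplied — both V and J genes are functional (ORF and
pseudogene segments excluded). Unproductive rearrangements are common in
γδ loci (the locus rearranges on both alleles) but they carry no protein
and are excluded before any analysis; `filter_productive()` is
idempotent and re-normalizes frequencies over the retained reads. Only
this filter is applied; no singleton or abundance post-filter is,
because the downstream statistics operate on major clones where such
filters are irrelevant.

## Major clonotypes and clonal architecture

A **major clonotype** has frequency ≥ `threshold` (default 0.05) in its
sample and chain; the boundary is inclusive. Entries are ranked by
descending frequency with ties broken by CDR3 amino-acid lexicographic
order, making ranks deterministic.

Clonal architecture is labelled from the per-chain major counts by their
maximum: 1 → monoclonal, 2 → biclonal, ≥ 3 → oligoclonal, and 0 →
polyclonal (the healthy-donor state). The per-chain **maximum** is the
natural reading because a single expanded cell clone contributes one
rearrangement per chain (plus occasional secondary rearrangements): a
sample with one dominant γ and one dominant δ clone is one clone, not
two. On the bundled pilot cohort this rule reproduces the reported four
monoclonal samples.

## V-(D)-J usage

`compute_vdj_usage()` counts **occurrences** — each major-clonotype entry
once — not distinct sequences. This is the convention that makes usage
fractions interpretable as "how often does this combination appear among
major clones" and reproduces the cohort's J-gene distribution (Jγ1/2 41%,
JγP 36% of the 22 gamma major entries). Three granularity decisions:

* Allele suffixes (`*01`) are stripped at ingestion; usage is gene-level.
* `TRGJ1/2` is treated as a single gene label because the TRGJ1 and
  TRGJ2 segments are indistinguishable to amplicon assays.
* JγP, JγP1 and JγP2 are three distinct genes; no pooling.

The KK dipeptide scan (`scan_kk_motif()`) is an exact substring test;
the motif is encoded by the TRGJ1/2 and TRGJP joining segments and is
relevant to phosphoantigen recognition by Vγ9/Vδ2 cells.

## CDR3 motif matrices

`build_motif_matrix()` replaces a guide-tree multiple aligner with a
deterministic **center-star** construction: the center is the sequence
minimizing summed pairwise edit distance (ties to the first in input
order); all others are globally aligned to it (BLOSUM62, gap open 10,
gap extend 1 — fixed constants, not tunables) and merged under
once-a-gap-always-a-gap. At CDR3 scale (9–21 residues, strong C…F
anchoring) the position-frequency output is insensitive to guide-tree
details, and determinism matters more than alignment optimality for a
visualization matrix. Column information content is `log2(20) − H` bits
with `H` the Shannon entropy over non-gap residues, the usual
information-scaled logo height; columns therefore lie in `[0, log2(20)]`.

## Publicity and enrichment

The query set is the pooled set of distinct patient major CDR3 amino-acid
sequences. Matching against every sample's full repertoire is **exact
amino-acid identity**, gene segments deliberately ignored, because
convergent recombination produces the same peptide from different
nucleotide rearrangements; frequencies of nucleotide variants encoding
one peptide are summed. Labels partition the query set:

* **public** — present in ≥ 1 healthy control;
* **private_to_disease** — absent from controls, present in ≥ 2 patients;
* **private_to_patient** — exactly one patient, no controls.

Enrichment per query sequence compares patient versus control frequency
vectors with the one-sided two-sample rank-sum test (patients
stochastically greater). Samples lacking the sequence contribute an
explicit **zero**: presence/absence is evidence and must influence the
ranks; restricting to carriers would condition away the main signal.
P-values are reported raw (per-clonotype, as in the underlying study
design); `stats::p.adjust()` can be applied downstream. The
Shapiro–Wilk gate (`normality_gate()`, Royston's algorithm via
`stats::shapiro.test`) records whether frequencies look Gaussian, but
the pipeline always proceeds nonparametrically — the gate exists to
document why.

## Exact statistics

The 2×2 and rank-sum kernels are implemented from first principles (the
base-R equivalents serve as independent oracles in the test suite):

* **Fisher two-sided** uses the probability-mass method: the p-value sums
  hypergeometric probabilities of all tables with the observed margins
  whose point probability is ≤ that of the observed table (relative
  tolerance 1e-7 for floating-point ties). Log-gamma arithmetic keeps it
  stable far beyond n = 1000. The probability-mass definition, rather
  than doubling one tail, is what reproduces the reference
  cohort's reported p-values (0.006, 0.002, 0.009, 0.025).
* **Pearson χ²** carries no Yates correction by default (a flag exists);
  df = 1, p from the survival function.
* **Test selection**: Fisher when any expected count < 5 or any observed
  cell is 0, else χ². The cohort report mixes both tests without stating
  a rule; this classical rule reproduces its mixed output (e.g. the
  NKG2 row matches χ², the CD5 row Fisher). Association reports can
  force Fisher throughout.
* **Rank-sum**: Mann–Whitney U with midranks. For n + m ≤ 12 the p-value
  enumerates all `choose(n+m, n)` assignments of the pooled observations
  — a permutation test that is exact **under ties as well**, which is
  essential because absence-as-zero creates heavy ties (the canonical
  separated example, three positive frequencies versus three zeros,
  gives exactly 1/20). Larger samples use the normal approximation with
  tie correction and 0.5 continuity correction. Two identical constant
  samples give p = 1 by construction.

Two feature rows of the bundled count table (Vδ1−/Vδ2− and
splenomegaly, both 4/17 vs 0/19) compute to p ≈ 0.04 under Fisher
although the reference annotation marks them non-significant; the
package reports the computed values without special-casing.

## VAF–clone concordance

The clone fraction used in ρ = VAF / f is the **flow-determined Tγδ
fraction of PBMC**, because PBMC is the substrate of the mutation assay;
using the within-chain NGS clone percentage would mis-scale patients
whose Tγδ compartment is itself a minority of PBMC (it would break the
pilot cohort's heterozygous call at ρ = 0.27/0.65 ≈ 0.41). The label
boundaries (0.35 and 0.75, both inclusive from below) sit midway between
the theoretical heterozygous (0.5) and homozygous (1.0) expectations and
zero, and are exposed as arguments. The **oligoclonality gate** —
second-largest major on either chain ≥ 0.10 → `indeterminate_oligoclonal`
— encodes that a mutation cannot be anchored to a clone when a
substantial second clone exists; it is what makes a sample with a single
dominant δ clone but an oligoclonal γ repertoire indeterminate. A VAF
exceeding the clone fraction by > 0.10 triggers a warning (possible
non-clone origin or phenotype/genotype inconsistency). Monoallelic
phase annotations are stored but not used in classification.

## Diagnostic classifier

`diagnostic_classifier()` encodes the stated phenotype/genotype
associations as a rule cascade: HSTCL → aggressive regardless of
genotype; Vδ2+/Vγ9+ → indolent expectation; Vδ2− → symptomatic
expectation; STAT3 mutation → neutropenia alert; STAT5B with CD56+ in
LGLL → indolent reinforcement; conflicting evidence → discordant flag;
unknown Vδ2 → unclassifiable. The exact decision-tree layout of the
source cohort's summary figure is not published in the main text, so the
cascade is this package's realization of the stated associations, not a
transcription.

## The synthetic cohort generator

`simulate_cohort()` generates the structure the analyses assume, with a
complete truth record:

* **Segment library** — synthetic sequences with correct anchors
  (conserved C/F codons) and KK-encoding TRGJ1/2 and TRGJP; IMGT
  sequences are not redistributed, but any library with the same columns
  can be dropped in.
* **Junction model** — capped geometric trimming (p = 0.25, cap 10 nt)
  of V 3', both D ends and J 5'; Poisson(λ = 4) N insertions per
  junction. These values are not measured quantities from any cohort;
  they were chosen once to give a realistic productive fraction (~0.30,
  frame 1/3 minus stop losses) and CDR3 length spread (gamma median
  ~13 aa, range ≈ 9–16; delta longer), and are recorded in the function
  signature.
* **Backgrounds** — a shared polyclonal pool per chain (geometric clone
  sizes, top weight ≈ 2%, so controls never carry a ≥ 5% clone; a
  power-law option exists). All samples draw their background from this
  pool, which models the shared public repertoire of healthy donors and
  is what gives control repertoires their mutual similarity.
* **Planted structure** — indolent patients: dominant TRGV9-TRGJP /
  TRDV2-TRDD3-TRDJ1 clones whose gamma CDR3s are convergent publics
  (each patient re-encodes them with its own nucleotide variant; the
  sequences are also seeded into the background pool near its head so
  every control carries them); the major sets are prefixes of one shared
  list, so dominant sequences recur across patients as observed in real
  indolent disease; two patients additionally carry one gamma sequence
  planted in no control (private to the disease). Symptomatic patients:
  diverse Vδ2-negative usage, patient-unique dominants. HSTCL: a single
  TRDV1 clone at 95%.
* **Reads** — multinomial sampling at 4×10⁵ reads per chain (the
  magnitude of real amplicon depths), so planted frequencies are
  recovered within the multinomial standard error.
* **Mutations** — per-patient gene (STAT3 for symptomatic, STAT5B for
  indolent/HSTCL, with configurable prevalences), zygosity and
  cancer-cell fraction; true VAF = clone fraction × ccf × (0.5
  heterozygous | 1 homozygous); observed VAF is a binomial draw at depth
  5×10³ (`simulate_patient_metadata()`), which also realizes tri-state
  markers from configurable group-conditional probabilities
  (deterministic STAT3 → CD56−/neutropenia by default).

Everything is driven by one integer seed through `withr::with_seed`;
fixed seed ⇒ bit-identical output.

**What passing recovery tests show** — that the pipeline's string
matching, counting, ranking and thresholding are correct, and that its
statistics are calibrated under the generative model. **What they do not
show** — robustness to sequencing error, PCR chimeras, UMI-free
quantification noise at low frequencies, incomplete productive
annotation, or real junctional statistics; none of those are modelled
(no error or chimera model, by design). Claims that depend on real
control repertoires (how many real query sequences are enriched, which
real sequences are private) are not reproducible from simulation and are
represented here only by the recovery properties.

## Clustering

Repertoire overlap uses amino-acid-keyed frequency vectors with
Morisita–Horn distance (`vegan::vegdist(method = "horn")`) by default —
robust to sequencing-depth differences because it works on relative
abundances — or binary Jaccard; average-linkage agglomeration and a
two-group cut. The validated property is qualitative: with planted
shared dominant clones, patients and controls separate at the 2-cut in
≥ 95% of seeded runs. No specific tree topology is asserted, because
the metric/linkage combination was this package's choice.

## Problem sizes and runtimes

The test suite and acceptance script scale simulations to desk size as
the package's own validation design: cohorts of 5–13 patients with
100–400 background clonotypes per chain, read depths 2×10⁴–4×10⁵
(full depth where the property concerns multinomial error), 10,000 null
simulations for the rank-sum size, 15–20 seeded runs for the clustering
separation rate, and five seeded cohorts (≥ 60 informative mutations)
for zygosity recovery. The complete suite runs in well under a minute on
one CPU.

## Known limitations

* Gene-segment-constrained publicity matching is available as a flagged
  variant of exact amino-acid matching only through pre-filtering; the
  default deliberately ignores segments.
* The exact rank-sum path is limited to n + m ≤ 12; the study-scale
  comparison (11 patients vs 23 controls) uses the tie-corrected normal
  approximation, as any exact implementation of `choose(34, 11)` splits
  would be impractical.
* The synthetic segment library covers the gene set needed for the
  analyses, not the full IMGT loci.
* `classify_architecture()` on samples where the two chains disagree
  wildly (e.g. secondary rearrangements) reports the maximum; it does
  not attempt clone lineage reconstruction.
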