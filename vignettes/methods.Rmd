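---
title: "Models and methods behind tsepipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tsepipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsepipe)
```

`tsepipe` re-implements, as tested and reusable code, the analysis
chain of a classic de novo floral-transcriptome study design:
annotation by reciprocal best hits, single-best-hit read counting with
RPKM under two reference strategies, rarefaction-based saturation
analysis, lineage-specific gene detection across five rosid taxa,
qualitative cross-platform presence/absence comparison, and qPCR
validation. This vignette explains the models, the tunable parameters,
the synthetic data the package is benchmarked on, and the design
choices made where the underlying procedures are conventionally left
vague.

## Annotation: reciprocal best hits

Similarity hits arrive as BLAST-style `outfmt 6` tables
(`parse_hit_table()`), the lingua franca emitted by every relevant
alignment engine; the engines themselves are out of scope. "Best hit"
is often under-specified; here it is total and deterministic:
maximal bit score, ties broken by lower e-value, then by
lexicographically smallest subject identifier. This total order makes
`reciprocal_best_hits()` invariant to input row order — a property the
test suite asserts against brute-force enumeration — and guarantees the
result is a partial matching (no contig or gene appears twice).

No e-value floor is applied during annotation by default (the RBH
criterion itself is stringent); a floor can be imposed upstream by
filtering the hit table.

### Chimera flagging

De novo assemblers occasionally concatenate fragments of two
transcripts. The detector (`flag_chimeras()`) declares a contig
chimeric when it has qualifying alignments to at least two distinct
genes: each spanning ≥ `min_segment` (100 nt) of the contig at
e ≤ `max_evalue` (1e-10), with pairwise query-interval overlap
≤ `max_overlap` (30 nt). Per gene only the strongest alignment is
considered, and compatible segments are selected greedily by earliest
interval end — the standard interval-scheduling choice, which is exact
whenever true segments are disjoint (as planted chimeras are). The
defaults reflect what a protein-space alignment of a genuine constituent
should achieve; 30 nt of slack absorbs boundary wobble without letting
two alignments of the same region count twice. Flagged contigs can be
excluded from contig-based quantification (`exclude_chimeras`), since
pooled reads from two genes otherwise inflate the annotated gene's
signal.

## Expression: TSE1, TSE2 and RPKM

Each read contributes one count to its single best hit;
`N_mappable` is the number of reads with at least one retained hit
under the active strategy, so the two strategies have separate,
internally consistent denominators. RPKM is
`count × 1e9 / (model_length × N_mappable)`; the gene-model length is
the orthologous reference CDS length under TSE1 and the full contig
length under TSE2. Profiles for comparison are ratios to a reference
gene (`normalize_to_reference()`), which cancels depth entirely —
`rpkm_table()` is itself invariant under joint rescaling of counts and
depth, and tests assert both properties.

The TSE2-vs-TSE1 contrast is scientifically the interesting one: when
the contig (the TSE2 gene model) is shorter than the transcript region
its reads actually derive from, length normalisation under-divides and
the contig-referenced value overestimates expression — the classic
"629 nt contig vs 2406 nt CDS with the same counted reads" situation,
giving a ratio of 2406/629 ≈ 3.8 between the two normalisations. The
validation comparison (`validate_against_qpcr()`) fits an ordinary
least-squares line between normalised profiles and reports squared
Pearson correlation; the comparison is done on fold-ratios, linear by
default with a `log_scale` option (the conventional plot scale for
expression spanning orders of magnitude, and the scale the pipeline
uses).

## Rarefaction

A library is the multiset of per-gene read supports N_i (total N,
richness S). The closed-form expectation of the richness of a uniform
without-replacement subsample of n reads is

$$E[S_n] = \sum_i \left(1 - \binom{N-N_i}{n}\Big/\binom{N}{n}\right),$$

computed via `lchoose` so that N = 10⁶, N_i = 10⁴ stays finite where
naive binomials overflow. The classical procedure — resample 1,000
times, average the discovered-gene count per depth — is provided as
`rarefaction_curve_mc()` and validated against the closed form; the
analytic path is the default because it is exact and fast. The
subsampling unit is the read: a gene is drawn with probability
proportional to its remaining support. The default grid is 50 evenly
spaced depths from 0 to N (the grid used by the original software is
not conventionalised; evenly spaced depths make tail slopes
well-defined).

"The curve flattens into a plateau" is quantified: the tail slope is
the expected-richness difference between the deepest grid point and the
point nearest 90% of that depth, divided by the depth difference, and
the library is saturated when this marginal discovery rate falls below
θ = 10⁻³ genes/read — i.e. fewer than one new gene per thousand extra
reads.

## Lineage-specific genes and Dollo interpretation

Presence of a contig in a comparator taxon is hit-existence at
e ≤ 10⁻¹⁰, with no additional coverage or identity requirement, and
one-directional (a reciprocal requirement would conflate annotation
quality with presence). The four flags define 16 subsets; the eight
conventionally lettered ones (B, C, E, G, I, K, O, Z) are labelled,
the rest carry their bitmask. On the fixed tree
`(Pt,(Cp,(Th,(At,Br))))` each mask is interpreted by Dollo parsimony:
the gain sits on the edge above the MRCA of the present leaves (the
focal taxon is always present), and losses are the edges to the maximal
all-absent clades below it. This reconstruction is minimal and unique,
and the implementation is verified against exhaustive enumeration of
all single-gain scenarios for all 16 masks.

## Cross-platform comparison

Microarray-defined presence (detection in ≥ 1 floral stage, threshold
supplied by the user because detection calls are platform-specific)
is compared with sequencing-defined presence (read count ≥ `min_count`,
default 1) strictly qualitatively, through the RBH homology matching.
Probes hybridising to more than one gene are removed first; genes
without a homology partner are reported separately and never enter the
differential lists, so the shared/only/unmapped classes partition each
side's present set.

## qPCR mathematics

Standard-dose-response series are fitted by least squares
(`Cq ~ log10(amount)`), with `E = 10^(−1/slope)`; perfect doubling
gives slope −log₂10 ≈ −3.3219. Quantification is efficiency-corrected
(Pfaffl-style) by default,
`fold = E_t^(−ΔCq_t) / E_r^(−ΔCq_r)`, which reduces exactly to
`2^(−ΔΔCq)` when both efficiencies are 2 — an identity asserted on
random inputs. Group means are arithmetic in Cq (geometric in
quantity), the standard convention. The degenerate one-way ANOVA cases
are defined explicitly: all-identical data give F = 0, p = 1; zero
within-group variance with a real group difference gives F = ∞, p = 0;
otherwise the classical F test (via `stats::anova`) applies.

## The synthetic-data generator

The generator emulates the data-generating process of a shallow
454-style floral transcriptome study, and its defaults are the study
conditions under which all stochastic guarantees are stated:

* **Families and the tree.** Families are born on one of the four
  branches leading to the focal taxon (defaults: root 0.80, malvid stem
  0.03, core-Brassicales stem 0.05, focal terminal 0.12) and lost
  independently below the birth point (2–4% per branch). These rates
  were chosen once so that the realised subset proportions resemble a
  real floral assembly — roughly 70% shared by all taxa and 10–12%
  focal-specific — and are not calibrated further.
* **Sequences.** CDS lengths are log-normal (median 800 nt, floor
  150 nt); 3' UTRs are Gamma(2, 125) (mean 250 nt, the scale of UTR
  carry-over reported for 454 floral assemblies).
* **Abundances** are i.i.d. log-normal (σ = 1.5, two orders of
  magnitude of dynamic range) with 20% of families silent.
* **Reads** are sampled family-wise proportional to
  abundance × transcript length (a fragmentation model — longer
  transcripts shed more fragments — which is what makes RPKM's length
  division the right correction), with lengths Normal(316, 80)
  truncated to [50, transcript length], split round-robin into two
  replicate libraries.
* **Contigs** carry a 3'-anchored fraction of the CDS plus the 3' UTR.
  The fraction (`completeness`) is coverage-dependent by default:
  `min(1, 0.45 + 0.18·log10(1 + expected reads))`, floored so that at
  least ~120 nt of CDS is assembled. Abundant housekeeping-class
  transcripts therefore assemble to full length while rare transcripts
  remain fragmentary — the behaviour real shallow assemblies show, and
  the mechanism by which contig-referenced expression (TSE2)
  overestimates: counts are essentially those of the full transcript
  while the normalising length is the shorter contig. With
  `completeness = 1` contig length equals CDS + UTR exactly.
  A configurable fraction (default 1%) of contigs are chimeras — the
  primary family's contig with a second family's contig concatenated;
  the 120 nt floor keeps every planted constituent above the detector's
  `min_segment`, so noise-free recovery is exact rather than
  vacuously limited by undetectable segments.
* **Hit tables** are identity-based: a query hits a subject iff they
  share an origin family and the family is present in the subject's
  taxon. True hits draw log₁₀ e ~ U(−180, −11) (always beyond the
  10⁻¹⁰ cutoff) and are dropped with probability `miss_rate`; spurious
  hits draw log₁₀ e ~ U(−12, −2) (straddling the cutoff) at rate
  `spurious_rate`; bit scores are a decreasing function of e-value.
  Alignment-level error (454 homopolymer noise, base quality) is *not*
  simulated — the hit-table noise model is the error model, because the
  inference logic downstream of alignment is what the package tests.
* **Cq data** follow `Cq = intercept − log10(amount)/log10(E)` exactly
  for dilution series, with Normal replicate noise (default SD 0.15
  cycles) for group measurements.

Consequently, passing tests demonstrate that the *inference* is correct
under a faithful abstraction of the study design; they do not
demonstrate robustness to misassembly beyond planted chimeras, to
alignment artefacts, or to cross-mapping within gene families (the
latter is modelled only as the planted discordant gene in the qPCR
validation panel).

## Numerical and design choices

* Every generator is a pure function of (parameters, seed); the
  pipeline derives per-stage child seeds from the global seed by fixed
  arithmetic, so stages are individually reproducible and `run_pipeline`
  is byte-deterministic.
* Hit coordinates follow the BLAST convention (1-based, inclusive);
  minus-strand hits are normalised with the orientation kept in a
  `s_strand` flag, so interval logic in the chimera detector never
  sees reversed intervals.
* Only the 12-column `outfmt 6` dialect is parsed; extra columns warn
  and are ignored. Parsing never silently drops lines.
* The Monte Carlo rarefaction comparison allows 3 standard errors plus
  0.01 genes; the absolute allowance covers depths at which every
  replicate already observes all genes (sample SD exactly 0) while the
  analytic expectation is within a few 10⁻⁵ of S.
* Problem sizes in the test suite — 200 enumeration libraries (N ≤ 12),
  a 1,000-gene/50,000-read resampling comparison, 200 random RBH
  instances, a 2,000-family noisy-recovery universe, 10⁵ reads for
  expression recovery, and an 800-family demo pipeline — were chosen as
  the smallest scales at which the stochastic properties are stable,
  and run in well under a minute each.

## Known limitations

* Annotation is one-to-one by construction; many-to-many ortholog
  groups, paralog resolution after whole-genome duplication, and
  synteny are out of scope.
* Expression is single-best-hit counting; no probabilistic multi-mapping
  assignment (EM), and no TPM/FPKM variants or differential testing.
* Rarefaction does not extrapolate beyond the observed depth
  (no Chao/ACE richness estimation).
* The cross-platform module never attempts magnitude normalisation
  between microarray and sequencing data; it is presence/absence only.
* Cq determination from raw fluorescence is out of scope; Cq values are
  inputs.
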