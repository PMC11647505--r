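---
title: "Classifying tRNA- and rRNA-derived small RNAs: methods and design"
author: "trflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tRNA- and rRNA-derived small RNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

trflow is a self-contained re-implementation of a small RNA-seq
classification and differential-abundance workflow of the kind used to
compare tRNA-derived fragment (tRF) and rRNA-derived small RNA (rsRNA)
content between conditions — for example between wild-type and
RNase-deficient epididymis, where loss of luminal ribonucleases depletes
tRFs and rsRNAs and shifts the read-length distribution toward longer
species. The package covers the complete path from raw reads to
significance calls: reference construction, adapter/UMI preprocessing,
best-hit mapping, single-primary-category resolution, fragment typing,
feature counting, and a negative-binomial Wald test. A synthetic read
generator with per-read ground truth makes the whole pipeline testable
without any external download.

This vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

# Reference construction

The alignment reference is a bundle of four compartments, in decreasing
classification precedence:

1. **Mature tRNAs.** Each genomic tRNA gene is processed into the mature
   transcript the sequencer actually observes: intron intervals (0-based,
   half-open on the gene sequence) are spliced out, the post-transcriptional
   3' `CCA` tail is appended, and histidine tRNAs receive the canonical
   extra `G` at position −1. So
   `len(mature) = len(gene) − Σ intron + 3 (+1 for His)`.
   Gene databases store untailed gene sequences, so `CCA` is appended
   unconditionally by default; the `assume_cca_absent` flag makes the rule
   explicit for references that already carry tails.
2. **rRNA subunits and their genomic repeat copies** (18S, 28S, 5.8S, 5S,
   mitochondrial rRNA). Repeat copies carry the subunit label of their
   parent, so a read hitting a subunit and its repeats still resolves to
   one subunit. Mitochondrial rRNA has no repeat set. Where an annotation
   provides two sequences for one subunit (as for 28S), both carry the same
   subunit label and are not distinguished downstream.
3. **Annotated small-RNA genes** (miRNA and other biotypes), matched by
   identity of the reference.
4. **Background segments** — unannotated genomic sequence; reads landing
   only here become the "Other" class.

Only the forward strand of each reference is indexed; the mapper reports
reverse-complement alignments with strand `−`, and the classifier treats
antisense tRNA hits as background (antisense tRF detection is out of
scope).

`synthetic_reference()` builds a randomized, scaled-down bundle with the
same structure: ten tRNA decoders (two decoders with identical gene
copies, two intron-containing genes, one histidine), five rRNA subunits at
reduced lengths with repeat copies, a panel of 100 miRNA-sized genes, and
background segments. Identical gene copies within a decoder reproduce how
real tRNA gene families force reads to the decoder specificity tier.
Random sequence content means cross-compartment collisions at small-RNA
lengths (≥ 16 nt) are vanishingly unlikely, which is what makes exact
truth-recovery tests meaningful.

# Read structure and preprocessing

Raw reads follow an end-labeling small-RNA library layout:

```
[7-nt UMI] [insert] [1 untemplated base] [3' adapter GATCGGAAGAGCACACGTCT] [spillover]
```

Trimming inverts this in three ordered steps: (1) the adapter is removed
from its earliest occurrence — internal occurrences must cover the full
adapter; a truncated occurrence is allowed where the read ends; up to 10%
mismatches over the matched length and a minimum terminal overlap of 3 are
tolerated (the tool the layout mimics does not pin these two knobs, so
they are config-exposed with common trimmer defaults); (2) the final
untemplated base is removed; (3) the 7-nt UMI is split off and retained
alongside the insert. Reads with no adapter occurrence are kept untrimmed
at step 1, since inserts longer than the cycle count legitimately lack
adapter. Reads too short for the layout are flagged discarded with a
reason, never silently dropped, so `input = output + discarded` holds
exactly at every stage. UMIs are recorded but not used for deduplication
(whether the original studies collapsed UMIs is not stated; we do not).

The minimum read size of 16 nt applies to **non-tRNA** reads only, and a
read's category is unknown until after mapping. `length_filter()`
therefore only flags short reads; the classifier consumes the flag and
drops flagged reads unless they resolved to the tRNA category. tRNA reads
have their own minimum, `min_trna_len = 15` — one below the non-tRNA
minimum; the established procedure fixes only the non-tRNA bound, so the
tRNA bound is a documented package choice.

# Mapping model

`map_reads()` performs ungapped end-to-end alignment under Hamming
distance on both strands and returns, per insert, **all alignments
achieving the minimum edit distance** (and at most `max_mismatches`,
default 1). This "all best mappings" contract is exactly what the
classifier consumes. At tRF lengths, on substitution-only data, ungapped
best-hit sets coincide with what a gapped seed-and-extend aligner reports;
the contract, not the aligner internals, is the interface, and a SAM
import/export pair (`write_sam_hits()` / `read_sam_hits()`) allows an
external aligner to stand in.

Hits are ordered deterministically by (class rank tRNA < rRNA < annotated
gene < background, reference id, start, strand) and truncated at
`max_hits` (default 100). Ranking by class before truncating guarantees
the cap can never drop a tRNA hit in favor of a background hit, which
would otherwise corrupt category precedence. `N` bases never match and
cost one mismatch each (an aligner-specific ambiguous-base penalty has no
direct analogue here; this is a documented divergence). The mapper is
validated against an independent exhaustive sliding-window search on the
full synthetic bundle.

# Classification

**Category precedence.** Each read's best-hit set resolves to a single
category: any forward-strand tRNA hit → `tRNA` (all other hits
discarded); else any rRNA/repeat hit → `rsRNA`; else any annotated gene →
`annotated_gene`; else `unannotated` ("Other"); no hits → `unmapped`. The
primary mapping is the first retained hit in the mapper's deterministic
order, and only this primary mapping enters per-read summaries, so no
read is double-counted.

**Fragment typing.** With `d5` the distance of the read's 5' end from the
mature transcript start and `d3` the distance of its 3' end from the CCA
terminus (CCA positions count toward the 3' end, since classification is
on mature sequences), rules apply in order:

| rule | condition | type |
|------|-----------|------|
| 1 | d5 ≤ 3 and d3 ≤ 5 | `whole` |
| 2 | d5 ≤ 3 | `tRF_5p` |
| 3 | d3 ≤ 5 | `tRF_3p` |
| 4 | otherwise | `tRF_other` |

The 3/5-nt tolerances are defined by the whole-tRNA rule; applying the
same tolerances to the end-proximity rules is a symmetry choice, exposed in `classifier_params()`. The whole > 5' > 3' evaluation
order only matters inside the tolerance bands (a read with d5 > 3 and
d3 > 5 is `tRF_other` under every ordering); the order follows the rules'
natural statement. The classifier is tested exhaustively against a
brute-force implementation on all 2,926 substrings of a 76-nt transcript.

**Specificity tiers.** The retained tRNA hits place each read at one of
four ambiguity levels: unique transcript; one decoder (isotype +
anticodon); one acceptor (isotype only); ambiguous. Counts are kept at
(decoder, fragment type) granularity, using transcript- and decoder-tier
reads. Whether acceptor-tier reads should be counted at the acceptor
level or excluded is genuinely ambiguous in the procedure this follows;
both behaviors are implemented (`count_acceptor_level`), with exclusion —
the stricter reading — as default. Ambiguous reads stay in category
totals but join no feature.

**rsRNA subunit.** Retained rRNA hits that agree on one subunit (subunit
sequences and their repeats collapse) yield that subunit; disagreement
yields `rsRNA_multi`.

# Quantification

`count_features()` tallies counted reads into a feature × sample matrix
and keeps exact per-sample tallies of everything else (ambiguous tRNA,
unannotated, unmapped, length-dropped), so
`Σ feature counts + tallies = total processed reads` per sample — an
invariant the tests enforce. `class_percentages()` reports per-sample
read-class percentages on either of two bases: `all_mapped` (unannotated
"Other" reads in the denominator) or `annotated_only` (renormalized
after removing them); published figures use both conventions, so neither
is hard-coded. `length_partition()` splits reads at 40 nt; a read of
exactly 40 nt goes to the short bucket (strict ">40" reading — the
boundary is not externally assigned), and the cutoff is config-exposed.

# Differential abundance

The differential module is a fully documented, self-contained stand-in for
a general NB GLM stage. Its claims-level behavior (direction + threshold
calls at |log2FC| > 1, padj < 0.05) is what the pipeline's conclusions
rest on; it deliberately implements no dispersion-trend shrinkage, no
fold-change shrinkage, and no outlier replacement, and will not reproduce
any particular external tool's output numerically.

**Normalization.** Median-of-ratios size factors:
`sf_j = median_g count_gj / geomean_g`, over features with nonzero counts
in every sample (optionally a pseudo-reference fallback for sparse
tables). Size factors are reported unnormalized; where they are compared
to true library factors, both sets are first scaled to geometric mean 1,
since only ratios between samples are identifiable. Multiplying one
sample's counts by c multiplies its factor *relative to any other
sample's* by exactly c. The estimator assumes **most counted features are
not differential**; under the KO preset below, where ~20% of counted
features are depleted 4-fold in one direction, the factors of KO samples
absorb part of the depletion (relative errors up to ~20% in our runs).
This is a property of median-of-ratios normalization itself under
asymmetric composition change, and the main reason the default synthetic
annotation carries a broad panel of stable genes.

**Dispersion.** Per feature, a method-of-moments estimate on normalized
counts, `(s² − μ̄)/μ̄²` within condition, averaged across the two
conditions (`estimate_dispersion()`, floored at 1e−8). With three
replicates per group this raw estimate is extremely noisy (≈ 4 residual
degrees of freedom), and plugging it into a Wald test with a normal
reference is badly anti-conservative: in our pilot simulations the
all-null rejection rate at nominal 5% was ~12%. `nb_wald_test()`
therefore moderates: each raw estimate is squeezed toward the
across-feature mean with prior weight `prior_df = 16` (an
empirical-Bayes compromise fixed ahead of the frozen validation runs:
small enough to track genuine dispersion differences at hundreds of
features, large enough to stabilize 4-df moment estimates), and the Wald
statistic is referred to a t distribution on residual + prior degrees of
freedom. In 30-seed pilot runs at the validation conditions (1,000
features, n = 3 vs 3, α = 0.1, base mean 200) this keeps the null
rejection rate at 2.9–5.7% and the Kolmogorov–Smirnov statistic of the
p-value distribution below the 1% critical value, while detecting ≥ 88%
of 4-fold depletions at FDR ≤ 5%.

**The test.** Group means of normalized counts give
`log2FC = log2(μ_KO/μ_WT)`; the delta-method standard error is
`se² = [(1/n_KO)(1/μ_KO + α) + (1/n_WT)(1/μ_WT + α)] / ln(2)²`.
A group that is all zero for a feature receives a 0.5 normalized
pseudo-count so fold changes stay finite; features that are zero
everywhere are reported with NA statistics and excluded from the BH
multiplicity count m (the simplest defensible analogue of independent
filtering). p-values are two-sided from the t reference; BH adjustment
uses `stats::p.adjust`. A feature is significant when |log2FC| exceeds
`lfc_cutoff` (default 1) **and** padj < `alpha` (default 0.05);
`overlap_analysis()` compares significant sets between two analyses using
padj alone by default, since overlap-style comparisons conventionally
drop the fold-change gate — both rules are exposed.

Known limitations: the se formula ignores size-factor estimation noise;
moderation assumes dispersions share a common scale across features; and
under heavy one-sided composition change the normalization bias above
propagates into fold-change estimates of stable features (in the KO
preset runs roughly +0.3 on log2FC of miRNAs, occasionally pushing one
over the significance gate).

# The synthetic data generator

`simulate_srna_experiment()` emulates the statistical structure the
analysis assumes, with known truth at both the read and feature level:

* **Counts.** Per feature and sample,
  `count ~ NB(mean = base_mean · 2^(log2fc·[KO]) · lib_factor, α)` with
  `Var = μ + αμ²`; α = 0 degenerates to Poisson. Library-size factors are
  drawn log-uniform on [0.5, 2] to exercise normalization. Default
  dispersion α = 0.1 matches the differential module's validation
  conditions.
* **Composition.** The default feature table mirrors a tRF-dominant
  epididymal library: ~55% tRF reads (30% tRF_5', 18% tRF_3', 7%
  tRF_other), 25% rsRNA split across subunits, 5% miRNA, <0.5%
  full-length tRNA (end-labeling libraries recover few intact tRNAs),
  and ~15% unannotated. Fragment-length models: tRF_5' 28–36 nt, tRF_3'
  18–22 nt, tRF_other 20–32 nt, rsRNA 20–58 nt, unannotated 20–45 nt;
  these are configurable defaults consistent with reported tRF length
  ranges, not assertions about any particular tissue.
* **The KO preset** applies a uniform log2 fold change (default −2) to
  every tRF-class feature and none to miRNA features — a test-harness
  contrast mirroring the qualitative biology (fragment loss when the
  fragmenting ribonucleases are absent), not a claim about effect sizes.
  Because tRFs are short and the surviving classes include longer rsRNA
  and full-length species, the preset also reproduces the >40-nt shift in
  KO samples.
* **Reads.** Each counted read receives an insert drawn from its
  feature's reference with an interval that respects the classifier's
  tolerance margins (a 5' fragment starts within 3 nt of the transcript
  start *and* ends more than 5 nt from the 3' end, and so on), so on
  error-free data the classifier must recover the truth label exactly —
  any mismatch is a pipeline defect, not generator slack. Raw reads are
  UMI + insert + untemplated base + adapter + spillover, truncated at 120
  cycles (long enough that full-length tRNA reads retain their complete
  adapter, keeping trimming exactly invertible). Substitution errors at a
  configurable per-base rate (default 0: the validation conditions are
  error-free); no indels, ligation bias, RNA-modification effects, PCR
  duplication, or quality-score realism are modeled.

What passing tests show — and what they do not: exact truth recovery on
this generator validates the *logic* of trimming, best-hit resolution,
precedence, fragment typing and counting. It does not certify behavior on
real libraries, where modification-induced misincorporations, indels,
adapter chimeras and reference incompleteness blur category boundaries;
those effects are deliberately out of scope.

# Determinism and problem sizes

Every stochastic step flows from explicit seeds (`sim_config(seed = )`
restores the caller's RNG state afterwards), and rerunning a pipeline
configuration reproduces byte-identical outputs. The validation runs use
6 samples × 50,000 expected reads (≈ 250–320k reads after library-size
variation) for end-to-end truth recovery, 10,000 reads for the trimming
round trip, and 1,000 features at n = 3 vs 3 for the differential
operating characteristics — sizes chosen to make sampling error small
relative to the tested margins while keeping a full validation run in the
low minutes on a single core.
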