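# trflow

Small RNA-seq classification and differential abundance for tRNA-derived
fragments (tRFs) and rRNA-derived small RNAs (rsRNAs).

## The problem

In tissues with high extracellular ribonuclease activity — the epididymal
lumen is the motivating example — most small RNA reads are not miRNAs but
cleavage fragments of abundant structural RNAs: tRFs (subtyped by position
on the mature tRNA as tRF-5', tRF-3', or internal tRF-other) and rsRNAs
(assigned to an rRNA subunit: 18S, 28S, 5.8S, 5S, mitochondrial).
Comparing their abundance between genotypes (e.g. wild-type vs
ribonuclease-knockout) requires a pipeline that handles three things
ordinary RNA-seq tooling does not:

* **reference construction for mature tRNAs** — introns spliced out, the
  post-transcriptional 3' CCA tail appended, a G added at position −1 of
  histidine tRNAs;
* **principled multi-mapping resolution** — tRNA gene families and rRNA
  repeats make most reads multi-mappers; reads are mapped with best-hit
  semantics, resolved to a single primary category with precedence
  tRNA > rRNA > annotated gene > unannotated, typed by position
  (a read is "whole" when its 5' end lies within 3 nt and its 3' end
  within 5 nt of the mature ends), and placed on a specificity tier
  (transcript / decoder = isotype+anticodon / acceptor = isotype /
  ambiguous), with counting at (decoder, fragment type) granularity;
* **differential abundance on few replicates** — median-of-ratios size
  factors, method-of-moments NB dispersions moderated toward the
  across-feature mean (prior df 16), and a Wald test of
  log2FC = log2(μ_KO/μ_WT) with
  se² = [(1/n_KO)(1/μ_KO+α) + (1/n_WT)(1/μ_WT+α)]/ln(2)², referred to a
  t distribution on residual+prior df, BH-adjusted; significance is
  |log2FC| > 1 and padj < 0.05.

A synthetic read generator (OTTR-style layout: 7-nt UMI, insert, one
untemplated base, fixed 3' adapter) emits WT/KO libraries with known
per-read labels and per-feature fold changes, so every stage is validated
end-to-end without downloading anything. The packaged study conditions are
3 vs 3 samples at 50,000 expected reads each with all tRF features
depleted 4-fold in KO.

## Worked example

```r
library(trflow)
library(dplyr)

bundle <- synthetic_reference(seed = 202)
run <- run_pipeline(bundle,
                    sim = sim_config(seed = 101, depth = 50000,
                                     n_per_condition = 3),
                    outdir = tempfile())

run$class_pct$all_mapped |>
  mutate(group = ifelse(grepl("^tRF", class), "tRF", class)) |>
  group_by(sample_id, group) |>
  summarise(percent = sum(percent), .groups = "drop") |>
  tidyr::pivot_wider(names_from = group, values_from = percent)
#>   sample_id Other miRNA rsRNA   tRF whole_tRNA
#> 1 KO1        30.7  8.52  38.1  22.1      0.607
#> 2 KO2        21.5  7.13  50.5  20.3      0.570
#> 3 KO3        29.7  7.14  41.6  21.1      0.551
#> 4 WT1        12.3  4.81  26.9  55.6      0.467
#> 5 WT2        11.8  4.94  28.7  54.0      0.579
#> 6 WT3        14.2  5.42  28.5  51.5      0.363

head(arrange(run$diff, padj), 5)
#>   feature_key       base_mean log2fc    se     pvalue     padj significant
#> 1 Glu-CTC_tRF_3p         521.  -2.72 0.412 0.00000205 0.000297 TRUE
#> 2 Leu-CAA_tRF_5p         638.  -1.95 0.334 0.0000108  0.000784 TRUE
#> 3 Val-CAC_tRF_5p         670.  -1.90 0.346 0.0000233  0.00113  TRUE
#> 4 Phe-GAA_tRF_3p         391.  -1.87 0.354 0.0000374  0.00136  TRUE
#> 5 Arg-TCT_tRF_other      142.  -1.83 0.361 0.0000595  0.00137  TRUE

validate_against_truth(run)[c("category_accuracy", "fragment_accuracy")]
#> $category_accuracy
#> [1] 1
#> $fragment_accuracy
#> [1] 1
```

Reading the output: tRFs fall from ~54% of mapped reads in WT to ~21% in
KO while rsRNA and miRNA shares rise passively; 30 features pass
|log2FC| > 1 & padj < 0.05, of which 29 are tRF features (the truly
depleted class) and the >40-nt read fraction shifts up in KO — the
qualitative signatures of fragment loss. On these error-free synthetic
reads, per-read category and fragment-type classification against the
generator's truth is exact.

The `analysis/` directory holds the same workflow as numbered narrative
drivers (`01_reference.R` … `05_validation.R`), each writing its tables
under `results/`.

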