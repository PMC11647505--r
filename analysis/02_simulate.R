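#!/usr/bin/env Rscript

# Simulate the WT-vs-KO small RNA-seq study: 3 replicates per condition at
# 50,000 expected reads per sample, tRF-dominant composition, and the KO
# preset (log2 fold change -2 on every tRF feature, 0 elsewhere).
# FASTQ files go under scratch/ (regenerable); the truth tables and sample
# sheet under results/.

suppressMessages(library(trflow))

dir.create("results", showWarnings = FALSE)
bundle <- synthetic_reference(seed = 202)
cfg <- sim_config(seed = 101, depth = 50000, n_per_condition = 3)
sim <- simulate_srna_experiment(bundle, cfg, outdir = "scratch/fastq")
print(sim)

invisible(file.copy("scratch/fastq/samples.tsv", "results/samples.tsv",
                    overwrite = TRUE))
invisible(file.copy("scratch/fastq/truth_counts.tsv",
                    "results/truth_counts.tsv", overwrite = TRUE))

tab <- table(sim$truth$true_class)
message("simulated read mixture:")
print(round(100 * prop.table(tab), 2))
message("FASTQ under scratch/fastq; truth tables under results/")
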