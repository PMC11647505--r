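test_that("count simulation matches its NB/Poisson model", {
  feats <- tibble::tibble(
    feature_key = sprintf("f%04d", 1:1000), class = "miRNA",
    ref_group = list("miR-001"), base_mean = 100, dispersion = 0,
    log2fc = 0
  )
  cfg <- sim_config(seed = 11, n_per_condition = 5,
                    lib_factor_range = c(1, 1))
  cs <- simulate_counts(feats, cfg)
  draws <- as.vector(cs$counts)  # 10,000 Poisson(100) draws
  expect_length(draws, 10000)
  se <- sqrt(100 / length(draws))
  expect_lt(abs(mean(draws) - 100), 3 * se)
  # Poisson variance, generous 4-SE bound on the sample variance
  expect_lt(abs(var(draws) - 100), 4 * sqrt(2 * 100^2 / length(draws)))

  # KO depletion scales the mean by 2^log2fc
  feats$log2fc <- -2
  cs2 <- simulate_counts(feats, cfg)
  ko <- cs2$samples$condition == "KO"
  expect_lt(abs(mean(cs2$counts[, ko]) - 25), 3 * sqrt(25 / 5000))
  expect_lt(abs(mean(cs2$counts[, !ko]) - 100), 3 * sqrt(100 / 5000))

  # degenerate: no samples
  cs0 <- simulate_counts(feats, sim_config(seed = 1, n_per_condition = 0))
  expect_equal(ncol(cs0$counts), 0)
  expect_equal(nrow(cs0$samples), 0)
})

test_that("fragment drawing respects class positional constraints", {
  b <- tiny_bundle()
  cfg <- sim_config(seed = 3)
  set.seed(31)
  gly_ids <- c("tRNA-Gly-GCC-1", "tRNA-Gly-GCC-2")
  L <- nchar(ref_seq(b, "tRNA-Gly-GCC-1"))
  for (cls in c("tRF_5p", "tRF_3p", "tRF_other", "whole_tRNA")) {
    d <- draw_fragment("f", cls, gly_ids, b, 300, cfg)
    d5 <- d$start
    d3 <- L - d$end
    lab <- vapply(seq_len(nrow(d)), function(i) {
      oracle_fragment_type(d$start[i], d$end[i], L)
    }, character(1))
    expected <- if (cls == "whole_tRNA") "whole" else cls
    expect_true(all(lab == expected), label = paste("class", cls))
    # insert sequence is the recorded interval on the reference
    ref <- ref_seq(b, d$ref_id[1])
    expect_identical(d$insert,
                     substring(ref, d$start + 1L, d$end))
  }
  # rsRNA inserts are substrings of the assigned subunit's references
  dr <- draw_fragment("5S", "rsRNA:5S", c("rRNA_5S", "rRNA_5S_repeat1"),
                      b, 100, cfg)
  for (i in seq_len(nrow(dr))) {
    expect_identical(dr$insert[i],
                     substring(ref_seq(b, dr$ref_id[i]), dr$start[i] + 1L,
                               dr$end[i]))
  }
  # reference shorter than the requested fragment range errors out
  expect_error(
    draw_fragment("m", "unannotated", "miR-001", b, 5,
                  sim_config(seed = 1,
                             length_models = list(unannotated = c(40, 45)))),
    "short")
})

test_that("raw read layout is UMI + insert + extra base + adapter", {
  cfg <- sim_config(seed = 5, read_length = 60)
  set.seed(8)
  ins <- tibble::tibble(read_id = "r1", insert = "GCATGCATGCATGCATGC")
  raw <- build_raw_reads(ins, cfg)
  expect_equal(nchar(raw$seq), 60)
  expect_equal(substr(raw$seq, 1, 7), raw$umi)
  expect_equal(substr(raw$seq, 8, 25), ins$insert)
  expect_equal(substr(raw$seq, 27, 46), cfg$adapter)
  # trimming inverts the construction
  tr <- trim_reads(raw, cfg$adapter)
  expect_equal(tr$insert, ins$insert)
  expect_equal(tr$umi, raw$umi)
})

test_that("simulation is deterministic and label mixture matches config", {
  b <- tiny_bundle()
  cfg <- sim_config(seed = 21, depth = 3000, n_per_condition = 2)
  feats <- tibble::tibble(
    feature_key = c("gly5p", "s5", "m1"),
    class = c("tRF_5p", "rsRNA:5S", "miRNA"),
    ref_group = list(c("tRNA-Gly-GCC-1", "tRNA-Gly-GCC-2"), "rRNA_5S",
                     "miR-001"),
    base_mean = c(1500, 900, 600), dispersion = 0,
    log2fc = c(-2, 0, 0)
  )
  s1 <- simulate_srna_experiment(b, cfg, features = feats)
  s2 <- simulate_srna_experiment(b, cfg, features = feats)
  expect_identical(s1$raw_reads, s2$raw_reads)
  expect_identical(s1$truth, s2$truth)
  # one truth record per emitted read
  expect_identical(sort(s1$truth$read_id), sort(s1$raw_reads$read_id))
  # per-sample read count equals the simulated count total
  per <- table(s1$truth$sample_id)
  expect_equal(as.integer(per[colnames(s1$counts)]),
               unname(colSums(s1$counts)))
  # class mixture within multinomial error of configuration (WT samples)
  wt <- s1$truth[s1$truth$sample_id %in% c("WT1", "WT2"), ]
  props <- prop.table(table(wt$true_class))
  expcfg <- c(miRNA = 600, `rsRNA:5S` = 900, tRF_5p = 1500) / 3000
  for (cl in names(expcfg)) {
    p <- expcfg[[cl]]
    tol <- 4 * sqrt(p * (1 - p) / nrow(wt))
    expect_lt(abs(props[[cl]] - p), tol)
  }
})

test_that("FASTQ emission writes byte-identical files for a fixed seed", {
  b <- tiny_bundle()
  cfg <- sim_config(seed = 77, depth = 400, n_per_condition = 1)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_srna_experiment(b, cfg, outdir = d1)
  s2 <- simulate_srna_experiment(b, cfg, outdir = d2)
  f1 <- sort(s1$fastq$path)
  f2 <- sort(s2$fastq$path)
  expect_equal(length(f1), 2)  # 1 WT + 1 KO
  for (i in seq_along(f1)) {
    r1 <- read_fastq(f1[i])
    expect_identical(r1, read_fastq(f2[i]))
    # record count equals reads simulated for that sample
    sid <- sub("\\.fastq.*$", "", basename(f1[i]))
    expect_equal(nrow(r1), sum(s1$truth$sample_id == sid))
  }
})
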