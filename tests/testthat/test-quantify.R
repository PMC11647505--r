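mk_ann <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      read_id = r[["id"]], sample_id = r[["s"]] %||% "S1",
      category = r[["cat"]], fragment_type = r[["frag"]] %||% NA_character_,
      specificity = r[["spec"]] %||% NA_character_,
      feature_key = r[["key"]] %||% NA_character_,
      biotype = r[["bio"]] %||% NA_character_,
      insert_len = r[["len"]] %||% 30L,
      counted = r[["counted"]] %||% TRUE, kept = r[["kept"]] %||% TRUE,
      drop_reason = NA_character_
    )
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("feature counting keys and tallies are exact", {
  ann <- mk_ann(
    list(id = "r1", cat = "tRNA", frag = "tRF_5p", spec = "decoder",
         key = "Gly-GCC_tRF_5p"),
    list(id = "r2", cat = "tRNA", frag = "tRF_5p", spec = "decoder",
         key = "Gly-GCC_tRF_5p"),
    list(id = "r3", cat = "rsRNA", key = "5S"),
    list(id = "r4", cat = "tRNA", frag = "tRF_3p", spec = "ambiguous",
         key = NA, counted = FALSE),
    list(id = "r5", cat = "unannotated", key = NA, counted = FALSE),
    list(id = "r6", cat = "unmapped", key = NA, counted = FALSE)
  )
  samples <- tibble::tibble(sample_id = "S1", condition = "WT")
  ct <- count_features(ann, samples)
  expect_equal(ct$counts["Gly-GCC_tRF_5p", "S1"], 2L)
  expect_equal(ct$counts["5S", "S1"], 1L)
  expect_equal(nrow(ct$counts), 2)
  expect_equal(ct$tallies$ambiguous_trna, 1L)
  expect_equal(ct$tallies$unannotated, 1L)
  expect_equal(ct$tallies$unmapped, 1L)
  # conservation: counted + tallies == total
  with(ct$tallies, expect_equal(counted + ambiguous_trna + unannotated +
                                  unmapped + dropped, total))
  expect_error(count_features(ann, tibble::tibble(sample_id = "S9",
                                                  condition = "WT")),
               "S1")
  # empty annotation set keeps the sample columns
  ct0 <- count_features(ann[0, ], samples)
  expect_equal(dim(ct0$counts), c(0L, 1L))
})

test_that("class percentages renormalize by basis", {
  ann <- dplyr::bind_rows(
    do.call(mk_ann, lapply(1:40, function(i) {
      list(id = paste0("t", i), cat = "tRNA", frag = "tRF_5p",
           spec = "decoder", key = "Gly-GCC_tRF_5p")
    })),
    do.call(mk_ann, lapply(1:40, function(i) {
      list(id = paste0("r", i), cat = "rsRNA", key = "5S")
    })),
    do.call(mk_ann, lapply(1:20, function(i) {
      list(id = paste0("o", i), cat = "unannotated", counted = FALSE)
    }))
  )
  pall <- class_percentages(ann, "all_mapped")
  expect_equal(sum(pall$percent), 100)
  expect_equal(pall$percent[pall$class == "tRF_5p"], 40)
  expect_equal(pall$percent[pall$class == "Other"], 20)
  pann <- class_percentages(ann, "annotated_only")
  expect_equal(sum(pann$percent), 100)
  expect_equal(pann$percent[pann$class == "tRF_5p"], 50)
  expect_equal(pann$percent[pann$class == "rsRNA"], 50)
  # single-class library
  one <- mk_ann(list(id = "x", cat = "rsRNA", key = "5S"))
  expect_equal(class_percentages(one)$percent, 100)
  expect_error(class_percentages(one[0, ]), "no mapped")
})

test_that("length partition is strict at the cutoff", {
  ann <- mk_ann(
    list(id = "a", cat = "rsRNA", key = "5S", len = 30L),
    list(id = "b", cat = "rsRNA", key = "5S", len = 45L),
    list(id = "c", cat = "rsRNA", key = "5S", len = 40L)
  )
  lp <- length_partition(ann, cutoff = 40)
  r <- lp[lp$class == "rsRNA", ]
  expect_equal(r$n_long, 1L)   # only 45 is long; 40 goes short
  expect_equal(r$n_short, 2L)
  expect_equal(r$frac_long, 1 / 3)
  all_row <- lp[lp$class == "all", ]
  expect_equal(all_row$n_long + all_row$n_short, 3L)
  # empty classes are reported as NA when requested
  lp2 <- length_partition(ann, cutoff = 40, classes = c("rsRNA", "miRNA"))
  expect_true(is.na(lp2$frac_long[lp2$class == "miRNA"]))
})

test_that("per-sample percentages always sum to 100 on simulated data", {
  b <- tiny_bundle()
  cfg <- sim_config(seed = 29, depth = 2000, n_per_condition = 2)
  sim <- simulate_srna_experiment(b, cfg)
  pr <- length_filter(trim_reads(sim$raw_reads, cfg$adapter))
  hits <- map_reads(unique(pr$insert[!pr$discarded]), b)
  ann <- annotate_reads(pr, hits, b)
  for (basis in c("all_mapped", "annotated_only")) {
    pct <- class_percentages(ann, basis)
    sums <- tapply(pct$percent, pct$sample_id, sum)
    expect_true(all(abs(sums - 100) < 1e-9), label = basis)
  }
  lp <- length_partition(ann)
  per_class <- lp[lp$class != "all", ]
  totals <- tapply(per_class$n_long + per_class$n_short, per_class$sample_id,
                   sum)
  all_rows <- lp[lp$class == "all", ]
  expect_equal(as.integer(totals[all_rows$sample_id]),
               all_rows$n_long + all_rows$n_short)
})
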