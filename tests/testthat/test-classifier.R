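test_that("fragment typing follows the positional rules", {
  p <- classifier_params()
  expect_equal(classify_trna_fragment(0, 76, 76, p), "whole")
  expect_equal(classify_trna_fragment(3, 71, 76, p), "whole")  # d5=3, d3=5
  expect_equal(classify_trna_fragment(0, 34, 76, p), "tRF_5p")
  expect_equal(classify_trna_fragment(46, 76, 76, p), "tRF_3p")
  expect_equal(classify_trna_fragment(20, 50, 76, p), "tRF_other")
  expect_equal(classify_trna_fragment(4, 70, 76, p), "tRF_other")
  expect_error(classify_trna_fragment(-1, 30, 76, p), "interval")
  expect_error(classify_trna_fragment(10, 80, 76, p), "interval")
})

test_that("fragment typing matches brute force on all substrings", {
  L <- 76L
  for (st in 0:(L - 1)) {
    ends <- (st + 1):L
    got <- classify_trna_fragment(rep(st, length(ends)), ends, L)
    want <- vapply(ends, function(e) oracle_fragment_type(st, e, L),
                   character(1))
    expect_identical(got, want)
  }
})

test_that("reads far from both ends are tRF_other under any rule order", {
  set.seed(2)
  L <- 76L
  for (i in 1:200) {
    st <- sample(4:60, 1)
    en <- sample(st + 1:10, 1)
    en <- min(en, L - 6L)
    if (en <= st) next
    # all 3! orderings of the whole/5p/3p checks agree here
    expect_equal(classify_trna_fragment(st, en, L), "tRF_other")
    expect_equal(oracle_fragment_type(st, en, L), "tRF_other")
  }
})

test_that("category precedence resolves mixed hit sets", {
  b <- tiny_bundle()
  gly <- ref_seq(b, "tRNA-Gly-GCC-1")
  mk_hits <- function(...) {
    rows <- list(...)
    dplyr::bind_rows(lapply(rows, function(r) {
      tibble::tibble(insert = "X", ref_id = r[[1]],
                     ref_class = b$refs$class[b$refs$ref_id == r[[1]]],
                     start = r[[2]], end = r[[3]],
                     strand = if (length(r) > 3) r[[4]] else "+",
                     mismatches = 0L)
    })) |> dplyr::mutate(hit_rank = dplyr::row_number())
  }
  # tRNA beats background
  rc <- resolve_category(mk_hits(list("tRNA-Gly-GCC-1", 0L, 30L),
                                 list("background_01", 5L, 35L)), b)
  expect_equal(rc$category, "tRNA")
  expect_equal(rc$retained$ref_id, "tRNA-Gly-GCC-1")
  expect_equal(rc$primary$ref_id, "tRNA-Gly-GCC-1")
  # rRNA repeat beats background
  rc2 <- resolve_category(mk_hits(list("rRNA_5S_repeat1", 0L, 20L),
                                  list("background_01", 5L, 25L)), b)
  expect_equal(rc2$category, "rsRNA")
  # background only
  rc3 <- resolve_category(mk_hits(list("background_01", 0L, 20L)), b)
  expect_equal(rc3$category, "unannotated")
  # empty
  rc4 <- resolve_category(mk_hits(list("background_01", 0L, 20L))[0, ], b)
  expect_equal(rc4$category, "unmapped")
  # antisense tRNA hits do not count as tRNA
  rc5 <- resolve_category(mk_hits(list("tRNA-Gly-GCC-1", 0L, 30L, "-")), b)
  expect_equal(rc5$category, "unannotated")
})

test_that("specificity tiers depend on the retained hit set", {
  b <- tiny_bundle()
  hit <- function(ids) tibble::tibble(ref_id = ids)
  s1 <- classify_trna_specificity(hit(c("tRNA-Gly-GCC-1",
                                        "tRNA-Gly-GCC-2")), b)
  expect_equal(s1$specificity, "decoder")
  expect_equal(s1$feature_key, "Gly-GCC")
  s2 <- classify_trna_specificity(hit(c("tRNA-Gly-GCC-1",
                                        "tRNA-Gly-CCC-1")), b)
  expect_equal(s2$specificity, "acceptor")
  expect_equal(s2$feature_key, "Gly")
  s3 <- classify_trna_specificity(hit("tRNA-Val-CAC-2"), b)
  expect_equal(s3$specificity, "transcript")
  expect_equal(s3$feature_key, "Val-CAC")
  s4 <- classify_trna_specificity(hit(c("tRNA-Gly-GCC-1",
                                        "tRNA-Val-CAC-2")), b)
  expect_equal(s4$specificity, "ambiguous")
})

test_that("rsRNA subunit assignment collapses repeats", {
  b <- tiny_bundle()
  hit <- function(ids) tibble::tibble(ref_id = ids)
  expect_equal(classify_rsrna_subunit(hit(c("rRNA_5S", "rRNA_5S_repeat1")),
                                      b), "5S")
  expect_equal(classify_rsrna_subunit(hit(c("rRNA_5S", "rRNA_18S")), b),
               "rsRNA_multi")
  expect_equal(classify_rsrna_subunit(hit("rRNA_18S"), b), "18S")
})

test_that("every processed read gets exactly one category", {
  b <- tiny_bundle()
  cfg <- sim_config(seed = 17, depth = 2500, n_per_condition = 1)
  sim <- simulate_srna_experiment(b, cfg)
  pr <- length_filter(trim_reads(sim$raw_reads, cfg$adapter))
  hits <- map_reads(unique(pr$insert[!pr$discarded]), b)
  ann <- annotate_reads(pr, hits, b)
  expect_equal(nrow(ann), sum(!pr$discarded))
  expect_false(any(is.na(ann$category)))
  tab <- table(ann$category)
  expect_equal(sum(tab), sum(!pr$discarded))
  # fragment type is defined iff category is tRNA
  expect_true(all(is.na(ann$fragment_type) != (ann$category == "tRNA")))
})

test_that("short reads survive only as tRNA", {
  b <- tiny_bundle()
  gly <- ref_seq(b, "tRNA-Gly-GCC-1")
  bg <- ref_seq(b, "background_01")
  ad <- "GATCGGAAGAGCACACGTCT"
  raw <- tibble::tibble(
    read_id = c("trna15", "bg15", "trna14", "bg20"),
    seq = paste0(strrep("A", 7),
                 c(substr(gly, 1, 15), substr(bg, 1, 15),
                   substr(gly, 1, 14), substr(bg, 1, 20)),
                 "T", ad),
    qual = "I"
  )
  raw$qual <- strrep("I", nchar(raw$seq))
  pr <- length_filter(trim_reads(raw, ad), min_non_trna = 16)
  hits <- map_reads(unique(pr$insert[!pr$discarded]), b)
  ann <- annotate_reads(pr, hits, b, min_trna_len = 15)
  ann <- ann[match(raw$read_id, ann$read_id), ]
  expect_equal(ann$kept, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(ann$drop_reason, c(NA, "short_non_trna", "short_trna", NA))
  expect_equal(ann$category[1], "tRNA")
})
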