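#' Run the full small-RNA analysis pipeline
#'
#' simulate (optional) -> trim -> map -> classify -> quantify ->
#' differential test, with per-stage read accounting and a JSON manifest.
#' Inputs are either a simulation config (FASTQ written then re-read, so
#' the run exercises the on-disk formats) or existing FASTQ files listed in
#' a sample sheet.
#'
#' @param bundle a `trf_reference_bundle`.
#' @param sim a `trf_sim_config` to generate input data, or `NULL`.
#' @param fastq_sheet tibble `sample_id`, `condition`, `path` when running
#'   on existing FASTQ files (ignored when `sim` is given).
#' @param outdir output directory for FASTQ (simulated runs), stage TSVs
#'   and the manifest.
#' @param params a [classifier_params()].
#' @param diff a [diff_params()].
#' @param max_mismatches,max_hits mapper settings.
#' @param min_non_trna minimum non-tRNA insert length.
#' @param min_trna_len minimum tRNA insert length.
#' @param length_cutoff long/short partition threshold.
#' @param write_tables write stage outputs as TSVs under `outdir`.
#' @return a `trf_run` list: `annotations`, `count_table`, `class_pct`
#'   (both bases), `length_part`, `diff` (when two conditions present),
#'   `accounting`, `manifest`, and `sim` (the simulation, for simulated
#'   runs).
#' @export
run_pipeline <- function(bundle, sim = NULL, fastq_sheet = NULL,
                         outdir = tempfile("trflow_run_"),
                         params = classifier_params(),
                         diff = diff_params(), max_mismatches = 1L,
                         max_hits = 100L, min_non_trna = 16L,
                         min_trna_len = 15L, length_cutoff = 40L,
                         write_tables = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sim) && is.null(fastq_sheet)) {
    stop("provide either a simulation config or a FASTQ sample sheet")
  }
  simulation <- NULL
  if (!is.null(sim)) {
    simulation <- simulate_srna_experiment(bundle, sim,
                                           outdir = file.path(outdir,
                                                              "fastq"))
    fastq_sheet <- simulation$fastq |>
      left_join(simulation$samples, by = "sample_id")
    adapter <- sim$adapter
    umi_len <- sim$umi_len
    trailing <- sim$trailing_bases
  } else {
    missing_files <- fastq_sheet$path[!file.exists(fastq_sheet$path)]
    if (length(missing_files) > 0) {
      stop("missing FASTQ file(s): ", paste(missing_files, collapse = ", "))
    }
    adapter <- "GATCGGAAGAGCACACGTCT"
    umi_len <- 7L
    trailing <- 1L
  }

  raw <- dplyr::bind_rows(lapply(seq_len(nrow(fastq_sheet)), function(i) {
    r <- read_fastq(fastq_sheet$path[i])
    r$sample_id <- fastq_sheet$sample_id[i]
    r
  }))

  processed <- trim_reads(raw, adapter = adapter, umi_len = umi_len,
                          trailing = trailing)
  processed <- length_filter(processed, min_non_trna = min_non_trna)

  live_inserts <- unique(processed$insert[!processed$discarded])
  hits <- map_reads(live_inserts, bundle, max_mismatches = max_mismatches,
                    max_hits = max_hits)
  ann <- annotate_reads(processed, hits, bundle, params = params,
                        min_trna_len = min_trna_len)
  samples <- fastq_sheet[, c("sample_id", "condition")]
  ct <- count_features(ann, samples)
  class_pct <- list(
    all_mapped = class_percentages(ann, "all_mapped"),
    annotated_only = class_percentages(ann, "annotated_only")
  )
  length_part <- length_partition(ann, cutoff = length_cutoff)

  diff_res <- NULL
  if (length(unique(samples$condition)) == 2 &&
      all(table(samples$condition) >= 2)) {
    diff_res <- nb_wald_test(ct, params = diff)
  }

  accounting <- processed |>
    group_by(.data$sample_id) |>
    summarise(raw = n(), trimmed = sum(!.data$discarded),
              discarded = sum(.data$discarded), .groups = "drop") |>
    left_join(ct$tallies, by = "sample_id")

  manifest <- list(
    package_version = as.character(utils::packageVersion("trflow")),
    seed = if (!is.null(sim)) sim$seed else NA,
    parameters = list(
      adapter = adapter, umi_len = umi_len, trailing = trailing,
      max_mismatches = max_mismatches, max_hits = max_hits,
      min_non_trna = min_non_trna, min_trna_len = min_trna_len,
      length_cutoff = length_cutoff,
      classifier = unclass(params), diff = unclass(diff)
    ),
    accounting = accounting
  )
  run <- list(annotations = ann, count_table = ct, class_pct = class_pct,
              length_part = length_part, diff = diff_res,
              accounting = accounting, manifest = manifest,
              sim = simulation, outdir = outdir)
  class(run) <- "trf_run"
  if (write_tables) {
    readr::write_tsv(ann[, setdiff(names(ann), "insert")],
                     file.path(outdir, "annotations.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(ct$counts, rownames = "feature_key"),
                     file.path(outdir, "counts.tsv"), progress = FALSE)
    readr::write_tsv(class_pct$all_mapped,
                     file.path(outdir, "class_percent_all_mapped.tsv"),
                     progress = FALSE)
    readr::write_tsv(class_pct$annotated_only,
                     file.path(outdir, "class_percent_annotated_only.tsv"),
                     progress = FALSE)
    readr::write_tsv(length_part, file.path(outdir, "length_partition.tsv"),
                     progress = FALSE)
    if (!is.null(diff_res)) {
      readr::write_tsv(diff_res, file.path(outdir, "differential.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.trf_run <- function(x, ...) {
  cat("<trf_run> ", sum(x$accounting$raw), " raw reads, ",
      nrow(x$count_table$counts), " features, ",
      nrow(x$accounting), " samples\n", sep = "")
  invisible(x)
}

#' Compare a pipeline run against simulation ground truth
#'
#' @param run a `trf_run` produced from a simulated input.
#' @param sim the matching `trf_simulation` (defaults to the one embedded
#'   in the run).
#' @param lfc_cutoff truth threshold: a feature is truly differential when
#'   `|true log2fc| > lfc_cutoff`.
#' @return list of accuracy metrics: per-read `category_accuracy` and
#'   `fragment_accuracy`, `size_factor_max_rel_err` (after normalizing
#'   both factor sets to geometric mean 1), and DE `sensitivity` and
#'   `fdr` against the true fold changes (NA when undefined).
#' @export
validate_against_truth <- function(run, sim = NULL, lfc_cutoff = 1) {
  if (is.null(sim)) sim <- run$sim
  if (is.null(sim)) stop("run has no attached simulation truth")
  ann <- run$annotations
  truth <- sim$truth
  if (!all(ann$read_id %in% truth$read_id)) {
    stop("read ids in run do not match simulation truth")
  }
  m <- truth[match(ann$read_id, truth$read_id), ]
  expected_category <- ifelse(
    m$true_class %in% c("tRF_5p", "tRF_3p", "tRF_other", "whole_tRNA"),
    "tRNA",
    ifelse(startsWith(m$true_class, "rsRNA"), "rsRNA",
           ifelse(m$true_class == "miRNA", "annotated_gene",
                  "unannotated")))
  category_accuracy <- mean(ann$category == expected_category)
  is_t <- expected_category == "tRNA"
  expected_fragment <- ifelse(m$true_class == "whole_tRNA", "whole",
                              m$true_class)
  fragment_accuracy <- if (any(is_t)) {
    mean(ann$fragment_type[is_t] == expected_fragment[is_t])
  } else NA_real_

  sf_metric <- NA_real_
  if (!is.null(run$diff)) {
    est <- attr(run$diff, "size_factors")
    tru <- setNames(sim$samples$lib_factor, sim$samples$sample_id)
    tru <- tru[names(est)]
    est_n <- est / exp(mean(log(est)))
    tru_n <- tru / exp(mean(log(tru)))
    sf_metric <- max(abs(est_n / tru_n - 1))
  }

  sens <- fdr <- NA_real_
  if (!is.null(run$diff)) {
    truth_lfc <- setNames(sim$features$log2fc, sim$features$feature_key)
    res <- run$diff[run$diff$feature_key %in% names(truth_lfc), ]
    tl <- truth_lfc[res$feature_key]
    true_de <- abs(tl) > lfc_cutoff
    called <- res$significant
    if (any(true_de)) sens <- mean(called[true_de])
    if (any(called)) fdr <- sum(called & !true_de) / sum(called) else fdr <- 0
  }
  list(category_accuracy = category_accuracy,
       fragment_accuracy = fragment_accuracy,
       size_factor_max_rel_err = sf_metric,
       sensitivity = sens, fdr = fdr)
}
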