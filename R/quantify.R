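#' Aggregate read annotations into a feature count table
#'
#' tRNA reads are counted under (decoder key, fragment type) when their
#' specificity tier is transcript or decoder; rsRNA reads under their
#' subunit; annotated-gene reads under their reference id. Ambiguous tRNA,
#' unannotated, unmapped and length-dropped reads are excluded from
#' features but tallied, so per-sample read accounting is exact.
#'
#' @param annotations output of [annotate_reads()].
#' @param samples tibble with `sample_id` and `condition`.
#' @return a `trf_count_table`: list with `counts` (feature x sample
#'   integer matrix), `features` (feature_key, class), `samples`, and
#'   `tallies` (per-sample counts of ambiguous tRNA, unannotated, unmapped
#'   and dropped reads).
#' @export
count_features <- function(annotations, samples) {
  if (!all(annotations$sample_id %in% samples$sample_id)) {
    bad <- setdiff(unique(annotations$sample_id), samples$sample_id)
    stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  }
  cnt <- annotations[annotations$counted & annotations$kept, ]
  keys <- sort(unique(cnt$feature_key))
  counts <- matrix(0L, length(keys), nrow(samples),
                   dimnames = list(keys, samples$sample_id))
  if (nrow(cnt) > 0) {
    tab <- table(factor(cnt$feature_key, levels = keys),
                 factor(cnt$sample_id, levels = samples$sample_id))
    counts[] <- as.integer(tab)
  }
  cls <- cnt$category[match(keys, cnt$feature_key)]
  frag <- cnt$fragment_type[match(keys, cnt$feature_key)]
  features <- tibble(
    feature_key = keys,
    class = ifelse(cls == "tRNA", frag,
                   ifelse(cls == "rsRNA", "rsRNA", "annotated_gene"))
  )
  tal <- annotations |>
    group_by(.data$sample_id) |>
    summarise(
      total = n(),
      n_counted = sum(.data$counted & .data$kept),
      ambiguous_trna = sum(.data$kept & .data$category == "tRNA" &
                             !.data$counted),
      unannotated = sum(.data$kept & .data$category == "unannotated"),
      unmapped = sum(.data$kept & .data$category == "unmapped"),
      dropped = sum(!.data$kept),
      .groups = "drop"
    ) |>
    dplyr::rename(counted = "n_counted")
  structure(list(counts = counts, features = features, samples = samples,
                 tallies = tal), class = "trf_count_table")
}

#' @export
print.trf_count_table <- function(x, ...) {
  cat("<trf_count_table> ", nrow(x$counts), " features x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

# read-level class label used by the percentage and length summaries
.read_class <- function(annotations) {
  ifelse(annotations$category == "tRNA",
         ifelse(annotations$fragment_type == "whole", "whole_tRNA",
                annotations$fragment_type),
         ifelse(annotations$category == "rsRNA", "rsRNA",
                ifelse(annotations$category == "annotated_gene",
                       annotations$biotype, "Other")))
}

#' Per-sample percentage of reads per small-RNA class
#'
#' Classes are tRF_5p / tRF_3p / tRF_other / whole_tRNA, rsRNA, annotated
#' biotypes (e.g. miRNA), and "Other" for mapped-but-unannotated reads.
#' With `basis = "all_mapped"` the Other reads are included in the
#' denominator; with `basis = "annotated_only"` they are removed and the
#' percentages renormalized.
#'
#' @param annotations output of [annotate_reads()] (kept, mapped reads are
#'   summarized).
#' @param basis `"all_mapped"` or `"annotated_only"`.
#' @return tibble: `sample_id`, `class`, `n`, `percent`; percentages sum to
#'   100 per sample.
#' @export
class_percentages <- function(annotations,
                              basis = c("all_mapped", "annotated_only")) {
  basis <- match.arg(basis)
  ann <- annotations[annotations$kept &
                       annotations$category != "unmapped", ]
  ann$class <- .read_class(ann)
  if (basis == "annotated_only") ann <- ann[ann$class != "Other", ]
  if (nrow(ann) == 0) stop("no mapped reads to summarize")
  out <- ann |>
    group_by(.data$sample_id, .data$class) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  out
}

#' Long/short read partition at a length cutoff
#'
#' Each read is "long" iff its insert is strictly longer than the cutoff
#' (a read of exactly 40 nt goes to the short bucket). Fractions are
#' reported per class and for all reads pooled (`class == "all"`).
#'
#' @param annotations output of [annotate_reads()].
#' @param cutoff length threshold in nucleotides.
#' @param classes optional class labels to report; classes with no reads
#'   get zero counts and `frac_long = NA`.
#' @return tibble: `sample_id`, `class`, `n_long`, `n_short`, `frac_long`
#'   (NA for empty classes).
#' @export
length_partition <- function(annotations, cutoff = 40L, classes = NULL) {
  ann <- annotations[annotations$kept &
                       annotations$category != "unmapped", ]
  ann$class <- .read_class(ann)
  pooled <- ann
  pooled$class <- "all"
  out <- dplyr::bind_rows(ann, pooled) |>
    group_by(.data$sample_id, .data$class) |>
    summarise(
      n_long = sum(.data$insert_len > cutoff),
      n_short = sum(.data$insert_len <= cutoff),
      .groups = "drop"
    )
  if (!is.null(classes)) {
    grid <- .class_grid(unique(ann$sample_id),
                                union(classes, "all"))
    out <- grid |> left_join(out, by = c("sample_id", "class"))
    out$n_long[is.na(out$n_long)] <- 0L
    out$n_short[is.na(out$n_short)] <- 0L
  }
  out |>
    mutate(frac_long = ifelse(.data$n_long + .data$n_short > 0,
                              .data$n_long / (.data$n_long + .data$n_short),
                              NA_real_))
}

# sample-by-class grid as a tibble
.class_grid <- function(sample_id, class) {
  g <- expand.grid(class = class, sample_id = sample_id,
                   stringsAsFactors = FALSE)
  tibble(sample_id = g$sample_id, class = g$class)
}
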