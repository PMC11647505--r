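#' Trim raw small-RNA reads to inserts
#'
#' Applies the three trimming steps in order: (1) remove the 3' adapter from
#' its earliest occurrence (up to 10% mismatches over the matched length,
#' minimum overlap 3; a truncated match is allowed where the read ends);
#' (2) remove the final untemplated base(s); (3) remove the UMI prefix,
#' keeping it alongside the insert. Reads too short for the layout are
#' flagged discarded, never dropped, so read accounting stays exact.
#' Reads with no adapter occurrence are kept untrimmed at step 1 (inserts
#' longer than the cycle count legitimately lack adapter).
#'
#' @param reads tibble with `read_id`, `seq`, and optionally `qual`,
#'   `sample_id`.
#' @param adapter 3' adapter sequence.
#' @param umi_len UMI prefix length.
#' @param trailing number of untemplated 3' bases to remove.
#' @param max_error_rate adapter-match mismatch tolerance (fraction of the
#'   matched length).
#' @param min_overlap minimum adapter overlap at the read end.
#' @return tibble: input columns plus `insert`, `umi`, `insert_len`,
#'   `discarded`, `reason`.
#' @export
trim_reads <- function(reads, adapter = "GATCGGAAGAGCACACGTCT",
                       umi_len = 7L, trailing = 1L, max_error_rate = 0.1,
                       min_overlap = 3L) {
  stopifnot(nzchar(adapter), umi_len >= 0)
  pos <- cpp_find_adapter(reads$seq, adapter, max_error_rate,
                          as.integer(min_overlap))
  kept <- ifelse(pos >= 0, substr(reads$seq, 1L, pos), reads$seq)
  min_len <- umi_len + trailing + 1L
  ok <- nchar(kept) >= min_len
  insert <- rep(NA_character_, nrow(reads))
  umi <- rep(NA_character_, nrow(reads))
  insert[ok] <- substr(kept[ok], umi_len + 1L, nchar(kept[ok]) - trailing)
  umi[ok] <- substr(kept[ok], 1L, umi_len)
  out <- reads
  out$insert <- insert
  out$umi <- umi
  out$insert_len <- ifelse(ok, nchar(insert), NA_integer_)
  out$discarded <- !ok
  out$reason <- ifelse(ok, NA_character_, "too_short")
  out
}

#' Flag reads below the non-tRNA minimum length
#'
#' The minimum read size applies to non-tRNA reads only, and a read's
#' category is not known until after mapping; the flag is therefore recorded
#' here and consumed by the classifier, which drops flagged reads unless
#' they resolve to the tRNA category.
#'
#' @param processed output of [trim_reads()].
#' @param min_non_trna minimum insert length for non-tRNA reads.
#' @return `processed` with a logical `short_flag` column (NA for discarded
#'   reads).
#' @export
length_filter <- function(processed, min_non_trna = 16L) {
  processed$short_flag <- !processed$discarded &
    processed$insert_len < min_non_trna
  processed$short_flag[processed$discarded] <- NA
  processed
}
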