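.class_rank <- c(trna = 1L, rrna = 2L, gene = 3L, background = 4L)

#' Map inserts to the reference bundle
#'
#' Ungapped end-to-end alignment with Hamming distance, both strands. For
#' each insert, only alignments achieving the minimum edit distance (and at
#' most `max_mismatches`) are returned — the "all best mappings" contract
#' the classifier consumes. Ns never match and so cost one mismatch each.
#' Hits are ordered deterministically by (class rank tRNA < rRNA <
#' annotated gene < background, ref_id, start, strand) and truncated at
#' `max_hits`, so the cap can never drop a tRNA hit in favor of a
#' background hit.
#'
#' @param inserts character vector of insert sequences (duplicates are
#'   mapped once and expanded back).
#' @param bundle a `trf_reference_bundle`.
#' @param max_mismatches maximum edit distance.
#' @param max_hits per-insert cap on reported hits.
#' @return tibble: `insert`, `ref_id`, `ref_class`, `start`, `end`,
#'   `strand`, `mismatches`, `hit_rank` (1 = primary candidate).
#' @export
map_reads <- function(inserts, bundle, max_mismatches = 1L,
                      max_hits = 100L) {
  uq <- unique(inserts)
  refs <- bundle$refs
  raw <- cpp_map_reads(uq, refs$seq, as.integer(max_mismatches))
  hits <- tibble(
    insert = uq[raw$insert_idx],
    ref_id = refs$ref_id[raw$ref_idx],
    ref_class = refs$class[raw$ref_idx],
    start = raw$start,
    end = raw$start + nchar(uq[raw$insert_idx]),
    strand = raw$strand,
    mismatches = raw$mismatches
  )
  g <- match(hits$insert, uq)
  hits <- hits[order(g, .class_rank[hits$ref_class], hits$ref_id,
                     hits$start, hits$strand), ]
  hits$hit_rank <- sequence(rle(sort(g))$lengths)
  hits[hits$hit_rank <= max_hits, ]
}

#' Map a single insert
#'
#' @inheritParams map_reads
#' @param insert a single insert sequence.
#' @return hit tibble as in [map_reads()].
#' @export
map_read <- function(insert, bundle, max_mismatches = 1L, max_hits = 100L) {
  stopifnot(length(insert) == 1, nchar(insert) >= 1)
  map_reads(insert, bundle, max_mismatches, max_hits)
}

#' Write alignment hits as SAM
#'
#' Minimal single-end SAM export for interoperability; one record per hit,
#' the first hit of each insert primary, the rest flagged secondary. The
#' stored sequence is the insert on the forward strand of the reference.
#'
#' @param hits hit tibble from [map_reads()] plus a `read_id` column.
#' @param bundle a `trf_reference_bundle`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam_hits <- function(hits, bundle, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", bundle$refs$ref_id,
                   bundle$refs$length))
  seq_out <- ifelse(hits$strand == "-", revcomp(hits$insert), hits$insert)
  flag <- ifelse(hits$strand == "-", 16L, 0L) +
    ifelse(hits$hit_rank > 1L, 256L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                 hits$read_id, flag, hits$ref_id, hits$start + 1L,
                 nchar(hits$insert), seq_out, hits$mismatches)
  writeLines(c(hdr, rec), con)
  invisible(path)
}

#' Read alignment hits back from SAM
#'
#' Reconstructs the hit tibble written by [write_sam_hits()] (or produced
#' by any aligner emitting ungapped single-end records with NM tags).
#'
#' @param path SAM path.
#' @param bundle a `trf_reference_bundle`.
#' @return tibble with `read_id`, `insert`, `ref_id`, `ref_class`, `start`,
#'   `end`, `strand`, `mismatches`, `hit_rank`.
#' @export
read_sam_hits <- function(path, bundle) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  seq_fwd <- vapply(f, function(x) x[10], character(1))
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x, value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else 0L
  }, integer(1))
  ref_id <- vapply(f, function(x) x[3], character(1))
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  hits <- tibble(
    read_id = vapply(f, function(x) x[1], character(1)),
    insert = ifelse(strand == "-", revcomp(seq_fwd), seq_fwd),
    ref_id = ref_id,
    ref_class = bundle$refs$class[match(ref_id, bundle$refs$ref_id)],
    start = start, end = start + nchar(seq_fwd), strand = strand,
    mismatches = nm
  )
  hits |>
    group_by(.data$read_id) |>
    mutate(hit_rank = dplyr::row_number()) |>
    ungroup()
}
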