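#' Classifier tolerance parameters
#'
#' Positional tolerances on the mature tRNA: a read is "whole" when its 5'
#' end lies within `whole_5p_tol` of the transcript start and its 3' end
#' within `whole_3p_tol` of the CCA terminus; the same tolerances
#' (`end5_tol`, `end3_tol`) define tRF_5' and tRF_3' end proximity.
#'
#' @param whole_5p_tol,whole_3p_tol,end5_tol,end3_tol non-negative
#'   tolerances in nucleotides.
#' @return a `trf_classifier_params` list.
#' @export
classifier_params <- function(whole_5p_tol = 3L, whole_3p_tol = 5L,
                              end5_tol = 3L, end3_tol = 5L) {
  p <- list(whole_5p_tol = whole_5p_tol, whole_3p_tol = whole_3p_tol,
            end5_tol = end5_tol, end3_tol = end3_tol)
  if (any(unlist(p) < 0)) stop("tolerances must be >= 0")
  structure(p, class = "trf_classifier_params")
}

#' Type a tRNA-mapped read by position on the mature transcript
#'
#' With `d5` the distance of the read's 5' end from the transcript start and
#' `d3` the distance of its 3' end from the CCA terminus, rules apply in
#' order: whole (d5 and d3 both within tolerance), tRF_5p (d5 within
#' tolerance), tRF_3p (d3 within tolerance), else tRF_other. Vectorized.
#'
#' @param start,end 0-based half-open read interval on the mature tRNA.
#' @param trna_len mature transcript length (CCA included).
#' @param params a [classifier_params()] object.
#' @return character vector: `whole`, `tRF_5p`, `tRF_3p`, or `tRF_other`.
#' @export
classify_trna_fragment <- function(start, end, trna_len,
                                   params = classifier_params()) {
  if (any(start < 0 | end > trna_len | start >= end)) {
    stop("hit interval outside [0, transcript length)")
  }
  d5 <- start
  d3 <- trna_len - end
  ifelse(d5 <= params$whole_5p_tol & d3 <= params$whole_3p_tol, "whole",
         ifelse(d5 <= params$end5_tol, "tRF_5p",
                ifelse(d3 <= params$end3_tol, "tRF_3p", "tRF_other")))
}

.category_label <- c("tRNA", "rsRNA", "annotated_gene", "unannotated")

# per-unique-insert resolution table from a hit set; base-vector group
# operations (contiguous groups after ordering) keep this fast at scale
.resolve_inserts <- function(hits, bundle, params) {
  refs <- bundle$refs
  m <- match(hits$ref_id, refs$ref_id)
  eff_class <- ifelse(refs$class[m] == "trna" & hits$strand == "-",
                      "background", refs$class[m])
  rank <- .class_rank[eff_class]
  uq <- unique(hits$insert)
  g <- match(hits$insert, uq)
  # order by (insert, effective class rank, mapper order): the first row of
  # each group is then the primary mapping of the winning category
  o <- order(g, rank, hits$hit_rank)
  g <- g[o]; rank <- rank[o]; m <- m[o]
  h <- hits[o, ]
  firsts <- !duplicated(g)
  win <- rank[firsts][g]
  keep <- rank == win  # retained hits of the winning category
  g <- g[keep]; m <- m[keep]; h <- h[keep, ]; win <- win[keep]
  firsts <- !duplicated(g)
  ngrp <- length(uq)

  n_unique_by <- function(x) {
    d <- !duplicated(paste0(g, "\r", x))
    tabulate(g[d], nbins = ngrp)
  }
  res <- tibble(
    insert = h$insert[firsts],
    category = .category_label[win[!duplicated(g)]],
    n_tx = n_unique_by(h$ref_id),
    n_dec = n_unique_by(refs$decoder_key[m]),
    n_acc = n_unique_by(refs$acceptor_key[m]),
    n_sub = n_unique_by(refs$subunit[m]),
    subunit = refs$subunit[m][firsts],
    decoder_key = refs$decoder_key[m][firsts],
    acceptor_key = refs$acceptor_key[m][firsts],
    biotype = refs$biotype[m][firsts],
    ref_id = h$ref_id[firsts],
    start = h$start[firsts],
    end = h$end[firsts],
    strand = h$strand[firsts],
    mismatches = h$mismatches[firsts],
    trna_len = refs$length[m][firsts]
  )
  is_t <- res$category == "tRNA"
  res$specificity <- NA_character_
  res$specificity[is_t] <- ifelse(
    res$n_tx[is_t] == 1L, "transcript",
    ifelse(res$n_dec[is_t] == 1L, "decoder",
           ifelse(res$n_acc[is_t] == 1L, "acceptor", "ambiguous")))
  res$fragment_type <- NA_character_
  if (any(is_t)) {
    res$fragment_type[is_t] <- classify_trna_fragment(
      res$start[is_t], res$end[is_t], res$trna_len[is_t], params)
  }
  res$subunit_key <- ifelse(res$category == "rsRNA",
                            ifelse(res$n_sub == 1L, res$subunit,
                                   "rsRNA_multi"), NA_character_)
  res
}

#' Resolve one read's hit set to a single primary category
#'
#' Category precedence: any tRNA (forward-strand) hit wins and discards the
#' rest; otherwise any rRNA/ribosomal-repeat hit; otherwise any annotated
#' gene; otherwise reads with hits are unannotated ("Other"); no hits is
#' unmapped. The primary mapping is the first retained hit in the mapper's
#' deterministic order.
#'
#' @param hits hit tibble for a single insert (as from [map_read()]); may
#'   have zero rows.
#' @param bundle a `trf_reference_bundle`.
#' @param params a [classifier_params()].
#' @return list with `category`, `retained` (hit tibble), `primary`
#'   (one-row tibble or NULL).
#' @export
resolve_category <- function(hits, bundle, params = classifier_params()) {
  if (nrow(hits) == 0) {
    return(list(category = "unmapped", retained = hits, primary = NULL))
  }
  stopifnot(length(unique(hits$insert)) == 1)
  res <- .resolve_inserts(hits, bundle, params)
  eff <- ifelse(hits$ref_class == "trna" & hits$strand == "-",
                "background", hits$ref_class)
  winner <- c(tRNA = "trna", rsRNA = "rrna", annotated_gene = "gene",
              unannotated = "background")[res$category]
  retained <- hits[eff == winner, ]
  list(category = res$category, retained = retained, primary = retained[1, ])
}

#' Specificity tier of a tRNA read's retained hits
#'
#' @param retained retained tRNA hits for one read.
#' @param bundle a `trf_reference_bundle`.
#' @return list with `specificity` (`transcript`, `decoder`, `acceptor`, or
#'   `ambiguous`) and `feature_key` (decoder key, or acceptor key for
#'   acceptor-tier reads).
#' @export
classify_trna_specificity <- function(retained, bundle) {
  refs <- bundle$refs
  m <- match(retained$ref_id, refs$ref_id)
  dec <- refs$decoder_key[m]
  acc <- refs$acceptor_key[m]
  spec <- if (length(unique(retained$ref_id)) == 1L) "transcript"
  else if (length(unique(dec)) == 1L) "decoder"
  else if (length(unique(acc)) == 1L) "acceptor"
  else "ambiguous"
  key <- switch(spec, transcript = dec[1], decoder = dec[1],
                acceptor = acc[1], NA_character_)
  list(specificity = spec, feature_key = key)
}

#' rRNA subunit of an rsRNA read
#'
#' A subunit and its genomic repeat copies collapse to the subunit label;
#' disagreement across subunits yields `rsRNA_multi`.
#'
#' @param retained retained rRNA hits for one read.
#' @param bundle a `trf_reference_bundle`.
#' @return the subunit feature key.
#' @export
classify_rsrna_subunit <- function(retained, bundle) {
  refs <- bundle$refs
  su <- unique(refs$subunit[match(retained$ref_id, refs$ref_id)])
  if (length(su) == 1L) su else "rsRNA_multi"
}

#' Annotate all reads of an experiment
#'
#' Joins processed reads with their hit sets, resolves the per-read
#' category, fragment type, specificity tier and feature key, and consumes
#' the deferred minimum-length filter: reads under the non-tRNA minimum are
#' kept only when they resolve to the tRNA category, and tRNA reads under
#' `min_trna_len` are dropped.
#'
#' @param processed output of [trim_reads()] + [length_filter()] (must
#'   carry `sample_id`).
#' @param hits output of [map_reads()] on the non-discarded inserts.
#' @param bundle a `trf_reference_bundle`.
#' @param params a [classifier_params()].
#' @param min_trna_len minimum retained insert length for tRNA reads.
#' @param count_acceptor_level when `TRUE`, acceptor-tier reads are counted
#'   under their acceptor key; the default counts only transcript- and
#'   decoder-tier reads, the stricter reading of decoder-level counting.
#' @return per-read annotation tibble: `read_id`, `sample_id`, `category`,
#'   `fragment_type`, `specificity`, `feature_key`, `counted`, `kept`,
#'   `drop_reason`, primary-hit fields and `insert_len`.
#' @export
annotate_reads <- function(processed, hits, bundle,
                           params = classifier_params(),
                           min_trna_len = 15L,
                           count_acceptor_level = FALSE) {
  live <- processed[!processed$discarded, ]
  res <- .resolve_inserts(hits, bundle, params)
  ann <- live[, intersect(c("read_id", "sample_id", "insert", "insert_len",
                            "short_flag"), names(live))] |>
    left_join(res[, c("insert", "category", "fragment_type", "specificity",
                      "subunit_key", "decoder_key", "acceptor_key",
                      "biotype", "ref_id", "start", "end", "strand",
                      "mismatches")], by = "insert")
  ann$category[is.na(ann$category)] <- "unmapped"

  is_t <- ann$category == "tRNA"
  ann$feature_key <- NA_character_
  ann$feature_key[is_t] <- ifelse(
    ann$specificity[is_t] %in% c("transcript", "decoder"),
    paste(ann$decoder_key[is_t], ann$fragment_type[is_t], sep = "_"),
    ifelse(ann$specificity[is_t] == "acceptor",
           paste(ann$acceptor_key[is_t], ann$fragment_type[is_t], sep = "_"),
           NA_character_))
  rs <- ann$category == "rsRNA"
  ann$feature_key[rs] <- ann$subunit_key[rs]
  ag <- ann$category == "annotated_gene"
  ann$feature_key[ag] <- ann$ref_id[ag]

  ann$counted <- FALSE
  ann$counted[is_t & ann$specificity %in%
                c("transcript", "decoder",
                  if (count_acceptor_level) "acceptor")] <- TRUE
  ann$counted[rs | ag] <- TRUE

  short <- if ("short_flag" %in% names(ann)) ann$short_flag else FALSE
  ann$kept <- TRUE
  ann$drop_reason <- NA_character_
  drop_non_trna <- short & ann$category != "tRNA"
  ann$kept[drop_non_trna] <- FALSE
  ann$drop_reason[drop_non_trna] <- "short_non_trna"
  drop_trna <- is_t & ann$insert_len < min_trna_len
  ann$kept[drop_trna] <- FALSE
  ann$drop_reason[drop_trna] <- "short_trna"
  ann$counted[!ann$kept] <- FALSE
  ann$subunit_key <- NULL
  ann
}
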