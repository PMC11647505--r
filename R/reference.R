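#' Splice introns out of a gene sequence
#'
#' Intron intervals are 0-based half-open coordinates on the gene sequence,
#' sorted and non-overlapping.
#'
#' @param seq gene sequence (single string).
#' @param introns integer matrix with columns `start`, `end` (0-based
#'   half-open), or `NULL`/0-row for an intronless gene.
#' @return the spliced sequence.
#' @export
splice_introns <- function(seq, introns = NULL) {
  if (is.null(introns) || NROW(introns) == 0) return(seq)
  introns <- matrix(as.integer(introns), ncol = 2)
  L <- nchar(seq)
  if (any(introns[, 1] < 0) || any(introns[, 2] > L) ||
      any(introns[, 1] >= introns[, 2])) {
    stop("intron interval out of range for gene of length ", L)
  }
  o <- order(introns[, 1])
  introns <- introns[o, , drop = FALSE]
  if (NROW(introns) > 1 &&
      any(introns[-1, 1] < introns[-NROW(introns), 2])) {
    stop("overlapping intron intervals")
  }
  keep_start <- c(0L, introns[, 2])
  keep_end <- c(introns[, 1], L)
  pieces <- substring(seq, keep_start + 1L, keep_end)
  paste(pieces, collapse = "")
}

#' Parse an intron string of the form "start-end;start-end"
#'
#' @param x a string such as `"3-5;10-12"`, or `""`/`NA` for none.
#' @return integer matrix with columns start, end (0-based half-open).
#' @export
parse_introns <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  colnames(m) <- c("start", "end")
  m
}

#' Build a mature tRNA from a genomic tRNA gene record
#'
#' Mature transcripts are the alignment reference for tRNA reads: introns are
#' spliced out, the 3' CCA tail is appended, and histidine tRNAs receive the
#' canonical extra G at position -1.
#'
#' @param gene_id,isotype,anticodon gene identifier, amino-acid acceptor
#'   label (e.g. `"Gly"`, `"His"`), and 3-letter anticodon.
#' @param genomic_seq gene sequence over A/C/G/T.
#' @param introns 0-based half-open intron intervals (matrix, or the string
#'   form accepted by [parse_introns()]).
#' @param assume_cca_absent if `TRUE` (default; gene databases store untailed
#'   gene sequences) CCA is always appended; if `FALSE`, genes already ending
#'   in CCA are left untouched.
#' @return a one-row tibble: `transcript_id`, `isotype`, `anticodon`,
#'   `decoder_key` (isotype-anticodon), `acceptor_key` (isotype), `seq`.
#' @export
build_mature_trna <- function(gene_id, isotype, anticodon, genomic_seq,
                              introns = NULL, assume_cca_absent = TRUE) {
  if (nchar(anticodon) != 3) stop("anticodon must be 3 nt: ", gene_id)
  if (is.character(introns) && length(introns) == 1) {
    introns <- parse_introns(introns)
  }
  seq <- splice_introns(genomic_seq, introns)
  if (assume_cca_absent || !grepl("CCA$", seq)) seq <- paste0(seq, "CCA")
  if (identical(isotype, "His")) seq <- paste0("G", seq)
  tibble(
    transcript_id = gene_id, isotype = isotype, anticodon = anticodon,
    decoder_key = paste(isotype, anticodon, sep = "-"),
    acceptor_key = isotype, seq = seq
  )
}

#' Read a tRNA gene table
#'
#' TSV with columns `gene_id`, `isotype`, `anticodon`, `seq`, `introns`
#' (intron string, possibly empty).
#'
#' @param path TSV path.
#' @return tibble of gene records.
#' @export
read_trna_gene_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Assemble the combined alignment reference bundle
#'
#' The bundle holds the four reference compartments consumed by the mapper
#' and classifier: mature tRNAs, rRNA subunits plus their genomic repeat
#' copies, other annotated small-RNA genes, and unannotated background
#' segments. Category precedence downstream is tRNA > rRNA > annotated gene
#' > background.
#'
#' @param trna_genes tibble of tRNA gene records (`gene_id`, `isotype`,
#'   `anticodon`, `seq`, `introns` as intron strings).
#' @param rrnas tibble with `ref_id`, `subunit` (one of 18S, 28S, 5.8S, 5S,
#'   mito_rRNA), `is_repeat`, `seq`; may have zero rows.
#' @param genes tibble with `ref_id`, `biotype`, `seq`; may have zero rows.
#' @param background tibble with `ref_id`, `seq`; may have zero rows.
#' @param assume_cca_absent passed to [build_mature_trna()].
#' @return an object of class `trf_reference_bundle`: a list with `refs`
#'   (one row per reference sequence, all compartments) and `mature_trnas`.
#' @export
build_reference_bundle <- function(trna_genes, rrnas = NULL, genes = NULL,
                                   background = NULL,
                                   assume_cca_absent = TRUE) {
  if (is.null(trna_genes) || nrow(trna_genes) == 0) {
    stop("at least one tRNA gene is required")
  }
  mat <- dplyr::bind_rows(lapply(seq_len(nrow(trna_genes)), function(i) {
    g <- trna_genes[i, ]
    build_mature_trna(g$gene_id, g$isotype, g$anticodon, g$seq,
                      if ("introns" %in% names(g)) g$introns else NULL,
                      assume_cca_absent = assume_cca_absent)
  }))
  empty <- tibble(ref_id = character(0), seq = character(0))
  if (is.null(rrnas)) rrnas <- tibble(ref_id = character(0),
                                      subunit = character(0),
                                      is_repeat = logical(0),
                                      seq = character(0))
  if (is.null(genes)) genes <- tibble(ref_id = character(0),
                                      biotype = character(0),
                                      seq = character(0))
  if (is.null(background)) background <- empty

  refs <- dplyr::bind_rows(
    tibble(ref_id = mat$transcript_id, class = "trna", seq = mat$seq,
           subunit = NA_character_, is_repeat = FALSE,
           biotype = NA_character_, isotype = mat$isotype,
           anticodon = mat$anticodon, decoder_key = mat$decoder_key,
           acceptor_key = mat$acceptor_key),
    tibble(ref_id = rrnas$ref_id, class = "rrna", seq = rrnas$seq,
           subunit = rrnas$subunit, is_repeat = rrnas$is_repeat,
           biotype = NA_character_, isotype = NA_character_,
           anticodon = NA_character_, decoder_key = NA_character_,
           acceptor_key = NA_character_),
    tibble(ref_id = genes$ref_id, class = "gene", seq = genes$seq,
           subunit = NA_character_, is_repeat = FALSE,
           biotype = genes$biotype, isotype = NA_character_,
           anticodon = NA_character_, decoder_key = NA_character_,
           acceptor_key = NA_character_),
    tibble(ref_id = background$ref_id, class = "background",
           seq = background$seq, subunit = NA_character_, is_repeat = FALSE,
           biotype = NA_character_, isotype = NA_character_,
           anticodon = NA_character_, decoder_key = NA_character_,
           acceptor_key = NA_character_)
  )
  dup <- refs$ref_id[duplicated(refs$ref_id)]
  if (length(dup) > 0) {
    stop("duplicate reference id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(refs$seq))) stop("empty reference sequence")
  refs$length <- nchar(refs$seq)
  out <- list(refs = refs, mature_trnas = mat)
  class(out) <- "trf_reference_bundle"
  out
}

#' @export
print.trf_reference_bundle <- function(x, ...) {
  tab <- table(x$refs$class)
  cat("<trf_reference_bundle> ", nrow(x$refs), " references (",
      paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
      "), total ", sum(x$refs$length), " nt\n", sep = "")
  invisible(x)
}

#' Write a reference bundle as FASTA plus a TSV manifest
#'
#' @param bundle a `trf_reference_bundle`.
#' @param fasta_path,manifest_path output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_reference_fasta <- function(bundle, fasta_path, manifest_path = NULL) {
  seqs <- Biostrings::DNAStringSet(setNames(bundle$refs$seq,
                                            bundle$refs$ref_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(manifest_path)) {
    man <- bundle$refs[, c("ref_id", "class", "subunit", "biotype",
                           "decoder_key", "length")]
    readr::write_tsv(man, manifest_path, progress = FALSE)
  }
  invisible(fasta_path)
}

#' Read a reference bundle back from FASTA + manifest
#'
#' Round-trips the output of [write_reference_fasta()]. tRNA metadata
#' (isotype, anticodon) is recovered from the decoder key.
#'
#' @param fasta_path,manifest_path paths written by [write_reference_fasta()].
#' @return a `trf_reference_bundle`.
#' @export
read_reference_fasta <- function(fasta_path, manifest_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  man <- readr::read_tsv(manifest_path, col_types = readr::cols(
    ref_id = "c", class = "c", subunit = "c", biotype = "c",
    decoder_key = "c", length = "i"), progress = FALSE)
  seq_chr <- as.character(seqs)
  man$seq <- unname(seq_chr[man$ref_id])
  iso <- ifelse(is.na(man$decoder_key), NA_character_,
                sub("-.*$", "", man$decoder_key))
  anti <- ifelse(is.na(man$decoder_key), NA_character_,
                 sub("^.*-", "", man$decoder_key))
  refs <- tibble(
    ref_id = man$ref_id, class = man$class, seq = man$seq,
    subunit = man$subunit,
    is_repeat = man$class == "rrna" & grepl("repeat", man$ref_id),
    biotype = man$biotype, isotype = iso, anticodon = anti,
    decoder_key = man$decoder_key, acceptor_key = iso,
    length = nchar(man$seq)
  )
  mat_rows <- refs[refs$class == "trna", ]
  mat <- tibble(transcript_id = mat_rows$ref_id, isotype = mat_rows$isotype,
                anticodon = mat_rows$anticodon,
                decoder_key = mat_rows$decoder_key,
                acceptor_key = mat_rows$acceptor_key, seq = mat_rows$seq)
  out <- list(refs = refs, mature_trnas = mat)
  class(out) <- "trf_reference_bundle"
  out
}

#' Generate a synthetic reference bundle
#'
#' Random sequences standing in for a scaled-down genome annotation: ten
#' tRNA decoders (two with identical gene copies, two with introns, one
#' histidine), five rRNA subunits with genomic repeat copies for the nuclear
#' subunits, a panel of miRNA-sized genes, and unannotated background
#' segments. Sequence content is random, so cross-compartment sequence
#' collisions at small-RNA lengths are vanishingly unlikely; gene copies
#' within a decoder are exact duplicates so that multi-mapping resolves at
#' the decoder tier, as for real tRNA gene families.
#'
#' @param seed RNG seed (the caller's RNG state is restored afterwards).
#' @param n_mirna number of miRNA-like genes.
#' @param n_background number of background segments.
#' @param background_len length of each background segment.
#' @return a `trf_reference_bundle`.
#' @export
synthetic_reference <- function(seed = 1L, n_mirna = 100L,
                                n_background = 6L, background_len = 400L) {
  with_seed(seed, {
    dec <- tibble(
      isotype = c("Gly", "Glu", "His", "Lys", "Val",
                  "Ala", "Ser", "Leu", "Arg", "Phe"),
      anticodon = c("GCC", "CTC", "GTG", "TTT", "CAC",
                    "AGC", "GCT", "CAA", "TCT", "GAA"),
      copies = c(2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
      has_intron = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, TRUE, TRUE, FALSE, FALSE)
    )
    genes <- dplyr::bind_rows(lapply(seq_len(nrow(dec)), function(i) {
      d <- dec[i, ]
      body_len <- 72L + sample(0:3, 1)
      intron <- ""
      seq <- random_dna(1, body_len)
      if (d$has_intron) {
        ilen <- 14L
        ipos <- 38L
        seq <- paste0(substr(seq, 1, ipos), random_dna(1, ilen),
                      substr(seq, ipos + 1, body_len))
        intron <- paste0(ipos, "-", ipos + ilen)
      }
      tibble(
        gene_id = paste0("tRNA-", d$isotype, "-", d$anticodon, "-",
                         seq_len(d$copies)),
        isotype = d$isotype, anticodon = d$anticodon,
        seq = seq, introns = intron
      )
    }))

    sub_len <- c(`18S` = 900L, `28S` = 1500L, `5.8S` = 157L, `5S` = 121L,
                 mito_rRNA = 700L)
    rrnas <- dplyr::bind_rows(lapply(names(sub_len), function(su) {
      main <- tibble(ref_id = paste0("rRNA_", su), subunit = su,
                     is_repeat = FALSE, seq = random_dna(1, sub_len[[su]]))
      if (su == "mito_rRNA") return(main)
      # repeat copies: genomic duplicates of stretches of the subunit
      reps <- lapply(1:2, function(k) {
        L <- sub_len[[su]]
        rl <- min(L, 200L)
        st <- sample.int(L - rl + 1L, 1) - 1L
        tibble(ref_id = paste0("rRNA_", su, "_repeat", k), subunit = su,
               is_repeat = TRUE,
               seq = substr(main$seq, st + 1L, st + rl))
      })
      dplyr::bind_rows(c(list(main), reps))
    }))

    mirnas <- tibble(
      ref_id = sprintf("miR-%03d", seq_len(n_mirna)),
      biotype = "miRNA",
      seq = random_dna(n_mirna, sample(20:23, n_mirna, replace = TRUE))
    )
    bg <- tibble(
      ref_id = sprintf("background_%02d", seq_len(n_background)),
      seq = random_dna(n_background, background_len)
    )
    build_reference_bundle(genes, rrnas, mirnas, bg)
  })
}
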