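# Small hand-assembled reference bundle used across tests: two identical
# Gly-GCC gene copies (decoder-tier multimapping), a Gly-CCC (acceptor-tier
# ambiguity partner), Val-CAC, His-GTG, a 5S rRNA with a repeat copy, an 18S
# stub, two miRNA genes and one background segment.
tiny_bundle <- function() {
  set.seed(424242)
  gly <- random_dna(1, 68)
  trna <- tibble::tibble(
    gene_id = c("tRNA-Gly-GCC-1", "tRNA-Gly-GCC-2", "tRNA-Gly-CCC-1",
                "tRNA-Val-CAC-2", "tRNA-His-GTG-1"),
    isotype = c("Gly", "Gly", "Gly", "Val", "His"),
    anticodon = c("GCC", "GCC", "CCC", "CAC", "GTG"),
    seq = c(gly, gly, random_dna(1, 70), random_dna(1, 73),
            random_dna(1, 71)),
    introns = ""
  )
  s5 <- random_dna(1, 120)
  rrna <- tibble::tibble(
    ref_id = c("rRNA_5S", "rRNA_5S_repeat1", "rRNA_18S"),
    subunit = c("5S", "5S", "18S"),
    is_repeat = c(FALSE, TRUE, FALSE),
    seq = c(s5, substr(s5, 21, 100), random_dna(1, 300))
  )
  genes <- tibble::tibble(
    ref_id = c("miR-001", "miR-002"), biotype = "miRNA",
    seq = random_dna(2, 22)
  )
  bg <- tibble::tibble(ref_id = "background_01", seq = random_dna(1, 250))
  build_reference_bundle(trna, rrna, genes, bg)
}

ref_seq <- function(bundle, id) {
  bundle$refs$seq[bundle$refs$ref_id == id]
}

# Independent brute-force fragment typing: enumerate the textual rules
# directly from end distances, no shared code with the classifier.
oracle_fragment_type <- function(start, end, L, w5 = 3, w3 = 5) {
  d5 <- start
  d3 <- L - end
  near5 <- d5 <= w5
  near3 <- d3 <= w3
  if (near5 && near3) return("whole")
  if (near5) return("tRF_5p")
  if (near3) return("tRF_3p")
  "tRF_other"
}

# Independent exhaustive Hamming search over a concatenated reference,
# vectorized over window offsets; returns the set of minimum-distance hits
# within max_mm, both strands.
oracle_hamming_hits <- function(insert, bundle, max_mm = 1L) {
  refs <- bundle$refs
  cat_seq <- paste(refs$seq, collapse = "")
  chars <- strsplit(cat_seq, "", fixed = TRUE)[[1]]
  seg <- rep(seq_len(nrow(refs)), refs$length)
  offset0 <- cumsum(c(0L, refs$length))[seq_len(nrow(refs))]
  scan <- function(q) {
    L <- nchar(q)
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    nwin <- length(chars) - L + 1L
    if (nwin < 1) return(NULL)
    mm <- integer(nwin)
    for (j in seq_len(L)) {
      cj <- chars[j:(j + nwin - 1L)]
      mm <- mm + as.integer(cj != qc[j] | cj == "N" | qc[j] == "N")
    }
    valid <- seg[seq_len(nwin)] == seg[seq_len(nwin) + L - 1L]
    data.frame(pos = which(valid), mm = mm[valid])
  }
  fwd <- scan(insert)
  rev <- scan(revcomp(insert))
  mk <- function(d, strand) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    r <- seg[d$pos]
    data.frame(ref_id = refs$ref_id[r], start = d$pos - 1L - offset0[r],
               strand = strand, mismatches = d$mm,
               stringsAsFactors = FALSE)
  }
  all <- rbind(mk(fwd, "+"), mk(rev, "-"))
  if (is.null(all) || nrow(all) == 0) return(all)
  best <- min(all$mismatches)
  if (best > max_mm) return(all[0, ])
  all[all$mismatches == best, ]
}

# canonical sorted key for comparing hit sets
hit_key <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(character(0))
  sort(paste(df$ref_id, df$start, df$strand, df$mismatches, sep = ":"))
}
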