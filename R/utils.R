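#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N (case preserved as
#'   upper case in the output).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Random DNA sequences
#'
#' Draws from the current RNG stream; seed management is the caller's job.
#'
#' @param n number of sequences.
#' @param len length of each sequence (scalar or vector of length `n`).
#' @return character vector of `n` sequences.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  out <- character(n)
  for (l in unique(len)) {
    idx <- which(len == l)
    if (l == 0) { out[idx] <- ""; next }
    m <- matrix(sample(c("A", "C", "G", "T"), length(idx) * l,
                       replace = TRUE), nrow = length(idx))
    out[idx] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  out
}

#' Read a FASTQ file into a tibble
#'
#' Plain or gzip-compressed four-line FASTQ.
#'
#' @param path file path.
#' @return tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  }
  idx <- seq(1L, length(lines), by = 4L)
  tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
    seq = lines[idx + 1L],
    qual = lines[idx + 3L]
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads tibble with `read_id`, `seq`, `qual`.
#' @param path output path; written gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", reads$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
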