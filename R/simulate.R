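#' Simulation configuration
#'
#' Defaults encode the library structure the preprocessing stage inverts
#' (7-nt UMI prefix, one untemplated 3' base, fixed 3' adapter) and the
#' study-like WT/KO contrast: negative-binomial counts with a uniform
#' depletion (default log2 fold change -2) on every tRF-class feature in the
#' "KO" condition and no change on miRNA features.
#'
#' @param seed integer seed controlling every random choice of a simulation.
#' @param n_per_condition samples per condition (conditions are WT and KO).
#' @param depth expected reads per sample before library-size variation.
#' @param adapter 3' adapter sequence.
#' @param umi_len UMI prefix length.
#' @param trailing_bases number of untemplated bases added 3' of the insert.
#' @param error_rate per-base substitution probability on the raw read.
#' @param read_length sequencing cycle count; raw reads are truncated here.
#' @param lib_factor_range library-size factors are drawn log-uniform on
#'   this interval.
#' @param ko_trf_log2fc true KO/WT log2 fold change applied to tRF-class
#'   features (tRF_5p, tRF_3p, tRF_other).
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2); 0 gives
#'   Poisson counts.
#' @param length_models named list of fragment-length ranges per class.
#' @return a `trf_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_per_condition = 3L, depth = 50000,
                       adapter = "GATCGGAAGAGCACACGTCT", umi_len = 7L,
                       trailing_bases = 1L, error_rate = 0,
                       read_length = 120L, lib_factor_range = c(0.5, 2),
                       ko_trf_log2fc = -2, dispersion = 0.1,
                       length_models = NULL) {
  if (umi_len < 0 || trailing_bases < 0) stop("negative layout lengths")
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  defaults <- list(
    tRF_5p = c(28L, 36L), tRF_3p = c(18L, 22L), tRF_other = c(20L, 32L),
    rsRNA = c(20L, 58L), miRNA = NULL,  # miRNA inserts are the whole gene
    unannotated = c(20L, 45L)
  )
  if (!is.null(length_models)) defaults[names(length_models)] <- length_models
  structure(list(
    seed = as.integer(seed), n_per_condition = as.integer(n_per_condition),
    depth = depth, adapter = adapter, umi_len = as.integer(umi_len),
    trailing_bases = as.integer(trailing_bases), error_rate = error_rate,
    read_length = as.integer(read_length),
    lib_factor_range = lib_factor_range, ko_trf_log2fc = ko_trf_log2fc,
    dispersion = dispersion, length_models = defaults
  ), class = "trf_sim_config")
}

#' Default simulated feature table
#'
#' One feature per tRNA decoder and fragment type, one per rRNA subunit, one
#' per miRNA gene, and a handful of unannotated background species. The
#' class mix (about 55% tRF reads, 25% rsRNA, 5% miRNA, under 0.5%
#' full-length tRNA, the rest unannotated) mirrors a tRF-dominant epididymal
#' small-RNA library. Expected counts are `prop * depth`; tRF-class features
#' carry the KO depletion from the config.
#'
#' @param bundle a `trf_reference_bundle`.
#' @param config a `trf_sim_config`.
#' @return tibble: `feature_key`, `class`, `ref_group` (reference ids the
#'   feature's reads are drawn from), `base_mean`, `dispersion`, `log2fc`.
#' @export
default_sim_features <- function(bundle, config = sim_config()) {
  refs <- bundle$refs
  decs <- unique(refs$decoder_key[refs$class == "trna"])
  subunits <- unique(refs$subunit[refs$class == "rrna"])
  mirna <- refs$ref_id[refs$class == "gene" & refs$biotype == "miRNA"]
  bg <- refs$ref_id[refs$class == "background"]

  class_prop <- c(tRF_5p = 0.30, tRF_3p = 0.18, tRF_other = 0.07,
                  whole_tRNA = 0.004, rsRNA = 0.25, miRNA = 0.05,
                  unannotated = 0.146)
  subunit_prop <- c(`18S` = 0.32, `28S` = 0.36, `5.8S` = 0.08, `5S` = 0.12,
                    mito_rRNA = 0.12)
  subunit_prop <- subunit_prop[subunits] / sum(subunit_prop[subunits])

  per_dec <- function(cls) {
    # feature keys match the quantifier's (decoder, fragment type) keys
    key_cls <- if (cls == "whole_tRNA") "whole" else cls
    tibble(feature_key = paste(decs, key_cls, sep = "_"), class = cls,
           ref_group = lapply(decs, function(d) {
             refs$ref_id[refs$class == "trna" &
                           refs$decoder_key == d]
           }),
           prop = class_prop[[cls]] / length(decs))
  }
  feats <- dplyr::bind_rows(
    per_dec("tRF_5p"), per_dec("tRF_3p"), per_dec("tRF_other"),
    per_dec("whole_tRNA"),
    tibble(feature_key = subunits, class = paste0("rsRNA:", subunits),
           ref_group = lapply(subunits, function(su) {
             refs$ref_id[refs$class == "rrna" & refs$subunit == su]
           }),
           prop = unname(class_prop[["rsRNA"]] * subunit_prop)),
    tibble(feature_key = mirna, class = "miRNA",
           ref_group = as.list(mirna),
           prop = class_prop[["miRNA"]] / length(mirna)),
    tibble(feature_key = paste0("unann_", seq_along(bg)),
           class = "unannotated", ref_group = as.list(bg),
           prop = class_prop[["unannotated"]] / length(bg))
  )
  feats$base_mean <- feats$prop * config$depth
  feats$dispersion <- config$dispersion
  feats$log2fc <- ifelse(feats$class %in% c("tRF_5p", "tRF_3p", "tRF_other"),
                         config$ko_trf_log2fc, 0)
  feats$prop <- NULL
  feats
}

#' Simulate a feature-by-sample count matrix
#'
#' Counts are NB(mean = base_mean * 2^(log2fc * [KO]) * lib_factor,
#' dispersion alpha) with Var = mu + alpha mu^2; alpha = 0 degenerates to
#' Poisson. Library-size factors are drawn log-uniform from the config
#' range. Deterministic given `seed`.
#'
#' @param features feature table as from [default_sim_features()].
#' @param config a `trf_sim_config`.
#' @param seed overrides `config$seed` when given.
#' @return list with `counts` (features x samples integer matrix), `samples`
#'   (sample_id, condition, lib_factor) and `features`.
#' @export
simulate_counts <- function(features, config = sim_config(), seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  n <- config$n_per_condition
  with_seed(seed, {
    samples <- tibble(
      sample_id = c(sprintf("WT%d", seq_len(n)), sprintf("KO%d", seq_len(n))),
      condition = rep(c("WT", "KO"), each = n),
      lib_factor = exp(runif(2 * n, log(config$lib_factor_range[1]),
                             log(config$lib_factor_range[2])))
    )
    counts <- matrix(0L, nrow(features), nrow(samples),
                     dimnames = list(features$feature_key,
                                     samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      ko <- samples$condition[j] == "KO"
      mu <- features$base_mean * 2^(features$log2fc * ko) *
        samples$lib_factor[j]
      alpha <- features$dispersion
      pois <- alpha <= 0
      cj <- integer(nrow(features))
      if (any(pois)) cj[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        cj[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                             size = 1 / alpha[!pois])
      }
      counts[, j] <- cj
    }
    list(counts = counts, samples = samples, features = features)
  })
}

# class-specific fragment interval on a reference of length L, honoring the
# positional tolerances the classifier uses (whole: d5<=3 & d3<=5; tRF_5p:
# d5<=3 & d3>5; tRF_3p: d5>3 & d3<=5; tRF_other: d5>3 & d3>5)
draw_interval <- function(class, L, len_range, n) {
  draw_len <- function(lo, hi, n) {
    if (hi < lo) stop("reference too short for requested fragment class")
    sample(seq.int(lo, hi), n, replace = TRUE)
  }
  if (class == "whole_tRNA") {
    d5 <- sample(0:3, n, replace = TRUE)
    d3 <- sample(0:5, n, replace = TRUE)
    keep <- (L - d5 - d3) >= 15L
    d3[!keep] <- 0L
    return(cbind(start = d5, end = L - d3))
  }
  lo <- len_range[1]; hi <- len_range[2]
  if (class == "tRF_5p") {
    # start within 3 of the 5' end, end more than 5 from the 3' end
    len <- draw_len(lo, min(hi, L - 6L), n)
    start <- vapply(len, function(l) {
      sample(0:min(3L, L - 6L - l), 1)
    }, integer(1))
    return(cbind(start = start, end = start + len))
  }
  if (class == "tRF_3p") {
    len <- draw_len(lo, min(hi, L - 4L), n)
    d3 <- vapply(len, function(l) {
      sample(0:min(5L, L - 4L - l), 1)
    }, integer(1))
    return(cbind(start = L - d3 - len, end = L - d3))
  }
  if (class == "tRF_other") {
    len <- draw_len(lo, min(hi, L - 10L), n)
    start <- vapply(len, function(l) {
      4L + sample.int(L - 9L - l, 1) - 1L
    }, integer(1))
    return(cbind(start = start, end = start + len))
  }
  # rsRNA / unannotated: any substring
  len <- draw_len(lo, min(hi, L), n)
  start <- vapply(len, function(l) sample.int(L - l + 1L, 1) - 1L,
                  integer(1))
  cbind(start = start, end = start + len)
}

#' Draw insert sequences for one feature
#'
#' Picks a reference from the feature's reference group and an interval on
#' it consistent with the feature's class, so that an error-free read is
#' guaranteed to be classified back to its true label. Uses the current RNG
#' stream.
#'
#' @param feature_key,class feature identity and class label (one of
#'   tRF_5p, tRF_3p, tRF_other, whole_tRNA, `rsRNA:<subunit>`, miRNA,
#'   unannotated).
#' @param ref_group character vector of candidate reference ids.
#' @param bundle a `trf_reference_bundle`.
#' @param n number of inserts.
#' @param config a `trf_sim_config` (length models).
#' @return tibble: `ref_id`, `start`, `end`, `insert`.
#' @export
draw_fragment <- function(feature_key, class, ref_group, bundle, n,
                          config = sim_config()) {
  if (n == 0) {
    return(tibble(ref_id = character(0), start = integer(0),
                  end = integer(0), insert = character(0)))
  }
  refs <- bundle$refs
  idx <- match(ref_group, refs$ref_id)
  if (anyNA(idx)) stop("unknown reference in feature ", feature_key)
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  base_class <- if (startsWith(class, "rsRNA")) "rsRNA" else class
  lm <- switch(base_class,
               miRNA = NULL,
               rsRNA = config$length_models$rsRNA,
               unannotated = config$length_models$unannotated,
               config$length_models[[base_class]])
  out <- lapply(split(seq_len(n), pick), function(rows) {
    r <- pick[rows[1]]
    L <- refs$length[r]
    if (base_class == "miRNA") {
      iv <- cbind(start = rep(0L, length(rows)), end = rep(L, length(rows)))
    } else {
      iv <- draw_interval(base_class, L, lm, length(rows))
    }
    tibble(ref_id = refs$ref_id[r], start = as.integer(iv[, "start"]),
           end = as.integer(iv[, "end"]),
           insert = substring(refs$seq[r], iv[, "start"] + 1L, iv[, "end"]))
  })
  dplyr::bind_rows(out)
}

# apply per-base substitution errors to a character vector of sequences
apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  nc <- nchar(seqs)
  nerr <- rbinom(length(seqs), nc, error_rate)
  hit <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(nc[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Assemble raw reads from inserts
#'
#' Raw read layout (the inverse of the trimming pipeline): 7-nt random UMI,
#' insert, one untemplated base, 3' adapter, random spillover, truncated at
#' the configured read length. Qualities are constant. Uses the current RNG
#' stream.
#'
#' @param inserts tibble with at least `read_id` and `insert`.
#' @param config a `trf_sim_config`.
#' @return tibble: `read_id`, `seq`, `qual`, `umi`.
#' @export
build_raw_reads <- function(inserts, config = sim_config()) {
  n <- nrow(inserts)
  umi <- random_dna(n, config$umi_len)
  extra <- random_dna(n, config$trailing_bases)
  raw <- paste0(umi, inserts$insert, extra, config$adapter)
  short <- nchar(raw) < config$read_length
  if (any(short)) {
    raw[short] <- paste0(raw[short],
                         random_dna(sum(short),
                                    config$read_length - nchar(raw[short])))
  }
  raw <- substr(raw, 1L, config$read_length)
  raw <- apply_substitutions(raw, config$error_rate)
  tibble(read_id = inserts$read_id, seq = raw,
         qual = strrep("I", nchar(raw)), umi = umi)
}

#' Write per-sample FASTQ files
#'
#' @param raw_reads tibble from [build_raw_reads()] with a `sample_id`
#'   column.
#' @param outdir output directory (created if needed).
#' @param gz write gzip-compressed files.
#' @return tibble `sample_id`, `path`.
#' @export
emit_fastq <- function(raw_reads, outdir, gz = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(raw_reads$sample_id)
  paths <- vapply(ids, function(s) {
    p <- file.path(outdir, paste0(s, ".fastq", if (gz) ".gz" else ""))
    write_fastq(raw_reads[raw_reads$sample_id == s, ], p)
    p
  }, character(1))
  tibble(sample_id = ids, path = unname(paths))
}

#' Simulate a complete WT-vs-KO small RNA-seq experiment
#'
#' Draws feature counts, then one insert per counted read, then raw reads.
#' Everything is deterministic given the config seed; the per-read truth
#' table records feature, class, and the insert's interval on its reference.
#'
#' @param bundle a `trf_reference_bundle`.
#' @param config a `trf_sim_config`.
#' @param features optional feature table; defaults to
#'   [default_sim_features()].
#' @param outdir when given, FASTQ files, the sample sheet and truth tables
#'   are written there.
#' @return a `trf_simulation` list: `config`, `features`, `samples`,
#'   `counts` (true counts), `truth` (per read), `raw_reads`, and `fastq`
#'   (paths, when written).
#' @export
simulate_srna_experiment <- function(bundle, config = sim_config(),
                                     features = NULL, outdir = NULL) {
  if (is.null(features)) features <- default_sim_features(bundle, config)
  cs <- simulate_counts(features, config)
  sim <- with_seed(config$seed + 1L, {
    per_sample <- lapply(seq_len(nrow(cs$samples)), function(j) {
      sid <- cs$samples$sample_id[j]
      nn <- cs$counts[, j]
      rows <- which(nn > 0)
      ins <- dplyr::bind_rows(lapply(rows, function(g) {
        f <- features[g, ]
        d <- draw_fragment(f$feature_key, f$class, f$ref_group[[1]],
                           bundle, nn[g], config)
        d$feature_key <- f$feature_key
        d$true_class <- f$class
        d
      }))
      if (nrow(ins) == 0) return(ins)
      ins <- ins[sample.int(nrow(ins)), ]  # shuffle read order
      ins$sample_id <- sid
      ins$read_id <- sprintf("%s_R%06d", sid, seq_len(nrow(ins)))
      ins
    })
    truth <- dplyr::bind_rows(per_sample)
    raw <- build_raw_reads(truth, config)
    raw$sample_id <- truth$sample_id
    list(truth = truth, raw_reads = raw)
  })
  truth <- sim$truth[, c("read_id", "sample_id", "feature_key", "true_class",
                         "ref_id", "start", "end", "insert")]
  truth$insert_len <- nchar(truth$insert)
  out <- list(config = config, features = features, samples = cs$samples,
              counts = cs$counts, truth = truth, raw_reads = sim$raw_reads)
  if (!is.null(outdir)) {
    out$fastq <- emit_fastq(sim$raw_reads, outdir)
    readr::write_tsv(cs$samples, file.path(outdir, "samples.tsv"),
                     progress = FALSE)
    readr::write_tsv(truth[, setdiff(names(truth), "insert")],
                     file.path(outdir, "truth_reads.tsv"), progress = FALSE)
    counts_df <- as_tibble(cs$counts, rownames = "feature_key")
    readr::write_tsv(counts_df, file.path(outdir, "truth_counts.tsv"),
                     progress = FALSE)
  }
  class(out) <- "trf_simulation"
  out
}

#' @export
print.trf_simulation <- function(x, ...) {
  cat("<trf_simulation> ", nrow(x$truth), " reads, ",
      nrow(x$samples), " samples, ", nrow(x$features), " features\n",
      sep = "")
  invisible(x)
}
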