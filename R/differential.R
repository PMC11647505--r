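#' Differential-test parameters
#'
#' @param lfc_cutoff absolute log2 fold-change threshold entering the
#'   significance call.
#' @param alpha adjusted-p threshold.
#' @param dispersion_floor lower bound on the per-feature NB dispersion.
#' @param prior_df prior degrees of freedom for the empirical-Bayes squeeze
#'   of the moment dispersions toward their across-feature mean; also added
#'   to the residual degrees of freedom of the t reference.
#' @param zero_pseudo normalized pseudo-count added to a group mean only
#'   when that group is all zero for the feature.
#' @param pseudo_reference when `TRUE`, size-factor estimation falls back
#'   to features expressed in at least half the samples if no feature is
#'   nonzero everywhere.
#' @return a `trf_diff_params` list.
#' @export
diff_params <- function(lfc_cutoff = 1, alpha = 0.05,
                        dispersion_floor = 1e-8, prior_df = 16,
                        zero_pseudo = 0.5, pseudo_reference = FALSE) {
  stopifnot(alpha > 0, alpha < 1, lfc_cutoff >= 0)
  structure(list(lfc_cutoff = lfc_cutoff, alpha = alpha,
                 dispersion_floor = dispersion_floor, prior_df = prior_df,
                 zero_pseudo = zero_pseudo,
                 pseudo_reference = pseudo_reference),
            class = "trf_diff_params")
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features of the ratio of
#' the sample's count to the feature's geometric mean across samples, using
#' only features with nonzero counts in every sample.
#'
#' @param counts feature x sample count matrix (or a `trf_count_table`).
#' @param pseudo_reference fallback when no feature is nonzero in all
#'   samples: use features nonzero in at least half the samples, with the
#'   geometric mean taken over their positive counts.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (inherits(counts, "trf_count_table")) counts <- counts$counts
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    if (!pseudo_reference) {
      stop("no feature has nonzero counts in all samples; ",
           "consider pseudo_reference = TRUE")
    }
    use <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(use)) stop("count table too sparse for size factors")
    logg <- apply(counts[use, , drop = FALSE], 1, function(x) {
      mean(log(x[x > 0]))
    })
  } else {
    logg <- rowMeans(log(counts[use, , drop = FALSE]))
  }
  sub <- counts[use, , drop = FALSE]
  sf <- apply(sub, 2, function(x) {
    r <- log(x) - logg
    exp(median(r[is.finite(r)]))
  })
  setNames(sf, colnames(counts))
}

# per-feature method-of-moments dispersion, averaged across conditions;
# signed (can go negative for under-dispersed features) unless clipped
.dispersion_mom <- function(norm, condition, clip = TRUE,
                            floor = 1e-8) {
  conds <- unique(condition)
  per <- sapply(conds, function(cc) {
    x <- norm[, condition == cc, drop = FALSE]
    if (ncol(x) < 2) stop("need >= 2 replicates per condition")
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    a <- (v - m) / m^2
    a[!is.finite(a)] <- NA
    a
  })
  a <- rowMeans(per, na.rm = TRUE)
  a[is.nan(a)] <- NA
  if (clip) a <- pmax(floor, a)
  a
}

#' Method-of-moments NB dispersion per feature
#'
#' On size-factor-normalized counts, within each condition the moment
#' estimate is (s^2 - mean)/mean^2; estimates are averaged across
#' conditions and floored. All-zero features yield the floor.
#'
#' @param counts feature x sample count matrix.
#' @param sf per-sample size factors.
#' @param condition per-sample condition labels.
#' @param floor lower clip for the estimate.
#' @return named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, sf, condition, floor = 1e-8) {
  norm <- sweep(counts, 2, sf, "/")
  a <- .dispersion_mom(norm, condition, clip = TRUE, floor = floor)
  a[is.na(a)] <- floor
  setNames(a, rownames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Moderated negative-binomial Wald test between two conditions
#'
#' A self-contained stand-in for a full NB GLM stage: per feature, group means
#' of size-factor-normalized counts give the log2 fold change; its standard
#' error comes from the NB delta method, se^2 = ((1/n2)(1/mu2 + a) +
#' (1/n1)(1/mu1 + a)) / ln(2)^2, with the dispersion a an empirical-Bayes
#' squeeze of the per-feature moment estimate toward the across-feature
#' mean (prior df from `params`). The Wald statistic is referred to a t
#' distribution on residual-plus-prior degrees of freedom, which keeps the
#' test calibrated at small replicate numbers where a plug-in normal
#' reference is anti-conservative. A group that is all zero receives a
#' small normalized pseudo-count so fold changes stay finite; features with
#' zero counts everywhere are reported with NA statistics and excluded from
#' the BH adjustment.
#'
#' @param counts feature x sample count matrix (or `trf_count_table`).
#' @param condition per-sample condition labels; a factor whose first
#'   level is the reference (default: treat `"WT"` as reference when
#'   present, otherwise first unique value). The reported log2 fold change
#'   is second level vs reference.
#' @param sf optional size factors; estimated by [size_factors()] when
#'   `NULL`.
#' @param params a [diff_params()] object.
#' @return tibble: `feature_key`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `df`, `pvalue`, `padj`, `significant`; size factors attached as the
#'   `"size_factors"` attribute.
#' @export
nb_wald_test <- function(counts, condition, sf = NULL,
                         params = diff_params()) {
  if (inherits(counts, "trf_count_table")) {
    if (missing(condition)) condition <- counts$samples$condition
    counts <- counts$counts
  }
  if (!is.factor(condition)) {
    lev <- unique(condition)
    if ("WT" %in% lev) lev <- c("WT", setdiff(lev, "WT"))
    condition <- factor(condition, levels = lev)
  }
  if (nlevels(condition) != 2) stop("exactly two conditions required")
  if (is.null(sf)) {
    sf <- size_factors(counts, pseudo_reference = params$pseudo_reference)
  }
  norm <- sweep(counts, 2, sf, "/")
  g1 <- condition == levels(condition)[1]
  g2 <- condition == levels(condition)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  all_zero <- m1 == 0 & m2 == 0
  m1a <- ifelse(m1 == 0, params$zero_pseudo, m1)
  m2a <- ifelse(m2 == 0, params$zero_pseudo, m2)

  a_raw <- .dispersion_mom(norm, condition, clip = FALSE)
  ok <- !all_zero & !is.na(a_raw)
  a0 <- max(0, mean(a_raw[ok]))
  df_res <- n1 + n2 - 2
  a_mod <- (df_res * pmax(a_raw, 0) + params$prior_df * a0) /
    (df_res + params$prior_df)
  a_mod <- pmax(params$dispersion_floor, a_mod)
  a_mod[is.na(a_mod)] <- a0

  lfc <- log2(m2a / m1a)
  se <- sqrt(((1 / n2) * (1 / m2a + a_mod) +
                (1 / n1) * (1 / m1a + a_mod)) / log(2)^2)
  df_t <- df_res + params$prior_df
  stat <- lfc / se
  pvalue <- 2 * pt(-abs(stat), df = df_t)
  pvalue[all_zero] <- NA
  lfc[all_zero] <- NA
  se[all_zero] <- NA
  stat[all_zero] <- NA
  padj <- bh_adjust(pvalue)
  res <- tibble(
    feature_key = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = rowMeans(norm),
    log2fc = lfc, se = se, stat = stat, df = df_t,
    pvalue = pvalue, padj = padj,
    significant = !is.na(padj) & abs(lfc) > params$lfc_cutoff &
      padj < params$alpha
  )
  attr(res, "size_factors") <- sf
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlap of significant features between two analyses
#'
#' @param results_a,results_b result tibbles from [nb_wald_test()].
#' @param alpha adjusted-p threshold for set membership.
#' @param use_lfc_cutoff also require `|log2fc| > lfc_cutoff` for
#'   membership.
#' @param lfc_cutoff threshold used when `use_lfc_cutoff` is `TRUE`.
#' @return list: significant sets, intersection, per-set sizes and
#'   fractions, and the direction-concordant and both-down subsets.
#' @export
overlap_analysis <- function(results_a, results_b, alpha = 0.05,
                             use_lfc_cutoff = FALSE, lfc_cutoff = 1) {
  pick <- function(res) {
    s <- !is.na(res$padj) & res$padj < alpha
    if (use_lfc_cutoff) s <- s & abs(res$log2fc) > lfc_cutoff
    res$feature_key[s]
  }
  if (length(intersect(results_a$feature_key,
                       results_b$feature_key)) == 0) {
    warning("disjoint feature namespaces; overlap is empty")
  }
  sig_a <- pick(results_a)
  sig_b <- pick(results_b)
  both <- intersect(sig_a, sig_b)
  dir_a <- setNames(sign(results_a$log2fc), results_a$feature_key)
  dir_b <- setNames(sign(results_b$log2fc), results_b$feature_key)
  concordant <- both[dir_a[both] == dir_b[both]]
  down_both <- both[dir_a[both] < 0 & dir_b[both] < 0]
  list(
    sig_a = sig_a, sig_b = sig_b, intersection = both,
    n_a = length(sig_a), n_b = length(sig_b), n_both = length(both),
    frac_of_a = if (length(sig_a)) length(both) / length(sig_a) else NA,
    frac_of_b = if (length(sig_b)) length(both) / length(sig_b) else NA,
    concordant = concordant, down_both = down_both
  )
}
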