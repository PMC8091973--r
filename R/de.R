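# Spike-in calibrated differential expression for two-condition, replicated
# count matrices. The pipeline:
#   1. spike-in gene counts are prenormalized by the per-sample gDNA
#      spike/target read ratio rho_i (cancels cell-mixing variation);
#   2. median-of-ratios size factors are computed from the prenormalized
#      spike block and applied to the target block, so a genuine global
#      shift of the target transcriptome survives normalization;
#   3. a per-gene negative-binomial model with a two-group condition effect
#      is fit in closed form (size-factor-weighted group means), dispersion
#      by moments shrunk toward a mean-dispersion trend, and tested with a
#      Wald statistic;
#   4. BH adjustment, empirical-Bayes normal shrinkage of the log2 fold
#      changes, significance classes, RPKM and a density-valley expression
#      threshold.

.count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stopifnot(is.data.frame(counts))
  id_col <- intersect("gene_id", names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), id_col), drop = FALSE])
  if (length(id_col) == 1) rownames(m) <- counts[[id_col]]
  m
}

#' Prenormalize spike-in counts by the gDNA mixing ratio
#'
#' Divides each sample's spike-in gene counts by its gDNA spike/target total
#' read ratio `rho`. Doubling the spike-in cell input doubles both the spike
#' counts and `rho`, so the division cancels mixing variation and leaves a
#' quantity that scales only with sequencing depth.
#'
#' @param spike_counts Spike-in count tibble (`gene_id` + one column per
#'   sample) or matrix.
#' @param rho Named per-sample ratios (or vector in column order).
#' @return Real-valued tibble of prenormalized counts.
#' @export
prenormalize_spike <- function(spike_counts, rho) {
  m <- .count_matrix(spike_counts)
  if (!is.null(names(rho))) {
    missing_rho <- setdiff(colnames(m), names(rho))
    if (length(missing_rho) > 0) {
      stop("rho missing for sample(s): ",
           paste(missing_rho, collapse = ", "), call. = FALSE)
    }
    rho <- rho[colnames(m)]
  }
  if (any(!is.finite(rho) | rho <= 0)) {
    stop("rho must be positive", call. = FALSE)
  }
  out <- sweep(m, 2, rho, "/")
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(out))
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (with nonzero
#' counts in every sample) of the ratio of the gene's count to its
#' geometric mean across samples.
#'
#' @param counts Count tibble (`gene_id` + samples) or matrix; real values
#'   allowed (e.g. prenormalized spike counts).
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  m <- .count_matrix(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    stop("no gene with nonzero counts in every sample", call. = FALSE)
  }
  sub <- m[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2, function(col) stats::median(col / geo))
}

#' Benjamini-Hochberg adjustment with NA pass-through
#'
#' Step-up BH with enforced monotonicity; `NA` p-values (untestable genes)
#' are passed through and excluded from the number of tests m.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# Method-of-moments dispersion shrunk 50/50 (log scale) toward a log-log
# mean-dispersion trend. mu_bar: per-gene mean of size-factor-normalized
# counts; v: pooled within-condition variance of the normalized counts.
.estimate_dispersion <- function(norm, condition, floor = 1e-8) {
  groups <- split(seq_along(condition), condition)
  ss <- 0
  df <- 0
  for (g in groups) {
    sub <- norm[, g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(g) - 1
  }
  v <- ss / df
  mu_bar <- rowMeans(norm)
  alpha_hat <- pmax((v - mu_bar) / mu_bar^2, floor)
  use <- is.finite(alpha_hat) & mu_bar > 0
  alpha_trend <- rep(floor, length(mu_bar))
  if (sum(use) >= 20) {
    # per-gene moment estimates are very noisy at few replicates; the trend
    # is fit log-log through mean-expression bin averages of alpha_hat
    # (bin means are approximately unbiased, unlike per-gene logs)
    nb <- max(min(20, floor(sum(use) / 20)), 2)
    bins <- cut(rank(mu_bar[use], ties.method = "first"), breaks = nb)
    bm <- tapply(mu_bar[use], bins, mean)
    ba <- tapply(alpha_hat[use], bins, mean)
    keep_bin <- is.finite(bm) & is.finite(ba) & bm > 0 & ba > floor
    if (sum(keep_bin) >= 2) {
      fit <- stats::lm(log(ba[keep_bin]) ~ log(bm[keep_bin]))
      pred <- cbind(1, log(pmax(mu_bar, .Machine$double.eps))) %*%
        stats::coef(fit)
      alpha_trend <- pmax(exp(as.numeric(pred)), floor)
    }
  }
  # empirical-Bayes shrink of alpha_hat toward the trend: the weight on the
  # per-gene estimate is its moment-matched signal fraction, so when true
  # dispersions are homogeneous the estimate collapses to the trend and the
  # Wald test stays calibrated at few replicates
  samp_var <- (2 / df) * (1 / pmax(mu_bar, .Machine$double.eps) +
                            alpha_trend)^2
  resid <- pmax(alpha_hat, floor) - alpha_trend
  tau2 <- max(mean(resid[use]^2) - mean(samp_var[use]), 0)
  w <- tau2 / (tau2 + samp_var)
  out <- alpha_trend + w * resid
  out[!is.finite(out)] <- floor
  pmax(out, floor)
}

#' Per-gene negative-binomial Wald test
#'
#' Fits, per gene, an NB model with a log link and a two-group condition
#' effect using closed-form size-factor-weighted group means
#' `q_c = sum_i(k_i) / sum_i(sf_i)`, dispersion by shrunken method of
#' moments, and tests `lfc = log2(q_B / q_A)` with a Wald statistic whose
#' standard error comes from the NB observed information. Genes with zero
#' counts in every sample are reported `NA` and excluded from multiple
#' testing. A half-count continuity correction is applied to a group whose
#' total is zero so one-sided-zero genes remain testable.
#'
#' @param counts Target count tibble (`gene_id` + samples) or matrix.
#' @param sf Named per-sample size factors.
#' @param condition Per-sample condition labels (two levels); the contrast
#'   is `contrast[1]` over `contrast[2]`.
#' @param contrast Character(2), numerator then denominator condition.
#' @return Tibble: `gene_id`, `baseMean`, `lfc_mle`, `se`, `stat`, `p`.
#' @export
nb_wald_test <- function(counts, sf, condition,
                         contrast = c("B", "A")) {
  m <- .count_matrix(counts)
  if (!is.null(names(sf))) sf <- sf[colnames(m)]
  stopifnot(length(sf) == ncol(m), length(condition) == ncol(m))
  if (!all(contrast %in% condition)) {
    stop("contrast levels not found in condition", call. = FALSE)
  }
  ib <- which(condition == contrast[1])
  ia <- which(condition == contrast[2])
  norm <- sweep(m, 2, sf, "/")
  base_mean <- rowMeans(norm)
  all_zero <- rowSums(m) == 0
  alpha <- .estimate_dispersion(norm, condition)

  group_q <- function(idx) {
    tot <- rowSums(m[, idx, drop = FALSE])
    s1 <- sum(sf[idx])
    q <- tot / s1
    # continuity correction for empty groups keeps the Wald statistic finite
    corrected <- tot == 0
    q[corrected] <- 0.5 / s1
    list(q = q, s1 = s1, s2 = sum(sf[idx]^2))
  }
  ga <- group_q(ia)
  gb <- group_q(ib)
  # Var(log q_c) from the NB observed information at the fitted mean
  vlog <- function(g) {
    (g$q * g$s1 + alpha * g$q^2 * g$s2) / (g$q * g$s1)^2
  }
  lfc <- log2(gb$q / ga$q)
  se <- sqrt(vlog(ga) + vlog(gb)) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  lfc[all_zero] <- NA_real_
  se[all_zero] <- NA_real_
  stat[all_zero] <- NA_real_
  p[all_zero] <- NA_real_
  tibble::tibble(
    gene_id = rownames(m) %||% sprintf("gene%05d", seq_len(nrow(m))),
    baseMean = unname(base_mean),
    lfc_mle = unname(lfc),
    se = unname(se),
    stat = unname(stat),
    p = unname(p)
  )
}

#' Empirical-Bayes normal shrinkage of log2 fold changes
#'
#' Uses a zero-centered normal prior whose variance `tau2` is fit to the
#' MLE fold changes by marginal moment matching: under the prior each MLE
#' is marginally `N(0, tau2 + se^2)`, so `tau2` solves
#' `mean(lfc^2 / (tau2 + se^2)) = 1`. Solving the standardized equation
#' (rather than differencing raw moments) keeps the fit stable when a few
#' low-count genes have enormous standard errors, and the uncentered second
#' moment ensures a genuine global shift survives shrinkage. The posterior
#' mean is `lfc * tau2 / (tau2 + se^2)`: as `se -> 0` the shrunken value
#' approaches the MLE; as `se` grows it approaches 0.
#'
#' @param lfc_mle,se Per-gene MLE log2 fold changes and standard errors.
#' @return Shrunken log2 fold changes.
#' @export
shrink_lfc <- function(lfc_mle, se) {
  ok <- is.finite(lfc_mle) & is.finite(se)
  x2 <- lfc_mle[ok]^2
  v <- se[ok]^2
  score <- function(tau2) mean(x2 / (tau2 + v)) - 1
  tau2 <- 1e-6
  if (score(1e-6) > 0) {
    upper <- max(x2) + 1
    tau2 <- if (score(upper) > 0) upper else
      stats::uniroot(score, c(1e-6, upper))$root
  }
  out <- lfc_mle * tau2 / (tau2 + se^2)
  out[!ok] <- NA_real_
  out
}

#' Significance classes
#'
#' A gene is `up` if `padj < padj_threshold` and its fold change exceeds
#' `fc_threshold`, `down` if `padj < padj_threshold` and the fold change is
#' below `1 / fc_threshold`, otherwise `no_change`.
#'
#' @param padj BH-adjusted p-values.
#' @param lfc Log2 fold changes used for thresholding (shrunken by default
#'   in [run_calibrated_de()]).
#' @param padj_threshold,fc_threshold Significance thresholds (defaults
#'   0.05 and 1.5).
#' @return Character vector in `{"up", "down", "no_change"}`.
#' @export
classify_significance <- function(padj, lfc, padj_threshold = 0.05,
                                  fc_threshold = 1.5) {
  stopifnot(padj_threshold > 0, fc_threshold > 0)
  fc <- 2^lfc
  dplyr::case_when(
    is.na(padj) | is.na(lfc) ~ "no_change",
    padj < padj_threshold & fc > fc_threshold ~ "up",
    padj < padj_threshold & fc < 1 / fc_threshold ~ "down",
    TRUE ~ "no_change"
  )
}

#' Density valley between the two main modes
#'
#' Finds the local minimum of a Gaussian kernel density estimate between the
#' two highest modes of `x`. Used to split the bimodal distribution of
#' log2-transformed expression levels into unexpressed and expressed genes.
#'
#' @param x Numeric vector (e.g. `log2(RPKM + 1)` values).
#' @param bw Bandwidth passed to [stats::density()].
#' @return The valley location, or `NA` with a warning when `x` is unimodal.
#' @export
expression_valley <- function(x, bw = "nrd0") {
  d <- stats::density(x[is.finite(x)], bw = bw)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2) {
    warning("density is unimodal; no valley found")
    return(NA_real_)
  }
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2)
  hi <- max(top2)
  between <- seq(lo, hi)
  d$x[between[which.min(y[between])]]
}

#' RPKM and the expression threshold
#'
#' Computes per-gene RPKM from replicate-averaged normalized counts
#' (`rpkm = mean count / (length_kb * total counts in millions)`), the
#' expression value `log2(RPKM + 1)`, and an expression threshold at the
#' KDE valley between the two highest modes of the expression distribution
#' (the antilog of the valley). Genes with `RPKM > threshold` are flagged
#' expressed.
#'
#' @param norm_counts Normalized count tibble/matrix; columns are averaged.
#' @param gene_lengths Per-gene lengths in bp (same order).
#' @param threshold Optional fixed RPKM threshold; `NULL` derives it from
#'   the valley. Required (with a warning) when the distribution is
#'   unimodal.
#' @return Tibble (`gene_id`, `rpkm`, `log2_rpkm`, `expressed`) with the
#'   RPKM threshold in the `threshold` attribute.
#' @export
rpkm_and_threshold <- function(norm_counts, gene_lengths, threshold = NULL) {
  m <- .count_matrix(norm_counts)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  mean_count <- rowMeans(m)
  total <- sum(mean_count)
  rpkm <- mean_count / ((gene_lengths / 1000) * (total / 1e6))
  log2_rpkm <- log2(rpkm + 1)
  if (is.null(threshold)) {
    valley <- expression_valley(log2_rpkm)
    if (is.na(valley)) {
      stop("expression distribution is unimodal; supply `threshold`",
           call. = FALSE)
    }
    threshold <- 2^valley - 1
  }
  out <- tibble::tibble(
    gene_id = rownames(m) %||% sprintf("gene%05d", seq_along(rpkm)),
    rpkm = unname(rpkm),
    log2_rpkm = unname(log2_rpkm),
    expressed = unname(rpkm > threshold)
  )
  attr(out, "threshold") <- threshold
  out
}

#' Spike-in calibrated differential expression
#'
#' Runs the full calibrated DE pipeline: gDNA prenormalization of the spike
#' block, spike-derived median-of-ratios size factors applied to the target
#' block, the closed-form NB Wald test, BH adjustment, normal-prior
#' shrinkage, significance classes, and (when gene lengths are supplied)
#' RPKM with the valley-derived expression threshold.
#'
#' @param counts Target count tibble (`gene_id` + samples).
#' @param spike_counts Spike-in count tibble.
#' @param sample_info Tibble (`sample`, `condition`, `rho`).
#' @param gene_lengths Optional per-gene lengths in bp (target block order).
#' @param contrast Character(2), numerator then denominator condition.
#' @param padj_threshold,fc_threshold Significance thresholds.
#' @param shrink_for_classes Use the shrunken LFC (default) or the MLE for
#'   fold-change thresholding.
#' @param size_factor_source `"spike"` (calibrated, default) or `"target"`
#'   (conventional library-composition normalization; a global shift of the
#'   target transcriptome is invisible to it).
#' @return An object of class `calq_de`: `results` tibble (`gene_id`,
#'   `baseMean`, `lfc_mle`, `lfc_shrunk`, `se`, `p`, `padj`, `sig_class`,
#'   plus `rpkm`/`expressed` when lengths are given), `size_factors`,
#'   `sample_info`, `params`.
#' @export
run_calibrated_de <- function(counts, spike_counts, sample_info,
                              gene_lengths = NULL, contrast = c("B", "A"),
                              padj_threshold = 0.05, fc_threshold = 1.5,
                              shrink_for_classes = TRUE,
                              size_factor_source = c("spike", "target")) {
  size_factor_source <- match.arg(size_factor_source)
  samples <- sample_info$sample
  condition <- sample_info$condition
  if (size_factor_source == "spike") {
    pre <- prenormalize_spike(
      spike_counts, stats::setNames(sample_info$rho, samples))
    sf <- size_factors(pre)
  } else {
    sf <- size_factors(counts)
  }
  res <- nb_wald_test(counts, sf, condition[match(names(sf), samples)],
                      contrast = contrast)
  res$padj <- bh_adjust(res$p)
  res$lfc_shrunk <- shrink_lfc(res$lfc_mle, res$se)
  class_lfc <- if (shrink_for_classes) res$lfc_shrunk else res$lfc_mle
  res$sig_class <- classify_significance(res$padj, class_lfc,
                                         padj_threshold, fc_threshold)
  threshold <- NA_real_
  if (!is.null(gene_lengths)) {
    norm <- sweep(.count_matrix(counts), 2, sf[samples], "/")
    rk <- rpkm_and_threshold(norm, gene_lengths)
    threshold <- attr(rk, "threshold")
    res$rpkm <- rk$rpkm
    res$expressed <- rk$expressed
  }
  res <- res[, c("gene_id", "baseMean", "lfc_mle", "lfc_shrunk", "se",
                 "stat", "p", "padj", "sig_class",
                 intersect(c("rpkm", "expressed"), names(res)))]
  structure(
    list(results = res, size_factors = sf, sample_info = sample_info,
         params = list(contrast = contrast,
                       padj_threshold = padj_threshold,
                       fc_threshold = fc_threshold,
                       size_factor_source = size_factor_source,
                       rpkm_threshold = threshold)),
    class = "calq_de"
  )
}

#' @export
print.calq_de <- function(x, ...) {
  n <- table(factor(x$results$sig_class,
                    levels = c("up", "down", "no_change")))
  cat("Spike-in calibrated differential expression\n")
  cat(sprintf("  %d genes, contrast %s vs %s (size factors: %s)\n",
              nrow(x$results), x$params$contrast[1], x$params$contrast[2],
              x$params$size_factor_source))
  cat(sprintf("  up: %d  down: %d  no_change: %d  (padj < %g, FC > %g)\n",
              n[["up"]], n[["down"]], n[["no_change"]],
              x$params$padj_threshold, x$params$fc_threshold))
  if (!is.na(x$params$rpkm_threshold)) {
    cat(sprintf("  expression threshold: RPKM = %.3f (%d genes expressed)\n",
                x$params$rpkm_threshold, sum(x$results$expressed)))
  }
  invisible(x)
}
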