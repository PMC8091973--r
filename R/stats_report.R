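# Inferential summaries in the variants the downstream figures use:
# Student's t-tests (two-sample pooled-variance, paired, one-sample;
# one- or two-tailed), one-sided Fisher's exact overlap tests for gene-set
# Venns, and Pearson correlation matrices of fold-change tables. All emit
# tidy one-row-per-test tibbles.

#' Student's t-test as a tidy row
#'
#' Wraps [stats::t.test()] with the classical pooled-variance form for the
#' two-sample case (the unqualified "Student's t-test"), plus paired and
#' one-sample variants and one-tailed alternatives.
#'
#' @param x Numeric sample.
#' @param y Optional second sample (two-sample or paired test).
#' @param mu Null value for the one-sample test.
#' @param paired Paired two-sample test.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `estimate`,
#'   `alternative`, `method`.
#' @export
t_test_report <- function(x, y = NULL, mu = 0, paired = FALSE,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(y) || paired) {
    v <- if (paired) stats::var(x - y) else stats::var(x)
    if (!is.finite(v) || v == 0) {
      stop("zero variance: t statistic undefined", call. = FALSE)
    }
  }
  ht <- if (is.null(y)) {
    stats::t.test(x, mu = mu, alternative = alternative)
  } else {
    stats::t.test(x, y, paired = paired, var.equal = TRUE,
                  alternative = alternative)
  }
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    estimate = unname(ht$estimate[1]),
    alternative = alternative,
    method = ht$method
  )
}

#' Fisher's exact overlap test for two gene sets
#'
#' Builds the 2x2 table of `universe` membership in `a` and `b` and tests
#' enrichment of the overlap: the one-sided hypergeometric tail
#' `P(X >= observed overlap)` (default), with the sample odds ratio from
#' the table. A two-sided p-value is available via `alternative`.
#'
#' @param a,b Character vectors of ids, subsets of `universe`.
#' @param universe Character vector of all ids under consideration.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return One-row tibble: `overlap`, `only_a`, `only_b`, `neither`,
#'   `odds_ratio`, `p_value`.
#' @export
fisher_overlap <- function(a, b, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  a <- unique(a)
  b <- unique(b)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("a and b must be subsets of the universe", call. = FALSE)
  }
  in_a <- universe %in% a
  in_b <- universe %in% b
  n11 <- sum(in_a & in_b)
  n10 <- sum(in_a & !in_b)
  n01 <- sum(!in_a & in_b)
  n00 <- sum(!in_a & !in_b)
  p <- if (alternative == "greater") {
    stats::phyper(n11 - 1, length(a), length(universe) - length(a),
                  length(b), lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(n11, n10, n01, n00), nrow = 2),
                       alternative = "two.sided")$p.value
  }
  tibble::tibble(
    overlap = n11, only_a = n10, only_b = n01, neither = n00,
    odds_ratio = (n11 * n00) / (n10 * n01),
    p_value = p
  )
}

#' Pearson correlation matrix of fold-change tables
#'
#' Aligns named LFC vectors on shared region/gene ids, drops missing values
#' pairwise, and reports the Pearson correlation and the number of complete
#' pairs per cell. Cells with fewer than 3 shared observations are `NA`.
#'
#' @param tables Wide tibble whose first column is the id and remaining
#'   numeric columns are LFC vectors, or a named list of named numeric
#'   vectors.
#' @return Long tibble (`var_a`, `var_b`, `r`, `n`) over all ordered pairs.
#' @export
lfc_correlation_matrix <- function(tables) {
  if (is.data.frame(tables)) {
    ids <- tables[[1]]
    m <- as.matrix(tables[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    stopifnot(is.list(tables), length(tables) >= 2)
    ids <- Reduce(union, lapply(tables, names))
    m <- sapply(tables, function(v) v[match(ids, names(v))])
    rownames(m) <- ids
  }
  if (ncol(m) < 2) stop("need >= 2 tables", call. = FALSE)
  vars <- colnames(m)
  grid <- tidyr::expand_grid(var_a = vars, var_b = vars)
  purrr::pmap(grid, function(var_a, var_b) {
    ok <- stats::complete.cases(m[, c(var_a, var_b)])
    n <- sum(ok)
    r <- if (n >= 3) {
      suppressWarnings(stats::cor(m[ok, var_a], m[ok, var_b]))
    } else NA_real_
    tibble::tibble(var_a = var_a, var_b = var_b, r = r, n = n)
  }) |>
    dplyr::bind_rows()
}
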