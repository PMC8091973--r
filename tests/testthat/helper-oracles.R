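# Brute-force oracles, kept deliberately independent of the package
# implementations they check: plain loops and first-principles formulas.

oracle_overlaps <- function(a, b, min_bp = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    shared <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
    any(b$chrom == a$chrom[i] & shared >= min_bp)
  }, logical(1))
}

oracle_nearest <- function(query, subject, max_dist) {
  res <- lapply(seq_len(nrow(query)), function(i) {
    same <- which(subject$chrom == query$chrom[i])
    if (length(same) == 0) return(c(NA_integer_, NA_real_))
    gap <- pmax(0,
                subject$start[same] - query$end[i],
                query$start[i] - subject$end[same])
    ok <- gap <= max_dist
    if (!any(ok)) return(c(NA_integer_, NA_real_))
    cand <- same[ok]
    gap <- gap[ok]
    ord <- order(gap, subject$start[cand], cand)
    c(cand[ord[1]], gap[ord[1]])
  })
  data.frame(subject = vapply(res, `[`, numeric(1), 1),
             distance = vapply(res, `[`, numeric(1), 2))
}

# total covered bp of an interval set (per-bp tally on a small genome)
oracle_coverage_bp <- function(x, genome) {
  sum(vapply(seq_len(nrow(genome)), function(ci) {
    hit <- rep(FALSE, genome$length[ci])
    rows <- which(x$chrom == genome$chrom[ci])
    for (i in rows) hit[(x$start[i] + 1):x$end[i]] <- TRUE
    sum(hit)
  }, numeric(1)))
}

oracle_count_regions <- function(frags, regions, min_bp = 1) {
  vapply(seq_len(nrow(regions)), function(j) {
    shared <- pmin(frags$end, regions$end[j]) -
      pmax(frags$start, regions$start[j])
    sum(frags$chrom == regions$chrom[j] & shared >= min_bp)
  }, numeric(1))
}

oracle_size_factors <- function(m) {
  keep <- apply(m > 0, 1, all)
  geo <- exp(rowMeans(log(m[keep, , drop = FALSE])))
  apply(m[keep, , drop = FALSE], 2,
        function(col) stats::median(col / geo))
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

random_intervals <- function(n, genome, max_len = 2000) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(stats::runif(n) * (genome$length[ci] - len))
  tibble::tibble(chrom = genome$chrom[ci], start = start,
                 end = start + len)
}

random_fragments <- function(n, genome, frag_len = 200) {
  x <- random_intervals(n, genome, max_len = frag_len)
  x$end <- pmin(x$start + frag_len, genome$length[match(x$chrom,
                                                        genome$chrom)])
  x
}
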