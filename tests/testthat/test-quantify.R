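test_that("region counting and per-kb densities follow stated semantics", {
  # 7 fragments fully inside a 2-kb region
  frags <- tibble::tibble(sample = "a",
                          chrom = "chr1", start = 100 * (1:7),
                          end = 100 * (1:7) + 50)
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 2000)
  q <- quantify_regions(frags, region,
                        tibble::tibble(sample = "a", condition = "A"),
                        contrast = c("A", "A"))
  expect_equal(q$density_num, 3.5)
  expect_equal(q$log2density_num, log2(4.5))
  # a fragment spanning two abutting regions is counted in both
  two <- tibble::tibble(chrom = "chr1", start = c(0, 1000),
                        end = c(1000, 2000))
  span <- tibble::tibble(chrom = "chr1", start = 900, end = 1100)
  counts <- count_in_regions(span, two)
  expect_equal(counts$count, c(1L, 1L))
  expect_error(count_in_regions(span, two[0, ]), "empty")
})

test_that("region counts match a brute-force overlap scan", {
  set.seed(23)
  g <- toy_genome(c(chr1 = 40000, chr2 = 20000))
  for (trial in 1:25) {
    fr <- random_fragments(200, g)
    rg <- random_intervals(25, g)
    got <- count_in_regions(fr, rg)
    expect_equal(got$count, as.integer(oracle_count_regions(fr, rg)))
  }
})

test_that("midpoint binning conserves the fragment count exactly", {
  g <- toy_genome(c(chr1 = 1e6))
  fr <- tibble::tibble(chrom = "chr1", start = 100, end = 300)
  bc <- binned_coverage(fr, g, bin = 250000)
  expect_equal(bc$count[bc$start == 0], 1L)
  expect_equal(sum(bc$count), 1L)
  set.seed(29)
  frs <- random_fragments(5000, g)
  bc2 <- binned_coverage(frs, g, bin = 10000)
  expect_equal(sum(bc2$count), 5000L)
  # uniform fragments land in bins like Poisson counts
  expected <- 5000 * 10000 / 1e6
  expect_true(all(abs(bc2$count - expected) < 4 * sqrt(expected) + 1))
})

test_that("LFC computations are antisymmetric in the contrast", {
  frags <- tibble::tibble(
    sample = rep(c("a1", "b1"), c(30, 60)),
    chrom = "chr1",
    start = c(seq(0, 2900, by = 100), seq(0, 5900, by = 100)),
    end = c(seq(0, 2900, by = 100), seq(0, 5900, by = 100)) + 50)
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 10000)
  info <- tibble::tibble(sample = c("a1", "b1"), condition = c("A", "B"))
  fwd <- quantify_regions(frags, region, info, contrast = c("B", "A"))
  rev <- quantify_regions(frags, region, info, contrast = c("A", "B"))
  expect_equal(fwd$lfc, -rev$lfc)
})

test_that("state fold changes summarize per-state LFC with a baseline", {
  g <- toy_genome(c(chr1 = 100000))
  states <- tibble::tibble(chrom = "chr1",
                           start = c(0, 50000), end = c(50000, 100000),
                           name = c("Active", "Intergenic"))
  # condition A: 2 fragments per kb everywhere; B: 4/kb in Active, 2/kb
  # elsewhere
  mk <- function(step, lo, hi) {
    s <- seq(lo, hi - step, by = step)
    tibble::tibble(chrom = "chr1", start = s, end = s + 100)
  }
  fa <- mk(500, 0, 100000)
  fb <- dplyr::bind_rows(mk(250, 0, 50000), mk(500, 50000, 100000))
  res <- state_fold_changes(fa, fb, states, g, bin = 5000, pseudocount = 1)
  sm <- res$summary
  active <- sm[sm$state == "Active", ]
  inter <- sm[sm$state == "Intergenic", ]
  # 10 vs 20 fragments per 5-kb bin: log2(21/11)
  expect_equal(active$median, log2(21 / 11))
  expect_equal(inter$median, 0)
  expect_equal(res$baseline, 0)
  # identical conditions: every state median 0
  same <- state_fold_changes(fa, fa, states, g, bin = 5000)
  expect_true(all(same$summary$median == 0))
  # absent state warns
  states3 <- dplyr::bind_rows(
    states, tibble::tibble(chrom = "chr1", start = 99999, end = 100000,
                           name = "Tiny"))
  expect_warning(state_fold_changes(fa, fb, states3, g, bin = 50000),
                 "Tiny")
})

test_that("metaprofiles are strand-aware and flat on constant tracks", {
  g <- toy_genome(c(chr1 = 10000))
  const <- tibble::tibble(chrom = "chr1", start = 0, end = 10000,
                          depth = 3)
  anchors <- tibble::tibble(chrom = "chr1", start = c(4000, 6000),
                            end = c(4200, 6200), strand = c("+", "-"))
  for (stat in c("mean", "median")) {
    prof <- metaprofile(const, anchors, g, flank_bp = 1000, nbins = 10,
                        stat = stat)
    expect_equal(prof$value, rep(3, 10))
  }
  # an asymmetric step around a minus-strand anchor is reversed
  step <- tibble::tibble(chrom = "chr1", start = c(0, 5000),
                         end = c(5000, 10000), depth = c(0, 6))
  plus <- metaprofile(step, tibble::tibble(chrom = "chr1", start = 4900,
                                           end = 5100, strand = "+"),
                      g, flank_bp = 500, nbins = 10)
  minus <- metaprofile(step, tibble::tibble(chrom = "chr1", start = 4900,
                                            end = 5100, strand = "-"),
                       g, flank_bp = 500, nbins = 10)
  expect_equal(minus$value, rev(plus$value))
  # clipped anchors warn
  expect_warning(
    metaprofile(const, tibble::tibble(chrom = "chr1", start = 0, end = 10),
                g, flank_bp = 500, nbins = 5),
    "clipped")
})

test_that("replicate concordance gates merging at the stated threshold", {
  counts <- tibble::tibble(region_id = sprintf("r%02d", 1:50),
                           length_kb = 1,
                           rep1 = rpois(50, 50))
  counts$rep2 <- counts$rep1  # duplicated replicate
  rc <- replicate_concordance(counts)
  expect_equal(rc$correlations$r, 1)
  expect_true(rc$merge)
  # discordant replicates are refused
  set.seed(37)
  counts$rep2 <- rpois(50, 50)
  rc2 <- replicate_concordance(counts, threshold = 0.9)
  expect_lt(rc2$min_r, 0.9)
  expect_false(rc2$merge)
  # zero-variance replicate: undefined r fails the gate
  counts$rep2 <- 7
  rc3 <- replicate_concordance(counts)
  expect_true(is.na(rc3$correlations$r))
  expect_false(rc3$merge)
  expect_error(replicate_concordance(counts[, 1:3]), "replicates")
})
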