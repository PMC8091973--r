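test_that("BED parsing handles minimal, malformed and round-trip records", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", path)
  bed <- read_bed(path)
  expect_equal(bed$chrom, "chr1")
  expect_equal(bed$start, 0)
  expect_equal(bed$end, 100)
  expect_equal(bed$strand, ".")

  writeLines("chr1\t100\t100", path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr1\t0\t100", "chr1\t50"), path)
  expect_error(read_bed(path), "line 2")

  # three-record BED6 fixture round-trips field by field
  fixture <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 150, 30),
    end = c(100, 300, 90),
    name = c("a", "b", "c"),
    score = c(1, 2.5, 0),
    strand = c("+", "-", ".")
  )
  write_bed(fixture, path)
  back <- read_bed(path)
  expect_equal(back, fixture)
  # and a BED3 fixture stays BED3
  write_bed(fixture[, 1:3], path)
  expect_equal(length(strsplit(readLines(path)[1], "\t")[[1]]), 3L)
  expect_equal(read_bed(path)[, 1:3], fixture[, 1:3])
})

test_that("unknown chromosomes are dropped with a warning or rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chrUn\t0\t50"), path)
  g <- toy_genome(c(chr1 = 1000))
  expect_warning(bed <- read_bed(path, genome = g), "chrUn")
  expect_equal(nrow(bed), 1L)
  expect_error(read_bed(path, genome = g, unknown_chrom = "error"), "chrUn")
})

test_that("overlap detection follows half-open semantics", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  expect_true(interval_overlaps(
    a, tibble::tibble(chrom = "chr1", start = 9, end = 20)))
  expect_false(interval_overlaps(
    a, tibble::tibble(chrom = "chr1", start = 10, end = 20)))
  expect_false(interval_overlaps(
    a, tibble::tibble(chrom = "chr2", start = 0, end = 10)))
  expect_error(interval_overlaps(a, a, min_bp = 0), "min_bp")
  # min_bp is a real threshold
  b <- tibble::tibble(chrom = "chr1", start = 8, end = 20)
  expect_true(interval_overlaps(a, b, min_bp = 2))
  expect_false(interval_overlaps(a, b, min_bp = 3))
})

test_that("complement tiles each chromosome exactly once", {
  g <- toy_genome(c(chr1 = 1000))
  genes <- tibble::tibble(chrom = "chr1", start = c(200, 600),
                          end = c(400, 700))
  comp <- interval_complement(genes, g)
  expect_equal(comp$start, c(0, 400, 700))
  expect_equal(comp$end, c(200, 600, 1000))
  # empty input: whole chromosomes
  empty <- genes[0, ]
  whole <- interval_complement(empty, g)
  expect_equal(whole$start, 0)
  expect_equal(whole$end, 1000)
})

test_that("nearest-within picks the closest subject with stated tie-breaks", {
  q <- tibble::tibble(chrom = "chr1", start = 10000, end = 10001)
  s <- tibble::tibble(chrom = "chr1", start = c(49000, 299000),
                      end = c(51000, 301000))
  near <- interval_nearest(q, s, max_dist = 250000)
  expect_equal(near$subject, 1L)
  expect_equal(near$distance, 38999)
  # overlap means distance zero
  near0 <- interval_nearest(
    tibble::tibble(chrom = "chr1", start = 49500, end = 49600), s, 250000)
  expect_equal(near0$distance, 0)
  # out of range: unassigned
  far <- interval_nearest(q, s[2, ], max_dist = 250000)
  expect_true(is.na(far$subject))
  # equidistant subjects: lower start wins
  tie <- interval_nearest(
    tibble::tibble(chrom = "chr1", start = 100, end = 200),
    tibble::tibble(chrom = "chr1", start = c(250, 0), end = c(300, 50)),
    1000)
  expect_equal(tie$subject, 2L)
})

test_that("interval algebra invariants hold on randomized sets", {
  set.seed(42)
  g <- toy_genome(c(chr1 = 50000, chr2 = 30000))
  for (trial in 1:25) {
    a <- random_intervals(40, g)
    m <- interval_merge(a)
    # length arithmetic and idempotence
    expect_true(all(m$end - m$start > 0))
    expect_equal(interval_merge(m), m)
    # complement of complement is the merge
    comp <- interval_complement(a, g)
    expect_equal(interval_complement(comp, g), m)
    # bp accounting: coverage(merge) + coverage(complement) = genome
    expect_equal(sum(m$end - m$start) + sum(comp$end - comp$start),
                 sum(g$length))
    expect_equal(sum(m$end - m$start), oracle_coverage_bp(a, g))
  }
})

test_that("overlaps and nearest agree with quadratic oracles", {
  set.seed(7)
  g <- toy_genome(c(chr1 = 50000, chr2 = 30000))
  for (trial in 1:50) {
    a <- random_intervals(60, g)
    b <- random_intervals(60, g)
    min_bp <- sample(c(1, 5, 100), 1)
    expect_identical(interval_overlaps(a, b, min_bp = min_bp),
                     oracle_overlaps(a, b, min_bp = min_bp))
    max_dist <- sample(c(100, 2000, 20000), 1)
    got <- interval_nearest(a, b, max_dist = max_dist)
    want <- oracle_nearest(a, b, max_dist)
    expect_equal(got$subject, as.integer(want$subject))
    expect_equal(got$distance, want$distance)
  }
})

test_that("TSS derivation and promoter windows respect strand and bounds", {
  genes <- tibble::tibble(chrom = "chr1", start = c(100, 5000),
                          end = c(2100, 7000), strand = c("+", "-"),
                          gene_id = c("g1", "g2"))
  tss <- gene_tss(genes)$tss
  expect_equal(tss, c(100, 6999))
  expect_true(all(tss >= genes$start & tss < genes$end))
  g <- toy_genome(c(chr1 = 7200))
  win <- position_windows(tibble::tibble(chrom = "chr1", pos = tss),
                          1000, g)
  expect_equal(win$start, c(0, 5999))
  expect_equal(win$end, c(1100, 7200))
  expect_warning(
    position_windows(tibble::tibble(chrom = "chr1", pos = 7205), 5, g),
    "dropped")
})
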