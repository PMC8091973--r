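# Coverage tracks are run-length encoded step functions stored as tibbles
# (chrom, start, end, depth) whose runs tile each chromosome exactly, zeros
# included. This is the bedGraph representation, so tracks round-trip through
# write_report_tsv/read pipelines unchanged.

#' Pile up fragment coverage
#'
#' `depth(x)` is the number of fragments covering base `x`; the base-pair
#' integral of the track equals the summed fragment lengths exactly.
#'
#' @param fragments Fragment tibble (only `chrom`, `start`, `end` used).
#' @param genome Genome tibble; tracks span every chromosome, zero runs
#'   included.
#' @return Coverage track tibble (`chrom`, `start`, `end`, `depth`).
#' @export
pileup <- function(fragments, genome) {
  frag <- tibble::as_tibble(fragments)
  if (nrow(frag) > 0) {
    validate_intervals(frag, genome = genome, context = "fragments")
  }
  purrr::pmap(genome, function(chrom, length, ...) {
    f <- frag[frag$chrom == chrom, , drop = FALSE]
    cov <- IRanges::coverage(
      IRanges::IRanges(start = f$start + 1L, end = f$end),
      width = length
    )
    ends <- cumsum(S4Vectors::runLength(cov))
    tibble::tibble(chrom = chrom,
                   start = c(0, utils::head(ends, -1)),
                   end = ends,
                   depth = as.numeric(S4Vectors::runValue(cov)))
  }) |>
    dplyr::bind_rows()
}

# track tibble -> named list of S4Vectors::Rle per chromosome
.track_rle <- function(track) {
  split(track, track$chrom) |>
    lapply(function(t) S4Vectors::Rle(t$depth, t$end - t$start))
}

#' Mean coverage in fixed-width bins
#'
#' @param track Coverage track tibble.
#' @param genome Genome tibble.
#' @param bin Bin width in bp (the last bin of a chromosome may be shorter).
#' @return Tibble (`chrom`, `start`, `end`, `depth`) with per-bin mean depth.
#' @export
bin_track <- function(track, genome, bin = 50) {
  stopifnot(bin >= 1)
  rles <- .track_rle(track)
  purrr::pmap(genome, function(chrom, length, ...) {
    starts <- seq(0, length - 1, by = bin)
    ends <- pmin(starts + bin, length)
    r <- rles[[chrom]]
    if (is.null(r)) r <- S4Vectors::Rle(0, length)
    v <- IRanges::Views(r, start = starts + 1, end = ends)
    tibble::tibble(chrom = chrom, start = starts, end = ends,
                   depth = IRanges::viewMeans(v))
  }) |>
    dplyr::bind_rows()
}

#' Differential (log2 ratio) track
#'
#' Bins both tracks to a common bin size, then computes
#' `log2((a + pc) / (b + pc))` per bin.
#'
#' @param a,b Coverage track tibbles on the same genome.
#' @param genome Genome tibble.
#' @param bin Common bin width in bp.
#' @param pseudocount Added to both bin means before the ratio.
#' @return Tibble (`chrom`, `start`, `end`, `log2_ratio`).
#' @export
ratio_track <- function(a, b, genome, bin = 50, pseudocount = 1) {
  if (!setequal(unique(a$chrom), unique(b$chrom))) {
    stop("tracks cover different chromosome sets", call. = FALSE)
  }
  ba <- bin_track(a, genome, bin)
  bb <- bin_track(b, genome, bin)
  dplyr::mutate(ba,
                log2_ratio = log2((.data$depth + pseudocount) /
                                    (bb$depth + pseudocount)),
                depth = NULL)
}

#' Meta-profile of coverage around anchor intervals
#'
#' Each anchor contributes a window of `2 * flank_bp` centered on its
#' midpoint, divided into `nbins` bins of mean depth; minus-strand anchors
#' are reversed so bins always run 5' to 3'. The profile is the per-bin
#' `mean` (default) or `median` across anchors -- the median is the robust
#' choice for signals with an extremely broad intensity range such as Pol II.
#' Windows running past a chromosome end are clipped with a warning and the
#' missing bins ignored.
#'
#' @param track Coverage track tibble.
#' @param anchors Interval tibble, optionally stranded.
#' @param genome Genome tibble.
#' @param flank_bp Half-width of the window around each anchor midpoint.
#' @param nbins Number of profile bins (>= 1).
#' @param stat `"mean"` or `"median"` across anchors.
#' @return Tibble (`bin`, `offset`, `value`) where `offset` is the bin-center
#'   distance from the anchor midpoint in bp.
#' @export
metaprofile <- function(track, anchors, genome, flank_bp = 2500, nbins = 50,
                        stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(nbins >= 1)
  anchors <- validate_intervals(anchors, context = "anchors")
  rles <- .track_rle(track)
  binw <- 2 * flank_bp / nbins
  center <- floor((anchors$start + anchors$end) / 2)
  strand <- if ("strand" %in% names(anchors)) anchors$strand else "."
  clipped <- FALSE
  rows <- purrr::map(seq_len(nrow(anchors)), function(i) {
    chrom <- anchors$chrom[i]
    len <- genome$length[match(chrom, genome$chrom)]
    r <- rles[[chrom]]
    if (is.null(r)) r <- S4Vectors::Rle(0, len)
    w0 <- center[i] - flank_bp
    w1 <- center[i] + flank_bp
    if (w0 < 0 || w1 > len) clipped <<- TRUE
    vals <- rep(NA_real_, 2 * flank_bp)
    lo <- max(w0, 0)
    hi <- min(w1, len)
    if (hi > lo) {
      vals[(lo - w0 + 1):(hi - w0)] <-
        as.numeric(S4Vectors::window(r, start = lo + 1, end = hi))
    }
    binned <- vapply(seq_len(nbins), function(b) {
      j0 <- floor((b - 1) * binw) + 1
      j1 <- floor(b * binw)
      mean(vals[j0:j1], na.rm = TRUE)
    }, numeric(1))
    if (strand[i] == "-") rev(binned) else binned
  })
  if (clipped) warning("anchor window(s) exceeded chromosome bounds; clipped")
  mat <- do.call(rbind, rows)
  value <- apply(mat, 2, match.fun(stat), na.rm = TRUE)
  tibble::tibble(
    bin = seq_len(nbins),
    offset = -flank_bp + binw * (seq_len(nbins) - 0.5),
    value = value
  )
}
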