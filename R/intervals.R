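# Genomic intervals are plain tibbles in BED convention: 0-based, half-open
# [start, end), with columns chrom/start/end and optionally strand ("+", "-",
# ".") plus name and score. A genome is a tibble with columns chrom and length.
# All interval arithmetic below is strand-blind unless stated otherwise.

#' Validate an interval tibble
#'
#' Checks the half-open interval invariants: `0 <= start < end`, and, when a
#' genome is supplied, that every chromosome is declared and no interval runs
#' past the chromosome end.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param genome Optional genome tibble (`chrom`, `length`).
#' @param context Label used in error messages.
#' @return `x` invisibly (as a tibble), for use in pipes.
#' @export
validate_intervals <- function(x, genome = NULL, context = "intervals") {
  if (!is.data.frame(x)) {
    stop(context, " must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    stop(context, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    stop(context, ": empty, negative or malformed interval at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  if ("strand" %in% names(x)) {
    if (!all(x$strand %in% c("+", "-", "."))) {
      stop(context, ": strand must be one of '+', '-', '.'", call. = FALSE)
    }
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown) > 0) {
      stop(context, ": unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    len <- genome$length[match(x$chrom, genome$chrom)]
    if (any(x$end > len)) {
      stop(context, ": interval(s) extend past chromosome end", call. = FALSE)
    }
  }
  invisible(x)
}

# tibble -> GRanges (1-based closed internally; strand ignored)
.as_gr <- function(x, genome = NULL) {
  seqlen <- NULL
  if (!is.null(genome)) {
    seqlen <- stats::setNames(genome$length, genome$chrom)
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    seqlengths = seqlen
  )
}

.gr_to_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Which query intervals overlap a subject set?
#'
#' Element `i` of the result is `TRUE` iff some interval of `b` shares at
#' least `min_bp` base pairs with `a[i, ]`. Overlap is strand-blind and uses
#' half-open arithmetic, so abutting intervals (`[0,10)` vs `[10,20)`) do not
#' overlap.
#'
#' @param a,b Interval tibbles on the same genome.
#' @param min_bp Minimum number of shared base pairs (default 1 = any overlap).
#' @return Logical vector along the rows of `a`.
#' @export
interval_overlaps <- function(a, b, min_bp = 1L) {
  if (!is.numeric(min_bp) || length(min_bp) != 1L || min_bp < 1) {
    stop("min_bp must be a single integer >= 1", call. = FALSE)
  }
  a <- validate_intervals(a, context = "a")
  b <- validate_intervals(b, context = "b")
  # disjoint chromosome sets are a legitimate no-overlap answer, not a
  # user error worth a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_gr(a), .as_gr(b),
                                minoverlap = as.integer(min_bp)))
  out <- logical(nrow(a))
  out[S4Vectors::queryHits(hits)] <- TRUE
  out
}

# All overlapping (query, subject) row pairs sharing >= min_bp.
.overlap_pairs <- function(a, b, min_bp = 1L) {
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_gr(a), .as_gr(b),
                                minoverlap = as.integer(min_bp)))
  tibble::tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
}

#' Merge overlapping or bookended intervals
#'
#' @param a Interval tibble.
#' @return Tibble of disjoint sorted intervals covering the same base pairs.
#' @export
interval_merge <- function(a) {
  a <- validate_intervals(a, context = "a")
  if (nrow(a) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  .gr_to_tbl(GenomicRanges::reduce(.as_gr(a), ignore.strand = TRUE)) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Complement of an interval set over a genome
#'
#' Returns the regions of the genome not covered by `a`. The union of the
#' merged input and its complement tiles every chromosome exactly once, so
#' base-pair accounting is exact: `coverage(merge(a)) + coverage(complement)`
#' equals the genome size.
#'
#' @param a Interval tibble (may be empty).
#' @param genome Genome tibble (`chrom`, `length`).
#' @return Interval tibble of uncovered regions.
#' @export
interval_complement <- function(a, genome) {
  a <- validate_intervals(a, genome = genome, context = "a")
  merged <- interval_merge(a)
  out <- purrr::pmap(genome, function(chrom, length, ...) {
    m <- merged[merged$chrom == chrom, ]
    starts <- c(0L, m$end)
    ends <- c(m$start, length)
    keep <- ends > starts
    tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Subtract one interval set from another
#'
#' @param a,b Interval tibbles.
#' @return The base pairs of `a` not covered by `b`, as merged intervals.
#' @export
interval_setdiff <- function(a, b) {
  a <- validate_intervals(a, context = "a")
  b <- validate_intervals(b, context = "b")
  if (nrow(a) == 0L) return(interval_merge(a))
  if (nrow(b) == 0L) return(interval_merge(a))
  .gr_to_tbl(GenomicRanges::setdiff(.as_gr(a), .as_gr(b),
                                    ignore.strand = TRUE))
}

#' Nearest subject interval within a maximum distance
#'
#' For each query interval, finds the closest subject interval no further
#' than `max_dist` base pairs away. Distance is 0 for any overlap or direct
#' abutment, otherwise the number of base pairs strictly between the closest
#' ends. Ties are broken toward the subject with the lower start, then the
#' lower row index.
#'
#' @param query,subject Interval tibbles on the same genome.
#' @param max_dist Maximum gap in bp (inclusive).
#' @return A tibble with one row per query row: `query` (row index),
#'   `subject` (row index of the nearest subject or `NA`), and `distance`
#'   (gap in bp or `NA`).
#' @export
interval_nearest <- function(query, subject, max_dist = 250000L) {
  query <- validate_intervals(query, context = "query")
  subject <- validate_intervals(subject, context = "subject")
  empty <- tibble::tibble(query = seq_len(nrow(query)),
                          subject = NA_integer_,
                          distance = NA_real_)
  if (nrow(query) == 0L || nrow(subject) == 0L) return(empty)
  # candidate pairs: extend queries so that any subject with gap <= max_dist
  # overlaps the extension
  ext <- dplyr::mutate(query,
                       start = pmax(0, .data$start - max_dist - 1),
                       end = .data$end + max_dist + 1)
  pairs <- .overlap_pairs(ext, subject)
  if (nrow(pairs) == 0L) return(empty)
  s_start <- subject$start
  s_end <- subject$end
  q_start <- query$start
  q_end <- query$end
  pairs <- pairs |>
    dplyr::mutate(
      distance = pmax(
        0,
        s_start[.data$subject] - q_end[.data$query],
        q_start[.data$query] - s_end[.data$subject]
      ),
      s_start = s_start[.data$subject]
    ) |>
    dplyr::filter(.data$distance <= max_dist) |>
    dplyr::arrange(.data$query, .data$distance, .data$s_start,
                   .data$subject) |>
    dplyr::distinct(.data$query, .keep_all = TRUE) |>
    dplyr::select("query", "subject", "distance")
  dplyr::rows_update(empty, pairs, by = "query")
}

#' Transcription start sites of a gene table
#'
#' The TSS of a plus-strand (or unstranded) gene is `start`; for a
#' minus-strand gene it is `end - 1`, the 5'-most base in half-open
#' coordinates, so the TSS always lies inside the gene interval.
#'
#' @param genes Gene tibble with `chrom`, `start`, `end`, `strand` and
#'   `gene_id` columns.
#' @return `genes` with a `tss` column added.
#' @export
gene_tss <- function(genes) {
  genes <- validate_intervals(genes, context = "genes")
  strand <- if ("strand" %in% names(genes)) genes$strand else "."
  dplyr::mutate(genes,
                tss = ifelse(strand == "-", .data$end - 1L, .data$start))
}

#' Fixed-width windows around genomic positions
#'
#' Builds `[pos - half_width, pos + half_width)` windows (e.g. TSS +/- 1 kb),
#' clipped to chromosome bounds when a genome is given. Windows that clip to
#' nothing are dropped with a warning.
#'
#' @param x Tibble with `chrom` and `pos` columns; other columns carried
#'   through.
#' @param half_width Half-width in bp.
#' @param genome Optional genome tibble for clipping.
#' @return Interval tibble with `start`/`end` replacing `pos`.
#' @export
position_windows <- function(x, half_width, genome = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "pos") %in% names(x)))
  out <- tibble::as_tibble(x) |>
    dplyr::mutate(start = .data$pos - half_width,
                  end = .data$pos + half_width) |>
    dplyr::select(-"pos")
  out$start <- pmax(out$start, 0)
  if (!is.null(genome)) {
    len <- genome$length[match(out$chrom, genome$chrom)]
    if (anyNA(len)) {
      stop("position_windows: unknown chromosome(s)", call. = FALSE)
    }
    out$end <- pmin(out$end, len)
  }
  drop <- out$end <= out$start
  if (any(drop)) {
    warning(sum(drop), " window(s) clipped to nothing and dropped")
    out <- out[!drop, ]
  }
  out
}
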