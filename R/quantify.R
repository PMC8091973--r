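# Quantitative readouts over calibrated fragments: per-region counts and
# densities, per-kb log2 quantification with pseudocounts, fixed-width bin
# profiles, per-chromatin-state fold-change distributions with the
# intergenic-median baseline, and replicate-concordance gating.

#' Count fragments in regions
#'
#' A fragment is counted in every region it overlaps by at least one base
#' pair (any-overlap, the multi-region semantics of standard coverage
#' summarizers), so a fragment spanning two abutting regions is counted in
#' both. With a `sample` column present the count is per region x sample.
#'
#' @param fragments Fragment tibble.
#' @param regions Interval tibble; a `region_id` column is added from `name`
#'   or the row index when absent.
#' @param min_bp Minimum overlap in bp.
#' @return Long tibble (`region_id`[, `sample`], `count`) including zero
#'   rows.
#' @export
count_in_regions <- function(fragments, regions, min_bp = 1L) {
  if (nrow(regions) == 0L) stop("empty region set", call. = FALSE)
  regions <- validate_intervals(regions, context = "regions")
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- if ("name" %in% names(regions) &&
                             !anyNA(regions$name) &&
                             !anyDuplicated(regions$name)) {
      regions$name
    } else {
      sprintf("region%05d", seq_len(nrow(regions)))
    }
  }
  by_sample <- "sample" %in% names(fragments)
  samples <- if (by_sample) unique(fragments$sample) else "all"
  pairs <- .overlap_pairs(fragments, regions, min_bp = min_bp)
  pairs$region_id <- regions$region_id[pairs$subject]
  pairs$sample <- if (by_sample) fragments$sample[pairs$query] else "all"
  grid <- tidyr::expand_grid(region_id = regions$region_id,
                             sample = samples)
  out <- pairs |>
    dplyr::count(.data$region_id, .data$sample, name = "count") |>
    dplyr::right_join(grid, by = c("region_id", "sample")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(match(.data$region_id, regions$region_id))
  if (!by_sample) out$sample <- NULL
  out
}

#' Per-region densities and a condition contrast
#'
#' Merges replicate counts per condition, normalizes to region size in kb,
#' and quantifies on the log2 scale with a pseudocount of 1:
#' `log2density = log2(count/kb + 1)` and, for the contrast B vs A,
#' `lfc = log2((count_B/kb + 1) / (count_A/kb + 1))`. Swapping the contrast
#' negates `lfc` exactly.
#'
#' @param fragments Calibrated fragment tibble with a `sample` column.
#' @param regions Interval tibble.
#' @param sample_info Tibble (`sample`, `condition`).
#' @param contrast Character vector `c(numerator, denominator)` of condition
#'   labels.
#' @param pseudocount Pseudocount added to per-kb densities.
#' @return Tibble with per-region counts, densities, log2 densities and
#'   `lfc`.
#' @export
quantify_regions <- function(fragments, regions, sample_info,
                             contrast = c("B", "A"), pseudocount = 1) {
  counts <- count_in_regions(fragments, regions)
  counts$condition <- sample_info$condition[match(counts$sample,
                                                  sample_info$sample)]
  if (!"region_id" %in% names(regions)) {
    regions <- dplyr::mutate(
      regions,
      region_id = if ("name" %in% names(regions) && !anyNA(regions$name) &&
                      !anyDuplicated(regions$name)) regions$name
                  else sprintf("region%05d", dplyr::row_number()))
  }
  kb <- (regions$end - regions$start) / 1000
  wide <- counts |>
    dplyr::filter(.data$condition %in% contrast) |>
    dplyr::count(.data$region_id, .data$condition, wt = .data$count,
                 name = "count") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "count",
                       values_fill = 0)
  wide <- wide[match(regions$region_id, wide$region_id), ]
  num <- wide[[contrast[1]]]
  den <- wide[[contrast[2]]]
  tibble::tibble(
    region_id = regions$region_id,
    length_kb = kb,
    count_num = num,
    count_den = den,
    density_num = num / kb,
    density_den = den / kb,
    log2density_num = log2(num / kb + pseudocount),
    log2density_den = log2(den / kb + pseudocount),
    lfc = log2((num / kb + pseudocount) / (den / kb + pseudocount))
  )
}

#' Fragment counts in fixed-width genomic bins
#'
#' With `mode = "midpoint"` (default) each fragment is assigned to exactly
#' one bin by its midpoint, so bin counts sum to the fragment count exactly;
#' `mode = "overlap"` counts a fragment in every bin it touches.
#'
#' @param fragments Fragment tibble.
#' @param genome Genome tibble.
#' @param bin Bin width in bp (default 250 kb, the chromosome-density scale).
#' @param mode Assignment semantics.
#' @return Tibble (`chrom`, `start`, `end`[, `sample`], `count`) covering
#'   every bin of the genome.
#' @export
binned_coverage <- function(fragments, genome, bin = 250000,
                            mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(bin > 0)
  bins <- purrr::pmap(genome, function(chrom, length, ...) {
    starts <- seq(0, length - 1, by = bin)
    tibble::tibble(chrom = chrom, start = starts,
                   end = pmin(starts + bin, length))
  }) |>
    dplyr::bind_rows()
  by_sample <- "sample" %in% names(fragments)
  if (mode == "midpoint") {
    mid <- floor((fragments$start + fragments$end) / 2)
    key <- paste0(fragments$chrom, ":", (mid %/% bin) * bin)
    binkey <- paste0(bins$chrom, ":", bins$start)
    grp <- if (by_sample) fragments$sample else rep("all", nrow(fragments))
    tab <- tibble::tibble(key = key, sample = grp) |>
      dplyr::count(.data$key, .data$sample, name = "count")
    grid <- tidyr::expand_grid(key = binkey,
                               sample = unique(if (by_sample) grp else "all"))
    out <- dplyr::right_join(tab, grid, by = c("key", "sample")) |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
    out <- dplyr::bind_cols(
      bins[match(out$key, binkey), ],
      out[, c("sample", "count")]
    )
  } else {
    bins$region_id <- sprintf("region%05d", seq_len(nrow(bins)))
    counted <- count_in_regions(fragments, bins)
    out <- dplyr::bind_cols(
      bins[match(counted$region_id, bins$region_id),
           c("chrom", "start", "end")],
      counted[, setdiff(names(counted), "region_id"), drop = FALSE]
    )
    if (!"sample" %in% names(out)) out$sample <- "all"
  }
  if (!by_sample && "sample" %in% names(out)) out$sample <- NULL
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Per-chromatin-state fold-change distributions
#'
#' Tiles the genome into fixed-width bins, assigns each bin the state
#' covering its midpoint (the segmentation must partition the genome),
#' computes the per-bin log2 fold change of condition B over condition A
#' fragment counts (pseudocount 1), and summarizes each state by its
#' quartiles with 1.5 x IQR whiskers. The baseline is the median bin LFC in
#' the intergenic state -- the overall genome-wide change against which
#' state-specific behavior is read.
#'
#' @param frags_a,frags_b Calibrated fragment tibbles for the two conditions
#'   (A = denominator, B = numerator).
#' @param states Interval tibble with a `name` column partitioning the
#'   genome.
#' @param genome Genome tibble.
#' @param bin Bin width in bp.
#' @param pseudocount Pseudocount for the per-bin ratio.
#' @param intergenic_state Name of the intergenic state used for the
#'   baseline.
#' @return List of class `calq_state_lfc`: `bins` (per-bin state and LFC),
#'   `summary` (per-state n, quartiles, whiskers), `baseline` (median
#'   intergenic LFC).
#' @export
state_fold_changes <- function(frags_a, frags_b, states, genome,
                               bin = 10000, pseudocount = 1,
                               intergenic_state = "Intergenic") {
  states <- validate_intervals(states, genome = genome, context = "states")
  ca <- binned_coverage(frags_a[, c("chrom", "start", "end")], genome, bin)
  cb <- binned_coverage(frags_b[, c("chrom", "start", "end")], genome, bin)
  mids <- tibble::tibble(chrom = ca$chrom,
                         start = floor((ca$start + ca$end) / 2))
  mids$end <- mids$start + 1
  pairs <- .overlap_pairs(mids, states)
  state <- rep(NA_character_, nrow(ca))
  state[pairs$query] <- states$name[pairs$subject]
  bins_tbl <- tibble::tibble(
    chrom = ca$chrom, start = ca$start, end = ca$end, state = state,
    count_a = ca$count, count_b = cb$count,
    lfc = log2((cb$count + pseudocount) / (ca$count + pseudocount))
  )
  missing_states <- setdiff(unique(states$name), unique(state))
  if (length(missing_states) > 0) {
    warning("state(s) with no bins: ",
            paste(missing_states, collapse = ", "))
  }
  summary <- bins_tbl |>
    dplyr::filter(!is.na(.data$state)) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$lfc, 0.25),
      median = stats::median(.data$lfc),
      q3 = stats::quantile(.data$lfc, 0.75),
      .groups = "drop"
    ) |>
    dplyr::mutate(iqr = .data$q3 - .data$q1,
                  whisker_lo = .data$q1 - 1.5 * .data$iqr,
                  whisker_hi = .data$q3 + 1.5 * .data$iqr)
  baseline <- stats::median(
    bins_tbl$lfc[!is.na(bins_tbl$state) &
                   bins_tbl$state == intergenic_state])
  structure(list(bins = bins_tbl, summary = summary, baseline = baseline),
            class = "calq_state_lfc")
}

#' Replicate concordance and the merge decision
#'
#' Computes pairwise Pearson correlations of per-region log2 densities
#' (`log2(count/kb + 1)`) between replicates; replicates may be merged only
#' when every pairwise correlation exceeds the threshold (default 0.9). A
#' zero-variance replicate yields an undefined correlation and fails the
#' gate.
#'
#' @param counts Wide tibble: `region_id`, `length_kb`, one numeric column
#'   per replicate.
#' @param threshold Minimum pairwise Pearson r permitting a merge.
#' @return List: `correlations` (long tibble `rep_a`, `rep_b`, `r`),
#'   `min_r`, `merge` (logical).
#' @export
replicate_concordance <- function(counts, threshold = 0.9) {
  rep_cols <- setdiff(names(counts), c("region_id", "length_kb"))
  if (length(rep_cols) < 2) stop("need >= 2 replicates", call. = FALSE)
  kb <- if ("length_kb" %in% names(counts)) counts$length_kb else 1
  m <- sapply(rep_cols, function(cn) log2(counts[[cn]] / kb + 1))
  cm <- suppressWarnings(stats::cor(m, method = "pearson"))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  correlations <- tibble::tibble(
    rep_a = rep_cols[idx[, 1]],
    rep_b = rep_cols[idx[, 2]],
    r = cm[idx]
  )
  min_r <- suppressWarnings(min(correlations$r))
  list(
    correlations = correlations,
    min_r = min_r,
    merge = all(!is.na(correlations$r)) && all(correlations$r > threshold)
  )
}
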