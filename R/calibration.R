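# Spike-in calibration. For ChIP/ATAC sample i with matched input/gDNA
# control:
#   S_i, M_i  spike-in and target fragment counts in the ChIP/ATAC library
#   s_i, m_i  the same counts in the matched control
#   alpha_i = s_i / m_i          mixing ratio (spike:target read ratio in
#                                the control, proportional to the cell mix)
#   D_i     = S_i / alpha_i      mixing-corrected spike-in depth
#   p_i     = min_j D_j / D_i    subsampling probability
# Dividing S by alpha cancels cell-mixing variation: doubling the spike-in
# cell input doubles both S and alpha, leaving D unchanged, so D varies only
# with per-cell target occupancy and sequencing depth. Subsampling each
# sample's target fragments by p_i equalizes the per-spike-cell depth across
# samples; the reference is the sample with the minimum corrected depth, the
# only choice with all p <= 1 (no read duplication).

#' Compute spike-in calibration factors
#'
#' @param fragments Fragment tibble covering ChIP/ATAC and control samples,
#'   with columns `sample`, `genome` (`"target"`/`"spike"`), `chrom`,
#'   `start`, `end`.
#' @param sample_info Tibble with one row per ChIP/ATAC sample: `sample` and
#'   its matched `control` sample id; other columns (condition, replicate)
#'   are carried through.
#' @return A tibble with per-sample `S`, `M`, `s`, `m`, `alpha`, `D` and the
#'   subsampling probability `p` (exactly one sample has `p = 1`).
#' @export
compute_calibration <- function(fragments, sample_info) {
  stopifnot(all(c("sample", "genome") %in% names(fragments)),
            all(c("sample", "control") %in% names(sample_info)))
  counts <- fragments |>
    dplyr::count(.data$sample, .data$genome) |>
    tidyr::pivot_wider(names_from = "genome", values_from = "n",
                       values_fill = 0L)
  for (col in c("target", "spike")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  lookup <- function(ids, col, role) {
    i <- match(ids, counts$sample)
    if (anyNA(i)) {
      stop("missing ", role, " sample(s): ",
           paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
    }
    counts[[col]][i]
  }
  out <- sample_info |>
    dplyr::mutate(
      S = lookup(.data$sample, "spike", "ChIP"),
      M = lookup(.data$sample, "target", "ChIP"),
      s = lookup(.data$control, "spike", "control"),
      m = lookup(.data$control, "target", "control")
    )
  zero <- out$S == 0 | out$M == 0 | out$s == 0 | out$m == 0
  if (any(zero)) {
    stop("zero spike-in or target fragment count in sample(s): ",
         paste(out$sample[zero], collapse = ", "), call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(alpha = .data$s / .data$m,
                  D = .data$S / .data$alpha,
                  p = min(.data$D) / .data$D)
  out
}

#' Randomly subsample target-genome fragments
#'
#' Each target fragment is kept independently with probability `p`; spike-in
#' fragments are dropped (they play no further role after factor
#' computation). Deterministic under `seed`; when `sample_id` is given the
#' RNG stream is keyed by (seed, sample id) so adding samples to a run never
#' perturbs the draws of the others.
#'
#' @param fragments Fragment tibble for one sample.
#' @param p Retention probability in (0, 1].
#' @param seed Integer seed.
#' @param sample_id Optional stream key (defaults to the `sample` column
#'   value when unique).
#' @return The retained target fragments.
#' @export
subsample_fragments <- function(fragments, p, seed = 1, sample_id = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("p must be a single probability in (0, 1]", call. = FALSE)
  }
  tgt <- fragments[fragments$genome == "target", , drop = FALSE]
  if (p == 1) return(tibble::as_tibble(tgt))
  if (is.null(sample_id)) {
    sample_id <- if ("sample" %in% names(tgt) && nrow(tgt) > 0)
      tgt$sample[[1]] else "sample"
  }
  keep <- .with_seed(.derive_seed(seed, paste0("subsample_", sample_id)),
                     stats::runif(nrow(tgt)) < p)
  tibble::as_tibble(tgt[keep, , drop = FALSE])
}

#' Calibrate all samples of an experiment
#'
#' Applies [subsample_fragments()] with each sample's computed probability
#' and returns the pooled calibrated target fragments.
#'
#' @param fragments Fragment tibble covering all samples.
#' @param calibration Output of [compute_calibration()].
#' @param seed Integer seed.
#' @return Tibble of retained target fragments for the ChIP/ATAC samples.
#' @export
calibrate_fragments <- function(fragments, calibration, seed = 1) {
  purrr::pmap(calibration[, c("sample", "p")], function(sample, p) {
    subsample_fragments(fragments[fragments$sample == sample, ], p,
                        seed = seed, sample_id = sample)
  }) |>
    dplyr::bind_rows()
}

#' Optional blacklist filter
#'
#' Removes fragments overlapping a blacklist interval set (regions with
#' artificially high counts or poor mappability, supplied by the user).
#'
#' @param fragments Fragment tibble.
#' @param blacklist Interval tibble.
#' @return Fragments with blacklist-overlapping rows removed.
#' @export
filter_blacklist <- function(fragments, blacklist) {
  if (nrow(blacklist) == 0L) return(fragments)
  hit <- interval_overlaps(fragments[, c("chrom", "start", "end")],
                           blacklist)
  fragments[!hit, , drop = FALSE]
}
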