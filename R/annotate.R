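# Region and gene taxonomies: active regulatory elements (ATAC peaks backed
# by H3K27ac), their promoter/enhancer split by TSS +/- 1 kb windows, the
# intergenic-enhancer flag, promoter-to-enhancer links, and the three-way
# gene partition (non-NMI / PcG / non-PcG) by promoter overlap with
# nonmethylated islands and Polycomb-bound sites.

#' Call active regulatory elements
#'
#' Active elements are the ATAC peaks that overlap at least one H3K27ac
#' peak; H3K27ac acts only as a filter, so element coordinates are the
#' accessibility footprint. Elements overlapping any TSS +/- `tss_halfwidth`
#' window are classed `active_promoter`, the rest `active_enhancer`. TSS
#' positions are deduplicated exactly.
#'
#' @param atac_peaks,h3k27ac_peaks Interval tibbles of peaks.
#' @param tss Tibble of TSS positions (`chrom`, `pos`).
#' @param genome Optional genome tibble for window clipping.
#' @param tss_halfwidth Promoter window half-width in bp (default 1 kb).
#' @return The ATAC peaks that are active elements, with an `element_class`
#'   column.
#' @export
call_active_elements <- function(atac_peaks, h3k27ac_peaks, tss,
                                 genome = NULL, tss_halfwidth = 1000) {
  if (is.null(tss) || nrow(tss) == 0L) {
    stop("TSS set is empty", call. = FALSE)
  }
  atac_peaks <- validate_intervals(atac_peaks, context = "atac_peaks")
  tss <- dplyr::distinct(tss, .data$chrom, .data$pos)
  active <- interval_overlaps(atac_peaks, h3k27ac_peaks)
  elements <- atac_peaks[active, , drop = FALSE]
  windows <- position_windows(tss, tss_halfwidth, genome)
  at_tss <- interval_overlaps(elements, windows)
  dplyr::mutate(elements,
                element_class = ifelse(at_tss, "active_promoter",
                                       "active_enhancer"))
}

#' Flag intergenic enhancers
#'
#' An element is intergenic iff it is an active enhancer with zero overlap
#' to any interval of the combined gene annotation.
#'
#' @param elements Output of [call_active_elements()].
#' @param genes Combined gene-annotation interval tibble.
#' @return `elements` with a logical `intergenic` column.
#' @export
flag_intergenic <- function(elements, genes) {
  in_gene <- interval_overlaps(elements, genes)
  dplyr::mutate(elements,
                intergenic = .data$element_class == "active_enhancer" &
                  !in_gene)
}

#' Link each gene promoter to its nearest intergenic enhancer
#'
#' @param promoters Interval tibble of promoter windows; a `gene_id` column
#'   is carried into the result if present.
#' @param enhancers Interval tibble of intergenic enhancers.
#' @param max_dist Maximum distance in bp (default 250 kb).
#' @return Tibble with one row per promoter: `gene_id` (if present),
#'   `enhancer` (row index into `enhancers`, `NA` if none within range) and
#'   `distance`.
#' @export
link_promoter_to_enhancer <- function(promoters, enhancers,
                                      max_dist = 250000) {
  near <- interval_nearest(promoters, enhancers, max_dist = max_dist)
  out <- tibble::tibble(enhancer = near$subject, distance = near$distance)
  if ("gene_id" %in% names(promoters)) {
    out <- dplyr::bind_cols(tibble::tibble(gene_id = promoters$gene_id), out)
  }
  out
}

#' Classify genes by promoter chromatin
#'
#' Partitions genes into three disjoint classes by the overlap of their
#' TSS +/- `promoter_halfwidth` promoter window: `non_NMI` when the promoter
#' overlaps no nonmethylated island; otherwise `PcG` when it overlaps at
#' least one RING1B-bound *and* one SUZ12-bound site (both Polycomb
#' complexes required); otherwise `non_PcG`.
#'
#' @param genes Gene tibble (`chrom`, `start`, `end`, `strand`, `gene_id`).
#' @param nmis,ring1b_sites,suz12_sites Interval tibbles.
#' @param genome Optional genome tibble for window clipping.
#' @param promoter_halfwidth Promoter half-width in bp (default 1 kb).
#' @return Tibble (`gene_id`, `class`); every gene appears exactly once.
#' @export
classify_genes <- function(genes, nmis, ring1b_sites, suz12_sites,
                           genome = NULL, promoter_halfwidth = 1000) {
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id", call. = FALSE)
  }
  genes <- gene_tss(genes)
  prom <- position_windows(
    dplyr::mutate(genes, pos = .data$tss)[, c("chrom", "pos", "gene_id")],
    promoter_halfwidth, genome
  )
  has_nmi <- interval_overlaps(prom, nmis)
  has_ring <- interval_overlaps(prom, ring1b_sites)
  has_suz <- interval_overlaps(prom, suz12_sites)
  tibble::tibble(
    gene_id = prom$gene_id,
    class = dplyr::case_when(
      !has_nmi ~ "non_NMI",
      has_ring & has_suz ~ "PcG",
      TRUE ~ "non_PcG"
    )
  )
}
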