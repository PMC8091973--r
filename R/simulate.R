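# Synthetic spike-in-mixed experiments with known ground truth. The
# generators are pure functions of their parameters and a seed: every sample
# draws from its own RNG stream keyed by (seed, sample id), so adding a
# sample never perturbs the others, and re-runs are identical.

# Deterministic per-sample sub-seed (kept below 2^31).
.derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 1000000007
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate code under a temporary RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Toy genomes for simulation and tests
#'
#' Defaults: a 2 x 5 Mb target genome and a 1 x 2 Mb spike-in genome, small
#' enough that full simulated experiments run in seconds.
#'
#' @param chroms Named vector of chromosome lengths.
#' @param label Genome label.
#' @return Genome tibble (`chrom`, `length`).
#' @export
toy_genome <- function(chroms = c(chr1 = 5e6, chr2 = 5e6), label = "target") {
  out <- tibble::tibble(chrom = names(chroms), length = unname(chroms))
  attr(out, "label") <- label
  out
}

#' @rdname toy_genome
#' @export
toy_spike_genome <- function(chroms = c(spk1 = 2e6)) {
  toy_genome(chroms, label = "spike")
}

# Draw n fragment intervals from a piecewise-constant intensity over states.
.draw_fragments <- function(n, states, weights, genome, frag_len) {
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  idx <- sample.int(nrow(states), n, replace = TRUE, prob = weights)
  width <- states$end[idx] - states$start[idx]
  pos <- floor(states$start[idx] + stats::runif(n) * width)
  len <- genome$length[match(states$chrom[idx], genome$chrom)]
  end <- pmin(pos + frag_len, len)
  tibble::tibble(chrom = states$chrom[idx], start = pos, end = end)
}

#' Simulate a two-condition spike-in calibrated ChIP experiment
#'
#' Emulates a spike-in-mixed ChIP-seq (or ATAC-seq) design: target-genome
#' fragments are drawn with intensity proportional to a per-state enrichment,
#' multiplied by `global_shift` in condition B; spike-in fragments are drawn
#' uniformly with an expected share proportional to the per-replicate cell
#' mixing (lognormal jitter around `mixing`); each ChIP sample has a matched
#' input drawn uniformly over both genomes at the same realized mixing.
#' Sequencing depth is fixed per sample, so a genuine global occupancy shift
#' changes the target:spike read ratio -- the signal the calibration stage
#' recovers.
#'
#' @param genome_target,genome_spike Genome tibbles.
#' @param states Interval tibble tiling the target genome, with a `name`
#'   column naming each state.
#' @param enrichment Named per-state enrichment multipliers (default all 1).
#' @param global_shift True genome-wide occupancy multiplier applied in
#'   condition B.
#' @param n_rep Replicates per condition.
#' @param depth Total fragments per sample (target + spike).
#' @param mixing Spike-in:target cell ratio (default 0.4, the 4e6:1e7 design).
#' @param mixing_sd Lognormal sigma of the per-replicate mixing jitter.
#' @param frag_len Fragment length in bp.
#' @param seed Integer seed.
#' @return A list of class `calq_chip_sim`: `fragments` (tibble with
#'   `sample`, `genome`, `chrom`, `start`, `end`), `samples` (per-sample
#'   metadata incl. matched `control`, realized `mixing` and the true
#'   `shift`), and `params`.
#' @export
simulate_chip_experiment <- function(genome_target, genome_spike, states,
                                     enrichment = NULL, global_shift = 2,
                                     n_rep = 1, depth = 2e5, mixing = 0.4,
                                     mixing_sd = 0.15, frag_len = 200,
                                     seed = 1) {
  stopifnot(global_shift > 0, depth > 0, mixing > 0, mixing < 1 * 10)
  if (any(genome_target$length <= 0) || any(genome_spike$length <= 0)) {
    stop("zero-length genome", call. = FALSE)
  }
  states <- validate_intervals(states, genome = genome_target,
                               context = "states")
  if (!"name" %in% names(states)) states$name <- "genome"
  if (is.null(enrichment)) {
    enrichment <- stats::setNames(rep(1, length(unique(states$name))),
                                  unique(states$name))
  }
  if (!all(states$name %in% names(enrichment))) {
    stop("enrichment missing for state(s): ",
         paste(setdiff(states$name, names(enrichment)), collapse = ", "),
         call. = FALSE)
  }
  spike_states <- dplyr::mutate(genome_spike, start = 0, end = .data$length,
                                name = "spike")[, c("chrom", "start", "end",
                                                    "name")]
  grid <- tidyr::expand_grid(condition = c("A", "B"),
                             replicate = seq_len(n_rep))
  sim_pair <- function(condition, replicate) {
    key <- paste0(condition, "_rep", replicate)
    .with_seed(.derive_seed(seed, key), {
      mix_i <- mixing * stats::rlnorm(1, meanlog = -mixing_sd^2 / 2,
                                      sdlog = mixing_sd)
      shift_i <- if (condition == "B") global_shift else 1
      w_target <- (states$end - states$start) *
        enrichment[states$name] * shift_i
      w_spike_total <- mix_i * sum(genome_spike$length)
      p_target <- sum(w_target) / (sum(w_target) + w_spike_total)
      draw_sample <- function(sample, target_weights, p_t, n) {
        n_target <- stats::rbinom(1, n, p_t)
        tgt <- .draw_fragments(n_target, states, target_weights,
                               genome_target, frag_len)
        spk <- .draw_fragments(n - n_target, spike_states,
                               spike_states$end - spike_states$start,
                               genome_spike, frag_len)
        dplyr::bind_rows(
          dplyr::mutate(tgt, genome = "target"),
          dplyr::mutate(spk, genome = "spike")
        ) |>
          dplyr::mutate(sample = sample, .before = 1)
      }
      chip <- draw_sample(paste0("chip_", key), w_target, p_target, depth)
      # matched input: uniform over the target genome at the same mixing
      w_input <- (states$end - states$start)
      p_input <- sum(w_input) / (sum(w_input) + w_spike_total)
      input <- draw_sample(paste0("input_", key), w_input, p_input, depth)
      list(
        fragments = dplyr::bind_rows(chip, input),
        info = tibble::tibble(
          sample = paste0("chip_", key),
          control = paste0("input_", key),
          condition = condition,
          replicate = replicate,
          mixing = mix_i,
          shift = shift_i
        )
      )
    })
  }
  pairs <- purrr::pmap(grid, sim_pair)
  structure(
    list(
      fragments = dplyr::bind_rows(purrr::map(pairs, "fragments")),
      samples = dplyr::bind_rows(purrr::map(pairs, "info")),
      params = list(global_shift = global_shift, enrichment = enrichment,
                    depth = depth, mixing = mixing, mixing_sd = mixing_sd,
                    frag_len = frag_len, seed = seed)
    ),
    class = "calq_chip_sim"
  )
}

#' Simulate a gene table on a genome
#'
#' Places non-overlapping fixed-length genes on a regular grid with
#' alternating strands, leaving room for promoter windows at both ends.
#'
#' @param genome Genome tibble.
#' @param n_genes Number of genes.
#' @param gene_length Gene length in bp.
#' @param seed Integer seed (strand assignment).
#' @return Gene tibble with `gene_id` and `tss`.
#' @export
simulate_gene_table <- function(genome, n_genes = 1000, gene_length = 4000,
                                seed = 1) {
  per_chrom <- diff(round(seq(0, n_genes,
                              length.out = nrow(genome) + 1)))
  out <- purrr::pmap(cbind(genome, n = per_chrom),
                     function(chrom, length, n, ...) {
    if (n == 0) return(NULL)
    spacing <- floor((length - 4000) / n)
    if (spacing < gene_length + 4000) {
      stop("genome too small for ", n, " genes of ", gene_length, " bp",
           call. = FALSE)
    }
    start <- 2000 + spacing * (seq_len(n) - 1)
    tibble::tibble(chrom = chrom, start = start, end = start + gene_length)
  })
  out <- dplyr::bind_rows(out)
  out <- .with_seed(.derive_seed(seed, "genes"), {
    dplyr::mutate(out,
                  strand = sample(c("+", "-"), nrow(out), replace = TRUE),
                  gene_id = sprintf("gene%05d", dplyr::row_number()))
  })
  gene_tss(out)
}

#' Simulate spike-in calibrated RNA-seq counts
#'
#' Target-gene counts are negative binomial with mean
#' `baseline * sf_i * 2^(lfc * [condition B])`; spike-in gene counts scale
#' only with the per-sample depth factor `sf_i` and the realized cell-mixing
#' jitter; the per-sample gDNA spike/target read ratio `rho` is emitted
#' proportional to the realized mixing, so dividing spike counts by `rho`
#' cancels mixing variation.
#'
#' @param genes_target Gene tibble (needs `gene_id`; `length` used for RPKM).
#' @param genes_spike Spike-in gene tibble (needs `gene_id`).
#' @param lfc True per-gene log2 fold changes (length `nrow(genes_target)`,
#'   recycled).
#' @param baseline Per-gene baseline mean counts; `NULL` draws lognormal
#'   means (meanlog `log(250)`, sdlog 1).
#' @param n_rep Replicates per condition (>= 2).
#' @param dispersion NB dispersion (0 gives Poisson counts).
#' @param sf True per-sample depth factors; `NULL` draws lognormal factors
#'   (sdlog 0.2).
#' @param mixing,mixing_sd Spike-in cell mixing and its lognormal jitter.
#' @param spike_baseline Per-spike-gene baseline means; `NULL` draws
#'   lognormal.
#' @param rho_scale Constant linking realized mixing to the gDNA spike/target
#'   read ratio.
#' @param seed Integer seed.
#' @return A list of class `calq_rna_sim`: `counts` and `spike_counts`
#'   (tibbles, `gene_id` + one column per sample), `samples` (`sample`,
#'   `condition`, `rho`, `sf_true`, `mixing`), `truth` (`gene_id`,
#'   `baseline`, `lfc`) and `params`.
#' @export
simulate_rna_counts <- function(genes_target, genes_spike, lfc = 0,
                                baseline = NULL, n_rep = 3,
                                dispersion = 0.05, sf = NULL, mixing = 0.4,
                                mixing_sd = 0.15, spike_baseline = NULL,
                                rho_scale = 0.1, seed = 1) {
  stopifnot(dispersion >= 0, n_rep >= 2)
  n_g <- nrow(genes_target)
  n_s <- nrow(genes_spike)
  lfc <- rep_len(lfc, n_g)
  samples <- tidyr::expand_grid(condition = c("A", "B"),
                                replicate = seq_len(n_rep)) |>
    dplyr::mutate(sample = paste0("rna_", .data$condition, "_rep",
                                  .data$replicate))
  n_samp <- nrow(samples)
  shared <- .with_seed(.derive_seed(seed, "rna_shared"), {
    list(
      baseline = if (is.null(baseline)) {
        stats::rlnorm(n_g, meanlog = log(250), sdlog = 1)
      } else rep_len(baseline, n_g),
      spike_baseline = if (is.null(spike_baseline)) {
        stats::rlnorm(n_s, meanlog = log(250), sdlog = 1)
      } else rep_len(spike_baseline, n_s),
      sf = if (is.null(sf)) {
        stats::rlnorm(n_samp, meanlog = 0, sdlog = 0.2)
      } else rep_len(sf, n_samp)
    )
  })
  rnb <- function(n, mu) {
    if (dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  per_sample <- purrr::pmap(
    dplyr::mutate(samples, sf_true = shared$sf),
    function(condition, replicate, sample, sf_true) {
      .with_seed(.derive_seed(seed, sample), {
        mix_i <- mixing * stats::rlnorm(1, meanlog = -mixing_sd^2 / 2,
                                        sdlog = mixing_sd)
        mu_t <- shared$baseline * sf_true *
          2^(lfc * (condition == "B"))
        mu_s <- shared$spike_baseline * sf_true * (mix_i / mixing)
        list(target = rnb(n_g, mu_t), spike = rnb(n_s, mu_s),
             mixing = mix_i, rho = rho_scale * mix_i / mixing)
      })
    }
  )
  counts <- tibble::as_tibble(
    stats::setNames(purrr::map(per_sample, "target"), samples$sample)
  )
  spike_counts <- tibble::as_tibble(
    stats::setNames(purrr::map(per_sample, "spike"), samples$sample)
  )
  structure(
    list(
      counts = dplyr::bind_cols(
        tibble::tibble(gene_id = genes_target$gene_id), counts),
      spike_counts = dplyr::bind_cols(
        tibble::tibble(gene_id = genes_spike$gene_id), spike_counts),
      samples = dplyr::mutate(
        samples,
        rho = purrr::map_dbl(per_sample, "rho"),
        sf_true = shared$sf,
        mixing = purrr::map_dbl(per_sample, "mixing")
      )[, c("sample", "condition", "replicate", "rho", "sf_true", "mixing")],
      truth = tibble::tibble(gene_id = genes_target$gene_id,
                             baseline = shared$baseline, lfc = lfc),
      params = list(dispersion = dispersion, mixing = mixing,
                    mixing_sd = mixing_sd, rho_scale = rho_scale,
                    seed = seed)
    ),
    class = "calq_rna_sim"
  )
}

#' Fixture annotations with known overlap structure
#'
#' Generates the annotation sets the region/gene taxonomy consumes -- genes,
#' TSS table, nonmethylated islands (NMIs), RING1B- and SUZ12-bound sites,
#' ATAC and H3K27ac peaks, and a chromatin-state segmentation tiling the
#' genome -- together with the truth labels the classifiers must recover.
#' A fraction `frac_nmi` of genes carry a promoter NMI; of those, a fraction
#' `frac_pcg` carry both RING1B and SUZ12 sites (Polycomb-occupied); some
#' NMI genes carry only one of the two, which must classify as non-PcG.
#'
#' @param genome Target genome tibble.
#' @param n_genes Number of genes.
#' @param frac_nmi Fraction of genes with a promoter NMI.
#' @param frac_pcg Fraction of NMI genes that are Polycomb-occupied.
#' @param frac_active Fraction of genes whose promoter is an active element.
#' @param n_intergenic_enh,n_genic_enh Numbers of intergenic / gene-body
#'   active enhancers.
#' @param seed Integer seed.
#' @return A list: `genes`, `tss`, `nmis`, `ring1b`, `suz12`, `atac_peaks`,
#'   `h3k27ac_peaks`, `states`, `truth_genes` (`gene_id`, `class`),
#'   `truth_elements` (intervals with `element_class` and `intergenic`).
#' @export
make_fixture_annotations <- function(genome, n_genes = 1000, frac_nmi = 0.7,
                                     frac_pcg = 0.4, frac_active = 0.3,
                                     n_intergenic_enh = 60,
                                     n_genic_enh = 40, seed = 1) {
  genes <- simulate_gene_table(genome, n_genes = n_genes, seed = seed)
  .with_seed(.derive_seed(seed, "annotations"), {
    n <- nrow(genes)
    idx <- sample.int(n)
    n_nmi <- round(frac_nmi * n)
    nmi_genes <- idx[seq_len(n_nmi)]
    n_pcg <- round(frac_pcg * n_nmi)
    pcg_genes <- nmi_genes[seq_len(n_pcg)]
    rest_nmi <- setdiff(nmi_genes, pcg_genes)
    # one-mark-only genes exercise the "both marks required" rule
    ring_only <- rest_nmi[seq_len(min(length(rest_nmi), round(0.1 * n)))]
    suz_only <- setdiff(rest_nmi, ring_only)
    suz_only <- suz_only[seq_len(min(length(suz_only), round(0.1 * n)))]

    site <- function(rows, hw) {
      tibble::tibble(chrom = genes$chrom[rows],
                     start = genes$tss[rows] - hw,
                     end = genes$tss[rows] + hw)
    }
    nmis <- site(nmi_genes, 500)
    ring1b <- dplyr::bind_rows(site(pcg_genes, 300), site(ring_only, 300))
    suz12 <- dplyr::bind_rows(site(pcg_genes, 300), site(suz_only, 300))

    truth_genes <- tibble::tibble(
      gene_id = genes$gene_id,
      class = dplyr::case_when(
        seq_len(n) %in% pcg_genes ~ "PcG",
        seq_len(n) %in% nmi_genes ~ "non_PcG",
        TRUE ~ "non_NMI"
      )
    )

    # active promoters: ATAC + H3K27ac peaks over a subset of TSSs
    act_genes <- sort(sample.int(n, round(frac_active * n)))
    prom_peaks <- site(act_genes, 400)
    # intergenic enhancers: midpoints of gaps between gene-grid slots,
    # > 1 kb away from any TSS and outside every gene interval
    tss_wins <- position_windows(
      tibble::tibble(chrom = genes$chrom, pos = genes$tss), 1200, genome)
    gaps <- interval_complement(
      dplyr::bind_rows(tss_wins, genes[, c("chrom", "start", "end")]),
      genome
    ) |>
      dplyr::filter(.data$end - .data$start > 2000)
    pick <- sample.int(nrow(gaps), min(n_intergenic_enh, nrow(gaps)))
    mid <- floor((gaps$start[pick] + gaps$end[pick]) / 2)
    inter_peaks <- tibble::tibble(chrom = gaps$chrom[pick],
                                  start = mid - 300, end = mid + 300)
    # genic (non-promoter) enhancers: in gene bodies, clear of TSS windows
    genic_rows <- sample(setdiff(seq_len(n), act_genes),
                         min(n_genic_enh, n - length(act_genes)))
    body_mid <- ifelse(genes$strand[genic_rows] == "-",
                       genes$start[genic_rows] + 1500,
                       genes$end[genic_rows] - 1500)
    genic_peaks <- tibble::tibble(chrom = genes$chrom[genic_rows],
                                  start = body_mid - 200,
                                  end = body_mid + 200)
    atac_peaks <- dplyr::bind_rows(prom_peaks, inter_peaks, genic_peaks)
    h3k27ac_peaks <- dplyr::mutate(atac_peaks,
                                   start = .data$start - 50,
                                   end = .data$end + 50)
    # a few ATAC-only peaks that must not become elements
    lone <- tibble::tibble(chrom = gaps$chrom[pick[1]],
                           start = gaps$start[pick[1]] + 10,
                           end = gaps$start[pick[1]] + 110)
    atac_peaks <- dplyr::bind_rows(atac_peaks, lone)

    truth_elements <- dplyr::bind_rows(
      dplyr::mutate(prom_peaks, element_class = "active_promoter",
                    intergenic = FALSE),
      dplyr::mutate(inter_peaks, element_class = "active_enhancer",
                    intergenic = TRUE),
      dplyr::mutate(genic_peaks, element_class = "active_enhancer",
                    intergenic = FALSE)
    )

    # chromatin states partitioning the genome: Promoter / GeneBody /
    # Enhancer / Intergenic
    prom_state <- interval_merge(site(seq_len(n), 1000))
    enh_state <- interval_merge(inter_peaks)
    body_state <- interval_setdiff(
      genes[, c("chrom", "start", "end")],
      dplyr::bind_rows(prom_state, enh_state))
    covered <- dplyr::bind_rows(prom_state, enh_state, body_state)
    inter_state <- interval_complement(covered, genome)
    states <- dplyr::bind_rows(
      dplyr::mutate(prom_state, name = "Promoter"),
      dplyr::mutate(body_state, name = "GeneBody"),
      dplyr::mutate(enh_state, name = "Enhancer"),
      dplyr::mutate(inter_state, name = "Intergenic")
    ) |>
      dplyr::arrange(.data$chrom, .data$start)

    list(genes = genes,
         tss = tibble::tibble(chrom = genes$chrom, pos = genes$tss),
         nmis = nmis, ring1b = ring1b, suz12 = suz12,
         atac_peaks = atac_peaks, h3k27ac_peaks = h3k27ac_peaks,
         states = states, truth_genes = truth_genes,
         truth_elements = truth_elements)
  })
}
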