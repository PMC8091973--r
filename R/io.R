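# Readers/writers for the plain-text formats the pipeline touches:
# BED3/BED6 interval files, two-column chrom-sizes tables, gene annotation
# TSVs and fragment BED files carrying a genome-of-origin tag.

#' Read a BED3/BED6 file
#'
#' Parses tab-separated BED records into an interval tibble. Lines with fewer
#' than three fields, non-numeric coordinates, or `start >= end` are reported
#' with their line numbers as an error. With a genome supplied, intervals on
#' undeclared chromosomes are either dropped with a warning or rejected.
#'
#' @param path Path to a BED file.
#' @param genome Optional genome tibble (`chrom`, `length`).
#' @param unknown_chrom What to do with intervals on chromosomes absent from
#'   `genome`: `"warn"` drops them with a warning, `"error"` fails.
#' @return Interval tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (the last three `NA`/`"."` for BED3 input).
#' @export
read_bed <- function(path, genome = NULL,
                     unknown_chrom = c("warn", "error")) {
  unknown_chrom <- match.arg(unknown_chrom)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line(s) (fewer than 3 fields): line ",
         paste(utils::head(lineno[nf < 3L], 5L), collapse = ", "),
         call. = FALSE)
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1))
  }
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    stop("invalid coordinates (non-numeric, negative or start >= end): line ",
         paste(utils::head(lineno[bad], 5L), collapse = ", "), call. = FALSE)
  }
  strand <- col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  out <- tibble::tibble(
    chrom = col(1),
    start = start,
    end = end,
    name = col(4),
    score = suppressWarnings(as.numeric(col(5))),
    strand = strand
  )
  if (!is.null(genome)) {
    unknown <- !out$chrom %in% genome$chrom
    if (any(unknown)) {
      msg <- paste0(sum(unknown), " interval(s) on chromosome(s) not in the ",
                    "genome: ",
                    paste(unique(out$chrom[unknown]), collapse = ", "))
      if (unknown_chrom == "error") stop(msg, call. = FALSE)
      warning(msg, "; dropped")
      out <- out[!unknown, ]
    }
    validate_intervals(out, genome = genome, context = path)
  }
  out
}

#' Write an interval tibble as BED
#'
#' Emits BED3 when no name/score/strand information is present, BED6
#' otherwise (missing names become `"."`, missing scores 0), so a file read
#' with [read_bed()] round-trips field-by-field.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x, context = "x")
  name <- if ("name" %in% names(x)) x$name else rep(NA_character_, nrow(x))
  score <- if ("score" %in% names(x)) x$score else rep(NA_real_, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  bed6 <- any(!is.na(name)) || any(!is.na(score)) || any(strand != ".")
  if (bed6) {
    df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE),
                     ifelse(is.na(name), ".", name),
                     ifelse(is.na(score), 0, score), strand)
  } else {
    df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom-sizes file into a genome tibble
#'
#' @param path Path to a tab-separated `chrom<TAB>length` file.
#' @param label Optional genome label (e.g. `"target"` or `"spike"`),
#'   attached as the `label` attribute.
#' @return Genome tibble (`chrom`, `length`).
#' @export
read_chrom_sizes <- function(path, label = "target") {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(is.na(df$length) | df$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "label") <- label
  out
}

#' Read a gene annotation TSV
#'
#' Expects a header with columns `chrom`, `start`, `end`, `strand`,
#' `gene_id`. Gene ids must be unique; a `tss` column is derived with
#' [gene_tss()].
#'
#' @param path Path to the TSV.
#' @param genome Optional genome tibble used for validation.
#' @return Gene tibble with a `tss` column.
#' @export
read_gene_table <- function(path, genome = NULL) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  need <- c("chrom", "start", "end", "strand", "gene_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("gene table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in gene table", call. = FALSE)
  }
  validate_intervals(df, genome = genome, context = path)
  gene_tss(df)
}

#' Write a tibble as a TSV report
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment BED file
#'
#' Fragment files are BED with the genome-of-origin (`target` or `spike`) in
#' the name column and the sample id carried alongside.
#'
#' @param path Path to a fragment BED.
#' @param sample Sample id to attach.
#' @return Fragment tibble (`sample`, `genome`, `chrom`, `start`, `end`).
#' @export
read_fragments <- function(path, sample) {
  bed <- read_bed(path)
  genome <- ifelse(bed$name %in% c("target", "spike"), bed$name, "target")
  tibble::tibble(sample = sample, genome = genome,
                 chrom = bed$chrom, start = bed$start, end = bed$end)
}

#' Write fragments as BED, tagging genome of origin in the name column
#'
#' @param frags Fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  x <- dplyr::mutate(frags, name = .data$genome, score = 0, strand = ".")
  write_bed(x[, c("chrom", "start", "end", "name", "score", "strand")], path)
}
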