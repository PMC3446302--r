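#' Write an expression matrix to TSV
#'
#' One wide TSV: columns `id`, `class`, `spike_subset`,
#' `spike_expected_lfc`, then one column per sample named
#' `line_sex_rep`. Sample metadata is recovered from the column names on
#' read.
#'
#' @param x an [expr_matrix()].
#' @param path output file.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- cbind(x$probes, as.data.frame(x$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#'
#' @param path input file.
#' @return An [expr_matrix()]. Rejects missing values with an error.
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta_cols <- c("id", "class", "spike_subset", "spike_expected_lfc")
  probes <- df[, meta_cols]
  vals <- as.matrix(df[, setdiff(names(df), meta_cols)])
  rownames(vals) <- probes$id
  if (any(is.na(vals))) {
    stop("expression TSV contains missing values; NA is not supported",
         call. = FALSE)
  }
  parts <- strsplit(colnames(vals), "_")
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) {
    stop("sample columns must be named line_sex_rep", call. = FALSE)
  }
  samples <- data.frame(
    sample = colnames(vals),
    line = vapply(parts, `[`, "", 1),
    sex = vapply(parts, `[`, "", 2),
    replicate = as.integer(vapply(parts, `[`, "", 3)),
    stringsAsFactors = FALSE
  )
  expr_matrix(vals, samples, probes)
}

#' Write a gene annotation as BED and 1-based TSV
#'
#' The TSV keeps the 1-based inclusive convention of the annotation
#' table; the BED file uses the 0-based half-open convention (handled by
#' rtracklayer).
#'
#' @param annotation a [generate_annotation()] table.
#' @param tsv_path,bed_path output files (either may be `NULL` to skip).
#' @export
write_annotation <- function(annotation, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(annotation, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    rtracklayer::export(annotation_to_granges(annotation), bed_path,
                        format = "BED")
  }
  invisible(NULL)
}

#' Convert a 1-based annotation table to GRanges
#'
#' The single crossing point between the external 1-based inclusive
#' convention and Bioconductor's GRanges (itself 1-based inclusive;
#' rtracklayer handles the 0-based shift on BED export/import).
#'
#' @param annotation a table with `gene`, `chrom`, `start`, `end`.
#' @return A GRanges object with gene names.
#' @export
annotation_to_granges <- function(annotation) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end,
                              names = annotation$gene)
  )
  gr$name <- annotation$gene
  gr
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track$counts)
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(
      start = (seq_len(n) - 1) * track$bin_size + 1,
      end = seq_len(n) * track$bin_size
    ),
    score = track$counts
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file as a coverage track
#'
#' Requires a single chromosome with constant-width, contiguous bins.
#'
#' @param path bedGraph file.
#' @param total_reads total mapped reads; defaults to the sum of scores.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, total_reads = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) != 1) {
    stop("bedGraph must cover a single chromosome", call. = FALSE)
  }
  w <- GenomicRanges::width(gr)
  if (length(unique(w)) != 1) {
    stop("bedGraph bins must have constant width", call. = FALSE)
  }
  coverage_track(
    chrom = as.character(GenomicRanges::seqnames(gr))[1],
    bin_size = w[1],
    counts = gr$score,
    total_reads = total_reads
  )
}

#' Write a deficiency table (breakpoint-table layout)
#'
#' @param deficiencies a [generate_deficiencies()] result or compatible
#'   data.frame.
#' @param path output TSV.
#' @export
write_deficiencies_tsv <- function(deficiencies, path) {
  tab <- if (inherits(deficiencies, "deficiency_set")) {
    deficiencies$table
  } else {
    deficiencies
  }
  out <- data.frame(
    Deficiency = tab$name,
    Chromosome = tab$chrom,
    `First missing base` = tab$first,
    `Last missing base` = tab$last,
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a deficiency table written by [write_deficiencies_tsv()]
#'
#' @param path TSV with columns Deficiency / Chromosome / First missing
#'   base / Last missing base.
#' @param annotation optional annotation to recompute one-dose gene sets.
#' @return A `deficiency_set` (gene sets empty unless `annotation` given).
#' @export
read_deficiencies_tsv <- function(path, annotation = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tab <- data.frame(
    name = df$Deficiency, chrom = df$Chromosome,
    first = df$`First missing base`, last = df$`Last missing base`,
    stringsAsFactors = FALSE
  )
  genes <- if (is.null(annotation)) {
    setNames(rep(list(character(0)), nrow(tab)), tab$name)
  } else {
    setNames(lapply(seq_len(nrow(tab)), function(j) {
      one_dose_genes(annotation, tab$first[j], tab$last[j])
    }), tab$name)
  }
  tab$n_genes <- vapply(genes, length, integer(1))
  structure(list(table = tab, genes = genes), class = "deficiency_set")
}

#' Write a dose table in the standard layout with 2-decimal folds
#'
#' @param dose_tab output of [dose_table()].
#' @param path output TSV.
#' @export
write_dose_table_tsv <- function(dose_tab, path) {
  out <- data.frame(
    Deficiency = dose_tab$region,
    `First missing base` = dose_tab$first,
    `Last missing base` = dose_tab$last,
    `Measured in` = dose_tab$measured_in,
    `RPM in Df region` = round(dose_tab$rpm_df, 1),
    `RPM in WT` = round(dose_tab$rpm_wt, 1),
    `Fold difference` = sprintf("%.2f", dose_tab$fold_difference),
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-complex membership table
#'
#' @param path TSV with columns `complex` and `gene`.
#' @return data.frame with `complex`, `gene`.
#' @export
read_complexes_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("complex", "gene") %in% names(df))) {
    stop("complex table must have columns 'complex' and 'gene'",
         call. = FALSE)
  }
  df
}

#' Write network edges as TSV and SIF
#'
#' @param pairs scored pair table (with `gene_a`, `gene_b`, `mi`, `p`),
#'   typically filtered to significant edges.
#' @param tsv_path,sif_path output files (`NULL` skips).
#' @export
write_network <- function(pairs, tsv_path = NULL, sif_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(pairs, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(sif_path)) {
    sif <- data.frame(a = pairs$gene_a, type = "mi", b = pairs$gene_b)
    write.table(sif, sif_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

#' Write compensation calls TSV and cutoffs JSON
#'
#' @param calls a `compensation_calls` object.
#' @param tsv_path calls TSV path (`NULL` skips).
#' @param cutoffs_json_path cutoffs JSON path (`NULL` skips).
#' @export
write_calls <- function(calls, tsv_path = NULL, cutoffs_json_path = NULL) {
  stopifnot(inherits(calls, "compensation_calls"))
  if (!is.null(tsv_path)) {
    write.table(calls$calls, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(cutoffs_json_path)) {
    jsonlite::write_json(calls$cutoffs, cutoffs_json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
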