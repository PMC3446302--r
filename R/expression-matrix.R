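#' Log2 expression matrix with sample and probe metadata
#'
#' The central data container: a genes-by-samples matrix of log2 expression
#' values together with a sample table (`sample`, `line`, `sex`,
#' `replicate`) and a probe table classifying each row as a measured `gene`,
#' a negative `control` probe or an external `spike` (spike rows carry their
#' ratio subset and expected log2 mix2/mix1 ratio).
#'
#' @param values numeric matrix, rows = probes, columns = samples, log2
#'   scale. Dimnames are required and must match the metadata tables.
#' @param samples data.frame with columns `sample`, `line`, `sex`,
#'   `replicate`; one row per column of `values`.
#' @param probes data.frame with columns `id`, `class`
#'   (`gene`/`control`/`spike`) and, for spike rows, `spike_subset` and
#'   `spike_expected_lfc`; one row per row of `values`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples, probes = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have row and column names", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must be finite; NA/Inf are not supported",
         call. = FALSE)
  }
  samples <- as.data.frame(samples)
  need <- c("sample", "line", "sex", "replicate")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns sample, line, sex, replicate",
         call. = FALSE)
  }
  if (!identical(colnames(values), as.character(samples$sample))) {
    stop("colnames(values) must equal samples$sample in order",
         call. = FALSE)
  }
  if (is.null(probes)) {
    probes <- data.frame(id = rownames(values), class = "gene",
                         spike_subset = NA_integer_,
                         spike_expected_lfc = NA_real_)
  }
  probes <- as.data.frame(probes)
  if (!all(c("id", "class") %in% names(probes))) {
    stop("probes must have columns id and class", call. = FALSE)
  }
  if (!identical(rownames(values), as.character(probes$id))) {
    stop("rownames(values) must equal probes$id in order", call. = FALSE)
  }
  if (!all(probes$class %in% c("gene", "control", "spike"))) {
    stop("probe class must be one of gene, control, spike", call. = FALSE)
  }
  structure(list(values = values, samples = samples, probes = probes),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples\n")
  cat("  probes:", sum(x$probes$class == "gene"), "genes,",
      sum(x$probes$class == "control"), "controls,",
      sum(x$probes$class == "spike"), "spikes\n")
  cat("  lines:", length(unique(x$samples$line)), " sexes:",
      paste(unique(x$samples$sex), collapse = "/"), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by sex and/or probe class
#'
#' @param x an [expr_matrix()].
#' @param sex optional, `"female"` or `"male"`; keeps that sex's samples.
#' @param probe_class optional character vector of probe classes to keep.
#' @param samples optional character vector of sample names to keep.
#' @return A new `expr_matrix`.
#' @export
subset_expr <- function(x, sex = NULL, probe_class = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  keep_s <- rep(TRUE, ncol(x$values))
  if (!is.null(sex)) keep_s <- keep_s & x$samples$sex %in% sex
  if (!is.null(samples)) keep_s <- keep_s & x$samples$sample %in% samples
  keep_p <- rep(TRUE, nrow(x$values))
  if (!is.null(probe_class)) keep_p <- x$probes$class %in% probe_class
  expr_matrix(x$values[keep_p, keep_s, drop = FALSE],
              x$samples[keep_s, , drop = FALSE],
              x$probes[keep_p, , drop = FALSE])
}

#' Gene rows of an expression matrix as a plain matrix
#'
#' @param x an [expr_matrix()].
#' @return The numeric sub-matrix of rows with probe class `gene`.
#' @export
gene_values <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$values[x$probes$class == "gene", , drop = FALSE]
}

# Sample names follow line_sex_rep (e.g. "Df03_female_2").
make_sample_table <- function(lines, sexes, n_replicates) {
  g <- expand.grid(replicate = seq_len(n_replicates), sex = sexes,
                   line = lines, stringsAsFactors = FALSE)
  g <- g[, c("line", "sex", "replicate")]
  g$sample <- sprintf("%s_%s_%d", g$line, g$sex, g$replicate)
  g[, c("sample", "line", "sex", "replicate")]
}
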