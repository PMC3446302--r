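#' Replicate quality control by rank correlation
#'
#' Within each (line, sex) group, removes replicates whose median pairwise
#' Spearman rank correlation with the other retained replicates of the
#' group falls below the threshold (kept when exactly at it). Removal is
#' iterative, worst offender first, because one corrupted hybridization
#' also depresses the median correlation of the intact replicates it is
#' compared against. Correlations are computed over gene rows only.
#'
#' @param x an [expr_matrix()].
#' @param min_rho retention threshold on the median pairwise Spearman
#'   correlation (default 0.8).
#' @return List with `expr` (the filtered [expr_matrix()]), `dropped`
#'   (character vector of dropped sample names) and `flagged_groups`
#'   (groups left with fewer than 2 replicates, if any).
#' @export
qc_replicates <- function(x, min_rho = 0.8) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- gene_values(x)
  keep <- rep(TRUE, ncol(vals))
  names(keep) <- colnames(vals)
  groups <- split(seq_len(ncol(vals)),
                  paste(x$samples$line, x$samples$sex, sep = "."))
  for (idx in groups) {
    while (sum(keep[idx]) >= 2) {
      cur <- idx[keep[idx]]
      rho <- cor(vals[, cur, drop = FALSE], method = "spearman")
      med <- vapply(seq_along(cur), function(i) median(rho[i, -i]),
                    numeric(1))
      if (min(med) >= min_rho) break
      keep[cur[which.min(med)]] <- FALSE
    }
  }
  dropped <- names(keep)[!keep]
  flagged <- character(0)
  for (g in names(groups)) {
    if (sum(keep[groups[[g]]]) < 2) {
      flagged <- c(flagged, g)
    }
  }
  if (length(flagged)) {
    warning("groups left with <2 replicates after QC: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  out <- subset_expr(x, samples = colnames(vals)[keep])
  list(expr = out, dropped = dropped, flagged_groups = flagged)
}

#' Detection mask from control probes
#'
#' A gene counts as detected in a line when its mean log2 expression over
#' that line's replicates exceeds (strictly) the line's detection
#' threshold, defined as the mean over that line's samples of
#' `mean(controls) + 2 * sd(controls)` computed per sample. The per-sex
#' mask requires detection in every tested line of that sex.
#'
#' @param x an [expr_matrix()] containing control probe rows.
#' @param sex `"female"` or `"male"`.
#' @return List with `detected` (named logical per gene: detected in all
#'   lines of the sex), `by_line` (genes x lines logical matrix) and
#'   `thresholds` (per line).
#' @export
detection_mask <- function(x, sex) {
  stopifnot(inherits(x, "expr_matrix"))
  xs <- subset_expr(x, sex = sex)
  ctrl <- xs$values[xs$probes$class == "control", , drop = FALSE]
  if (nrow(ctrl) < 2) {
    stop("detection_mask needs at least 2 control probe rows", call. = FALSE)
  }
  genes <- gene_values(xs)
  thr_sample <- apply(ctrl, 2, function(v) mean(v) + 2 * sd(v))
  lines <- unique(xs$samples$line)
  by_line <- matrix(FALSE, nrow(genes), length(lines),
                    dimnames = list(rownames(genes), lines))
  thr_line <- setNames(numeric(length(lines)), lines)
  for (ln in lines) {
    cols <- xs$samples$line == ln
    thr_line[ln] <- mean(thr_sample[cols])
    by_line[, ln] <- rowMeans(genes[, cols, drop = FALSE]) > thr_line[ln]
  }
  list(detected = apply(by_line, 1, all), by_line = by_line,
       thresholds = thr_line)
}

#' Reference expression profile (parental or composite)
#'
#' The parental reference is the per-gene median over the parental line's
#' replicates of one sex (used when testing global dose effects); the
#' composite reference is the per-gene median over all deficiency-line
#' samples of that sex (used when testing effects of particular
#' deficiencies).
#'
#' @param x an [expr_matrix()].
#' @param mode `"parental"` or `"composite"`.
#' @param sex `"female"` or `"male"`.
#' @param parental_line name of the parental line (default `"w1118"`).
#' @return Named numeric vector, one reference value per gene row.
#' @export
build_reference <- function(x, mode = c("parental", "composite"), sex,
                            parental_line = "w1118") {
  stopifnot(inherits(x, "expr_matrix"))
  mode <- match.arg(mode)
  xs <- subset_expr(x, sex = sex)
  vals <- gene_values(xs)
  cols <- if (mode == "parental") {
    which(xs$samples$line == parental_line)
  } else {
    which(xs$samples$line != parental_line)
  }
  if (!length(cols)) {
    stop("no samples available for ", mode, " reference", call. = FALSE)
  }
  apply(vals[, cols, drop = FALSE], 1, median)
}

# Invert the trigamma function by Newton iteration (for the empirical-Bayes
# prior fit on log variances).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Fit the scaled-inverse-chi-square variance prior
#'
#' Moment-matches the prior degrees of freedom `d0` and prior variance
#' `s02` of the hierarchical model `s_g^2 ~ s0^2 * F(d_g, d0)` on the log
#' scale: `E[log s^2]` and `Var[log s^2]` have closed forms in digamma /
#' trigamma functions. When the observed log-variances are no more
#' dispersed than sampling alone predicts (degenerate fit), the prior
#' collapses to a point mass: `d0 = Inf` and `s02 = ` the ensemble
#' geometric-mean-based estimate, i.e. fully pooled variance.
#'
#' @param s2 per-gene residual variances.
#' @param df per-gene residual degrees of freedom (scalar or vector).
#' @return List with `d0`, `s02`, `degenerate` flag.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- df > 0 & is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e)), degenerate = TRUE))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02, degenerate = FALSE)
}

#' Empirical-Bayes moderated one-sample t-test
#'
#' For each gene, tests whether the mean of its per-replicate log2 ratios
#' equals `null_lfc` (`-1` for "expression follows dose", `0` for
#' differential expression), using a posterior variance that shrinks the
#' per-gene residual variance toward an ensemble prior fitted by
#' [fit_variance_prior()]:
#' `s2_post = (d0*s02 + d_g*s2_g) / (d0 + d_g)`, with the t statistic
#' referred to a t distribution on `d0 + d_g` degrees of freedom.
#' Benjamini-Hochberg q-values are computed within the tested set.
#'
#' Input can be a matrix of log-ratios (genes x replicates) or a list of
#' unequal-length per-gene log-ratio vectors (genes one-dose in several
#' lines contribute replicates from each).
#'
#' @param ratios numeric matrix or list of numeric vectors of per-replicate
#'   log2 ratios to the reference.
#' @param null_lfc null value of the mean log2 fold change.
#' @return data.frame with per-gene `lfc`, `s2`, `df`, `n`, `s2_post`, `t`,
#'   `df_total`, `p`, `q`, plus attributes `d0`, `s02`, `degenerate`.
#' @export
moderated_t <- function(ratios, null_lfc = 0) {
  if (is.matrix(ratios)) {
    ratios <- lapply(seq_len(nrow(ratios)), function(i) ratios[i, ])
    names(ratios) <- rownames(as.matrix(ratios)) %||% NULL
  }
  n <- vapply(ratios, length, integer(1))
  if (any(n < 2)) {
    stop("moderated_t needs >= 2 replicate ratios per gene", call. = FALSE)
  }
  lfc <- vapply(ratios, mean, numeric(1))
  s2 <- vapply(ratios, var, numeric(1))
  df <- n - 1L
  prior <- fit_variance_prior(s2, df)
  if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s02, length(s2))
    df_total <- rep(Inf, length(s2))
    tstat <- (lfc - null_lfc) / sqrt(s2_post / n)
    p <- 2 * pnorm(-abs(tstat))
  } else {
    s2_post <- (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
    df_total <- prior$d0 + df
    tstat <- (lfc - null_lfc) / sqrt(s2_post / n)
    p <- 2 * pt(-abs(tstat), df_total)
  }
  out <- data.frame(
    gene = names(ratios) %||% as.character(seq_along(ratios)),
    lfc = lfc, s2 = s2, df = df, n = n, s2_post = s2_post,
    t = tstat, df_total = df_total, p = p, q = bh_fdr(p),
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  attr(out, "degenerate") <- prior$degenerate
  attr(out, "null_lfc") <- null_lfc
  out
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, the
#' adjustment used throughout the pipeline.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values (adjusted p-values), same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Reads per kilobase per million mapped (RPKM)
#'
#' @param counts read counts per gene.
#' @param gene_length_bp gene length(s) in bp.
#' @param total_mapped total mapped reads of the library.
#' @return RPKM values, `counts * 1e9 / (gene_length_bp * total_mapped)`.
#' @export
rpkm <- function(counts, gene_length_bp, total_mapped) {
  if (any(gene_length_bp <= 0)) stop("gene length must be > 0",
                                     call. = FALSE)
  if (total_mapped <= 0) stop("total mapped reads must be > 0",
                              call. = FALSE)
  counts * 1e9 / (gene_length_bp * total_mapped)
}

#' Spike-in ratio calibration
#'
#' For each spike-in subset, compares the observed mean log2 ratio of
#' deficiency samples (carrying mix 2) over parental samples (carrying
#' mix 1) with the expected log2 mix2/mix1 ratio, and fits a slope of
#' observed on expected per-spike ratios across the concentration range.
#'
#' @param x an [expr_matrix()] with annotated spike rows.
#' @param sex optional sex restriction.
#' @param parental_line name of the parental line.
#' @return List with `by_subset` (data.frame: subset, expected and observed
#'   mean log2 ratio, deviation, n spikes) and `slope` of the
#'   observed-vs-expected per-spike regression (NA when expected ratios do
#'   not vary).
#' @export
spikein_calibration <- function(x, sex = NULL, parental_line = "w1118") {
  stopifnot(inherits(x, "expr_matrix"))
  xs <- if (is.null(sex)) x else subset_expr(x, sex = sex)
  spk <- xs$probes$class == "spike"
  if (!any(spk)) stop("no spike rows in matrix", call. = FALSE)
  meta <- xs$probes[spk, ]
  if (any(is.na(meta$spike_subset)) || any(is.na(meta$spike_expected_lfc))) {
    stop("spike rows must carry subset and expected ratio annotation",
         call. = FALSE)
  }
  vals <- xs$values[spk, , drop = FALSE]
  is_par <- xs$samples$line == parental_line
  if (!any(is_par) || all(is_par)) {
    stop("need both parental and deficiency samples", call. = FALSE)
  }
  obs <- rowMeans(vals[, !is_par, drop = FALSE]) -
    rowMeans(vals[, is_par, drop = FALSE])
  by_subset <- do.call(rbind, lapply(split(seq_len(nrow(meta)),
                                           meta$spike_subset),
                                     function(i) {
    data.frame(subset = meta$spike_subset[i[1]],
               expected_lfc = meta$spike_expected_lfc[i[1]],
               observed_lfc = mean(obs[i]),
               deviation = mean(obs[i]) - meta$spike_expected_lfc[i[1]],
               n = length(i))
  }))
  rownames(by_subset) <- NULL
  slope <- if (length(unique(meta$spike_expected_lfc)) > 1) {
    unname(coef(stats::lm(obs ~ meta$spike_expected_lfc))[2])
  } else {
    NA_real_
  }
  list(by_subset = by_subset, slope = slope)
}

#' Per-replicate log2 ratios of one-dose genes to a reference
#'
#' Collects, for every one-dose gene of one sex, the log2 ratios of the
#' replicates of the line(s) in which the gene is one-dose against a
#' per-gene reference. Genes uncovered by two overlapping deficiencies
#' contribute the replicates of both lines.
#'
#' @param x an [expr_matrix()].
#' @param deficiencies a [generate_deficiencies()] result (or compatible
#'   list with `genes` per line).
#' @param sex `"female"` or `"male"`.
#' @param reference named per-gene reference vector from
#'   [build_reference()].
#' @param detected optional named logical detection mask; undetected genes
#'   are skipped.
#' @return Named list of per-gene numeric ratio vectors, with a `lines`
#'   attribute naming the deletion line(s) per gene.
#' @export
onedose_ratios <- function(x, deficiencies, sex, reference,
                           detected = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  xs <- subset_expr(x, sex = sex)
  vals <- gene_values(xs)
  gene_lines <- list()
  for (ln in names(deficiencies$genes)) {
    for (g in deficiencies$genes[[ln]]) {
      gene_lines[[g]] <- c(gene_lines[[g]], ln)
    }
  }
  keep <- names(gene_lines)[names(gene_lines) %in% rownames(vals)]
  if (!is.null(detected)) keep <- keep[detected[keep] %in% TRUE]
  out <- lapply(keep, function(g) {
    cols <- xs$samples$line %in% gene_lines[[g]]
    vals[g, cols] - reference[[g]]
  })
  names(out) <- keep
  attr(out, "lines") <- gene_lines[keep]
  out
}
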