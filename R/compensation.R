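#' Two-step five-class dosage-compensation classifier
#'
#' Step 1: genes whose moderated test of "expression follows dose"
#' (`null_lfc = -1`) is not rejected (`q >= alpha`) are *non*-compensated;
#' rejected genes with mean log2 fold change below -1 are
#' *anti*-compensated. Step 2: the remaining rejected genes (LFC above -1)
#' are stratified by a bootstrap-calibrated band: their LFC vector is
#' resampled `n_boot` times with replacement, normal-theory 2.5% / 97.5%
#' cutoffs (`mean +/- 1.96 * sd` of the resampled distribution) are
#' computed and recentred at zero ("no change") by subtracting the
#' bootstrap mean. Genes inside the band are *fully* compensated, above it
#' *over*-compensated, below it *partially* compensated. Band ties go to
#' *full*.
#'
#' Because the band adapts to the spread of the step-2 group, planted
#' partial/over effects are only separable when they are well away from
#' both boundaries and form a minor share of the step-2 group; see the
#' methods vignette.
#'
#' @param results a [moderated_t()] result computed with `null_lfc = -1`
#'   on one-dose genes of one sex.
#' @param alpha FDR level for step 1 (default 0.05).
#' @param n_boot bootstrap resamples for the cutoffs (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param min_step2 minimum step-2 group size for cutoff estimation; below
#'   it all step-2 genes are conservatively called partial, with a warning.
#' @return List of class `compensation_calls`: `calls` (data.frame with
#'   `gene`, `lfc`, `p`, `q`, `class`) and `cutoffs` (list `lower`,
#'   `upper`, `boot_mean`, `n_boot`).
#' @export
classify_compensation <- function(results, alpha = 0.05, n_boot = 1000L,
                                  seed = 1L, min_step2 = 10L) {
  stopifnot(is.data.frame(results), all(c("lfc", "q") %in% names(results)))
  if (!isTRUE(all.equal(attr(results, "null_lfc"), -1))) {
    stop("classify_compensation expects results tested against null_lfc = -1",
         call. = FALSE)
  }
  lfc <- results$lfc
  q <- results$q
  class <- rep("non", nrow(results))
  class[q < alpha & lfc < -1] <- "anti"
  step2 <- which(q < alpha & lfc > -1)
  cutoffs <- list(lower = NA_real_, upper = NA_real_,
                  boot_mean = NA_real_, n_boot = n_boot)
  if (length(step2) >= min_step2) {
    boot <- with_seed(seed, {
      replicate(n_boot, sample(lfc[step2], replace = TRUE))
    })
    boot_mean <- mean(boot)
    boot_sd <- sd(as.vector(boot))
    lower <- (boot_mean - 1.96 * boot_sd) - boot_mean
    upper <- (boot_mean + 1.96 * boot_sd) - boot_mean
    cutoffs <- list(lower = lower, upper = upper, boot_mean = boot_mean,
                    n_boot = n_boot)
    l2 <- lfc[step2]
    class[step2] <- ifelse(l2 < lower, "partial",
                           ifelse(l2 > upper, "over", "full"))
  } else if (length(step2) > 0) {
    warning("fewer than ", min_step2, " genes entered step 2; ",
            "classifying them all as partial (conservative)", call. = FALSE)
    class[step2] <- "partial"
  }
  calls <- data.frame(gene = results$gene, lfc = lfc,
                      p = results$p, q = q, class = class,
                      stringsAsFactors = FALSE)
  structure(list(calls = calls, cutoffs = cutoffs, alpha = alpha),
            class = "compensation_calls")
}

#' @export
print.compensation_calls <- function(x, ...) {
  cat("compensation_calls:", nrow(x$calls), "genes\n")
  print(table(factor(x$calls$class, COMP_CLASSES)))
  if (!is.na(x$cutoffs$lower)) {
    cat(sprintf("  step-2 band (centred): [%.3f, %.3f]\n",
                x$cutoffs$lower, x$cutoffs$upper))
  }
  invisible(x)
}

#' Resample contiguous blocks of two-dose genes
#'
#' Draws `n_draws` contiguous blocks of detected two-dose genes in genome
#' order, each matching a deficiency's one-dose gene count, and returns
#' per-draw statistics of the blocks' log2 fold changes to the reference.
#' Sampling contiguous blocks (rather than random gene sets) preserves the
#' local co-regulation structure of physically linked genes.
#'
#' @param lfc named per-gene log2 fold change vector (two-dose genes,
#'   vs the parental reference).
#' @param annotation gene table in genome order.
#' @param block_size genes per block (the matched deficiency's one-dose
#'   count).
#' @param exclude genes to exclude (e.g. all one-dose genes).
#' @param n_draws number of resampling draws (default 2000).
#' @param seed RNG seed.
#' @return List of class `block_resample`: `draws` data.frame with
#'   per-draw `mean`, `var` (of the log2 fold changes) and `start` index,
#'   plus `values` (matrix of drawn LFCs, draws in columns).
#' @export
block_resample_two_dose <- function(lfc, annotation, block_size,
                                    exclude = character(0),
                                    n_draws = 2000L, seed = 1L) {
  ord <- annotation$gene[annotation$gene %in% names(lfc) &
                           !(annotation$gene %in% exclude)]
  if (block_size > length(ord)) {
    stop("no valid block: block_size exceeds available two-dose genes",
         call. = FALSE)
  }
  n_starts <- length(ord) - block_size + 1L
  vals <- lfc[ord]
  draws <- with_seed(seed, {
    starts <- sample.int(n_starts, n_draws, replace = TRUE)
    m <- vapply(starts, function(s) vals[s:(s + block_size - 1L)],
                numeric(block_size))
    list(starts = starts, m = matrix(m, nrow = block_size))
  })
  structure(list(
    draws = data.frame(start = draws$starts,
                       mean = colMeans(draws$m),
                       var = apply(draws$m, 2, var)),
    values = draws$m,
    block_size = block_size
  ), class = "block_resample")
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (S^2 + K^2/4)` where `S` is the sample skewness and `K` the
#' excess kurtosis, referred to a chi-square distribution with 2 degrees of
#' freedom.
#'
#' @param x numeric sample.
#' @return List with `statistic`, `skewness`, `kurtosis_excess`, `p`.
#' @export
jarque_bera <- function(x) {
  n <- length(x)
  if (n < 8) stop("jarque_bera needs n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  S <- mean((x - m)^3) / m2^1.5
  K <- mean((x - m)^4) / m2^2 - 3
  stat <- n / 6 * (S^2 + K^2 / 4)
  list(statistic = stat, skewness = S, kurtosis_excess = K,
       p = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Distribution comparison of one-dose vs resampled two-dose fold changes
#'
#' Tests normality of the one-dose log2 fold-change distribution
#' (Jarque-Bera) and compares its shape with the resampled two-dose
#' distribution (two-sample Kolmogorov-Smirnov), reporting the mean fold
#' reduction `2^(-mean LFC)` of the one-dose genes.
#'
#' @param one_dose_lfc log2 fold changes of one-dose genes.
#' @param two_dose_lfc resampled two-dose log2 fold changes (e.g. pooled
#'   draws from [block_resample_two_dose()]).
#' @return List with `jb` ([jarque_bera()] result), `ks_p`, `mean_lfc_one`,
#'   `mean_lfc_two`, `mean_fold_reduction`.
#' @export
distribution_tests <- function(one_dose_lfc, two_dose_lfc) {
  if (length(one_dose_lfc) < 20 || length(two_dose_lfc) < 20) {
    stop("distribution_tests needs >= 20 values per sample", call. = FALSE)
  }
  ks <- suppressWarnings(ks.test(one_dose_lfc, two_dose_lfc))
  list(
    jb = jarque_bera(one_dose_lfc),
    ks_p = ks$p.value,
    ks_D = unname(ks$statistic),
    mean_lfc_one = mean(one_dose_lfc),
    mean_lfc_two = mean(two_dose_lfc),
    mean_fold_reduction = 2^(-mean(one_dose_lfc))
  )
}

#' Variance of fold differences: one-dose vs two-dose state
#'
#' Bootstraps (over genes) the variance of fold differences `2^lfc` of the
#' same genes measured in the one-dose and the two-dose state, and returns
#' the per-state draw distributions with notched-boxplot summaries (median,
#' 95% CI of the median, quartiles).
#'
#' @param one_dose_lfc,two_dose_lfc named log2 fold-change vectors for the
#'   same genes in the two states (matched by name when names are present).
#' @param n_draws bootstrap draws (default 2000).
#' @param seed RNG seed.
#' @return List with `draws` (data.frame `var_one`, `var_two`), `summary`
#'   (per state: median, ci_lo, ci_hi, q1, q3) and `median_diff_ci`
#'   (bootstrap 95% CI of the paired difference of variances).
#' @export
variance_comparison <- function(one_dose_lfc, two_dose_lfc,
                                n_draws = 2000L, seed = 1L) {
  if (!is.null(names(one_dose_lfc)) && !is.null(names(two_dose_lfc))) {
    common <- intersect(names(one_dose_lfc), names(two_dose_lfc))
    one_dose_lfc <- one_dose_lfc[common]
    two_dose_lfc <- two_dose_lfc[common]
  }
  n <- length(one_dose_lfc)
  stopifnot(n == length(two_dose_lfc), n >= 3)
  f1 <- 2^one_dose_lfc
  f2 <- 2^two_dose_lfc
  draws <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_draws, replace = TRUE), nrow = n)
    data.frame(var_one = apply(idx, 2, function(i) var(f1[i])),
               var_two = apply(idx, 2, function(i) var(f2[i])))
  })
  notch <- function(v) {
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    half <- 1.57 * (qs[3] - qs[1]) / sqrt(length(v))
    c(median = qs[2], ci_lo = qs[2] - half, ci_hi = qs[2] + half,
      q1 = qs[1], q3 = qs[3])
  }
  dd <- draws$var_one - draws$var_two
  structure(list(
    draws = draws,
    summary = rbind(one_dose = notch(draws$var_one),
                    two_dose = notch(draws$var_two)),
    median_diff_ci = quantile(dd, c(0.025, 0.975), names = FALSE)
  ), class = "variance_comparison")
}

#' Association between compensation and expression level
#'
#' Spearman correlation between two-dose expression level and the
#' compensation ratio (log2 fold change), with an MA-style binned trend.
#'
#' @param calls a `compensation_calls` object or a data.frame with `gene`
#'   and `lfc`.
#' @param two_dose_level named per-gene two-dose expression level (log2).
#' @param n_bins bins for the trend summary.
#' @return List with `rho`, `p`, `n`, `trend` (per-bin mean level and mean
#'   LFC) or, for constant levels, `rho = NA` with `constant = TRUE`.
#' @export
compensation_vs_expression <- function(calls, two_dose_level, n_bins = 5L) {
  df <- if (inherits(calls, "compensation_calls")) calls$calls else calls
  common <- intersect(df$gene, names(two_dose_level))
  if (length(common) < 10) {
    stop("need >= 10 genes with both calls and levels", call. = FALSE)
  }
  lfc <- df$lfc[match(common, df$gene)]
  lev <- two_dose_level[common]
  if (sd(lev) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(common),
                constant = TRUE, trend = NULL))
  }
  ct <- suppressWarnings(cor.test(lev, lfc, method = "spearman"))
  bins <- cut(rank(lev, ties.method = "first"), n_bins, labels = FALSE)
  trend <- data.frame(
    bin = seq_len(n_bins),
    mean_level = tapply(lev, bins, mean),
    mean_lfc = tapply(lfc, bins, mean)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common),
       constant = FALSE, trend = trend)
}

#' Between-sex concordance of compensation by sex-bias group
#'
#' Spearman correlation of per-gene compensation ratios (log2 fold
#' changes) between females and males, within each sex-bias group. Lower
#' concordance for sex-biased genes than for unbiased genes indicates that
#' compensation depends on the expression network context, which differs
#' between the sexes.
#'
#' @param calls_female,calls_male `compensation_calls` objects (or data
#'   frames with `gene`, `lfc`).
#' @param bias_labels named vector with values `female`, `male`, `none`.
#' @param min_genes smallest group size for which a correlation is
#'   reported (default 5; smaller groups give `NA`).
#' @return data.frame with `bias`, `n`, `rho`, `p`.
#' @export
sex_concordance <- function(calls_female, calls_male, bias_labels,
                            min_genes = 5L) {
  f <- if (inherits(calls_female, "compensation_calls")) {
    calls_female$calls
  } else {
    calls_female
  }
  m <- if (inherits(calls_male, "compensation_calls")) {
    calls_male$calls
  } else {
    calls_male
  }
  common <- intersect(f$gene, m$gene)
  lf <- f$lfc[match(common, f$gene)]
  lm_ <- m$lfc[match(common, m$gene)]
  bias <- bias_labels[common]
  out <- lapply(c("female", "male", "none"), function(b) {
    i <- which(bias == b)
    if (length(i) < min_genes) {
      return(data.frame(bias = b, n = length(i), rho = NA_real_,
                        p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(lf[i], lm_[i], method = "spearman"))
    data.frame(bias = b, n = length(i), rho = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Consistency of compensation across overlapping deficiencies
#'
#' For genes one-dose in two or more lines, tests equality of the mean
#' log2 fold change across deletion contexts with a moderated one-way
#' F-test (between-line mean square over the posterior variance), BH
#' corrected within the family. Few significant genes indicate that the
#' dose response is a property of the gene, not of the particular
#' deficiency.
#'
#' @param x an [expr_matrix()].
#' @param deficiencies a [generate_deficiencies()] result.
#' @param sex `"female"` or `"male"`.
#' @param reference per-gene reference from [build_reference()].
#' @param alpha significance level on q (default 0.05).
#' @return data.frame per multi-line gene: `gene`, `n_lines`, `F`, `p`,
#'   `q`, `significant`; empty when no gene is uncovered by >= 2 lines.
#' @export
cross_df_consistency <- function(x, deficiencies, sex, reference,
                                 alpha = 0.05) {
  ratios <- onedose_ratios(x, deficiencies, sex, reference)
  lines <- attr(ratios, "lines")
  multi <- names(ratios)[vapply(lines, length, integer(1)) >= 2]
  if (!length(multi)) {
    return(data.frame(gene = character(0), n_lines = integer(0),
                      F = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  xs <- subset_expr(x, sex = sex)
  vals <- gene_values(xs)
  # per (gene, line) replicate ratio groups
  per_gene <- lapply(multi, function(g) {
    lapply(lines[[g]], function(ln) {
      vals[g, xs$samples$line == ln] - reference[[g]]
    })
  })
  # pooled residual variances feed the prior
  s2 <- vapply(per_gene, function(gr) {
    res <- unlist(lapply(gr, function(v) v - mean(v)))
    sum(res^2) / (length(res) - length(gr))
  }, numeric(1))
  dfr <- vapply(per_gene, function(gr) {
    length(unlist(gr)) - length(gr)
  }, numeric(1))
  prior <- fit_variance_prior(s2, dfr)
  stats <- do.call(rbind, lapply(seq_along(per_gene), function(i) {
    gr <- per_gene[[i]]
    k <- length(gr)
    ns <- vapply(gr, length, integer(1))
    ms <- vapply(gr, mean, numeric(1))
    grand <- sum(ns * ms) / sum(ns)
    ms_between <- sum(ns * (ms - grand)^2) / (k - 1)
    if (is.infinite(prior$d0)) {
      s2_post <- prior$s02
      df2 <- Inf
    } else {
      s2_post <- (prior$d0 * prior$s02 + dfr[i] * s2[i]) /
        (prior$d0 + dfr[i])
      df2 <- prior$d0 + dfr[i]
    }
    Fv <- ms_between / s2_post
    data.frame(gene = multi[i], n_lines = k, F = Fv,
               p = pf(Fv, k - 1, df2, lower.tail = FALSE))
  }))
  stats$q <- bh_fdr(stats$p)
  stats$significant <- stats$q < alpha
  rownames(stats) <- NULL
  stats
}

#' Association of compensation class with deficiency extent and position
#'
#' Spearman correlations of per-deficiency class proportions against the
#' deletion's extent in bp, its gene count and its chromosomal midpoint.
#'
#' @param calls a `compensation_calls` object (or `calls` data.frame).
#' @param deficiencies a [generate_deficiencies()] result.
#' @return data.frame with one row per (class, covariate): `class`,
#'   `covariate`, `rho`, `p`.
#' @export
extent_position_association <- function(calls, deficiencies) {
  df <- if (inherits(calls, "compensation_calls")) calls$calls else calls
  tab <- deficiencies$table
  if (nrow(tab) < 5) stop("need >= 5 deficiencies", call. = FALSE)
  props <- sapply(seq_len(nrow(tab)), function(j) {
    g <- intersect(deficiencies$genes[[tab$name[j]]], df$gene)
    cls <- factor(df$class[match(g, df$gene)], COMP_CLASSES)
    if (!length(g)) return(rep(NA_real_, length(COMP_CLASSES)))
    as.numeric(table(cls)) / length(g)
  })
  rownames(props) <- COMP_CLASSES
  covs <- list(bp_removed = tab$last - tab$first + 1,
               n_genes = tab$n_genes,
               midpoint = (tab$first + tab$last) / 2)
  out <- list()
  for (cl in COMP_CLASSES) {
    for (cv in names(covs)) {
      ok <- !is.na(props[cl, ])
      ct <- if (sum(ok) >= 5 && sd(props[cl, ok]) > 0) {
        suppressWarnings(cor.test(props[cl, ok], covs[[cv]][ok],
                                  method = "spearman"))
      } else {
        NULL
      }
      out[[length(out) + 1L]] <- data.frame(
        class = cl, covariate = cv,
        rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
        p = if (is.null(ct)) NA_real_ else ct$p.value
      )
    }
  }
  do.call(rbind, out)
}
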