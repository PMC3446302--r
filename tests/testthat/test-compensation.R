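make_mt <- function(lfc, sem = 0.05, n = 3) {
  # moderated-test-result stand-in with tight, known uncertainties
  ratios <- lapply(lfc, function(m) m + sem * c(-1, 0, 1))
  names(ratios) <- sprintf("g%04d", seq_along(lfc))
  moderated_t(ratios, null_lfc = -1)
}

test_that("classification step 1: null-true genes are non, strong deficits
           are anti", {
  set.seed(71)
  # the step-2 band adapts to the group spread, so the planted partial and
  # over effects are kept rare (3 of 40 step-2 genes each) and far from
  # both the -1 rejection boundary and the band
  lfc <- c(rep(-1, 30), rep(-1.8, 10), rep(0, 34), rep(-0.9, 3),
           rep(0.9, 3))
  mt <- make_mt(lfc)
  cc <- classify_compensation(mt, seed = 1)
  cls <- cc$calls$class
  expect_true(all(cls[1:30] == "non"))
  expect_true(all(cls[31:40] == "anti"))
  # partition: every gene gets exactly one class and counts add up
  expect_equal(sum(table(cls)), length(lfc))
  # cutoffs centred at zero
  expect_lt(cc$cutoffs$lower, 0)
  expect_gt(cc$cutoffs$upper, 0)
  expect_equal(cc$cutoffs$lower, -cc$cutoffs$upper)
  # step 2 stratification with these well-separated effects
  expect_true(all(cls[41:74] == "full"))
  expect_true(all(cls[75:77] == "partial"))
  expect_true(all(cls[78:80] == "over"))
})

test_that("LFC exactly 0 with a tiny variance is fully compensated", {
  set.seed(72)
  lfc <- c(rep(0, 40), rep(-0.6, 5), rep(0.6, 5), rep(-1, 20))
  cc <- classify_compensation(make_mt(lfc), seed = 2)
  expect_true(all(cc$calls$class[1:40] == "full"))
})

test_that("classification is reproducible under a fixed seed", {
  set.seed(73)
  lfc <- c(rnorm(60, -0.2, 0.3), rep(-1, 20))
  mt <- make_mt(lfc)
  c1 <- classify_compensation(mt, seed = 9)
  c2 <- classify_compensation(mt, seed = 9)
  expect_identical(c1$calls, c2$calls)
  expect_identical(c1$cutoffs, c2$cutoffs)
})

test_that("too few step-2 genes fall back to a conservative partial call", {
  set.seed(74)
  lfc <- c(rep(-1, 30), rep(-0.2, 3))
  mt <- make_mt(lfc)
  expect_warning(cc <- classify_compensation(mt, seed = 1),
                 "step 2")
  expect_true(all(cc$calls$class[31:33] == "partial"))
})

test_that("the step-2 band widens monotonically with noise", {
  widths <- vapply(c(0.05, 0.15, 0.3), function(s) {
    set.seed(75)
    lfc <- c(rep(-1, 30), rnorm(60, -0.2, s))
    cc <- classify_compensation(make_mt(lfc), seed = 3)
    cc$cutoffs$upper - cc$cutoffs$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("classifier recovers planted classes under the separable profile", {
  cfg <- classifier_benchmark_config(seed = 7)
  sim <- simulate_expression(cfg)
  defs <- sim$truth$deficiencies
  mask <- detection_mask(sim$expr, "female")
  ref <- build_reference(sim$expr, "composite", "female")
  ratios <- onedose_ratios(sim$expr, defs, "female", ref,
                           detected = mask$detected)
  mt <- moderated_t(ratios, null_lfc = -1)
  cc <- classify_compensation(mt, seed = 7)
  truth <- sim$truth$classes
  truth <- truth[truth$sex == "female", ]
  m <- merge(cc$calls, truth, by = "gene")
  expect_gt(nrow(m), 300)
  expect_gte(mean(m$class.x == m$class.y), 0.9)
  # the recovered non and anti proportions track the planted mixture
  planted <- table(factor(m$class.y, levels = unique(m$class.y))) / nrow(m)
  called <- table(factor(m$class.x, levels = names(planted))) / nrow(m)
  expect_lt(abs(called[["non"]] - planted[["non"]]), 0.05)
  expect_lt(abs(called[["anti"]] - planted[["anti"]]), 0.05)
})

test_that("block resampling draws contiguous blocks with matched size", {
  sim <- tiny_sim()
  ann <- sim$truth$annotation
  set.seed(76)
  lfc <- setNames(rnorm(nrow(ann), 0, 0.3), ann$gene)
  br <- block_resample_two_dose(lfc, ann, block_size = 8, n_draws = 500,
                                seed = 3)
  expect_equal(dim(br$values), c(8, 500))
  # reproducible under seed
  br2 <- block_resample_two_dose(lfc, ann, block_size = 8, n_draws = 500,
                                 seed = 3)
  expect_identical(br$draws, br2$draws)
  # mean of block means converges to the global mean (law of large numbers)
  expect_lt(abs(mean(br$draws$mean) - mean(lfc)), 3 * sd(lfc) / sqrt(500) +
              0.02)
  # block equal to everything -> every draw identical
  br3 <- block_resample_two_dose(lfc, ann, block_size = length(lfc),
                                 n_draws = 10, seed = 1)
  expect_equal(var(br3$draws$mean), 0)
  expect_error(block_resample_two_dose(lfc, ann,
                                       block_size = length(lfc) + 1),
               "block_size")
})

test_that("block resampling SE scales as n_draws^(-1/2)", {
  sim <- tiny_sim()
  ann <- sim$truth$annotation
  set.seed(77)
  lfc <- setNames(rnorm(nrow(ann), 0, 0.5), ann$gene)
  se_of_mean <- function(n_draws, seed) {
    vapply(seq_len(20), function(k) {
      mean(block_resample_two_dose(lfc, ann, 6, n_draws = n_draws,
                                   seed = seed + k)$draws$mean)
    }, numeric(1))
  }
  s_small <- sd(se_of_mean(50, 100))
  s_big <- sd(se_of_mean(800, 200))
  expect_gt(s_small / s_big, 4 / 2)  # expect ~4, allow margin
})

test_that("jarque_bera calibrates on normal data and rejects skewed data", {
  set.seed(78)
  # type-I calibration over repeated normal samples
  pvals <- replicate(400, jarque_bera(rnorm(300))$p)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
  # exponential: strong skew, decisive rejection at n = 1000
  expect_lt(jarque_bera(rexp(1000))$p, 1e-6)
})

test_that("distribution_tests reports identity for identical samples and
           the mean fold reduction", {
  set.seed(79)
  x <- rnorm(500, -0.68, 0.3)
  dt <- distribution_tests(x, x)
  expect_equal(dt$ks_D, 0)
  expect_equal(dt$ks_p, 1)
  expect_equal(dt$mean_fold_reduction, 2^(-mean(x)))
  expect_error(distribution_tests(x[1:5], x), ">= 20")
})

test_that("variance comparison: equal inputs give identical draw
           distributions; extra noise in one state is detected", {
  set.seed(81)
  lfc <- setNames(rnorm(80, -0.5, 0.3), sprintf("g%02d", 1:80))
  vc <- variance_comparison(lfc, lfc, n_draws = 500, seed = 2)
  expect_equal(vc$draws$var_one, vc$draws$var_two)
  expect_true(vc$median_diff_ci[1] <= 0 && vc$median_diff_ci[2] >= 0)
  # planted equal variance, independent draws: CI covers 0
  lfc2 <- setNames(rnorm(80, -0.5, 0.3), names(lfc))
  vc2 <- variance_comparison(lfc, lfc2, n_draws = 1000, seed = 3)
  expect_true(vc2$median_diff_ci[1] <= 0 && vc2$median_diff_ci[2] >= 0)
  # doubling the spread of one state shifts the variance distribution
  lfc3 <- setNames(rnorm(80, -0.5, 0.6), names(lfc))
  vc3 <- variance_comparison(lfc3, lfc2, n_draws = 1000, seed = 4)
  expect_gt(vc3$median_diff_ci[1], 0)
})

test_that("compensation_vs_expression recovers a planted level trend and
           flags constant levels", {
  set.seed(82)
  n <- 200
  level <- runif(n, 4, 14)
  # planted: high expression -> less compensation (more negative LFC)
  lfc <- -0.1 * (level - 4) + rnorm(n, 0, 0.2)
  calls <- data.frame(gene = sprintf("g%03d", 1:n), lfc = lfc)
  lev <- setNames(level, calls$gene)
  res <- compensation_vs_expression(calls, lev)
  expect_lt(res$rho, -0.5)
  expect_lt(res$p, 0.01)
  expect_true(all(diff(res$trend$mean_lfc) < 0.2))
  # null planting: p roughly uniform over simulations
  pv <- replicate(200, {
    cl <- data.frame(gene = names(lev), lfc = rnorm(n, 0, 0.2))
    compensation_vs_expression(cl, lev)$p
  })
  expect_lt(abs(mean(pv < 0.1) - 0.1), 0.08)
  # constant levels flagged
  res0 <- compensation_vs_expression(calls, setNames(rep(5, n),
                                                     calls$gene))
  expect_true(res0$constant)
  expect_true(is.na(res0$rho))
})

test_that("sex concordance: identical ratios give rho 1, independent give
           ~0, and a shared-component model ranks none > biased", {
  set.seed(83)
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  bias <- setNames(sample(c("female", "male", "none"), n, TRUE), genes)
  shared <- rnorm(n, -0.5, 0.4)
  # non-biased genes: same signal both sexes; biased genes: half shared
  noise_f <- rnorm(n, 0, 0.1)
  wf <- ifelse(bias == "none", 0.1, 0.8)
  lfc_f <- shared + noise_f * 0.1
  lfc_m <- ifelse(bias == "none",
                  shared + rnorm(n, 0, 0.1),
                  0.5 * shared + rnorm(n, 0, 0.45))
  cf <- data.frame(gene = genes, lfc = lfc_f)
  cm <- data.frame(gene = genes, lfc = lfc_m)
  sc <- sex_concordance(cf, cm, bias)
  rho <- setNames(sc$rho, sc$bias)
  expect_gt(rho[["none"]], rho[["female"]])
  expect_gt(rho[["none"]], rho[["male"]])
  # identical ratios
  sc1 <- sex_concordance(cf, cf, bias)
  expect_equal(sc1$rho, rep(1, 3), tolerance = 1e-12)
  # independent ratios
  cm0 <- data.frame(gene = genes, lfc = rnorm(n))
  sc0 <- sex_concordance(cf, cm0, bias)
  expect_true(all(abs(sc0$rho) < 0.25))
  # tiny group -> NA
  bias2 <- bias
  bias2[bias2 == "male"] <- "none"
  bias2[1:2] <- "male"
  sc2 <- sex_concordance(cf, cm, bias2, min_genes = 5)
  expect_true(is.na(sc2$rho[sc2$bias == "male"]))
})

test_that("cross-deficiency consistency: shared effects pass, line-specific
           effects are detected", {
  sim <- tiny_sim()
  defs <- sim$truth$deficiencies
  ref <- build_reference(sim$expr, "composite", "female")
  res <- cross_df_consistency(sim$expr, defs, "female", ref)
  expect_gt(nrow(res), 0)   # overlap pairs guarantee multi-line genes
  # the generator plants the same effect in every line: no significant
  # differences expected
  expect_equal(sum(res$significant), 0)
  # now plant a line-specific effect for one multi-line gene
  g <- res$gene[1]
  lns <- attr(onedose_ratios(sim$expr, defs, "female", ref),
              "lines")[[g]]
  x2 <- sim$expr
  pick <- x2$samples$line == lns[1] & x2$samples$sex == "female"
  x2$values[g, pick] <- x2$values[g, pick] + 2
  res2 <- cross_df_consistency(x2, defs, "female", ref)
  expect_true(res2$significant[res2$gene == g])
})

test_that("extent/position association is null for homogeneous planting", {
  set.seed(84)
  cfg <- synthetic_config(n_genes = 300, n_lines = 10, genes_per_df = 8,
                          chrom_length = 3e6, seed = 19)
  sim <- simulate_expression(cfg)
  defs <- sim$truth$deficiencies
  truth <- sim$truth$classes
  truth <- truth[truth$sex == "female", ]
  calls <- data.frame(gene = truth$gene, class = truth$class,
                      lfc = truth$true_lfc)
  res <- extent_position_association(calls, defs)
  expect_equal(nrow(res), 15)   # 5 classes x 3 covariates
  # homogeneous class assignment: no strong association expected
  expect_gt(min(res$p, na.rm = TRUE), 0.001)
  # planted extent-dependent classes are detected
  tab <- defs$table[order(defs$table$n_genes), ]
  calls2 <- calls
  big <- defs$genes[tab$name[tail(seq_len(nrow(tab)), 5)]]
  calls2$class <- ifelse(calls2$gene %in% unlist(big), "anti", "full")
  res2 <- extent_position_association(calls2, defs)
  hit <- res2[res2$class == "anti" & res2$covariate == "n_genes", ]
  expect_lt(hit$p, 0.05)
})
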