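test_that("per-line DE: a line identical to the composite yields no calls,
           planted shifts are recovered with direction", {
  set.seed(101)
  G <- 120
  lines <- sprintf("L%02d", 1:8)
  base <- runif(G, 6, 14)
  vals <- matrix(rnorm(G * 24, base, 0.2), G, 24,
                 dimnames = list(sprintf("g%03d", 1:G), NULL))
  # plant shifts in line L01: 10 genes up, 10 down
  up <- 1:10; down <- 11:20
  vals[up, 1:3] <- vals[up, 1:3] + 1.5
  vals[down, 1:3] <- vals[down, 1:3] - 1.5
  x <- toy_expr(vals, lines = lines, reps = 3)
  ref <- build_reference(x, "composite", "female")
  de <- per_line_de(x, "female", ref)
  t1 <- de$lines$L01
  expect_true(all(t1$changed[up]))
  expect_true(all(t1$direction[up] == 1))
  expect_true(all(t1$changed[down]))
  expect_true(all(t1$direction[down] == -1))
  # unperturbed line: BH controls false calls
  expect_lte(sum(de$lines$L05$changed), 3)
})

test_that("per-line false positives are near alpha before BH correction", {
  set.seed(102)
  G <- 2000
  vals <- matrix(rnorm(G * 12, 8, 0.3), G, 12,
                 dimnames = list(sprintf("g%04d", 1:G), NULL))
  x <- toy_expr(vals, lines = sprintf("L%d", 1:4), reps = 3)
  ref <- build_reference(x, "composite", "female")
  de <- per_line_de(x, "female", ref)
  # raw p < 0.05 rate: reference subtraction and the median's own noise
  # push this slightly above nominal, but it stays in the right range
  raw <- mean(de$lines$L1$p < 0.05)
  expect_lt(raw, 0.12)
  expect_gt(raw, 0.01)
  # after BH essentially nothing survives
  expect_lte(sum(de$lines$L1$changed), G * 0.005)
})

test_that("first-degree neighbors match a brute-force adjacency scan and
           exclude same-line one-dose genes", {
  set.seed(103)
  g <- igraph::sample_gnm(40, 80)
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  el <- igraph::as_edgelist(g)
  od <- c("n01", "n02", "n03")
  nbs <- first_degree_neighbors(g, od)
  for (v in od) {
    brute <- unique(c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))
    expect_setequal(nbs[[v]], setdiff(brute, od))
  }
  # gene absent from the network -> empty set
  expect_equal(first_degree_neighbors(g, "absent")[["absent"]],
               character(0))
  # isolated gene -> empty set
  g2 <- igraph::add_vertices(g, 1, name = "iso")
  expect_equal(first_degree_neighbors(g2, "iso")[["iso"]], character(0))
})

test_that("neighbor change chi-square matches a hand-computed toy", {
  # one class, 10 neighbors, 4 changed, global rate 0.1:
  # X2 = (4-1)^2/1 + (6-9)^2/9 = 10, p = pchisq upper
  p_hand <- pchisq((4 - 1)^2 / 1 + (6 - 9)^2 / 9, 1, lower.tail = FALSE)
  expect_equal(dosenet:::rate_test(4, 10, 0.1),
               binom.test(4, 10, 0.1)$p.value)  # expected cell 1 < 5
  # with large n the chi-square branch is used and matches the formula
  p_big <- dosenet:::rate_test(40, 100, 0.1)
  x2 <- (40 - 10)^2 / 10 + (60 - 90)^2 / 90
  expect_equal(p_big, pchisq(x2, 1, lower.tail = FALSE))
  # observed at exactly the global rate: p ~ 1
  expect_gt(dosenet:::rate_test(10, 100, 0.1), 0.99)
})

test_that("neighbor summaries pool pairs by class with the documented
           multiplicity convention", {
  # tiny constructed world: 2 lines, network as hand-drawn graph
  net <- igraph::graph_from_data_frame(
    data.frame(a = c("h1", "h1", "h2", "x1"),
               b = c("x1", "x2", "x1", "x3")),
    directed = FALSE)
  defs <- structure(list(
    table = data.frame(name = c("L1", "L2")),
    genes = list(L1 = c("h1"), L2 = c("h2"))
  ), class = "deficiency_set")
  calls <- data.frame(gene = c("h1", "h2"), class = c("anti", "full"))
  mk_tab <- function(genes, changed, dir) {
    data.frame(gene = genes, lfc = dir * 1, p = 0.001, q = 0.001,
               changed = changed, direction = dir)
  }
  de <- structure(list(lines = list(
    L1 = mk_tab(c("x1", "x2", "x3"), c(TRUE, TRUE, FALSE), c(-1L, -1L, 1L)),
    L2 = mk_tab(c("x1", "x2", "x3"), c(TRUE, FALSE, FALSE), c(1L, 1L, 1L))
  ), alpha = 0.05, sex = "female"), class = "per_line_de")
  pairs <- neighbor_pair_table(net, defs, calls, de)
  # h1 -> x1, x2 in L1; h2 -> x1 in L2: x1 counted once per hub
  expect_equal(nrow(pairs), 3)
  nc <- neighbor_change_by_class(net, defs, calls, de)
  bc <- nc$by_class
  expect_equal(bc$n_changed[bc$class == "anti"], 2L)
  expect_equal(bc$prob_change[bc$class == "anti"], 1)
  expect_equal(bc$n_changed[bc$class == "full"], 1L)
  # classes without hubs give NA rows
  expect_true(is.na(bc$prob_change[bc$class == "partial"]))
  nd <- neighbor_direction_by_class(net, defs, calls, de)
  bd <- nd$by_class
  expect_equal(bd$prop_positive[bd$class == "anti"], 0)
  expect_equal(bd$prop_positive[bd$class == "full"], 1)
})

test_that("direction proportions: all-positive gives 1.0; balanced signs
           are unremarkable against a balanced global", {
  set.seed(104)
  pairs <- data.frame(
    line = "L1", hub = "h", class = "over",
    neighbor = sprintf("x%02d", 1:40),
    changed = TRUE, direction = rep(1L, 40)
  )
  glob <- list(n = 4000, changed = 400, rate = 0.1, prop_positive = 0.5)
  s <- summarize_neighbor_direction(pairs, glob)
  expect_equal(s$by_class$prop_positive[s$by_class$class == "over"], 1)
  expect_lt(s$by_class$p[s$by_class$class == "over"], 1e-6)
  pairs$direction <- rep(c(1L, -1L), 20)
  s2 <- summarize_neighbor_direction(pairs, glob)
  expect_gt(s2$by_class$p[s2$by_class$class == "over"], 0.5)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # universe 20, 5 changed; complex of 4 with 3 changed:
  # p = [C(5,3)C(15,1) + C(5,4)C(15,0)] / C(20,4)
  oracle <- (choose(5, 3) * choose(15, 1) + choose(5, 4) * choose(15, 0)) /
    choose(20, 4)
  expect_equal(hyper_enrichment_p(k = 3, m = 4, K = 5, N = 20), oracle)
  expect_equal(round(oracle, 3), 0.032)
  # zero changed members: p = 1
  expect_equal(hyper_enrichment_p(0, 4, 5, 20), 1)
})

test_that("complex coherence enumerates every (complex, line, sex) cell and
           respects the membership floor", {
  set.seed(105)
  G <- 300
  genes <- sprintf("g%03d", 1:G)
  mk_de <- function(n_lines, seed) {
    set.seed(seed)
    lines <- lapply(seq_len(n_lines), function(i) {
      ch <- rbinom(G, 1, 0.05) == 1
      data.frame(gene = genes, lfc = rnorm(G), p = 0.5, q = 0.5,
                 changed = ch,
                 direction = sample(c(-1L, 1L), G, TRUE))
    })
    names(lines) <- sprintf("L%02d", seq_len(n_lines))
    structure(list(lines = lines, alpha = 0.05), class = "per_line_de")
  }
  de_by_sex <- list(female = mk_de(21, 1), male = mk_de(21, 2))
  complexes <- data.frame(
    complex = rep(sprintf("C%02d", 1:23), each = 12),
    gene = sample(genes, 23 * 12, replace = FALSE)
  )
  res <- complex_coherence(de_by_sex, complexes)
  expect_equal(nrow(res), 23 * 21 * 2)
  expect_true(all(res$members_changed <= res$members_measured))
  expect_true(all(res$p_joint > 0 & res$p_joint <= 1))
  # under random change labels, about 1% of cells pass at 0.01
  expect_lt(mean(res$significant), 0.05)
  # a complex with fewer than 10 measured members is excluded
  complexes2 <- rbind(complexes,
                      data.frame(complex = "tiny", gene = genes[1:4]))
  res2 <- complex_coherence(de_by_sex, complexes2)
  expect_false("tiny" %in% res2$complex)
})

test_that("complex coherence p-values are calibrated under label
           permutation", {
  set.seed(106)
  G <- 400
  genes <- sprintf("g%03d", 1:G)
  cx <- data.frame(complex = "C1", gene = genes[1:15])
  pvals <- replicate(300, {
    ch <- sample(c(rep(TRUE, 40), rep(FALSE, G - 40)))
    de <- structure(list(lines = list(
      L1 = data.frame(gene = genes, lfc = 0, p = 1, q = 1, changed = ch,
                      direction = sample(c(-1L, 1L), G, TRUE))
    ), alpha = 0.05), class = "per_line_de")
    complex_coherence(list(female = de), cx)$p_enrich
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
  expect_lt(mean(pvals < 0.01), 0.04)
})

test_that("a coherently perturbed complex is flagged while neutral
           complexes are not", {
  set.seed(107)
  G <- 300
  genes <- sprintf("g%03d", 1:G)
  ch <- rep(FALSE, G); ch[1:20] <- TRUE   # background 20 changed
  ch[101:112] <- TRUE                      # the perturbed complex members
  dir <- sample(c(-1L, 1L), G, TRUE)
  dir[101:112] <- 1L                       # uniform direction
  de <- structure(list(lines = list(
    L1 = data.frame(gene = genes, lfc = dir, p = 0.001, q = 0.001,
                    changed = ch, direction = dir)
  ), alpha = 0.05), class = "per_line_de")
  cxs <- data.frame(
    complex = c(rep("hit", 12), rep("neutral", 12)),
    gene = c(genes[101:112], genes[201:212])
  )
  res <- complex_coherence(list(female = de), cxs)
  expect_true(res$significant[res$complex == "hit"])
  expect_false(res$significant[res$complex == "neutral"])
  expect_equal(res$p_enrich[res$complex == "neutral"], 1,
               tolerance = 0.2)
})
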