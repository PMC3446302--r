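#' Per-line differential expression against the composite reference
#'
#' For each deficiency line and one sex, moderated one-sample t-tests
#' (null log2 fold change 0) of the line's replicate log2 ratios to the
#' composite reference, BH corrected within the line. The "one versus
#' everyone" design: each line is contrasted with the median behaviour of
#' the whole panel, so line-specific changes stand out while panel-wide
#' trends cancel.
#'
#' @param x an [expr_matrix()].
#' @param sex `"female"` or `"male"`.
#' @param reference per-gene composite reference ([build_reference()],
#'   mode `"composite"`).
#' @param alpha FDR level for calling a gene changed (default 0.05).
#' @param lines lines to test; defaults to all non-parental lines.
#' @param genes optional gene subset (e.g. the detection mask).
#' @param parental_line parental line name, excluded from testing.
#' @return List of class `per_line_de`: per line a data.frame (`gene`,
#'   `lfc`, `p`, `q`, `changed`, `direction`), plus `alpha`.
#' @export
per_line_de <- function(x, sex, reference, alpha = 0.05, lines = NULL,
                        genes = NULL, parental_line = "w1118") {
  stopifnot(inherits(x, "expr_matrix"))
  xs <- subset_expr(x, sex = sex)
  vals <- gene_values(xs)
  if (!is.null(genes)) vals <- vals[rownames(vals) %in% genes, ,
                                    drop = FALSE]
  lines <- lines %||% setdiff(unique(xs$samples$line), parental_line)
  res <- list()
  for (ln in lines) {
    cols <- which(xs$samples$line == ln)
    if (length(cols) < 2) {
      warning("line ", ln, " has <2 replicates; skipped", call. = FALSE)
      next
    }
    ratios <- vals[, cols, drop = FALSE] - reference[rownames(vals)]
    mt <- moderated_t(ratios_to_list(ratios), null_lfc = 0)
    mt$changed <- mt$q < alpha
    mt$direction <- ifelse(mt$lfc > 0, 1L, -1L)
    res[[ln]] <- mt[, c("gene", "lfc", "p", "q", "changed", "direction")]
  }
  structure(list(lines = res, alpha = alpha, sex = sex),
            class = "per_line_de")
}

ratios_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  names(out) <- rownames(m)
  out
}

#' @export
print.per_line_de <- function(x, ...) {
  n_changed <- vapply(x$lines, function(d) sum(d$changed), integer(1))
  cat("per_line_de (", x$sex, "): ", length(x$lines), " lines; changed ",
      "genes/line: mean ", round(mean(n_changed), 1), ", range ",
      min(n_changed), "-", max(n_changed), "\n", sep = "")
  invisible(x)
}

#' First-degree two-dose neighbors of one-dose genes
#'
#' For every one-dose gene, the unique network neighbors minus all
#' one-dose genes of the same line. One-dose genes absent from the network
#' yield empty sets (counted separately by downstream summaries).
#'
#' @param net an igraph network.
#' @param one_dose_genes character vector of the line's one-dose genes.
#' @return Named list of neighbor character vectors, one per one-dose
#'   gene.
#' @export
first_degree_neighbors <- function(net, one_dose_genes) {
  nodes <- igraph::V(net)$name
  out <- lapply(one_dose_genes, function(g) {
    if (!(g %in% nodes)) return(character(0))
    nb <- igraph::neighbors(net, g)$name
    setdiff(unique(nb), one_dose_genes)
  })
  names(out) <- one_dose_genes
  out
}

#' Assemble the (hub, neighbor, line) pair table for one sex
#'
#' With the default union-with-multiplicity convention each (one-dose
#' gene -> neighbor) pair counts once, so a neighbor shared by two hubs
#' of the same class counts once per hub. With
#' `distinct_neighbors = TRUE` the table is collapsed to unique
#' (line, class, neighbor) rows instead. The table underlies the
#' by-class summaries and can be pooled across sexes before summarising.
#'
#' @param net an igraph network.
#' @param deficiencies a [generate_deficiencies()] result.
#' @param calls `compensation_calls` (or a data.frame `gene`/`class`).
#' @param de a [per_line_de()] result of the matching sex.
#' @param distinct_neighbors collapse to unique (line, class, neighbor)
#'   rows (default `FALSE`).
#' @return data.frame with `line`, `hub`, `class`, `neighbor`, `changed`,
#'   `direction`.
#' @export
neighbor_pair_table <- function(net, deficiencies, calls, de,
                                distinct_neighbors = FALSE) {
  df <- if (inherits(calls, "compensation_calls")) calls$calls else calls
  cls <- setNames(df$class, df$gene)
  rows <- list()
  for (ln in names(de$lines)) {
    od <- deficiencies$genes[[ln]]
    od <- od[od %in% names(cls)]
    if (!length(od)) next
    nbs <- first_degree_neighbors(net, od)
    tab <- de$lines[[ln]]
    changed <- setNames(tab$changed, tab$gene)
    dir <- setNames(tab$direction, tab$gene)
    for (g in od) {
      nb <- nbs[[g]]
      nb <- nb[nb %in% tab$gene]
      if (!length(nb)) next
      rows[[length(rows) + 1L]] <- data.frame(
        line = ln, hub = g, class = cls[[g]], neighbor = nb,
        changed = unname(changed[nb]), direction = unname(dir[nb]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(line = character(0), hub = character(0),
                      class = character(0), neighbor = character(0),
                      changed = logical(0), direction = integer(0)))
  }
  out <- do.call(rbind, rows)
  if (distinct_neighbors) {
    out <- out[!duplicated(out[, c("line", "class", "neighbor")]), ]
    rownames(out) <- NULL
  }
  out
}

# Global change statistics over all network nodes tested in the per-line
# DE (the expected rate under no propagation), pooled across lines.
global_change_rate <- function(net, de, exclude_one_dose = NULL) {
  nodes <- igraph::V(net)$name
  tot <- 0L
  chg <- 0L
  pos <- 0L
  for (ln in names(de$lines)) {
    tab <- de$lines[[ln]]
    keep <- tab$gene %in% nodes
    if (!is.null(exclude_one_dose)) {
      keep <- keep & !(tab$gene %in% exclude_one_dose[[ln]])
    }
    tot <- tot + sum(keep)
    chg <- chg + sum(tab$changed[keep])
    pos <- pos + sum(tab$changed[keep] & tab$direction[keep] > 0)
  }
  list(n = tot, changed = chg, rate = chg / tot,
       prop_positive = if (chg > 0) pos / chg else NA_real_)
}

# chi-square GOF of observed changed count vs a global rate (1 df), exact
# binomial fallback when an expected cell is below 5.
rate_test <- function(k, n, p0) {
  if (n == 0 || is.na(p0)) return(NA_real_)
  expected <- c(n * p0, n * (1 - p0))
  if (any(expected < 5)) {
    return(binom.test(k, n, p0)$p.value)
  }
  x2 <- (k - expected[1])^2 / expected[1] +
    ((n - k) - expected[2])^2 / expected[2]
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Probability of neighbor expression change by compensation class
#'
#' Pools (hub, neighbor) pairs per compensation class and compares the
#' pooled change probability with the global change rate over all network
#' nodes (chi-square, 1 df; exact binomial when expected counts fall
#' below 5).
#'
#' @param net an igraph network.
#' @param deficiencies a [generate_deficiencies()] result.
#' @param calls `compensation_calls` (or a data.frame `gene`/`class`).
#' @param de a [per_line_de()] result of the matching sex.
#' @return List of class `neighbor_change`: `by_class` data.frame
#'   (`class`, `n_hubs`, `n_neighbors`, `n_changed`, `prob_change`, `p`),
#'   `global` (list `n`, `changed`, `rate`, `prop_positive`), and `pairs`
#'   (the pooled pair table).
#' @export
neighbor_change_by_class <- function(net, deficiencies, calls, de) {
  pairs <- neighbor_pair_table(net, deficiencies, calls, de)
  glob <- global_change_rate(net, de, exclude_one_dose =
                               deficiencies$genes[names(de$lines)])
  summarize_neighbor_change(pairs, glob)
}

#' Summarise a neighbor pair table (possibly pooled across sexes)
#'
#' @param pairs a [neighbor_pair_table()] (or several, row-bound).
#' @param global a global change-rate list (`n`, `changed`, `rate`,
#'   `prop_positive`), e.g. from one sex or pooled with
#'   [pool_global_rates()].
#' @return A `neighbor_change` summary (see
#'   [neighbor_change_by_class()]).
#' @export
summarize_neighbor_change <- function(pairs, global) {
  by_class <- do.call(rbind, lapply(COMP_CLASSES, function(cl) {
    pp <- pairs[pairs$class == cl, ]
    n <- nrow(pp)
    k <- sum(pp$changed)
    data.frame(
      class = cl,
      n_hubs = length(unique(pp$hub)),
      n_neighbors = n,
      n_changed = k,
      prob_change = if (n > 0) k / n else NA_real_,
      p = if (n > 0) rate_test(k, n, global$rate) else NA_real_
    )
  }))
  structure(list(by_class = by_class, global = global, pairs = pairs),
            class = "neighbor_change")
}

#' Pool per-sex global change-rate summaries
#'
#' @param ... global-rate lists as attached to the neighbor summaries.
#' @return A pooled global-rate list.
#' @export
pool_global_rates <- function(...) {
  gs <- list(...)
  tot <- sum(vapply(gs, `[[`, numeric(1), "n"))
  chg <- sum(vapply(gs, `[[`, numeric(1), "changed"))
  pos <- sum(vapply(gs, function(g) {
    if (is.na(g$prop_positive)) 0 else g$prop_positive * g$changed
  }, numeric(1)))
  list(n = tot, changed = chg, rate = chg / tot,
       prop_positive = if (chg > 0) pos / chg else NA_real_)
}

#' Direction of neighbor expression change by compensation class
#'
#' Among changed neighbors, the proportion with increased expression per
#' compensation class, compared with the global proportion positive among
#' all changed network nodes (chi-square, 1 df, binomial fallback), plus
#' an overall class-by-direction association test. Sympathetic
#' propagation shows as below-global proportions for anti/non classes and
#' above-global for partial/full/over.
#'
#' @inheritParams neighbor_change_by_class
#' @return List of class `neighbor_direction`: `by_class` data.frame
#'   (`class`, `n_changed`, `n_positive`, `prop_positive`, `p`), `global`
#'   (including the `prop_positive` diagnostic: the global near-balance is
#'   reported, not assumed), and `overall_p` (class x direction
#'   chi-square).
#' @export
neighbor_direction_by_class <- function(net, deficiencies, calls, de) {
  pairs <- neighbor_pair_table(net, deficiencies, calls, de)
  glob <- global_change_rate(net, de, exclude_one_dose =
                               deficiencies$genes[names(de$lines)])
  summarize_neighbor_direction(pairs, glob)
}

#' Summarise changed-neighbor directions (possibly pooled across sexes)
#'
#' @inheritParams summarize_neighbor_change
#' @return A `neighbor_direction` summary (see
#'   [neighbor_direction_by_class()]).
#' @export
summarize_neighbor_direction <- function(pairs, global) {
  glob <- global
  ch <- pairs[pairs$changed, ]
  by_class <- do.call(rbind, lapply(COMP_CLASSES, function(cl) {
    pp <- ch[ch$class == cl, ]
    n <- nrow(pp)
    k <- sum(pp$direction > 0)
    data.frame(
      class = cl,
      n_changed = n,
      n_positive = k,
      prop_positive = if (n > 0) k / n else NA_real_,
      p = if (n > 0) rate_test(k, n, glob$prop_positive) else NA_real_
    )
  }))
  overall_p <- if (nrow(ch) > 0 &&
                   length(unique(ch$class)) > 1 &&
                   length(unique(ch$direction)) > 1) {
    suppressWarnings(chisq.test(table(ch$class, ch$direction))$p.value)
  } else {
    NA_real_
  }
  structure(list(by_class = by_class, global = glob, overall_p = overall_p),
            class = "neighbor_direction")
}

#' Coherent expression change in protein complexes
#'
#' For every (complex, line, sex) cell: enrichment of changed members by
#' the upper-tail hypergeometric test against the universe of measured
#' two-dose genes, direction uniformity by a two-sided binomial test of
#' the dominant-direction count at the global proportion-positive rate,
#' and the joint probability as their product (the pure hypergeometric p
#' is also reported). Complexes with fewer than `min_members` measured
#' members are excluded.
#'
#' @param de_by_sex named list (`female`, `male`) of [per_line_de()]
#'   results.
#' @param complexes data.frame with columns `complex` and `gene`.
#' @param min_members minimum measured members (default 10).
#' @param alpha significance threshold on the joint p (default 0.01).
#' @return data.frame of class `complex_coherence`: one row per (complex,
#'   line, sex) with `members_measured`, `members_changed`,
#'   `dominant_direction_n`, `p_enrich`, `p_direction`, `p_joint`,
#'   `significant`.
#' @export
complex_coherence <- function(de_by_sex, complexes, min_members = 10L,
                              alpha = 0.01) {
  stopifnot(all(c("complex", "gene") %in% names(complexes)))
  rows <- list()
  for (sx in names(de_by_sex)) {
    de <- de_by_sex[[sx]]
    for (ln in names(de$lines)) {
      tab <- de$lines[[ln]]
      universe <- tab$gene
      n_changed_universe <- sum(tab$changed)
      prop_pos <- if (any(tab$changed)) {
        sum(tab$direction[tab$changed] > 0) / sum(tab$changed)
      } else {
        NA_real_
      }
      changed <- setNames(tab$changed, tab$gene)
      dir <- setNames(tab$direction, tab$gene)
      for (cx in unique(complexes$complex)) {
        members <- intersect(complexes$gene[complexes$complex == cx],
                             universe)
        m <- length(members)
        if (m < min_members) next
        k <- sum(changed[members])
        p_enrich <- phyper(k - 1, n_changed_universe,
                           length(universe) - n_changed_universe, m,
                           lower.tail = FALSE)
        if (k > 0 && !is.na(prop_pos)) {
          n_pos <- sum(dir[members][changed[members]] > 0)
          dom <- max(n_pos, k - n_pos)
          p_direction <- binom.test(n_pos, k, prop_pos)$p.value
        } else {
          dom <- 0L
          p_direction <- 1
        }
        p_joint <- min(1, p_enrich * p_direction)
        rows[[length(rows) + 1L]] <- data.frame(
          complex = cx, line = ln, sex = sx,
          members_measured = m, members_changed = k,
          dominant_direction_n = dom,
          p_enrich = p_enrich, p_direction = p_direction,
          p_joint = p_joint, significant = p_joint < alpha,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("complex_coherence", class(out))
  out
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `k` changed members in a complex of
#' `m` measured members, when `K` of the `N` universe genes changed.
#'
#' @param k changed members observed.
#' @param m measured members of the complex.
#' @param K changed genes in the universe.
#' @param N universe size.
#' @return Upper-tail p-value `P(X >= k)`.
#' @export
hyper_enrichment_p <- function(k, m, K, N) {
  phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Run the full propagation pipeline for one sex
#'
#' Convenience wrapper chaining composite reference, per-line DE, MI
#' network inference, one-dose classification and the neighbor summaries.
#'
#' @param x an [expr_matrix()].
#' @param deficiencies a [generate_deficiencies()] result.
#' @param sex `"female"` or `"male"`.
#' @param alpha_de FDR level for DE calls.
#' @param alpha_edge MI edge threshold.
#' @param n_perm MI permutations.
#' @param seed RNG seed.
#' @param genes optional gene universe (defaults to the detection mask).
#' @param calls optional precomputed `compensation_calls`; when `NULL`
#'   the one-dose genes are classified from the data.
#' @return List with `reference`, `de`, `network`, `mt` (moderated test of
#'   one-dose genes vs dose), `calls`, `neighbor_change`,
#'   `neighbor_direction`.
#' @export
run_propagation_pipeline <- function(x, deficiencies, sex,
                                     alpha_de = 0.05, alpha_edge = 0.005,
                                     n_perm = 2000L, seed = 1L,
                                     genes = NULL, calls = NULL) {
  mask <- detection_mask(x, sex)
  genes <- genes %||% names(mask$detected)[mask$detected]
  comp_ref <- build_reference(x, "composite", sex)
  de <- per_line_de(x, sex, comp_ref, alpha = alpha_de, genes = genes)
  netfit <- infer_mi_network(x, sex, genes = genes, alpha = alpha_edge,
                             n_perm = n_perm, seed = seed,
                             max_genes = 2000L)
  if (is.null(calls)) {
    ratios <- onedose_ratios(x, deficiencies, sex, comp_ref,
                             detected = mask$detected)
    mt <- moderated_t(ratios, null_lfc = -1)
    calls <- classify_compensation(mt, seed = seed)
  } else {
    mt <- NULL
  }
  list(
    reference = comp_ref,
    de = de,
    network = netfit$network,
    network_stats = netfit$stats,
    mt = mt,
    calls = calls,
    neighbor_change = neighbor_change_by_class(netfit$network,
                                               deficiencies, calls, de),
    neighbor_direction = neighbor_direction_by_class(netfit$network,
                                                     deficiencies, calls,
                                                     de)
  )
}
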