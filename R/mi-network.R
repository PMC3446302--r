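#' Standardize expression profiles within one sex
#'
#' Per-gene z-scores across all lines and replicates of one sex: subtract
#' the gene's mean and divide by its standard deviation. Zero-variance
#' genes are excluded with a warning.
#'
#' @param x an [expr_matrix()].
#' @param sex `"female"` or `"male"`.
#' @param genes optional subset of gene ids to keep.
#' @return Numeric matrix (genes x samples) of z-scores.
#' @export
standardize <- function(x, sex, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- gene_values(subset_expr(x, sex = sex))
  if (!is.null(genes)) vals <- vals[rownames(vals) %in% genes, ,
                                    drop = FALSE]
  sds <- apply(vals, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance genes excluded from ",
            "standardization", call. = FALSE)
    vals <- vals[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (vals - rowMeans(vals)) / sds
}

# Gaussian kernel sum matrix for one profile: K[i, j] = exp(-(x_i-x_j)^2 /
# (2 h^2)).  Shared by the single-pair and all-pairs estimators.
kernel_matrix <- function(x, h) {
  d <- outer(x, x, "-")
  exp(-d^2 / (2 * h^2))
}

#' Kernel-density mutual information between two profiles
#'
#' Plug-in estimate with Gaussian kernels of bandwidth `h` for the
#' marginals and a diagonal bandwidth `h*I` for the joint, evaluated at
#' the sample points (leave-none-out):
#' `MI = mean_i log( f_xy(x_i, y_i) / (f_x(x_i) f_y(y_i)) )`.
#' The kernel normalisation constants cancel, leaving
#' `MI_i = log( n * Sxy_i / (Sx_i * Sy_i) )` with `S` the kernel sums.
#' Result in nats.
#'
#' @param x,y numeric profiles of equal length (>= 8); intended to be
#'   z-scored ([standardize()]).
#' @param h kernel bandwidth (default 0.3).
#' @return MI estimate in nats.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- x + rnorm(200, sd = 0.5)
#' kernel_mi(scale(x)[, 1], scale(y)[, 1])
kernel_mi <- function(x, y, h = 0.3) {
  n <- length(x)
  if (length(y) != n) stop("profiles must have equal length", call. = FALSE)
  if (n < 8) stop("kernel_mi needs n >= 8", call. = FALSE)
  Kx <- kernel_matrix(x, h)
  Ky <- kernel_matrix(y, h)
  Sx <- rowSums(Kx)
  Sy <- rowSums(Ky)
  Sxy <- rowSums(Kx * Ky)
  mean(log(n * Sxy / (Sx * Sy)))
}

# MI for all row pairs of a z-scored matrix; returns the pair table.
# Kernel matrices are precomputed per gene (the dominant cost is the
# elementwise product per pair).
mi_all_pairs <- function(z, h = 0.3) {
  g <- nrow(z)
  n <- ncol(z)
  if (g < 2) stop("need >= 2 genes", call. = FALSE)
  K <- lapply(seq_len(g), function(i) kernel_matrix(z[i, ], h))
  S <- vapply(K, rowSums, numeric(n))
  pairs <- utils::combn(g, 2)
  mi <- numeric(ncol(pairs))
  logn <- log(n)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    mi[k] <- mean(log(rowSums(K[[i]] * K[[j]]))) -
      mean(log(S[, i]) + log(S[, j])) + logn
  }
  data.frame(gene_a = rownames(z)[pairs[1, ]],
             gene_b = rownames(z)[pairs[2, ]],
             mi = mi, stringsAsFactors = FALSE)
}

#' Permutation significance of mutual-information edges
#'
#' Computes MI for all gene pairs of a standardized matrix and a pooled
#' permutation null: `n_perm` MI values from independently permuted
#' profile pairs at the same sample size. After z-scoring, the null MI
#' distribution depends only on the sample size and bandwidth, so a pooled
#' null is exchangeable across pairs; per-pair permutation for all O(G^2)
#' pairs at alpha = 0.005 would need >= 400 permutations per pair and is
#' intractable. P-values use the add-one rule
#' `p = (1 + #null >= observed) / (1 + n_perm)`, so `p` is always in
#' (0, 1].
#'
#' @param z standardized matrix from [standardize()].
#' @param h kernel bandwidth (default 0.3).
#' @param n_perm permutations (default 2000; must satisfy
#'   `n_perm >= 2/alpha` for the target alpha).
#' @param alpha target edge significance level (used only to validate
#'   `n_perm`).
#' @param seed RNG seed for the permutations.
#' @return data.frame with `gene_a`, `gene_b`, `mi`, `p`; the null MI
#'   sample is attached as attribute `null`.
#' @export
edge_significance <- function(z, h = 0.3, n_perm = 2000L, alpha = 0.005,
                              seed = 1L) {
  if (n_perm < 1000L) stop("n_perm must be >= 1000", call. = FALSE)
  if (n_perm < 2 / alpha) {
    stop("n_perm too small for requested alpha: need >= 2/alpha",
         call. = FALSE)
  }
  pairs <- mi_all_pairs(z, h)
  g <- nrow(z)
  n <- ncol(z)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      i <- sample.int(g, 1)
      j <- sample.int(g, 1)
      kernel_mi(z[i, sample.int(n)], z[j, sample.int(n)], h)
    }, numeric(1))
  })
  null_sorted <- sort(null)
  # #null >= mi via binary search on the sorted null
  ge <- n_perm - findInterval(pairs$mi, null_sorted)
  pairs$p <- (1 + ge) / (1 + n_perm)
  attr(pairs, "null") <- null
  pairs
}

#' Build a mutual-information network from scored pairs
#'
#' Keeps edges with `p < alpha` and returns a simple undirected igraph
#' graph. Isolated measured genes are retained as nodes so that one-dose
#' genes without significant edges remain queryable.
#'
#' @param pairs data.frame from [edge_significance()] (columns `gene_a`,
#'   `gene_b`, `mi`, `p`).
#' @param alpha edge threshold (default 0.005).
#' @param nodes optional character vector of all measured genes to retain
#'   as vertices.
#' @return An igraph graph with edge attributes `mi` and `p`.
#' @export
build_mi_network <- function(pairs, alpha = 0.005, nodes = NULL) {
  keep <- pairs$p < alpha
  el <- pairs[keep, , drop = FALSE]
  verts <- unique(c(nodes, el$gene_a, el$gene_b))
  g <- igraph::graph_from_data_frame(
    el[, c("gene_a", "gene_b", "mi", "p")],
    directed = FALSE,
    vertices = data.frame(name = verts)
  )
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Topology statistics of a network
#'
#' Average local clustering coefficient (isolated and degree-1 vertices
#' count 0), mean degree (`2|E|/|V|`, "average neighbors"), density and
#' the power-law exponent of the degree distribution fitted by least
#' squares on the log-log histogram (degrees >= 1).
#'
#' @param net an igraph graph.
#' @return List with `n_nodes`, `n_edges`, `clustering`, `avg_neighbors`,
#'   `density`, `powerlaw_exponent` (negative slope convention; `NA`
#'   without edges).
#' @export
topology_stats <- function(net) {
  nv <- igraph::vcount(net)
  if (nv < 3) stop("topology_stats needs >= 3 nodes", call. = FALSE)
  ne <- igraph::ecount(net)
  clust <- if (ne == 0) 0 else {
    mean(igraph::transitivity(net, type = "localundirected",
                              isolates = "zero"))
  }
  expo <- if (ne == 0) NA_real_ else {
    powerlaw_exponent(igraph::degree(net))
  }
  list(
    n_nodes = nv,
    n_edges = ne,
    clustering = clust,
    avg_neighbors = 2 * ne / nv,
    density = igraph::edge_density(net),
    powerlaw_exponent = expo
  )
}

#' Least-squares power-law exponent of a degree distribution
#'
#' Slope of `log10(frequency)` on `log10(degree)` over degrees >= 1 with
#' non-zero frequency (the convention of standard network-analysis
#' plug-ins).
#'
#' @param degrees integer vector of node degrees.
#' @return Fitted slope (typically negative); `NA` when fewer than two
#'   distinct positive degrees exist.
#' @export
powerlaw_exponent <- function(degrees) {
  degrees <- degrees[degrees >= 1]
  if (!length(degrees)) return(NA_real_)
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(k) < 2) return(NA_real_)
  unname(coef(stats::lm(log10(f) ~ log10(k)))[2])
}

#' Degree-preserving edge randomization
#'
#' Generates null networks by double-edge swaps (endpoints of two edges
#' exchanged) that reject self-loops and already-existing edges, so the
#' full degree multiset is preserved exactly, and computes an empirical
#' upper-tail p-value for a network statistic. Graphs admitting no legal
#' swap (e.g. a triangle) are returned unchanged with a warning.
#'
#' @param net an igraph graph with >= 2 edges.
#' @param statistic function mapping a graph to a numeric scalar (default:
#'   average local clustering).
#' @param n_swaps_factor attempted swaps per randomization, as a multiple
#'   of the edge count (default 10).
#' @param n_randomizations number of null networks (default 100).
#' @param seed RNG seed.
#' @return List with `observed`, `null` (numeric vector), `p`
#'   (`(1 + #null >= observed) / (1 + n_randomizations)`), and
#'   `degenerate` flag set when no randomization changed the graph.
#' @export
degree_preserving_shuffle <- function(net,
                                      statistic = function(g) {
                                        mean(igraph::transitivity(
                                          g, type = "localundirected",
                                          isolates = "zero"))
                                      },
                                      n_swaps_factor = 10L,
                                      n_randomizations = 100L,
                                      seed = 1L) {
  ne <- igraph::ecount(net)
  if (ne < 2) stop("degree_preserving_shuffle needs >= 2 edges",
                   call. = FALSE)
  obs <- statistic(net)
  niter <- n_swaps_factor * ne
  changed_any <- FALSE
  null <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(k) {
      r <- igraph::rewire(net, igraph::keeping_degseq(loops = FALSE,
                                                      niter = niter))
      if (igraph::ecount(igraph::intersection(r, net)) != ne) {
        changed_any <<- TRUE
      }
      statistic(r)
    }, numeric(1))
  })
  if (!changed_any) {
    warning("graph admits no degree-preserving swap; null equals observed",
            call. = FALSE)
  }
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (1 + n_randomizations),
       degenerate = !changed_any)
}

#' Clustering of bias-group subnetworks with randomization significance
#'
#' Induced-subgraph average clustering per sex-bias group, with
#' significance from degree-preserving randomizations of the full network
#' (group clustering recomputed on each null).
#'
#' @param net an igraph graph.
#' @param bias_labels named vector (`female`/`male`/`none`) covering the
#'   nodes.
#' @param n_randomizations,n_swaps_factor,seed passed to the
#'   randomization.
#' @return data.frame per group: `bias`, `n_nodes`, `clustering`,
#'   `null_mean`, `p` (upper tail); groups under 3 nodes give `NA`.
#' @export
subnetwork_clustering_by_bias <- function(net, bias_labels,
                                          n_randomizations = 100L,
                                          n_swaps_factor = 10L,
                                          seed = 1L) {
  groups <- c("female", "male", "none")
  nodes <- igraph::V(net)$name
  grp_nodes <- lapply(groups, function(b) nodes[bias_labels[nodes] == b])
  names(grp_nodes) <- groups
  grp_clust <- function(g) {
    vapply(groups, function(b) {
      vs <- grp_nodes[[b]]
      if (length(vs) < 3) return(NA_real_)
      sub <- igraph::induced_subgraph(g, vs)
      mean(igraph::transitivity(sub, type = "localundirected",
                                isolates = "zero"))
    }, numeric(1))
  }
  obs <- grp_clust(net)
  niter <- n_swaps_factor * igraph::ecount(net)
  null <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(k) {
      r <- igraph::rewire(net, igraph::keeping_degseq(loops = FALSE,
                                                      niter = niter))
      grp_clust(r)
    }, numeric(length(groups)))
  })
  null <- matrix(null, nrow = length(groups))
  data.frame(
    bias = groups,
    n_nodes = vapply(grp_nodes, length, integer(1)),
    clustering = obs,
    null_mean = rowMeans(null, na.rm = TRUE),
    p = vapply(seq_along(groups), function(i) {
      if (is.na(obs[i])) return(NA_real_)
      (1 + sum(null[i, ] >= obs[i], na.rm = TRUE)) /
        (1 + n_randomizations)
    }, numeric(1)),
    row.names = NULL
  )
}

#' Sex-specific mutual-information network from an expression matrix
#'
#' Convenience wrapper: standardize one sex's detected genes, score all
#' pairs with permutation significance and build the network.
#'
#' @param x an [expr_matrix()].
#' @param sex `"female"` or `"male"`.
#' @param genes optional gene subset (e.g. the detection mask).
#' @param h kernel bandwidth (default 0.3).
#' @param alpha edge threshold (default 0.005).
#' @param n_perm permutations for the pooled null.
#' @param seed RNG seed.
#' @param max_genes guard against accidental all-pairs runs on very large
#'   matrices; raise deliberately for full runs.
#' @return List with `network` (igraph), `pairs` (scored pair table) and
#'   `stats` ([topology_stats()]).
#' @export
infer_mi_network <- function(x, sex, genes = NULL, h = 0.3, alpha = 0.005,
                             n_perm = 2000L, seed = 1L, max_genes = 1000L) {
  z <- standardize(x, sex, genes)
  if (nrow(z) > max_genes) {
    stop("matrix has ", nrow(z), " genes; raise max_genes to confirm an ",
         "all-pairs run of this size", call. = FALSE)
  }
  pairs <- edge_significance(z, h = h, n_perm = n_perm, alpha = alpha,
                             seed = seed)
  net <- build_mi_network(pairs, alpha = alpha, nodes = rownames(z))
  list(network = net, pairs = pairs, stats = topology_stats(net))
}
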