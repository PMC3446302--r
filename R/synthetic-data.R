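#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping gene intervals on one chromosome arm.
#' Each gene is drawn inside its own equal-width slot so intervals are
#' disjoint and sorted by construction. Coordinates are 1-based inclusive
#' (the convention of deficiency breakpoint tables); [annotation_to_granges()]
#' converts to the 0-based half-open convention used by BED output.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`, `length`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  L <- config$chrom_length
  slot <- floor(L / n)
  if (slot < 200) {
    stop("invalid config: less than 200 bp available per gene",
         call. = FALSE)
  }
  with_seed(derive_seed(config$seed, 1L), {
    len <- pmax(100L, floor(runif(n, 0.3, 0.7) * slot))
    offset <- floor(runif(n) * (slot - len))
    start <- (seq_len(n) - 1L) * slot + 1L + offset
    end <- start + len - 1L
    data.frame(
      gene = sprintf("g%04d", seq_len(n)),
      chrom = "2L",
      start = as.integer(start),
      end = as.integer(end),
      length = as.integer(len),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate deficiency lines over an annotation
#'
#' Draws `n_lines` deletion intervals, each removing at least one gene, with
#' at least `n_overlap_pairs` pairs of deficiencies overlapping so that the
#' same one-dose genes recur in several deletion contexts. A gene is called
#' one-dose in a line when its interval overlaps the deletion by at least
#' 1 bp (removed "in full or part").
#'
#' @param config a [synthetic_config()].
#' @param annotation output of [generate_annotation()].
#' @return An object of class `deficiency_set`: a list with `table`
#'   (columns `name`, `chrom`, `first`, `last`, `n_genes`) and `genes`
#'   (named list of one-dose gene ids per line).
#' @export
generate_deficiencies <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"))
  n_lines <- config$n_lines
  n_genes <- nrow(annotation)
  if (n_lines > n_genes / 2) {
    stop("cannot place deficiencies: n_lines must be <= n_genes/2",
         call. = FALSE)
  }
  with_seed(derive_seed(config$seed, 2L), {
    counts <- pmax(1L, rpois(n_lines, config$genes_per_df))
    counts <- pmin(counts, max(1L, floor(n_genes / n_lines)))
    n_pairs <- if (n_lines >= 2L) min(config$n_overlap_pairs,
                                      floor(n_lines / 2)) else 0L
    starts <- integer(n_lines)
    taken <- rep(FALSE, n_genes)  # genes already inside a non-overlap line
    place_free <- function(cnt) {
      ok <- which(!taken)
      ok <- ok[ok + cnt - 1L <= n_genes]
      ok <- ok[vapply(ok, function(s) !any(taken[s:(s + cnt - 1L)]),
                      logical(1))]
      if (!length(ok)) {
        stop("cannot place requested deficiencies without collision",
             call. = FALSE)
      }
      if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    i <- 1L
    pair <- 0L
    while (i <= n_lines) {
      if (pair < n_pairs && i + 1L <= n_lines) {
        # overlapping pair: the partner starts midway through the first
        c1 <- max(2L, counts[i])
        s1 <- place_free(c1 + counts[i + 1L])
        starts[i] <- s1
        counts[i] <- c1
        starts[i + 1L] <- s1 + max(1L, c1 %/% 2L)
        span <- s1:(starts[i + 1L] + counts[i + 1L] - 1L)
        taken[span] <- TRUE
        pair <- pair + 1L
        i <- i + 2L
      } else {
        s <- place_free(counts[i])
        starts[i] <- s
        taken[s:(s + counts[i] - 1L)] <- TRUE
        i <- i + 1L
      }
    }
    first_gene <- starts
    last_gene <- starts + counts - 1L
    tab <- data.frame(
      name = sprintf("Df%02d", seq_len(n_lines)),
      chrom = annotation$chrom[1],
      first = annotation$start[first_gene],
      last = annotation$end[last_gene],
      n_genes = as.integer(counts),
      stringsAsFactors = FALSE
    )
    genes <- lapply(seq_len(n_lines), function(j) {
      one_dose_genes(annotation, tab$first[j], tab$last[j])
    })
    names(genes) <- tab$name
    structure(list(table = tab, genes = genes), class = "deficiency_set")
  })
}

#' @export
print.deficiency_set <- function(x, ...) {
  cat("deficiency_set:", nrow(x$table), "lines;",
      length(unique(unlist(x$genes))), "one-dose genes in union\n")
  print(utils::head(x$table))
  invisible(x)
}

#' One-dose genes for a deletion interval
#'
#' @param annotation gene table with 1-based inclusive `start`, `end`.
#' @param first,last deletion breakpoints, 1-based inclusive.
#' @return Character vector of gene ids overlapping the deletion by >= 1 bp.
#' @export
one_dose_genes <- function(annotation, first, last) {
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(annotation$start, annotation$end),
    IRanges::IRanges(first, last)
  )
  annotation$gene[S4Vectors::queryHits(hits)]
}

# --- planted network ------------------------------------------------------

# Random labelled tree with degrees targeting a power-law exponent, by
# Prufer-sequence decoding (node i appears degree_i - 1 times in the
# sequence).  A tree is used so that pairwise expression coupling can be
# planted exactly along edges by an AR cascade.
sample_powerlaw_tree <- function(n, exponent, max_degree = 20L) {
  stopifnot(n >= 2)
  if (n == 2) return(data.frame(from = 1L, to = 2L))
  kmax <- max(2L, min(n - 1L, max_degree))
  pk <- (1:kmax)^(-exponent)
  deg <- sample.int(kmax, n, replace = TRUE, prob = pk)
  # repair to the tree constraint sum(deg) = 2(n-1)
  pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  excess <- sum(deg) - 2L * (n - 1L)
  while (excess > 0L) {
    i <- pick1(which(deg > 1L))
    d <- min(deg[i] - 1L, excess)
    deg[i] <- deg[i] - d
    excess <- excess - d
  }
  while (excess < 0L) {
    i <- pick1(which(deg < kmax))
    d <- min(kmax - deg[i], -excess)
    deg[i] <- deg[i] + d
    excess <- excess + d
  }
  stubs <- rep.int(seq_len(n), deg - 1L)
  prufer <- if (length(stubs) > 1L) sample(stubs) else stubs
  decode_prufer(prufer, n)
}

# Standard linear-time Prufer decode: repeatedly join the smallest current
# leaf to the next sequence element.
decode_prufer <- function(prufer, n) {
  deg <- tabulate(prufer, n) + 1L
  from <- integer(n - 1L)
  to <- integer(n - 1L)
  ptr <- 1L
  while (deg[ptr] != 1L) ptr <- ptr + 1L
  leaf <- ptr
  for (k in seq_along(prufer)) {
    v <- prufer[k]
    from[k] <- leaf
    to[k] <- v
    deg[leaf] <- 0L
    deg[v] <- deg[v] - 1L
    if (deg[v] == 1L && v < ptr) {
      leaf <- v
    } else {
      repeat {
        ptr <- ptr + 1L
        if (ptr > n || deg[ptr] == 1L) break
      }
      leaf <- ptr
    }
  }
  rem <- which(deg == 1L)
  from[n - 1L] <- rem[1L]
  to[n - 1L] <- rem[2L]
  data.frame(from = from, to = to)
}

# BFS parent vector rooted at node 1 for a tree edge list.
tree_parents <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, n)
  order <- integer(n)
  parent[1L] <- 0L
  queue <- 1L
  qi <- 1L
  oi <- 1L
  while (qi <= length(queue)) {
    v <- queue[qi]; qi <- qi + 1L
    order[oi] <- v; oi <- oi + 1L
    for (w in adj[[v]]) {
      if (is.na(parent[w])) {
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  list(parent = parent, order = order)
}

# --- coverage -------------------------------------------------------------

#' Simulate DNA-seq coverage tracks for a deficiency panel
#'
#' Poisson read counts per bin at `coverage_depth` expected reads, with the
#' expectation halved (pro-rated for partially overlapping bins) inside each
#' line's deletion. The parental track has no reduction.
#'
#' @param config a [synthetic_config()].
#' @param deficiencies a [generate_deficiencies()] result.
#' @param sex `"female"` or `"male"`; selects an independent seed stream so
#'   the two sexes' libraries differ.
#' @return Named list of [coverage_track()] objects, one per deficiency line
#'   plus `"w1118"` (the parental line).
#' @export
simulate_coverage <- function(config, deficiencies, sex = "female") {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(deficiencies, "deficiency_set"))
  bin <- config$coverage_bin
  n_bins <- ceiling(config$chrom_length / bin)
  bin_start <- (seq_len(n_bins) - 1) * bin + 1
  bin_end <- pmin(bin_start + bin - 1, config$chrom_length)
  sex_off <- if (identical(sex, "male")) 500L else 0L
  tabs <- deficiencies$table
  out <- vector("list", nrow(tabs) + 1L)
  names(out) <- c(tabs$name, "w1118")
  for (j in seq_len(nrow(tabs))) {
    frac <- pmax(0, (pmin(bin_end, tabs$last[j]) -
                       pmax(bin_start, tabs$first[j]) + 1)) / (bin_end -
                                                                bin_start + 1)
    lambda <- config$coverage_depth * (1 - 0.5 * frac)
    out[[j]] <- with_seed(derive_seed(config$seed, 100L + sex_off + j), {
      coverage_track(chrom = tabs$chrom[1], bin_size = bin,
                     counts = rpois(n_bins, lambda))
    })
  }
  out[["w1118"]] <- with_seed(derive_seed(config$seed, 100L + sex_off), {
    coverage_track(chrom = tabs$chrom[1], bin_size = bin,
                   counts = rpois(n_bins, config$coverage_depth))
  })
  out
}

# --- expression -----------------------------------------------------------

#' Simulate the expression matrix with planted ground truth
#'
#' Builds the full synthetic study: gene baselines, a planted
#' compensation class and true log2 dose response for every one-dose gene
#' (per sex), a planted scale-free co-expression network carried by a
#' per-sample latent AR cascade, sympathetic expression shifts for the
#' first-degree neighbors of one-dose genes in the corresponding line,
#' sex-biased expression offsets, i.i.d. Gaussian noise, negative control
#' probes and spike-ins at the three planted mix ratios.
#'
#' @param config a [synthetic_config()].
#' @param deficiencies a [generate_deficiencies()] result; defaults to
#'   generating one from `config`.
#' @param annotation gene table; defaults to [generate_annotation()].
#' @return A list with `expr` (an [expr_matrix()]) and `truth` (a
#'   `planted_truth` list: `classes` per gene x sex with true log2
#'   responses, `network` edge list, `bias` labels, `neighbor_shifts`,
#'   `deficiencies`, `annotation`, `config`).
#' @export
simulate_expression <- function(config,
                                deficiencies = NULL,
                                annotation = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(annotation)) annotation <- generate_annotation(config)
  if (is.null(deficiencies)) {
    deficiencies <- generate_deficiencies(config, annotation)
  }
  n <- config$n_genes
  genes <- annotation$gene
  sexes <- c("female", "male")
  lines <- c(deficiencies$table$name, "w1118")
  samples <- make_sample_table(lines, sexes, config$n_replicates)
  ns <- nrow(samples)

  truth_seed <- derive_seed(config$seed, 3L)
  truth <- with_seed(truth_seed, {
    edges <- sample_powerlaw_tree(n, config$network_degree_exponent,
                                  config$max_degree)
    bias <- sample(names(config$sex_bias_props), n, TRUE,
                   prob = config$sex_bias_props)
    od_union <- sort(unique(unlist(deficiencies$genes)))
    base_class <- sample(COMP_CLASSES, length(od_union), TRUE,
                         prob = config$class_mixture)
    names(base_class) <- od_union
    classes <- do.call(rbind, lapply(sexes, function(sx) {
      cls <- base_class
      biased <- bias[match(od_union, genes)] != "none"
      if (sx == "male") {
        redraw <- biased & runif(length(od_union)) < config$bias_class_decouple
        if (any(redraw)) {
          cls[redraw] <- sample(COMP_CLASSES, sum(redraw), TRUE,
                                prob = config$class_mixture)
        }
      }
      data.frame(gene = od_union, sex = sx, class = unname(cls),
                 true_lfc = unname(config$class_effects[cls]),
                 stringsAsFactors = FALSE)
    }))
    list(edges = edges, bias = bias, classes = classes)
  })
  edges <- truth$edges

  # per-line one-dose index sets and neighbor maps
  gidx <- setNames(seq_len(n), genes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  tp <- tree_parents(edges, n)

  values <- matrix(0, nrow = n, ncol = ns,
                   dimnames = list(genes, samples$sample))
  with_seed(derive_seed(config$seed, 4L), {
    baseline <- runif(n, config$baseline_range[1], config$baseline_range[2])
    # latent AR cascade over the tree, per sample
    phi <- config$edge_cor
    eps <- matrix(rnorm(n * ns), n, ns)
    z <- matrix(0, n, ns)
    for (v in tp$order) {
      p <- tp$parent[v]
      z[v, ] <- if (p == 0L) eps[v, ] else {
        phi * z[p, ] + sqrt(1 - phi^2) * eps[v, ]
      }
    }
    # remove the sample-wide latent mode: the strongly coupled tree carries
    # a global factor that per-array normalization would eliminate in real
    # data, so the generator emulates post-normalization values
    z <- sweep(z, 2L, colMeans(z))
    values[] <- baseline + config$latent_sd * z +
      matrix(rnorm(n * ns, 0, config$noise_sd), n, ns)
    # sex-biased offsets
    fb <- truth$bias == "female"
    mb <- truth$bias == "male"
    fem <- samples$sex == "female"
    values[fb, fem] <- values[fb, fem] + config$sex_bias_offset
    values[mb, !fem] <- values[mb, !fem] + config$sex_bias_offset
    # dose responses and neighbor propagation, line by line
    for (ln in deficiencies$table$name) {
      od <- gidx[deficiencies$genes[[ln]]]
      for (sx in sexes) {
        cols <- which(samples$line == ln & samples$sex == sx)
        cl <- truth$classes
        cl <- cl[cl$sex == sx, ]
        cls <- setNames(cl$class, cl$gene)
        lfc <- setNames(cl$true_lfc, cl$gene)
        values[od, cols] <- values[od, cols] + lfc[genes[od]]
        for (g in od) {
          nb <- setdiff(adj[[g]], od)
          if (length(nb)) {
            shift <- config$neighbor_shifts[[cls[[genes[g]]]]]
            values[nb, cols] <- values[nb, cols] + shift
          }
        }
      }
    }
    # control probes
    ctrl <- matrix(rnorm(config$n_control * ns, config$control_baseline,
                         config$noise_sd),
                   config$n_control, ns,
                   dimnames = list(sprintf("ctrl%03d",
                                           seq_len(config$n_control)),
                                   samples$sample))
    # spike-ins: mix 1 in parental samples, mix 2 in Df/+ samples
    nsub <- length(config$spike_ratios)
    nspk <- nsub * config$n_spikes_per_subset
    spike_base <- runif(nspk, config$spike_range[1], config$spike_range[2])
    subset <- rep(seq_len(nsub), each = config$n_spikes_per_subset)
    expected_lfc <- log2(1 / config$spike_ratios)[subset]
    is_df <- samples$line != "w1118"
    spk <- matrix(rnorm(nspk * ns, 0, config$noise_sd), nspk, ns) +
      spike_base
    spk[, is_df] <- spk[, is_df] + expected_lfc
    dimnames(spk) <- list(sprintf("spike%03d", seq_len(nspk)),
                          samples$sample)
    probes <- data.frame(
      id = c(genes, rownames(ctrl), rownames(spk)),
      class = rep(c("gene", "control", "spike"),
                  c(n, config$n_control, nspk)),
      spike_subset = c(rep(NA_integer_, n + config$n_control), subset),
      spike_expected_lfc = c(rep(NA_real_, n + config$n_control),
                             expected_lfc),
      stringsAsFactors = FALSE
    )
    expr <- expr_matrix(rbind(values, ctrl, spk), samples, probes)
    truth_out <- structure(list(
      classes = truth$classes,
      network = data.frame(from = genes[edges$from], to = genes[edges$to],
                           stringsAsFactors = FALSE),
      bias = setNames(truth$bias, genes),
      neighbor_shifts = config$neighbor_shifts,
      deficiencies = deficiencies,
      annotation = annotation,
      config = config
    ), class = "planted_truth")
    list(expr = expr, truth = truth_out)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", nrow(x$classes) / 2, "one-dose genes/sex,",
      nrow(x$network), "network edges\n")
  print(table(x$classes$sex, x$classes$class))
  invisible(x)
}
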