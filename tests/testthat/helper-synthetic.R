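# Small shared fixtures, built fresh per test run.

tiny_config <- function(seed = 1L, ...) {
  synthetic_config(n_genes = 60L, n_lines = 4L, genes_per_df = 4L,
                   chrom_length = 6e5, seed = seed, ...)
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_expression(tiny_config(seed = 101L))
    }
    cache
  }
})

# Toy expression matrix with hand-set values: g genes x (lines x reps),
# one sex, plus simple control probes.
toy_expr <- function(values, lines, reps = ncol(values) / length(lines),
                     sex = "female", controls = NULL) {
  samples <- make_toy_samples(lines, reps, sex)
  rows <- rownames(values)
  if (!is.null(controls)) {
    values <- rbind(values, controls)
    rows <- c(rows, rownames(controls))
  }
  colnames(values) <- samples$sample
  probes <- data.frame(
    id = rows,
    class = c(rep("gene", nrow(values) - NROW(controls)),
              rep("control", NROW(controls))),
    spike_subset = NA_integer_, spike_expected_lfc = NA_real_
  )
  expr_matrix(values, samples, probes)
}

make_toy_samples <- function(lines, reps, sex = "female") {
  g <- expand.grid(replicate = seq_len(reps), line = lines,
                   stringsAsFactors = FALSE)
  data.frame(
    sample = sprintf("%s_%s_%d", g$line, sex, g$replicate),
    line = g$line, sex = sex, replicate = g$replicate,
    stringsAsFactors = FALSE
  )
}

zscore <- function(v) (v - mean(v)) / sd(v)
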