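#' Binned sequencing-coverage track
#'
#' Read counts per fixed-width bin along one chromosome, plus the total
#' mapped read count used for reads-per-million (RPM) normalisation.
#'
#' @param chrom chromosome id.
#' @param bin_size bin width in bp.
#' @param counts integer vector of reads per bin; bins tile the chromosome
#'   from position 1.
#' @param total_reads total mapped reads of the library; defaults to
#'   `sum(counts)` (single-chromosome library).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, bin_size, counts, total_reads = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  total_reads <- total_reads %||% sum(counts)
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 counts = counts, total_reads = total_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$chrom, "-", length(x$counts), "bins of",
      x$bin_size, "bp;", format(x$total_reads, big.mark = ","),
      "total reads\n")
  invisible(x)
}

#' Reads per million over a region
#'
#' Sums bin counts over a 1-based inclusive region, pro-rating bins that
#' only partially overlap the region by their overlap fraction, and scales
#' to reads per million mapped.
#'
#' @param track a [coverage_track()].
#' @param first,last region bounds, 1-based inclusive.
#' @return RPM (numeric scalar).
#' @export
#' @examples
#' tr <- coverage_track("2L", 100, rep(10, 100), total_reads = 1e6)
#' region_rpm(tr, 1, 1000)  # 100 reads in a million -> 100 RPM
region_rpm <- function(track, first, last) {
  stopifnot(inherits(track, "coverage_track"))
  if (last < first) stop("empty region: last < first", call. = FALSE)
  if (track$total_reads <= 0) {
    stop("track has zero total mapped reads", call. = FALSE)
  }
  n_bins <- length(track$counts)
  chrom_end <- n_bins * track$bin_size
  if (first < 1 || last > chrom_end) {
    stop("region outside chromosome", call. = FALSE)
  }
  bin_start <- (seq_len(n_bins) - 1) * track$bin_size + 1
  bin_end <- bin_start + track$bin_size - 1
  ov <- pmax(0, pmin(bin_end, last) - pmax(bin_start, first) + 1)
  frac <- ov / track$bin_size
  sum(track$counts * frac) * 1e6 / track$total_reads
}

#' Wild-type vs deficiency dose estimate for one region
#'
#' Computes RPM in a region for a deficiency and a wild-type track and their
#' fold difference `rpm_wt / rpm_df`. A fold near 2 confirms that the
#' deletion halved DNA dose. When the deficiency RPM is zero the region is
#' flagged fully absent and the fold is undefined (`NA`).
#'
#' @param wt,df [coverage_track()] objects for the wild-type (parental) and
#'   deficiency libraries.
#' @param first,last region bounds, 1-based inclusive.
#' @param name optional region label.
#' @param measured_in optional label (e.g. `"Female"`) carried to output.
#' @return data.frame row with `region`, `first`, `last`, `measured_in`,
#'   `rpm_df`, `rpm_wt`, `fold_difference`, `fully_absent`.
#' @export
fold_difference <- function(wt, df, first, last, name = NA_character_,
                            measured_in = NA_character_) {
  rpm_wt <- region_rpm(wt, first, last)
  rpm_df <- region_rpm(df, first, last)
  data.frame(
    region = name, first = first, last = last, measured_in = measured_in,
    rpm_df = rpm_df, rpm_wt = rpm_wt,
    fold_difference = if (rpm_df > 0) rpm_wt / rpm_df else NA_real_,
    fully_absent = rpm_df == 0,
    stringsAsFactors = FALSE
  )
}

#' Summarise a table of dose fold differences
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' fold-difference column, the summary printed under deficiency dose
#' tables.
#'
#' @param folds numeric vector of fold differences (or a data.frame with a
#'   `fold_difference` column).
#' @return List with `n`, `mean`, `sd`.
#' @export
summarize_dose_table <- function(folds) {
  if (is.data.frame(folds)) folds <- folds$fold_difference
  folds <- folds[!is.na(folds)]
  if (length(folds) < 2) {
    stop("need at least 2 fold differences to summarise", call. = FALSE)
  }
  list(n = length(folds), mean = mean(folds), sd = sd(folds))
}

#' Scan paired coverage tracks for unannotated deletions
#'
#' Tiles the chromosome into windows of `window` bins, computes the
#' deficiency/wild-type RPM ratio per window and reports maximal runs of
#' consecutive windows at or below `ratio_threshold` as candidate
#' heterozygous deletions (a true Df/+ deletion gives a ratio near 0.5).
#' Known engineered intervals can be masked. Resolution is window-limited:
#' deletions much shorter than a window dilute below the threshold and can
#' be missed.
#'
#' @param df_track,wt_track [coverage_track()] objects with identical
#'   binning.
#' @param window windows size in bins (>= 1).
#' @param ratio_threshold call threshold for the df/wt RPM ratio; the
#'   default 0.66 is the log-space midpoint between dose 1 (ratio 0.5) and
#'   dose 2 (ratio 1).
#' @param mask optional data.frame with `first`, `last` (1-based inclusive)
#'   of known intervals to exclude from calls.
#' @return data.frame of candidate intervals with `first`, `last` (1-based
#'   inclusive bp), `n_windows`, `mean_ratio`.
#' @export
scan_novel_deletions <- function(df_track, wt_track, window = 5L,
                                 ratio_threshold = 0.66, mask = NULL) {
  stopifnot(inherits(df_track, "coverage_track"),
            inherits(wt_track, "coverage_track"))
  if (df_track$bin_size != wt_track$bin_size ||
      length(df_track$counts) != length(wt_track$counts)) {
    stop("tracks must share binning", call. = FALSE)
  }
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  n_bins <- length(df_track$counts)
  n_win <- floor(n_bins / window)
  if (n_win == 0) stop("window larger than track", call. = FALSE)
  idx <- rep(seq_len(n_win), each = window)
  used <- seq_len(n_win * window)
  df_sum <- as.vector(tapply(df_track$counts[used], idx, sum))
  wt_sum <- as.vector(tapply(wt_track$counts[used], idx, sum))
  df_rpm <- df_sum * 1e6 / df_track$total_reads
  wt_rpm <- wt_sum * 1e6 / wt_track$total_reads
  ratio <- ifelse(wt_rpm > 0, df_rpm / wt_rpm, 1)
  hit <- ratio <= ratio_threshold
  if (!any(hit)) {
    return(data.frame(first = integer(0), last = integer(0),
                      n_windows = integer(0), mean_ratio = numeric(0)))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  bs <- df_track$bin_size
  out <- data.frame(
    first = (starts[keep] - 1L) * window * bs + 1L,
    last = pmin(ends[keep] * window * bs, n_bins * bs),
    n_windows = r$lengths[keep],
    mean_ratio = vapply(keep, function(k) {
      mean(ratio[starts[k]:ends[k]])
    }, numeric(1))
  )
  if (!is.null(mask) && nrow(out)) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(out$first, out$last),
      IRanges::IRanges(mask$first, mask$last)
    )
    drop <- unique(S4Vectors::queryHits(ov))
    if (length(drop)) out <- out[-drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Deficiency dose table from coverage tracks
#'
#' Builds the standard dose-confirmation table (one row per deficiency per
#' sex) from simulated or imported tracks, with folds reported to two
#' decimals in the `fold_2dec` column.
#'
#' @param tracks_by_sex named list (`female`, `male`) of track lists as
#'   returned by [simulate_coverage()] (each containing one track per line
#'   plus `w1118`).
#' @param deficiencies a [generate_deficiencies()] result or a data.frame
#'   with `name`, `first`, `last`.
#' @return data.frame in dose-table layout.
#' @export
dose_table <- function(tracks_by_sex, deficiencies) {
  tab <- if (inherits(deficiencies, "deficiency_set")) {
    deficiencies$table
  } else {
    deficiencies
  }
  rows <- list()
  for (sx in names(tracks_by_sex)) {
    tracks <- tracks_by_sex[[sx]]
    for (j in seq_len(nrow(tab))) {
      rows[[length(rows) + 1L]] <- fold_difference(
        wt = tracks[["w1118"]], df = tracks[[tab$name[j]]],
        first = tab$first[j], last = tab$last[j],
        name = tab$name[j],
        measured_in = paste0(toupper(substring(sx, 1, 1)), substring(sx, 2))
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fold_2dec <- round(out$fold_difference, 2)
  out
}
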