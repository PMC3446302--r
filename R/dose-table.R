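#' Published DNA-seq dose table for the 21-line deficiency panel
#'
#' The published per-sex RPM measurements for the deficiency panel's
#' deleted segments (one row per deficiency per sex, with the reported
#' fold difference). RPM values are as printed (rounded to 1-2 decimals),
#' so a fold recomputed from them can differ from the printed fold by one
#' unit in the last printed digit.
#'
#' @return data.frame with `deficiency`, `first`, `last`, `measured_in`,
#'   `rpm_df`, `rpm_wt`, `fold_printed`.
#' @export
published_dose_table <- function() {
  path <- system.file("extdata", "dnaseq_dose_table.tsv",
                      package = "dosenet", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Recompute fold differences from published RPM pairs
#'
#' @param tab a table in the layout of [published_dose_table()].
#' @return The table with `fold_computed` (`rpm_wt/rpm_df` rounded to two
#'   decimals) and `fold_delta` (computed minus printed) columns added.
#' @export
recompute_dose_folds <- function(tab = published_dose_table()) {
  tab$fold_computed <- round(tab$rpm_wt / tab$rpm_df, 2)
  tab$fold_delta <- tab$fold_computed - tab$fold_printed
  tab
}
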