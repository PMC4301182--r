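# Flow-cytometry genome size estimation: sample 2C from the ratio of the
# sample to the reference fluorescence peak means, scaled by the
# reference standard's 2C value, plus a pooled repeatability summary of
# replicate runs.

#' Estimate genome size from a flow-cytometry run
#'
#' The holoploid (2C) genome size of the sample is
#' `reference_2C x sample_peak_mean / reference_peak_mean`,
#' the standard internal-standard ratio formula. The monoploid-by-division
#' 1C value (2C / 2) is returned alongside.
#'
#' @param sample_peak_mean,reference_peak_mean Fluorescence peak means
#'   (arbitrary units, > 0) of the sample and of the co-chopped reference
#'   standard.
#' @param reference_2C 2C DNA amount of the reference standard in pg
#'   (e.g. 9.49 for the pea standard *Pisum sativum* 'Torstag').
#' @return A list with `genome_size_2C` and `genome_size_1C` (pg).
#'   Vectorized over runs.
#' @examples
#' genome_size_from_run(200, 200, 9.49)   # ratio 1 -> 9.49 pg
#' genome_size_from_run(100, 200, 1.77)   # ratio 1/2 of the Acacia standard
#' @export
genome_size_from_run <- function(sample_peak_mean, reference_peak_mean,
                                 reference_2C) {
  if (any(reference_peak_mean <= 0))
    stop("reference peak mean must be > 0")
  if (any(sample_peak_mean <= 0)) stop("sample peak mean must be > 0")
  if (any(reference_2C <= 0)) stop("reference 2C value must be > 0")
  c2 <- reference_2C * sample_peak_mean / reference_peak_mean
  list(genome_size_2C = c2, genome_size_1C = c2 / 2)
}

#' Pooled SD of log10 genome size across replicate runs
#'
#' Repeatability of replicate cytometry runs within samples:
#' `pooled SD = sqrt( sum_s sum_r (log10 x_sr - mean_s)^2 / sum_s (n_s - 1) )`,
#' i.e. a classical pooled variance weighting each sample by its
#' degrees of freedom. The percent-scale equivalent reported alongside is
#' `(10^SD - 1) x 100` (approximately `ln(10) x SD` for small SD).
#'
#' @param values Positive 2C values (pg), one per run.
#' @param sample_id Sample identifier per run.
#' @return List with `pooled_sd` (on log10 scale), `percent` (linear-scale
#'   equivalent), `df` (pooled degrees of freedom) and `n_samples`.
#' @examples
#' pooled_log_sd(c(5.0, 5.1, 2.0, 2.02), c("a", "a", "b", "b"))
#' @export
pooled_log_sd <- function(values, sample_id) {
  stopifnot(length(values) == length(sample_id))
  if (any(values <= 0)) stop("2C values must be > 0")
  lx <- log10(values)
  idx <- split(seq_along(lx), sample_id)
  n_s <- lengths(idx)
  if (!any(n_s >= 2))
    stop("no sample has >= 2 replicate runs; pooled SD undefined")
  ss <- vapply(idx, function(i) sum((lx[i] - mean(lx[i]))^2), numeric(1))
  df <- sum(n_s - 1)
  sd_pooled <- sqrt(sum(ss) / df)
  list(pooled_sd = sd_pooled, percent = (10^sd_pooled - 1) * 100,
       df = df, n_samples = length(idx))
}

#' Read a cytometry peak table from CSV
#'
#' Expected columns: `sample_id`, `run_id`, `sample_peak`, `ref_peak`,
#' `ref_2C`.
#'
#' @param file Path to a CSV file.
#' @return Data frame with the computed `genome_size_2C` and
#'   `genome_size_1C` columns appended.
#' @export
read_cytometry_runs <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  needed <- c("sample_id", "run_id", "sample_peak", "ref_peak", "ref_2C")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("cytometry table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  est <- genome_size_from_run(tab$sample_peak, tab$ref_peak, tab$ref_2C)
  tab$genome_size_2C <- est$genome_size_2C
  tab$genome_size_1C <- est$genome_size_1C
  tab
}
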