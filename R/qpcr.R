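#' Fit a qPCR standard curve
#'
#' Absolute quantification fits the quantification cycle (Ct) of a dilution
#' series against log10 of the known template copy number:
#' `ct = intercept + slope * log10(copies)`. Under the exponential
#' amplification model the slope is `-1/log10(1 + E)` for efficiency `E`,
#' so a perfect ten-fold series at 100% efficiency has slope
#' `-1/log10(2) = -3.3219` (printed as -3.32). Replicates enter the
#' regression as individual points, not means.
#'
#' @param points A data frame with columns `known_copies` (> 0) and `ct`
#'   (finite cycles); an optional `replicate` column is ignored by the fit.
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept` (Ct at 1 copy), `r_squared`, `efficiency`, `n_points`,
#'   `n_levels` and `flags` (character vector, empty for a good curve;
#'   `"low_r_squared"` when R-squared < 0.99, `"slope_out_of_range"` when
#'   the slope falls outside [-3.6, -3.1]).
#' @examples
#' pts <- simulate_dilution_series(series_spec(seed = 1))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("known_copies", "ct") %in% names(points)))
    stop("'points' must be a data frame with columns known_copies and ct")
  if (any(points$known_copies <= 0))
    stop("known_copies must be positive")
  if (any(!is.finite(points$ct)))
    stop("all ct values must be finite")
  lvl <- unique(points$known_copies)
  if (length(lvl) < 3L)
    stop("need at least 3 distinct copy levels, got ", length(lvl))
  x <- log10(points$known_copies)
  fit <- stats::lm(ct ~ x, data = data.frame(ct = points$ct, x = x))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # direct R^2 (summary.lm warns on exact fits)
  sst <- sum((points$ct - mean(points$ct))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  flags <- character(0)
  if (r2 < 0.99) flags <- c(flags, "low_r_squared")
  if (slope < -3.6 || slope > -3.1) flags <- c(flags, "slope_out_of_range")
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = if (slope < 0) efficiency(slope) else NA_real_,
                 n_points = nrow(points), n_levels = length(lvl),
                 flags = flags),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, intercept %.2f, R^2 %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  cat(sprintf("  %d points over %d copy levels%s\n", x$n_points, x$n_levels,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope) - 1`; a slope of -3.3219 corresponds to 100%
#' efficiency (the template doubles every cycle).
#'
#' @param slope Standard-curve slope in cycles per log10 copies (< 0).
#' @return Efficiency as a fraction (1.0 = 100%).
#' @export
efficiency <- function(slope) {
  if (!is.numeric(slope) || any(slope >= 0))
    stop("slope must be negative")
  10^(-1 / slope) - 1
}

#' Quantify template copies from a Ct value
#'
#' Extrapolates `copies = 10^((ct - intercept) / slope)` from a fitted
#' standard curve; strictly decreasing in Ct for a negative slope.
#'
#' @param ct Quantification cycle(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Estimated copies per reaction (vectorized over `ct`).
#' @export
quantify <- function(ct, curve) {
  if (!inherits(curve, "standard_curve"))
    stop("'curve' must be a fitted standard_curve")
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalize copies per reaction to copies per genome equivalent
#'
#' One haploid human genome weighs about 3.3 pg, so copies measured in a
#' reaction loaded with `input_mass` pg of genomic DNA are rescaled by
#' `genome_mass / input_mass` to give copies per genome equivalent (the
#' unit in which satellite copy numbers are reported).
#'
#' @param copies Copies per reaction.
#' @param input_mass Template mass per reaction, pg (> 0).
#' @param genome_mass Genome-equivalent mass, pg (default 3.3).
#' @return Copies per genome equivalent.
#' @examples
#' copies_per_genome(1000, 33)  # 100 per 3.3 pg
#' @export
copies_per_genome <- function(copies, input_mass, genome_mass = 3.3) {
  if (any(input_mass <= 0)) stop("input mass must be positive")
  copies * genome_mass / input_mass
}

#' Read a dilution-series TSV
#'
#' Columns: `known_copies`, `ct`, optional `replicate`.
#'
#' @param path TSV file with header row.
#' @return A data frame of dilution points.
#' @export
read_dilution_series <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("known_copies", "ct") %in% names(tab)))
    stop("dilution series needs columns known_copies and ct")
  tab
}

#' Read an unknowns TSV for quantification
#'
#' Columns: `sample`, `ct`, `input_mass_pg`.
#'
#' @param path TSV file with header row.
#' @return A data frame of unknown reactions.
#' @export
read_unknowns <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("sample", "ct", "input_mass_pg") %in% names(tab)))
    stop("unknowns table needs columns sample, ct and input_mass_pg")
  tab
}
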