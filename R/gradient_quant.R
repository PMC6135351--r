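#' Construct a gradient absorbance trace
#' @param positions monotone increasing numeric vector.
#' @param absorbance A254 readings, same length (>= 10 points).
#' @return \code{data.table} of class \code{gradient_trace}.
#' @export
gradient_trace <- function(positions, absorbance) {
  stopifnot(length(positions) == length(absorbance), length(positions) >= 10L,
            !is.unsorted(positions, strictly = TRUE))
  tr <- data.table(position = as.numeric(positions),
                   absorbance = as.numeric(absorbance))
  setattr(tr, "class", c("gradient_trace", class(tr)))
  tr[]
}

# left-endpoint Riemann sum of (absorbance - baseline) over [lo, hi)
riemann_area <- function(trace, lo, hi, baseline) {
  x <- trace$position; y <- trace$absorbance
  if (lo < x[1] || hi > x[length(x)]) stop("boundaries outside trace range")
  dx <- diff(x)
  use <- which(x[-length(x)] >= lo & x[-length(x)] < hi)
  sum((y[use] - baseline) * dx[use])
}

#' Polysome-to-monosome ratio of a gradient trace
#'
#' Baseline is the global minimum of the trace excluding the caller-selected
#' free-RNP region; the monosome area is the left-Riemann sum between the
#' 80S start and end boundaries, the polysome area between the 80S end and
#' the final point. Returns polysome/monosome.
#'
#' @param trace a \code{gradient_trace}.
#' @param boundaries list with \code{s80_start}, \code{s80_end}, and
#'   \code{free_rnp_end} (positions at or before it are excluded from the
#'   baseline search; use the trace start to exclude nothing).
#' @return polysome area / monosome area.
#' @export
polysome_monosome_ratio <- function(trace, boundaries) {
  b <- boundaries
  stopifnot(!is.null(b$s80_start), !is.null(b$s80_end))
  if (b$s80_start >= b$s80_end) stop("boundaries out of order")
  keep <- trace$position > (b$free_rnp_end %||% trace$position[1] - 1)
  baseline <- min(trace$absorbance[keep])
  mono <- riemann_area(trace, b$s80_start, b$s80_end, baseline)
  poly <- riemann_area(trace, b$s80_end, trace$position[nrow(trace)], baseline)
  if (mono <= 0) stop("degenerate trace: non-positive monosome area")
  poly / mono
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monosome-to-subunit ratio of a gradient trace
#'
#' Baseline is the global minimum of the trace; the monosome area is the
#' left-Riemann sum between the 60S end and 80S end boundaries, the subunit
#' area between the 40S start and the 60S end.
#'
#' @param trace a \code{gradient_trace}.
#' @param boundaries list with \code{s40_start}, \code{s60_end},
#'   \code{s80_end}.
#' @return monosome area / subunit area.
#' @export
monosome_subunit_ratio <- function(trace, boundaries) {
  b <- boundaries
  stopifnot(!is.null(b$s40_start), !is.null(b$s60_end), !is.null(b$s80_end))
  if (b$s40_start >= b$s60_end || b$s60_end >= b$s80_end)
    stop("boundaries out of order")
  baseline <- min(trace$absorbance)
  subunit <- riemann_area(trace, b$s40_start, b$s60_end, baseline)
  mono <- riemann_area(trace, b$s60_end, b$s80_end, baseline)
  if (subunit <= 0) stop("degenerate trace: non-positive subunit area")
  mono / subunit
}

#' Epitope intensity from a dilution series
#'
#' Over all windows of 3 or 4 consecutive points, fits OLS of band
#' intensity versus dilution factor and returns the slope of the window
#' with the highest r-squared (ties broken toward the larger window, then
#' the earlier window).
#'
#' @param series \code{data.frame(dilution, intensity)} ordered by loading,
#'   at least 3 points.
#' @return slope (the epitope intensity) with attributes \code{r2} and
#'   \code{window} (point indices used).
#' @export
dilution_slope <- function(series) {
  s <- as.data.table(series)
  n <- nrow(s)
  if (n < 3L) stop("insufficient data: need at least 3 points")
  best <- NULL
  for (w in c(4L, 3L)) {
    if (n < w) next
    for (i0 in seq_len(n - w + 1L)) {
      idx <- i0:(i0 + w - 1L)
      fit <- lm(intensity ~ dilution, data = s[idx])
      r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits expected
      if (is.null(best) || r2 > best$r2 + 1e-12)
        best <- list(slope = unname(coef(fit)[2]), r2 = r2, window = idx)
    }
  }
  structure(best$slope, r2 = best$r2, window = best$window)
}

#' Ratio of dilution-series slopes (relative protein abundance)
#' @param numerator,denominator \code{data.frame(dilution, intensity)}
#'   series for the two epitopes.
#' @return slope(numerator) / slope(denominator).
#' @export
abundance_ratio <- function(numerator, denominator) {
  den <- dilution_slope(denominator)
  if (abs(as.numeric(den)) < .Machine$double.eps)
    stop("degenerate denominator: zero slope")
  as.numeric(dilution_slope(numerator)) / as.numeric(den)
}

#' Protein ratios as per-replicate medians over distinct peptide ratios
#'
#' @param peptide_ratios \code{data.frame(protein, replicate, ratio)} of
#'   distinct-peptide ratios (> 0).
#' @param flip_replicates optional integer vector of replicate indices whose
#'   labels were swapped; their ratios are inverted before aggregation.
#' @return \code{data.table(protein, replicate, ratio)} of median ratios;
#'   proteins with no ratios in a replicate are absent.
#' @export
protein_ratio <- function(peptide_ratios, flip_replicates = integer()) {
  pr <- as.data.table(peptide_ratios)
  stopifnot(all(pr$ratio > 0))
  pr[replicate %in% flip_replicates, ratio := 1 / ratio]
  pr[, .(ratio = median(ratio)), by = .(protein, replicate)][order(protein, replicate)]
}
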