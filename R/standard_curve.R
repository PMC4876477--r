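#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 dilution. Replicate Ct values at the
#' same dilution level enter the regression as separate observations (this
#' preserves degrees of freedom for R^2, and mirrors how duplicate serial
#' dilutions are normally fed to the fit). The slope is converted to a
#' per-cycle amplification factor \eqn{A = 10^{-1/slope}} and percent
#' efficiency \eqn{E = (A - 1) \times 100}; a perfectly doubling assay has
#' slope -3.32193, amplification 2 and efficiency 100\%.
#'
#' @param points Data frame whose first two columns (or columns named
#'   `log10_dilution` and `ct`) give log10 dilution and Ct. Output of
#'   [simulate_dilution_series()] works directly.
#' @return A `standard_curve` object with elements `slope`, `intercept`,
#'   `r_squared`, `efficiency_pct`, `amplification`, `n`, and
#'   `positive_slope` (flag; efficiency is undefined and reported `NA` when
#'   the fitted slope is >= 0, which indicates a failed assay).
#' @examples
#' pts <- simulate_dilution_series(100, 20, c(0, -1, -2, -3), replicate_sd = 0)
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  pts <- tibble::as_tibble(points)
  if (!all(c("log10_dilution", "ct") %in% names(pts))) {
    if (ncol(pts) < 2) abort("Need columns log10_dilution and ct.")
    keep <- setdiff(names(pts), "replicate")
    pts <- pts[keep[1:2]]
    names(pts) <- c("log10_dilution", "ct")
  }
  pts <- pts[stats::complete.cases(pts[c("log10_dilution", "ct")]), ]
  if (length(unique(pts$log10_dilution)) < 3) {
    abort("A standard curve needs >= 3 distinct dilution levels.")
  }
  if (stats::var(pts$log10_dilution) == 0) {
    abort("Zero variance in dilution levels; cannot fit a slope.")
  }
  fit <- stats::lm(ct ~ log10_dilution, data = pts)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_tot <- sum((pts$ct - mean(pts$ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  if (slope >= 0) {
    warn("Fitted slope is >= 0; amplification efficiency is undefined.")
    amp <- NA_real_
    eff <- NA_real_
  } else {
    conv <- efficiency_from_slope(slope)
    amp <- conv$amplification
    eff <- conv$efficiency_pct
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency_pct = eff, amplification = amp,
         n = nrow(pts), positive_slope = slope >= 0, data = pts),
    class = "standard_curve"
  )
}

#' Convert a standard-curve slope to amplification and efficiency
#'
#' @param slope Slope of Ct on log10 dilution (must be < 0); vectorized.
#' @return A tibble with columns `slope`, `amplification`
#'   (\eqn{10^{-1/slope}}) and `efficiency_pct`
#'   (\eqn{(10^{-1/slope} - 1) \times 100}).
#' @examples
#' efficiency_from_slope(-3.32193) # amplification 2, efficiency 100%
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    abort("Slope must be finite and < 0.")
  }
  amp <- 10^(-1 / slope)
  tibble::tibble(slope = slope, amplification = amp,
                 efficiency_pct = (amp - 1) * 100)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve (n = %d): slope %.4f, intercept %.3f, R^2 %.4f, efficiency %.1f%%, amplification %.3f\n",
    x$n, x$slope, x$intercept, x$r_squared, x$efficiency_pct, x$amplification))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency_pct = x$efficiency_pct,
                 amplification = x$amplification)
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  dplyr::mutate(tidy.standard_curve(x), n = x$n,
                positive_slope = x$positive_slope)
}

#' Fit standard curves for several genes at once
#'
#' @param points Data frame with columns `gene`, `log10_dilution`, `ct`.
#' @return A tibble with one row per gene and the columns of
#'   [tidy.standard_curve()] — the usual "Slope / R^2 / Efficiency /
#'   Amplification" reporting table.
#' @export
standard_curve_table <- function(points) {
  pts <- tibble::as_tibble(points)
  stopifnot(all(c("gene", "log10_dilution", "ct") %in% names(pts)))
  dplyr::bind_rows(lapply(split(pts, pts$gene), function(d) {
    dplyr::bind_cols(tibble::tibble(gene = d$gene[1]),
                     tidy.standard_curve(fit_standard_curve(d)))
  }))
}
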