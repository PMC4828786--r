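#' Inflation curve container
#'
#' Paired (time, volume, pressure, central diameter) samples from a bench
#' experiment, a simulation, or a synthetic generator.  Volume must be
#' strictly increasing and pressure non-negative.
#'
#' @param time_s sample times (s).
#' @param volume_ml cavity volumes (ml), strictly increasing.
#' @param pressure_mmHg cavity pressures (mmHg), `>= 0`.
#' @param diameter_mm central-section diameters (mm).
#' @param provenance `"experimental"`, `"computational"` or `"synthetic"`.
#' @param contact_flag,slack_flag optional logical per-sample flags.
#' @return an `inflation_curve` data frame.
#' @examples
#' inflation_curve(0:2 * 15, c(21, 21.2, 21.4), c(0, 120, 300), c(23, 23.1, 23.3))
#' @export
inflation_curve <- function(time_s, volume_ml, pressure_mmHg, diameter_mm,
                            provenance = "experimental",
                            contact_flag = NULL, slack_flag = NULL) {
  n <- length(volume_ml)
  if (length(time_s) != n || length(pressure_mmHg) != n || length(diameter_mm) != n)
    bm_stop("all curve columns must have equal length",
            class = "balloonmech_invalid_input")
  if (n >= 2 && any(diff(volume_ml) <= 0))
    bm_stop("volume must be strictly increasing", class = "balloonmech_invalid_input")
  if (any(pressure_mmHg < -1e-9))
    bm_stop("pressure must be non-negative", class = "balloonmech_invalid_input")
  df <- data.frame(time_s = time_s, volume_ml = volume_ml,
                   pressure_mmHg = pmax(pressure_mmHg, 0),
                   diameter_mm = diameter_mm)
  if (!is.null(contact_flag)) df$contact_flag <- contact_flag
  if (!is.null(slack_flag)) df$slack_flag <- slack_flag
  attr(df, "provenance") <- provenance
  class(df) <- c("inflation_curve", "data.frame")
  df
}

#' Read/write inflation-curve CSV
#'
#' Column layout `time_s,volume_ml,pressure_mmHg,diameter_mm[,contact_flag]`.
#'
#' @param path CSV path.
#' @param curve an [inflation_curve()] (for writing).
#' @param provenance provenance tag on reading.
#' @return the curve, or `path` invisibly on writing.
#' @export
read_inflation_csv <- function(path, provenance = "experimental") {
  df <- utils::read.csv(path)
  need <- c("time_s", "volume_ml", "pressure_mmHg", "diameter_mm")
  if (!all(need %in% names(df)))
    bm_stop("CSV must have columns time_s,volume_ml,pressure_mmHg,diameter_mm",
            class = "balloonmech_format_error")
  inflation_curve(df$time_s, df$volume_ml, df$pressure_mmHg, df$diameter_mm,
                  provenance = provenance,
                  contact_flag = if ("contact_flag" %in% names(df)) df$contact_flag)
}

#' @rdname read_inflation_csv
#' @export
write_inflation_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.inflation_curve <- function(x, ...) {
  cat(sprintf("Inflation curve (%s): %d samples, V %.2f-%.2f ml, P %.0f-%.0f mmHg, d %.1f-%.1f mm\n",
              attr(x, "provenance") %||% "?", nrow(x),
              min(x$volume_ml), max(x$volume_ml),
              min(x$pressure_mmHg), max(x$pressure_mmHg),
              min(x$diameter_mm), max(x$diameter_mm)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more rows\n", nrow(x) - 4))
  invisible(x)
}

#' @export
plot.inflation_curve <- function(x, which = c("pv", "dv"), ...) {
  which <- match.arg(which)
  if (which == "pv")
    graphics::plot(x$volume_ml, x$pressure_mmHg, type = "b",
                   xlab = "Volume (ml)", ylab = "Pressure (mmHg)", ...)
  else
    graphics::plot(x$volume_ml, x$diameter_mm, type = "b",
                   xlab = "Volume (ml)", ylab = "Central diameter (mm)", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample two inflation curves onto a common volume grid
#'
#' Linearly interpolates both curves' pressure and diameter onto a uniform
#' volume grid spanning the overlap of their volume ranges, so samples can
#' be compared "at equal volume".
#'
#' @param a,b [inflation_curve()]s with overlapping volume ranges.
#' @param n_grid grid size (default 200).
#' @return data frame `volume_ml, P_a, P_b, d_a, d_b`.
#' @export
resample_at_equal_volume <- function(a, b, n_grid = 200) {
  lo <- max(min(a$volume_ml), min(b$volume_ml))
  hi <- min(max(a$volume_ml), max(b$volume_ml))
  if (hi <= lo)
    bm_stop("curves have no overlapping volume range",
            class = "balloonmech_invalid_input")
  grid <- seq(lo, hi, length.out = n_grid)
  data.frame(volume_ml = grid,
             P_a = stats::approx(a$volume_ml, a$pressure_mmHg, grid)$y,
             P_b = stats::approx(b$volume_ml, b$pressure_mmHg, grid)$y,
             d_a = stats::approx(a$volume_ml, a$diameter_mm, grid)$y,
             d_b = stats::approx(b$volume_ml, b$diameter_mm, grid)$y)
}

#' Root-mean-square error between paired samples
#'
#' \eqn{RMSE = \sqrt{\mathrm{mean}((x - y)^2)}}.
#'
#' @param x,y numeric vectors of equal positive length.
#' @return the RMSE (units of the inputs).
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 3))   # 0
#' rmse(1:3, 1:3 + 5)             # 5
#' @export
rmse <- function(x, y) {
  if (!length(x) || length(x) != length(y))
    bm_stop("need equal-length, non-empty paired samples",
            class = "balloonmech_invalid_input")
  sqrt(mean((x - y)^2))
}

#' RMSE as a percentage of the maximum experimental value
#'
#' @param rmse_value an RMSE (e.g. of pressure, mmHg).
#' @param reference the experimental series the maximum is taken from
#'   (numeric vector or [inflation_curve()], in which case its pressure
#'   column is used).
#' @return `100 * rmse_value / max(reference)`.
#' @examples
#' rmse_percent_of_max(161.98, c(0, 2000, 4242))
#' @export
rmse_percent_of_max <- function(rmse_value, reference) {
  ref <- if (inherits(reference, "inflation_curve")) reference$pressure_mmHg
         else reference
  m <- max(ref)
  if (m <= 0) bm_stop("maximum of the reference series must be positive",
                      class = "balloonmech_invalid_input")
  100 * rmse_value / m
}

#' Compare experimental and computational inflation curves
#'
#' Pairs the two curves at equal volume on a uniform grid over the overlap
#' and reports the pressure and diameter RMSEs, the pressure RMSE as a
#' percentage of the maximum experimental pressure, and whether the
#' diameter RMSE is below the fluoroscopy image resolution (0.5 mm), the
#' acquisition-limited bound on meaningful diameter agreement.
#'
#' @param exp,comp [inflation_curve()]s (experimental/reference first).
#' @param n_grid comparison grid size (default 200).
#' @param d_resolution_mm image resolution threshold for the diameter flag.
#' @return object of class `curve_comparison`: list with `pairs`, `rmse_P`,
#'   `rmse_d`, `rmse_P_pct_of_max`, `d_within_resolution`, `grid`.
#' @examples
#' a <- inflation_curve(0:3, 21 + 0:3 * 0.2, c(0, 100, 250, 450), 23 + 0:3 * 0.1)
#' compare_curves(a, a)$rmse_P   # 0
#' @export
compare_curves <- function(exp, comp, n_grid = 200, d_resolution_mm = 0.5) {
  pr <- resample_at_equal_volume(exp, comp, n_grid)
  rp <- rmse(pr$P_a, pr$P_b)
  rd <- rmse(pr$d_a, pr$d_b)
  structure(list(pairs = pr,
                 rmse_P = rp,
                 rmse_d = rd,
                 rmse_P_pct_of_max = rmse_percent_of_max(rp, exp),
                 d_within_resolution = rd < d_resolution_mm,
                 d_resolution_mm = d_resolution_mm,
                 grid = c(min(pr$volume_ml), max(pr$volume_ml), n_grid)),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("Curve comparison on %d-point volume grid [%.3f, %.3f] ml\n",
              x$grid[3], x$grid[1], x$grid[2]))
  cat(sprintf("  RMSE_P = %.2f mmHg (%.2f %% of max experimental pressure)\n",
              x$rmse_P, x$rmse_P_pct_of_max))
  cat(sprintf("  RMSE_d = %.3f mm (%s image resolution %.1f mm)\n",
              x$rmse_d, if (x$d_within_resolution) "below" else "NOT below",
              x$d_resolution_mm))
  invisible(x)
}
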