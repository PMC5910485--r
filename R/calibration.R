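#' Fluorescence-to-concentration calibration curve
#'
#' A straight line `intensity = slope * concentration + intercept` fitted
#' through per-concentration replicate means, mirroring the lysate-based
#' standard-curve procedure: known dye concentrations are added to a dense
#' cell lysate, each measured in triplicate, and the mean intensity per
#' concentration anchors the line. The intercept absorbs lysate
#' autofluorescence and detector offset.
#'
#' @param dye_name dye label.
#' @param points data.frame with columns `concentration_uM`,
#'   `mean_intensity`, `sd_intensity`, `n` (one row per concentration).
#' @param slope fitted slope (intensity per uM), must be > 0.
#' @param intercept fitted intercept (intensity units).
#' @return object of class `calibration_curve`.
#' @export
calibration_curve <- function(dye_name, points, slope, intercept) {
  if (nrow(points) < 2) stop("calibration needs >= 2 distinct concentrations")
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration-quality error: fitted slope must be positive, got ", slope)
  }
  structure(list(dye_name = dye_name, points = points,
                 slope = slope, intercept = intercept),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve '%s': intensity = %.6g * conc_uM + %.6g (%d points)\n",
              x$dye_name, x$slope, x$intercept, nrow(x$points)))
  invisible(x)
}

#' Fit a calibration line to replicate measurements
#'
#' Ordinary least squares through the per-concentration replicate means,
#' with per-point SD retained for reporting (the error bars of a standard
#' curve). Replicates may be supplied long (repeated concentrations) or as
#' list columns.
#'
#' @param concentration_uM numeric vector, one entry per replicate.
#' @param intensity numeric vector, same length.
#' @param dye_name dye label.
#' @return a [calibration_curve()].
#' @export
fit_calibration <- function(concentration_uM, intensity, dye_name = "") {
  stopifnot(length(concentration_uM) == length(intensity))
  if (length(unique(concentration_uM)) < 2) {
    stop("degenerate design: need >= 2 distinct concentrations")
  }
  means <- tapply(intensity, concentration_uM, mean)
  sds <- tapply(intensity, concentration_uM, stats::sd)
  ns <- tapply(intensity, concentration_uM, length)
  conc <- as.numeric(names(means))
  fit <- stats::lm(y ~ x, data = data.frame(x = conc, y = as.numeric(means)))
  co <- stats::coef(fit)
  pts <- data.frame(concentration_uM = conc,
                    mean_intensity = as.numeric(means),
                    sd_intensity = as.numeric(sds),
                    n = as.integer(ns))
  calibration_curve(dye_name, pts, slope = co[["x"]], intercept = co[["(Intercept)"]])
}

#' Calibrate calcein against the known extracellular concentration
#'
#' Calcein is natively fluorescent, so its top anchor point comes from the
#' bath itself: cell-free regions of the recording at the known loading
#' concentration (200 uM in the standard protocol) are averaged and used as
#' the intensity of that concentration. Lower-concentration cell-free
#' measurements, if given, complete the line; with no extra points the line
#' is anchored through the origin-side point (0, 0).
#'
#' @param cell_free_intensities intensities measured in cell-free regions at
#'   `known_conc`.
#' @param known_conc the loading concentration in uM (default 200).
#' @param extra_points optional data.frame `concentration_uM`, `intensity`
#'   of lower-concentration cell-free measurements (replicates long-form).
#' @param dye_name dye label, default "calcein".
#' @return a [calibration_curve()].
#' @export
anchor_calcein <- function(cell_free_intensities, known_conc = 200,
                           extra_points = NULL, dye_name = "calcein") {
  if (length(cell_free_intensities) == 0) {
    stop("need at least one cell-free intensity measurement")
  }
  if (known_conc <= 0) stop("'known_conc' must be positive")
  conc <- rep(known_conc, length(cell_free_intensities))
  int <- cell_free_intensities
  if (!is.null(extra_points) && nrow(extra_points) > 0) {
    conc <- c(conc, extra_points$concentration_uM)
    int <- c(int, extra_points$intensity)
  } else {
    conc <- c(conc, 0)
    int <- c(int, 0)
  }
  fit_calibration(conc, int, dye_name = dye_name)
}

#' Predict intensity from concentration
#'
#' @param curve a [calibration_curve()].
#' @param concentration_uM concentration(s) in uM.
#' @return intensity on the curve's scale.
#' @export
calibration_forward <- function(curve, concentration_uM) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * concentration_uM + curve$intercept
}

#' Convert intensity to concentration
#'
#' Inverts the fitted line, `(intensity - intercept) / slope`, clamping
#' negative results to 0 uM (background fluctuations below the intercept
#' carry no concentration information).
#'
#' @param curve a [calibration_curve()].
#' @param intensity intensity value(s); vectors, matrices and data.frames
#'   pass through elementwise.
#' @return concentration(s) in uM, >= 0.
#' @export
to_concentration <- function(curve, intensity) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.data.frame(intensity)) {
    intensity[] <- lapply(intensity, function(v) pmax((v - curve$intercept) / curve$slope, 0))
    return(intensity)
  }
  pmax((intensity - curve$intercept) / curve$slope, 0)
}

#' Write a calibration curve to CSV
#'
#' Two sections in one file: a header row of fit coefficients, then the
#' per-point means and SDs. Reads back with [read_calibration()].
#'
#' @param curve a [calibration_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curve, path) {
  df <- data.frame(dye_name = curve$dye_name,
                   slope = curve$slope, intercept = curve$intercept,
                   curve$points)
  utils::write.csv(format_df_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration curve written by [write_calibration()], or fit one
#' from a raw points table
#'
#' A raw table has columns `concentration_uM`, `intensity` (one row per
#' replicate) and is fitted with [fit_calibration()]; a fitted table (as
#' written by [write_calibration()]) is loaded as-is.
#'
#' @param path CSV path.
#' @param dye_name dye label used when fitting a raw table.
#' @return a [calibration_curve()].
#' @export
read_calibration <- function(path, dye_name = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("slope", "intercept", "mean_intensity") %in% names(df))) {
    pts <- df[, c("concentration_uM", "mean_intensity", "sd_intensity", "n")]
    calibration_curve(df$dye_name[1], pts, df$slope[1], df$intercept[1])
  } else if (all(c("concentration_uM", "intensity") %in% names(df))) {
    fit_calibration(df$concentration_uM, df$intensity, dye_name = dye_name)
  } else {
    stop("unrecognized calibration CSV layout: ", path)
  }
}
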