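#' Fluoroscopy calibration arch
#'
#' Bead-marker calibration geometry: two known real distances between
#' radiopaque bead pairs and their measured counterparts on each projection
#' image.  Averaging two independent distance ratios damps X-ray beam
#' distortion.
#'
#' @param b_real length-2 numeric: the known projected bead distances (mm).
#' @param b_image_ap,b_image_lat length-2 numeric: the corresponding
#'   measured distances on the AP and LAT images (image units).
#' @return object of class `calibration_arch`.
#' @examples
#' calibration_arch(c(50, 80), c(25, 40), c(25, 40))   # w = 2 on both views
#' @export
calibration_arch <- function(b_real, b_image_ap, b_image_lat = b_image_ap) {
  for (v in list(b_real, b_image_ap, b_image_lat))
    if (length(v) != 2 || any(!is.finite(v)) || any(v <= 0))
      bm_stop("bead distances must be two positive numbers per set",
              class = "balloonmech_invalid_input")
  structure(list(b_real = b_real, b_image_ap = b_image_ap,
                 b_image_lat = b_image_lat),
            class = "calibration_arch")
}

#' Geometric calibration coefficient from bead markers
#'
#' \deqn{w = \frac{b_{1,real}}{2 b_{1,image}} + \frac{b_{2,real}}{2 b_{2,image}},}
#' i.e. the mean of the two single-pair scale ratios (mm per image unit).
#'
#' @param arch a [calibration_arch()].
#' @param projection `"AP"` or `"LAT"`.
#' @return scalar calibration coefficient w.
#' @examples
#' calibration_coefficient(calibration_arch(c(10, 10), c(5, 5)), "AP")  # 2
#' @export
calibration_coefficient <- function(arch, projection = c("AP", "LAT")) {
  projection <- match.arg(projection)
  bi <- if (projection == "AP") arch$b_image_ap else arch$b_image_lat
  if (any(bi == 0)) bm_stop("zero image distance", class = "balloonmech_invalid_input")
  arch$b_real[1] / (2 * bi[1]) + arch$b_real[2] / (2 * bi[2])
}

#' Projection image container
#'
#' A grayscale pixel grid (values in [0, 1]) with isotropic pixel size and
#' optional bead-marker image coordinates.  Rows index the transverse
#' (radial) direction, columns the axial direction.
#'
#' @param pixels numeric matrix of grayscale values.
#' @param pixel_size_mm isotropic pixel size on the image plane
#'   (mm-on-image per pixel; 0.5 by default).
#' @param beads optional matrix (n x 2) of bead marker image coordinates
#'   (axial, transverse) in image mm.
#' @return object of class `projection_image`.
#' @export
projection_image <- function(pixels, pixel_size_mm = 0.5, beads = NULL) {
  if (!is.matrix(pixels)) bm_stop("pixels must be a matrix",
                                  class = "balloonmech_invalid_input")
  check_positive(pixel_size_mm, "pixel_size_mm")
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm, beads = beads),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("Projection image: %d x %d px at %.2g mm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm))
  invisible(x)
}

#' Extract a balloon half-contour from a projection image
#'
#' Thresholds the grayscale image, checks that exactly one connected
#' silhouette is present, and traces its boundary column by column with
#' sub-pixel resolution: within each axial column the upper and lower
#' threshold crossings are located by linear interpolation between the
#' bracketing pixels.  The revolution axis is estimated as the
#' least-squares symmetry axis (mean of the per-column midlines) unless
#' given, and the half-contour radius is the half-width about that axis.
#'
#' The column-wise tracer assumes an axially convex silhouette (at most one
#' super-threshold run per column), which holds for balloon profiles.
#'
#' @param image a [projection_image()].
#' @param threshold grayscale threshold in (0, 1).
#' @param axis optional transverse coordinate (image mm) of the revolution
#'   axis; default: estimated.
#' @return a `contour_polyline` data frame with columns `z`, `r` (image mm,
#'   scale `"raw"`), and attributes `scale`, `axis`.
#' @export
extract_contour <- function(image, threshold = 0.5, axis = NULL) {
  px <- image$pixels
  h <- image$pixel_size_mm
  nr <- nrow(px); nc <- ncol(px)
  bin <- px >= threshold
  col_any <- which(colSums(bin) > 0)
  if (!length(col_any))
    bm_stop("no super-threshold region in image", class = "balloonmech_segmentation_error")
  if (any(diff(col_any) > 1))
    bm_stop("multiple super-threshold regions (axially disconnected)",
            class = "balloonmech_segmentation_error")
  zs <- rs <- mid <- numeric(0)
  for (j in col_any) {
    on <- which(bin[, j])
    if (any(diff(on) > 1))
      bm_stop("multiple super-threshold regions within a column",
              class = "balloonmech_segmentation_error")
    i_top <- on[1]; i_bot <- on[length(on)]
    # sub-pixel crossing above the first ON pixel and below the last
    top <- if (i_top > 1) {
      f <- (threshold - px[i_top - 1, j]) / (px[i_top, j] - px[i_top - 1, j])
      (i_top - 1) + f
    } else i_top
    bot <- if (i_bot < nr) {
      f <- (threshold - px[i_bot + 1, j]) / (px[i_bot, j] - px[i_bot + 1, j])
      (i_bot + 1) - f
    } else i_bot
    zs <- c(zs, j * h)
    mid <- c(mid, (top + bot) / 2 * h)
    rs <- c(rs, (bot - top) / 2 * h)
  }
  ax <- if (is.null(axis)) mean(mid) else axis
  df <- data.frame(z = zs, r = pmax(rs, 0))
  attr(df, "scale") <- "raw"
  attr(df, "axis") <- ax
  class(df) <- c("contour_polyline", "data.frame")
  df
}

#' Contour polyline constructor
#'
#' @param z axial coordinates (mm, or image mm when `scale = "raw"`).
#' @param r radial distances from the axis, `>= 0`.
#' @param scale `"calibrated"` (real mm) or `"raw"` (image units).
#' @return a `contour_polyline` data frame.
#' @export
contour_polyline <- function(z, r, scale = c("calibrated", "raw")) {
  scale <- match.arg(scale)
  if (length(z) != length(r) || length(z) < 3)
    bm_stop("contour needs >= 3 matched (z, r) points", class = "balloonmech_invalid_input")
  if (any(r < 0)) bm_stop("radial values must be >= 0", class = "balloonmech_invalid_input")
  df <- data.frame(z = z, r = r)
  attr(df, "scale") <- scale
  class(df) <- c("contour_polyline", "data.frame")
  df
}

#' Solid-of-revolution volume of a contour
#'
#' Scales the contour by the calibration coefficient `w` and revolves it
#' about the axis using conical-frustum quadrature (second-order accurate
#' in point spacing).  A raw (uncalibrated) contour requires `w`.
#'
#' @param contour a `contour_polyline`.
#' @param w calibration coefficient (mm per image unit); default 1 for
#'   already-calibrated contours.
#' @return volume in ml.
#' @examples
#' cp <- contour_polyline(seq(0, 40, 1), rep(10, 41))
#' revolve_volume(cp)   # 12.566 ml
#' @export
revolve_volume <- function(contour, w = NULL) {
  if (is.null(w)) {
    if (identical(attr(contour, "scale"), "raw"))
      bm_stop("uncalibrated contour: supply the calibration coefficient w",
              class = "balloonmech_invalid_input")
    w <- 1
  }
  z <- contour$z * w; r <- contour$r * w
  mm3_to_ml(revolved_volume_mm3(z, r))
}

#' Initial volume from biplane projections
#'
#' Arithmetic mean of the two revolved volumes of the same frame seen in
#' the AP and LAT projections (each scaled by its own calibration
#' coefficient).
#'
#' @param contour_ap,contour_lat `contour_polyline`s of one frame.
#' @param w_ap,w_lat per-projection calibration coefficients.
#' @return V0 in ml.
#' @export
average_initial_volume <- function(contour_ap, contour_lat, w_ap = NULL,
                                   w_lat = NULL) {
  (revolve_volume(contour_ap, w_ap) + revolve_volume(contour_lat, w_lat)) / 2
}

#' Central-section diameter from biplane contours
#'
#' Full silhouette width at the axial midpoint of each projection's contour
#' bounding box, averaged across AP and LAT.
#'
#' @param contour_ap,contour_lat `contour_polyline`s.
#' @param w_ap,w_lat calibration coefficients (default 1, calibrated
#'   contours).
#' @return diameter in mm.
#' @export
central_diameter <- function(contour_ap, contour_lat, w_ap = 1, w_lat = 1) {
  one <- function(ct, w) {
    zmid <- (min(ct$z) + max(ct$z)) / 2
    if (zmid < min(ct$z) || zmid > max(ct$z))
      bm_stop("midpoint outside contour span", class = "balloonmech_invalid_input")
    2 * w * stats::approx(ct$z, ct$r, xout = zmid)$y
  }
  (one(contour_ap, w_ap) + one(contour_lat, w_lat)) / 2
}

#' Injected-volume timeline
#'
#' \eqn{V(t) = V_0 + \dot V (t - t_0)} for the constant-flow syringe pump.
#'
#' @param V0 initial volume (ml), from [average_initial_volume()].
#' @param protocol an [inflation_protocol()] providing the flow rate.
#' @param times sample times (s).
#' @param t0 time of the initial frame (s).
#' @return numeric vector of volumes (ml).
#' @examples
#' volume_timeline(21, inflation_protocol(flow_rate_ml_h = 40), times = c(0, 15))
#' @export
volume_timeline <- function(V0, protocol, times, t0 = times[1]) {
  check_positive(V0, "V0")
  V0 + (protocol$flow_rate_ml_h / 3600) * (times - t0)
}

#' Read/write a calibration arch as JSON
#'
#' Layout: `{"b_real":[..,..],"b_image_ap":[..,..],"b_image_lat":[..,..]}`.
#'
#' @param path JSON path.
#' @param arch a [calibration_arch()] (for writing).
#' @return the arch, or `path` invisibly.
#' @export
read_arch_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_arch(x$b_real, x$b_image_ap,
                   if (!is.null(x$b_image_lat)) x$b_image_lat else x$b_image_ap)
}

#' @rdname read_arch_json
#' @export
write_arch_json <- function(arch, path) {
  jsonlite::write_json(list(b_real = arch$b_real,
                            b_image_ap = arch$b_image_ap,
                            b_image_lat = arch$b_image_lat),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read/write contour CSV (`z_mm,r_mm`, or `z_px,r_px` for raw scale)
#'
#' @param path CSV path.
#' @param contour a `contour_polyline` (for writing).
#' @return the contour, or `path` invisibly.
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("z_mm", "r_mm") %in% names(df)))
    contour_polyline(df$z_mm, df$r_mm, "calibrated")
  else if (all(c("z_px", "r_px") %in% names(df)))
    contour_polyline(df$z_px, df$r_px, "raw")
  else bm_stop("CSV must have columns z_mm,r_mm or z_px,r_px",
               class = "balloonmech_format_error")
}

#' @rdname read_contour_csv
#' @export
write_contour_csv <- function(contour, path) {
  nm <- if (identical(attr(contour, "scale"), "raw")) c("z_px", "r_px")
        else c("z_mm", "r_mm")
  df <- stats::setNames(data.frame(contour$z, contour$r), nm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
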