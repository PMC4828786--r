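#' Parametric valvuloplasty balloon design
#'
#' A non-compliant balloon is a central cylindrical region closed by two
#' pseudo-conical heads that taper down to the catheter shaft.  The default
#' arguments describe a 23 mm nominal-diameter device: cylindrical region
#' 40 mm, total length 75 mm, uniform membrane thickness 0.09 mm.
#'
#' @param diameter nominal (cylindrical-region) diameter, mm.
#' @param cyl_length length of the cylindrical region l, mm.
#' @param total_length total balloon length, mm; must exceed `cyl_length`.
#' @param thickness uniform membrane thickness, mm.
#' @param shaft_radius radius at which the heads meet the catheter shaft, mm.
#' @param head_power taper exponent of the pseudo-conical heads: the head
#'   radius grows as `(z/Lh)^head_power` from the shaft to the cylinder;
#'   1 gives a straight cone.
#' @return object of class `balloon_design`.
#' @examples
#' balloon_design()                    # the default 23/40/75/0.09 device
#' balloon_design(diameter = 20, cyl_length = 30, total_length = 60)
#' @export
balloon_design <- function(diameter = 23, cyl_length = 40, total_length = 75,
                           thickness = 0.09, shaft_radius = 3, head_power = 1) {
  check_positive(diameter, "diameter")
  check_positive(thickness, "thickness")
  check_positive(total_length, "total_length")
  check_positive(cyl_length, "cyl_length")
  if (cyl_length >= total_length)
    bm_stop("cyl_length must be < total_length", class = "balloonmech_invalid_input")
  if (shaft_radius <= 0 || shaft_radius >= diameter / 2)
    bm_stop("shaft_radius must lie in (0, diameter/2)", class = "balloonmech_invalid_input")
  if (head_power <= 0)
    bm_stop("head_power must be positive", class = "balloonmech_invalid_input")
  structure(list(diameter = diameter, cyl_length = cyl_length,
                 total_length = total_length, thickness = thickness,
                 shaft_radius = shaft_radius, head_power = head_power),
            class = "balloon_design")
}

#' @export
print.balloon_design <- function(x, ...) {
  cat(sprintf(paste0("Balloon design: d = %g mm, cylinder %g mm, total %g mm,",
                     " t = %g mm, shaft r = %g mm\n"),
              x$diameter, x$cyl_length, x$total_length, x$thickness, x$shaft_radius))
  invisible(x)
}

# internal: profile radius at axial position z (0 <= z <= total_length)
profile_radius <- function(design, z) {
  R <- design$diameter / 2
  rs <- design$shaft_radius
  lh <- (design$total_length - design$cyl_length) / 2
  p <- design$head_power
  r <- numeric(length(z))
  left <- z < lh
  right <- z > design$total_length - lh
  mid <- !left & !right
  r[left] <- rs + (R - rs) * (z[left] / lh)^p
  r[mid] <- R
  r[right] <- rs + (R - rs) * ((design$total_length - z[right]) / lh)^p
  r
}

#' Build a meridian mesh from a balloon design
#'
#' Samples the parametric meridian profile (two pseudo-conical heads plus
#' the central cylinder) at approximately uniform arc length into
#' `n_elements` two-node axisymmetric membrane elements.  Under
#' axisymmetry, this 1D meridian discretisation plays the role of a full
#' 3D membrane mesh.
#'
#' @param design a [balloon_design()].
#' @param n_elements number of meridian elements, `>= 20`.
#' @return object of class `meridian_mesh` with reference nodal coordinates
#'   `z0`, `r0` (mm), per-element reference lengths `L0`, reference
#'   thickness `t0`, and the design.
#' @examples
#' mesh <- build_profile_mesh(balloon_design(), 200)
#' mesh$n_elements
#' @export
build_profile_mesh <- function(design, n_elements) {
  if (!is.numeric(n_elements) || n_elements < 20)
    bm_stop("n_elements must be >= 20", class = "balloonmech_invalid_input")
  n_elements <- as.integer(n_elements)
  lh <- (design$total_length - design$cyl_length) / 2
  if (lh <= 0) bm_stop("degenerate design: zero-length head region",
                       class = "balloonmech_invalid_input")
  # fine polyline along the profile, then resample at uniform arc length;
  # node positions are snapped onto the exact profile via z
  zf <- sort(unique(c(seq(0, design$total_length, length.out = 4001),
                      lh, design$total_length - lh)))
  rf <- profile_radius(design, zf)
  s <- c(0, cumsum(sqrt(diff(zf)^2 + diff(rf)^2)))
  s_nodes <- seq(0, s[length(s)], length.out = n_elements + 1L)
  z0 <- stats::approx(s, zf, xout = s_nodes)$y
  # keep the exact breakpoints representable
  r0 <- profile_radius(design, z0)
  L0 <- sqrt(diff(z0)^2 + diff(r0)^2)
  if (any(L0 <= 0)) bm_stop("degenerate mesh: zero-length element",
                            class = "balloonmech_invalid_input")
  structure(list(z0 = z0, r0 = r0, L0 = L0, t0 = design$thickness,
                 n_elements = n_elements, design = design),
            class = "meridian_mesh")
}

#' @export
print.meridian_mesh <- function(x, ...) {
  cat(sprintf("Meridian mesh: %d membrane elements, %d nodes, t0 = %g mm\n",
              x$n_elements, length(x$z0), x$t0))
  cat(sprintf("reference enclosed volume: %.3f ml\n",
              mm3_to_ml(revolved_volume_mm3(x$z0, x$r0))))
  invisible(x)
}

# internal: solid-of-revolution volume (mm^3) of a meridian polyline by
# conical-frustum quadrature; exact for piecewise-linear profiles,
# second-order accurate on smooth ones
revolved_volume_mm3 <- function(z, r) {
  n <- length(z)
  dz <- z[-1] - z[-n]
  rl <- r[-n]; rr <- r[-1]
  sum((pi / 3) * (rl^2 + rl * rr + rr^2) * dz)
}

#' Enclosed cavity volume of a membrane state or meridian
#'
#' Volume of the solid of revolution of the (deformed) meridian about the
#' balloon axis, by conical-frustum quadrature between consecutive nodes.
#' The same revolution rule is used for contour volumetry in the imaging
#' module.
#'
#' @param state a `membrane_state`, a `meridian_mesh` (reference
#'   configuration), or a list with numeric `z` and `r`.
#' @return volume in ml.
#' @examples
#' enclosed_volume(list(z = c(0, 40), r = c(10, 10)))   # 12.566 ml cylinder
#' @export
enclosed_volume <- function(state) {
  if (inherits(state, "meridian_mesh")) {
    z <- state$z0; r <- state$r0
  } else {
    z <- state$z; r <- state$r
  }
  if (is.null(z) || is.null(r) || length(z) != length(r) || length(z) < 2)
    bm_stop("state must carry matching z and r coordinates",
            class = "balloonmech_invalid_input")
  if (any(r < 0))
    bm_stop("meridian has negative radius", class = "balloonmech_invalid_input")
  if (any(diff(z) <= 0))
    bm_stop("meridian z must be strictly increasing (self-intersecting or folded meridian)",
            class = "balloonmech_invalid_input")
  mm3_to_ml(revolved_volume_mm3(z, r))
}

#' Inflation protocol
#'
#' Volume-controlled loading protocol of the syringe-pump bench: constant
#' flow rate with image/pressure sampling every `dT_s` seconds.
#'
#' @param flow_rate_ml_h injection rate (ml/h), default 40.
#' @param V0_ml starting cavity volume (ml); `NULL` means "the model's
#'   reference (stress-free) volume", resolved by the solver.
#' @param injected_ml total injected volume (ml) defining the schedule span.
#' @param dT_s sampling interval (s), default 15.
#' @return object of class `inflation_protocol`.
#' @examples
#' inflation_protocol(injected_ml = 2.5)
#' @export
inflation_protocol <- function(flow_rate_ml_h = 40, V0_ml = NULL,
                               injected_ml = 2.5, dT_s = 15) {
  check_positive(flow_rate_ml_h, "flow_rate_ml_h")
  check_positive(dT_s, "dT_s")
  check_positive(injected_ml, "injected_ml")
  if (!is.null(V0_ml)) check_positive(V0_ml, "V0_ml")
  structure(list(flow_rate_ml_h = flow_rate_ml_h, V0_ml = V0_ml,
                 injected_ml = injected_ml, dT_s = dT_s),
            class = "inflation_protocol")
}

#' Volume schedule of a protocol
#'
#' Target cavity volumes at the sampling instants:
#' \eqn{V(t_k) = V_0 + \dot V (t_k - t_0)} with \eqn{t_k} spaced `dT_s`
#' apart.
#'
#' @param protocol an [inflation_protocol()].
#' @param V0_ml starting volume override (required if the protocol carries
#'   `V0_ml = NULL`).
#' @return data frame with `time_s` and `volume_ml`.
#' @examples
#' volume_schedule(inflation_protocol(V0_ml = 21, injected_ml = 1))
#' @export
volume_schedule <- function(protocol, V0_ml = protocol$V0_ml) {
  if (is.null(V0_ml))
    bm_stop("V0_ml must be given (protocol has no starting volume)",
            class = "balloonmech_invalid_input")
  rate_ml_s <- protocol$flow_rate_ml_h / 3600
  duration <- protocol$injected_ml / rate_ml_s
  times <- seq(0, duration, by = protocol$dT_s)
  if (times[length(times)] < duration) times <- c(times, duration)
  data.frame(time_s = times, volume_ml = V0_ml + rate_ml_s * times)
}
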