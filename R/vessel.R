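#' Cylindrical implantation-site phantom geometry
#'
#' Parametric thin-walled cylinder used both for compliance-test analysis
#' and as the implantation-site obstacle in constrained inflation.  The
#' terminal `end_band` regions are held at the reference radius during
#' pressurisation, mimicking the clamped ends of the bench set-up.
#'
#' @param diameter inner diameter d (mm).
#' @param thickness wall thickness t (mm).
#' @param length cylinder length l (mm).
#' @param end_band constrained end-band length at each end (mm); must
#'   satisfy `2*end_band < length`.
#' @param material optional [linear_elastic_model()] attached for reporting.
#' @return object of class `cylinder_phantom`.
#' @examples
#' cylinder_phantom(20, 0.8, 60, end_band = 10.6)   # compliance-test sample
#' cylinder_phantom(22, 1.2, 75)                    # implantation-site phantom
#' @export
cylinder_phantom <- function(diameter, thickness, length, end_band = 10.6,
                             material = NULL) {
  check_positive(diameter, "diameter")
  check_positive(thickness, "thickness")
  check_positive(length, "length")
  if (end_band < 0 || 2 * end_band >= length)
    bm_stop("need 0 <= 2*end_band < length", class = "balloonmech_invalid_input")
  structure(list(diameter = diameter, thickness = thickness, length = length,
                 end_band = end_band, material = material),
            class = "cylinder_phantom")
}

#' @export
print.cylinder_phantom <- function(x, ...) {
  cat(sprintf("Cylinder phantom: d = %g mm, t = %g mm, l = %g mm (end bands %g mm)\n",
              x$diameter, x$thickness, x$length, x$end_band))
  if (!is.null(x$material)) print(x$material)
  invisible(x)
}

#' Equivalent cylinder radius from internal volume
#'
#' Inverts the cylinder volume: \eqn{r = \sqrt{V / (\pi l)}}, the relation
#' used to convert compliance-test volumes into an equivalent radius.
#'
#' @param V internal volume (ml); vectorised.
#' @param l cylinder length (mm).
#' @return radius (mm).
#' @examples
#' radius_from_volume(12.566, 40)   # ~10 mm
#' @export
radius_from_volume <- function(V, l) {
  check_positive(l, "l")
  if (any(!is.finite(V)) || any(V <= 0))
    bm_stop("V must be positive", class = "balloonmech_invalid_input")
  sqrt(ml_to_mm3(V) / (pi * l))
}

#' Laplace hoop stress of a thin-walled cylinder
#'
#' \eqn{\sigma_\theta = P r / t}.  Unit-agnostic: the stress comes out in
#' the units of `P` (scaled by the dimensionless r/t).
#'
#' @param P internal pressure; vectorised.
#' @param r radius (mm).
#' @param t wall thickness (mm).
#' @return hoop stress in the units of `P`.
#' @examples
#' hoop_stress(1, 2, 0.5)   # 4
#' @export
hoop_stress <- function(P, r, t) {
  if (t <= 0) bm_stop("thickness must be positive", class = "balloonmech_invalid_input")
  P * r / t
}

#' Circumferential engineering strain
#'
#' \eqn{\varepsilon = (r - r_{in}) / r_{in}}.
#'
#' @param r current radius (mm); vectorised.
#' @param r_in reference (initial) radius (mm).
#' @return strain (dimensionless), negative for `r < r_in`.
#' @examples
#' hoop_strain(11, 10)   # 0.1
#' @export
hoop_strain <- function(r, r_in) {
  if (r_in <= 0) bm_stop("r_in must be positive", class = "balloonmech_invalid_input")
  (r - r_in) / r_in
}

#' Compliance-test record container
#'
#' Paired pressure--volume samples from a phantom compliance test; the first
#' sample defines the zero-gauge-pressure initial state (volume `V_in`).
#'
#' @param pressure_mmHg gauge pressures (mmHg).
#' @param volume_ml internal volumes (ml), all `> 0`.
#' @return a `compliance_record` data frame with attribute `V_in`.
#' @examples
#' compliance_record(c(0, 50, 100), c(18.85, 19.0, 19.15))
#' @export
compliance_record <- function(pressure_mmHg, volume_ml) {
  if (length(pressure_mmHg) != length(volume_ml) || length(volume_ml) < 2)
    bm_stop("need >= 2 paired (P, V) samples", class = "balloonmech_invalid_input")
  if (any(volume_ml <= 0))
    bm_stop("volumes must be positive", class = "balloonmech_invalid_input")
  df <- data.frame(pressure_mmHg = as.numeric(pressure_mmHg),
                   volume_ml = as.numeric(volume_ml))
  attr(df, "V_in") <- df$volume_ml[1]
  class(df) <- c("compliance_record", "data.frame")
  df
}

#' Read a compliance record from CSV (`pressure_mmHg,volume_ml`)
#'
#' @param path CSV file path.
#' @return a [compliance_record()].
#' @export
read_compliance_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("pressure_mmHg", "volume_ml") %in% names(df)))
    bm_stop("CSV must have columns `pressure_mmHg,volume_ml`",
            class = "balloonmech_format_error")
  compliance_record(df$pressure_mmHg, df$volume_ml)
}

#' Distensibility from a compliance record
#'
#' \eqn{D = \Delta V / (\Delta P \cdot V_{in})} in 1/mmHg, evaluated by
#' default between the first and last record samples; a sub-window can be
#' selected with `window` (indices).
#'
#' @param record a [compliance_record()].
#' @param window length-2 integer vector of sample indices (default
#'   first/last).
#' @return distensibility D (1/mmHg).
#' @examples
#' rec <- compliance_record(c(0, 10), c(10, 11))
#' distensibility(rec)   # 0.01
#' @export
distensibility <- function(record, window = c(1L, nrow(record))) {
  i <- window[1]; j <- window[2]
  dP <- record$pressure_mmHg[j] - record$pressure_mmHg[i]
  if (dP == 0) bm_stop("record must span a nonzero pressure change",
                       class = "balloonmech_invalid_input")
  dV <- record$volume_ml[j] - record$volume_ml[i]
  dV / (dP * attr(record, "V_in"))
}

#' Young's modulus from a compliance record via Laplace's law
#'
#' Treats the sample as a thin-walled cylinder of linear elastic, isotropic,
#' homogeneous material and evaluates, at the record's final state,
#' \eqn{E = \sigma_\theta/\varepsilon} with
#' \eqn{r = \sqrt{V/(\pi l)}}, \eqn{\sigma_\theta = P r/t},
#' \eqn{\varepsilon = (r - r_{in})/r_{in}}, where \eqn{r_{in}} is the radius
#' at the initial (zero-gauge-pressure) volume.  The analysis assumes a
#' uniform cylinder; constrained end bands bias the apparent volume change
#' and hence the recovered modulus (see the methods vignette), so recovery
#' checks use band-free phantoms.
#'
#' @param record a [compliance_record()].
#' @param phantom a [cylinder_phantom()] providing `t` and `l`.
#' @return Young's modulus (MPa).
#' @examples
#' ph <- cylinder_phantom(20, 0.8, 60, end_band = 0)
#' mat <- linear_elastic_model(1.0)
#' rec <- gen_compliance(ph, mat, pressures = seq(0, 30, 5),
#'                       noise = noise_spec(seed = 1, volume_sd = 0))
#' young_modulus_from_compliance(rec, ph)
#' @export
young_modulus_from_compliance <- function(record, phantom) {
  l <- phantom$length; t <- phantom$thickness
  if (t / (phantom$diameter / 2) > 0.2)
    warning("t/r > 0.2: thin-wall assumption is advisory only")
  r_in <- radius_from_volume(attr(record, "V_in"), l)
  n <- nrow(record)
  r <- radius_from_volume(record$volume_ml[n], l)
  eps <- hoop_strain(r, r_in)
  if (eps == 0) bm_stop("zero hoop strain at the final state",
                        class = "balloonmech_invalid_input")
  sigma <- hoop_stress(mmHg_to_MPa(record$pressure_mmHg[n]), r, t)
  sigma / eps
}

#' Linearised (small-strain) distensibility of a thin-walled cylinder
#'
#' Combines Laplace hoop stress, linear elasticity and the volume--radius
#' relation in the small-strain limit: \eqn{D = 2r/(E t)}, converted to
#' 1/mmHg.
#'
#' @param E Young's modulus (MPa).
#' @param r inner radius (mm).
#' @param t wall thickness (mm).
#' @return distensibility (1/mmHg).
#' @examples
#' linearized_distensibility(0.55, 10, 0.8)   # ~0.0061 per mmHg
#' @export
linearized_distensibility <- function(E, r, t) {
  check_positive(E, "E"); check_positive(r, "r"); check_positive(t, "t")
  (2 * r / (E * t)) * 133.322e-6   # (1/MPa) -> (1/mmHg)
}

#' Pressure--volume response of a clamped thin-walled elastic cylinder
#'
#' Small-strain thin-wall response: over the free length the radius dilates
#' to \eqn{r(P) = r_{in}(1 + P r_{in}/(E t))}; over each constrained end
#' band the radius interpolates linearly from \eqn{r_{in}} at the clamp to
#' the free-length radius.  The internal volume follows by revolving that
#' profile (conical-frustum quadrature, exact for the linear taper).  The
#' returned radial stiffness \eqn{dP/dr = E t/r_{in}^2} (free-length limit)
#' is what the contact solver uses as the phantom's local compliance.
#'
#' @param phantom a [cylinder_phantom()].
#' @param material a [linear_elastic_model()].
#' @param P internal gauge pressure(s), mmHg; vectorised.
#' @return list with `volume_ml`, `radius_mm` (free-length radius),
#'   `stiffness_MPa_per_mm` (dP/dr), `strain`, and `strain_warning` flag
#'   (TRUE where hoop strain exceeds 10 %, outside the linear model's
#'   validity).
#' @examples
#' ph <- cylinder_phantom(20, 0.8, 60, end_band = 10.6)
#' cylinder_pv_response(ph, linear_elastic_model(0.55), P = c(0, 20, 40))
#' @export
cylinder_pv_response <- function(phantom, material, P) {
  r_in <- phantom$diameter / 2
  t <- phantom$thickness
  E <- material$young_modulus
  b <- phantom$end_band
  lf <- phantom$length - 2 * b
  P_MPa <- mmHg_to_MPa(P)
  rf <- r_in * (1 + P_MPa * r_in / (E * t))
  # volume: free cylinder + two linear-taper frusta (exact frustum formula)
  v_free <- pi * rf^2 * lf
  v_band <- 2 * (pi * b / 3) * (r_in^2 + r_in * rf + rf^2)
  strain <- (rf - r_in) / r_in
  list(volume_ml = mm3_to_ml(v_free + v_band),
       radius_mm = rf,
       stiffness_MPa_per_mm = E * t / r_in^2,
       strain = strain,
       strain_warning = abs(strain) > 0.10)
}

#' Relative volume-difference report under three denominator conventions
#'
#' Compares an experimental and a computational volume and reports the
#' percentage difference normalised by each volume and by their mean, since
#' a single "error" convention is ambiguous.
#'
#' @param v_exp,v_comp volumes (same units).
#' @return named numeric vector `pct_of_exp`, `pct_of_comp`, `pct_of_mean`.
#' @examples
#' volume_error_report(10.26, 9.97)
#' @export
volume_error_report <- function(v_exp, v_comp) {
  d <- abs(v_exp - v_comp)
  c(pct_of_exp = 100 * d / abs(v_exp),
    pct_of_comp = 100 * d / abs(v_comp),
    pct_of_mean = 100 * d / ((abs(v_exp) + abs(v_comp)) / 2))
}

#' Reference properties of TangoPlus/VeroWhite printed composites
#'
#' Loads the shipped table of rubber-like rapid-prototyping composite
#' properties (composition, test thickness, measured distensibility and
#' Young's modulus).  Entries marked `synthetic` in the `source` column are
#' plausible interpolations between the measured series endpoints, shipped
#' so the monotone stiffness/distensibility trend across the composition
#' series can be asserted; see the CSV comments.
#'
#' @return data frame with columns `name`, `pct_tango`, `pct_vero`,
#'   `thickness_mm`, `D_per_mmHg`, `E_MPa`, `source`.
#' @examples
#' rp_composite_properties()
#' @export
rp_composite_properties <- function() {
  path <- system.file("extdata", "rp_composites.csv", package = "balloonmech")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
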