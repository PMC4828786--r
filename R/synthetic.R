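#' Measurement-noise specification for the synthetic generators
#'
#' Additive Gaussian noise plus uniform quantisation, all driven by one
#' seed.  Defaults emulate the bench instrumentation: a strain-gauge
#' pressure transducer (smooth noise, a few mmHg), fluoroscopy diameter
#' readings quantised to the 0.5 mm isotropic image resolution, and small
#' extensometer/load-cell noise on tensile data.
#'
#' @param seed integer seed fixing all randomness of a generator call.
#' @param pressure_sd_mmHg pressure noise standard deviation (mmHg).
#' @param pressure_quant_mmHg pressure quantisation step (mmHg; 0 = none).
#'   The clinical inflation manometer quantises at 0.2 atm (152 mmHg); the
#'   bench transducer is treated as continuous.
#' @param diameter_quant_mm diameter quantisation step (mm), default 0.5.
#' @param strain_sd,stress_sd tensile-test noise standard deviations
#'   (dimensionless strain; stress in MPa).
#' @param volume_sd_ml volume noise for compliance records (ml).
#' @return object of class `noise_spec`.
#' @examples
#' noise_spec(seed = 7)
#' noise_spec(seed = 1, pressure_sd_mmHg = 0, diameter_quant_mm = 0)  # noiseless
#' @export
noise_spec <- function(seed = 1L, pressure_sd_mmHg = 5, pressure_quant_mmHg = 0,
                       diameter_quant_mm = 0.5, strain_sd = 0, stress_sd = 0,
                       volume_sd_ml = 0.01) {
  vals <- c(pressure_sd_mmHg, pressure_quant_mmHg, diameter_quant_mm,
            strain_sd, stress_sd, volume_sd_ml)
  if (any(vals < 0)) bm_stop("noise magnitudes must be >= 0",
                             class = "balloonmech_invalid_input")
  structure(list(seed = as.integer(seed),
                 pressure_sd_mmHg = pressure_sd_mmHg,
                 pressure_quant_mmHg = pressure_quant_mmHg,
                 diameter_quant_mm = diameter_quant_mm,
                 strain_sd = strain_sd, stress_sd = stress_sd,
                 volume_sd_ml = volume_sd_ml),
            class = "noise_spec")
}

quantize <- function(x, step) if (step > 0) round(x / step) * step else x

#' Synthetic uniaxial tensile curves
#'
#' Generates monotonic or cyclic engineering stress--strain curves from a
#' constitutive model plus seeded noise.  In cyclic mode each cycle `k`
#' loads from the previous residual strain up to `strain_max` and unloads
#' along a branch shifted so it crosses zero stress at the prescribed
#' residual offset — emulating the progressive 3--5 % residual strain
#' rubber-like balloon membranes accumulate over repeated 10 % cycles
#' (measured descriptively; no elastoplastic law is simulated).
#'
#' @param model an [ogden_model()] or [linear_elastic_model()].
#' @param strain strain grid for monotonic mode (default 0 to 0.12).
#' @param noise a [noise_spec()].
#' @param cycles number of load/unload cycles (`NULL` = monotonic mode).
#' @param strain_max cyclic peak strain (default 0.10).
#' @param residual_offsets residual strain after each cycle; default ramps
#'   3 % to 5 % across the cycles.
#' @param n_per_branch samples per loading/unloading branch.
#' @param direction direction label on the returned curve.
#' @return a [stress_strain_curve()]; cyclic curves carry `cycle` and
#'   `branch` columns.
#' @examples
#' crv <- gen_uniaxial(ogden_model(mu = 100, alpha = 3),
#'                     noise = noise_spec(seed = 2))
#' head(crv)
#' @export
gen_uniaxial <- function(model, strain = seq(0, 0.12, by = 0.002),
                         noise = noise_spec(), cycles = NULL,
                         strain_max = 0.10, residual_offsets = NULL,
                         n_per_branch = 26, direction = NA_character_) {
  stress_of <- function(eps) {
    if (inherits(model, "linear_elastic_model")) model$young_modulus * eps
    else ogden_uniaxial_stress(1 + eps, model, "nominal")
  }
  withr::with_seed(noise$seed, {
    if (is.null(cycles)) {
      s <- stress_of(strain)
      if (noise$strain_sd > 0) strain <- strain + c(0, stats::rnorm(length(strain) - 1, 0, noise$strain_sd))
      if (noise$stress_sd > 0) s <- s + c(0, stats::rnorm(length(s) - 1, 0, noise$stress_sd))
      return(stress_strain_curve(strain, s, direction = direction))
    }
    if (is.null(residual_offsets))
      residual_offsets <- if (cycles == 1) 0.03 else seq(0.03, 0.05, length.out = cycles)
    if (length(residual_offsets) != cycles)
      bm_stop("residual_offsets must have one entry per cycle",
              class = "balloonmech_invalid_input")
    out <- NULL
    prev <- 0
    for (k in seq_len(cycles)) {
      rk <- residual_offsets[k]
      # loading branch: from the previous residual strain up to strain_max,
      # stress following the law on a rescaled material strain
      e_load <- seq(prev, strain_max, length.out = n_per_branch)
      s_load <- stress_of((e_load - prev) / (strain_max - prev) * strain_max)
      # unloading branch: crosses zero stress at the new residual offset
      e_unld <- seq(strain_max, rk, length.out = n_per_branch)
      s_unld <- stress_of((e_unld - rk) / (strain_max - rk) * strain_max)
      add_noise <- function(e, s) {
        if (noise$strain_sd > 0) e <- e + stats::rnorm(length(e), 0, noise$strain_sd)
        if (noise$stress_sd > 0) s <- s + stats::rnorm(length(s), 0, noise$stress_sd)
        list(e = e, s = s)
      }
      ld <- add_noise(e_load, s_load); ul <- add_noise(e_unld, s_unld)
      out <- rbind(out,
                   data.frame(strain = ld$e, stress = ld$s, cycle = k, branch = "load"),
                   data.frame(strain = ul$e, stress = ul$s, cycle = k, branch = "unload"))
      prev <- rk
    }
    stress_strain_curve(out$strain, out$stress, direction = direction,
                        cycle = out$cycle, branch = out$branch)
  })
}

#' Synthetic compliance-test record
#'
#' Pressure--volume record of a thin-walled linear-elastic cylinder phantom
#' from [cylinder_pv_response()], plus seeded volume noise.
#'
#' @param phantom a [cylinder_phantom()].
#' @param material a [linear_elastic_model()].
#' @param pressures gauge-pressure grid (mmHg) starting at 0.
#' @param noise a [noise_spec()].
#' @return a [compliance_record()].
#' @examples
#' rec <- gen_compliance(cylinder_phantom(20, 0.8, 60, end_band = 0),
#'                       linear_elastic_model(0.55),
#'                       noise = noise_spec(seed = 3, volume_sd = 0))
#' distensibility(rec)
#' @export
gen_compliance <- function(phantom, material, pressures = seq(0, 40, by = 5),
                           noise = noise_spec()) {
  resp <- cylinder_pv_response(phantom, material, pressures)
  withr::with_seed(noise$seed, {
    V <- resp$volume_ml
    if (noise$volume_sd_ml > 0)
      V <- V + c(0, stats::rnorm(length(V) - 1, 0, noise$volume_sd_ml))
    compliance_record(pressures, V)
  })
}

#' Synthetic inflation experiment
#'
#' Runs the membrane solver forward (free or constrained), then corrupts
#' the outputs the way the bench instrumentation would: Gaussian pressure
#' noise (plus optional manometer quantisation) and 0.5 mm quantisation of
#' the fluoroscopy diameter.  The clean solver curve is retained as ground
#' truth.
#'
#' @param design a [balloon_design()].
#' @param material an [ogden_model()].
#' @param phantom `NULL` for free inflation, else a [cylinder_phantom()].
#' @param phantom_material [linear_elastic_model()] for a compliant phantom.
#' @param protocol an [inflation_protocol()].
#' @param noise a [noise_spec()].
#' @param n_elements,options passed to the solver.
#' @return list with `curve` (noisy, provenance `"synthetic"`), `truth`
#'   (clean solver curve), and `solution` (full solver output).
#' @export
gen_inflation_experiment <- function(design, material, phantom = NULL,
                                     phantom_material = NULL, protocol,
                                     noise = noise_spec(), n_elements = 100,
                                     options = list()) {
  sol <- if (is.null(phantom))
    solve_free_inflation(design, material, protocol, n_elements, options)
  else
    solve_constrained_inflation(design, material, phantom, phantom_material,
                                protocol, n_elements, options)
  clean <- sol$curve
  withr::with_seed(noise$seed, {
    P <- clean$pressure_mmHg
    if (noise$pressure_sd_mmHg > 0)
      P <- P + stats::rnorm(length(P), 0, noise$pressure_sd_mmHg)
    P <- pmax(quantize(P, noise$pressure_quant_mmHg), 0)
    d <- quantize(clean$diameter_mm, noise$diameter_quant_mm)
    noisy <- inflation_curve(clean$time_s, clean$volume_ml, P, d,
                             provenance = "synthetic")
  })
  list(curve = noisy, truth = clean, solution = sol)
}

#' Synthetic biplane projections of a membrane state
#'
#' Renders AP and LAT silhouette images of the revolved balloon at image
#' scale `1/w_true` (real mm = w_true x image mm), with bead markers at the
#' calibration arch's real positions mapped into image coordinates (and
#' optionally quantised to the pixel grid).  A light separable blur makes
#' the silhouette boundary sub-pixel interpolable, as on real fluoroscopy.
#'
#' @param state a `membrane_state` (or list with `z`, `r` in mm).
#' @param arch_real length-2 real bead-pair distances (mm) for the arch.
#' @param pixel_size_mm image pixel size (default 0.5).
#' @param w_true true calibration coefficient.
#' @param seed integer seed (bead measurement quantisation jitter).
#' @param quantize_beads quantise bead image coordinates to the pixel grid.
#' @return list with `ap`, `lat` ([projection_image()]s), `arch`
#'   (a [calibration_arch()] holding the measured image distances), and
#'   `truth` (list: `w_true`, `volume_ml`, `diameter_mm`).
#' @export
gen_projections <- function(state, arch_real = c(120, 160), pixel_size_mm = 0.5,
                            w_true = 1.05, seed = 1L, quantize_beads = TRUE) {
  z <- state$z; r <- state$r
  truth_V <- mm3_to_ml(revolved_volume_mm3(z, r))
  zmid <- (min(z) + max(z)) / 2
  truth_d <- 2 * stats::approx(z, r, xout = zmid)$y

  render <- function() {
    # image-plane extent (image mm): balloon scaled by 1/w plus margins
    zi <- z / w_true; ri <- r / w_true
    margin <- 8
    width <- diff(range(zi)) + 2 * margin
    height <- 2 * max(ri) + 2 * margin
    nc <- ceiling(width / pixel_size_mm)
    nr <- ceiling(height / pixel_size_mm)
    axis_row <- height / 2
    xs <- (seq_len(nc)) * pixel_size_mm - margin + min(zi)   # column centres
    ys <- (seq_len(nr)) * pixel_size_mm                       # row centres
    Rcol <- stats::approx(zi, ri, xout = xs, yleft = 0, yright = 0)$y
    Rcol[is.na(Rcol)] <- 0
    # anti-aliased silhouette: pixel value is the linear edge coverage, so
    # the 0.5-level crossing sits on the true boundary (as the partial-volume
    # grey levels of real fluoroscopy let threshold segmentation do)
    px <- outer(ys, Rcol, function(y, R) {
      pmin(pmax(0.5 + (R - abs(y - axis_row)) / pixel_size_mm, 0), 1)
    })
    px[, Rcol <= 0] <- 0
    px
  }

  withr::with_seed(seed, {
    ap_px <- render(); lat_px <- render()
    # bead pairs placed along the arch; measured image distances
    measure <- function() {
      b_img <- arch_real / w_true
      if (quantize_beads)
        b_img <- quantize(b_img + stats::runif(2, -pixel_size_mm / 4, pixel_size_mm / 4),
                          pixel_size_mm)
      b_img
    }
    arch <- calibration_arch(arch_real, measure(), measure())
  })
  list(ap = projection_image(ap_px, pixel_size_mm),
       lat = projection_image(lat_px, pixel_size_mm),
       arch = arch,
       truth = list(w_true = w_true, volume_ml = truth_V, diameter_mm = truth_d))
}
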