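# Configuration schema: one YAML document with unit-tagged keys, e.g.
#
#   schema_version: 1
#   balloon:   {diameter_mm: 23, cyl_length_mm: 40, total_length_mm: 75,
#               thickness_mm: 0.09, shaft_radius_mm: 3}
#   material:  {type: ogden, mu: [...], alpha: [...], delta: [...],
#               units: MPa, poisson: 0.45}
#   phantom:   {diameter_mm: 22, thickness_mm: 1.2, length_mm: 75,
#               end_band_mm: 5}
#   phantom_material: {type: linear, young_modulus_MPa: 13.19, poisson: 0.25}
#   protocol:  {flow_rate_ml_h: 40, injected_ml: 2.5, dT_s: 15}
#   noise:     {seed: 1, pressure_sd_mmHg: 5, diameter_quant_mm: 0.5}
#   solver:    {n_elements: 100, dV_max_ml: 0.25, tol: 1.0e-9}
#
# Unknown keys are rejected with the offending key named.

config_schema <- list(
  top = c("schema_version", "balloon", "material", "phantom",
          "phantom_material", "protocol", "noise", "solver", "output"),
  balloon = c("diameter_mm", "cyl_length_mm", "total_length_mm",
              "thickness_mm", "shaft_radius_mm", "head_power"),
  material = c("type", "mu", "alpha", "delta", "units", "poisson",
               "young_modulus_MPa"),
  phantom = c("diameter_mm", "thickness_mm", "length_mm", "end_band_mm"),
  phantom_material = c("type", "young_modulus_MPa", "poisson", "units"),
  protocol = c("flow_rate_ml_h", "V0_ml", "injected_ml", "dT_s"),
  noise = c("seed", "pressure_sd_mmHg", "pressure_quant_mmHg",
            "diameter_quant_mm", "strain_sd", "stress_sd", "volume_sd_ml"),
  solver = c("n_elements", "dV_max_ml", "tol", "max_iter", "reg", "penalty"),
  output = c("curve_csv", "report_json")
)

check_keys <- function(x, allowed, section) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    bm_stop(sprintf("unknown key `%s` in config section `%s`", bad[1], section),
            class = "balloonmech_config_error")
}

parse_material <- function(m, default_poisson = 0.45) {
  if (identical(m$type, "linear"))
    linear_elastic_model(m$young_modulus_MPa,
                         poisson = m$poisson %||% 0.25,
                         units = m$units %||% "MPa")
  else
    ogden_model(unlist(m$mu), unlist(m$alpha),
                if (!is.null(m$delta)) unlist(m$delta) else rep(0, length(m$mu)),
                poisson = m$poisson %||% default_poisson,
                units = m$units %||% "MPa")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing the balloon design, materials,
#' phantom, inflation protocol, noise and solver options, validates it
#' (unknown keys and non-physical values are rejected with the offending
#' key named), and constructs the corresponding package objects.
#'
#' @param path YAML file path.
#' @return object of class `run_config`: list with `balloon`, `material`,
#'   `phantom`, `phantom_material`, `protocol`, `noise`, `solver`,
#'   `output`, `schema_version`, plus attribute `config_hash`.
#' @examples
#' cfg <- load_config(system.file("extdata", "free_inflation.yaml",
#'                                package = "balloonmech"))
#' cfg$balloon
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    bm_stop(sprintf("config file not found: %s", path),
            class = "balloonmech_config_error")
  y <- yaml::read_yaml(path)
  check_keys(y, config_schema$top, "<top level>")
  for (sec in intersect(names(y), names(config_schema)))
    check_keys(y[[sec]], config_schema[[sec]], sec)

  num_keys <- function(x, section) {
    for (k in names(x)) {
      v <- x[[k]]
      if (grepl("_(mm|ml|mmHg|MPa|s|ml_h)$", k) && is.numeric(v) && any(v < 0))
        bm_stop(sprintf("config key `%s.%s` must be non-negative", section, k),
                class = "balloonmech_config_error")
    }
  }
  for (sec in c("balloon", "phantom", "protocol"))
    if (!is.null(y[[sec]])) num_keys(y[[sec]], sec)

  b <- y$balloon %||% list()
  balloon <- balloon_design(
    diameter = b$diameter_mm %||% 23, cyl_length = b$cyl_length_mm %||% 40,
    total_length = b$total_length_mm %||% 75,
    thickness = b$thickness_mm %||% 0.09,
    shaft_radius = b$shaft_radius_mm %||% 3,
    head_power = b$head_power %||% 1)
  material <- if (!is.null(y$material)) parse_material(y$material)
              else balloon_ogden_coefficients()
  phantom <- if (!is.null(y$phantom))
    cylinder_phantom(y$phantom$diameter_mm, y$phantom$thickness_mm,
                     y$phantom$length_mm,
                     end_band = y$phantom$end_band_mm %||% 10.6)
  phantom_material <- if (!is.null(y$phantom_material))
    parse_material(y$phantom_material)
  p <- y$protocol %||% list()
  protocol <- inflation_protocol(
    flow_rate_ml_h = p$flow_rate_ml_h %||% 40, V0_ml = p$V0_ml,
    injected_ml = p$injected_ml %||% 2.5, dT_s = p$dT_s %||% 15)
  nz <- y$noise %||% list()
  noise <- noise_spec(seed = nz$seed %||% 1L,
                      pressure_sd_mmHg = nz$pressure_sd_mmHg %||% 5,
                      pressure_quant_mmHg = nz$pressure_quant_mmHg %||% 0,
                      diameter_quant_mm = nz$diameter_quant_mm %||% 0.5,
                      strain_sd = nz$strain_sd %||% 0,
                      stress_sd = nz$stress_sd %||% 0,
                      volume_sd_ml = nz$volume_sd_ml %||% 0.01)
  solver <- y$solver %||% list()
  out <- structure(list(schema_version = y$schema_version %||% 1,
                        balloon = balloon, material = material,
                        phantom = phantom, phantom_material = phantom_material,
                        protocol = protocol, noise = noise,
                        solver = solver, output = y$output),
                   class = "run_config")
  attr(out, "config_hash") <- sum(utf8ToInt(paste(deparse(y), collapse = "")))
  out
}

#' Save a run configuration back to YAML
#'
#' Writes the unit-tagged YAML representation; `load_config()` of the
#' result reconstructs an equivalent configuration (round-trip identity on
#' the constructed objects).
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  b <- config$balloon
  y <- list(schema_version = config$schema_version,
            balloon = list(diameter_mm = b$diameter, cyl_length_mm = b$cyl_length,
                           total_length_mm = b$total_length, thickness_mm = b$thickness,
                           shaft_radius_mm = b$shaft_radius, head_power = b$head_power))
  m <- config$material
  y$material <- if (inherits(m, "ogden_model"))
    list(type = "ogden", mu = m$mu, alpha = m$alpha, delta = m$delta,
         units = m$units, poisson = m$poisson)
  else list(type = "linear", young_modulus_MPa = m$young_modulus,
            poisson = m$poisson)
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    y$phantom <- list(diameter_mm = ph$diameter, thickness_mm = ph$thickness,
                      length_mm = ph$length, end_band_mm = ph$end_band)
  }
  if (!is.null(config$phantom_material)) {
    pm <- config$phantom_material
    y$phantom_material <- list(type = "linear",
                               young_modulus_MPa = pm$young_modulus,
                               poisson = pm$poisson)
  }
  pr <- config$protocol
  y$protocol <- list(flow_rate_ml_h = pr$flow_rate_ml_h, injected_ml = pr$injected_ml,
                     dT_s = pr$dT_s)
  if (!is.null(pr$V0_ml)) y$protocol$V0_ml <- pr$V0_ml
  nz <- config$noise
  y$noise <- list(seed = nz$seed, pressure_sd_mmHg = nz$pressure_sd_mmHg,
                  pressure_quant_mmHg = nz$pressure_quant_mmHg,
                  diameter_quant_mm = nz$diameter_quant_mm,
                  strain_sd = nz$strain_sd, stress_sd = nz$stress_sd,
                  volume_sd_ml = nz$volume_sd_ml)
  if (length(config$solver)) y$solver <- config$solver
  if (!is.null(config$output)) y$output <- config$output
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (schema", x$schema_version, ")\n")
  print(x$balloon)
  if (!is.null(x$phantom)) print(x$phantom)
  cat(sprintf("Protocol: %g ml/h, +%g ml, dT = %g s\n",
              x$protocol$flow_rate_ml_h, x$protocol$injected_ml, x$protocol$dT_s))
  invisible(x)
}

#' End-to-end validation workflow on synthetic data
#'
#' The full desk-scale counterpart of a bench validation campaign:
#' generate a noisy synthetic inflation "experiment" (forward model plus
#' instrument noise), run the clean forward simulation, compare the two
#' curves at equal volume, and write the report.  With `mode =
#' "constrained"` the configured phantom constrains the balloon.
#'
#' @param config a `run_config` from [load_config()].
#' @param mode `"free"` or `"constrained"`.
#' @param seed overrides the config's noise seed if given.
#' @param out_dir optional output directory for `curve.csv` (noisy
#'   experiment), `truth.csv` (clean simulation) and `report.json`.
#' @return list with `comparison` (a `curve_comparison`), `experiment`,
#'   `simulation` (curves), `seed`, `config_hash`, and for constrained
#'   runs `contact_report`.
#' @export
run_workflow <- function(config, mode = c("free", "constrained"),
                         seed = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  noise <- config$noise
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  n_el <- config$solver$n_elements %||% 100
  opts <- config$solver[setdiff(names(config$solver), "n_elements")]
  phantom <- if (mode == "constrained") {
    if (is.null(config$phantom))
      bm_stop("constrained mode needs a `phantom` config section",
              class = "balloonmech_config_error")
    config$phantom
  }
  gen <- gen_inflation_experiment(config$balloon, config$material,
                                  phantom = phantom,
                                  phantom_material = if (mode == "constrained")
                                    config$phantom_material,
                                  protocol = config$protocol, noise = noise,
                                  n_elements = n_el, options = opts)
  cmp <- compare_curves(gen$curve, gen$truth)
  out <- list(comparison = cmp, experiment = gen$curve, simulation = gen$truth,
              seed = noise$seed, mode = mode,
              config_hash = attr(config, "config_hash"))
  if (mode == "constrained") out$contact_report <- gen$solution$contact_report
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_inflation_csv(gen$curve, file.path(out_dir, "curve.csv"))
    write_inflation_csv(gen$truth, file.path(out_dir, "truth.csv"))
    jsonlite::write_json(
      list(mode = mode, seed = noise$seed, config_hash = out$config_hash,
           rmse_P_mmHg = cmp$rmse_P, rmse_d_mm = cmp$rmse_d,
           rmse_P_pct_of_max = cmp$rmse_P_pct_of_max,
           d_within_resolution = cmp$d_within_resolution,
           grid = cmp$grid),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
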