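test_that("Laplace-law building blocks evaluate correctly and reject bad input", {
  # r = sqrt(V / (pi l)): cylinder of r = 10 mm, l = 40 mm holds 12.566 ml
  expect_equal(radius_from_volume(mm3_to_ml(pi * 100 * 40), 40), 10)
  expect_equal(radius_from_volume(12.566, 40), 10, tolerance = 1e-4)
  expect_error(radius_from_volume(-1, 40), class = "balloonmech_invalid_input")

  expect_equal(hoop_stress(0, 10, 0.8), 0)
  expect_equal(hoop_stress(1, 2, 0.5), 4)
  expect_equal(hoop_stress(1, 2, 1.0), 2)   # doubling t halves the stress
  expect_error(hoop_stress(1, 2, 0), class = "balloonmech_invalid_input")

  expect_equal(hoop_strain(10, 10), 0)
  expect_equal(hoop_strain(11, 10), 0.1)
  expect_lt(hoop_strain(9, 10), 0)
  expect_error(hoop_strain(1, 0), class = "balloonmech_invalid_input")
})

test_that("radius_from_volume round-trips with enclosed_volume on a straight meridian", {
  V <- enclosed_volume(list(z = c(0, 25, 60), r = c(7.3, 7.3, 7.3)))
  expect_equal(radius_from_volume(V, 60), 7.3)
})

test_that("distensibility matches arithmetic and the linearized closed form", {
  rec <- compliance_record(c(0, 10), c(10, 11))
  expect_equal(distensibility(rec), 0.01)   # 1 ml / (10 mmHg * 10 ml)
  expect_error(distensibility(compliance_record(c(5, 5), c(10, 10.1))),
               class = "balloonmech_invalid_input")

  # synthetic record from a linear cylinder of known E vs 2r/(Et)
  mat <- linear_elastic_model(1.0)
  rec2 <- gen_compliance(phantom_compliance, mat, pressures = seq(0, 10, 2),
                         noise = noise_spec(seed = 1, volume_sd_ml = 0))
  D_meas <- distensibility(rec2)
  D_lin <- linearized_distensibility(1.0, 10, 0.8)
  expect_equal(D_meas, D_lin, tolerance = 0.02)
})

test_that("distensibility and linearized_distensibility agree in the small-strain limit", {
  mat <- linear_elastic_model(2.0)
  # pressures chosen so hoop strain stays ~0.5 %
  rec <- gen_compliance(phantom_compliance, mat, pressures = c(0, 6),
                        noise = noise_spec(seed = 1, volume_sd_ml = 0))
  expect_equal(distensibility(rec), linearized_distensibility(2.0, 10, 0.8),
               tolerance = 0.01)
  # D halves when t doubles
  expect_equal(linearized_distensibility(2, 10, 1.6),
               linearized_distensibility(2, 10, 0.8) / 2)
})

test_that("Young's modulus is recovered from synthetic compliance records within 2 %", {
  for (E in c(0.55, 1.0, 13.19)) {
    mat <- linear_elastic_model(E)
    # target ~1 % hoop strain: P = E*t*eps/r
    P_top <- MPa_to_mmHg(E * 0.8 * 0.01 / 10)
    rec <- gen_compliance(phantom_compliance, mat,
                          pressures = seq(0, P_top, length.out = 6),
                          noise = noise_spec(seed = 1, volume_sd_ml = 0))
    expect_equal(young_modulus_from_compliance(rec, phantom_compliance), E,
                 tolerance = 0.02)
  }
})

test_that("recovered modulus is invariant to the pressure unit of the source data", {
  mat <- linear_elastic_model(1.0)
  rec <- gen_compliance(phantom_compliance, mat, pressures = seq(0, 8, 2),
                        noise = noise_spec(seed = 1, volume_sd_ml = 0))
  # same record expressed via Pa-scaled pressures converted back to mmHg
  rec2 <- compliance_record(MPa_to_mmHg(mmHg_to_MPa(rec$pressure_mmHg)),
                            rec$volume_ml)
  expect_equal(young_modulus_from_compliance(rec, phantom_compliance),
               young_modulus_from_compliance(rec2, phantom_compliance))
})

test_that("recovery bias grows monotonically with strain", {
  mat <- linear_elastic_model(1.0)
  errs <- vapply(c(0.005, 0.02, 0.05), function(eps_target) {
    P_top <- MPa_to_mmHg(1.0 * 0.8 * eps_target / 10)
    rec <- gen_compliance(phantom_compliance, mat, pressures = c(0, P_top),
                          noise = noise_spec(seed = 1, volume_sd_ml = 0))
    abs(young_modulus_from_compliance(rec, phantom_compliance) - 1.0)
  }, 0)
  expect_true(all(diff(errs) > 0))
})

test_that("clamped-cylinder P-V response has the analytic stiffness and volume", {
  ph <- cylinder_phantom(20, 0.8, 60, end_band = 10.6)
  mat <- linear_elastic_model(0.55)
  r0 <- cylinder_pv_response(ph, mat, 0)
  expect_equal(r0$volume_ml, mm3_to_ml(pi * 100 * 60))
  expect_equal(r0$stiffness_MPa_per_mm, 0.55 * 0.8 / 100)

  resp <- cylinder_pv_response(ph, mat, 30)
  # brute-force quadrature of the tapered profile
  zb <- seq(0, 60, length.out = 20001)
  rb <- ifelse(zb < 10.6, 10 + (resp$radius_mm - 10) * zb / 10.6,
        ifelse(zb > 49.4, 10 + (resp$radius_mm - 10) * (60 - zb) / 10.6,
               resp$radius_mm))
  V_bf <- mm3_to_ml(sum(pi * ((rb[-1] + rb[-length(rb)]) / 2)^2 * diff(zb)))
  expect_equal(resp$volume_ml, V_bf, tolerance = 1e-3)
  expect_false(resp$strain_warning)
  expect_true(cylinder_pv_response(ph, linear_elastic_model(0.01), 40)$strain_warning)
})

test_that("composite property fixture shows the stiffness/distensibility trend", {
  tab <- rp_composite_properties()
  series <- tab[tab$thickness_mm == 0.8, ]
  series <- series[order(series$pct_vero), ]
  expect_true(all(diff(series$E_MPa) > 0))       # stiffer with more VeroWhite
  expect_true(all(diff(series$D_per_mmHg) < 0))  # less distensible
  t50 <- tab[tab$name == "T50", ]
  expect_equal(t50$D_per_mmHg, 0.00025)
  expect_equal(t50$E_MPa, 13.19)
})

test_that("volume error report gives all three denominator conventions", {
  r <- volume_error_report(10.26, 9.97)
  expect_equal(unname(r["pct_of_exp"]), 100 * 0.29 / 10.26, tolerance = 1e-10)
  expect_equal(unname(r["pct_of_comp"]), 100 * 0.29 / 9.97, tolerance = 1e-10)
  expect_equal(unname(r["pct_of_mean"]), 100 * 0.29 / 10.115, tolerance = 1e-10)
  expect_true(all(r > 2.8 & r < 3.0))
})

test_that("compliance CSV round-trips", {
  tf <- tempfile(fileext = ".csv")
  rec <- compliance_record(c(0, 10, 20), c(18.85, 18.95, 19.05))
  utils::write.csv(as.data.frame(rec), tf, row.names = FALSE)
  rec2 <- read_compliance_csv(tf)
  expect_equal(rec2$volume_ml, rec$volume_ml)
  expect_equal(attr(rec2, "V_in"), 18.85)
})
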