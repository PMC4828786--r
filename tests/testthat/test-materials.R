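test_that("ogden energy vanishes at the reference state and respects permutation symmetry", {
  models <- list(table2, soft_ogden, ogden_model(mu = 1, alpha = 2))
  for (m in models)
    expect_identical(ogden_energy(stretch_state(1, 1, 1), m), 0)
  s1 <- stretch_state(1.10, 0.95, 0.96)
  s2 <- stretch_state(0.95, 1.10, 0.96)
  for (m in models)
    expect_equal(ogden_energy(s1, m), ogden_energy(s2, m))
})

test_that("ogden energy matches hand evaluation for N=1 incompressible uniaxial", {
  # mu = 1, alpha = 2, lambda = (2, 2^-1/2, 2^-1/2):
  # U = (2*1/4) * (4 + 0.5 + 0.5 - 3) = 1.0
  m <- ogden_model(mu = 1, alpha = 2)
  expect_equal(ogden_energy(stretch_state(2, 2^-0.5, 2^-0.5), m), 1.0)
})

test_that("ogden energy is non-negative for incompressible states of stable models", {
  m <- ogden_model(mu = c(2, 0.5), alpha = c(2, 4))   # all mu_i*alpha_i > 0
  set.seed(42)
  for (i in 1:50) {
    l1 <- exp(rnorm(1, 0, 0.2)); l2 <- exp(rnorm(1, 0, 0.2))
    u <- ogden_energy(stretch_state(l1, l2, 1 / (l1 * l2)), m)
    expect_gte(u, 0)
  }
  expect_identical(ogden_energy(stretch_state(1, 1, 1), m), 0)
})

test_that("invalid stretches and invalid models are rejected", {
  expect_error(stretch_state(0, 1, 1), class = "balloonmech_invalid_input")
  expect_error(stretch_state(-1, 1, 1), class = "balloonmech_invalid_input")
  expect_error(ogden_model(mu = c(-2, 1), alpha = c(2, 2)),
               class = "balloonmech_invalid_input")  # sum(mu) <= 0
  expect_error(ogden_model(mu = 1, alpha = 2, delta = -1),
               class = "balloonmech_invalid_input")
  expect_error(ogden_uniaxial_stress(-0.5, table2),
               class = "balloonmech_invalid_input")
})

test_that("uniaxial stress reduces to the neo-Hookean closed form for N=1, alpha=2", {
  for (mu in c(0.7, 3)) {
    m <- ogden_model(mu = mu, alpha = 2)
    lam <- c(0.8, 1, 1.1, 1.6, 2.4)
    expect_equal(ogden_uniaxial_stress(lam, m), mu * (lam^2 - 1 / lam),
                 tolerance = 1e-12)
  }
  expect_equal(ogden_uniaxial_stress(1, table2), 0)
  expect_equal(ogden_uniaxial_stress(1, table2, "nominal"), 0)
})

test_that("initial tangent modulus of the nominal stress is 3*sum(mu)", {
  for (m in list(table2, soft_ogden)) {
    h <- 1e-6
    slope <- (ogden_uniaxial_stress(1 + h, m, "nominal") -
              ogden_uniaxial_stress(1 - h, m, "nominal")) / (2 * h)
    expect_equal(slope, 3 * sum(m$mu), tolerance = 1e-6)
  }
})

test_that("uniaxial stress is the derivative of the energy along the incompressible uniaxial path", {
  # nominal stress = d/d(lambda) of U(lambda, lambda^-1/2, lambda^-1/2)
  path_energy <- function(l, m) ogden_energy(stretch_state(l, l^-0.5, l^-0.5), m)
  for (m in list(table2, soft_ogden)) {
    for (lam in c(0.95, 1.05, 1.10)) {
      h <- 1e-6 * lam
      fd <- (path_energy(lam + h, m) - path_energy(lam - h, m)) / (2 * h)
      expect_equal(ogden_uniaxial_stress(lam, m, "nominal"), fd,
                   tolerance = 1e-6)
    }
  }
})

test_that("membrane stresses are consistent with the plane-stress energy derivative", {
  m <- table2
  for (lt in c(1.02, 1.1)) {
    lm <- 1.03
    h <- 1e-6
    u <- function(a, b) {
      e <- 0
      for (i in 1:m$N)
        e <- e + 2 * m$mu[i] / m$alpha[i]^2 *
          (a^m$alpha[i] + b^m$alpha[i] + (a * b)^(-m$alpha[i]) - 3)
      e
    }
    st_fd <- lt * (u(lm, lt + h) - u(lm, lt - h)) / (2 * h)
    expect_equal(ogden_membrane_stress(lm, lt, m)$sigma_t, st_fd,
                 tolerance = 1e-6)
  }
})

test_that("shipped balloon coefficients have a positive initial shear modulus", {
  m <- balloon_ogden_coefficients()
  expect_equal(m$N, 3L)
  expect_gt(sum(m$mu), 0)
  expect_equal(m$delta[2:3], c(0, 0))
  expect_equal(m$poisson, 0.45)
  # constructor validation would reject a sign-flipped set
  expect_error(ogden_model(-m$mu, m$alpha), class = "balloonmech_invalid_input")
})

test_that("fit_ogden reproduces the generating stress curve on noiseless data", {
  eps <- seq(0, 0.12, by = 0.003)
  truth <- soft_ogden
  crv <- stress_strain_curve(eps, ogden_uniaxial_stress(1 + eps, truth, "nominal"))
  fit <- fit_ogden(crv, N = 2)
  lam_chk <- seq(1.001, 1.12, length.out = 60)
  s_true <- ogden_uniaxial_stress(lam_chk, truth, "nominal")
  s_fit <- ogden_uniaxial_stress(lam_chk, fit, "nominal")
  expect_lt(max(abs(s_fit - s_true)) / max(abs(s_true)), 1e-6)
  expect_gt(sum(fit$mu), 0)
  expect_true(is.finite(attr(fit, "fit")$residual_norm))
})

test_that("fit_ogden recovers the small-strain modulus of linear-elastic data", {
  E <- 600
  eps <- seq(0, 0.02, by = 0.0005)
  crv <- stress_strain_curve(eps, E * eps)
  fit <- fit_ogden(crv, N = 1)
  expect_equal(3 * sum(fit$mu), E, tolerance = 0.01)
})

test_that("fit_ogden is invariant to uniform stress rescaling", {
  eps <- seq(0, 0.1, by = 0.004)
  s <- ogden_uniaxial_stress(1 + eps, soft_ogden, "nominal")
  f1 <- fit_ogden(stress_strain_curve(eps, s), N = 2)
  f2 <- fit_ogden(stress_strain_curve(eps, 1000 * s), N = 2)
  lam <- seq(1.01, 1.1, length.out = 20)
  expect_equal(1000 * ogden_uniaxial_stress(lam, f1, "nominal"),
               ogden_uniaxial_stress(lam, f2, "nominal"),
               tolerance = 1e-5)
})

test_that("fit_ogden rejects under-determined problems", {
  crv <- stress_strain_curve(c(0, 0.05, 0.1), c(0, 10, 25))
  expect_error(fit_ogden(crv, N = 3), class = "balloonmech_fit_error")
})

test_that("isotropy deviation is zero for identical curves and matches a constructed offset", {
  eps <- seq(0, 0.12, by = 0.004)
  s <- ogden_uniaxial_stress(1 + eps, table2, "nominal")
  a <- stress_strain_curve(eps, s, "longitudinal")
  expect_identical(check_isotropy(a, a), 0)
  b <- stress_strain_curve(eps, 1.05 * s, "circumferential")
  # |1.05 s - s| / max = 0.05/1.05
  expect_equal(check_isotropy(a, b), 0.05 / 1.05, tolerance = 1e-9)
  short <- stress_strain_curve(eps[eps < 0.05], s[eps < 0.05])
  expect_error(check_isotropy(a, short), class = "balloonmech_invalid_input")
})

test_that("residual strain is zero for an elastic cycle and recovers constructed offsets", {
  elastic <- gen_uniaxial(soft_ogden, cycles = 1, residual_offsets = 0,
                          noise = noise_spec(seed = 1))
  expect_lt(abs(residual_strain(elastic)), 1e-4)

  one <- gen_uniaxial(soft_ogden, cycles = 1, residual_offsets = 0.03,
                      noise = noise_spec(seed = 1))
  expect_equal(residual_strain(one), 0.03, tolerance = 0.01)

  offs <- seq(0.03, 0.05, length.out = 10)
  ten <- gen_uniaxial(soft_ogden, cycles = 10, noise = noise_spec(seed = 2))
  rec <- residual_strain(ten)
  expect_length(rec, 10)
  expect_equal(rec, offs, tolerance = 0.01)
  expect_true(all(rec >= 0.029 & rec <= 0.051))   # the observed 3-5 % band
})

test_that("residual strain errors when unloading never reaches zero stress", {
  crv <- stress_strain_curve(c(0, 0.05, 0.1, 0.08), c(0, 20, 50, 30),
                             cycle = rep(1L, 4))
  expect_error(residual_strain(crv), class = "balloonmech_invalid_input")
})

test_that("material JSON and stress-strain CSV round-trip", {
  tf <- tempfile(fileext = ".json")
  write_material_json(table2, tf)
  m2 <- read_material_json(tf)
  expect_equal(m2$mu, table2$mu)
  expect_equal(m2$alpha, table2$alpha)
  expect_equal(m2$units, "MPa")

  tc <- tempfile(fileext = ".csv")
  eps <- seq(0, 0.1, 0.01)
  utils::write.csv(data.frame(strain = eps, stress_MPa = 500 * eps), tc,
                   row.names = FALSE)
  crv <- read_stress_strain_csv(tc)
  expect_s3_class(crv, "stress_strain_curve")
  expect_equal(nrow(crv), length(eps))
})
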