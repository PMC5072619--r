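# ---- dimensionless constants ----------------------------------------------

test_that("scaling constant A has its closed-form anchors and limits", {
  expect_equal(scaling_constant_A(2), pi^2, tolerance = 1e-14)
  # frozen from a 25-digit evaluation of pi^(5/3) Gamma(5/3) sin(pi/3)
  expect_equal(scaling_constant_A(3), 5.26840296480899207, tolerance = 1e-14)
  # vanishes monotonically toward the d_f -> 1 boundary (like sin(pi/d_f))
  dfs <- c(1 + 1e-6, 1.001, 1.01, 1.05, 1.2)
  vals <- vapply(dfs, scaling_constant_A, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(vals[1], 1e-3)
  expect_error(scaling_constant_A(1), "d_f")
  expect_error(scaling_constant_A(3.2), "d_f")
})

test_that("MSD constant B matches closed form and the mode-sum prefactor", {
  expect_equal(msd_constant_B(2, 1), sqrt(pi), tolerance = 1e-14)
  expect_equal(msd_constant_B(1.64, 0.8), 1.56108804090021408,
               tolerance = 1e-14)
  # independent oracle: extract the short-time prefactor from the numerical
  # mode sum (exp-approx kernel, deep asymptotic regime) and compare with
  # 2 B / (A Gamma(1+alpha)); fixes the grouping of the Gamma factors
  for (par in list(c(0.8, 1.64), c(0.9, 2.62), c(1, 2), c(0.6, 3))) {
    a <- par[1]; d_f <- par[2]
    m <- fractal_domain_model(a, d_f, 5000, 0.3)
    tau <- relaxation_time(m)
    t0 <- 1e-7 * tau
    num <- msd_mode_sum(m, t0, max_modes = 2e6, kernel = "exp_approx")
    pred <- 2 * msd_constant_B(d_f, a) * m$r_rms^2 /
      (scaling_constant_A(d_f) * gamma(1 + a)) *
      (t0 / tau)^(2 * a / (2 + d_f))
    expect_equal(num / pred, 1, tolerance = 0.01,
                 label = sprintf("prefactor a=%g df=%g", a, d_f))
  }
})

test_that("apparent-diffusion constant C is positive, continuous and nearly alpha-independent", {
  grid_df <- seq(1.2, 3, length.out = 20)
  for (a in c(0.6, 0.8, 1)) {
    v <- vapply(grid_df, function(d) dapp_constant_C(d, a), numeric(1))
    expect_true(all(is.finite(v) & v > 0))
    expect_true(all(abs(diff(v)) < 0.2))   # no jumps on a fine grid
  }
  # alpha in [0.6, 1] moves C by less than 20% at fixed d_f
  for (d_f in c(1.5, 2, 2.5, 3)) {
    v <- vapply(seq(0.6, 1, by = 0.1), function(a) dapp_constant_C(d_f, a),
                numeric(1))
    expect_lt(max(v) / min(v) - 1, 0.2)
  }
})

# ---- normal modes ----------------------------------------------------------

test_that("mode variances scale as the theory dictates", {
  m <- fractal_domain_model(0.8, 2, 1000, 0.3)
  # exponent -1 - 2/d_f = -2 at d_f = 2: doubling p quarters the variance
  expect_equal(mode_variance(m, 2) / mode_variance(m, 1), 1 / 4,
               tolerance = 1e-14)
  m2 <- fractal_domain_model(0.8, 2, 1000, 0.6)
  expect_equal(mode_variance(m2, 1:5), 4 * mode_variance(m, 1:5),
               tolerance = 1e-14)
  expect_true(all(diff(mode_variance(m, 1:50)) < 0))
  expect_error(mode_variance(m, 0), "center of mass")
})

test_that("mode stiffness obeys equipartition and the Rouse spectrum", {
  m <- fractal_domain_model(0.8, 2.3, 2000, 0.25)
  p <- 1:40
  expect_equal(mode_stiffness(m, p) * mode_variance(m, p),
               rep(3 / (2 * m$n_nucleosomes), length(p)), tolerance = 1e-12)
  expect_identical(mode_stiffness(m, 0), 0)
  rouse <- fractal_domain_model(1, 2, 1000, 0.3)
  k <- mode_stiffness(rouse, p)
  expect_equal(k / k[1], p^2, tolerance = 1e-12)
})

test_that("mode correlation decays from the variance, faster for higher p", {
  m <- interior_model()
  expect_equal(mode_correlation(m, 3, 0), mode_variance(m, 3))
  t <- c(0.1, 0.5, 2)
  c1 <- mode_correlation(m, 1, t) / mode_variance(m, 1)
  c2 <- mode_correlation(m, 2, t) / mode_variance(m, 2)
  expect_true(all(c2 < c1))
  expect_true(all(diff(mode_correlation(m, 1, seq(0, 5, by = 0.25))) < 0))
  # alpha = 1: exact exponential decay with rate p^(1+2/d_f)/tau
  r <- fractal_domain_model(1, 2, 1000, 0.3)
  tau <- relaxation_time(r)
  expect_equal(mode_correlation(r, 2, t),
               mode_variance(r, 2) * exp(-2^2 * t / tau), tolerance = 1e-12)
})

test_that("relaxation time matches the reference estimate and scales linearly at alpha = 1", {
  # interior fit, alpha = 0.8: published value 4.65 s
  est <- estimate_domain(power_law_fit(0.018, 0.44), alpha = 0.8)
  m <- fractal_domain_model(0.8, est$d_f, 5000, est$r_cd_nm / 1000)
  expect_equal(relaxation_time(m), 4.65, tolerance = 1e-3)
  # alpha = 1: tau is linear in N R^2 / (3 A D_EGFP)
  m1 <- fractal_domain_model(1, 2.5, 1000, 0.2)
  m2 <- fractal_domain_model(1, 2.5, 2000, 0.2)
  expect_equal(relaxation_time(m2) / relaxation_time(m1), 2,
               tolerance = 1e-12)
})

# ---- MSD curves ------------------------------------------------------------

test_that("center-of-mass MSD is an exact power law with exponent alpha", {
  m <- interior_model(alpha = 0.8)
  tau <- relaxation_time(m)
  expect_identical(com_msd(m, 0), 0)
  expect_equal(com_msd(m, tau),
               2 * m$r_rms^2 / (scaling_constant_A(m$d_f) * gamma(1.8)),
               tolerance = 1e-12)
  t <- 10^seq(-2, 1, length.out = 7)
  slope <- diff(log(com_msd(m, t))) / diff(log(t))
  expect_equal(slope, rep(0.8, 6), tolerance = 1e-12)
})

test_that("asymptotic internal MSD carries exponent 2 alpha / (2 + d_f) and equals D_app t^beta", {
  for (par in list(c(0.7, 1.8), c(0.9, 2.09), c(1, 3))) {
    m <- fractal_domain_model(par[1], par[2], 5000, 0.3)
    t <- 10^seq(-3, -1, length.out = 9)
    v <- internal_msd_asymptotic(m, t)
    slope <- diff(log(v)) / diff(log(t))
    beta <- subdiffusion_exponent(par[1], par[2])
    expect_equal(slope, rep(beta, 8), tolerance = 1e-12)
    expect_equal(v, apparent_diffusion_coefficient(m) * t^beta,
                 tolerance = 1e-12)
  }
})

test_that("subdiffusion exponent anchors: fractal globule, Rouse, hydrodynamic variant", {
  expect_equal(subdiffusion_exponent(1, 3), 0.4)
  expect_equal(subdiffusion_exponent(1, 2), 0.5)
  expect_equal(subdiffusion_exponent(0.9, 1.5, hydrodynamics = TRUE), 0.6)
  expect_equal(subdiffusion_exponent(0.9, 2.8, hydrodynamics = TRUE), 0.6)
})

test_that("mode-sum MSD: zero at t = 0, equilibrium plateau, correct short-time exponent", {
  m <- fractal_domain_model(0.8, 2.2, 800, 0.25)
  expect_identical(msd_mode_sum(m, 0, max_modes = 100), 0)
  expect_identical(msd_mode_sum(m, 0, max_modes = 100, include_com = TRUE), 0)
  # plateau (CoM excluded) -> 4 sum <X_p^2>
  tau <- relaxation_time(m)
  P <- 2000
  plateau <- msd_mode_sum(m, 1e4 * tau, max_modes = P)
  expect_equal(plateau, 4 * sum(mode_variance(m, 1:P)), tolerance = 1e-3)
  # short-time finite-difference log-log slope -> 2 alpha / (2 + d_f)
  t <- tau * 10^c(-6, -5.9)
  v <- msd_mode_sum(m, t, max_modes = 2e5, kernel = "exp_approx")
  slope <- diff(log(v)) / diff(log(t))
  expect_equal(slope, subdiffusion_exponent(m$alpha, m$d_f), tolerance = 0.02)
})

test_that("mode-sum warns when truncation cannot support the requested time", {
  m <- fractal_domain_model(0.8, 2.2, 800, 0.25)
  tau <- relaxation_time(m)
  expect_warning(msd_mode_sum(m, 1e-4 * tau, max_modes = 5), "truncation")
  expect_silent(msd_mode_sum(m, 10 * tau, max_modes = 3000))
})

test_that("mode sum converges to the closed-form asymptotic law deep in the short-time regime", {
  # the closed form replaces the mode sum by an integral; the discrepancy
  # shrinks as t/tau decreases (more modes relaxed). Deep in the regime the
  # two routes agree to ~1%; at the upper end of the experimental window the
  # integral approximation itself is 5-20% off (documented in the vignette).
  for (par in list(c(0.8, 1.64), c(0.9, 2.09), c(1, 2.62))) {
    m <- fractal_domain_model(par[1], par[2], 5000, 0.3)
    tau <- relaxation_time(m)
    t <- tau * 10^seq(-7, -6, length.out = 4)
    num <- msd_mode_sum(m, t, max_modes = 2e6, kernel = "exp_approx")
    expect_equal(num / internal_msd_asymptotic(m, t), rep(1, 4),
                 tolerance = 0.015,
                 label = sprintf("a=%g df=%g", par[1], par[2]))
  }
})

test_that("Rouse limit: alpha = 1, d_f = 2 reproduces the classical intermediate-regime MSD", {
  # Doi-Edwards: MSD(t) = sqrt(12 k_BT b^2 t / (pi zeta)) with bead
  # diffusivity D = k_BT/zeta = D_EGFP/4
  m <- fractal_domain_model(1, 2, 4000, 0.3)
  D_bead <- m$d_egfp / 4
  t <- relaxation_time(m) * 10^seq(-7, -5, length.out = 5)
  classical <- sqrt(12 * D_bead * m$b_eff^2 * t / pi)
  expect_equal(internal_msd_asymptotic(m, t), classical, tolerance = 1e-10)
})

test_that("predict() dispatches the three theoretical curves", {
  m <- interior_model()
  t <- c(0.05, 0.1)
  expect_identical(predict(m, t), internal_msd_asymptotic(m, t))
  expect_identical(predict(m, t, type = "com"), com_msd(m, t))
  expect_equal(predict(m, t, type = "mode_sum", max_modes = 1000),
               msd_mode_sum(m, t, max_modes = 1000))
})

test_that("model constructor validates its domain", {
  expect_error(fractal_domain_model(0, 2, 100, 0.3), "alpha")
  expect_error(fractal_domain_model(0.8, 1, 100, 0.3), "d_f")
  expect_error(fractal_domain_model(0.8, 3.5, 100, 0.3), "d_f")
  expect_error(fractal_domain_model(0.8, 2, 1, 0.3), "n_nucleosomes")
  expect_error(fractal_domain_model(0.8, 2, 100, -1), "r_rms")
  m <- fractal_domain_model(0.8, 2, 100, 0.3)
  expect_equal(m$b_eff, 0.3 / sqrt(100))
  expect_named(coef(m), c("alpha", "d_f", "n_nucleosomes", "r_rms", "d_egfp"))
})
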