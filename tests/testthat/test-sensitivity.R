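# Cheap analytic models keep the estimator tests fast; the thermal
# surrogate itself is exercised at the end and in the acceptance suite.

lin_model <- function(a) function(par) sum(a * par)

test_that("unit-hypercube mapping respects family, bounds, and moments", {
  dists <- list(u = param_distribution("u", 10, 0.05, "uniform"),
                n = param_distribution("n", 10, 0.05, "normal"),
                s = param_distribution("s", 10, 0.05, "normal_sd"))
  U <- matrix(seq(0, 1, length.out = 2001), ncol = 1)
  X <- map_unit_sample(cbind(U, U, U), dists)
  expect_true(all(X[, "u"] >= 9.5 - 1e-9 & X[, "u"] <= 10.5 + 1e-9))
  # normal: 95% half-width reading -> SD = 5%/1.96; truncated at 3 SD
  expect_true(all(abs(X[, "n"] - 10) <= 3 * 10 * 0.05 / 1.96 + 1e-9))
  expect_equal(unname(X[1001, "n"]), 10) # median maps to baseline
  # normal_sd: the half-width is the SD itself
  expect_true(max(abs(X[, "s"] - 10)) > 3 * 10 * 0.05 * 0.9)
})

test_that("MOAT zeroes ignored parameters and flags pure additivity", {
  dists <- list(x1 = param_distribution("x1", 1, 0.5, "uniform"),
                x2 = param_distribution("x2", 1, 0.5, "uniform"),
                x3 = param_distribution("x3", 1, 0.5, "uniform"))
  ignores_x3 <- function(par) 2 * par[["x1"]] + 0.5 * par[["x2"]]
  mo <- moat_screen(ignores_x3, dists, n_trajectories = 8, seed = 1)
  s <- mo$summary
  expect_equal(s$moat_mean[s$name == "x3"], 0)
  expect_equal(s$moat_sd[s$name == "x3"], 0)
  # additive linear model: elementary effects are constant
  expect_lt(max(s$moat_sd), 1e-9)
  expect_gt(s$moat_mean[s$name == "x1"], s$moat_mean[s$name == "x2"])
  # failing model evaluations drop trajectories with a warning
  flaky <- function(par) if (par[["x1"]] > 1.2) stop("boom") else par[["x1"]]
  expect_warning(mf <- moat_screen(flaky, dists, n_trajectories = 8, seed = 2),
                 "discarded")
  expect_lt(mf$n_trajectories, 8)
})

test_that("Sobol indices match analytic variance shares", {
  dists <- list(x1 = param_distribution("x1", 1, 0.9, "uniform"),
                x2 = param_distribution("x2", 1, 0.9, "uniform"))
  # single active parameter: everything attributed to it
  one <- sobol_indices(function(p) 3 * p[["x1"]], dists, n_base = 256,
                       seed = 4, n_boot = 40)
  s1 <- one$summary
  expect_equal(s1$first_order[1], 1, tolerance = 3 * one$mc_error + 0.02)
  expect_equal(s1$total[1], 1, tolerance = 3 * one$mc_error + 0.02)
  expect_equal(s1$first_order[2], 0, tolerance = 1e-9)
  expect_equal(s1$total[2], 0, tolerance = 1e-9)
  # additive model: shares proportional to a_i^2 (equal input variances)
  a1 <- 2; a2 <- 1
  add <- sobol_indices(function(p) a1 * p[["x1"]] + a2 * p[["x2"]], dists,
                       n_base = 512, seed = 5, n_boot = 40)
  expect_equal(add$summary$first_order[1], a1^2 / (a1^2 + a2^2),
               tolerance = 3 * add$mc_error + 0.02)
  expect_equal(add$summary$first_order[2], a2^2 / (a1^2 + a2^2),
               tolerance = 3 * add$mc_error + 0.02)
  # invariant: 0 <= Si <= Ti <= 1 within the Monte-Carlo error
  for (res in list(one, add)) {
    s <- res$summary; e <- 3 * res$mc_error + 0.02
    expect_true(all(s$first_order >= -e))
    expect_true(all(s$first_order <= s$total + e))
    expect_true(all(s$total <= 1 + e))
    expect_lte(sum(s$first_order), 1 + e)
  }
  expect_error(sobol_indices(function(p) 1, dists, n_base = 256, seed = 6),
               "variance")
  expect_error(sobol_indices(lin_model(1), dists, n_base = 64, seed = 6),
               "256")
})

test_that("bootstrap error shrinks as the sample grows", {
  dists <- list(x1 = param_distribution("x1", 1, 0.9, "uniform"),
                x2 = param_distribution("x2", 1, 0.9, "uniform"))
  f <- function(p) p[["x1"]]^2 + 0.3 * p[["x2"]]
  small <- sobol_indices(f, dists, n_base = 256, seed = 7, n_boot = 60)
  big <- sobol_indices(f, dists, n_base = 1024, seed = 7, n_boot = 60)
  expect_lt(big$mc_error, small$mc_error)
})

test_that("uncertainty propagation matches the quadratic delta method", {
  # dT = c H^2 with H ~ normal, relative SD 5% -> sd/mean ~ 10%
  dists <- list(H_gel = param_distribution("H_gel", 9.78, 0.05, "normal_sd"))
  quad <- function(par) 0.24 * par[["H_gel"]]^2
  pdf <- uncertainty_pdf(quad, dists, n_samples = 4000, seed = 8)
  expect_equal(pdf$sd / pdf$mean, 0.10, tolerance = 0.01 / 0.10)
  expect_true(all(pdf$kde$density >= 0))
  # the KDE integrates to one
  area <- sum(diff(pdf$kde$T) * (head(pdf$kde$density, -1) +
                                   tail(pdf$kde$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-2)
  # reproducibility
  pdf2 <- uncertainty_pdf(quad, dists, n_samples = 4000, seed = 8)
  expect_identical(pdf$samples, pdf2$samples)
})

test_that("the thermal surrogate closes its calibration and scales physically", {
  fn <- build_surrogate()
  base <- fn(c())
  expect_equal(base, 23, tolerance = 0.3 / 23)
  expect_equal(fn(c(H_gel = 9.78 * 1.05)) / base, 1.05^2, tolerance = 1e-9)
  # moving the probe outward lowers the read temperature
  expect_lt(fn(c(dist = 1.3e-3 * 1.05)), base)
  expect_gt(fn(c(dist = 1.3e-3 * 0.95)), base)
})

test_that("field amplitude dominates the thermal surrogate's sensitivity", {
  fn <- build_surrogate()
  dists <- thermal_input_distributions()
  mo <- moat_screen(fn, dists, n_trajectories = 6, seed = 31)
  s <- mo$summary
  expect_equal(s$name[which.max(s$moat_mean)], "H_gel")
  # steady-state inert parameters screen to exactly zero
  for (nm in c("sigma_gel", "cp_gel", "rho_gel")) {
    expect_equal(s$moat_mean[s$name == nm], 0)
  }
})
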