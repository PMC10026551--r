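#' Input parameter distribution
#'
#' Symmetric uncertainty around a baseline, read as a half-width fraction.
#' `"uniform"` spans `baseline * (1 +/- uncertainty)`; `"normal"` (default)
#' interprets the half-width as a 95% interval (SD = uncertainty/1.96),
#' truncated at +/- 3 SD; `"normal_sd"` reads the half-width directly as the
#' relative standard deviation (same truncation).
#'
#' @param name parameter name.
#' @param baseline baseline value, physical units.
#' @param uncertainty half-width as a fraction of baseline (> 0).
#' @param family `"normal"`, `"uniform"`, or `"normal_sd"`.
#' @return A `param_distribution` object.
#' @export
param_distribution <- function(name, baseline,
                               uncertainty,
                               family = c("normal", "uniform", "normal_sd")) {
  family <- match.arg(family)
  stopifnot(uncertainty > 0, baseline != 0)
  structure(list(name = name, baseline = baseline,
                 uncertainty = uncertainty, family = family),
            class = "param_distribution")
}

#' Default thermal-model input distributions
#'
#' The seven inputs of the phantom model with their baseline values and
#' uncertainty half-widths: field amplitude `H_gel` (9.78 kA/m, 5%), probe
#' distance `dist` (1.3 mm, 5%), gel thermal conductivity `k_gel`
#' (0.566 W/m/K, 1%), gel electrical conductivity `sigma_gel` (2.1 S/m,
#' 5%), specific heat `cp_gel` (3900 J/kg/K, 1%), density `rho_gel`
#' (960 kg/m^3, 1%), and surface film coefficient `h_conv`
#' (21 W/m^2/K, 5%).
#'
#' @param family distribution family passed to every parameter.
#' @param high_uncertainty widen `H_gel` and `dist` to 10% (the
#'   higher-experimental-uncertainty preset).
#' @return Named list of [param_distribution()] objects.
#' @export
thermal_input_distributions <- function(family = "normal",
                                        high_uncertainty = FALSE) {
  hw <- if (high_uncertainty) 0.10 else 0.05
  lst <- list(
    param_distribution("H_gel", 9.78, hw, family),
    param_distribution("dist", 1.3e-3, hw, family),
    param_distribution("k_gel", 0.566, 0.01, family),
    param_distribution("sigma_gel", 2.1, 0.05, family),
    param_distribution("cp_gel", 3900, 0.01, family),
    param_distribution("rho_gel", 960, 0.01, family),
    param_distribution("h_conv", 21, 0.05, family))
  names(lst) <- vapply(lst, `[[`, character(1), "name")
  lst
}

# Map unit-hypercube coordinates (one column per parameter) to physical
# values. Normal family truncates at +/-3 SD via clamped quantiles.
map_unit_sample <- function(U, dists) {
  stopifnot(ncol(U) == length(dists))
  X <- U
  for (i in seq_along(dists)) {
    d <- dists[[i]]
    X[, i] <- if (d$family == "uniform") {
      d$baseline * (1 + d$uncertainty * (2 * U[, i] - 1))
    } else {
      sd_frac <- if (d$family == "normal_sd") d$uncertainty else d$uncertainty / 1.96
      p3 <- stats::pnorm(3)
      u <- stats::qnorm(pmin(pmax(U[, i], 1 - p3), p3))
      d$baseline * (1 + sd_frac * u)
    }
  }
  colnames(X) <- vapply(dists, `[[`, character(1), "name")
  X
}

eval_model <- function(model_fn, X) {
  apply(X, 1, function(row) {
    tryCatch(model_fn(row), error = function(e) NA_real_)
  })
}

#' Morris elementary-effects (MOAT) screening
#'
#' Randomized one-at-a-time trajectories on a `levels`-level grid over the
#' unit hypercube, mapped through the input distributions. Each elementary
#' effect is the model change per unit-hypercube jump of one parameter; the
#' per-parameter mean of absolute effects ranks influence and the standard
#' deviation of effects flags nonlinearity/interaction. Trajectories whose
#' model evaluation fails are discarded with a warning.
#'
#' @param model_fn function taking a named parameter vector and returning a
#'   scalar output (probe temperature rise, kelvin).
#' @param dists named list of [param_distribution()] objects.
#' @param n_trajectories number of trajectories.
#' @param levels grid levels (even).
#' @param seed RNG seed (required).
#' @return A `moat_result`: data frame `summary` with `name`, `moat_mean`,
#'   `moat_sd`, plus `n_trajectories` used and `seed`.
#' @export
moat_screen <- function(model_fn, dists, n_trajectories = 20, levels = 4,
                        seed) {
  if (missing(seed)) stop("moat_screen requires an explicit seed")
  set.seed(seed)
  k <- length(dists)
  delta <- levels / (2 * (levels - 1))
  base_levels <- seq(0, 1 - delta, length.out = levels / 2 + (levels %% 2))
  base_levels <- seq(0, 1, length.out = levels)
  base_levels <- base_levels[base_levels + delta <= 1 + 1e-12]

  effects <- matrix(NA_real_, 0, k)
  dropped <- 0L
  for (tr in seq_len(n_trajectories)) {
    x0 <- base_levels[sample.int(length(base_levels), k, replace = TRUE)]
    ord <- sample.int(k)
    pts <- matrix(NA_real_, k + 1, k)
    pts[1, ] <- x0
    for (s in seq_len(k)) {
      pts[s + 1, ] <- pts[s, ]
      pts[s + 1, ord[s]] <- pts[s, ord[s]] + delta
    }
    y <- eval_model(model_fn, map_unit_sample(pts, dists))
    if (anyNA(y)) { dropped <- dropped + 1L; next }
    ee <- numeric(k)
    for (s in seq_len(k)) ee[ord[s]] <- (y[s + 1] - y[s]) / delta
    effects <- rbind(effects, ee)
  }
  if (dropped > 0) {
    warning(sprintf("%d of %d trajectories discarded due to model failures",
                    dropped, n_trajectories))
  }
  if (!nrow(effects)) stop("all trajectories failed")
  structure(list(
    summary = data.frame(
      name = vapply(dists, `[[`, character(1), "name"),
      moat_mean = apply(abs(effects), 2, mean),
      moat_sd = apply(effects, 2, stats::sd)),
    n_trajectories = nrow(effects), seed = seed),
    class = "moat_result")
}

#' Sobol variance decomposition (Saltelli sampling)
#'
#' First-order and total sensitivity indices by Saltelli's paired-matrix
#' scheme with Jansen estimators, `n_base * (k + 2)` model evaluations in
#' total. The Monte-Carlo error is the largest bootstrap standard error of
#' any index.
#'
#' @inheritParams moat_screen
#' @param n_base base sample size (>= 256).
#' @param n_boot bootstrap resamples for the error estimate.
#' @return A `sobol_result`: data frame `summary` with `name`,
#'   `first_order`, `total`, plus `n_samples`, `mc_error`, `seed`.
#' @export
sobol_indices <- function(model_fn, dists, n_base = 1024, seed,
                          n_boot = 100) {
  if (missing(seed)) stop("sobol_indices requires an explicit seed")
  if (n_base < 256) stop("n_base must be at least 256")
  set.seed(seed)
  k <- length(dists)
  A <- matrix(stats::runif(n_base * k), n_base, k)
  B <- matrix(stats::runif(n_base * k), n_base, k)
  fA <- eval_model(model_fn, map_unit_sample(A, dists))
  fB <- eval_model(model_fn, map_unit_sample(B, dists))
  fAB <- matrix(NA_real_, n_base, k)
  for (i in seq_len(k)) {
    ABi <- A; ABi[, i] <- B[, i]
    fAB[, i] <- eval_model(model_fn, map_unit_sample(ABi, dists))
  }
  ok <- stats::complete.cases(cbind(fA, fB, fAB))
  fA <- fA[ok]; fB <- fB[ok]; fAB <- fAB[ok, , drop = FALSE]
  V <- stats::var(c(fA, fB))
  if (!is.finite(V) || V <= 0) stop("degenerate model output: variance is zero")

  est <- function(idx) {
    v <- stats::var(c(fA[idx], fB[idx]))
    mu <- mean(c(fA[idx], fB[idx])) # centering keeps the estimator variance low
    si <- vapply(seq_len(k), function(i) {
      mean((fB[idx] - mu) * (fAB[idx, i] - fA[idx])) / v
    }, numeric(1))
    ti <- vapply(seq_len(k), function(i) {
      0.5 * mean((fA[idx] - fAB[idx, i])^2) / v
    }, numeric(1))
    c(si, ti)
  }
  point <- est(seq_along(fA))
  boot <- replicate(n_boot, est(sample.int(length(fA), replace = TRUE)))
  mc_error <- max(apply(boot, 1, stats::sd))

  structure(list(
    summary = data.frame(
      name = vapply(dists, `[[`, character(1), "name"),
      first_order = point[seq_len(k)],
      total = point[k + seq_len(k)]),
    n_samples = length(fA), mc_error = mc_error, seed = seed),
    class = "sobol_result")
}

#' Monte-Carlo uncertainty propagation with KDE summary
#'
#' Samples the input distributions, evaluates the model, and summarizes the
#' output with its mean, standard deviation, and a Gaussian-kernel density
#' estimate (Silverman bandwidth by default).
#'
#' @inheritParams moat_screen
#' @param n_samples Monte-Carlo sample size (>= 1000).
#' @param bandwidth KDE bandwidth: `"silverman"` or a numeric value.
#' @return A `pdf_summary`: `mean`, `sd`, `kde` (data frame `T`, `density`;
#'   `NULL` for a degenerate point mass), `samples`, `n_samples`, `seed`.
#' @export
uncertainty_pdf <- function(model_fn, dists, n_samples = 1000, seed,
                            bandwidth = "silverman") {
  if (missing(seed)) stop("uncertainty_pdf requires an explicit seed")
  if (n_samples < 1000) stop("n_samples must be at least 1000")
  set.seed(seed)
  k <- length(dists)
  U <- matrix(stats::runif(n_samples * k), n_samples, k)
  y <- eval_model(model_fn, map_unit_sample(U, dists))
  failed <- sum(is.na(y))
  if (failed > 0) warning(sprintf("%d of %d model evaluations failed", failed, n_samples))
  y <- y[!is.na(y)]
  m <- mean(y); s <- stats::sd(y)
  kde <- if (s > 0) {
    d <- if (identical(bandwidth, "silverman")) stats::density(y)
         else stats::density(y, bw = bandwidth)
    data.frame(T = d$x, density = d$y)
  } else NULL
  structure(list(mean = m, sd = s, kde = kde, samples = y,
                 n_samples = length(y), seed = seed),
            class = "pdf_summary")
}

#' Fast steady-state surrogate of the thermal model
#'
#' Returns a parameter-vector to probe-temperature-rise map used by the
#' sensitivity routines. Each evaluation performs one steady conduction
#' solve on a coarse grid with the sampled `k_gel` and `h_conv`, reads the
#' field at the sampled probe distance, and applies the exact quadratic
#' field scaling `(H / H_ref)^2` (so field variation needs no re-solve).
#' The source constant is calibrated on the surrogate's own grid, so the
#' baseline vector reproduces the calibration target rise. At steady state
#' the density, specific heat, and (with the calibrated wire source) the
#' gel's electrical conductivity have no influence; their indices come out
#' as exact zeros.
#'
#' @param geom a [phantom_geometry()] (its grid counts are replaced by the
#'   surrogate grid).
#' @param props a [material_props()] holding the baseline values.
#' @param target_dT calibration rise, kelvin.
#' @param H_ref calibration field, kA/m.
#' @param grid_nr,grid_nz surrogate grid (coarse for speed; must still resolve the wire).
#' @return A function mapping a named vector with any of `H_gel`, `dist`,
#'   `k_gel`, `sigma_gel`, `cp_gel`, `rho_gel`, `h_conv` to the steady probe
#'   temperature rise in kelvin.
#' @export
build_surrogate <- function(geom = phantom_geometry(),
                            props = material_props(),
                            target_dT = 23, H_ref = 9.78,
                            grid_nr = 18, grid_nz = 36) {
  sgeom <- phantom_geometry(gel_radius = geom$gel_radius,
                            gel_height = geom$gel_height,
                            wire_radius = geom$wire_radius,
                            wire_length = geom$wire_length,
                            probe_offset = geom$probe_offset,
                            grid_nr = grid_nr, grid_nz = grid_nz)
  sar <- calibrate_sar(sgeom, props, target_dT = target_dT, H_ref = H_ref)
  function(par) {
    get_par <- function(nm, default) if (nm %in% names(par)) par[[nm]] else default
    p <- material_props(rho_gel = get_par("rho_gel", props$rho_gel),
                        cp_gel = get_par("cp_gel", props$cp_gel),
                        k_gel = get_par("k_gel", props$k_gel),
                        sigma_gel = get_par("sigma_gel", props$sigma_gel),
                        h_conv = get_par("h_conv", props$h_conv),
                        T_inf = props$T_inf)
    dT_ref <- steady_probe_dT(sgeom, p, sar, H = sar$H_ref,
                              probe_offset = get_par("dist", sgeom$probe_offset))
    dT_ref * (get_par("H_gel", sar$H_ref) / sar$H_ref)^2
  }
}
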