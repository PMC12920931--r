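## In silico applications: mapping day-10 split ratios to day-11 initial
## densities, protocol simulation under the two media regimes, response
## variables, and split-ratio / media-change comparisons.

#' Construct a split-ratio -> day-11 density mapping
#'
#' Both day-11 densities are linear in the seeded fraction SR:
#' `n_a0 = kappa1 SR + kappa01`, `n_p0 = kappa2 SR + kappa02`.
#'
#' @param kappa1,kappa2 Slopes (cells mm^-2 per unit SR).
#' @param kappa01,kappa02 Intercepts (cells mm^-2).
#' @param valid_sr Interval of split ratios covered by the calibration data
#'   (default the experimental interval 1:5 to 1:2).
#' @return An object of class `afe_split_mapping`.
#' @export
split_mapping <- function(kappa1, kappa2, kappa01, kappa02,
                          valid_sr = c(0.2, 0.5)) {
  structure(
    list(kappa1 = kappa1, kappa2 = kappa2,
         kappa01 = kappa01, kappa02 = kappa02, valid_sr = valid_sr),
    class = "afe_split_mapping"
  )
}

#' The packaged split-ratio mapping coefficients
#'
#' Robust-regression estimates of the day-10 split ratio to day-11 density
#' mapping: 407.845, 140.941, -13.2916, -2.04044 cells mm^-2. The
#' slope-implied day-11 LP share is `kappa2 / (kappa1 + kappa2)` (about
#' 25.7%).
#'
#' @return An `afe_split_mapping`.
#' @export
default_split_mapping <- function() {
  split_mapping(407.845, 140.941, -13.2916, -2.04044)
}

#' Fit a split-ratio mapping by robust regression
#'
#' Fits each density as a linear function of SR with a Huber M-estimator
#' (tuning constant 1.345, via [MASS::rlm()]); falls back to ordinary least
#' squares if the M-estimation fails to converge.
#'
#' @param sr Split ratios (>= 2 distinct values).
#' @param n_a0,n_p0 Observed day-11 AFE and LP densities.
#' @return An `afe_split_mapping` with a `residuals` attribute.
#' @export
fit_split_mapping <- function(sr, n_a0, n_p0) {
  if (length(unique(sr)) < 2) stop("need at least 2 distinct split ratios")
  fit1 <- function(y) {
    f <- tryCatch(
      MASS::rlm(y ~ sr, psi = MASS::psi.huber, k = 1.345, maxit = 100),
      error = function(e) stats::lm(y ~ sr),
      warning = function(w) stats::lm(y ~ sr)
    )
    list(coef = stats::coef(f), resid = stats::residuals(f))
  }
  fa <- fit1(n_a0); fp <- fit1(n_p0)
  out <- split_mapping(unname(fa$coef[2]), unname(fp$coef[2]),
                       unname(fa$coef[1]), unname(fp$coef[1]),
                       valid_sr = range(sr))
  attr(out, "residuals") <- cbind(n_a0 = fa$resid, n_p0 = fp$resid)
  out
}

#' Map a split ratio to day-11 initial densities
#'
#' @param mapping An `afe_split_mapping`.
#' @param sr Seeded fraction (1:2 -> 0.5, 1:5 -> 0.2). Values outside the
#'   mapping's valid interval trigger an extrapolation warning.
#' @return Named vector `c(n_a = , n_p = )` in cells mm^-2.
#' @examples
#' map_sr(default_split_mapping(), 0.5)  # about (190.6, 68.4)
#' @export
map_sr <- function(mapping, sr) {
  stopifnot(inherits(mapping, "afe_split_mapping"))
  if (sr < mapping$valid_sr[1] || sr > mapping$valid_sr[2]) {
    warning("split ratio ", sr, " outside the calibrated interval [",
            mapping$valid_sr[1], ", ", mapping$valid_sr[2],
            "]; extrapolation is unreliable")
  }
  out <- c(n_a = mapping$kappa1 * sr + mapping$kappa01,
           n_p = mapping$kappa2 * sr + mapping$kappa02)
  if (any(out < 0)) {
    stop("mapped initial density is negative at SR = ", sr)
  }
  out
}

#' Inferred parameters of the selected exponential-Glu M1 model
#'
#' The packaged point estimates for the selected two-population model with
#' glucose-modulated exponential growth and additive errors. The reference
#' fit does not report the lactate reaction constants (lactate does not
#' feed back on growth under `env = "glu"`), so `V_l` and `cbar_l` here are
#' synthetic stand-ins that only shape the simulated lactate trace.
#'
#' @return List with `spec`, `theta`, `xi`.
#' @export
selected_m1_params <- function() {
  list(
    spec = model_spec("M1", "exponential", "glu", "additive"),
    theta = c(beta_a = 10.58, p_ap = 0.7975, delta_a = 2.002,
              beta_p = 1.178, delta_p = 3.869,
              V_g = 0.1257, V_l = 0.08, cbar_g = 398.5, cbar_l = 10,
              K_g = 29.56),
    xi = c(a_n = 89.77, a_c = 0.9900)
  )
}

#' Inferred parameters of the selected exponential-Glu M0 model
#'
#' As [selected_m1_params()] but for the one-population model; `V_l`/`cbar_l`
#' are again synthetic stand-ins.
#'
#' @return List with `spec`, `theta`, `xi`.
#' @export
selected_m0_params <- function() {
  list(
    spec = model_spec("M0", "exponential", "glu", "additive"),
    theta = c(beta_q = 8.209, delta_q = 1.710,
              V_g = 0.2059, V_l = 0.08, cbar_g = 662.4, cbar_l = 10,
              K_g = 52.70),
    xi = c(a_n = 145.8, a_c = 0.9732)
  )
}

#' Simulate a culture protocol
#'
#' Integrates the model from day-11 initial conditions over the horizon
#' with dense output; under `"MCH1"` glucose and lactate are fully reset to
#' the fresh-medium concentrations at every interior integer day (after
#' that day's measurement instant).
#'
#' @param spec,theta Model and structural parameters.
#' @param initial_state Named day-11 state.
#' @param media_change `"MCH0"` or `"MCH1"`.
#' @param horizon Days (default 4; longer horizons allowed).
#' @param media_conc Fresh-medium concentrations.
#' @param dt Output grid step (days).
#' @return An `afe_trajectory`.
#' @export
simulate_protocol <- function(spec, theta, initial_state,
                              media_change = "MCH0", horizon = 4,
                              media_conc = c(c_g = 17.5, c_l = 1.0),
                              dt = 0.02) {
  simulate_condition(spec, theta, initial_state,
                     times = seq(0, horizon, by = dt),
                     media_change = media_change, media_conc = media_conc)
}

#' Protocol response variables
#'
#' Evaluated at model day 4 (protocol day 15): the LP density `n_p4`, the
#' yield per input cell `n_p(4) / n_q(0)`, and the LP ratio
#' `n_p(4) / n_q(4)`.
#'
#' @param traj An `afe_trajectory` from an M1 model spanning day 4.
#' @param initial_state The day-11 state used for the simulation.
#' @return Named vector `c(n_p4, yield_per_input, lp_ratio)`.
#' @export
response_variables <- function(traj, initial_state) {
  if (max(traj$time) < 4 - 1e-9) stop("trajectory must span day 4")
  n_p4 <- trajectory_at(traj, 4, "n_p")
  n_a4 <- trajectory_at(traj, 4, "n_a")
  n_q0 <- if ("n_q" %in% names(initial_state)) {
    initial_state[["n_q"]]
  } else {
    initial_state[["n_a"]] + initial_state[["n_p"]]
  }
  c(n_p4 = n_p4,
    yield_per_input = n_p4 / n_q0,
    lp_ratio = n_p4 / (n_a4 + n_p4))
}

#' Sweep split ratios and media regimes
#'
#' For every (SR, regime) pair: map SR to day-11 densities, simulate the
#' protocol, and evaluate the response variables. Also reports the
#' MCH1/MCH0 ratio of each response per SR.
#'
#' @param spec,theta Model and structural parameters (M1).
#' @param mapping An `afe_split_mapping`.
#' @param sr_grid Split ratios inside the mapping's valid interval.
#' @param regimes Media regimes to compare.
#' @param media_conc Fresh-medium (and day-11) concentrations.
#' @param horizon Days.
#' @return List with elements `responses` (long data.frame: sr, regime,
#'   n_p4, yield_per_input, lp_ratio, day-1 LP density) and `ratios`
#'   (MCH1/MCH0 per response per SR, when both regimes are present).
#' @export
sweep_and_compare <- function(spec, theta, mapping, sr_grid,
                              regimes = c("MCH0", "MCH1"),
                              media_conc = c(c_g = 17.5, c_l = 1.0),
                              horizon = 4) {
  rows <- list()
  for (sr in sr_grid) {
    dens <- map_sr(mapping, sr)
    init <- c(dens, c_g = media_conc[["c_g"]], c_l = media_conc[["c_l"]])
    for (regime in regimes) {
      traj <- simulate_protocol(spec, theta, init, media_change = regime,
                                horizon = horizon, media_conc = media_conc)
      rv <- response_variables(traj, init)
      rows[[length(rows) + 1L]] <- data.frame(
        sr = sr, regime = regime,
        n_p4 = rv[["n_p4"]], yield_per_input = rv[["yield_per_input"]],
        lp_ratio = rv[["lp_ratio"]],
        n_p_day1 = trajectory_at(traj, 1, "n_p"),
        stringsAsFactors = FALSE
      )
    }
  }
  responses <- do.call(rbind, rows)
  ratios <- NULL
  if (all(c("MCH0", "MCH1") %in% regimes)) {
    a <- responses[responses$regime == "MCH0", ]
    b <- responses[responses$regime == "MCH1", ]
    b <- b[match(a$sr, b$sr), ]
    ratios <- data.frame(
      sr = a$sr,
      n_p4 = b$n_p4 / a$n_p4,
      yield_per_input = b$yield_per_input / a$yield_per_input,
      lp_ratio = b$lp_ratio / a$lp_ratio
    )
  }
  list(responses = responses, ratios = ratios)
}
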