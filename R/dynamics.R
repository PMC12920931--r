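## Model dynamics: per-capita growth factors, right-hand sides, and the
## condition integrator (compiled rhs via deSolve, media resets handled by
## piecewise integration so pre- and post-reset states are both reported).

.growth_code <- function(growth) match(growth, .afedyn_growths)
.env_code <- function(env) match(env, .afedyn_envs) - 1L

#' Per-capita growth multiplier
#'
#' Evaluates `F_env(c_g, c_l) * f_n(n_j)`: the product of the environmental
#' Michaelis-Menten factor (glucose promoting, lactate inhibiting) and the
#' density-dependent factor (1 for exponential, `1 - n/n_max` logistic,
#' `log(n_max/n)` Gompertz, with `n` floored at 1e-9 in the Gompertz log).
#'
#' @param growth,env Growth-law and environment names (see [model_spec()]).
#' @param n_j Own-population density (cells mm^-2), >= 0.
#' @param c_g,c_l Glucose and lactate concentrations (mmol L^-1), >= 0.
#' @param theta Named parameters; must carry `K_g`/`K_l`/`n_max` when active.
#' @return Dimensionless multiplier.
#' @examples
#' growth_multiplier("exponential", "glu", 100, 29.56, 0, c(K_g = 29.56)) # 0.5
#' @export
growth_multiplier <- function(growth, env, n_j, c_g, c_l, theta = c()) {
  growth <- match.arg(growth, .afedyn_growths)
  env <- match.arg(env, .afedyn_envs)
  if (any(c(n_j, c_g, c_l) < 0)) stop("densities and concentrations must be >= 0")
  f_n <- switch(growth,
    exponential = 1,
    logistic = {
      if (!"n_max" %in% names(theta)) stop("logistic growth requires n_max")
      1 - n_j / theta[["n_max"]]
    },
    gompertz = {
      if (!"n_max" %in% names(theta)) stop("Gompertz growth requires n_max")
      log(theta[["n_max"]] / pmax(n_j, 1e-9))
    }
  )
  f_env <- 1
  if (env %in% c("glu", "glulac")) {
    f_env <- f_env * c_g / (theta[["K_g"]] + c_g)
  }
  if (env %in% c("lac", "glulac")) {
    f_env <- f_env * theta[["K_l"]] / (theta[["K_l"]] + c_l)
  }
  unname(f_env * f_n)
}

#' Time derivatives of the active states
#'
#' Direct R evaluation of the model right-hand side (the integrator uses an
#' equivalent compiled version). For M0 the states are `(n_q, c_g, c_l)`;
#' for M1, `(n_a, n_p, c_g, c_l)` with the differentiation flux
#' `2 (1 - p_ap) b_a n_a` feeding the LP pool and glucose consumed by the
#' total population.
#'
#' @param spec An `afe_model_spec`.
#' @param state Named non-negative state vector.
#' @param theta Named structural parameters (see [structural_param_names()]).
#' @return Named vector of time derivatives (per day).
#' @export
rhs <- function(spec, state, theta) {
  check_params(spec, theta)
  if (any(is.na(state))) stop("state contains NA")
  if (any(state < 0)) stop("state must be non-negative")
  c_g <- state[["c_g"]]; c_l <- state[["c_l"]]
  mmk_g <- c_g / (c_g + theta[["cbar_g"]])
  mmk_l <- c_l / (c_l + theta[["cbar_l"]])
  if (spec$lineage == "M0") {
    n_q <- state[["n_q"]]
    f <- growth_multiplier(spec$growth, spec$env, n_q, c_g, c_l, theta)
    c(n_q = theta[["beta_q"]] * f * n_q - theta[["delta_q"]] * n_q,
      c_g = -theta[["V_g"]] * n_q * mmk_g,
      c_l = theta[["V_l"]] * n_q * mmk_l)
  } else {
    n_a <- state[["n_a"]]; n_p <- state[["n_p"]]
    b_a <- theta[["beta_a"]] *
      growth_multiplier(spec$growth, spec$env, n_a, c_g, c_l, theta)
    b_p <- theta[["beta_p"]] *
      growth_multiplier(spec$growth, spec$env, n_p, c_g, c_l, theta)
    p_a <- 2 * (1 - theta[["p_ap"]]) * b_a
    ntot <- n_a + n_p
    c(n_a = b_a * n_a - theta[["delta_a"]] * n_a - p_a * n_a,
      n_p = b_p * n_p - theta[["delta_p"]] * n_p + p_a * n_a,
      c_g = -theta[["V_g"]] * ntot * mmk_g,
      c_l = theta[["V_l"]] * ntot * mmk_l)
  }
}

.state_names <- function(spec) {
  if (spec$lineage == "M0") c("n_q", "c_g", "c_l") else c("n_a", "n_p", "c_g", "c_l")
}

.compiled_parms <- function(spec, theta) {
  gi <- function(nm, default = 1) {
    if (nm %in% names(theta)) theta[[nm]] else default
  }
  if (spec$lineage == "M0") {
    c(.growth_code(spec$growth), .env_code(spec$env),
      theta[["beta_q"]], theta[["delta_q"]],
      theta[["V_g"]], theta[["V_l"]], theta[["cbar_g"]], theta[["cbar_l"]],
      gi("K_g"), gi("K_l"), gi("n_max"))
  } else {
    c(.growth_code(spec$growth), .env_code(spec$env),
      theta[["beta_a"]], theta[["p_ap"]], theta[["delta_a"]],
      theta[["beta_p"]], theta[["delta_p"]],
      theta[["V_g"]], theta[["V_l"]], theta[["cbar_g"]], theta[["cbar_l"]],
      gi("K_g"), gi("K_l"), gi("n_max"))
  }
}

#' Integrate one culture condition
#'
#' Solves the model from time 0 (protocol day 11) to the horizon. Under
#' daily media change (`"MCH1"`) glucose and lactate are reset to the fresh
#' medium concentrations at every interior integer day, immediately *after*
#' that day's measurement instant: the returned trajectory carries two rows
#' at each reset time (pre-reset first, then post-reset), and observation
#' sampling uses the pre-reset row.
#'
#' @param spec An `afe_model_spec`.
#' @param theta Named structural parameters.
#' @param init_state Named initial state (`n_q`/`n_a`,`n_p`, `c_g`, `c_l`).
#' @param times Output times in days (0 and the horizon are added).
#' @param media_change `"MCH0"` (none) or `"MCH1"` (daily full replacement).
#' @param media_conc Fresh-medium concentrations, named `c_g`, `c_l`.
#' @param rtol,atol Integrator tolerances (lsoda).
#' @return A data.frame of class `afe_trajectory`: `time` plus state columns.
#' @export
simulate_condition <- function(spec, theta, init_state, times,
                               media_change = c("MCH0", "MCH1"),
                               media_conc = c(c_g = 17.5, c_l = 1.0),
                               rtol = 1e-8, atol = 1e-8) {
  media_change <- match.arg(media_change)
  check_params(spec, theta)
  snames <- .state_names(spec)
  if (length(setdiff(snames, names(init_state)))) {
    stop("initial state must contain: ", paste(snames, collapse = ", "))
  }
  y0 <- unlist(init_state[snames])
  horizon <- max(times)
  times <- sort(unique(c(0, times, horizon)))
  resets <- if (media_change == "MCH1") {
    seq_len(max(0L, ceiling(horizon) - 1L))
  } else {
    numeric(0)
  }
  resets <- resets[resets > 0 & resets < horizon]

  fn <- if (spec$lineage == "M0") "afedyn_derivs_m0" else "afedyn_derivs_m1"
  ifn <- if (spec$lineage == "M0") "afedyn_initmod_m0" else "afedyn_initmod_m1"
  parms <- .compiled_parms(spec, theta)

  bounds <- c(0, resets, horizon)
  segments <- vector("list", length(bounds) - 1L)
  y <- y0
  for (k in seq_along(segments)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    seg_times <- sort(unique(c(a, times[times > a & times < b], b)))
    sol <- suppressWarnings(
      deSolve::lsoda(y = y, times = seg_times, func = fn, parms = parms,
                     dllname = "afedyn", initfunc = ifn,
                     rtol = rtol, atol = atol))
    if (attr(sol, "istate")[1L] < 0) {
      stop("integration failed for spec ", spec_string(spec),
           " in segment [", a, ", ", b, "]")
    }
    sol <- as.data.frame(sol)
    names(sol) <- c("time", snames)
    segments[[k]] <- sol
    y <- unlist(sol[nrow(sol), snames])
    y[y < 0] <- 0
    if (b %in% resets) {
      y[["c_g"]] <- media_conc[["c_g"]]
      y[["c_l"]] <- media_conc[["c_l"]]
      post <- as.data.frame(as.list(c(time = b, y)))
      names(post) <- c("time", snames)
      segments[[k]] <- rbind(sol, post)
    }
  }
  for (k in seq_along(segments)[-1L]) {
    segments[[k]] <- segments[[k]][-1L, , drop = FALSE]
  }
  out <- do.call(rbind, segments)
  rownames(out) <- NULL
  structure(out, class = c("afe_trajectory", "data.frame"),
            spec = spec, media_change = media_change)
}

## Fast path used by the likelihood: integrate all conditions at once as
## stacked independent copies of the system (shared parameters), handling
## per-condition media resets piecewise.  Returns one matrix per condition
## (rows = requested times, columns = states, pre-reset values at resets).
.multi_integrate <- function(spec, theta, inits, times, mch1,
                             media_conc = c(c_g = 17.5, c_l = 1.0),
                             rtol = 1e-7, atol = 1e-7) {
  if (!is.list(media_conc)) media_conc <- rep(list(media_conc), length(inits))
  mc_g <- vapply(media_conc, `[[`, numeric(1), "c_g")
  mc_l <- vapply(media_conc, `[[`, numeric(1), "c_l")
  snames <- .state_names(spec)
  ns <- length(snames)
  nblk <- length(inits)
  y <- unlist(lapply(inits, function(s) unlist(s[snames])))
  times <- sort(unique(times))
  horizon <- max(times)
  resets <- if (any(mch1)) seq_len(max(0L, ceiling(horizon) - 1L)) else numeric(0)
  resets <- resets[resets < horizon]

  fn <- if (spec$lineage == "M0") "afedyn_derivs_m0m" else "afedyn_derivs_m1m"
  ifn <- if (spec$lineage == "M0") "afedyn_initmod_m0m" else "afedyn_initmod_m1m"
  parms <- c(nblk, .compiled_parms(spec, theta))

  out <- matrix(NA_real_, nrow = length(times), ncol = ns * nblk)
  if (any(times == 0)) out[times == 0, ] <- y
  bounds <- c(0, resets, horizon)
  cg_idx <- seq(0, nblk - 1L) * ns + match("c_g", snames)
  cl_idx <- seq(0, nblk - 1L) * ns + match("c_l", snames)
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    want <- times[times > a & times <= b]
    seg_times <- sort(unique(c(a, want, b)))
    ## solver-internal step-size chatter is suppressed; hard failures still
    ## surface through istate below
    sol <- suppressWarnings(
      deSolve::lsoda(y = y, times = seg_times, func = fn, parms = parms,
                     dllname = "afedyn", initfunc = ifn,
                     rtol = rtol, atol = atol))
    if (attr(sol, "istate")[1L] < 0) {
      stop("integration failed for spec ", spec_string(spec))
    }
    if (length(want)) {
      out[match(want, times), ] <- sol[match(want, seg_times), -1L]
    }
    y <- sol[nrow(sol), -1L]
    y[y < 0] <- 0
    if (b %in% resets) {
      y[cg_idx[mch1]] <- mc_g[mch1]
      y[cl_idx[mch1]] <- mc_l[mch1]
    }
  }
  lapply(seq_len(nblk), function(j) {
    m <- out[, (j - 1L) * ns + seq_len(ns), drop = FALSE]
    colnames(m) <- snames
    m
  })
}

#' Extract state values from a trajectory at given times
#'
#' @param traj An `afe_trajectory`.
#' @param times Times to extract (must be present in the trajectory).
#' @param observable State column name.
#' @param post_reset Use the post-reset row where a media reset duplicated
#'   the time point (default `FALSE`: pre-reset, the measurement instant).
#' @return Numeric vector of state values.
#' @export
trajectory_at <- function(traj, times, observable, post_reset = FALSE) {
  pick <- if (post_reset) function(i) i[length(i)] else function(i) i[1L]
  vapply(times, function(t) {
    idx <- which(abs(traj$time - t) < 1e-9)
    if (!length(idx)) stop("time ", t, " not in trajectory")
    traj[[observable]][pick(idx)]
  }, numeric(1))
}

#' Closed-form exponential/no-environment trajectory
#'
#' With exponential growth and no environmental coupling every population
#' obeys `n(t) = n0 exp((beta - delta) t)`; used as an integrator oracle.
#'
#' @param n0 Initial density.
#' @param beta,delta Proliferation and death rates (d^-1).
#' @param t Times (days).
#' @return Densities at `t`.
#' @export
closed_form_exponential <- function(n0, beta, delta, t) {
  n0 * exp((beta - delta) * t)
}
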