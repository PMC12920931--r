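## Identifiability: an analytic-symmetry witness plus a numerical local rank
## test on noiseless multi-condition sensitivities (structural screen), and
## profile-likelihood confidence intervals (practical identifiability).

#' Plausible reference parameters for any spec
#'
#' Generic in-bounds values used by the structural screen when no fitted
#' parameters are supplied; chosen so every active mechanism (growth,
#' crowding, environmental coupling, metabolite turnover) is dynamically
#' expressed over a 4-day trajectory.
#'
#' @param spec An `afe_model_spec`.
#' @return Named structural parameter vector.
#' @export
reference_params <- function(spec) {
  all <- c(beta_q = 1.2, delta_q = 0.4,
           beta_a = 1.5, p_ap = 0.8, delta_a = 0.5,
           beta_p = 0.6, delta_p = 0.7,
           V_g = 0.02, V_l = 0.015, cbar_g = 20, cbar_l = 10,
           K_g = 10, K_l = 50, n_max = 3000)
  all[structural_param_names(spec)]
}

.screen_outputs <- function(spec, theta, times, rtol = 1e-10, atol = 1e-10) {
  ## two MCH0 conditions at distinct seeding densities
  inits <- list(
    c(n_a = 190, n_p = 68, n_q = 258, c_g = 17.5, c_l = 1),
    c(n_a = 68, n_p = 26, n_q = 94, c_g = 17.5, c_l = 1)
  )
  cols <- .state_names(spec)
  out <- lapply(inits, function(init) {
    traj <- simulate_condition(spec, theta, init, times = times,
                               media_change = "MCH0",
                               rtol = rtol, atol = atol)
    as.matrix(traj[traj$time > 0, cols, drop = FALSE])
  })
  do.call(rbind, out)
}

#' Structural-identifiability screen
#'
#' Two-part screen on noiseless dense multi-condition trajectories:
#' (a) a symmetry witness — for exponential growth with no environmental
#' coupling, the rate translation `(beta, delta) -> (beta + c, delta + c)`
#' is verified numerically to leave every observable unchanged, so only
#' `beta - delta` is observable; (b) a numerical local test — the rank of
#' the Gram matrix of output sensitivities to log-parameters; a singular
#' value below `tol` times the largest marks a rank deficiency (a locally
#' unobservable parameter combination).
#'
#' @param spec An `afe_model_spec`.
#' @param theta Structural parameters at which to test (default
#'   [reference_params()]).
#' @param times Dense output grid (days).
#' @param h Relative step of the central finite differences.
#' @param tol Relative singular-value threshold for rank deficiency.
#' @return List of class `afe_screen`: `spec`, `structural`
#'   (`"identifiable"`/`"unidentifiable"`), `method` (`"witness"` or
#'   `"rank"`), `rank`, `deficiency`, `singular_values`, and for the
#'   witness case the invariant direction.
#' @export
structural_screen <- function(spec, theta = reference_params(spec),
                              times = seq(0, 4, length.out = 26),
                              h = 1e-3, tol = 1e-4) {
  check_params(spec, theta)
  pnames <- structural_param_names(spec)

  if (is_structurally_unidentifiable(spec)) {
    ## M0: only beta_q - delta_q reaches the output.  M1: the differentiation
    ## flux 2(1-p_ap) beta_a n_a ties the AFE pair to the observed LP inflow,
    ## but the LP pair enters only through beta_p - delta_p, so the exact
    ## translation symmetry lives on (beta_p, delta_p).
    beta_nm <- if (spec$lineage == "M0") "beta_q" else "beta_p"
    delta_nm <- if (spec$lineage == "M0") "delta_q" else "delta_p"
    g0 <- .screen_outputs(spec, theta, times)
    sh <- theta
    sh[[beta_nm]] <- sh[[beta_nm]] + 0.1
    sh[[delta_nm]] <- sh[[delta_nm]] + 0.1
    g1 <- .screen_outputs(spec, sh, times)
    rel <- max(abs(g1 - g0) / pmax(abs(g0), 1e-6))
    if (rel < 1e-6) {
      return(structure(
        list(spec = spec, structural = "unidentifiable", method = "witness",
             witness = c(beta_nm, delta_nm), witness_residual = rel,
             rank = NA_integer_, deficiency = NA_integer_,
             singular_values = NULL),
        class = "afe_screen"
      ))
    }
  }

  g0 <- .screen_outputs(spec, theta, times)
  scale_g <- apply(abs(g0), 2, max)
  S <- matrix(NA_real_, nrow = length(g0), ncol = length(pnames),
              dimnames = list(NULL, pnames))
  for (p in pnames) {
    up <- theta; up[[p]] <- theta[[p]] * (1 + h)
    dn <- theta; dn[[p]] <- theta[[p]] * (1 - h)
    gp <- .screen_outputs(spec, up, times)
    gm <- .screen_outputs(spec, dn, times)
    d <- (gp - gm) / (2 * h)                     # d g / d log(theta_p)
    S[, p] <- as.vector(sweep(d, 2, scale_g, "/"))
  }
  sv <- svd(S, nu = 0, nv = 0)$d
  deficiency <- sum(sv < tol * sv[1])
  structure(
    list(spec = spec,
         structural = if (deficiency > 0) "unidentifiable" else "identifiable",
         method = "rank", witness = NULL,
         rank = length(sv) - deficiency, deficiency = deficiency,
         singular_values = sv),
    class = "afe_screen"
  )
}

#' @export
print.afe_screen <- function(x, ...) {
  cat("<afe_screen>", spec_string(x$spec), "->", x$structural,
      "(", x$method, ")\n")
  if (!is.null(x$witness)) {
    cat("  invariant direction: +c on (",
        paste(x$witness, collapse = ", "), ")\n")
  } else {
    cat("  rank", x$rank, "of", length(x$singular_values),
        "( deficiency", x$deficiency, ")\n")
  }
  invisible(x)
}

## Re-optimize nuisance parameters at a fixed profiled value.
.reopt_nuisance <- function(objective, nuisance_start, maxit, reltol) {
  if (length(nuisance_start) == 0L) {
    return(list(par = nuisance_start, value = objective(numeric(0))))
  }
  if (length(nuisance_start) == 1L) {
    ## 1-d: golden-section around the warm start
    f <- function(x) objective(x)
    o <- optim(nuisance_start, f, method = "Brent",
               lower = nuisance_start - abs(nuisance_start) - 1,
               upper = nuisance_start + abs(nuisance_start) + 1)
    return(list(par = o$par, value = o$value))
  }
  o <- optim(nuisance_start, objective, method = "Nelder-Mead",
             control = list(maxit = maxit, reltol = reltol))
  list(par = o$par, value = o$value)
}

#' Profile a single parameter of a -2 log-likelihood surface
#'
#' Steps the profiled parameter outward from its maximum-likelihood value
#' in both directions, re-optimizing all other parameters warm-started from
#' the previous step. Stops at the threshold crossing
#' `PL < l_max - delta` (the endpoint is located by linear interpolation)
#' or at a bound (the corresponding interval side is marked open). Step
#' sizes double adaptively while the profile changes by less than
#' `min_drop`.
#'
#' @param objective Function of the full free-parameter vector returning
#'   `-2 l`.
#' @param mle Named MLE parameter vector.
#' @param parameter Name of the profiled parameter.
#' @param lower,upper Named bound vectors (same names as `mle`).
#' @param delta Log-likelihood drop defining the interval (default
#'   `qchisq(0.95, 1) / 2`, about 1.92: a 95% profile CI).
#' @param init_step Initial step (default 2% of `|mle|`, floored).
#' @param n_steps Maximum steps per direction.
#' @param min_drop Profile change (in l units) below which the step doubles.
#' @param nm_maxit,reltol Nuisance re-optimization controls.
#' @return An `afe_profile`: `parameter`, `psi` (grid), `pl` (profile
#'   log-likelihood), `l_max`, `threshold`, `ci`, `lower_open`,
#'   `upper_open`.
#' @export
profile_curve <- function(objective, mle, parameter, lower, upper,
                          delta = qchisq(0.95, 1) / 2,
                          init_step = NULL, n_steps = 20, min_drop = 0.1,
                          nm_maxit = 500, reltol = 1e-6) {
  stopifnot(parameter %in% names(mle))
  pidx <- match(parameter, names(mle))
  nuis_idx <- setdiff(seq_along(mle), pidx)
  loss_mle <- objective(mle)
  l_max <- -loss_mle / 2
  threshold <- l_max - delta
  if (is.null(init_step)) {
    init_step <- max(abs(mle[[pidx]]) * 0.02,
                     (upper[[parameter]] - lower[[parameter]]) * 1e-3)
  }

  pl_at <- function(psi, nuis_start) {
    obj_n <- function(nu) {
      par <- mle
      par[pidx] <- psi
      par[nuis_idx] <- nu
      objective(par)
    }
    o <- .reopt_nuisance(obj_n, nuis_start, nm_maxit, reltol)
    list(pl = -o$value / 2, nuis = o$par)
  }

  psi_grid <- mle[[pidx]]
  pl_grid <- l_max
  side <- list()
  for (dir in c(-1, 1)) {
    step <- init_step
    psi <- mle[[pidx]]
    nuis <- mle[nuis_idx]
    prev_pl <- l_max
    grid <- numeric(0); pls <- numeric(0)
    endpoint <- NA_real_
    open <- FALSE
    for (k in seq_len(n_steps)) {
      psi_next <- psi + dir * step
      at_bound <- FALSE
      if (psi_next <= lower[[parameter]]) {
        psi_next <- lower[[parameter]]; at_bound <- TRUE
      }
      if (psi_next >= upper[[parameter]]) {
        psi_next <- upper[[parameter]]; at_bound <- TRUE
      }
      res <- tryCatch(pl_at(psi_next, nuis), error = function(e) NULL)
      if (is.null(res)) {  # invalid grid point; shrink and retry once
        step <- step / 2
        next
      }
      grid <- c(grid, psi_next); pls <- c(pls, res$pl)
      nuis <- res$nuis
      if (res$pl < threshold) {
        ## bracketing: refine the crossing by bisection, then interpolate
        lo_psi <- psi; lo_pl <- prev_pl      # inside (pl >= threshold)
        hi_psi <- psi_next; hi_pl <- res$pl  # outside
        nu <- nuis
        for (bs in 1:5) {
          mid <- (lo_psi + hi_psi) / 2
          rm_ <- tryCatch(pl_at(mid, nu), error = function(e) NULL)
          if (is.null(rm_)) break
          grid <- c(grid, mid); pls <- c(pls, rm_$pl)
          nu <- rm_$nuis
          if (rm_$pl >= threshold) {
            lo_psi <- mid; lo_pl <- rm_$pl
          } else {
            hi_psi <- mid; hi_pl <- rm_$pl
          }
        }
        endpoint <- approx(c(lo_pl, hi_pl), c(lo_psi, hi_psi),
                           xout = threshold)$y
        break
      }
      if (at_bound) {
        open <- TRUE
        break
      }
      if (abs(prev_pl - res$pl) < min_drop) step <- step * 2
      prev_pl <- res$pl
      psi <- psi_next
      if (k == n_steps) open <- TRUE  # ran out of steps above threshold
    }
    side[[as.character(dir)]] <- list(grid = grid, pls = pls,
                                      endpoint = endpoint, open = open)
    psi_grid <- c(psi_grid, grid)
    pl_grid <- c(pl_grid, pls)
  }
  o <- order(psi_grid)
  lo <- side[["-1"]]; hi <- side[["1"]]
  structure(
    list(parameter = parameter, psi = psi_grid[o], pl = pl_grid[o],
         l_max = l_max, threshold = threshold, delta = delta,
         mle = mle[[pidx]],
         ci = c(lower = lo$endpoint, upper = hi$endpoint),
         lower_open = lo$open, upper_open = hi$open),
    class = "afe_profile"
  )
}

#' @export
print.afe_profile <- function(x, ...) {
  ci <- sprintf("(%s, %s)",
                if (x$lower_open) "open" else format(signif(x$ci[["lower"]], 4)),
                if (x$upper_open) "open" else format(signif(x$ci[["upper"]], 4)))
  cat("<afe_profile>", x$parameter, "mle", format(signif(x$mle, 4)),
      "95% CI", ci, "\n")
  invisible(x)
}

#' Profile likelihood for one parameter of a fitted model
#'
#' @param fit An `afe_fit`.
#' @param dataset The dataset the fit used.
#' @param parameter Free parameter to profile.
#' @param ... Passed to [profile_curve()].
#' @return An `afe_profile`.
#' @export
profile_fit <- function(fit, dataset, parameter, ...) {
  bounds <- fit$bounds
  mle <- c(fit$theta_hat, fit$xi_hat)[bounds$parameter]
  snames <- structural_param_names(fit$spec)
  enames <- error_param_names(fit$spec)
  objective <- function(par) {
    if (any(par < bounds$lower - 1e-12) || any(par > bounds$upper + 1e-12)) {
      return(Inf)
    }
    full <- c(setNames(par, bounds$parameter), fit$fixed)
    v <- tryCatch(
      neg2loglik(fit$spec, full[intersect(names(full), snames)],
                 full[intersect(names(full), enames)],
                 dataset, role = fit$role),
      error = function(e) Inf
    )
    if (is.finite(v)) v else Inf
  }
  profile_curve(objective, mle, parameter,
                lower = setNames(bounds$lower, bounds$parameter),
                upper = setNames(bounds$upper, bounds$parameter), ...)
}

#' Practical-identifiability filter over a shortlist
#'
#' Eliminates shortlisted specs with any open or flat parameter profile;
#' among the survivors picks the spec with the best (lowest) BIC.
#' Parameters whose closed interval contains zero are flagged
#' possibly-insignificant without eliminating the spec.
#'
#' @param profiles Named list (by spec string) of lists of `afe_profile`.
#' @param selection An `afe_selection` (for the BIC ordering).
#' @return List: `chosen` (spec string or `NA`), `eliminated`,
#'   `flags` (possibly-insignificant parameters per spec).
#' @export
practical_filter <- function(profiles, selection) {
  verdicts <- lapply(profiles, function(prs) {
    open <- vapply(prs, function(p) isTRUE(p$lower_open) || isTRUE(p$upper_open),
                   logical(1))
    flat <- vapply(prs, function(p) max(p$pl) - min(p$pl) < 1e-6, logical(1))
    zero <- vapply(prs, function(p) {
      !p$lower_open && !p$upper_open &&
        is.finite(p$ci[["lower"]]) && is.finite(p$ci[["upper"]]) &&
        p$ci[["lower"]] <= 0 && p$ci[["upper"]] >= 0
    }, logical(1))
    list(identifiable = !any(open | flat),
         flagged = vapply(prs[zero], function(p) p$parameter, character(1)))
  })
  ok <- names(verdicts)[vapply(verdicts, `[[`, logical(1), "identifiable")]
  eliminated <- setdiff(names(verdicts), ok)
  tab <- selection$table
  tab <- tab[tab$spec %in% ok, , drop = FALSE]
  chosen <- if (nrow(tab)) tab$spec[which.min(tab$bic)] else NA_character_
  list(chosen = chosen, eliminated = eliminated,
       flags = lapply(verdicts, `[[`, "flagged"))
}
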