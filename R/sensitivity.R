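## Variance-based global sensitivity analysis: Saltelli-type sampling with
## the Saltelli (2010) first-order and Jansen total-order estimators, and
## bootstrap confidence intervals.

#' Sobol indices of a scalar (or vector-valued) function
#'
#' Builds the Saltelli design A, B, AB_i (`n * (d + 2)` evaluations for `d`
#' inputs, uniform over the box), evaluates `f` row-wise, and estimates
#' first-order indices `S1_i = mean(B (AB_i - A)) / V` and total-order
#' indices `ST_i = mean((A - AB_i)^2) / (2 V)`.
#'
#' @param f Function of one numeric input vector returning a scalar or a
#'   fixed-length named numeric vector (multiple outputs).
#' @param lower,upper Input bounds (length d).
#' @param n Base sample size.
#' @param seed Optional seed.
#' @param n_boot Bootstrap resamples for CIs (0 disables).
#' @param conf Bootstrap confidence level.
#' @return An `afe_sobol`: data.frame `indices` with columns `output`,
#'   `parameter`, `S1`, `ST`, `S1_lo`, `S1_hi`, `ST_lo`, `ST_hi`, plus
#'   `n`, `n_evals`.
#' @examples
#' s <- sobol_saltelli(function(x) x[1] + 2 * x[2], c(0, 0), c(1, 1),
#'                     n = 256, seed = 1)
#' @export
sobol_saltelli <- function(f, lower, upper, n = 1024, seed = NULL,
                           n_boot = 100, conf = 0.95) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  scale_rows <- function(u) {
    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  }
  ## Latin-hypercube base matrices: same estimators as with plain Monte
  ## Carlo, with per-coordinate stratification as variance reduction
  A <- scale_rows(lhs::randomLHS(n, d))
  B <- scale_rows(lhs::randomLHS(n, d))
  eval_mat <- function(m) {
    out <- lapply(seq_len(nrow(m)), function(i) f(m[i, ]))
    do.call(rbind, out)
  }
  yA <- eval_mat(A)
  yB <- eval_mat(B)
  n_out <- ncol(yA)
  out_names <- colnames(yA)
  if (is.null(out_names)) out_names <- paste0("y", seq_len(n_out))
  pnames <- names(lower)
  if (is.null(pnames)) pnames <- paste0("x", seq_len(d))

  yAB <- vector("list", d)
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    yAB[[i]] <- eval_mat(ABi)
  }

  est <- function(idx) {
    res <- list()
    for (k in seq_len(n_out)) {
      ya <- yA[idx, k]; yb <- yB[idx, k]
      v <- var(c(ya, yb))
      for (i in seq_len(d)) {
        yab <- yAB[[i]][idx, k]
        res[[length(res) + 1L]] <- c(
          S1 = mean(yb * (yab - ya)) / v,
          ST = mean((ya - yab)^2) / (2 * v)
        )
      }
    }
    do.call(rbind, res)
  }
  point <- est(seq_len(n))
  key <- expand.grid(parameter = pnames, output = out_names,
                     stringsAsFactors = FALSE)
  indices <- data.frame(output = key$output, parameter = key$parameter,
                        S1 = point[, "S1"], ST = point[, "ST"],
                        stringsAsFactors = FALSE)
  if (n_boot > 0) {
    boots <- array(NA_real_, dim = c(nrow(indices), 2, n_boot))
    for (b in seq_len(n_boot)) {
      boots[, , b] <- est(sample.int(n, n, replace = TRUE))
    }
    alpha <- (1 - conf) / 2
    q <- apply(boots, c(1, 2), stats::quantile, probs = c(alpha, 1 - alpha))
    indices$S1_lo <- q[1, , 1]; indices$S1_hi <- q[2, , 1]
    indices$ST_lo <- q[1, , 2]; indices$ST_hi <- q[2, , 2]
  }
  structure(list(indices = indices, n = n, n_evals = n * (d + 2)),
            class = "afe_sobol")
}

#' @export
print.afe_sobol <- function(x, ...) {
  cat("<afe_sobol>", x$n_evals, "model evaluations ( base n =", x$n, ")\n")
  print(x$indices, digits = 3)
  invisible(x)
}

#' Saltelli base size under an evaluation budget
#'
#' Largest power of two `n` with `n (d + 2) <= budget` (a total-evaluation
#' reading of the sampling budget).
#'
#' @param d Number of inputs.
#' @param budget Total model-evaluation budget (default 40000).
#' @return Integer base sample size.
#' @export
sobol_base_n <- function(d, budget = 40000) {
  2^floor(log2(budget / (d + 2)))
}

.sobol_box <- function(theta, span) {
  stopifnot(span > 1)
  list(lower = theta / span, upper = theta * span)
}

#' Sobol indices of model outputs with respect to structural parameters
#'
#' Samples structural parameters uniformly over the per-parameter box
#' `[theta / span, theta * span]` (default span 1.1, i.e. the bracket
#' `[0.909, 1.10] theta`), integrates the condition once per sample, and
#' estimates first- and total-order indices of the requested state
#' observables at time `t`. Initial conditions are held fixed.
#'
#' @param spec An `afe_model_spec`.
#' @param theta Nominal (e.g. inferred) structural parameters; the box
#'   centre.
#' @param condition An `afe_condition` (default: split ratio 1:2, MCH0).
#' @param outputs State names (default `c("n_a", "n_p", "c_g")`).
#' @param t Evaluation time in days (default 4, i.e. 96 h).
#' @param span Multiplicative half-width of the box.
#' @param n Base sample size (default from [sobol_base_n()] at the 40000
#'   evaluation budget).
#' @param seed,n_boot Passed to [sobol_saltelli()].
#' @param max_fail_frac Abort if more than this fraction of integrations
#'   fail.
#' @return An `afe_sobol`.
#' @export
sobol_indices <- function(spec, theta,
                          condition = NULL,
                          outputs = c("n_a", "n_p", "c_g"),
                          t = 4, span = 1.1, n = NULL, seed = NULL,
                          n_boot = 100, max_fail_frac = 0.05) {
  check_params(spec, theta)
  pnames <- structural_param_names(spec)
  theta <- theta[pnames]
  if (is.null(condition)) {
    dens <- map_sr(default_split_mapping(), 0.5)
    condition <- condition("SR5_MCH0", 0.5, "MCH0",
                           c(dens, c_g = 17.5, c_l = 1.0))
  }
  if (is.null(n)) n <- sobol_base_n(length(pnames))
  box <- .sobol_box(theta, span)
  n_fail <- 0L
  f <- function(par) {
    th <- setNames(par, pnames)
    traj <- tryCatch(
      simulate_condition(spec, th, condition$initial_state, times = t,
                         media_change = condition$media_change,
                         media_conc = condition$media_conc,
                         rtol = 1e-6, atol = 1e-6),
      error = function(e) NULL
    )
    if (is.null(traj)) {
      n_fail <<- n_fail + 1L
      return(setNames(rep(NA_real_, length(outputs)), outputs))
    }
    setNames(vapply(outputs, function(o) trajectory_at(traj, t, o),
                    numeric(1)), outputs)
  }
  res <- sobol_saltelli(f, box$lower, box$upper, n = n, seed = seed,
                        n_boot = n_boot)
  if (n_fail > max_fail_frac * res$n_evals) {
    stop(n_fail, " of ", res$n_evals, " integrations failed")
  }
  res$condition <- condition$condition_id
  res$t <- t
  res
}

#' Total-order Sobol indices of the LP accumulation rate over time
#'
#' For each grid time, evaluates the instantaneous LP rate `dn_p/dt` along
#' the perturbed trajectories and estimates the total-order index of every
#' structural parameter.
#'
#' @param spec,theta,condition,span,seed As in [sobol_indices()] (M1 specs
#'   only).
#' @param times Evaluation grid (days).
#' @param n Base sample size (default 256: the time course trades sample
#'   size for time resolution).
#' @return Data.frame `time`, `parameter`, `ST`.
#' @export
sobol_timecourse <- function(spec, theta, times = seq(0.25, 4, by = 0.25),
                             condition = NULL, span = 1.1, n = 256,
                             seed = NULL) {
  if (spec$lineage != "M1") stop("LP rate time course requires an M1 spec")
  check_params(spec, theta)
  pnames <- structural_param_names(spec)
  theta <- theta[pnames]
  if (is.null(condition)) {
    dens <- map_sr(default_split_mapping(), 0.5)
    condition <- condition("SR5_MCH0", 0.5, "MCH0",
                           c(dens, c_g = 17.5, c_l = 1.0))
  }
  f <- function(par) {
    th <- setNames(par, pnames)
    traj <- simulate_condition(spec, th, condition$initial_state,
                               times = times,
                               media_change = condition$media_change,
                               media_conc = condition$media_conc,
                               rtol = 1e-6, atol = 1e-6)
    vapply(times, function(t) {
      st <- c(n_a = trajectory_at(traj, t, "n_a"),
              n_p = trajectory_at(traj, t, "n_p"),
              c_g = trajectory_at(traj, t, "c_g"),
              c_l = trajectory_at(traj, t, "c_l"))
      rhs(spec, st, th)[["n_p"]]
    }, numeric(1))
  }
  box <- .sobol_box(theta, span)
  res <- sobol_saltelli(f, box$lower, box$upper, n = n, seed = seed,
                        n_boot = 0)
  idx <- res$indices
  idx$time <- times[match(idx$output, paste0("y", seq_along(times)))]
  data.frame(time = idx$time, parameter = idx$parameter, ST = idx$ST,
             stringsAsFactors = FALSE)
}
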