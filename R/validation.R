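## Goodness of fit: pooled and per-class error metrics, prediction-band
## coverage of replicate means, leave-one-condition-out cross-validation,
## and the error-parameter correlation identity.

#' Pooled prediction-error metrics
#'
#' `RMSE = sqrt(mean((Z - g)^2))`, `NRMSE = RMSE / (max(Z) - min(Z))`,
#' `MAE = mean(|Z - g|)`, `ME = mean(Z - g)`.
#'
#' @param observed Measurements Z.
#' @param predicted Model means g (matched pairs).
#' @return Named vector `c(rmse, nrmse, mae, me)`.
#' @export
error_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  r <- observed - predicted
  rmse <- sqrt(mean(r^2))
  rng <- max(observed) - min(observed)
  if (rng == 0) stop("zero observed range: NRMSE undefined")
  c(rmse = rmse, nrmse = rmse / rng, mae = mean(abs(r)), me = mean(r))
}

## Predictions of a fitted (or given) model for every record of a dataset.
.predict_records <- function(spec, theta, dataset, role = NULL) {
  design <- attr(dataset, "design")
  d <- .dataset_records(dataset, spec$lineage, role)
  d$g <- NA_real_
  for (cid in unique(d$condition_id)) {
    i <- which(d$condition_id == cid)
    cond <- design_condition(design, cid)
    traj <- simulate_condition(spec, theta, cond$initial_state,
                               times = sort(unique(d$time_d[i])),
                               media_change = cond$media_change,
                               media_conc = cond$media_conc)
    d$g[i] <- mapply(function(t, obs) trajectory_at(traj, t, obs),
                     d$time_d[i], d$observable[i])
  }
  d
}

#' Validate a fitted model on a hold-out role
#'
#' Computes the error metrics pooled within each observable class (the
#' mixed units of densities and concentrations forbid pooling their
#' ranges).
#'
#' @param fit An `afe_fit`.
#' @param dataset Role-tagged dataset.
#' @param role Hold-out role (default `"validation"`).
#' @return A data.frame with one row per class (`density`,
#'   `concentration`): `rmse`, `nrmse`, `mae`, `me`, `n`.
#' @export
validate_fit <- function(fit, dataset, role = "validation") {
  d <- .predict_records(fit$spec, fit$theta_hat, dataset, role)
  d$class <- .observable_class(d$observable)
  out <- lapply(split(d, d$class), function(x) {
    m <- error_metrics(x$value, x$g)
    data.frame(class = x$class[1], rmse = m[["rmse"]], nrmse = m[["nrmse"]],
               mae = m[["mae"]], me = m[["me"]], n = nrow(x))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Prediction-band coverage of replicate means
#'
#' For every (condition, time, observable) cell, the mean of the replicate
#' measurements is compared against the model band `g +/- k * eps` (model
#' mean plus/minus `k` model standard deviations from the error model;
#' default `k = 1`). Reports the covered fraction separately for densities
#' and concentrations.
#'
#' @param spec,theta,xi Model and parameters.
#' @param dataset Dataset with replicate records.
#' @param role Optional role restriction.
#' @param k Band half-width in model standard deviations.
#' @return Data.frame `class`, `covered`, `n_cells`, `fraction`.
#' @export
coverage <- function(spec, theta, xi, dataset, role = NULL, k = 1) {
  d <- .predict_records(spec, theta, dataset, role)
  d$class <- .observable_class(d$observable)
  key <- interaction(d$condition_id, d$time_d, d$observable, drop = TRUE)
  cells <- lapply(split(d, key), function(x) {
    if (!nrow(x)) return(NULL)
    g <- x$g[1]
    eps <- error_sd(spec$error_model, xi, g, x$class[1])
    data.frame(class = x$class[1],
               inside = abs(mean(x$value) - g) <= k * eps)
  })
  cells <- do.call(rbind, cells)
  out <- lapply(split(cells, cells$class), function(x) {
    data.frame(class = x$class[1], covered = sum(x$inside),
               n_cells = nrow(x), fraction = mean(x$inside))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## Subset a dataset's rows, preserving its attributes.
.subset_dataset <- function(dataset, keep) {
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("design", "spec", "theta", "xi", "seed")) {
    attr(out, a) <- attr(dataset, a)
  }
  class(out) <- class(dataset)
  out
}

#' Leave-one-condition-out cross-validation
#'
#' One fold per experimental condition: the model is recalibrated on all
#' records of the remaining conditions (all replicates) and the held-out
#' condition's population records are scored with [error_metrics()]
#' (NRMSE normalized by the held-out population range).
#'
#' @param spec An `afe_model_spec`.
#' @param dataset Dataset covering at least 2 conditions.
#' @param bounds,n_starts,control,fixed Passed to [fit()].
#' @param seed Base seed (incremented per fold).
#' @return List: `folds` (per-fold data.frame with condition and metrics),
#'   `aggregate` (mean and sd per metric over successful folds).
#' @export
loocv <- function(spec, dataset, bounds = NULL, n_starts = 4,
                  control = list(), fixed = NULL, seed = 1L) {
  cids <- unique(dataset$condition_id)
  if (length(cids) < 2) stop("cross-validation needs >= 2 conditions")
  rows <- list()
  for (i in seq_along(cids)) {
    held <- cids[i]
    train <- .subset_dataset(dataset, dataset$condition_id != held)
    test <- .subset_dataset(dataset, dataset$condition_id == held)
    f <- tryCatch(
      fit(spec, train, role = NULL, bounds = bounds, n_starts = n_starts,
          control = control, fixed = fixed, seed = seed + i),
      error = function(e) NULL
    )
    if (is.null(f)) {
      warning("fold ", held, " failed to refit; excluded")
      next
    }
    pred <- .predict_records(spec, f$theta_hat, test)
    pop <- pred[.observable_class(pred$observable) == "density", ]
    m <- error_metrics(pop$value, pop$g)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = held, rmse = m[["rmse"]], nrmse = m[["nrmse"]],
      mae = m[["mae"]], me = m[["me"]]
    )
  }
  folds <- do.call(rbind, rows)
  agg <- if (!is.null(folds) && nrow(folds)) {
    data.frame(
      metric = c("rmse", "nrmse", "mae", "me"),
      mean = vapply(folds[, -1], mean, numeric(1)),
      sd = vapply(folds[, -1], sd, numeric(1))
    )
  } else {
    NULL
  }
  list(folds = folds, aggregate = agg)
}

#' Correlation between the two population measurement errors
#'
#' If the total-population additive error of the one-population model
#' reflects the sum of two equally noisy, correlated population
#' measurements, then `a_M0 = sqrt(2 (1 + rho)) a_M1`; inverting gives
#' `rho = a_M0^2 / (2 a_M1^2) - 1`.
#'
#' @param a_n_m0 Additive density error of the one-population model.
#' @param a_n_m1 Additive density error of the two-population model.
#' @return Scalar `rho`; values outside `[-1, 1]` are returned as-is with
#'   a validity warning.
#' @examples
#' correlation_from_error_params(145.8, 89.77)  # about 0.319
#' @export
correlation_from_error_params <- function(a_n_m0, a_n_m1) {
  if (a_n_m0 <= 0 || a_n_m1 <= 0) stop("error parameters must be positive")
  rho <- a_n_m0^2 / (2 * a_n_m1^2) - 1
  if (rho < -1 || rho > 1) {
    warning("implied correlation ", signif(rho, 4),
            " outside [-1, 1]: the equal-noise assumption is inconsistent")
  }
  rho
}
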