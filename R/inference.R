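## Maximum-likelihood calibration: heteroscedastic Gaussian -2 log-likelihood
## with one ODE solve per condition, maximin-LHS multistart, a bounded
## differential-evolution global phase refined by Nelder-Mead, and BIC model
## selection on the held-out selection split.

.consumed_observables <- function(lineage) {
  if (lineage == "M0") c("n_q", "c_g", "c_l") else c("n_a", "n_p", "c_g", "c_l")
}

.dataset_records <- function(dataset, lineage, role = NULL) {
  d <- dataset
  if (!is.null(role)) {
    d <- d[!is.na(d$role) & d$role == role, , drop = FALSE]
    if (!nrow(d)) stop("no records with role ", sQuote(role))
  }
  d <- d[d$observable %in% .consumed_observables(lineage), , drop = FALSE]
  if (!nrow(d)) stop("no records consumed by lineage ", lineage)
  d
}

#' Negative two log-likelihood of a candidate model
#'
#' Computes `sum(eps^-2 (Z - g)^2) + sum(2 log eps) + m log(2 pi)` over the
#' requested records, with the model means `g` obtained from one ODE solve
#' per condition and the standard deviations `eps` from the spec's error
#' model. Non-positive `eps` (possible for the combined model with
#' pathological parameters) or integration failure yield `Inf`.
#'
#' @param spec An `afe_model_spec`.
#' @param theta,xi Named structural and error parameters.
#' @param dataset An `afe_dataset` (its `design` attribute supplies initial
#'   states and media schedules).
#' @param role Restrict to records with this role (`NULL`: all records).
#' @param per_record Return the vector of per-record contributions instead
#'   of their sum.
#' @return Scalar `-2 l` (or per-record vector).
#' @export
## Records of a dataset with the model mean `g` attached (one stacked ODE
## solve for all conditions); NULL on integration failure.
.records_g <- function(spec, theta, dataset, role = NULL) {
  design <- attr(dataset, "design")
  if (is.null(design)) stop("dataset carries no design attribute")
  d <- .dataset_records(dataset, spec$lineage, role)
  cids <- unique(d$condition_id)
  conds <- lapply(cids, function(cid) design_condition(design, cid))
  times <- sort(unique(d$time_d))
  mats <- tryCatch(
    .multi_integrate(spec, theta,
                     inits = lapply(conds, `[[`, "initial_state"),
                     times = times,
                     mch1 = vapply(conds, function(cc)
                       cc$media_change == "MCH1", logical(1)),
                     media_conc = lapply(conds, `[[`, "media_conc")),
    error = function(e) NULL
  )
  if (is.null(mats)) return(NULL)
  snames <- .state_names(spec)
  ci <- match(d$condition_id, cids)
  ti <- match(d$time_d, times)
  oi <- match(d$observable, snames)
  d$g <- vapply(seq_len(nrow(d)), function(r) mats[[ci[r]]][ti[r], oi[r]],
                numeric(1))
  d
}

neg2loglik <- function(spec, theta, xi, dataset, role = NULL,
                       per_record = FALSE) {
  d <- .records_g(spec, theta, dataset, role)
  if (is.null(d)) {
    m <- nrow(.dataset_records(dataset, spec$lineage, role))
    return(if (per_record) rep(Inf, m) else Inf)
  }
  cls <- .observable_class(d$observable)
  eps <- numeric(nrow(d))
  for (cl in unique(cls)) {
    j <- cls == cl
    eps[j] <- error_sd(spec$error_model, xi, d$g[j], cl)
  }
  if (any(!is.finite(d$g)) || any(!is.finite(eps)) || any(eps <= 0)) {
    return(if (per_record) rep(Inf, nrow(d)) else Inf)
  }
  out <- ((d$value - d$g) / eps)^2 + 2 * log(eps) + log(2 * pi)
  if (per_record) out else sum(out)
}

#' Latin-hypercube start points
#'
#' Draws a maximin Latin hypercube (space-filling: exactly one point per
#' equal-width bin in every coordinate) and scales it into the bounds.
#'
#' @param n_points Number of starts.
#' @param bounds Data.frame with `parameter`, `lower`, `upper` (as from
#'   [default_bounds()]).
#' @param seed Optional seed.
#' @return `n_points` x d matrix with parameter column names.
#' @export
lhs_starts <- function(n_points, bounds, seed = NULL) {
  stopifnot(n_points >= 1)
  if (any(bounds$upper <= bounds$lower)) {
    stop("degenerate bounds (upper <= lower) for: ",
         paste(bounds$parameter[bounds$upper <= bounds$lower], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(bounds)
  u <- lhs::maximinLHS(n_points, d)
  m <- sweep(sweep(u, 2, bounds$upper - bounds$lower, "*"),
             2, bounds$lower, "+")
  colnames(m) <- bounds$parameter
  m
}

## Bounded differential evolution, DE/rand/1/bin with dithered F in
## [0.4, 1.0] and CR = 0.9; box constraints by clamping. Budget counts
## objective evaluations (including the initial population).
de_optimize <- function(fn, lower, upper, init = NULL,
                        pop_size = NULL, max_evals = 2000, cr = 0.9) {
  d <- length(lower)
  if (is.null(pop_size)) pop_size <- max(10L, 10L * d)
  pop <- sweep(sweep(lhs::randomLHS(pop_size, d), 2, upper - lower, "*"),
               2, lower, "+")
  if (!is.null(init)) pop[1L, ] <- pmin(pmax(init, lower), upper)
  val <- apply(pop, 1L, fn)
  evals <- pop_size
  while (evals + pop_size <= max_evals) {
    f <- runif(1, 0.4, 1.0)
    for (i in seq_len(pop_size)) {
      idx <- sample(seq_len(pop_size)[-i], 3L)
      mutant <- pop[idx[1L], ] + f * (pop[idx[2L], ] - pop[idx[3L], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      tv <- fn(trial)
      evals <- evals + 1L
      if (tv <= val[i]) {
        pop[i, ] <- trial
        val[i] <- tv
      }
      if (evals >= max_evals) break
    }
  }
  best <- which.min(val)
  list(par = pop[best, ], value = val[best], evals = evals)
}

## Iteratively reweighted Levenberg-Marquardt refinement of one start:
## holds the observation SDs fixed at the incumbent, minimizes the weighted
## residual vector within bounds, and re-weights; a candidate is accepted
## only if it lowers the full -2 log-likelihood.
.lm_polish <- function(spec, dataset, role, bounds, build, objective, par,
                       cycles = 2L) {
  value <- objective(par)
  for (cy in seq_len(cycles)) {
    p <- build(par)
    d <- .records_g(spec, p$theta, dataset, role)
    if (is.null(d) || any(!is.finite(d$g))) break
    cls <- .observable_class(d$observable)
    eps <- numeric(nrow(d))
    for (cl in unique(cls)) {
      j <- cls == cl
      eps[j] <- error_sd(spec$error_model, p$xi, d$g[j], cl)
    }
    if (any(!is.finite(eps)) || any(eps <= 0)) break
    resfun <- function(q) {
      pq <- build(q)
      dq <- .records_g(spec, pq$theta, dataset, role)
      if (is.null(dq) || any(!is.finite(dq$g))) return(rep(1e6, nrow(d)))
      (dq$value - dq$g) / eps
    }
    lmctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                        ptol = 1e-14, epsfcn = 1e-10)
    o <- tryCatch(
      minpack.lm::nls.lm(par, lower = bounds$lower, upper = bounds$upper,
                         fn = resfun, control = lmctl),
      error = function(e) NULL
    )
    if (is.null(o)) break
    cand <- pmin(pmax(o$par, bounds$lower), bounds$upper)
    ## bounded LM can stagnate on an active bound; follow up with a free
    ## interior pass (positivity floor only) and keep it when the clamped
    ## result still improves the likelihood
    o2 <- tryCatch(
      minpack.lm::nls.lm(cand, fn = function(q) resfun(pmax(q, 1e-9)),
                         control = lmctl),
      error = function(e) NULL
    )
    if (!is.null(o2)) {
      cand2 <- pmin(pmax(o2$par, bounds$lower), bounds$upper)
      if (objective(cand2) < objective(cand)) cand <- cand2
    }
    cv <- objective(cand)
    if (cv < value - 1e-12) {
      par <- cand
      value <- cv
    } else {
      break
    }
  }
  list(par = par, value = value)
}

#' Fit a candidate model by multistart maximum likelihood
#'
#' For each start, a bounded differential-evolution global phase is refined
#' by a Nelder-Mead simplex (relative tolerance `reltol`, default 1e-6;
#' out-of-bounds proposals score `Inf`). The best of the per-start results
#' is returned with all per-start losses retained.
#'
#' @param spec An `afe_model_spec`.
#' @param dataset An `afe_dataset` with roles assigned (see
#'   [split_dataset()]), or any dataset when `role = NULL`.
#' @param role Records used for calibration (default `"calibration"`).
#' @param bounds Data.frame `parameter`/`lower`/`upper`; defaults to the
#'   packaged search space for the spec's active parameters.
#' @param n_starts Number of LHS starts (the study fidelity is 100;
#'   desk-scale defaults are smaller).
#' @param starts Optional explicit start matrix (overrides `n_starts`).
#' @param fixed Named vector of parameters held fixed (not inferred).
#' @param control List: `de_evals` (DE budget per start), `de_pop`
#'   (population size, default 10 x dimension), `nm_maxit`, `reltol`,
#'   `nm_restarts` (extra Nelder-Mead polish cycles), `lm_polish`
#'   (default `FALSE`: optionally finish each start with an iteratively
#'   reweighted Levenberg-Marquardt pass on the weighted residual vector,
#'   accepted only when it lowers the loss -- useful for near-noiseless
#'   recovery problems whose likelihood valley is too flat for the
#'   simplex), `lm_cycles` (reweighting cycles).
#' @param seed Seed for starts and DE.
#' @return An `afe_fit` with elements `spec`, `theta_hat`, `xi_hat`,
#'   `loss`, `start_losses`, `converged`, `seed`, `bounds`, `fixed`,
#'   `role`, `n_data`.
#' @export
fit <- function(spec, dataset, role = "calibration", bounds = NULL,
                n_starts = 10, starts = NULL, fixed = NULL,
                control = list(), seed = 1L) {
  ctl <- modifyList(list(de_evals = 2000, de_pop = NULL, nm_maxit = 2000,
                         reltol = 1e-6, nm_restarts = 1L,
                         lm_polish = FALSE, lm_cycles = 2L), control)
  if (is.null(bounds)) bounds <- default_bounds(spec)
  free <- setdiff(bounds$parameter, names(fixed))
  bounds <- bounds[bounds$parameter %in% free, , drop = FALSE]
  d <- nrow(bounds)
  if (d == 0L) stop("no free parameters to fit")
  snames <- structural_param_names(spec)
  enames <- error_param_names(spec)

  build <- function(par) {
    full <- c(setNames(par, bounds$parameter), fixed)
    list(theta = full[intersect(names(full), snames)],
         xi = full[intersect(names(full), enames)])
  }
  objective <- function(par) {
    if (any(!is.finite(par)) || any(par < bounds$lower) ||
        any(par > bounds$upper)) {
      return(Inf)
    }
    p <- build(par)
    v <- tryCatch(neg2loglik(spec, p$theta, p$xi, dataset, role = role),
                  error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  set.seed(seed)
  if (is.null(starts)) starts <- lhs_starts(n_starts, bounds)
  n_starts <- nrow(starts)

  best <- NULL
  start_losses <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    de <- de_optimize(objective, bounds$lower, bounds$upper,
                      init = starts[s, ], pop_size = ctl$de_pop,
                      max_evals = ctl$de_evals)
    par <- de$par
    value <- de$value
    for (r in seq_len(1L + ctl$nm_restarts)) {
      nm <- optim(par, objective, method = "Nelder-Mead",
                  control = list(maxit = ctl$nm_maxit, reltol = ctl$reltol))
      if (nm$value <= value) {
        par <- nm$par
        value <- nm$value
      }
      if (isTRUE(ctl$lm_polish)) {
        lp <- .lm_polish(spec, dataset, role, bounds, build, objective, par,
                         cycles = ctl$lm_cycles)
        if (lp$value <= value) {
          par <- lp$par
          value <- lp$value
        }
      }
    }
    start_losses[s] <- value
    if (is.null(best) || value < best$value) {
      best <- list(par = par, value = value)
    }
  }
  if (!is.finite(best$value)) {
    stop("all optimization starts failed for spec ", spec_string(spec))
  }
  p <- build(best$par)
  n_data <- nrow(.dataset_records(dataset, spec$lineage, role))
  structure(
    list(spec = spec, theta_hat = p$theta, xi_hat = p$xi,
         loss = best$value, n_starts = n_starts,
         start_losses = start_losses, converged = is.finite(best$value),
         seed = seed, bounds = bounds, fixed = fixed, role = role,
         n_data = n_data),
    class = "afe_fit"
  )
}

#' @export
print.afe_fit <- function(x, ...) {
  cat("<afe_fit>", spec_string(x$spec), "\n")
  cat("  -2 loglik:", format(x$loss), "on", x$n_data, "records (",
      x$n_starts, "starts )\n")
  cat("  theta_hat:\n")
  print(signif(x$theta_hat, 4))
  if (length(x$xi_hat)) {
    cat("  xi_hat:\n")
    print(signif(x$xi_hat, 4))
  }
  invisible(x)
}

#' Bayesian information criterion on the selection split
#'
#' `BIC = k log(m_s) + (-2 l)` where `k` is the number of inferred
#' (structural + error) parameters, `m_s` the number of selection records
#' consumed by the lineage, and `-2 l` the loss at the calibration-fitted
#' parameters evaluated on the selection records.
#'
#' @param fit An `afe_fit`.
#' @param dataset The role-tagged dataset.
#' @param role Selection role name.
#' @return Scalar BIC.
#' @export
bic <- function(fit, dataset, role = "selection") {
  d <- .dataset_records(dataset, fit$spec$lineage, role)
  m_s <- nrow(d)
  loss_sel <- neg2loglik(fit$spec, fit$theta_hat, fit$xi_hat, dataset,
                         role = role)
  k <- nrow(fit$bounds)
  k * log(m_s) + loss_sel
}

#' Rank fitted candidates by BIC within lineage
#'
#' The two lineages use different observables, so their likelihoods (and
#' BICs) are not comparable; ranking is always within lineage. Ties are
#' broken by fewer parameters, then by the spec string. The top
#' `shortlist_k` specs per lineage form the shortlist handed to the
#' practical-identifiability filter.
#'
#' @param fits List of `afe_fit` objects.
#' @param dataset Role-tagged dataset.
#' @param shortlist_k Shortlist size per lineage (default 4).
#' @return An `afe_selection` with a per-spec `table` (spec, lineage, k,
#'   loss_sel, bic, rank) and a `shortlist` of spec strings per lineage.
#' @export
select_models <- function(fits, dataset, shortlist_k = 4) {
  rows <- lapply(fits, function(f) {
    data.frame(spec = spec_string(f$spec), lineage = f$spec$lineage,
               k = nrow(f$bounds),
               bic = bic(f, dataset), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$rank <- NA_integer_
  shortlist <- list()
  for (lin in unique(tab$lineage)) {
    i <- which(tab$lineage == lin)
    o <- order(tab$bic[i], tab$k[i], tab$spec[i])
    tab$rank[i[o]] <- seq_along(i)
    shortlist[[lin]] <- tab$spec[i[o]][seq_len(min(shortlist_k, length(i)))]
  }
  tab <- tab[order(tab$lineage, tab$rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab, shortlist = shortlist,
                 fits = setNames(fits, vapply(fits, function(f)
                   spec_string(f$spec), character(1)))),
            class = "afe_selection")
}

#' @export
print.afe_selection <- function(x, ...) {
  cat("<afe_selection>\n")
  print(x$table)
  invisible(x)
}
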