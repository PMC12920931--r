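## Observation model: z = g + epsilon * eta, with eta ~ N(0, 1) i.i.d. and
## epsilon given by one of three error models, parameterised separately for
## densities (a_n, b_n) and concentrations (a_c, b_c).

.observable_class <- function(observable) {
  ifelse(observable %in% c("n_q", "n_a", "n_p"), "density",
         ifelse(observable %in% c("c_g", "c_l"), "concentration",
                NA_character_))
}

#' Observation standard deviation under an error model
#'
#' Additive: `a`; proportional: `b * g`; combined: `a + b * g`, with the
#' `(a_n, b_n)` pair for densities and the disjoint `(a_c, b_c)` pair for
#' concentrations.
#'
#' @param error_model `"additive"`, `"proportional"`, or `"combined"`.
#' @param xi Named error parameters.
#' @param mean_value Model mean `g` (vectorised).
#' @param observable_class `"density"` or `"concentration"`.
#' @return Standard deviation(s), same length as `mean_value`.
#' @examples
#' error_sd("proportional", c(b_n = 0.3), 100, "density")  # 30
#' @export
error_sd <- function(error_model, xi, mean_value,
                     observable_class = c("density", "concentration")) {
  error_model <- match.arg(error_model, .afedyn_errors)
  observable_class <- match.arg(observable_class)
  if (any(!is.finite(mean_value))) stop("mean_value must be finite")
  suffix <- if (observable_class == "density") "n" else "c"
  need <- switch(error_model,
    additive = paste0("a_", suffix),
    proportional = paste0("b_", suffix),
    combined = paste0(c("a_", "b_"), suffix)
  )
  if (length(setdiff(need, names(xi)))) {
    stop("error model needs parameter(s): ", paste(need, collapse = ", "))
  }
  if (any(xi[need] < 0)) stop("error parameters must be non-negative")
  switch(error_model,
    additive = rep_len(xi[[need[1]]], length(mean_value)),
    proportional = xi[[need[1]]] * mean_value,
    combined = xi[[need[1]]] + xi[[need[2]]] * mean_value
  )
}

#' Sample noisy observations from a mean trajectory
#'
#' Draws one record per (observable, time) in the schedule with value
#' `g + epsilon * eta`, `eta` standard normal. Negative draws are retained:
#' the likelihood assumes untruncated Gaussian residuals and truncation
#' would bias inference (set `clip_negative = TRUE` for display only).
#' Measurements at a media-reset instant use the pre-reset state.
#'
#' @param traj An `afe_trajectory` (see [simulate_condition()]).
#' @param schedule Data.frame with columns `time_d` and `observable`.
#' @param error_model Error model name.
#' @param xi Named error parameters; an empty/zero `xi` with
#'   `error_model = "additive"` reproduces the means exactly.
#' @param seed Optional integer seed for reproducible draws.
#' @param clip_negative Clamp sampled values at 0 (display only).
#' @return Data.frame with columns `time_d`, `observable`, `value`.
#' @export
observe <- function(traj, schedule, error_model, xi, seed = NULL,
                    clip_negative = FALSE) {
  stopifnot(is.data.frame(schedule),
            all(c("time_d", "observable") %in% names(schedule)))
  if (any(schedule$time_d > max(traj$time) + 1e-9) ||
      any(schedule$time_d < min(traj$time) - 1e-9)) {
    stop("schedule time outside the integrated span")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  g <- mapply(function(t, obs) trajectory_at(traj, t, obs),
              schedule$time_d, schedule$observable)
  cls <- .observable_class(schedule$observable)
  eps <- numeric(length(g))
  for (cl in unique(cls)) {
    i <- cls == cl
    eps[i] <- error_sd(error_model, xi, g[i], cl)
  }
  eta <- rnorm(length(g))
  value <- g + eps * eta
  if (clip_negative) value <- pmax(value, 0)
  data.frame(time_d = schedule$time_d, observable = schedule$observable,
             value = value, stringsAsFactors = FALSE)
}
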