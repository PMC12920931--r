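## Synthetic experiments with the statistical design of the in vitro study:
## 4 conditions (split ratio 1:2 / 1:5 x media change MCH0 / MCH1), N
## replicates, populations sampled every 48 h and concentrations every 24 h
## over a 4-day window (protocol days 11-15).

#' Define one culture condition
#'
#' @param condition_id Identifier string.
#' @param split_ratio Seeded fraction in (0, 1]; 1:k is encoded as 1/k.
#' @param media_change `"MCH0"` or `"MCH1"`.
#' @param initial_state Named day-11 state (`n_a`, `n_p`, `c_g`, `c_l`).
#' @param media_conc Fresh-medium concentrations used at resets.
#' @return An object of class `afe_condition`.
#' @export
condition <- function(condition_id, split_ratio, media_change,
                      initial_state, media_conc = c(c_g = 17.5, c_l = 1.0)) {
  stopifnot(split_ratio > 0, split_ratio <= 1)
  media_change <- match.arg(media_change, c("MCH0", "MCH1"))
  structure(
    list(condition_id = condition_id, split_ratio = split_ratio,
         media_change = media_change,
         initial_state = initial_state, media_conc = media_conc),
    class = "afe_condition"
  )
}

#' The study's four-condition experiment design
#'
#' Two split ratios (1:2, 1:5) crossed with two media regimes (MCH0, MCH1),
#' a 4-day horizon, populations sampled every `population_period` days
#' (default 2 d = 48 h) and concentrations every `concentration_period`
#' days (default 1 d = 24 h). With the defaults each replicate contributes
#' 2 population observables x 2 times x 4 conditions = 16 density points
#' and 2 concentration observables x 4 times x 4 conditions = 32
#' concentration points: 48 records per replicate.
#'
#' Day-11 initial densities come from the split-ratio mapping (see
#' [map_sr()]); initial and fresh-medium concentrations default to 17.5
#' mmol/L glucose and 1 mmol/L lactate (configurable; the fresh-lactate
#' default is positive so the lactate production term can act).
#'
#' @param replicates Number of replicates N (default 4).
#' @param horizon Culture horizon in days.
#' @param population_period,concentration_period Sampling periods (days).
#' @param media_conc Fresh-medium concentrations (used at MCH1 resets and
#'   as day-11 initial concentrations).
#' @param mapping Split-ratio mapping (default: packaged coefficients).
#' @return An object of class `afe_design`.
#' @export
study_design <- function(replicates = 4, horizon = 4,
                         population_period = 2, concentration_period = 1,
                         media_conc = c(c_g = 17.5, c_l = 1.0),
                         mapping = default_split_mapping()) {
  stopifnot(replicates >= 1, horizon > 0,
            population_period > 0, concentration_period > 0)
  conds <- list()
  for (sr in c(0.5, 0.2)) {
    for (mch in c("MCH0", "MCH1")) {
      dens <- map_sr(mapping, sr)
      init <- c(dens, n_q = unname(dens[["n_a"]] + dens[["n_p"]]),
                c_g = media_conc[["c_g"]], c_l = media_conc[["c_l"]])
      id <- sprintf("SR%s_%s", sub("^0[.]", "", format(sr)), mch)
      conds[[id]] <- condition(id, sr, mch, init, media_conc)
    }
  }
  structure(
    list(conditions = conds, replicates = as.integer(replicates),
         horizon = horizon, population_period = population_period,
         concentration_period = concentration_period),
    class = "afe_design"
  )
}

#' @export
print.afe_design <- function(x, ...) {
  cat("<afe_design>", length(x$conditions), "conditions x",
      x$replicates, "replicates; horizon", x$horizon, "d;",
      "population period", x$population_period, "d,",
      "concentration period", x$concentration_period, "d\n")
  invisible(x)
}

#' Sampling schedule of a design for one replicate
#'
#' @param design An `afe_design`.
#' @param lineage `"M0"` (total population) or `"M1"` (AFE + LP).
#' @return Data.frame `time_d`, `observable` (one row per record).
#' @export
design_schedule <- function(design, lineage = "M1") {
  pop_obs <- if (lineage == "M0") "n_q" else c("n_a", "n_p")
  pop_t <- seq(design$population_period, design$horizon,
               by = design$population_period)
  conc_t <- seq(design$concentration_period, design$horizon,
                by = design$concentration_period)
  rbind(
    expand.grid(time_d = pop_t, observable = pop_obs,
                stringsAsFactors = FALSE),
    expand.grid(time_d = conc_t, observable = c("c_g", "c_l"),
                stringsAsFactors = FALSE)
  )
}

#' Generate a synthetic dataset
#'
#' Integrates every condition of the design under the given model (with
#' MCH1 media resets at interior integer days), then samples noisy
#' observations per the error model. The returned dataset carries the
#' generating ground truth (`spec`, `theta`, `xi`, `seed`) as attributes
#' for recovery tests.
#'
#' @param design An `afe_design`.
#' @param spec An `afe_model_spec`.
#' @param theta,xi Named structural and error parameters.
#' @param seed Integer seed (required: generation is reproducible).
#' @return A data.frame of class `afe_dataset` with columns
#'   `condition_id`, `replicate`, `time_d`, `observable`, `value`,
#'   `split_ratio`, `media_change`, `role`.
#' @export
generate <- function(design, spec, theta, xi, seed) {
  stopifnot(inherits(design, "afe_design"))
  check_params(spec, theta)
  schedule <- design_schedule(design, spec$lineage)
  set.seed(seed)
  rows <- list()
  for (cond in design$conditions) {
    traj <- simulate_condition(spec, theta, cond$initial_state,
                               times = sort(unique(schedule$time_d)),
                               media_change = cond$media_change,
                               media_conc = cond$media_conc)
    for (r in seq_len(design$replicates)) {
      obs <- observe(traj, schedule, spec$error_model, xi)
      obs$condition_id <- cond$condition_id
      obs$replicate <- r
      obs$split_ratio <- cond$split_ratio
      obs$media_change <- cond$media_change
      rows[[length(rows) + 1L]] <- obs
    }
  }
  out <- do.call(rbind, rows)
  out$role <- NA_character_
  out <- out[, c("condition_id", "replicate", "time_d", "observable",
                 "value", "split_ratio", "media_change", "role")]
  rownames(out) <- NULL
  structure(out, class = c("afe_dataset", "data.frame"),
            design = design, spec = spec_string(spec),
            theta = theta, xi = xi, seed = seed)
}

#' Assign calibration / selection / validation roles by replicate
#'
#' Whole replicates are assigned to roles in the given integer proportions
#' (default 2:1:1, i.e. with N = 4 replicates: two for calibration, one for
#' selection, one for validation). The assignment is deterministic; a seed
#' permutes which replicate lands in which role but the same seed always
#' yields the same split.
#'
#' @param dataset An `afe_dataset`.
#' @param ratios Integer proportions for calibration:selection:validation.
#' @param seed Optional seed for the replicate permutation (default: keep
#'   replicate order, so replicates 1,2 -> calibration, 3 -> selection,
#'   4 -> validation with the defaults).
#' @return The dataset with its `role` column filled.
#' @export
split_dataset <- function(dataset, ratios = c(2, 1, 1), seed = NULL) {
  stopifnot(length(ratios) == 3, all(ratios >= 1))
  reps <- sort(unique(dataset$replicate))
  n <- length(reps)
  if (n %% sum(ratios) != 0) {
    stop("cannot split ", n, " replicates in ", paste(ratios, collapse = ":"),
         " proportions by whole replicates")
  }
  k <- n / sum(ratios)
  if (!is.null(seed)) {
    set.seed(seed)
    reps <- sample(reps)
  }
  roles <- rep(c("calibration", "selection", "validation"), times = ratios * k)
  map <- setNames(roles, reps)
  dataset$role <- unname(map[as.character(dataset$replicate)])
  dataset
}

#' Collapse M1 population records to total-population records
#'
#' Sums matched AFE and LP records (same condition, replicate, time) into
#' `n_q` records so that M0 candidates can be fitted to data generated
#' under an M1 ground truth; concentration records pass through.
#'
#' @param dataset An `afe_dataset` with `n_a`/`n_p` records.
#' @return A dataset with `n_q` and concentration records.
#' @export
as_total_population <- function(dataset) {
  pop <- dataset[dataset$observable %in% c("n_a", "n_p"), ]
  rest <- dataset[!dataset$observable %in% c("n_a", "n_p"), ]
  if (!nrow(pop)) return(dataset)
  key <- interaction(pop$condition_id, pop$replicate, pop$time_d, drop = TRUE)
  agg <- lapply(split(pop, key), function(d) {
    out <- d[1L, , drop = FALSE]
    out$observable <- "n_q"
    out$value <- sum(d$value)
    out
  })
  out <- rbind(do.call(rbind, agg), rest)
  out <- out[order(out$condition_id, out$replicate, out$time_d,
                   out$observable), ]
  rownames(out) <- NULL
  for (a in c("design", "spec", "theta", "xi", "seed")) {
    attr(out, a) <- attr(dataset, a)
  }
  class(out) <- c("afe_dataset", "data.frame")
  out
}

#' Look up a design condition by id
#' @param design An `afe_design`.
#' @param condition_id Identifier.
#' @return The `afe_condition`.
#' @export
design_condition <- function(design, condition_id) {
  cond <- design$conditions[[condition_id]]
  if (is.null(cond)) stop("unknown condition: ", condition_id)
  cond
}
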