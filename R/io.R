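## Dataset I/O (tidy CSV + JSON provenance sidecar) and the end-to-end
## pipeline driver.

.dataset_columns <- c("condition_id", "replicate", "time_d", "observable",
                      "value", "split_ratio", "media_change", "role")

.design_to_list <- function(design) {
  list(
    replicates = design$replicates, horizon = design$horizon,
    population_period = design$population_period,
    concentration_period = design$concentration_period,
    conditions = lapply(design$conditions, function(cc) {
      list(condition_id = cc$condition_id, split_ratio = cc$split_ratio,
           media_change = cc$media_change,
           initial_state = as.list(cc$initial_state),
           media_conc = as.list(cc$media_conc))
    })
  )
}

.design_from_list <- function(x) {
  conds <- lapply(x$conditions, function(cc) {
    condition(cc$condition_id, cc$split_ratio, cc$media_change,
              unlist(cc$initial_state), unlist(cc$media_conc))
  })
  names(conds) <- vapply(conds, `[[`, character(1), "condition_id")
  structure(
    list(conditions = conds, replicates = as.integer(x$replicates),
         horizon = x$horizon, population_period = x$population_period,
         concentration_period = x$concentration_period),
    class = "afe_design"
  )
}

.sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a dataset to tidy CSV with a JSON provenance sidecar
#'
#' The CSV holds the tidy schema (UTF-8, '.' decimal separator, header);
#' the sidecar (`<path>.json` with the `.csv` suffix swapped) stores the
#' design, generating spec, ground-truth parameters and seed so the
#' dataset round-trips exactly.
#'
#' @param dataset An `afe_dataset`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  write.csv(as.data.frame(dataset)[, .dataset_columns], path,
            row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  meta <- list(
    design = .design_to_list(attr(dataset, "design")),
    spec = attr(dataset, "spec"),
    theta = as.list(attr(dataset, "theta")),
    xi = as.list(attr(dataset, "xi")),
    seed = attr(dataset, "seed")
  )
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates the tidy schema; unknown extra columns are preserved in an
#' `extra_columns` attribute and ignored by the pipeline. Negative density
#' values trigger a warning, not an error (the Gaussian observation model
#' permits them).
#'
#' @param path CSV path (sidecar looked up next to it).
#' @return An `afe_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.dataset_columns, names(d))
  if (length(missing)) {
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(d), .dataset_columns)
  bad <- which(!is.finite(d$value))
  if (length(bad)) {
    stop("unparseable value in row(s): ", paste(utils::head(bad), collapse = ", "))
  }
  if (any(d$value < 0 & d$observable %in% c("n_q", "n_a", "n_p"))) {
    warning("negative density values present (permitted under Gaussian noise)")
  }
  out <- d[, .dataset_columns]
  out$role <- ifelse(out$role %in% c("", "NA"), NA_character_, out$role)
  sidecar <- .sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "design") <- .design_from_list(meta$design)
    attr(out, "spec") <- meta$spec
    attr(out, "theta") <- unlist(meta$theta)
    attr(out, "xi") <- unlist(meta$xi)
    attr(out, "seed") <- meta$seed
  }
  if (length(extra)) attr(out, "extra_columns") <- d[, extra, drop = FALSE]
  class(out) <- c("afe_dataset", "data.frame")
  out
}

## Small deterministic hash of a serialized config (provenance tag).
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full model-development pipeline
#'
#' Executes synthetic-data generation, structural screening, multistart
#' calibration, BIC selection, profile-likelihood filtering and hold-out
#' validation, writing each stage's JSON/CSV artifact (with the seed and a
#' config hash embedded) into `out_dir`. Defaults are desk-scale; raise
#' `n_starts`/`control` budgets for study-scale runs.
#'
#' @param config List: `seed` (required), `out_dir` (required), `specs`
#'   (character vector of spec strings to fit), `truth` (list with `spec`,
#'   `theta`, `xi`; default [selected_m1_params()]), `replicates`, `n_starts`,
#'   `control` (see [fit()]), `bounds`, `profile_params` (parameters of
#'   the chosen spec to profile; `NULL` for none).
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config) {
  defaults <- list(specs = "M1:exponential:glu:additive",
                   truth = selected_m1_params(), replicates = 4,
                   n_starts = 4, control = list(), bounds = NULL,
                   profile_params = NULL)
  config <- modifyList(defaults, config)
  if (is.null(config$seed) || is.null(config$out_dir)) {
    stop("config needs 'seed' and 'out_dir'")
  }
  if (config$n_starts < 1) stop("config: n_starts must be >= 1")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  prov <- list(seed = config$seed, config_hash = hash,
               package_version = as.character(utils::packageVersion("afedyn")))
  emit <- function(name, payload) {
    jsonlite::write_json(c(list(provenance = prov), payload),
                         file.path(config$out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  truth <- config$truth
  design <- study_design(replicates = config$replicates)
  dataset <- generate(design, truth$spec, truth$theta, truth$xi,
                      seed = config$seed)
  dataset <- split_dataset(dataset)
  write_dataset(dataset, file.path(config$out_dir, "dataset.csv"))

  specs <- lapply(config$specs, parse_spec)
  screens <- lapply(specs, structural_screen)
  emit("screen", list(screen = lapply(screens, function(s) {
    list(spec = spec_string(s$spec), structural = s$structural,
         method = s$method, deficiency = s$deficiency)
  })))
  keep <- vapply(screens, function(s) s$structural == "identifiable",
                 logical(1))
  specs <- specs[keep]
  if (!length(specs)) stop("pipeline stage 'screen': no identifiable specs")

  fits <- lapply(seq_along(specs), function(i) {
    fit(specs[[i]], dataset, bounds = config$bounds,
        n_starts = config$n_starts, control = config$control,
        seed = config$seed + i)
  })
  emit("fits", list(fits = lapply(fits, function(f) {
    list(spec = spec_string(f$spec), loss = f$loss,
         theta_hat = as.list(f$theta_hat), xi_hat = as.list(f$xi_hat))
  })))

  selection <- select_models(fits, dataset)
  emit("selection", list(table = selection$table,
                         shortlist = selection$shortlist))
  best_spec <- selection$table$spec[which.min(selection$table$bic)]
  best_fit <- selection$fits[[best_spec]]

  profiles <- NULL
  if (!is.null(config$profile_params)) {
    profiles <- lapply(config$profile_params, function(p) {
      profile_fit(best_fit, dataset, p)
    })
    emit("profiles", list(profiles = lapply(profiles, function(p) {
      list(parameter = p$parameter, psi = p$psi, pl = p$pl,
           ci = as.list(p$ci), lower_open = p$lower_open,
           upper_open = p$upper_open)
    })))
  }

  val <- validate_fit(best_fit, dataset)
  emit("validation", list(chosen = best_spec, metrics = val))

  invisible(list(dataset = dataset, screens = screens, fits = fits,
                 selection = selection, profiles = profiles,
                 validation = val, chosen = best_spec, provenance = prov))
}
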