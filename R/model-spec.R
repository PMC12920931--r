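#' @useDynLib afedyn, .registration = FALSE
#' @importFrom stats optim runif rnorm setNames var sd median qchisq approx
#' @importFrom utils read.csv write.csv modifyList
NULL

.afedyn_lineages <- c("M0", "M1")
.afedyn_growths  <- c("exponential", "logistic", "gompertz")
.afedyn_envs     <- c("none", "glu", "lac", "glulac")
.afedyn_errors   <- c("additive", "proportional", "combined")

#' Define one candidate model
#'
#' A candidate model is the combination of a lineage structure (`M0`: total
#' live population only; `M1`: AFE and LP populations with a differentiation
#' flux), a density-dependent growth law, a multiplicative Michaelis-Menten
#' environmental effect of glucose and/or lactate on growth, and an
#' observation error model.
#'
#' @param lineage `"M0"` or `"M1"`.
#' @param growth `"exponential"`, `"logistic"`, or `"gompertz"`.
#' @param env `"none"`, `"glu"`, `"lac"`, or `"glulac"`.
#' @param error_model `"additive"`, `"proportional"`, or `"combined"`.
#' @return An object of class `afe_model_spec`.
#' @examples
#' model_spec("M1", "exponential", "glu", "additive")
#' @export
model_spec <- function(lineage, growth, env, error_model) {
  spec <- structure(
    list(
      lineage = match.arg(lineage, .afedyn_lineages),
      growth = match.arg(growth, .afedyn_growths),
      env = match.arg(env, .afedyn_envs),
      error_model = match.arg(error_model, .afedyn_errors)
    ),
    class = "afe_model_spec"
  )
  spec
}

#' Serialize a model spec to its 4-token string
#'
#' @param spec An `afe_model_spec`.
#' @return A string such as `"M1:exponential:glu:additive"`.
#' @export
spec_string <- function(spec) {
  stopifnot(inherits(spec, "afe_model_spec"))
  paste(spec$lineage, spec$growth, spec$env, spec$error_model, sep = ":")
}

#' Parse a 4-token model spec string
#'
#' @param x A string such as `"M0:logistic:none:combined"`.
#' @return An `afe_model_spec`.
#' @export
parse_spec <- function(x) {
  tokens <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(tokens) != 4L) {
    stop("spec string must have 4 ':'-separated tokens, got ", sQuote(x))
  }
  model_spec(tokens[1], tokens[2], tokens[3], tokens[4])
}

#' @export
format.afe_model_spec <- function(x, ...) spec_string(x)

#' @export
print.afe_model_spec <- function(x, ...) {
  cat("<afe_model_spec>", spec_string(x), "\n")
  invisible(x)
}

#' @export
as.character.afe_model_spec <- function(x, ...) spec_string(x)

#' Is the structural part of a spec a priori unidentifiable?
#'
#' Exponential growth with no environmental coupling admits the exact rate
#' translation (beta, delta) -> (beta + c, delta + c): only beta - delta is
#' observable, so these candidates are flagged and excluded from inference.
#'
#' @param spec An `afe_model_spec`.
#' @return Logical.
#' @export
is_structurally_unidentifiable <- function(spec) {
  spec$growth == "exponential" && spec$env == "none"
}

#' Enumerate the candidate model family
#'
#' The full family crosses 2 lineages x 3 growth laws x 4 environmental
#' effects x 3 error models = 72 candidates; dropping the a priori
#' unidentifiable exponential/no-environment structures leaves 66.
#'
#' @param include_unidentifiable Keep the exponential/no-environment specs?
#' @return A list of `afe_model_spec`, in a fixed deterministic order,
#'   named by their spec strings.
#' @examples
#' length(enumerate_models())       # 66
#' length(enumerate_models(TRUE))   # 72
#' @export
enumerate_models <- function(include_unidentifiable = FALSE) {
  grid <- expand.grid(
    error_model = .afedyn_errors, env = .afedyn_envs,
    growth = .afedyn_growths, lineage = .afedyn_lineages,
    stringsAsFactors = FALSE
  )
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    model_spec(grid$lineage[i], grid$growth[i], grid$env[i],
               grid$error_model[i])
  })
  if (!include_unidentifiable) {
    specs <- Filter(function(s) !is_structurally_unidentifiable(s), specs)
  }
  names(specs) <- vapply(specs, spec_string, character(1))
  specs
}

#' Names of the active structural parameters of a spec
#'
#' @param spec An `afe_model_spec`.
#' @return Character vector in canonical order.
#' @export
structural_param_names <- function(spec) {
  base <- if (spec$lineage == "M0") {
    c("beta_q", "delta_q")
  } else {
    c("beta_a", "p_ap", "delta_a", "beta_p", "delta_p")
  }
  nm <- c(base, "V_g", "V_l", "cbar_g", "cbar_l")
  if (spec$env %in% c("glu", "glulac")) nm <- c(nm, "K_g")
  if (spec$env %in% c("lac", "glulac")) nm <- c(nm, "K_l")
  if (spec$growth %in% c("logistic", "gompertz")) nm <- c(nm, "n_max")
  nm
}

#' Names of the active error parameters of a spec
#'
#' @param spec An `afe_model_spec`.
#' @return Character vector: additive uses `a_n`, `a_c`; proportional
#'   `b_n`, `b_c`; combined all four.
#' @export
error_param_names <- function(spec) {
  switch(spec$error_model,
    additive = c("a_n", "a_c"),
    proportional = c("b_n", "b_c"),
    combined = c("a_n", "b_n", "a_c", "b_c")
  )
}

#' Structural and error parameter counts
#'
#' M0 has 6 base structural parameters and M1 has 9; logistic or Gompertz
#' growth adds `n_max`, and each environmental coupling adds its
#' Michaelis-Menten constant (`K_g` and/or `K_l`), so structural counts
#' range from 6 to 12. Error models add 2 (additive, proportional) or 4
#' (combined) parameters.
#'
#' @param spec An `afe_model_spec`.
#' @return Named integer vector `c(structural = , error = )`.
#' @examples
#' param_count(model_spec("M1", "logistic", "glulac", "combined"))  # 12, 4
#' @export
param_count <- function(spec) {
  c(structural = length(structural_param_names(spec)),
    error = length(error_param_names(spec)))
}

#' Physical bounds for the maximum monolayer density
#'
#' The upper bound is the number of cells of the given diameter that tile a
#' unit area as a confluent monolayer, `1 / (pi (d/2)^2)`; the lower bound
#' is one tenth of that.
#'
#' @param cell_diameter_um Cell diameter in micrometres (default 15).
#' @return Named numeric `c(lower = , upper = )` in cells mm^-2.
#' @examples
#' nmax_bounds(15)  # c(565.9, 5658.8)
#' @export
nmax_bounds <- function(cell_diameter_um = 15) {
  if (!is.numeric(cell_diameter_um) || cell_diameter_um <= 0) {
    stop("cell diameter must be a positive number")
  }
  d_mm <- cell_diameter_um / 1000
  upper <- 1 / (pi * (d_mm / 2)^2)
  c(lower = upper / 10, upper = upper)
}

## Parameter search space (per-parameter lower/upper and unit)
.afedyn_bounds_table <- data.frame(
  parameter = c("beta_q", "delta_q", "beta_a", "p_ap", "delta_a", "beta_p",
                "delta_p", "V_g", "V_l", "K_g", "K_l", "cbar_g", "cbar_l",
                "n_max", "a_n", "b_n", "a_c", "b_c"),
  lower = c(1e-4, 1e-4, 1e-4, 0, 1e-4, 1e-4, 1e-4,
            1e-4, 1e-4, 0.01, 0.5, 1e-4, 1e-4,
            565.8, 0.1, 0.001, 0.1, 0.001),
  upper = c(10, 10, 10, 1, 10, 10, 10,
            1, 1, 50, 200, 50, 50,
            5659.0, 500, 2, 20, 2),
  unit = c(rep("d^-1", 3), "dimensionless", rep("d^-1", 3),
           rep("mmol L^-1 mm^2 cell^-1 d^-1", 2),
           rep("mmol L^-1", 4),
           "cells mm^-2", "cells mm^-2", "dimensionless",
           "mmol L^-1", "dimensionless"),
  stringsAsFactors = FALSE
)

#' Default parameter search bounds for a spec
#'
#' Returns the packaged search-space bounds for every active (structural and
#' error) parameter of the spec.
#'
#' @param spec An `afe_model_spec`.
#' @return A data.frame with columns `parameter`, `lower`, `upper`, `unit`.
#' @export
default_bounds <- function(spec) {
  nm <- c(structural_param_names(spec), error_param_names(spec))
  out <- .afedyn_bounds_table[match(nm, .afedyn_bounds_table$parameter), ]
  rownames(out) <- NULL
  out
}

#' Validate a parameter vector against a spec
#'
#' Checks that every active structural (and, if `xi` given, error)
#' parameter is present, finite, and respects its hard sign constraints.
#'
#' @param spec An `afe_model_spec`.
#' @param theta Named numeric vector of structural parameters.
#' @param xi Optional named numeric vector of error parameters.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_params <- function(spec, theta, xi = NULL) {
  need <- structural_param_names(spec)
  missing <- setdiff(need, names(theta))
  if (length(missing)) {
    stop("missing structural parameter(s): ", paste(missing, collapse = ", "))
  }
  th <- theta[need]
  if (any(!is.finite(th))) stop("non-finite structural parameter value")
  if ("p_ap" %in% need && (th[["p_ap"]] < 0 || th[["p_ap"]] > 1)) {
    stop("p_ap must lie in [0, 1]")
  }
  pos <- setdiff(need, "p_ap")
  if (any(th[pos] <= 0)) {
    stop("rates, reaction constants, MMK constants and n_max must be > 0")
  }
  if (!is.null(xi)) {
    neede <- error_param_names(spec)
    if (length(setdiff(neede, names(xi)))) {
      stop("missing error parameter(s): ",
           paste(setdiff(neede, names(xi)), collapse = ", "))
    }
    if (any(!is.finite(xi[neede])) || any(xi[neede] <= 0)) {
      stop("active error parameters must be positive and finite")
    }
  }
  invisible(TRUE)
}
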