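## Shared fixtures: fast optimizer budgets and small generated datasets.

fast_control <- list(de_evals = 400, nm_maxit = 800, reltol = 1e-8,
                     nm_restarts = 1)

## Warm bounds around a parameter vector (factor box, p_ap handled apart).
warm_bounds <- function(spec, theta, factor = 2) {
  nm <- structural_param_names(spec)
  b <- data.frame(parameter = nm, lower = theta[nm] / factor,
                  upper = theta[nm] * factor)
  if ("p_ap" %in% nm) {
    b[b$parameter == "p_ap", c("lower", "upper")] <-
      c(max(0, theta[["p_ap"]] - 0.2), min(1, theta[["p_ap"]] + 0.2))
  }
  b
}

## A small noiseless M1 dataset under the packaged point estimates.
noiseless_m1_dataset <- function(replicates = 1) {
  tp <- selected_m1_params()
  generate(study_design(replicates), tp$spec, tp$theta,
           c(a_n = 0, a_c = 0), seed = 1)
}
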