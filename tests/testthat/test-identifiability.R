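test_that("the screen flags the rate-translation symmetry and clears glu models", {
  s_m0 <- structural_screen(model_spec("M0", "exponential", "none", "additive"))
  expect_equal(s_m0$structural, "unidentifiable")
  expect_equal(s_m0$method, "witness")
  expect_setequal(s_m0$witness, c("beta_q", "delta_q"))

  s_m1 <- structural_screen(model_spec("M1", "exponential", "none", "additive"))
  expect_equal(s_m1$structural, "unidentifiable")
  expect_setequal(s_m1$witness, c("beta_p", "delta_p"))

  s_glu <- structural_screen(model_spec("M1", "exponential", "glu", "additive"))
  expect_equal(s_glu$structural, "identifiable")
  expect_equal(s_glu$deficiency, 0)
})

test_that("rank deficiency localises to the degenerate parameter subspace", {
  # one-population crowding without environmental coupling: only
  # (beta - delta, beta / n_max) [logistic] or
  # (beta log(n_max) - delta, beta) [Gompertz] reach the output, an exact
  # 1-dimensional symmetry the rank test must find
  for (growth in c("logistic", "gompertz")) {
    s <- structural_screen(model_spec("M0", growth, "none", "additive"))
    expect_equal(s$deficiency, 1)
    expect_equal(s$structural, "unidentifiable")
  }
  # the differentiation flux cross-term breaks both symmetries for M1
  for (growth in c("logistic", "gompertz")) {
    s <- structural_screen(model_spec("M1", growth, "none", "additive"))
    expect_equal(s$deficiency, 0)
  }
  # environmental coupling restores identifiability for M0 too
  s <- structural_screen(model_spec("M0", "logistic", "glu", "additive"))
  expect_equal(s$deficiency, 0)
})

test_that("profile of a quadratic loss reproduces the chi-square interval", {
  # l(psi) = -(psi - 2)^2, Delta = 1.92 -> CI = 2 +/- sqrt(1.92)
  objective <- function(par) 2 * (par[["psi"]] - 2)^2  # -2 l
  pr <- profile_curve(objective, c(psi = 2), "psi",
                      lower = c(psi = -10), upper = c(psi = 10),
                      delta = 1.92)
  expect_false(pr$lower_open)
  expect_false(pr$upper_open)
  expect_equal(unname(pr$ci[["lower"]]), 2 - sqrt(1.92), tolerance = 1e-2)
  expect_equal(unname(pr$ci[["upper"]]), 2 + sqrt(1.92), tolerance = 1e-2)
  # MLE inside the interval; profile never exceeds the maximum
  expect_true(pr$ci[["lower"]] <= 2 && 2 <= pr$ci[["upper"]])
  expect_true(all(pr$pl <= pr$l_max + 1e-6))
})

test_that("profile CIs agree with Wald intervals for a quadratic surface", {
  # two-parameter quadratic with correlation: -2l = q(psi, nu)
  # with hessian H = [[2, 1], [1, 2]] (on the -2l scale)
  objective <- function(par) {
    x <- par[["a"]] - 1
    y <- par[["b"]] + 0.5
    2 * x^2 + 2 * y^2 + 2 * x * y
  }
  pr <- profile_curve(objective, c(a = 1, b = -0.5), "a",
                      lower = c(a = -10, b = -10), upper = c(a = 10, b = 10),
                      delta = qchisq(0.95, 1) / 2)
  # profile of a: -2l_prof = (2 - 1/2) * 2 * x^2 = 3 x^2; crossing at
  # 3 x^2 = 2 * delta
  half <- sqrt(2 * qchisq(0.95, 1) / 2 / 1.5)
  expect_equal(unname(pr$ci[["upper"]] - pr$ci[["lower"]]) / 2, half,
               tolerance = 1e-2)
})

test_that("a parameter with no data support yields an open profile side", {
  # carrying density on data simulated far below capacity
  spec <- model_spec("M1", "logistic", "glu", "additive")
  th <- c(selected_m1_params()$theta, n_max = 3000)
  th[["beta_a"]] <- 1.2; th[["delta_a"]] <- 0.6  # keep populations low
  dat <- generate(study_design(1), spec, th, c(a_n = 0, a_c = 0), seed = 2)
  nm <- structural_param_names(spec)
  b <- data.frame(parameter = nm, lower = th[nm] / 3, upper = th[nm] * 3)
  b[b$parameter == "p_ap", c("lower", "upper")] <- c(0.5, 0.95)
  b[b$parameter == "n_max", c("lower", "upper")] <- c(565.8, 5659)
  mle <- th[nm]
  objective <- function(par) {
    v <- tryCatch(
      neg2loglik(spec, setNames(par, nm), c(a_n = 50, a_c = 1), dat),
      error = function(e) Inf)
    if (is.finite(v)) v else Inf
  }
  pr <- profile_curve(objective, mle, "n_max",
                      lower = setNames(b$lower, nm),
                      upper = setNames(b$upper, nm),
                      n_steps = 12, nm_maxit = 200)
  expect_true(pr$upper_open)
})

test_that("the practical filter eliminates open profiles and flags zero-spanning CIs", {
  mk_profile <- function(parameter, ci, lower_open = FALSE,
                         upper_open = FALSE) {
    structure(list(parameter = parameter, psi = c(ci[1], mean(ci), ci[2]),
                   pl = c(-2, 0, -2), l_max = 0, threshold = -1.92,
                   mle = mean(ci),
                   ci = c(lower = ci[1], upper = ci[2]),
                   lower_open = lower_open, upper_open = upper_open),
              class = "afe_profile")
  }
  profiles <- list(
    "M1:exponential:glu:additive" = list(
      mk_profile("beta_a", c(10.4, 10.7)),
      mk_profile("beta_p", c(-2.9, 3.6))),       # spans zero: flag only
    "M1:logistic:glu:additive" = list(
      mk_profile("beta_a", c(1, 2)),
      mk_profile("n_max", c(1000, 5659), upper_open = TRUE))
  )
  sel <- list(table = data.frame(
    spec = names(profiles), lineage = "M1", k = c(12, 13),
    bic = c(100, 90), rank = c(2, 1)))
  out <- practical_filter(profiles, sel)
  # the better-BIC spec dies on its open profile; the survivor is chosen
  expect_equal(out$chosen, "M1:exponential:glu:additive")
  expect_equal(out$eliminated, "M1:logistic:glu:additive")
  expect_equal(unname(out$flags[["M1:exponential:glu:additive"]]), "beta_p")
})

test_that("model-based profiles stay below the maximum and bracket the MLE", {
  tp <- selected_m1_params()
  dat <- generate(study_design(2), tp$spec, tp$theta, tp$xi, seed = 4)
  nm <- structural_param_names(tp$spec)
  b <- warm_bounds(tp$spec, tp$theta, factor = 1.5)
  f <- fit(tp$spec, dat, role = NULL, bounds = b,
           starts = matrix(tp$theta[nm], 1, dimnames = list(NULL, nm)),
           fixed = tp$xi,
           control = list(de_evals = 0, nm_maxit = 800, nm_restarts = 1,
                          lm_polish = TRUE),
           seed = 3)
  pr <- profile_fit(f, dat, "delta_a", n_steps = 8, nm_maxit = 150)
  expect_true(all(pr$pl <= pr$l_max + 1e-4))
  if (!pr$lower_open && !pr$upper_open) {
    expect_true(pr$ci[["lower"]] <= f$theta_hat[["delta_a"]])
    expect_true(pr$ci[["upper"]] >= f$theta_hat[["delta_a"]])
  }
})
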