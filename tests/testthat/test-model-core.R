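test_that("candidate enumeration has the expected size and members", {
  all72 <- enumerate_models(include_unidentifiable = TRUE)
  kept66 <- enumerate_models(include_unidentifiable = FALSE)
  expect_length(all72, 72)
  expect_length(kept66, 66)

  dropped <- setdiff(names(all72), names(kept66))
  expect_length(dropped, 6)
  for (s in dropped) {
    spec <- parse_spec(s)
    expect_equal(spec$growth, "exponential")
    expect_equal(spec$env, "none")
    expect_true(is_structurally_unidentifiable(spec))
  }

  expect_equal(sum(names(all72) == "M0:exponential:glu:additive"), 1)
  expect_false(any(duplicated(names(all72))))
})

test_that("spec strings round-trip", {
  for (s in c("M0:gompertz:lac:combined", "M1:logistic:glulac:proportional")) {
    expect_equal(spec_string(parse_spec(s)), s)
  }
  expect_error(parse_spec("M1:exponential:glu"), "4")
})

test_that("growth multiplier matches its defining cases", {
  expect_equal(growth_multiplier("exponential", "none", 123, 5, 5), 1)
  expect_equal(
    growth_multiplier("logistic", "none", 3000, 5, 5, c(n_max = 3000)), 0)
  # half-saturation: c_g equal to K_g halves growth
  expect_equal(
    growth_multiplier("exponential", "glu", 10, 29.56, 0, c(K_g = 29.56)),
    0.5)
  # lactate inhibits, glucose promotes, effects multiply
  th <- c(K_g = 10, K_l = 50)
  expect_equal(
    growth_multiplier("exponential", "glulac", 1, 10, 50, th),
    0.5 * 0.5)
  expect_error(growth_multiplier("logistic", "none", 10, 1, 1), "n_max")
  expect_error(growth_multiplier("exponential", "none", -1, 1, 1), ">= 0")
})

test_that("rhs reproduces a hand-evaluated two-population derivative", {
  tp <- selected_m1_params()
  d <- rhs(tp$spec, c(n_a = 100, n_p = 50, c_g = 17.5, c_l = 1), tp$theta)
  # manual evaluation of the lineage equations at the packaged reference estimates
  expect_equal(d[["n_a"]], 33.89, tolerance = 1e-3)
  expect_equal(d[["n_p"]], -12.21, tolerance = 1e-3)
  expect_equal(d[["c_g"]], -0.793, tolerance = 1e-3)
})

test_that("rhs degenerate cases: empty populations and spent glucose", {
  tp <- selected_m1_params()
  d0 <- rhs(tp$spec, c(n_a = 0, n_p = 0, c_g = 17.5, c_l = 1), tp$theta)
  expect_equal(unname(d0[c("n_a", "n_p")]), c(0, 0))
  dg <- rhs(tp$spec, c(n_a = 100, n_p = 50, c_g = 0, c_l = 1), tp$theta)
  expect_equal(dg[["c_g"]], 0)
  expect_error(rhs(tp$spec, c(n_a = NA, n_p = 1, c_g = 1, c_l = 1), tp$theta),
               "NA")
  expect_error(rhs(tp$spec, c(n_a = 1, n_p = 1, c_g = 1, c_l = 1),
                   tp$theta[-1]), "missing")
})

test_that("parameter counts span 6-12 structural and 2-4 error", {
  pc <- function(...) param_count(model_spec(...))
  expect_equal(pc("M0", "exponential", "none", "additive"),
               c(structural = 6, error = 2))
  expect_equal(pc("M1", "exponential", "none", "additive")[["structural"]], 9)
  expect_equal(pc("M1", "logistic", "glulac", "combined"),
               c(structural = 12, error = 4))
  expect_equal(pc("M1", "exponential", "glu", "additive"),
               c(structural = 10, error = 2))
  counts <- vapply(enumerate_models(TRUE), function(s)
    param_count(s)[["structural"]], numeric(1))
  expect_equal(range(counts), c(6, 12))
})

test_that("monolayer density bounds follow the packing geometry", {
  b <- nmax_bounds(15)
  expect_equal(unname(b[["upper"]]), 5659, tolerance = 1e-4)
  expect_equal(unname(b[["lower"]]), unname(b[["upper"]]) / 10)
  # inverse-square scaling in the diameter
  expect_equal(unname(nmax_bounds(30)[["upper"]]),
               unname(nmax_bounds(15)[["upper"]]) / 4)
  expect_error(nmax_bounds(0), "positive")
})

test_that("default bounds reproduce the packaged search space", {
  b <- default_bounds(model_spec("M1", "logistic", "glulac", "combined"))
  row <- function(p) b[b$parameter == p, ]
  expect_equal(c(row("beta_a")$lower, row("beta_a")$upper), c(1e-4, 10))
  expect_equal(c(row("K_l")$lower, row("K_l")$upper), c(0.5, 200))
  expect_equal(c(row("p_ap")$lower, row("p_ap")$upper), c(0, 1))
  expect_equal(c(row("n_max")$lower, row("n_max")$upper), c(565.8, 5659.0))
  expect_equal(c(row("a_n")$lower, row("a_n")$upper), c(0.1, 500))
  # bounds cover exactly the active parameters
  expect_setequal(b$parameter, c(structural_param_names(b_spec <- model_spec(
    "M1", "logistic", "glulac", "combined")), error_param_names(b_spec)))
})

test_that("M1 aggregates to M0 when renewal is certain and rates match", {
  # p_ap = 1, beta_a = beta_p, delta_a = delta_p: total population obeys M0
  m1 <- model_spec("M1", "exponential", "glu", "additive")
  m0 <- model_spec("M0", "exponential", "glu", "additive")
  th1 <- c(beta_a = 1.3, p_ap = 1, delta_a = 0.5, beta_p = 1.3, delta_p = 0.5,
           V_g = 0.02, V_l = 0.01, cbar_g = 20, cbar_l = 10, K_g = 10)
  th0 <- c(beta_q = 1.3, delta_q = 0.5,
           V_g = 0.02, V_l = 0.01, cbar_g = 20, cbar_l = 10, K_g = 10)
  st <- c(n_a = 120, n_p = 60, c_g = 15, c_l = 2)
  d1 <- rhs(m1, st, th1)
  d0 <- rhs(m0, c(n_q = 180, c_g = 15, c_l = 2), th0)
  expect_equal(d1[["n_a"]] + d1[["n_p"]], d0[["n_q"]], tolerance = 1e-12)
  expect_equal(d1[["c_g"]], d0[["c_g"]], tolerance = 1e-12)
})

test_that("glucose is consumed and lactate produced for all valid states", {
  set.seed(1)
  specs <- enumerate_models(TRUE)
  for (i in sample(length(specs), 12)) {
    spec <- specs[[i]]
    th <- reference_params(spec)
    st <- c(n_a = runif(1, 0, 500), n_p = runif(1, 0, 500),
            n_q = runif(1, 0, 1000),
            c_g = runif(1, 0, 20), c_l = runif(1, 0, 10))
    d <- rhs(spec, st[afedyn:::.state_names(spec)], th)
    expect_lte(d[["c_g"]], 0)
    expect_gte(d[["c_l"]], 0)
  }
})

test_that("exponential/no-environment output depends on beta - delta only", {
  spec <- model_spec("M0", "exponential", "none", "additive")
  th <- c(beta_q = 1.2, delta_q = 0.4, V_g = 0.02, V_l = 0.015,
          cbar_g = 20, cbar_l = 10)
  init <- c(n_q = 150, c_g = 17.5, c_l = 1)
  t1 <- simulate_condition(spec, th, init, times = seq(0.5, 4, 0.5))
  th2 <- th
  th2[c("beta_q", "delta_q")] <- th[c("beta_q", "delta_q")] + 0.7
  t2 <- simulate_condition(spec, th2, init, times = seq(0.5, 4, 0.5))
  expect_equal(t1$n_q, t2$n_q, tolerance = 1e-8)
  expect_equal(t1$c_g, t2$c_g, tolerance = 1e-8)
})

test_that("integrator matches the exponential closed form", {
  spec <- model_spec("M0", "exponential", "none", "additive")
  th <- c(beta_q = 1.2, delta_q = 0.4, V_g = 0.02, V_l = 0.015,
          cbar_g = 20, cbar_l = 10)
  tr <- simulate_condition(spec, th, c(n_q = 100, c_g = 17.5, c_l = 1),
                           times = seq(0, 4, 0.25))
  cf <- closed_form_exponential(100, 1.2, 0.4, tr$time)
  expect_lt(max(abs(tr$n_q - cf) / cf), 1e-6)
})
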