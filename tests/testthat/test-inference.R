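test_that("the loss matches direct per-record arithmetic", {
  tp <- selected_m1_params()
  dat <- split_dataset(generate(study_design(4), tp$spec, tp$theta, tp$xi,
                                seed = 2))
  # single-record arithmetic: Z = 10, g = 8, eps = 2
  one <- (10 - 8)^2 / 4 + 2 * log(2) + log(2 * pi)
  expect_equal(one, 4.224, tolerance = 1e-3)

  # full decomposition: sum of per-record contributions equals the total
  l <- neg2loglik(tp$spec, tp$theta, tp$xi, dat, role = "calibration")
  pr <- neg2loglik(tp$spec, tp$theta, tp$xi, dat, role = "calibration",
                   per_record = TRUE)
  expect_equal(sum(pr), l, tolerance = 1e-10)

  # independent oracle: per-record terms recomputed from scratch
  d <- afedyn:::.predict_records(tp$spec, tp$theta, dat, role = "calibration")
  eps <- ifelse(d$observable %in% c("n_a", "n_p"),
                tp$xi[["a_n"]], tp$xi[["a_c"]])
  oracle <- ((d$value - d$g) / eps)^2 + 2 * log(eps) + log(2 * pi)
  expect_equal(sum(oracle), l, tolerance = 1e-4)
})

test_that("a perfect additive fit with unit sd leaves only the constant", {
  tp <- selected_m1_params()
  dat <- generate(study_design(1), tp$spec, tp$theta, c(a_n = 0, a_c = 0),
                  seed = 1)
  m <- nrow(dat)
  l <- neg2loglik(tp$spec, tp$theta, c(a_n = 1, a_c = 1), dat)
  expect_equal(l, m * log(2 * pi), tolerance = 1e-4)
})

test_that("the residual term is an exact quadratic form", {
  tp <- selected_m1_params()
  dat <- generate(study_design(1), tp$spec, tp$theta, c(a_n = 0, a_c = 0),
                  seed = 1)
  m <- nrow(dat)
  # doubling all residuals at fixed eps quadruples the residual sum
  d1 <- dat; d1$value <- d1$value + 1
  d2 <- dat; d2$value <- d2$value + 2
  base <- m * log(2 * pi)  # zero-residual loss at eps = 1
  r1 <- neg2loglik(tp$spec, tp$theta, c(a_n = 1, a_c = 1), d1) - base
  r2 <- neg2loglik(tp$spec, tp$theta, c(a_n = 1, a_c = 1), d2) - base
  expect_equal(r2 / r1, 4, tolerance = 1e-6)
})

test_that("pathological error parameters yield an infinite loss", {
  tp <- selected_m1_params()
  dat <- generate(study_design(1), tp$spec, tp$theta, tp$xi, seed = 1)
  spec_c <- model_spec("M1", "exponential", "glu", "combined")
  l <- neg2loglik(spec_c, tp$theta, c(a_n = 0, b_n = 0, a_c = 0, b_c = 0), dat)
  expect_identical(l, Inf)
})

test_that("Latin hypercube starts stratify every coordinate", {
  spec <- model_spec("M1", "exponential", "glu", "additive")
  b <- default_bounds(spec)
  m <- lhs_starts(100, b, seed = 4)
  expect_equal(dim(m), c(100, 12))  # 10 structural + 2 error
  expect_true(all(sweep(m, 2, b$lower, ">=")))
  expect_true(all(sweep(m, 2, b$upper, "<=")))
  # one point per equal-width bin in every column
  for (j in seq_len(ncol(m))) {
    bins <- floor(100 * (m[, j] - b$lower[j]) / (b$upper[j] - b$lower[j]))
    bins <- pmin(bins, 99)
    expect_equal(sort(bins), 0:99)
  }
  one <- lhs_starts(1, b, seed = 4)
  expect_true(all(one >= b$lower & one <= b$upper))
  bad <- b; bad$upper[1] <- bad$lower[1]
  expect_error(lhs_starts(5, bad), "degenerate")
})

test_that("BIC arithmetic and parsimony ordering", {
  # k = 2, m_s = 48, loss 200
  expect_equal(2 * log(48) + 200, 207.74, tolerance = 1e-3)

  tp <- selected_m1_params()
  dat <- split_dataset(generate(study_design(4), tp$spec, tp$theta, tp$xi,
                                seed = 6))
  # two pseudo-fits with identical parameters (hence identical selection
  # loss) but different inferred-parameter counts: fewer parameters wins
  f_small <- structure(list(spec = tp$spec, theta_hat = tp$theta,
                            xi_hat = tp$xi, role = "calibration",
                            bounds = default_bounds(tp$spec)[1:10, ]),
                       class = "afe_fit")
  f_big <- f_small
  f_big$bounds <- default_bounds(tp$spec)
  b_small <- bic(f_small, dat)
  b_big <- bic(f_big, dat)
  expect_lt(b_small, b_big)
  # adding one parameter with an identical fit costs exactly log(m_s)
  m_s <- sum(dat$role == "selection")
  expect_equal(b_big - b_small, 2 * log(m_s), tolerance = 1e-10)

  sel <- select_models(list(f_small, f_big), dat)
  expect_equal(sel$table$rank[sel$table$k == 10], 1)
})

test_that("lineages are ranked separately and shortlists are capped", {
  tp <- selected_m1_params()
  tm0 <- selected_m0_params()
  dat <- split_dataset(generate(study_design(4), tp$spec, tp$theta, tp$xi,
                                seed = 7))
  dat_tot <- as_total_population(dat)
  mk <- function(spec, theta, xi) {
    structure(list(spec = spec, theta_hat = theta, xi_hat = xi,
                   role = "calibration", bounds = default_bounds(spec)),
              class = "afe_fit")
  }
  fits <- list(mk(tp$spec, tp$theta, tp$xi), mk(tm0$spec, tm0$theta, tm0$xi))
  # M0 fits consume n_q records: merge the two views of the experiment
  merged <- structure(
    rbind(as.data.frame(dat),
          as.data.frame(dat_tot[dat_tot$observable == "n_q", ])),
    class = class(dat), design = attr(dat, "design"))
  sel <- select_models(fits, merged, shortlist_k = 4)
  expect_equal(sort(unique(sel$table$lineage)), c("M0", "M1"))
  # each lineage has its own rank-1 model
  expect_equal(sum(sel$table$rank == 1), 2)
  expect_equal(lengths(sel$shortlist)[["M0"]], 1)
  expect_equal(lengths(sel$shortlist)[["M1"]], 1)
})

test_that("multistart refinement recovers noiseless ground truth", {
  # calibrating the generating model on its own noiseless data must return
  # the generating structural parameters (error scale fixed: zero-noise
  # data carries no information about it)
  tp <- selected_m1_params()
  dat <- noiseless_m1_dataset()
  nm <- structural_param_names(tp$spec)
  b <- warm_bounds(tp$spec, tp$theta, factor = 1.3)
  f <- fit(tp$spec, dat, role = NULL, bounds = b, n_starts = 2,
           fixed = c(a_n = 1, a_c = 0.05),
           control = list(de_evals = 500, nm_maxit = 800, reltol = 1e-10,
                          nm_restarts = 1, lm_polish = TRUE),
           seed = 11)
  rel <- abs(f$theta_hat[nm] - tp$theta[nm]) / abs(tp$theta[nm])
  expect_lt(median(rel), 0.05)
  # best-incumbent bookkeeping: reported loss is the minimum across starts
  expect_equal(f$loss, min(f$start_losses))
  # loss is recomputable from the stored parameters
  expect_equal(
    neg2loglik(tp$spec, f$theta_hat, c(a_n = 1, a_c = 0.05), dat),
    f$loss, tolerance = 1e-8)
})
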