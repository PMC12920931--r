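test_that("the four-condition design yields 48 records per replicate", {
  des <- study_design(4)
  expect_length(des$conditions, 4)
  expect_setequal(
    vapply(des$conditions, `[[`, character(1), "media_change"),
    c("MCH0", "MCH1"))
  expect_setequal(
    unique(vapply(des$conditions, `[[`, numeric(1), "split_ratio")),
    c(0.5, 0.2))

  sched <- design_schedule(des, "M1")
  expect_equal(nrow(sched) * length(des$conditions), 48)
  pop <- sched[sched$observable %in% c("n_a", "n_p"), ]
  conc <- sched[sched$observable %in% c("c_g", "c_l"), ]
  expect_setequal(unique(pop$time_d), c(2, 4))
  expect_setequal(unique(conc$time_d), 1:4)
  expect_equal(nrow(pop) * 4, 16)   # density points per replicate
  expect_equal(nrow(conc) * 4, 32)  # concentration points per replicate

  # halving the concentration period doubles the concentration grid
  des2 <- study_design(4, concentration_period = 0.5)
  conc2 <- design_schedule(des2, "M1")
  conc2 <- conc2[conc2$observable == "c_g", ]
  expect_length(unique(conc2$time_d), 8)
})

test_that("generate produces the full record set with ground truth attached", {
  tp <- selected_m1_params()
  dat <- generate(study_design(1), tp$spec, tp$theta, tp$xi, seed = 3)
  expect_equal(nrow(dat), 48)
  dat4 <- generate(study_design(4), tp$spec, tp$theta, tp$xi, seed = 3)
  expect_equal(nrow(dat4), 192)
  expect_equal(attr(dat4, "spec"), spec_string(tp$spec))
  expect_equal(attr(dat4, "theta"), tp$theta)
  expect_equal(attr(dat4, "seed"), 3)
  # same seed, same data; different seed, different noise
  again <- generate(study_design(4), tp$spec, tp$theta, tp$xi, seed = 3)
  expect_identical(as.data.frame(dat4), as.data.frame(again))
  other <- generate(study_design(4), tp$spec, tp$theta, tp$xi, seed = 4)
  expect_false(identical(dat4$value, other$value))
})

test_that("zero-noise generation hits the closed form at grid times", {
  spec <- model_spec("M0", "exponential", "none", "additive")
  th <- c(beta_q = 1.1, delta_q = 0.3, V_g = 0.02, V_l = 0.01,
          cbar_g = 20, cbar_l = 10)
  des <- study_design(1)
  # overwrite initial states with a known density, MCH0 only
  dat <- generate(des, spec, th, c(a_n = 0, a_c = 0), seed = 1)
  d <- dat[dat$observable == "n_q" & dat$media_change == "MCH0", ]
  for (cid in unique(d$condition_id)) {
    n0 <- design_condition(des, cid)$initial_state[["n_q"]]
    sub <- d[d$condition_id == cid, ]
    expect_equal(sub$value, closed_form_exponential(n0, 1.1, 0.3, sub$time_d),
                 tolerance = 1e-6)
  }
})

test_that("media regimes shape the metabolite traces as expected", {
  tp <- selected_m1_params()
  des <- study_design(1)
  dat <- generate(des, tp$spec, tp$theta, c(a_n = 0, a_c = 0), seed = 1)
  # MCH0: glucose non-increasing, lactate non-decreasing along each condition
  for (cid in grep("MCH0", unique(dat$condition_id), value = TRUE)) {
    g <- dat[dat$condition_id == cid & dat$observable == "c_g", ]
    l <- dat[dat$condition_id == cid & dat$observable == "c_l", ]
    expect_true(all(diff(g$value[order(g$time_d)]) <= 1e-9))
    expect_true(all(diff(l$value[order(l$time_d)]) >= -1e-9))
  }
  # MCH1: trajectory state just after a reset equals the fresh medium
  cond <- design_condition(des, grep("MCH1", names(des$conditions),
                                     value = TRUE)[1])
  traj <- simulate_condition(tp$spec, tp$theta, cond$initial_state,
                             times = 0:4, media_change = "MCH1",
                             media_conc = cond$media_conc)
  expect_equal(trajectory_at(traj, 1, "c_g", post_reset = TRUE),
               cond$media_conc[["c_g"]])
  # and the measurement instant (pre-reset) differs from it
  expect_lt(trajectory_at(traj, 1, "c_g"), cond$media_conc[["c_g"]])
})

test_that("noiseless M1 population records sum to the mean total", {
  tp <- selected_m1_params()
  des <- study_design(1)
  dat <- generate(des, tp$spec, tp$theta, c(a_n = 0, a_c = 0), seed = 1)
  tot <- as_total_population(dat)
  for (cid in unique(dat$condition_id)) {
    cond <- design_condition(des, cid)
    traj <- simulate_condition(tp$spec, tp$theta, cond$initial_state,
                               times = c(2, 4),
                               media_change = cond$media_change,
                               media_conc = cond$media_conc)
    nq <- tot[tot$condition_id == cid & tot$observable == "n_q", ]
    expect_equal(nq$value[order(nq$time_d)],
                 trajectory_at(traj, c(2, 4), "n_a") +
                   trajectory_at(traj, c(2, 4), "n_p"),
                 tolerance = 1e-8)
  }
})

test_that("role splitting is by replicate, 2:1:1, deterministic", {
  tp <- selected_m1_params()
  dat <- generate(study_design(4), tp$spec, tp$theta, tp$xi, seed = 5)
  sp <- split_dataset(dat)
  expect_equal(as.vector(table(sp$role)[c("calibration", "selection",
                                          "validation")]),
               c(96, 48, 48))
  # default assignment: replicates 1,2 calibrate
  expect_setequal(unique(sp$replicate[sp$role == "calibration"]), c(1, 2))
  # role is constant within replicate
  expect_true(all(tapply(sp$role, sp$replicate,
                         function(x) length(unique(x))) == 1))
  # seeded permutation is reproducible
  a <- split_dataset(dat, seed = 9)
  b <- split_dataset(dat, seed = 9)
  expect_identical(a$role, b$role)

  dat3 <- generate(study_design(3), tp$spec, tp$theta, tp$xi, seed = 5)
  expect_error(split_dataset(dat3), "whole replicates")
})

test_that("ground truth round-trips through CSV + sidecar exactly", {
  tp <- selected_m1_params()
  dat <- split_dataset(generate(study_design(4), tp$spec, tp$theta, tp$xi,
                                seed = 8))
  path <- file.path(tempdir(), "afe_roundtrip.csv")
  write_dataset(dat, path)
  back <- suppressWarnings(read_dataset(path))
  expect_equal(attr(back, "theta"), attr(dat, "theta"))
  expect_equal(attr(back, "xi"), attr(dat, "xi"))
  expect_equal(attr(back, "seed"), attr(dat, "seed"))
  expect_equal(back$value, dat$value)
  expect_equal(back$role, dat$role)
  unlink(c(path, sub("\\.csv$", ".json", path)))
})
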