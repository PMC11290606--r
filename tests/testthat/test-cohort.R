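test_that("the generating rules encode the recovery-study distributions", {
  r <- default_sim_rules()
  expect_equal(r$lam_mean, c(0, 0.0026, 0.1537, 0.1537))
  expect_equal(r$lam_sd, c(0, 0.001, 0.1, 0.1))
  expect_equal(r$lam_upper[2], lambda_star())
  expect_equal(r$lam_upper[3:4], c(0.3022, 0.3022))
  expect_equal(r$sigma, c(2.5, 0.5, 0.5, 0.5))
  expect_equal(r$w0_mean, c(0, -2, -2, -2))
  expect_equal(r$w0_sd, c(5, 1, 1, 1))
  expect_true(all(r$w1_shape == 10 & r$w1_rate == 1))
  set.seed(11)
  p1 <- genmix:::draw_sim_params(1L)
  expect_equal(p1$alpha, 0)
  expect_equal(p1$lam, 0)
  lam2 <- replicate(200, genmix:::draw_sim_params(2L)$lam)
  expect_true(all(lam2 > 0 & lam2 <= lambda_star()))
  lam34 <- replicate(200, genmix:::draw_sim_params(sample(3:4, 1))$lam)
  expect_true(all(lam34 > lambda_star() & lam34 <= 0.3022))
})

test_that("simulated percepts are noisy clipped copies of the physical sizes", {
  sch <- realize_schedule(build_exp2_design(), stimuli_exp2(), seed = 3)
  # degenerate noise reproduces the stimulus sizes, and perceptual
  # distances then coincide with physical distances on every trial
  p0 <- simulate_percepts(sch, 0, seed = 1)
  expect_equal(p0, sch$size_mm)
  st <- build_percept_stream(sch, p0)
  cs_p <- sch$size_mm[match("CSplus", sch$role)]
  cs_m <- sch$size_mm[match("CSminus", sch$role)]
  expect_equal(st$d_perc_plus, physical_distance(cs_p, sch$size_mm))
  expect_equal(st$d_perc_minus, physical_distance(cs_m, sch$size_mm))
  # Monte-Carlo noise scale
  set.seed(2)
  big <- replicate(60, simulate_percepts(sch, 5) - sch$size_mm)
  expect_equal(sd(big), 5, tolerance = 0.1)
  expect_true(all(simulate_percepts(sch, 80, seed = 3) >= 0 &
                    simulate_percepts(sch, 80, seed = 3) <= 200))
  expect_error(simulate_percepts(sch, -1), "non-negative")
})

test_that("the default cohort matches the recovery-study dimensions", {
  co <- simulate_cohort(cohort_spec(seed = 77))
  expect_equal(length(co$truth), 200)
  expect_equal(nrow(co$trials), 200 * 180)
  tru <- ground_truth(co)
  expect_equal(as.integer(table(tru$m)), rep(50L, 4))
  expect_true(all(tru$lam[tru$m == 1] == 0))
  expect_true(all(tru$lam[tru$m == 2] <= lambda_star()))
  expect_true(all(tru$lam[tru$m >= 3] > lambda_star()))
})

test_that("stored ground-truth trajectories round-trip through the forward model", {
  co <- simulate_cohort(cohort_spec(n_per_group = c(1L, 1L, 1L, 1L),
                                    seed = 13))
  for (t in co$truth) {
    tr <- co$trials[co$trials$participant_id == t$participant_id, ]
    st <- build_percept_stream(tr, tr$size_estimate_mm)
    redo <- forward_trajectory(tr, t, st, paradigm = "differential")
    expect_equal(redo$theta, t$trajectory$theta, tolerance = 1e-12)
  }
})

test_that("cohort generation is deterministic and honours the response model", {
  a <- simulate_cohort(cohort_spec(n_per_group = c(2L, 2L, 2L, 2L),
                                   seed = 17))
  b <- simulate_cohort(cohort_spec(n_per_group = c(2L, 2L, 2L, 2L),
                                   seed = 17))
  expect_identical(a$trials, b$trials)
  # Non-Learner: ratings scatter around sigmoid(w0) with sd ~ 2.5
  co <- simulate_cohort(cohort_spec(n_per_group = c(6L, 0L, 0L, 0L),
                                    seed = 19))
  for (t in co$truth) {
    y <- co$trials$expectancy[co$trials$participant_id == t$participant_id]
    expect_equal(mean(y), sigmoid_map(0, t$w0, t$w1), tolerance = 0.6)
    expect_equal(sd(y), 2.5, tolerance = 0.45)
  }
  # strong learner with fast decay: at stimuli far from both CSs the
  # similarity vanishes and the response reverts to the baseline
  rules <- default_sim_rules()
  rules$lam_lower[3] <- 0.28
  co3 <- simulate_cohort(cohort_spec(n_per_group = c(0L, 0L, 4L, 0L),
                                     rules = rules, seed = 23))
  for (t in co3$truth) {
    tr <- co3$trials[co3$trials$participant_id == t$participant_id, ]
    cs_p <- tr$size_mm[match("CSplus", tr$role)]
    cs_m <- tr$size_mm[match("CSminus", tr$role)]
    mid <- tr$phase == "generalization" &
      abs(tr$size_mm - cs_p) > 25 & abs(tr$size_mm - cs_m) > 25
    expect_lt(abs(mean(tr$expectancy[mid]) - sigmoid_map(0, t$w0, t$w1)),
              0.5)
  }
})

test_that("higher percept noise flattens the perceptual generalization gradient", {
  grad_range <- function(noise, seed) {
    co <- simulate_cohort(cohort_spec(n_per_group = c(0L, 0L, 0L, 12L),
                                      percept_noise_sd = noise,
                                      seed = seed))
    gs <- gradient_summary(co$trials)
    diff(range(gs$overall$mean))
  }
  for (s in c(5, 9)) {
    spans <- vapply(c(0, 5, 15), grad_range, numeric(1), seed = s)
    expect_true(all(diff(spans) < 0))
  }
})

test_that("cohorts round-trip through the CSV reader", {
  co <- simulate_cohort(cohort_spec(n_per_group = c(1L, 0L, 1L, 0L),
                                    seed = 29))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_cohort(co, csv, js)
  back <- read_trials(csv)
  expect_equal(back$expectancy, co$trials$expectancy, tolerance = 1e-12)
  expect_equal(back$role, co$trials$role)
  tru <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(tru$m, ground_truth(co)$m)
})
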