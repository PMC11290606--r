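test_that("the error-driven update moves strength as prescribed", {
  expect_equal(rw_update(0, 0.5, 1, 1), 0.5)
  expect_equal(rw_update(0.6, 0.2, 0, 1), 0.48)
  expect_equal(rw_update(0.9, 0.7, 1, 0), 0.9)  # no update off CS trials
  # Non-Learners never acquire strength
  expect_equal(rw_update(0.9, 0.7, 1, 1, m = 1L), 0)
  expect_error(rw_update(0.5, 1.2, 1, 1), "alpha")
})

test_that("iterated updates match the closed form under constant reinforcement", {
  for (alpha in c(0, 0.05, 0.3, 0.62, 1)) {
    v <- 0
    for (j in 1:50) {
      v <- rw_update(v, alpha, 1, 1)
      expect_equal(v, 1 - (1 - alpha)^j, tolerance = 1e-12)
    }
  }
})

test_that("physical distance is the absolute diameter difference", {
  expect_equal(physical_distance(96.544, 96.544), 0)
  expect_equal(physical_distance(96.544, 73.672), 22.872)
  expect_equal(round(physical_distance(50.80, 119.416), 2), 68.62)
  expect_equal(physical_distance(50, 70), physical_distance(70, 50))
  expect_error(physical_distance(-1, 5), "non-negative")
})

test_that("the percept stream tracks cumulative CS means and distances", {
  sch <- data.frame(trial = 1:3, role = c("CSplus", "CSplus", "TS"),
                    size_mm = c(96.5, 96.5, 73.7))
  st <- build_percept_stream(sch, c(100, 98, 90))
  expect_equal(st$cum_cs_plus, c(100, 99, 99))
  expect_equal(perceptual_distance(st, 3, "plus"), 9)
  # the current CS percept enters its own cumulative mean before differencing
  sch2 <- data.frame(trial = 1:2, role = c("CSplus", "CSplus"),
                     size_mm = c(96.5, 96.5))
  st2 <- build_percept_stream(sch2, c(100, 104))
  expect_equal(st2$cum_cs_plus[2], 102)
  expect_equal(perceptual_distance(st2, 2, "plus"), 2)
  # a TS percept equal to the cumulative mean has zero distance
  st3 <- build_percept_stream(sch, c(100, 98, 99))
  expect_equal(perceptual_distance(st3, 3, "plus"), 0)
  # undefined before any CS percept exists
  expect_error(perceptual_distance(st, 2, "minus"), "undefined")
})

test_that("missing size estimates leave the cumulative mean unchanged", {
  sch <- data.frame(trial = 1:4,
                    role = c("CSplus", "CSplus", "CSplus", "TS"),
                    size_mm = c(96.5, 96.5, 96.5, 73.7))
  st <- build_percept_stream(sch, c(100, NA, 104, 90))
  expect_equal(st$cum_cs_plus, c(100, 100, 102, 102))
})

test_that("similarity decays exponentially except for degenerate cases", {
  expect_equal(similarity(0.1, 0), 1)
  expect_equal(similarity(0.0052, 68.62), 0.70, tolerance = 0.005)
  expect_equal(similarity(0.1, 10), exp(-1))
  expect_equal(similarity(0.5, 100, m = 1L), 1)     # no learning
  expect_equal(similarity(0.5, 100, m = 3L, v = 0), 1)  # no strength
  # strictly decreasing in distance and rate
  expect_true(all(diff(similarity(0.05, seq(0, 50, 10))) < 0))
  expect_true(all(diff(similarity(seq(0.01, 0.2, 0.05), 20)) < 0))
  expect_error(similarity(-0.1, 5), "non-negative")
  expect_error(similarity(0.1, -5), "non-negative")
})

test_that("generalized strength combines excitatory and inhibitory terms", {
  expect_equal(generalized_strength(1, 1, paradigm = "simple"), 1)
  expect_equal(generalized_strength(0.8, 0.5, -0.6, 0.25, "differential"),
               0.25)
  expect_equal(generalized_strength(0, 0.9, 0, 0.4, "differential"), 0)
  expect_error(generalized_strength(0.5, 0.5, paradigm = "differential"),
               "inhibitory")
})

test_that("the sigmoid mapping respects its anchors and monotonicity", {
  expect_equal(sigmoid_map(0, 0, 1), 5.5)
  expect_equal(sigmoid_map(1e6, 0, 1), 10, tolerance = 1e-9)
  expect_equal(sigmoid_map(1, -2, 10), 9.9969822, tolerance = 1e-6)
  g <- seq(-1, 1, 0.2)
  expect_true(all(diff(sigmoid_map(g, -1, 3)) > 0))
  expect_true(all(sigmoid_map(g, -1, 3) > 1 & sigmoid_map(g, -1, 3) < 10))
  expect_error(sigmoid_map(0, 0, -1), "positive")
})

test_that("forward trajectories reproduce hand-computed expectations", {
  sch <- realize_schedule(build_exp2_design(), stimuli_exp2(), seed = 2)
  # Non-Learner: constant response at sigmoid(w0)
  tr1 <- forward_trajectory(sch, list(m = 1L, alpha = 0, lam = 0, w0 = 0.4,
                                      w1 = 2))
  expect_equal(unique(tr1$theta), sigmoid_map(0, 0.4, 2))
  # full update: v = 1 immediately after the first reinforced CS+ trial
  tr2 <- forward_trajectory(sch, list(m = 3L, alpha = 1, lam = 0.05,
                                      w0 = -2, w1 = 8))
  first_us <- which(sch$role == "CSplus" & sch$us == 1)[1]
  expect_equal(tr2$v_plus[first_us + 1], 1)
  # iterated update on a 3-trial outcome sequence
  v <- 0
  for (r in c(1, 1, 0)) v <- c(v, rw_update(v[length(v)], 0.5, r, 1))
  expect_equal(v[-1], c(0.5, 0.75, 0.375))
})

test_that("a short trajectory equals a hand-unrolled computation", {
  sch <- data.frame(trial = 1:5, phase = "acquisition", block = 0L,
                    role = c("CSplus", "CSminus", "CSplus", "TS", "CSplus"),
                    stimulus = c("S1", "S10", "S1", "S5", "S1"),
                    size_mm = c(50.8, 119.416, 50.8, 81.296, 50.8),
                    us = c(1L, 0L, 0L, 0L, 1L),
                    k = c(1L, 1L, 1L, 0L, 1L))
  p <- list(m = 3L, alpha = 0.4, lam = 0.02, w0 = -1, w1 = 6)
  traj <- forward_trajectory(sch, p, paradigm = "differential")
  # spreadsheet-style unroll, independent of the implementation
  vp <- 0; vm <- 0; theta <- numeric(5)
  r_p <- c(1, 0, 0, 0, 1); k_p <- c(1, 0, 1, 0, 1)
  r_m <- c(0, -1, 0, 0, 0); k_m <- c(0, 1, 0, 0, 0)
  for (j in 1:5) {
    dp <- abs(50.8 - sch$size_mm[j]); dm <- abs(119.416 - sch$size_mm[j])
    sp <- if (vp == 0) 1 else exp(-0.02 * dp)
    sm <- if (vm == 0) 1 else exp(-0.02 * dm)
    g <- vp * sp + vm * sm
    theta[j] <- 1 + 9 / (1 + exp(-(-1 + 6 * g)))
    vp <- vp + 0.4 * (r_p[j] - vp) * k_p[j]
    vm <- vm + 0.4 * (r_m[j] - vm) * k_m[j]
  }
  expect_equal(traj$theta, theta, tolerance = 1e-12)
  expect_equal(traj$v_plus[5], 0.24, tolerance = 1e-12)  # 0.4, 0.24
  expect_equal(traj$v_minus[3], -0.4, tolerance = 1e-12)
})

test_that("latent states stay within their bounds on random inputs", {
  set.seed(8)
  sch <- realize_schedule(build_exp2_design(), stimuli_exp2(), seed = 8)
  per <- simulate_percepts(sch, 8, seed = 9)
  st <- build_percept_stream(sch, per)
  for (rep in 1:10) {
    m <- sample(1:4, 1)
    p <- list(m = m, alpha = if (m == 1) 0 else runif(1),
              lam = if (m == 1) 0 else runif(1, 0.001, 0.4),
              w0 = rnorm(1, 0, 3), w1 = rgamma(1, 10, 1))
    tr <- forward_trajectory(sch, p, st)
    expect_true(all(tr$v_plus >= 0 & tr$v_plus <= 1))
    expect_true(all(tr$v_minus >= -1 & tr$v_minus <= 0))
    expect_true(all(tr$s_plus > 0 & tr$s_plus <= 1))
    expect_true(all(tr$theta > 1 & tr$theta < 10))
  }
})

test_that("response at a test stimulus is non-increasing in physical distance", {
  sch <- realize_schedule(build_exp2_design(), stimuli_exp2(), seed = 5)
  p <- list(m = 3L, alpha = 0.8, lam = 0.08, w0 = -2, w1 = 8)
  tr <- forward_trajectory(sch, p)
  gen <- sch$phase == "generalization"
  mean_theta <- tapply(tr$theta[gen], sch$size_mm[gen], mean)
  d <- abs(as.numeric(names(mean_theta)) - 50.8)
  expect_true(all(diff(mean_theta[order(d)]) <= 1e-9))
})

test_that("the overgeneralization boundary retains 70% at the extreme stimulus", {
  b <- lambda_boundary(68.62, 0.7)
  expect_equal(round(b, 4), 0.0052)
  expect_equal(round(b, 6), 0.005198)
  expect_equal(lambda_boundary(10, 1.0), 0)
  expect_equal(lambda_boundary(10, exp(-1)), 0.1)
  expect_equal(lambda_star(), 0.0052)
  # for an overgeneralizer at the boundary, the farthest response retains
  # at least 70% of the CS response on the latent scale
  expect_gte(similarity(lambda_star(), 68.62), 0.70 - 1e-3)
  expect_error(lambda_boundary(-1, 0.7), "positive")
  expect_error(lambda_boundary(10, 1.5), "retain")
})

test_that("the response log-likelihood is Gaussian and additive", {
  expect_equal(loglik_response(3, 3, 1), -0.5 * log(2 * pi))
  expect_equal(loglik_response(4, 3, 1),
               loglik_response(3, 3, 1) - 0.5)
  y <- c(2.5, 6, 9.1); th <- c(3, 5, 9)
  expect_equal(loglik_response(y, th, 0.7),
               sum(vapply(1:3, function(i)
                 loglik_response(y[i], th[i], 0.7), numeric(1))))
  expect_equal(loglik_response(c(2, NA, 3), c(2, 5, 3), 1),
               loglik_response(c(2, 3), c(2, 3), 1))
  expect_error(loglik_response(1, 1, 0), "positive")
})
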