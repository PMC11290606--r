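test_that("retained-draw accounting matches the closed form", {
  ref <- fit_config("full", preset = "reference", seed = 1)
  rd <- retained_draws(ref)
  expect_equal(rd$per_chain, 2500)
  expect_equal(rd$total, 10000)
  tst <- fit_config("full", preset = "test", seed = 1)
  expect_equal(retained_draws(tst)$per_chain, 1000)
  set.seed(44)
  for (rep in 1:10) {
    it <- sample(1000:20000, 1); bi <- sample(100:(it - 1), 1)
    th <- sample(1:10, 1); ch <- sample(1:4, 1)
    cfg <- fit_config("full", chains = ch, iterations = it, burn_in = bi,
                      thin = th, seed = 1)
    expect_equal(retained_draws(cfg)$per_chain, (it - bi) %/% th)
    expect_equal(retained_draws(cfg)$total, ((it - bi) %/% th) * ch)
  }
  expect_error(fit_config("full", chains = 2, iterations = 100,
                          burn_in = 200, thin = 1, seed = 1))
  expect_error(fit_config("full", preset = "test"), "seed")
})

test_that("fits are reproducible given the seed", {
  co <- simulate_cohort(cohort_spec(n_per_group = c(1L, 0L, 1L, 0L),
                                    seed = 51))
  cfg <- fit_config("full", chains = 2, iterations = 400, burn_in = 200,
                    thin = 2, seed = 52)
  a <- fit(co$trials, cfg)
  b <- fit(co$trials, cfg)
  expect_identical(a$chains, b$chains)
  expect_equal(nrow(a$chains[[1]]), 100)
  expect_true(all(membership_draws(a) %in% 1:4))
})

test_that("a well-determined learner is recovered as its own group", {
  prm <- list(m = 3L, alpha = 0.9, lam = 0.05, w0 = -2, w1 = 8,
              sigma = 0.3)
  tr <- single_trials(prm)
  cfg <- fit_config("full", chains = 2, iterations = 2000, burn_in = 1000,
                    thin = 2, seed = 7)
  ps <- fit(tr, cfg)
  md <- membership_draws(ps)
  expect_equal(as.integer(names(which.max(table(md)))), 3L)
  expect_gt(mean(md == 3L), 0.75)
  lam_med <- posterior_median(ps, "lam")
  expect_equal(unname(lam_med), 0.05, tolerance = 0.3)
})

test_that("with no data the sampler reproduces the hyperpriors", {
  mc <- prior_fit_draws()
  pri <- hyperprior_draws()
  for (p in colnames(pri)) {
    x <- if (p == "pi1") mc[, "pi[1]"] else mc[, p]
    y <- pri[, p]
    expect_lt(abs(median(x) - median(y)),
              0.1 * max(1, abs(median(y))))
    expect_lt(abs(quantile(x, 0.25) - quantile(y, 0.25)),
              0.15 * max(1, abs(quantile(y, 0.25))))
    expect_lt(abs(quantile(x, 0.75) - quantile(y, 0.75)),
              0.15 * max(1, abs(quantile(y, 0.75))))
  }
})

test_that("split R-hat flags divergence and passes convergent chains", {
  # identical constant chains: 1 by convention
  const <- matrix(1, 50, 1, dimnames = list(NULL, "x"))
  expect_equal(rhat(list(const, const, const, const), "x"), 1)
  # one well-mixed target
  set.seed(61)
  ch <- lapply(1:4, function(i)
    matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(rhat(ch, "x"), 1.01)
  # shifted means blow up
  ch2 <- lapply(1:4, function(i)
    matrix(rnorm(1000, mean = i * 3), ncol = 1,
           dimnames = list(NULL, "x")))
  expect_gt(rhat(ch2, "x"), 2)
  expect_error(rhat(list(const), "x"), "two chains")
})

test_that("split R-hat agrees with the classical Gelman-Rubin diagnostic", {
  set.seed(62)
  ch <- lapply(1:4, function(i) matrix(rnorm(4000, 0, 1), ncol = 1,
                                       dimnames = list(NULL, "x")))
  mine <- rhat(ch, "x")
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(ch, coda::mcmc)),
                           autoburnin = FALSE)$psrf[1, 1]
  expect_equal(mine, ref, tolerance = 0.01)
})

test_that("the fitted posterior exposes an R-hat table and persists to disk", {
  st <- recovery_study()
  rt <- rhat_table(st$samples)
  expect_true(all(c("parameter", "rhat", "converged") %in% names(rt)))
  expect_false(any(startsWith(rt$parameter, "m[")))
  # location hyperparameters of a healthy run converge (scale parameters
  # tied to borderline members can stay multimodal across chains)
  hy <- rt[rt$parameter %in% c("mu_alpha", "kappa_alpha", "mu_lambda",
                               "mu_w0", sprintf("pi[%d]", 1:4)), ]
  expect_true(all(hy$rhat < 1.1))
  stem <- tempfile()
  files <- write_posterior(st$samples, stem)
  expect_true(all(file.exists(files)))
  back <- utils::read.csv(files[1], check.names = FALSE)
  expect_equal(nrow(back), retained_draws(st$samples$config)$per_chain)
})

test_that("simplified variants reduce the model as specified", {
  co <- simulate_cohort(cohort_spec(n_per_group = c(1L, 0L, 1L, 1L),
                                    seed = 71))
  cfg <- fit_config("full", chains = 2, iterations = 400, burn_in = 200,
                    thin = 2, seed = 72)
  s1 <- fit_simplified(co$trials, "simplified1", cfg)
  expect_equal(s1$n_groups, 3L)
  expect_true(all(membership_draws(s1) %in% 1:3))
  expect_true("pi[3]" %in% colnames(s1$chains[[1]]))
  expect_false("pi[4]" %in% colnames(s1$chains[[1]]))
  s2 <- fit_simplified(co$trials, "simplified2", cfg)
  expect_equal(s2$n_groups, 4L)
  # the learning rate is not estimated: reported as degenerate zero
  expect_true(all(as.matrix(s2)[, sprintf("alpha[%d]",
                                          s2$participants)] == 0))
})
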