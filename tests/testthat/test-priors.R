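test_that("hyperprior draws respect their supports", {
  set.seed(31)
  draws <- replicate(2000, sample_hyperpriors(), simplify = FALSE)
  get <- function(f) vapply(draws, f, numeric(1))
  expect_true(all(get(function(h) h$kappa_alpha) >= 1 &
                    get(function(h) h$kappa_alpha) <= 10))
  expect_true(all(get(function(h) h$mu_lambda) > 0))
  expect_true(all(get(function(h) h$sigma_lambda) > 0 &
                    get(function(h) h$sigma_lambda) <= 1))
  expect_true(all(get(function(h) h$sigma_learner) < 1.5))
  expect_true(all(get(function(h) h$sigma_nonlearner) >= 1.5 &
                    get(function(h) h$sigma_nonlearner) <= 3))
  pis <- t(vapply(draws, function(h) h$pi, numeric(4)))
  expect_equal(rowSums(pis), rep(1, 2000))
  # symmetric Dirichlet(1,1,1,1): each component mean ~ 0.25
  expect_lt(max(abs(colMeans(pis) - 0.25)), 0.03)
  # derived Beta shapes positive and consistent
  h <- draws[[1]]
  expect_equal(h$a_alpha, h$mu_alpha * h$kappa_alpha)
  expect_equal(h$b_alpha, (1 - h$mu_alpha) * h$kappa_alpha)
})

test_that("participant draws satisfy the group-conditional constraints", {
  h <- hyperparams(mu_alpha = 0.4, kappa_alpha = 5, mu_lambda = 0.1,
                   sigma_lambda = 0.3, mu_w0 = -2, sigma_w0 = 1,
                   a_w1 = 10, b_w1 = 1, sigma_learner = 0.5,
                   sigma_nonlearner = 2.5)
  p1 <- sample_participant(h, 1, seed = 1)
  expect_equal(p1$alpha, 0)
  expect_equal(p1$lam, 0)
  expect_equal(p1$sigma, 2.5)
  set.seed(2)
  lam2 <- replicate(300, sample_participant(h, 2)$lam)
  expect_true(all(lam2 > 0 & lam2 <= lambda_star()))
  lam34 <- replicate(300, sample_participant(h, sample(3:4, 1))$lam)
  expect_true(all(lam34 > lambda_star()))
  # Beta mean: a / (a + b) = mu_alpha
  alphas <- replicate(3000, sample_participant(h, 3)$alpha)
  expect_equal(mean(alphas), 0.4, tolerance = 0.02)
  expect_error(sample_participant(h, 7), "group")
})

test_that("the log prior enforces truncations and degeneracies", {
  h <- hyperparams(mu_alpha = 0.4, kappa_alpha = 5, mu_lambda = 0.1,
                   sigma_lambda = 0.3, mu_w0 = -2, sigma_w0 = 1,
                   a_w1 = 10, b_w1 = 1, sigma_learner = 0.5,
                   sigma_nonlearner = 2.5)
  # an overgeneralizer above the boundary is impossible
  expect_identical(log_prior(list(m = 2, alpha = 0.3, lam = 0.01, w0 = 0,
                                  w1 = 2), h), -Inf)
  expect_identical(log_prior(list(m = 3, alpha = 1.3, lam = 0.1, w0 = 0,
                                  w1 = 2), h), -Inf)
  # Non-Learner: only the w0, w1 and membership terms remain
  lp <- log_prior(list(m = 1, alpha = 0, lam = 0, w0 = -1, w1 = 2), h)
  expect_equal(lp, log(0.25) + dnorm(-1, -2, 1, log = TRUE) +
                 dgamma(2, 10, 1, log = TRUE))
  expect_identical(log_prior(list(m = 1, alpha = 0.2, lam = 0, w0 = 0,
                                  w1 = 2), h), -Inf)
})

test_that("truncated densities normalize over their support", {
  # quadrature oracle for the overgeneralizer truncation
  q <- integrate(function(x) dtnorm(x, 0.1, 0.3, 0, lambda_star()),
                 0, lambda_star())
  expect_equal(q$value, 1, tolerance = 1e-6)
  q2 <- integrate(function(x) dtnorm(x, 0.1, 0.3, lambda_star(), Inf),
                  lambda_star(), Inf)
  expect_equal(q2$value, 1, tolerance = 1e-6)
  expect_identical(dtnorm(0.01, 0.1, 0.3, lower = 0.02), 0)
  # inverse-CDF draws respect bounds and match the density's mean
  set.seed(5)
  x <- rtnorm(20000, 0.1, 0.3, 0, lambda_star())
  expect_true(all(x > 0 & x <= lambda_star()))
  mu_num <- integrate(function(z)
    z * dtnorm(z, 0.1, 0.3, 0, lambda_star()), 0, lambda_star())$value
  expect_lt(abs(mean(x) - mu_num), 5e-5)
})

test_that("the half-Cauchy helpers are consistent", {
  expect_equal(integrate(function(x) dhalfcauchy(x, 2), 0, Inf)$value, 1,
               tolerance = 1e-6)
  expect_identical(dhalfcauchy(-1, 2), 0)
  set.seed(6)
  x <- rhalfcauchy(20000, 2)
  expect_true(all(x > 0))
  expect_equal(median(x), 2, tolerance = 0.1)  # median of |Cauchy(0,s)| = s
})

test_that("the declarative prior specification covers every model parameter", {
  spec <- prior_spec()
  expect_setequal(unique(spec$parameter),
                  c("alpha", "lambda", "w0", "w1", "m", "mu_alpha",
                    "kappa_alpha", "mu_lambda", "sigma_lambda", "mu_w0",
                    "sigma_w0", "a_w1", "b_w1", "sigma_learner",
                    "sigma_nonlearner", "pi"))
  # single source of truth for the group boundary
  lam_rows <- spec[spec$parameter == "lambda" & spec$family == "normal", ]
  expect_equal(sort(unique(c(lam_rows$lower, lam_rows$upper))),
               c(0, lambda_star(), Inf))
  path <- tempfile(fileext = ".yaml")
  prior_spec_yaml(path)
  expect_equal(length(yaml::read_yaml(path)), nrow(spec))
})
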