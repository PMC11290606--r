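## ---- truncated normal and half-Cauchy helpers (inverse-CDF sampling) ----

#' Truncated normal distribution
#'
#' Density, and inverse-CDF random generation, of a Normal(mean, sd^2)
#' truncated to `(lower, upper)`. Normal notation throughout the package is
#' parameterized by the standard deviation.
#'
#' @param x,n quantiles / number of draws.
#' @param mean,sd location and standard deviation.
#' @param lower,upper truncation bounds.
#' @param log return log-density.
#' @return `dtnorm`: (log-)density; `rtnorm`: draws.
#' @export
dtnorm <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf,
                   log = FALSE) {
  lz <- stats::pnorm(lower, mean, sd)
  uz <- stats::pnorm(upper, mean, sd)
  ld <- ifelse(x >= lower & x <= upper,
               stats::dnorm(x, mean, sd, log = TRUE) - base::log(uz - lz),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname dtnorm
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  lz <- stats::pnorm(lower, mean, sd)
  uz <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lz + (uz - lz) * stats::runif(n), mean, sd)
}

#' Half-Cauchy distribution
#'
#' Density and random generation of the Cauchy(0, scale) distribution folded
#' onto `(0, Inf)`.
#'
#' @param x,n quantiles / number of draws.
#' @param scale scale parameter.
#' @param log return log-density.
#' @return `dhalfcauchy`: (log-)density; `rhalfcauchy`: draws.
#' @export
dhalfcauchy <- function(x, scale = 2, log = FALSE) {
  ld <- ifelse(x > 0, base::log(2) + stats::dcauchy(x, 0, scale, log = TRUE),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname dhalfcauchy
#' @export
rhalfcauchy <- function(n, scale = 2) abs(stats::rcauchy(n, 0, scale))

## ---- hyperparameters --------------------------------------------------

#' Construct and validate group-level (hyper)parameters
#'
#' Bundles the population-level parameters of the hierarchical mixture:
#' the Beta mean/concentration of the learning rate (`mu_alpha`,
#' `kappa_alpha`, with derived shapes `a = mu*kappa`, `b = (1-mu)*kappa`),
#' the truncated-normal location/scale of the generalization rate
#' (`mu_lambda`, `sigma_lambda`), the Normal location/scale of the baseline
#' (`mu_w0`, `sigma_w0`), the Gamma shape/rate of the scaling parameter
#' (`a_w1`, `b_w1`), the group-level response noise for learners
#' (`sigma_learner`, in (0, 1.5)) and Non-Learners (`sigma_nonlearner`, in
#' (1.5, 3)), and the mixture weights `pi` (length matching the number of
#' groups, summing to 1).
#'
#' @param mu_alpha,kappa_alpha Beta mean in (0,1) and concentration in [1,10].
#' @param mu_lambda,sigma_lambda truncated-normal location (> 0) and sd.
#' @param mu_w0,sigma_w0 baseline location and sd (> 0).
#' @param a_w1,b_w1 Gamma shape and rate (> 0).
#' @param sigma_learner,sigma_nonlearner response noise sds.
#' @param pi mixture weights.
#' @return A list of class `gm_hyperparams`.
#' @export
hyperparams <- function(mu_alpha, kappa_alpha, mu_lambda, sigma_lambda,
                        mu_w0, sigma_w0, a_w1, b_w1,
                        sigma_learner, sigma_nonlearner,
                        pi = rep(0.25, 4)) {
  stopifnot(mu_alpha > 0, mu_alpha < 1, kappa_alpha >= 1, kappa_alpha <= 10,
            mu_lambda > 0, sigma_lambda > 0, sigma_lambda <= 1,
            sigma_w0 > 0, a_w1 > 0, b_w1 > 0,
            sigma_learner > 0, sigma_learner < 1.5,
            sigma_nonlearner >= 1.5, sigma_nonlearner <= 3,
            all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  structure(list(mu_alpha = mu_alpha, kappa_alpha = kappa_alpha,
                 a_alpha = mu_alpha * kappa_alpha,
                 b_alpha = (1 - mu_alpha) * kappa_alpha,
                 mu_lambda = mu_lambda, sigma_lambda = sigma_lambda,
                 mu_w0 = mu_w0, sigma_w0 = sigma_w0,
                 a_w1 = a_w1, b_w1 = b_w1,
                 sigma_learner = sigma_learner,
                 sigma_nonlearner = sigma_nonlearner,
                 pi = pi),
            class = "gm_hyperparams")
}

#' Draw one set of hyperparameters from the hyperpriors
#'
#' Hyperpriors: `mu_alpha ~ Beta(1,1)`, `kappa_alpha ~ Uniform(1,10)`,
#' `mu_lambda ~ Normal(0.1, 1) T(0,Inf)`, `sigma_lambda ~ Uniform(1e-9, 1)`,
#' `mu_w0 ~ Normal(0, 10^2)`, `sigma_w0 ~ Half-Cauchy(0, 2)`,
#' `a_w1 ~ Half-Cauchy(0, 2)`, `b_w1 ~ Half-Cauchy(0, 2)`,
#' `sigma_learner ~ Uniform(1e-9, 1.5)`,
#' `sigma_nonlearner ~ Uniform(1.5, 3)`, `pi ~ Dirichlet(1, 1, 1, 1)`.
#'
#' @param seed optional integer seed.
#' @param n_groups number of mixture components (4 for the full model).
#' @return A `gm_hyperparams`.
#' @export
sample_hyperpriors <- function(seed = NULL, n_groups = 4L) {
  draw <- function() {
    g <- stats::rgamma(n_groups, 1, 1)  # Dirichlet(1,...,1)
    hyperparams(mu_alpha = stats::rbeta(1, 1, 1),
                kappa_alpha = stats::runif(1, 1, 10),
                mu_lambda = rtnorm(1, 0.1, 1, lower = 0),
                sigma_lambda = stats::runif(1, 1e-9, 1),
                mu_w0 = stats::rnorm(1, 0, 10),
                sigma_w0 = rhalfcauchy(1, 2),
                a_w1 = rhalfcauchy(1, 2),
                b_w1 = rhalfcauchy(1, 2),
                sigma_learner = stats::runif(1, 1e-9, 1.5),
                sigma_nonlearner = stats::runif(1, 1.5, 3),
                pi = g / sum(g))
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Draw person-specific parameters conditional on group membership
#'
#' Group-conditional priors: Non-Learners (`m = 1`) have `alpha = 0` and
#' `lam = 0`; other groups draw `alpha ~ Beta(a_alpha, b_alpha)`.
#' Overgeneralizers (`m = 2`) draw
#' `lam ~ Normal(mu_lambda, sigma_lambda^2) T(0, 0.0052]`; Physical and
#' Perceptual Generalizers truncate to `(0.0052, Inf)`. All groups draw
#' `w0 ~ Normal(mu_w0, sigma_w0^2)` and `w1 ~ Gamma(a_w1, b_w1)`. The
#' response noise is `sigma_nonlearner` for group 1 and `sigma_learner`
#' otherwise.
#'
#' @param hyper a `gm_hyperparams`.
#' @param m latent group in `{1, 2, 3, 4}`.
#' @param seed optional integer seed.
#' @return A list of class `gm_participant_params` with `m`, `alpha`, `lam`,
#'   `w0`, `w1`, `sigma`.
#' @export
sample_participant <- function(hyper, m, seed = NULL) {
  stopifnot(inherits(hyper, "gm_hyperparams"))
  m <- as.integer(m)
  if (!m %in% 1:4) stop("invalid group code")
  b <- lambda_star()
  draw <- function() {
    alpha <- if (m == 1L) 0 else stats::rbeta(1, hyper$a_alpha, hyper$b_alpha)
    lam <- if (m == 1L) 0 else if (m == 2L)
      rtnorm(1, hyper$mu_lambda, hyper$sigma_lambda, 0, b) else
      rtnorm(1, hyper$mu_lambda, hyper$sigma_lambda, b, Inf)
    structure(list(m = m, alpha = alpha, lam = lam,
                   w0 = stats::rnorm(1, hyper$mu_w0, hyper$sigma_w0),
                   w1 = stats::rgamma(1, hyper$a_w1, hyper$b_w1),
                   sigma = if (m == 1L) hyper$sigma_nonlearner else
                     hyper$sigma_learner),
              class = "gm_participant_params")
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Group-conditional log prior density of person-specific parameters
#'
#' Sum of the log densities of `alpha`, `lam`, `w0`, `w1` under the
#' group-conditional priors (including truncation normalizers) and of the
#' group membership under the mixture weights. Constraint violations (e.g.
#' an Overgeneralizer with `lam` above the boundary, or a Non-Learner with
#' nonzero `alpha`) return `-Inf`.
#'
#' @param params a `gm_participant_params` (or compatible list).
#' @param hyper a `gm_hyperparams`.
#' @return Log prior density.
#' @export
log_prior <- function(params, hyper) {
  m <- as.integer(params$m)
  b <- lambda_star()
  lp <- log(hyper$pi[m])
  if (m == 1L) {
    if (params$alpha != 0 || params$lam != 0) return(-Inf)
  } else {
    if (params$alpha < 0 || params$alpha > 1) return(-Inf)
    lp <- lp + stats::dbeta(params$alpha, hyper$a_alpha, hyper$b_alpha,
                            log = TRUE)
    lp <- lp + if (m == 2L)
      dtnorm(params$lam, hyper$mu_lambda, hyper$sigma_lambda, 0, b,
             log = TRUE) else
      dtnorm(params$lam, hyper$mu_lambda, hyper$sigma_lambda, b, Inf,
             log = TRUE)
  }
  lp <- lp + stats::dnorm(params$w0, hyper$mu_w0, hyper$sigma_w0, log = TRUE)
  lp <- lp + stats::dgamma(params$w1, hyper$a_w1, hyper$b_w1, log = TRUE)
  lp
}

#' Declarative prior specification
#'
#' Enumerates every prior and hyperprior of the model -- family, support,
#' truncation bounds, and group conditioning -- as a data frame suitable for
#' audit and YAML export. The generalization-rate truncation bound is
#' [lambda_star()].
#'
#' @return A data frame with columns `parameter`, `condition`, `family`,
#'   `arg1`, `arg2`, `lower`, `upper`, `level`.
#' @export
prior_spec <- function() {
  b <- lambda_star()
  rbind(
    data.frame(parameter = "alpha", condition = "m=1", family = "point",
               arg1 = 0, arg2 = NA, lower = 0, upper = 0, level = "person"),
    data.frame(parameter = "alpha", condition = "m>1", family = "beta",
               arg1 = NA, arg2 = NA, lower = 0, upper = 1, level = "person"),
    data.frame(parameter = "lambda", condition = "m=1", family = "point",
               arg1 = 0, arg2 = NA, lower = 0, upper = 0, level = "person"),
    data.frame(parameter = "lambda", condition = "m=2", family = "normal",
               arg1 = NA, arg2 = NA, lower = 0, upper = b, level = "person"),
    data.frame(parameter = "lambda", condition = "m in {3,4}",
               family = "normal", arg1 = NA, arg2 = NA, lower = b,
               upper = Inf, level = "person"),
    data.frame(parameter = "w0", condition = "all", family = "normal",
               arg1 = NA, arg2 = NA, lower = -Inf, upper = Inf,
               level = "person"),
    data.frame(parameter = "w1", condition = "all", family = "gamma",
               arg1 = NA, arg2 = NA, lower = 0, upper = Inf,
               level = "person"),
    data.frame(parameter = "m", condition = "all", family = "categorical",
               arg1 = NA, arg2 = NA, lower = 1, upper = 4, level = "person"),
    data.frame(parameter = "mu_alpha", condition = "", family = "beta",
               arg1 = 1, arg2 = 1, lower = 0, upper = 1, level = "group"),
    data.frame(parameter = "kappa_alpha", condition = "", family = "uniform",
               arg1 = 1, arg2 = 10, lower = 1, upper = 10, level = "group"),
    data.frame(parameter = "mu_lambda", condition = "", family = "normal",
               arg1 = 0.1, arg2 = 1, lower = 0, upper = Inf,
               level = "group"),
    data.frame(parameter = "sigma_lambda", condition = "",
               family = "uniform", arg1 = 1e-9, arg2 = 1, lower = 1e-9,
               upper = 1, level = "group"),
    data.frame(parameter = "mu_w0", condition = "", family = "normal",
               arg1 = 0, arg2 = 10, lower = -Inf, upper = Inf,
               level = "group"),
    data.frame(parameter = "sigma_w0", condition = "",
               family = "half-cauchy", arg1 = 2, arg2 = NA, lower = 0,
               upper = Inf, level = "group"),
    data.frame(parameter = "a_w1", condition = "", family = "half-cauchy",
               arg1 = 2, arg2 = NA, lower = 0, upper = Inf, level = "group"),
    data.frame(parameter = "b_w1", condition = "", family = "half-cauchy",
               arg1 = 2, arg2 = NA, lower = 0, upper = Inf, level = "group"),
    data.frame(parameter = "sigma_learner", condition = "m in {2,3,4}",
               family = "uniform", arg1 = 1e-9, arg2 = 1.5, lower = 1e-9,
               upper = 1.5, level = "group"),
    data.frame(parameter = "sigma_nonlearner", condition = "m=1",
               family = "uniform", arg1 = 1.5, arg2 = 3, lower = 1.5,
               upper = 3, level = "group"),
    data.frame(parameter = "pi", condition = "", family = "dirichlet",
               arg1 = 1, arg2 = NA, lower = 0, upper = 1, level = "group"))
}

#' Write the prior specification to YAML for audit
#'
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
prior_spec_yaml <- function(path) {
  spec <- prior_spec()
  yaml::write_yaml(lapply(seq_len(nrow(spec)), function(i)
    as.list(spec[i, ])), path)
  invisible(path)
}
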