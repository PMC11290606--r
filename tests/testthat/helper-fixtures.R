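## Shared fixtures. Expensive fits are memoized for the duration of a test
## run; every fixture is generated in code under fixed seeds.

gm_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = gm_cache)) assign(key, expr, envir = gm_cache)
  get(key, envir = gm_cache)
}

empty_trials <- function() {
  data.frame(participant_id = integer(0), trial = integer(0),
             phase = character(0), block = integer(0), role = character(0),
             stimulus = character(0), size_mm = numeric(0), us = integer(0),
             k = integer(0), size_estimate_mm = numeric(0),
             expectancy = numeric(0))
}

## compact differential design used where the canonical protocol length is
## not itself under test
mini_design <- function() {
  build_design("differential", acq_cs_plus = 8L, acq_cs_minus = 8L,
               reinforcement_rate = 0.83, blocks = 2L,
               per_block = c(cs_plus = 6L, cs_minus = 4L, ts = 8L),
               reacquisition = 2L)
}

## one-participant trial table from explicit parameters
single_trials <- function(params, design = build_exp2_design(),
                          sched_seed = 4, percept_seed = 5, y_seed = 6,
                          noise_sd = 5) {
  sch <- realize_schedule(design, stimuli_exp2(), seed = sched_seed)
  per <- simulate_percepts(sch, noise_sd, seed = percept_seed)
  st <- build_percept_stream(sch, per)
  traj <- forward_trajectory(sch, params, st)
  set.seed(y_seed)
  data.frame(participant_id = 1L, sch, size_estimate_mm = per,
             expectancy = rnorm(nrow(sch), traj$theta, params$sigma))
}

## a posterior object built directly from a draw matrix (unit tests of
## allocation / report arithmetic that need exact control of the draws)
fake_posterior <- function(draws, participants, n_groups = 4L) {
  cfg <- fit_config("full", chains = 2, iterations = 40, burn_in = 20,
                    thin = 1, seed = 1)
  half <- nrow(draws) %/% 2
  structure(list(chains = list(draws[seq_len(half), , drop = FALSE],
                               draws[seq.int(half + 1, nrow(draws)), ,
                                     drop = FALSE]),
                 participants = participants, config = cfg,
                 differential = TRUE, n_groups = n_groups),
            class = "gm_posterior")
}

fake_posterior_from_m <- function(m_draws, extra = list()) {
  ids <- seq_len(ncol(m_draws))
  n <- nrow(m_draws)
  cols <- list()
  for (i in ids) cols[[sprintf("m[%d]", i)]] <- m_draws[, i]
  for (p in c("alpha", "lam", "w0", "w1")) {
    vals <- extra[[p]]
    for (i in ids)
      cols[[sprintf("%s[%d]", p, i)]] <-
        if (is.null(vals)) rep(0.1, n) else rep(vals[i], n)
  }
  for (h in c("mu_alpha", "kappa_alpha", "mu_lambda", "sigma_lambda",
              "mu_w0", "sigma_w0", "a_w1", "b_w1"))
    cols[[h]] <- rep(0.5, n)
  cols[["sigma_learner"]] <- rep(if (is.null(extra$sigma_learner)) 0.5 else
    extra$sigma_learner, n)
  cols[["sigma_nonlearner"]] <- rep(2.5, n)
  for (g in 1:4) cols[[sprintf("pi[%d]", g)]] <- rep(0.25, n)
  fake_posterior(do.call(cbind, cols), ids)
}

## the scaled-down recovery study: 10 participants per latent group on the
## differential protocol, test MCMC preset
recovery_study <- function() {
  memo("recovery", {
    cohort <- simulate_cohort(cohort_spec(n_per_group = rep(10L, 4),
                                          seed = 1))
    samples <- fit(cohort$trials, fit_config("full", preset = "test",
                                             seed = 101))
    allocation <- allocate(samples)
    list(cohort = cohort, samples = samples, allocation = allocation,
         recovery = recovery_report(ground_truth(cohort), samples,
                                    allocation))
  })
}

recovery_ppc <- function() {
  memo("recovery_ppc", {
    st <- recovery_study()
    rep <- posterior_predictive(st$samples, st$cohort$trials, R = 100,
                                seed = 7)
    list(rep = rep, report = ppc_quantiles(rep))
  })
}

## empty-data fit: the posterior is the prior; validates every hyper update
prior_fit_draws <- function() {
  memo("prior_fit", {
    cfg <- fit_config("full", chains = 2, iterations = 6000,
                      burn_in = 1000, thin = 2, seed = 3)
    as.matrix(fit(empty_trials(), cfg))
  })
}

hyperprior_draws <- function() {
  memo("hyperprior_draws", {
    set.seed(91)
    t(vapply(seq_len(4000), function(i) {
      h <- sample_hyperpriors()
      c(mu_alpha = h$mu_alpha, kappa_alpha = h$kappa_alpha,
        mu_lambda = h$mu_lambda, sigma_lambda = h$sigma_lambda,
        sigma_learner = h$sigma_learner,
        sigma_nonlearner = h$sigma_nonlearner, pi1 = h$pi[1])
    }, numeric(7)))
  })
}
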