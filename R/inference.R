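#' Configuration of a posterior sampling run
#'
#' The reference preset mirrors the original analysis settings (4 chains,
#' 100,000 iterations, 75,000 burn-in, thinning 10, i.e. 2,500 retained
#' draws per chain and 10,000 in total). The `test` preset (4 chains, 4,000
#' iterations, 2,000 burn-in, thinning 2) is the scaled-down configuration
#' used throughout the test suite.
#'
#' @param variant `"full"` (four-group mixture), `"simplified1"` (no
#'   perceptual-distance pathway: a three-group mixture in which all
#'   generalization follows physical distance) or `"simplified2"` (no
#'   learning process: associative strength fixed at its asymptote from the
#'   first trial, learning rate removed).
#' @param preset `"reference"`, `"test"`, or `"custom"` (use the explicit
#'   chain settings).
#' @param chains,iterations,burn_in,thin MCMC settings; `burn_in <
#'   iterations`, `thin >= 1`.
#' @param seed integer seed; mandatory, drives every chain.
#' @return A list of class `gm_fit_config`.
#' @export
fit_config <- function(variant = c("full", "simplified1", "simplified2"),
                       preset = c("custom", "reference", "test"),
                       chains = 4L, iterations = 100000L, burn_in = 75000L,
                       thin = 10L, seed) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  if (missing(seed)) stop("seed is required")
  if (preset == "reference") {
    chains <- 4L; iterations <- 100000L; burn_in <- 75000L; thin <- 10L
  } else if (preset == "test") {
    chains <- 4L; iterations <- 4000L; burn_in <- 2000L; thin <- 2L
  }
  stopifnot(burn_in < iterations, thin >= 1, chains >= 1)
  structure(list(variant = variant, chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 n_groups = if (variant == "simplified1") 3L else 4L,
                 learning = variant != "simplified2"),
            class = "gm_fit_config")
}

#' Retained draws implied by a configuration
#'
#' @param config a `gm_fit_config`.
#' @return List with `per_chain` (`(iterations - burn_in) / thin`) and
#'   `total`.
#' @export
retained_draws <- function(config) {
  per <- (config$iterations - config$burn_in) %/% config$thin
  list(per_chain = per, total = per * config$chains)
}

## Assemble per-participant matrices (NA-padded) from a long trial table.
## Distances: physical from the participant's CS sizes; perceptual from the
## size-estimate stream (physical fallback before the first CS percept).
prepare_fit_data <- function(trials) {
  if (nrow(trials) == 0) {
    e <- matrix(numeric(0), 0, 1)
    return(list(y = e, dphys_p = e, dperc_p = e, dphys_m = e, dperc_m = e,
                rp = e, kp = e, rm = e, km = e, participants = integer(0),
                differential = FALSE))
  }
  ids <- unique(trials$participant_id)
  differential <- any(trials$role == "CSminus")
  per <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    tr <- tr[order(tr$trial), ]
    stream <- build_percept_stream(tr, tr$size_estimate_mm)
    cs_p <- tr$size_mm[match("CSplus", tr$role)]
    cs_m <- tr$size_mm[match("CSminus", tr$role)]
    list(y = tr$expectancy,
         dphys_p = physical_distance(cs_p, tr$size_mm),
         dperc_p = stream$d_perc_plus,
         dphys_m = if (differential) physical_distance(cs_m, tr$size_mm)
                   else rep(0, nrow(tr)),
         dperc_m = if (differential) stream$d_perc_minus
                   else rep(0, nrow(tr)),
         rp = ifelse(tr$role == "CSplus", tr$us, 0),
         kp = as.numeric(tr$role == "CSplus"),
         rm = ifelse(tr$role == "CSminus", -1, 0),
         km = as.numeric(tr$role == "CSminus"))
  })
  J <- max(vapply(per, function(p) length(p$y), integer(1)))
  pad <- function(x, fill = 0) c(x, rep(fill, J - length(x)))
  tomat <- function(field, fill = 0)
    do.call(rbind, lapply(per, function(p) pad(p[[field]], fill)))
  list(y = tomat("y", NA_real_), dphys_p = tomat("dphys_p"),
       dperc_p = tomat("dperc_p"), dphys_m = tomat("dphys_m"),
       dperc_m = tomat("dperc_m"), rp = tomat("rp"), kp = tomat("kp"),
       rm = tomat("rm"), km = tomat("km"), participants = ids,
       differential = differential)
}

## moderate starting state, jittered per chain through the active RNG
make_inits <- function(N, n_groups) {
  b <- lambda_star()
  list(m = if (N > 0) sample.int(n_groups, N, replace = TRUE) else integer(0),
       alpha_raw = stats::runif(N, 0.2, 0.8),
       lam2 = stats::runif(N, b / 4, 3 * b / 4),
       lam34 = stats::runif(N, 0.02, 0.2),
       w0 = stats::rnorm(N, 0, 1),
       w1 = stats::runif(N, 1, 4),
       mu_alpha = stats::runif(1, 0.3, 0.7),
       kappa_alpha = stats::runif(1, 1.5, 4),
       mu_lambda = stats::runif(1, 0.05, 0.2),
       sigma_lambda = stats::runif(1, 0.2, 0.8),
       mu_w0 = stats::rnorm(1, 0, 1),
       sigma_w0 = stats::runif(1, 1, 3),
       a_w1 = stats::runif(1, 1.5, 3),
       b_w1 = stats::runif(1, 0.5, 1.5),
       sigma_learner = stats::runif(1, 0.4, 1.2),
       sigma_nonlearner = stats::runif(1, 1.7, 2.8),
       pi = rep(1 / n_groups, n_groups))
}

#' Fit the hierarchical mixture model by MCMC
#'
#' Posterior sampling for the full four-group mixture (or a simplified
#' ablation variant) by Gibbs and adaptive Metropolis-within-Gibbs updates:
#' group membership and mixture weights are drawn from their exact full
#' conditionals; continuous parameters use adaptive random-walk proposals
#' (adaptation during burn-in only). Membership is exposed as per-draw
#' integer `m[id]` columns. Reproducible given the configuration seed.
#' With an empty trial table the sampler has no likelihood terms and the
#' draws are samples from the (hyper)priors.
#'
#' Non-convergence is reported through [rhat_table()], never raised.
#'
#' @param trials long-format trial table (see [simulate_cohort()] or
#'   [read_trials()]); expectancy may be `NA` (dropped from the
#'   likelihood).
#' @param config a `gm_fit_config`.
#' @return An object of class `gm_posterior`: per-chain draw matrices with
#'   named columns (`m[id]`, `alpha[id]`, `lam[id]`, `w0[id]`, `w1[id]`,
#'   hyperparameters, `pi[g]`), the participant ids, and the configuration.
#' @export
fit <- function(trials, config) {
  stopifnot(inherits(config, "gm_fit_config"))
  if (nrow(trials) > 0) validate_trials(trials)
  fd <- prepare_fit_data(trials)
  N <- length(fd$participants)
  G <- config$n_groups
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    chains[[ch]] <- withr_seed(config$seed + ch - 1L, {
      inits <- make_inits(N, G)
      res <- gm_run_chain(fd, inits, G, config$learning, fd$differential,
                          lambda_star(), config$iterations, config$burn_in,
                          config$thin)
      res$draws
    })
  }
  cn <- c(sprintf("m[%s]", fd$participants),
          sprintf("alpha[%s]", fd$participants),
          sprintf("lam[%s]", fd$participants),
          sprintf("w0[%s]", fd$participants),
          sprintf("w1[%s]", fd$participants),
          "mu_alpha", "kappa_alpha", "mu_lambda", "sigma_lambda",
          "mu_w0", "sigma_w0", "a_w1", "b_w1", "sigma_learner",
          "sigma_nonlearner", sprintf("pi[%d]", seq_len(G)))
  chains <- lapply(chains, function(m) { colnames(m) <- cn; m })
  structure(list(chains = chains, participants = fd$participants,
                 config = config, differential = fd$differential,
                 n_groups = G),
            class = "gm_posterior")
}

#' Fit a simplified ablation variant
#'
#' `"simplified1"` removes the perceptual-distance pathway (all learners
#' generalize over physical distance; three-group mixture).
#' `"simplified2"` removes the learning process (associative strength fixed
#' at asymptote, `v+ = 1`, `v- = -1`, from the first trial; the learning
#' rate is not estimated).
#'
#' @param trials long-format trial table.
#' @param variant `"simplified1"` or `"simplified2"`.
#' @param config a `gm_fit_config`; its variant is overridden.
#' @return A `gm_posterior`.
#' @export
fit_simplified <- function(trials, variant = c("simplified1", "simplified2"),
                           config) {
  variant <- match.arg(variant)
  config <- fit_config(variant = variant, chains = config$chains,
                       iterations = config$iterations,
                       burn_in = config$burn_in, thin = config$thin,
                       seed = config$seed)
  fit(trials, config)
}

#' @export
print.gm_posterior <- function(x, ...) {
  rd <- retained_draws(x$config)
  cat(sprintf("Posterior (%s variant): %d participants, %d chains x %d draws\n",
              x$config$variant, length(x$participants), x$config$chains,
              rd$per_chain))
  invisible(x)
}

#' @export
as.matrix.gm_posterior <- function(x, ...) do.call(rbind, x$chains)

#' Per-draw group-membership matrix
#'
#' @param samples a `gm_posterior`.
#' @return Integer matrix, draws x participants.
#' @export
membership_draws <- function(samples) {
  m <- as.matrix(samples)[, sprintf("m[%s]", samples$participants),
                          drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- as.character(samples$participants)
  m
}

#' Posterior medians of person-specific parameters
#'
#' @param samples a `gm_posterior`.
#' @param parameter one of `"alpha"`, `"lam"`, `"w0"`, `"w1"`.
#' @return Named numeric vector, one entry per participant.
#' @export
posterior_median <- function(samples,
                             parameter = c("lam", "alpha", "w0", "w1")) {
  parameter <- match.arg(parameter)
  m <- as.matrix(samples)[, sprintf("%s[%s]", parameter,
                                    samples$participants), drop = FALSE]
  stats::setNames(apply(m, 2, stats::median),
                  as.character(samples$participants))
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic computed on split half-chains: each
#' chain is halved, and the ratio of pooled to within-sequence variance is
#' folded into `sqrt((n-1)/n + B/(n W))`. Identical constant chains return
#' exactly 1 by convention. Requires at least two chains.
#'
#' @param samples a `gm_posterior` (or list of draw matrices).
#' @param parameter column name, e.g. `"mu_lambda"` or `"lam[3]"`.
#' @return The R-hat statistic.
#' @export
rhat <- function(samples, parameter) {
  chains <- if (inherits(samples, "gm_posterior")) samples$chains else
    samples
  if (length(chains) < 2) stop("rhat requires at least two chains")
  seqs <- unlist(lapply(chains, function(ch) {
    x <- ch[, parameter]
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq.int(length(x) - n2 + 1, length(x))])
  }), recursive = FALSE)
  split_rhat(seqs)
}

split_rhat <- function(seqs) {
  n <- length(seqs[[1]])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) {
    if (stats::var(means) == 0 || !is.finite(B)) return(1)
    return(Inf)
  }
  sqrt((n - 1) / n + B / (n * W))
}

#' R-hat table for all continuous parameters
#'
#' @param samples a `gm_posterior`.
#' @param threshold values below this are flagged converged (default 1.05).
#' @return Data frame with `parameter`, `rhat`, `converged`; membership
#'   columns (discrete) are excluded.
#' @export
rhat_table <- function(samples, threshold = 1.05) {
  cn <- colnames(samples$chains[[1]])
  cn <- cn[!startsWith(cn, "m[")]
  if (samples$config$variant == "simplified2")
    cn <- cn[!startsWith(cn, "alpha[")]
  r <- vapply(cn, function(p) rhat(samples, p), numeric(1))
  data.frame(parameter = cn, rhat = unname(r),
             converged = unname(r) < threshold, row.names = NULL)
}

#' Persist posterior draws chain-by-chain
#'
#' Writes one CSV per chain (`<stem>_chain<k>.csv`) plus a JSON echo of the
#' configuration for provenance.
#'
#' @param samples a `gm_posterior`.
#' @param stem path stem.
#' @return Invisibly, the files written.
#' @export
write_posterior <- function(samples, stem) {
  files <- character(0)
  for (ch in seq_along(samples$chains)) {
    f <- sprintf("%s_chain%d.csv", stem, ch)
    utils::write.csv(as.data.frame(samples$chains[[ch]]), f,
                     row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- sprintf("%s_config.json", stem)
  jsonlite::write_json(samples$config[c("variant", "chains", "iterations",
                                        "burn_in", "thin", "seed")],
                       cfg, auto_unbox = TRUE)
  invisible(c(files, cfg))
}
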