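#' Generating rules of the recovery simulation
#'
#' The per-group parameter-generating distributions of the simulation study:
#' \itemize{
#'   \item learning rate: `alpha = 0` for Non-Learners,
#'     `alpha ~ Beta(1, 1)` otherwise;
#'   \item generalization rate: `lam = 0` for Non-Learners,
#'     `lam ~ Normal(0.0026, 0.001) T(0, 0.0052)` for Overgeneralizers,
#'     `lam ~ Normal(0.1537, 0.1) T(0.0052, 0.3022)` for Physical and
#'     Perceptual Generalizers (Normal second arguments are standard
#'     deviations);
#'   \item response noise: `sigma = 2.5` for Non-Learners, 0.5 otherwise;
#'   \item baseline: `w0 ~ Normal(0, 5)` for Non-Learners,
#'     `w0 ~ Normal(-2, 1)` otherwise;
#'   \item scaling: `w1 ~ Gamma(10, 1)` for all groups.
#' }
#'
#' @return A data frame with one row per group and the rule parameters.
#' @export
default_sim_rules <- function() {
  data.frame(
    m = 1:4,
    group = c("NonLearner", "Overgeneralizer", "Physical", "Perceptual"),
    lam_mean = c(0, 0.0026, 0.1537, 0.1537),
    lam_sd = c(0, 0.001, 0.1, 0.1),
    lam_lower = c(0, 0, lambda_star(), lambda_star()),
    lam_upper = c(0, lambda_star(), 0.3022, 0.3022),
    sigma = c(2.5, 0.5, 0.5, 0.5),
    w0_mean = c(0, -2, -2, -2),
    w0_sd = c(5, 1, 1, 1),
    w1_shape = 10, w1_rate = 1)
}

## one parameter draw under the simulation rules
draw_sim_params <- function(m, rules = default_sim_rules()) {
  r <- rules[rules$m == m, ]
  list(m = m,
       alpha = if (m == 1L) 0 else stats::rbeta(1, 1, 1),
       lam = if (m == 1L) 0 else
         rtnorm(1, r$lam_mean, r$lam_sd, r$lam_lower, r$lam_upper),
       w0 = stats::rnorm(1, r$w0_mean, r$w0_sd),
       w1 = stats::rgamma(1, r$w1_shape, r$w1_rate),
       sigma = r$sigma)
}

#' Simulate perceived stimulus sizes
#'
#' Size estimates are drawn as `Normal(true size, noise_sd)` and clipped to
#' the 0-200 mm response scale of the size VAS; `noise_sd = 0` reproduces
#' the physical sizes exactly. This generator is a synthetic stand-in for
#' empirical size-estimation data (the protocols collect real estimates; no
#' generative percept model is implied by the fitted model itself).
#'
#' @param schedule a `gm_schedule`.
#' @param noise_sd perceptual noise in mm (>= 0).
#' @param seed optional integer seed.
#' @return Numeric vector of percepts, one per trial.
#' @export
simulate_percepts <- function(schedule, noise_sd = 5, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  draw <- function()
    pmin(pmax(stats::rnorm(nrow(schedule), schedule$size_mm, noise_sd), 0),
         200)
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group integer vector of length 4: participants per latent
#'   group (Non-Learner, Overgeneralizer, Physical, Perceptual). The
#'   recovery-study default is 50 per group (N = 200).
#' @param design a `gm_design`; default differential-conditioning protocol.
#' @param stimuli a `gm_stimulus_set` consistent with the design.
#' @param percept_noise_sd perceptual noise in mm.
#' @param rules generating-rule table, see [default_sim_rules()].
#' @param seed integer seed (required).
#' @param shared_schedule if `TRUE` (default) all participants share one
#'   realized schedule and percept realization structure, mirroring a
#'   recovery study built on a single participant's experimental structure.
#' @return A list of class `gm_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(50L, 50L, 50L, 50L),
                        design = build_exp2_design(),
                        stimuli = stimuli_exp2(),
                        percept_noise_sd = 5,
                        rules = default_sim_rules(),
                        seed,
                        shared_schedule = TRUE) {
  if (missing(seed)) stop("seed is required")
  stopifnot(length(n_per_group) == 4, all(n_per_group >= 0),
            percept_noise_sd >= 0)
  structure(list(n_per_group = as.integer(n_per_group), design = design,
                 stimuli = stimuli, percept_noise_sd = percept_noise_sd,
                 rules = rules, seed = as.integer(seed),
                 shared_schedule = isTRUE(shared_schedule)),
            class = "gm_cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each participant: draw latent group and parameters under the
#' generating rules, realize (or reuse) the trial schedule, simulate
#' percepts, run the deterministic forward model, and draw expectancy
#' ratings `y ~ Normal(theta, sigma_group)`. Ratings are not clipped to the
#' 1-10 scale, matching the untruncated response likelihood. Deterministic
#' given the spec's seed.
#'
#' @param spec a `gm_cohort_spec`.
#' @return A list of class `gm_cohort`: `trials` (long-format data frame,
#'   one row per participant x trial, columns `participant_id`, `trial`,
#'   `phase`, `block`, `role`, `stimulus`, `size_mm`, `us`, `k`,
#'   `size_estimate_mm`, `expectancy`) and `truth` (per-participant list of
#'   true parameters and per-trial latent states).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "gm_cohort_spec"))
  withr_seed(spec$seed, {
    schedule <- realize_schedule(spec$design, spec$stimuli,
                                 seed = sample.int(.Machine$integer.max, 1))
    groups <- rep(1:4, times = spec$n_per_group)
    trials <- vector("list", length(groups))
    truth <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      sched_i <- if (spec$shared_schedule) schedule else
        realize_schedule(spec$design, spec$stimuli,
                         seed = sample.int(.Machine$integer.max, 1))
      pars <- draw_sim_params(groups[i], spec$rules)
      percepts <- simulate_percepts(sched_i, spec$percept_noise_sd)
      stream <- build_percept_stream(sched_i, percepts)
      traj <- forward_trajectory(sched_i, pars, percepts = stream,
                                 paradigm = spec$design$paradigm)
      y <- stats::rnorm(nrow(sched_i), traj$theta, pars$sigma)
      tr <- as.data.frame(sched_i)
      tr$participant_id <- i
      tr$size_estimate_mm <- percepts
      tr$expectancy <- y
      trials[[i]] <- tr
      truth[[i]] <- list(participant_id = i, m = pars$m, alpha = pars$alpha,
                         lam = pars$lam, w0 = pars$w0, w1 = pars$w1,
                         sigma = pars$sigma, trajectory = traj)
    }
    trials <- do.call(rbind, trials)
    trials <- trials[, c("participant_id", "trial", "phase", "block", "role",
                         "stimulus", "size_mm", "us", "k",
                         "size_estimate_mm", "expectancy")]
    structure(list(trials = trials, truth = truth, spec = spec),
              class = "gm_cohort")
  })
}

#' @export
print.gm_cohort <- function(x, ...) {
  n <- length(x$truth)
  cat(sprintf("Synthetic cohort: %d participants (%s per group), %d trials each\n",
              n, paste(x$spec$n_per_group, collapse = "/"),
              nrow(x$trials) / max(n, 1)))
  invisible(x)
}

#' True parameter table of a synthetic cohort
#'
#' @param cohort a `gm_cohort`.
#' @return Data frame with one row per participant: `participant_id`, `m`,
#'   `alpha`, `lam`, `w0`, `w1`, `sigma`.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "gm_cohort"))
  do.call(rbind, lapply(cohort$truth, function(t)
    data.frame(participant_id = t$participant_id, m = t$m, alpha = t$alpha,
               lam = t$lam, w0 = t$w0, w1 = t$w1, sigma = t$sigma)))
}

#' Write a cohort as CSV trials plus a JSON ground-truth sidecar
#'
#' The CSV schema is identical to the one accepted by [read_trials()], so
#' model fitting is agnostic to data provenance.
#'
#' @param cohort a `gm_cohort`.
#' @param csv_path,json_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, csv_path, json_path = NULL) {
  stopifnot(inherits(cohort, "gm_cohort"))
  utils::write.csv(cohort$trials, csv_path, row.names = FALSE, na = "")
  if (!is.null(json_path)) {
    jsonlite::write_json(ground_truth(cohort), json_path, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
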