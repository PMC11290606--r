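#' Rescorla-Wagner associative-strength update
#'
#' One error-driven learning step: `v + alpha * (r - v) * k`. The update flag
#' `k` is 1 on CS trials only, so strength changes only when the relevant cue
#' is presented. Non-Learners (group `m = 1`) never acquire strength and the
#' update returns 0 regardless of the inputs. The trial outcome `r` is coded
#' 1 (US delivered) or 0 (US omitted) for the CS+, and -1 for every CS-
#' trial, driving inhibitory strength towards -1.
#'
#' @param v current associative strength.
#' @param alpha learning rate in `[0, 1]`.
#' @param r trial outcome in `{-1, 0, 1}`.
#' @param k update flag in `{0, 1}`.
#' @param m latent group (1 = Non-Learner, 2 = Overgeneralizer, 3 = Physical,
#'   4 = Perceptual Generalizer).
#' @return Updated associative strength.
#' @export
rw_update <- function(v, alpha, r, k, m = 3L) {
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha must be in [0, 1]")
  ifelse(m == 1L, 0, v + alpha * (r - v) * k)
}

#' Physical stimulus distance
#'
#' Absolute difference between the CS diameter and a test-stimulus diameter,
#' on the physical (mm) dimension; invariant between and within individuals.
#'
#' @param cs_size,ts_size diameters in millimetres.
#' @return Distance in millimetres.
#' @export
physical_distance <- function(cs_size, ts_size) {
  if (any(cs_size < 0) || any(ts_size < 0)) stop("sizes must be non-negative")
  abs(cs_size - ts_size)
}

#' Build a percept stream from trial-level size estimates
#'
#' Tracks, per trial, the running cumulative mean of the perceived CS sizes
#' (separately for CS+ and CS-) and the perceptual distance of the current
#' percept from each cumulative mean. On a CS trial the current percept is
#' included in its own cumulative mean before differencing, so a misperceived
#' CS produces a nonzero within-CS distance. Missing size estimates leave the
#' cumulative mean unchanged; for such trials the physical size stands in for
#' the percept. Before the first CS percept exists the perceptual distance is
#' undefined; `d_perc_*` then falls back to the physical distance (inhibitory
#' strength is still zero at that point, so the value never reaches the
#' likelihood).
#'
#' @param schedule a `gm_schedule` (or data frame with `role`, `size_mm`).
#' @param percepts numeric vector of perceived sizes (VAS, 0-200 mm), one per
#'   trial; `NA` for missing estimates.
#' @param cs_plus_size,cs_minus_size physical CS diameters (mm), used for the
#'   pre-CS fallback and for missing percepts.
#' @return A data frame of class `gm_percept_stream` with columns `percept`,
#'   `cum_cs_plus`, `cum_cs_minus`, `d_perc_plus`, `d_perc_minus`.
#' @export
build_percept_stream <- function(schedule, percepts,
                                 cs_plus_size = NULL, cs_minus_size = NULL) {
  n <- nrow(schedule)
  if (length(percepts) != n) stop("one percept per trial required")
  if (any(percepts < 0 | percepts > 200, na.rm = TRUE))
    stop("percepts must lie in [0, 200] mm")
  if (is.null(cs_plus_size)) {
    i <- which(schedule$role == "CSplus")[1]
    cs_plus_size <- if (is.na(i)) NA_real_ else schedule$size_mm[i]
  }
  if (is.null(cs_minus_size)) {
    i <- which(schedule$role == "CSminus")[1]
    cs_minus_size <- if (is.na(i)) NA_real_ else schedule$size_mm[i]
  }
  cum_p <- cum_m <- rep(NA_real_, n)
  dp <- dm <- rep(NA_real_, n)
  sp <- sm <- 0; np <- nm <- 0L
  for (j in seq_len(n)) {
    x <- percepts[j]
    if (is.na(x)) x <- schedule$size_mm[j]  # physical stand-in
    role <- schedule$role[j]
    if (role == "CSplus" && !is.na(percepts[j])) { np <- np + 1L; sp <- sp + x }
    if (role == "CSminus" && !is.na(percepts[j])) { nm <- nm + 1L; sm <- sm + x }
    cum_p[j] <- if (np > 0) sp / np else NA_real_
    cum_m[j] <- if (nm > 0) sm / nm else NA_real_
    dp[j] <- if (np > 0) abs(cum_p[j] - x) else
      abs(cs_plus_size - schedule$size_mm[j])
    dm[j] <- if (nm > 0) abs(cum_m[j] - x) else
      abs(cs_minus_size - schedule$size_mm[j])
  }
  structure(data.frame(percept = percepts, cum_cs_plus = cum_p,
                       cum_cs_minus = cum_m, d_perc_plus = dp,
                       d_perc_minus = dm),
            class = c("gm_percept_stream", "data.frame"))
}

#' Perceptual distance at a trial
#'
#' `|cumulative mean of CS percepts up to trial j - percept at trial j|`.
#' Errors if no CS percept with index `<= j` exists.
#'
#' @param stream a `gm_percept_stream`.
#' @param j trial index.
#' @param which_cs `"plus"` or `"minus"`.
#' @return Distance in millimetres.
#' @export
perceptual_distance <- function(stream, j, which_cs = c("plus", "minus")) {
  which_cs <- match.arg(which_cs)
  cum <- if (which_cs == "plus") stream$cum_cs_plus[j] else
    stream$cum_cs_minus[j]
  if (is.na(cum))
    stop("perceptual distance undefined: no prior CS", which_cs, " percept")
  if (which_cs == "plus") stream$d_perc_plus[j] else stream$d_perc_minus[j]
}

#' Exponential similarity (Shepard's law) with group conditioning
#'
#' `exp(-lam * d)`, falling to 1 when no learning occurred (`m = 1`) or when
#' associative strength is zero -- a flat response is then independent of the
#' generalization rate.
#'
#' @param lam generalization (decay) rate, per mm; larger values mean faster
#'   similarity decay, i.e. narrower generalization.
#' @param d stimulus distance in mm.
#' @param m latent group.
#' @param v current associative strength.
#' @return Similarity in `(0, 1]`.
#' @export
similarity <- function(lam, d, m = 3L, v = 1) {
  if (any(lam < 0)) stop("lam must be non-negative")
  if (any(d < 0)) stop("distance must be non-negative")
  ifelse(m == 1L | v == 0, 1, exp(-lam * d))
}

#' Generalized associative strength
#'
#' Simple conditioning: `v_plus * s_plus` in `[0, 1]`. Differential
#' conditioning sums the generalized excitatory and inhibitory strengths:
#' `v_plus * s_plus + v_minus * s_minus` in `[-1, 1]`.
#'
#' @param v_plus,s_plus excitatory strength and similarity.
#' @param v_minus,s_minus inhibitory strength (in `[-1, 0]`) and similarity;
#'   required for the differential paradigm.
#' @param paradigm `"simple"` or `"differential"`.
#' @return Generalized strength `g`.
#' @export
generalized_strength <- function(v_plus, s_plus, v_minus = NULL,
                                 s_minus = NULL,
                                 paradigm = c("simple", "differential")) {
  paradigm <- match.arg(paradigm)
  if (paradigm == "simple") return(v_plus * s_plus)
  if (is.null(v_minus) || is.null(s_minus))
    stop("differential paradigm requires inhibitory terms")
  v_plus * s_plus + v_minus * s_minus
}

#' Sigmoid response mapping
#'
#' Maps latent generalized strength onto the expectancy rating scale:
#' `theta = A + (K - A) / (1 + exp(-(w0 + w1 * g)))` with floor `A = 1` and
#' ceiling `K = 10` matching the 1-10 expectancy VAS.
#'
#' @param g generalized associative strength.
#' @param w0 baseline response parameter (logit scale); governs responding in
#'   the absence of associative strength.
#' @param w1 scaling parameter (> 0) between latent and observed scales.
#' @param A,K response floor and ceiling.
#' @return Mean expected rating `theta` in `(A, K)`.
#' @export
sigmoid_map <- function(g, w0, w1, A = 1, K = 10) {
  if (any(w1 <= 0)) stop("w1 must be positive")
  A + (K - A) / (1 + exp(-(w0 + w1 * g)))
}

#' Deterministic forward trajectory of the generative model
#'
#' Runs the composed learning/generalization/response model over a trial
#' schedule for one participant: Rescorla-Wagner updates of excitatory (and,
#' for differential conditioning, inhibitory) strength on CS trials,
#' exponential similarity over physical (groups 2 and 3) or perceptual
#' (group 4) distance, and the sigmoid mapping to the mean rating. The rating
#' on trial `j` reflects the strength *entering* the trial; the trial's
#' outcome updates strength for trial `j + 1` (initial strengths are zero).
#'
#' @param schedule a `gm_schedule`.
#' @param params list with `m`, `alpha`, `lam`, `w0`, `w1` (see
#'   [sample_participant()]).
#' @param percepts a `gm_percept_stream`, required for group 4; ignored for
#'   the physical-distance groups.
#' @param paradigm `"simple"` or `"differential"`; defaults to differential
#'   when the schedule contains CS- trials.
#' @return A data frame of class `gm_trajectory` with per-trial columns
#'   `v_plus`, `v_minus`, `d_plus`, `d_minus`, `s_plus`, `s_minus`, `g`,
#'   `theta`.
#' @export
forward_trajectory <- function(schedule, params, percepts = NULL,
                               paradigm = NULL) {
  n <- nrow(schedule)
  if (is.null(paradigm))
    paradigm <- if (any(schedule$role == "CSminus")) "differential" else
      "simple"
  m <- as.integer(params$m)
  if (m == 4L && is.null(percepts))
    stop("perceptual generalizers require a percept stream")
  if (!is.null(percepts) && nrow(percepts) != n)
    stop("schedule and percept stream are misaligned")
  cs_plus_size <- schedule$size_mm[match("CSplus", schedule$role)]
  cs_minus_size <- schedule$size_mm[match("CSminus", schedule$role)]

  r_plus <- ifelse(schedule$role == "CSplus", schedule$us, 0)
  k_plus <- as.numeric(schedule$role == "CSplus")
  r_minus <- ifelse(schedule$role == "CSminus", -1, 0)
  k_minus <- as.numeric(schedule$role == "CSminus")

  v_plus <- v_minus <- d_plus <- d_minus <-
    s_plus <- s_minus <- g <- theta <- numeric(n)
  vp <- vm <- 0
  for (j in seq_len(n)) {
    v_plus[j] <- vp; v_minus[j] <- vm
    if (m == 4L) {
      d_plus[j] <- percepts$d_perc_plus[j]
      d_minus[j] <- if (paradigm == "differential")
        percepts$d_perc_minus[j] else NA_real_
    } else {
      d_plus[j] <- physical_distance(cs_plus_size, schedule$size_mm[j])
      d_minus[j] <- if (paradigm == "differential")
        physical_distance(cs_minus_size, schedule$size_mm[j]) else NA_real_
    }
    s_plus[j] <- similarity(params$lam, d_plus[j], m, vp)
    g[j] <- if (paradigm == "differential") {
      s_minus[j] <- similarity(params$lam, d_minus[j], m, vm)
      generalized_strength(vp, s_plus[j], vm, s_minus[j], "differential")
    } else {
      s_minus[j] <- NA_real_
      generalized_strength(vp, s_plus[j], paradigm = "simple")
    }
    theta[j] <- sigmoid_map(g[j], params$w0, params$w1)
    vp <- rw_update(vp, params$alpha, r_plus[j], k_plus[j], m)
    vm <- rw_update(vm, params$alpha, r_minus[j], k_minus[j], m)
  }
  structure(data.frame(trial = schedule$trial, v_plus = v_plus,
                       v_minus = v_minus, d_plus = d_plus, d_minus = d_minus,
                       s_plus = s_plus, s_minus = s_minus, g = g,
                       theta = theta),
            class = c("gm_trajectory", "data.frame"))
}

#' Gaussian response log-likelihood
#'
#' Ratings are modelled as `y ~ Normal(theta, sigma^2)` with no truncation to
#' the 1-10 scale (the model may predict values outside the observed response
#' range). Missing ratings contribute nothing.
#'
#' @param y observed rating(s); `NA` allowed.
#' @param theta mean expected rating(s).
#' @param sigma response noise standard deviation (> 0).
#' @return Sum of per-trial Gaussian log-densities.
#' @export
loglik_response <- function(y, theta, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  sum(stats::dnorm(y, theta, sigma, log = TRUE), na.rm = TRUE)
}

#' Overgeneralization boundary for the generalization rate
#'
#' The decay rate at which exponential similarity retains a fraction
#' `retain` of the learned response at the maximum CS-to-stimulus distance:
#' `-log(retain) / d_max`. With the canonical maximum physical distance
#' 68.62 mm and 70% retention this gives 0.005198..., i.e. 0.0052 after
#' 4-dp rounding -- the boundary separating Overgeneralizers (group 2,
#' `lam <= 0.0052`) from Physical/Perceptual Generalizers (`lam > 0.0052`).
#'
#' @param d_max maximum distance in mm (> 0).
#' @param retain retained response fraction in `(0, 1]`.
#' @return Decay rate (1/mm).
#' @export
lambda_boundary <- function(d_max = 68.62, retain = 0.7) {
  if (d_max <= 0) stop("d_max must be positive")
  if (retain <= 0 || retain > 1) stop("retain must be in (0, 1]")
  -log(retain) / d_max
}

#' The canonical group-boundary value of the generalization rate
#'
#' `round(lambda_boundary(68.62, 0.7), 4)` = 0.0052; the single source of
#' truth shared by the prior truncations, the cohort generator, and the
#' sampler.
#'
#' @return The boundary 0.0052 (1/mm).
#' @export
lambda_star <- function() round(lambda_boundary(68.62, 0.7), 4)
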