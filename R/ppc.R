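#' Draw replicated data sets from the posterior predictive distribution
#'
#' Each replicate pairs one joint posterior draw (all parameters of all
#' participants from a single MCMC row) with one pass of the forward model
#' plus Gaussian response noise -- no mixing of draws within a replicate.
#' Replicated ratings are not truncated to the 1-10 scale, so values outside
#' the observed response range can and do occur.
#'
#' @param samples a `gm_posterior`.
#' @param trials the trial table the model was fitted to.
#' @param R number of replicates (reference analyses use 5000; the test
#'   preset uses 200).
#' @param seed integer seed.
#' @return An object of class `gm_ppc_rep`: list with `yrep` (matrix,
#'   `R` x `nrow(trials)`, columns aligned with the rows of `trials`),
#'   `trials`, and `R`.
#' @export
posterior_predictive <- function(samples, trials, R = 200, seed = 1) {
  stopifnot(R >= 1)
  fd <- prepare_fit_data(trials)
  draws <- as.matrix(samples)
  ids <- samples$participants
  learning <- samples$config$learning
  rows_of <- lapply(ids, function(id)
    which(trials$participant_id == id)[order(trials$trial[
      trials$participant_id == id])])
  nobs_i <- vapply(rows_of, length, integer(1))
  withr_seed(seed, {
    picks <- sample.int(nrow(draws), R, replace = TRUE)
    yrep <- matrix(NA_real_, R, nrow(trials))
    for (r in seq_len(R)) {
      dr <- draws[picks[r], ]
      for (ii in seq_along(ids)) {
        id <- ids[ii]
        m <- dr[sprintf("m[%s]", id)]
        sigma <- if (m == 1) dr["sigma_nonlearner"] else dr["sigma_learner"]
        J <- nobs_i[ii]
        fw <- gm_cpp_forward(fd$y[ii, seq_len(J)],
                             fd$dphys_p[ii, seq_len(J)],
                             fd$dperc_p[ii, seq_len(J)],
                             fd$dphys_m[ii, seq_len(J)],
                             fd$dperc_m[ii, seq_len(J)],
                             fd$rp[ii, seq_len(J)], fd$kp[ii, seq_len(J)],
                             fd$rm[ii, seq_len(J)], fd$km[ii, seq_len(J)],
                             as.integer(m), dr[sprintf("alpha[%s]", id)],
                             dr[sprintf("lam[%s]", id)],
                             dr[sprintf("w0[%s]", id)],
                             dr[sprintf("w1[%s]", id)], sigma,
                             learning, fd$differential)
        yrep[r, rows_of[[ii]]] <- stats::rnorm(J, fw$theta, sigma)
      }
    }
    structure(list(yrep = yrep, trials = trials, R = R),
              class = "gm_ppc_rep")
  })
}

ppc_stats <- function(y, stim, levels, probs) {
  sapply(levels, function(s) {
    v <- y[stim == s]
    v <- v[!is.na(v)]
    c(mean = mean(v), stats::quantile(v, probs, names = TRUE))
  })
}

#' Posterior predictive check: per-stimulus means and quantiles
#'
#' Compares, across the stimulus dimension of the generalization phase, the
#' observed mean and the 10/30/50/70/90% quantiles of the ratings with the
#' distribution of the same statistics over replicated data sets (central
#' 95% band over replicates). Quantiles use the linear-interpolation sample
#' estimator (type 7).
#'
#' @param rep a `gm_ppc_rep` from [posterior_predictive()].
#' @param phase trials to summarize (default generalization phase).
#' @return An object of class `gm_ppc_report`: data frame with one row per
#'   stimulus x statistic: `stimulus`, `size_mm`, `stat`, `observed`,
#'   `rep_lo`, `rep_med`, `rep_hi`, `inside`; attribute `R`.
#' @export
ppc_quantiles <- function(rep, phase = "generalization") {
  tr <- rep$trials
  keep <- tr$phase == phase
  if (!any(keep)) stop("no trials in the requested phase")
  stim <- tr$stimulus[keep]
  levels <- unique(stim[order(tr$size_mm[keep])])
  if (any(!vapply(levels, function(s) any(stim == s), logical(1))))
    stop("empty stimulus cell")
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  obs <- ppc_stats(tr$expectancy[keep], stim, levels, probs)
  reps <- apply(rep$yrep[, keep, drop = FALSE], 1, function(y)
    ppc_stats(y, stim, levels, probs))
  # reps: (stat x stimulus) flattened by replicate
  nstat <- nrow(obs)
  out <- do.call(rbind, lapply(seq_along(levels), function(si) {
    do.call(rbind, lapply(seq_len(nstat), function(ki) {
      idx <- (si - 1) * nstat + ki
      band <- stats::quantile(reps[idx, ], c(0.025, 0.5, 0.975))
      data.frame(stimulus = levels[si],
                 size_mm = tr$size_mm[keep][match(levels[si], stim)],
                 stat = rownames(obs)[ki], observed = obs[ki, si],
                 rep_lo = band[[1]], rep_med = band[[2]],
                 rep_hi = band[[3]],
                 inside = obs[ki, si] >= band[[1]] &
                   obs[ki, si] <= band[[3]])
    }))
  }))
  rownames(out) <- NULL
  structure(out, class = c("gm_ppc_report", "data.frame"), R = rep$R)
}

#' Parameter-recovery report against known ground truth
#'
#' For each of the generalization and learning rates: true vs
#' posterior-median pairs, mean signed bias, RMSE, and Spearman rank
#' correlation (overall and restricted to correctly allocated learners),
#' plus the confusion matrix of true group against allocated label.
#'
#' @param truth ground-truth data frame from [ground_truth()].
#' @param samples a `gm_posterior`.
#' @param allocation optional `gm_allocation`; computed at 0.75 if missing.
#' @return An object of class `gm_recovery`: list with `pairs` (per
#'   participant: true and estimated `lam`, `alpha`, labels), `metrics`
#'   (per parameter), and `confusion`.
#' @export
recovery_report <- function(truth, samples, allocation = NULL) {
  if (is.null(truth)) stop("ground truth is required")
  if (is.null(allocation)) allocation <- allocate(samples)
  est_lam <- posterior_median(samples, "lam")
  est_alpha <- posterior_median(samples, "alpha")
  key <- as.character(truth$participant_id)
  pairs <- data.frame(participant_id = truth$participant_id,
                      true_m = truth$m,
                      label = allocation$label[match(key,
                        allocation$participant_id)],
                      true_lam = truth$lam, est_lam = est_lam[key],
                      true_alpha = truth$alpha, est_alpha = est_alpha[key])
  metric <- function(true, est, sel) {
    true <- true[sel]; est <- est[sel]
    data.frame(n = sum(sel), bias = mean(est - true),
               rmse = sqrt(mean((est - true)^2)),
               rank_cor = if (sum(sel) > 2 && stats::sd(true) > 0)
                 stats::cor(true, est, method = "spearman") else NA_real_)
  }
  learners <- pairs$true_m >= 2
  correct <- !is.na(pairs$label) &
    pairs$label == group_labels()[pairs$true_m]
  metrics <- rbind(
    cbind(parameter = "lam", subset = "learners",
          metric(pairs$true_lam, pairs$est_lam, learners)),
    cbind(parameter = "lam", subset = "correctly allocated learners",
          metric(pairs$true_lam, pairs$est_lam, learners & correct)),
    cbind(parameter = "alpha", subset = "learners",
          metric(pairs$true_alpha, pairs$est_alpha, learners)),
    cbind(parameter = "alpha", subset = "correctly allocated learners",
          metric(pairs$true_alpha, pairs$est_alpha, learners & correct)))
  labs <- c(group_labels(), "Unknown")
  confusion <- table(true = factor(group_labels()[pairs$true_m],
                                   levels = group_labels()),
                     allocated = factor(pairs$label, levels = labs))
  structure(list(pairs = pairs, metrics = metrics, confusion = confusion),
            class = "gm_recovery")
}

#' @export
print.gm_recovery <- function(x, ...) {
  cat("Parameter recovery:\n")
  print(x$metrics, row.names = FALSE)
  cat("\nConfusion (true x allocated):\n")
  print(x$confusion)
  invisible(x)
}

#' Fraction of participants allocated to their true group
#'
#' @param recovery a `gm_recovery` (or truth + allocation pair via
#'   [recovery_report()]).
#' @param count_unknown whether Unknown allocations count as errors
#'   (default) or are excluded from the denominator.
#' @return Correct-allocation fraction.
#' @export
allocation_accuracy <- function(recovery, count_unknown = TRUE) {
  p <- recovery$pairs
  correct <- !is.na(p$label) & p$label == group_labels()[p$true_m]
  if (count_unknown) mean(correct) else
    mean(correct[p$label != "Unknown"])
}

#' Mean generalization gradients
#'
#' Per-stimulus mean expectancy over the generalization phase: the cohort
#' average, per-group averages when an allocation is supplied, and the
#' individual gradients.
#'
#' @param trials long-format trial table.
#' @param allocation optional `gm_allocation` used to group participants.
#' @return A list with `overall` (stimulus, size_mm, mean), `by_group`
#'   (when allocated) and `individual` (participant x stimulus matrix of
#'   means).
#' @export
gradient_summary <- function(trials, allocation = NULL) {
  g <- trials[trials$phase == "generalization", ]
  if (nrow(g) == 0) stop("no generalization-phase data")
  ord <- order(g$size_mm)
  levels <- unique(g$stimulus[ord])
  sizes <- g$size_mm[match(levels, g$stimulus)]
  indiv <- tapply(g$expectancy, list(g$participant_id, g$stimulus),
                  mean, na.rm = TRUE)
  indiv <- indiv[, levels, drop = FALSE]
  overall <- data.frame(stimulus = levels, size_mm = sizes,
                        mean = colMeans(indiv, na.rm = TRUE))
  by_group <- NULL
  if (!is.null(allocation)) {
    lab <- allocation$label[match(rownames(indiv),
                                  allocation$participant_id)]
    by_group <- do.call(rbind, lapply(unique(lab), function(l) {
      data.frame(label = l, stimulus = levels, size_mm = sizes,
                 mean = colMeans(indiv[lab == l, , drop = FALSE],
                                 na.rm = TRUE))
    }))
  }
  list(overall = overall, by_group = by_group, individual = indiv)
}

#' Plot mean generalization gradients
#'
#' @param gs result of [gradient_summary()].
#' @return A ggplot object.
#' @export
plot_gradient <- function(gs) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- if (!is.null(gs$by_group)) gs$by_group else
    cbind(label = "all", gs$overall)
  ggplot2::ggplot(df, ggplot2::aes(x = size_mm, y = mean,
                                   colour = label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus size (mm)", y = "mean US expectancy")
}

#' Plot a posterior predictive report
#'
#' @param report a `gm_ppc_report`.
#' @return A ggplot object.
#' @export
plot_ppc <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(report, ggplot2::aes(x = size_mm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = rep_lo,
                                      ymax = rep_hi), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = observed)) +
    ggplot2::facet_wrap(~stat) +
    ggplot2::labs(x = "stimulus size (mm)", y = "US expectancy")
}
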