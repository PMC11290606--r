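#' Latent-group labels
#'
#' @return Character vector naming groups 1-4.
#' @export
group_labels <- function() c("NonLearner", "Overgeneralizer", "Physical",
                             "Perceptual")

#' Allocate participants to latent groups from membership draws
#'
#' A participant is assigned to their modal posterior group when at least
#' `threshold` of the membership draws agree (the comparison is inclusive:
#' a fraction exactly at the threshold allocates); otherwise they fall into
#' the Unknown category. Ties for the mode are Unknown. Cohort-level group
#' proportions are reported two ways: the empirical share of allocated
#' labels, and equal-tailed 95% credible intervals of the mixture weights
#' `pi` -- these are distinct quantities and both are returned.
#'
#' @param samples a `gm_posterior`.
#' @param threshold allocation threshold in `(0.25, 1]`; default 0.75.
#' @return An object of class `gm_allocation`: a data frame with
#'   `participant_id`, `modal_group`, `fraction`, `label`; attributes
#'   `threshold`, `proportions` (share of each label among participants)
#'   and `pi_ci` (posterior mixture-weight intervals).
#' @export
allocate <- function(samples, threshold = 0.75) {
  if (threshold <= 0.25 || threshold > 1)
    stop("threshold must lie in (0.25, 1]")
  md <- membership_draws(samples)
  labs <- group_labels()[seq_len(samples$n_groups)]
  per <- lapply(seq_len(ncol(md)), function(i) {
    tab <- tabulate(md[, i], nbins = samples$n_groups)
    frac <- max(tab) / sum(tab)
    tie <- sum(tab == max(tab)) > 1
    modal <- which.max(tab)
    label <- if (!tie && frac >= threshold) labs[modal] else "Unknown"
    data.frame(participant_id = colnames(md)[i], modal_group = modal,
               fraction = frac, label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  prop <- table(factor(out$label, levels = c(labs, "Unknown"))) / nrow(out)
  pim <- as.matrix(samples)[, sprintf("pi[%d]", seq_len(samples$n_groups)),
                            drop = FALSE]
  ci <- t(apply(pim, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  rownames(ci) <- labs
  structure(out, class = c("gm_allocation", "data.frame"),
            threshold = threshold, proportions = c(prop), pi_ci = ci)
}

#' @export
print.gm_allocation <- function(x, ...) {
  cat(sprintf("Allocation at threshold %.2f (n = %d):\n",
              attr(x, "threshold"), nrow(x)))
  print(round(attr(x, "proportions"), 3))
  invisible(x)
}

#' Allocation sensitivity over a set of thresholds
#'
#' Re-allocates at each threshold; because the allocation rule only
#' tightens, the Unknown count is monotone non-decreasing in the threshold.
#'
#' @param samples a `gm_posterior`.
#' @param thresholds numeric vector of thresholds.
#' @return A data frame with one row per threshold: `threshold`,
#'   `n_unknown`, and one count column per group label; attribute
#'   `allocations` holds the full `gm_allocation` objects.
#' @export
sensitivity <- function(samples, thresholds = c(0.5, 0.75, 0.9)) {
  allocs <- lapply(thresholds, function(t) allocate(samples, t))
  labs <- c(group_labels()[seq_len(samples$n_groups)], "Unknown")
  tab <- do.call(rbind, lapply(seq_along(thresholds), function(k) {
    cnt <- table(factor(allocs[[k]]$label, levels = labs))
    cbind(data.frame(threshold = thresholds[k],
                     n_unknown = unname(cnt[["Unknown"]])),
          as.data.frame.matrix(t(as.matrix(cnt))))
  }))
  attr(tab, "allocations") <- allocs
  tab
}

#' Write an allocation table as CSV
#'
#' @param allocation a `gm_allocation`.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_allocation <- function(allocation, path) {
  utils::write.csv(as.data.frame(allocation), path, row.names = FALSE)
  invisible(path)
}
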