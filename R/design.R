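#' Construct an equally spaced stimulus set
#'
#' Builds the circle-diameter grid used in size-based fear generalization
#' protocols: `n_stimuli` diameters starting at `min_mm` with constant spacing
#' `step_mm`, labelled `S1 ... Sn` (or custom labels, e.g. the `S4 ... S10`
#' subset used in a simple-conditioning variant).
#'
#' The canonical grid of the implemented protocols runs from 50.80 mm to
#' 119.416 mm in steps of 7.624 mm (printed to two decimals: 50.80, ...,
#' 96.54, ..., 119.42).
#'
#' @param n_stimuli number of stimuli (>= 2).
#' @param min_mm smallest diameter in millimetres.
#' @param step_mm constant spacing in millimetres (> 0).
#' @param cs_plus label of the CS+ stimulus.
#' @param cs_minus label of the CS- stimulus, or `NULL` for simple
#'   conditioning.
#' @param labels optional character vector of stimulus labels; defaults to
#'   `S1 ... Sn`.
#' @return An object of class `gm_stimulus_set`: a list with `diameters_mm`
#'   (named numeric vector), `labels`, `cs_plus`, `cs_minus`.
#' @examples
#' ss <- build_stimulus_set(10, 50.80, 7.624, cs_plus = "S7")
#' ss$diameters_mm[["S7"]]  # 96.544
#' @export
build_stimulus_set <- function(n_stimuli, min_mm, step_mm, cs_plus,
                               cs_minus = NULL, labels = NULL) {
  if (n_stimuli < 2) stop("need at least two stimuli")
  if (step_mm <= 0) stop("step_mm must be positive")
  if (is.null(labels)) labels <- paste0("S", seq_len(n_stimuli))
  if (length(labels) != n_stimuli) stop("labels length must equal n_stimuli")
  d <- min_mm + (seq_len(n_stimuli) - 1) * step_mm
  if (any(d <= 0) || any(d >= 200))
    stop("diameters must lie in (0, 200) mm")
  names(d) <- labels
  if (!cs_plus %in% labels) stop("cs_plus label not in stimulus set")
  if (!is.null(cs_minus) && !cs_minus %in% labels)
    stop("cs_minus label not in stimulus set")
  structure(list(diameters_mm = d, labels = labels,
                 cs_plus = cs_plus, cs_minus = cs_minus),
            class = "gm_stimulus_set")
}

#' @export
print.gm_stimulus_set <- function(x, ...) {
  cat("Stimulus set:", length(x$labels), "stimuli,",
      sprintf("%.2f-%.2f mm", min(x$diameters_mm), max(x$diameters_mm)), "\n")
  cat("  CS+:", x$cs_plus,
      if (!is.null(x$cs_minus)) paste(" CS-:", x$cs_minus) else "(simple)",
      "\n")
  invisible(x)
}

#' Canonical stimulus sets of the two implemented protocols
#'
#' `stimuli_exp1()` returns the seven-circle subset (labels S4--S10 of the
#' ten-circle grid) with the middle circle S7 (96.544 mm, printed 96.54) as
#' CS+. `stimuli_exp2()` returns the full ten-circle grid with the extreme
#' circles as CS+ and CS- (counterbalancing chooses which).
#'
#' @param cs_plus for `stimuli_exp2`, either `"S1"` or `"S10"`.
#' @return A `gm_stimulus_set`.
#' @export
stimuli_exp1 <- function() {
  build_stimulus_set(7, 50.80 + 3 * 7.624, 7.624, cs_plus = "S7",
                     labels = paste0("S", 4:10))
}

#' @rdname stimuli_exp1
#' @export
stimuli_exp2 <- function(cs_plus = c("S1", "S10")) {
  cs_plus <- match.arg(cs_plus)
  cs_minus <- if (cs_plus == "S1") "S10" else "S1"
  build_stimulus_set(10, 50.80, 7.624, cs_plus = cs_plus, cs_minus = cs_minus)
}

#' Construct a conditioning design
#'
#' A design specifies the acquisition-phase trial counts per cue, the CS+
#' reinforcement rate, and the block structure of the generalization phase,
#' including the leading run of consecutive CS+ reacquisition trials that
#' opens every block after the first (the first generalization block follows
#' acquisition immediately and contains none).
#'
#' @param paradigm `"simple"` (CS+ only) or `"differential"` (CS+ and CS-).
#' @param acq_cs_plus,acq_cs_minus acquisition trial counts per cue.
#' @param reinforcement_rate fraction of CS+ trials followed by the US.
#' @param blocks number of generalization blocks.
#' @param per_block named counts `c(cs_plus=, cs_minus=, ts=)` per block
#'   (reacquisition trials are included in the CS+ count).
#' @param reacquisition leading consecutive CS+ trials per block (skipped in
#'   block 1).
#' @return An object of class `gm_design`.
#' @export
build_design <- function(paradigm = c("simple", "differential"),
                         acq_cs_plus, acq_cs_minus = 0L,
                         reinforcement_rate, blocks, per_block,
                         reacquisition = 0L) {
  paradigm <- match.arg(paradigm)
  if (reinforcement_rate < 0 || reinforcement_rate > 1)
    stop("reinforcement_rate must be in [0, 1]")
  per_block <- as.integer(per_block[c("cs_plus", "cs_minus", "ts")])
  names(per_block) <- c("cs_plus", "cs_minus", "ts")
  per_block[is.na(per_block)] <- 0L
  if (reacquisition > per_block[["cs_plus"]])
    stop("reacquisition cannot exceed the per-block CS+ count")
  if (paradigm == "simple" && (acq_cs_minus > 0 || per_block[["cs_minus"]] > 0))
    stop("simple conditioning has no CS- trials")
  structure(list(paradigm = paradigm,
                 acq_cs_plus = as.integer(acq_cs_plus),
                 acq_cs_minus = as.integer(acq_cs_minus),
                 reinforcement_rate = reinforcement_rate,
                 blocks = as.integer(blocks),
                 per_block = per_block,
                 reacquisition = as.integer(reacquisition)),
            class = "gm_design")
}

#' Canonical designs of the two implemented protocols
#'
#' `build_exp1_design()`: simple conditioning; 14 CS+ acquisition trials at
#' 50% reinforcement; 4 generalization blocks of 22 CS+ and 24 TS trials,
#' blocks 2--4 opening with 10 consecutive CS+ reacquisition trials
#' (generalization total: (22+24)*4 - 10 = 174 trials).
#'
#' `build_exp2_design()`: differential conditioning; 12 CS+ and 12 CS-
#' acquisition trials at 83% CS+ reinforcement; 3 generalization blocks of
#' 14 CS+, 8 CS- and 32 TS trials, blocks 2--3 opening with 6 consecutive
#' CS+ trials (generalization total: (14+8+32)*3 - 6 = 156 trials).
#'
#' @return A `gm_design`.
#' @export
build_exp1_design <- function() {
  build_design("simple", acq_cs_plus = 14L, reinforcement_rate = 0.50,
               blocks = 4L, per_block = c(cs_plus = 22L, cs_minus = 0L,
                                          ts = 24L),
               reacquisition = 10L)
}

#' @rdname build_exp1_design
#' @export
build_exp2_design <- function() {
  build_design("differential", acq_cs_plus = 12L, acq_cs_minus = 12L,
               reinforcement_rate = 0.83, blocks = 3L,
               per_block = c(cs_plus = 14L, cs_minus = 8L, ts = 32L),
               reacquisition = 6L)
}

#' Closed-form trial totals of a design
#'
#' @param design a `gm_design`.
#' @return Named list: `acquisition`, `generalization`
#'   (`blocks * block_size - reacquisition`), `total`, and `acq_us`
#'   (`round(rate * CS+ acquisition count)`).
#' @export
design_totals <- function(design) {
  stopifnot(inherits(design, "gm_design"))
  block_size <- sum(design$per_block)
  gen <- design$blocks * block_size - design$reacquisition
  acq <- design$acq_cs_plus + design$acq_cs_minus
  list(acquisition = acq, generalization = gen, total = acq + gen,
       acq_us = round(design$reinforcement_rate * design$acq_cs_plus))
}

#' @export
print.gm_design <- function(x, ...) {
  tot <- design_totals(x)
  cat(sprintf("%s conditioning design: %d acquisition + %d generalization trials\n",
              x$paradigm, tot$acquisition, tot$generalization))
  cat(sprintf("  reinforcement %.0f%%, %d blocks, reacquisition run %d\n",
              100 * x$reinforcement_rate, x$blocks, x$reacquisition))
  invisible(x)
}

## seeded US assignment: exactly round(rate * n) reinforced positions
assign_us <- function(n, rate) {
  n_us <- round(rate * n)
  us <- rep(0L, n)
  if (n_us > 0) us[sample.int(n, n_us)] <- 1L
  us
}

## balanced-with-random-remainder assignment of TS identities
balanced_ts <- function(ts_labels, n) {
  reps <- rep(ts_labels, length.out = 0)
  full <- n %/% length(ts_labels)
  rem <- n %% length(ts_labels)
  out <- rep(ts_labels, full)
  if (rem > 0) out <- c(out, sample(ts_labels, rem))
  sample(out)
}

#' Realize a trial schedule from a design and stimulus set
#'
#' Produces the ordered per-trial descriptors: phase, block, cue role,
#' stimulus and physical size, the administered US outcome `us`, and the
#' update flag `k` (1 on CS trials only, where associative strength is
#' updated). The US is delivered on `round(rate * n)` CS+ trials per phase
#' segment (positions shuffled), never on CS- or TS trials. Reacquisition
#' CS+ trials lead every generalization block except the first; the
#' remaining trials within a block are uniformly permuted. TS identities are
#' balanced within block, any remainder randomized. Deterministic given
#' `seed`.
#'
#' @param design a `gm_design`.
#' @param stimuli a `gm_stimulus_set` consistent with the design.
#' @param seed integer seed (required for reproducibility).
#' @return A data frame of class `gm_schedule` with columns `trial`, `phase`,
#'   `block`, `role` (`CSplus`/`CSminus`/`TS`), `stimulus`, `size_mm`, `us`,
#'   `k`.
#' @export
realize_schedule <- function(design, stimuli, seed) {
  stopifnot(inherits(design, "gm_design"), inherits(stimuli, "gm_stimulus_set"))
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (design$paradigm == "differential" && is.null(stimuli$cs_minus))
    stop("differential design needs a stimulus set with a CS-")
  ts_labels <- setdiff(stimuli$labels, c(stimuli$cs_plus, stimuli$cs_minus))
  if (design$per_block[["ts"]] > 0 && length(ts_labels) == 0)
    stop("design has TS trials but the stimulus set has no TS stimuli")

  res <- withr_seed(seed, {
    ## acquisition
    acq_roles <- sample(c(rep("CSplus", design$acq_cs_plus),
                          rep("CSminus", design$acq_cs_minus)))
    acq_us <- integer(length(acq_roles))
    acq_us[acq_roles == "CSplus"] <-
      assign_us(design$acq_cs_plus, design$reinforcement_rate)
    acq <- data.frame(phase = "acquisition", block = 0L, role = acq_roles,
                      us = acq_us, stringsAsFactors = FALSE)

    ## generalization blocks
    blocks <- lapply(seq_len(design$blocks), function(b) {
      ## block 1 follows acquisition directly: no reacquisition run, and the
      ## block is shorter by that many CS+ trials
      reacq <- if (b == 1L) 0L else design$reacquisition
      n_plus <- design$per_block[["cs_plus"]] - design$reacquisition
      n_minus <- design$per_block[["cs_minus"]]
      n_ts <- design$per_block[["ts"]]
      roles <- sample(c(rep("CSplus", n_plus), rep("CSminus", n_minus),
                        rep("TS", n_ts)))
      roles <- c(rep("CSplus", reacq), roles)
      us <- integer(length(roles))
      us[roles == "CSplus"] <-
        assign_us(reacq + n_plus, design$reinforcement_rate)
      df <- data.frame(phase = "generalization", block = b, role = roles,
                       us = us, stringsAsFactors = FALSE)
      if (n_ts > 0) {
        df$stimulus <- NA_character_
        df$stimulus[df$role == "TS"] <- balanced_ts(ts_labels, n_ts)
      }
      df
    })
    acq$stimulus <- NA_character_
    do.call(rbind, c(list(acq), blocks))
  })

  res$stimulus[res$role == "CSplus"] <- stimuli$cs_plus
  res$stimulus[res$role == "CSminus"] <- stimuli$cs_minus
  res$size_mm <- unname(stimuli$diameters_mm[res$stimulus])
  res$k <- as.integer(res$role %in% c("CSplus", "CSminus"))
  res$trial <- seq_len(nrow(res))
  res <- res[, c("trial", "phase", "block", "role", "stimulus",
                 "size_mm", "us", "k")]
  class(res) <- c("gm_schedule", "data.frame")
  res
}

## evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Serialize a design to/from YAML
#'
#' @param design a `gm_design`.
#' @param path file path.
#' @return `design_to_yaml` invisibly returns `path`; `design_from_yaml`
#'   returns a `gm_design`.
#' @export
design_to_yaml <- function(design, path) {
  stopifnot(inherits(design, "gm_design"))
  x <- unclass(design)
  x$per_block <- as.list(x$per_block)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname design_to_yaml
#' @export
design_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  build_design(x$paradigm, x$acq_cs_plus, x$acq_cs_minus,
               x$reinforcement_rate, x$blocks, unlist(x$per_block),
               x$reacquisition)
}
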