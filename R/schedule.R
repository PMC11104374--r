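#' Build a task schedule of advice-accuracy probabilities
#'
#' A schedule fixes, per trial, the probability that the adviser's advice is
#' correct and the phase label. The default emulates the study task: a
#' stable phase of helpful advice followed by a volatile phase of block
#' reversals that contains a noisy stretch where advice carries almost no
#' information.
#'
#' @param blocks Data.frame (or list coercible to one) with columns `len`
#'   (block lengths, positive integers) and `accuracy` (advice-accuracy
#'   probability per block, in `[0, 1]`).
#' @param stable_trials Number of leading trials labelled `"stable"`; all
#'   later trials are `"volatile"`. Must be `< ` the total trial count.
#' @param cue_levels Discrete set of cue probabilities (advice-congruent
#'   outcome), each strictly inside `(0, 1)`, sampled uniformly by
#'   [realize_inputs()].
#' @return Object of class `hgf_schedule`: list with `n_trials`,
#'   `phase_labels`, `advice_accuracy_prob`, `cue_levels`.
#' @seealso [default_schedule()] for the study-design default.
#' @export
make_schedule <- function(blocks, stable_trials,
                          cue_levels = c(0.55, 0.65, 0.75, 0.85)) {
  blocks <- as.data.frame(blocks)
  if (!all(c("len", "accuracy") %in% names(blocks)))
    stop("blocks needs columns 'len' and 'accuracy'", call. = FALSE)
  if (any(blocks$len < 1 | blocks$len != round(blocks$len)))
    stop("block lengths must be positive integers", call. = FALSE)
  if (any(blocks$accuracy < 0 | blocks$accuracy > 1))
    stop("accuracy must lie in [0, 1]", call. = FALSE)
  if (any(cue_levels <= 0 | cue_levels >= 1))
    stop("cue levels must lie strictly inside (0, 1)", call. = FALSE)
  n <- sum(blocks$len)
  if (stable_trials >= n)
    stop("stable_trials must be smaller than the total trial count",
         call. = FALSE)
  if (stable_trials < 0) stop("stable_trials must be >= 0", call. = FALSE)
  acc <- rep(blocks$accuracy, times = blocks$len)
  phase <- rep("volatile", n)
  phase[seq_len(stable_trials)] <- "stable"
  structure(list(n_trials = n, phase_labels = phase,
                 advice_accuracy_prob = acc, cue_levels = cue_levels),
            class = "hgf_schedule")
}

#' The default volatility schedule
#'
#' 170 trials. Trials 1-67: stable helpful advice (accuracy 0.85). Trials
#' 68-119: volatile reversal blocks alternating between 0.9 and 0.1. Trials
#' 120-136: a noisy stretch at 0.55 where advice is barely informative.
#' Trials 137-170: further reversal blocks.
#'
#' @inheritParams make_schedule
#' @return An `hgf_schedule`.
#' @export
default_schedule <- function(cue_levels = c(0.55, 0.65, 0.75, 0.85)) {
  blocks <- data.frame(
    len      = c(67, 13, 13, 13, 13, 17, 12, 11, 11),
    accuracy = c(0.85, 0.9, 0.1, 0.9, 0.1, 0.55, 0.1, 0.9, 0.1)
  )
  make_schedule(blocks, stable_trials = 67, cue_levels = cue_levels)
}

#' Realise the stochastic inputs of a schedule
#'
#' Draws the binary advice-accuracy outcomes `u_k ~ Bernoulli(accuracy_k)`
#' and the cue probabilities `c_k` (uniform over the schedule's cue levels).
#' Responses `y` are left `NA`; [simulate_agent()] fills them.
#'
#' @param schedule An [make_schedule()] object.
#' @param seed Integer seed; identical seeds give identical realisations.
#' @return Data.frame with columns `trial`, `phase`, `u`, `c`, `y`.
#' @export
realize_inputs <- function(schedule, seed = NULL) {
  stopifnot(inherits(schedule, "hgf_schedule"))
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  n <- schedule$n_trials
  data.frame(
    trial = seq_len(n),
    phase = schedule$phase_labels,
    u = as.integer(rbinom(n, 1, schedule$advice_accuracy_prob)),
    c = sample(schedule$cue_levels, n, replace = TRUE),
    y = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
}
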