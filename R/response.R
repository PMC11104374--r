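#' Integrate the advice prediction with the non-social cue
#'
#' The integrated belief that the advised option wins is a convex
#' combination of the predicted advice accuracy and the cue probability of
#' the advice-congruent outcome: `b = zeta * muhat1 + (1 - zeta) * c`.
#'
#' @param muhat1 Predicted advice accuracy, in `(0, 1)` (vectorised).
#' @param c Cue probability for the advice-congruent outcome, in `(0, 1)`.
#' @param zeta Advice weight in `[0, 1]`.
#' @return Integrated belief `b` in `(0, 1)`.
#' @export
integrate_belief <- function(muhat1, c, zeta) {
  if (any(muhat1 <= 0 | muhat1 >= 1)) stop("muhat1 must lie in (0, 1)", call. = FALSE)
  if (any(c <= 0 | c >= 1)) stop("c must lie in (0, 1)", call. = FALSE)
  if (zeta < 0 || zeta > 1) stop("zeta must lie in [0, 1]", call. = FALSE)
  zeta * muhat1 + (1 - zeta) * c
}

#' Volatility-gated inverse decision temperature
#'
#' `beta = nu * exp(-muhat3)`: choices become more deterministic when the
#' environment is predicted to be stable (low `muhat3`) and noisier when it
#' is predicted to be volatile, modulated by the subject's
#' volatility-independent noise parameter `nu`.
#'
#' @param muhat3 Predicted log-volatility (vectorised).
#' @param nu Decision-noise parameter, `> 0`.
#' @return Inverse temperature `beta > 0`.
#' @export
inverse_temperature <- function(muhat3, nu) {
  if (nu <= 0) stop("nu must be > 0", call. = FALSE)
  nu * exp(-muhat3)
}

#' Probability of taking the advice
#'
#' `p(y = 1 | b) = b^beta / (b^beta + (1 - b)^beta)`, evaluated in log space
#' so that large inverse temperatures do not overflow.
#'
#' @param b Integrated belief in `(0, 1)` (vectorised).
#' @param muhat3 Predicted log-volatility (vectorised, recycled against `b`).
#' @param nu Decision-noise parameter, `> 0`.
#' @return Probability of going with the advice, in `(0, 1)`.
#' @export
choice_probability <- function(b, muhat3, nu) {
  if (any(b <= 0 | b >= 1))
    stop("integrated belief b must lie strictly inside (0, 1)", call. = FALSE)
  beta <- inverse_temperature(muhat3, nu)
  # log p = -log(1 + exp(beta * (log(1-b) - log(b))))
  z <- beta * (log1p(-b) - log(b))
  hgf_sigmoid(-z)
}

.clip_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Bernoulli log-likelihood of observed choices
#'
#' Sum over trials of `y * log(p) + (1 - y) * log(1 - p)` where `p` is the
#' per-trial [choice_probability()] implied by a belief trajectory, the cue
#' sequence and the response parameters. Probabilities are clipped at 1e-12
#' for likelihood evaluation only, so a single surprising choice cannot
#' produce `-Inf` during optimisation.
#'
#' @param trajectory An [hgf_filter()] trajectory.
#' @param c_seq Cue probabilities per trial.
#' @param y_seq Binary responses per trial (1 = went with the advice).
#' @param rparams A [response_params()] object.
#' @return Scalar log-likelihood.
#' @export
response_loglik <- function(trajectory, c_seq, y_seq, rparams) {
  n <- nrow(trajectory)
  if (length(c_seq) != n || length(y_seq) != n)
    stop("trajectory, c_seq and y_seq must have equal length", call. = FALSE)
  if (n == 0) return(0)
  if (!all(y_seq %in% c(0, 1))) stop("y must be binary", call. = FALSE)
  b <- integrate_belief(trajectory$muhat1, c_seq, rparams$zeta)
  p <- .clip_p(choice_probability(b, trajectory$muhat3, rparams$nu))
  sum(y_seq * log(p) + (1 - y_seq) * log1p(-p))
}

#' Sample responses from the response model
#'
#' Bernoulli draws from the per-trial choice probabilities; deterministic
#' given `seed`.
#'
#' @inheritParams response_loglik
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Integer 0/1 vector of simulated responses.
#' @export
sample_responses <- function(trajectory, c_seq, rparams, seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  n <- nrow(trajectory)
  if (length(c_seq) != n)
    stop("trajectory and c_seq must have equal length", call. = FALSE)
  if (n == 0) return(integer(0))
  b <- integrate_belief(trajectory$muhat1, c_seq, rparams$zeta)
  p <- choice_probability(b, trajectory$muhat3, rparams$nu)
  as.integer(rbinom(n, 1, p))
}

# Seed hygiene: set the RNG reproducibly, then restore whatever state the
# caller had, so seeded operations compose without clobbering each other.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
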