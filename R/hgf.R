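#' Numerically stable logistic sigmoid
#'
#' @param z Numeric vector.
#' @return `1 / (1 + exp(-z))`, computed without overflow for large `|z|`.
#' @export
hgf_sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

.traj_cols <- c("muhat1", "pihat1", "muhat2", "pihat2", "muhat3", "pihat3",
                "mu2", "sigma2", "mu3", "sigma3", "delta1", "delta2",
                "v2", "w2", "lr1")

#' Run the 3-level HGF over a binary input sequence
#'
#' Folds the one-step variational updates over the advice-accuracy sequence
#' `u`, starting from the initial beliefs in `pparams`. Per trial the filter
#' computes the predictions `muhat1` (predicted probability of accurate
#' advice), `muhat2`, `muhat3` and their precisions, the posterior means and
#' variances `mu2, sigma2, mu3, sigma3`, the prediction errors `delta1`
#' (outcome level) and `delta2` (volatility level), the predicted level-2
#' volatility `v2 = exp(kappa2 * mu3 + omega2)`, the precision weight
#' `w2 = v2 * pihat2`, and the level-1 learning rate `lr1 = pihat1 / pi2`.
#'
#' For the mean-reverting variant the volatility-level prediction drifts
#' towards the equilibrium: `muhat3 = mu3 + phi3 * (m3 - mu3)`; `v2` is
#' evaluated at the previous posterior `mu3` (not the drifted prediction) in
#' both variants — see the package vignette for the rationale and
#' `v2_at_prediction` to flip the convention.
#'
#' @param u Integer/numeric vector of 0/1 advice-accuracy outcomes.
#' @param pparams A [perceptual_params()] object.
#' @param check If `TRUE` (default) an invalid trajectory (non-positive
#'   post-update precision) raises an error naming the failing trial; if
#'   `FALSE` the truncated trajectory is returned with attribute
#'   `valid_until`.
#' @param v2_at_prediction If `TRUE`, evaluate `v2` at the drifted
#'   prediction `muhat3` instead of the previous posterior (mean-reverting
#'   variant only).
#' @return A data.frame of class `hgf_trajectory`, one row per trial, with
#'   attribute `pparams`.
#' @examples
#' u <- c(1, 1, 0, 1, 1)
#' tr <- hgf_filter(u, perceptual_params())
#' tr$muhat1
#' @export
hgf_filter <- function(u, pparams, check = TRUE, v2_at_prediction = FALSE) {
  stopifnot(inherits(pparams, "hgf_pparams"))
  u <- as.integer(u)
  if (length(u) && !all(u %in% c(0L, 1L)))
    stop("u must be a binary (0/1) sequence", call. = FALSE)
  mr <- pparams$variant == "mean_reverting"
  if (v2_at_prediction && !mr)
    stop("v2_at_prediction applies to the mean-reverting variant only",
         call. = FALSE)
  if (!length(u)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(.traj_cols)),
                                  .traj_cols))
    attr(out, "pparams") <- pparams
    class(out) <- c("hgf_trajectory", "data.frame")
    return(out)
  }
  m <- if (v2_at_prediction) {
    hgf_filter_r_drifted(u, pparams)
  } else {
    hgf_filter_cpp(u, pparams$kappa2, pparams$omega2, pparams$theta,
                   pparams$mu2_0, pparams$sigma2_0,
                   pparams$mu3_0, pparams$sigma3_0,
                   pparams$m3, pparams$phi3, mr)
  }
  vu <- attr(m, "valid_until")
  if (check && vu < length(u))
    stop("invalid trajectory: non-positive precision at trial ", vu + 1,
         call. = FALSE)
  out <- as.data.frame(m)
  names(out) <- .traj_cols
  attr(out, "valid_until") <- vu
  attr(out, "pparams") <- pparams
  class(out) <- c("hgf_trajectory", "data.frame")
  out
}

# Alternate convention: evaluate the level-2 volatility at the drifted
# volatility prediction. Only reachable through hgf_filter(); kept in R
# because it is a diagnostic path, not the fitting path.
hgf_filter_r_drifted <- function(u, p) {
  n <- length(u)
  m <- matrix(NA_real_, n, 15)
  mu2 <- p$mu2_0; sigma2 <- p$sigma2_0
  mu3 <- p$mu3_0; sigma3 <- p$sigma3_0
  vu <- n
  for (k in seq_len(n)) {
    muhat2 <- mu2
    muhat3 <- mu3 + p$phi3 * (p$m3 - mu3)
    muhat1 <- min(max(hgf_sigmoid(muhat2), 1e-15), 1 - 1e-15)
    pihat1 <- 1 / (muhat1 * (1 - muhat1))
    v2 <- exp(p$kappa2 * muhat3 + p$omega2)
    pihat2 <- 1 / (sigma2 + v2)
    delta1 <- u[k] - muhat1
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    mu2n <- muhat2 + delta1 / pi2
    sigma2n <- 1 / pi2
    pihat3 <- 1 / (sigma3 + p$theta)
    w2 <- v2 * pihat2
    delta2 <- (sigma2n + (mu2n - muhat2)^2) * pihat2 - 1
    pi3 <- pihat3 + 0.5 * p$kappa2^2 * w2 * (w2 + (2 * w2 - 1) * delta2)
    if (!is.finite(pi3) || pi2 <= 0 || pi3 <= 0) { vu <- k - 1; break }
    mu3n <- muhat3 + 0.5 * p$kappa2 * (w2 / pi3) * delta2
    m[k, ] <- c(muhat1, pihat1, muhat2, pihat2, muhat3, pihat3,
                mu2n, sigma2n, mu3n, 1 / pi3, delta1, delta2, v2, w2,
                pihat1 / pi2)
    mu2 <- mu2n; sigma2 <- sigma2n; mu3 <- mu3n; sigma3 <- 1 / pi3
  }
  attr(m, "valid_until") <- vu
  m
}

#' Single one-step HGF update
#'
#' Convenience wrapper applying one update to an explicit belief state;
#' mainly useful for inspecting the update equations trial by trial.
#'
#' @param state Named list with `mu2`, `sigma2`, `mu3`, `sigma3`.
#' @param u_k Single binary outcome.
#' @param pparams A [perceptual_params()] object (initial-belief fields are
#'   ignored; the state argument supplies them).
#' @inheritParams hgf_filter
#' @return Named list: the new state plus the per-trial quantities of
#'   [hgf_filter()].
#' @export
hgf_update_step <- function(state, u_k, pparams, v2_at_prediction = FALSE) {
  p <- pparams
  p$mu2_0 <- state$mu2; p$sigma2_0 <- state$sigma2
  p$mu3_0 <- state$mu3; p$sigma3_0 <- state$sigma3
  tr <- hgf_filter(u_k, p, check = TRUE, v2_at_prediction = v2_at_prediction)
  as.list(tr[1, ])
}
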