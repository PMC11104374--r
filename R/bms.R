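#' Random-effects Bayesian model selection
#'
#' Variational fixed-point scheme over a subjects-by-models matrix of log
#' model evidences. Model identity is treated as a random effect across
#' subjects with Dirichlet-distributed frequencies: the per-subject
#' attribution is `u_nk \propto exp(L_nk + psi(alpha_k) - psi(sum alpha))`
#' and the Dirichlet parameters are `alpha = alpha0 + colSums(u)`, iterated
#' to convergence.
#'
#' @param lme Numeric matrix, subjects in rows, models in columns (named
#'   columns are carried through).
#' @param alpha0 Prior Dirichlet count per model (flat prior 1 by default).
#' @param tol Convergence tolerance on the change in `alpha`.
#' @param max_iter Iteration cap.
#' @return List with `alpha`, `freq` (`alpha / sum(alpha)`), `attribution`
#'   (subjects x models, rows on the simplex) and `iterations`.
#' @seealso [bms()] for the full report including exceedance probabilities.
#' @export
rfx_bms <- function(lme, alpha0 = 1, tol = 1e-8, max_iter = 500) {
  lme <- as.matrix(lme)
  if (ncol(lme) < 2) stop("need at least 2 models", call. = FALSE)
  if (nrow(lme) < 1) stop("need at least 1 subject", call. = FALSE)
  if (!all(is.finite(lme))) stop("log evidences must be finite", call. = FALSE)
  K <- ncol(lme)
  alpha <- rep(alpha0, K)
  u <- matrix(1 / K, nrow(lme), K)
  for (it in seq_len(max_iter)) {
    logu <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    logu <- logu - apply(logu, 1, max)
    u <- exp(logu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (sqrt(sum((alpha_new - alpha)^2)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  dimnames(u) <- dimnames(lme)
  names(alpha) <- colnames(lme)
  list(alpha = alpha, freq = alpha / sum(alpha), attribution = u,
       iterations = it)
}

#' Exceedance probabilities of Dirichlet-distributed model frequencies
#'
#' `XP_k = P(r_k > r_j for all j != k)` for Dirichlet(`alpha`)-distributed
#' frequencies. For
#' two models the probability is computed exactly through the regularised
#' incomplete Beta function; otherwise (or when `force_mc = TRUE`) by Monte
#' Carlo over independent Gamma draws.
#'
#' @param alpha Positive Dirichlet parameter vector.
#' @param n_samples Monte-Carlo sample count (warned below 1e4).
#' @param seed Seed for the Monte-Carlo path.
#' @param force_mc Use Monte Carlo even for two models (used to cross-check
#'   the closed form).
#' @return Numeric vector summing to 1.
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = 1,
                            force_mc = FALSE) {
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  K <- length(alpha)
  if (K == 2 && !force_mc) {
    xp1 <- pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    out <- c(xp1, 1 - xp1)
  } else {
    if (n_samples < 1e4)
      warning("n_samples < 1e4 gives imprecise exceedance probabilities")
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                    n_samples, K)
    win <- max.col(draws, ties.method = "first")
    out <- tabulate(win, nbins = K) / n_samples
  }
  setNames(out, names(alpha))
}

#' Bayesian omnibus risk
#'
#' Probability that the observed differences in model frequencies arose by
#' chance alone: `BOR = 1 / (1 + exp(F1 - F0))`, where `F0` is the log
#' evidence of the null model with frequencies fixed at `1/K` and `F1` the
#' variational free energy of the random-effects model (expected log joint
#' plus the entropies of the Dirichlet and attribution posteriors).
#'
#' @inheritParams rfx_bms
#' @param fit A converged [rfx_bms()] result for `lme`.
#' @return Scalar in `[0, 1]`.
#' @export
omnibus_risk <- function(lme, fit, alpha0 = 1) {
  lme <- as.matrix(lme)
  K <- ncol(lme)
  a0 <- rep(alpha0, K)
  # F0: null model, r = 1/K fixed
  mx <- apply(lme, 1, max)
  F0 <- sum(mx + log(rowSums(exp(lme - mx))) - log(K))
  # F1: variational free energy at the converged posteriors
  alpha <- fit$alpha; u <- fit$attribution
  Elogr <- digamma(alpha) - digamma(sum(alpha))
  exp_log_joint <- sum(u * sweep(lme, 2, Elogr, `+`)) +
    lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * Elogr)
  ent_u <- -sum(ifelse(u > 0, u * log(u), 0))
  ent_dir <- -(lgamma(sum(alpha)) - sum(lgamma(alpha)) +
                 sum((alpha - 1) * Elogr))
  F1 <- exp_log_joint + ent_u + ent_dir
  1 / (1 + exp(F1 - F0))
}

#' Protected exceedance probabilities
#'
#' `phi_k = XP_k * (1 - BOR) + BOR / K`: exceedance probabilities shrunk
#' towards chance by the Bayesian omnibus risk.
#'
#' @param xp Exceedance probabilities (sum to 1).
#' @param bor Bayesian omnibus risk in `[0, 1]`.
#' @return Numeric vector summing to 1.
#' @export
protected_xp <- function(xp, bor) {
  if (abs(sum(xp) - 1) > 1e-8) stop("xp must sum to 1", call. = FALSE)
  if (bor < 0 || bor > 1) stop("bor must lie in [0, 1]", call. = FALSE)
  xp * (1 - bor) + bor / length(xp)
}

#' Full random-effects model-selection report
#'
#' Runs [rfx_bms()], computes exceedance probabilities, the Bayesian
#' omnibus risk, and the protected exceedance probabilities.
#'
#' @inheritParams rfx_bms
#' @inheritParams exceedance_prob
#' @return Object of class `hgf_bms`: `alpha`, `freq`, `attribution`,
#'   `xp`, `bor`, `pxp`.
#' @export
bms <- function(lme, alpha0 = 1, n_samples = 1e6, seed = 1, tol = 1e-8) {
  fit <- rfx_bms(lme, alpha0 = alpha0, tol = tol)
  xp <- exceedance_prob(fit$alpha, n_samples = n_samples, seed = seed)
  bor <- omnibus_risk(lme, fit, alpha0 = alpha0)
  structure(c(fit, list(xp = xp, bor = bor, pxp = protected_xp(xp, bor))),
            class = "hgf_bms")
}

#' @export
print.hgf_bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  cat(sprintf("  subjects: %d, models: %d, BOR = %.4f\n",
              nrow(x$attribution), length(x$alpha), x$bor))
  tab <- rbind(freq = x$freq, xp = x$xp, pxp = x$pxp)
  print(round(tab, 4))
  invisible(x)
}
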