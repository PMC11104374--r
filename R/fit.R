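#' Log joint density of a candidate model
#'
#' Response log-likelihood at the native parameters implied by the
#' estimation-space vector, plus independent Gaussian log-prior terms in
#' estimation space. Parameter vectors whose perceptual filter produces an
#' invalid trajectory (non-positive post-update precision) score `-Inf`:
#' they are rejected rather than clamped, so the optimiser steers away from
#' them without biasing the estimates.
#'
#' @param est Named (or model-ordered) numeric vector over the model's free
#'   parameters, estimation space.
#' @param data Subject data.frame with columns `u`, `c`, `y`.
#' @param model_def An [hgf_model()].
#' @return Scalar log joint (`-Inf` for invalid parameter vectors).
#' @export
log_joint <- function(est, data, model_def) {
  if (any(!is.finite(est))) return(-Inf)
  pars <- try(model_native_params(est, model_def), silent = TRUE)
  if (inherits(pars, "try-error")) return(-Inf)
  traj <- hgf_filter(data$u, pars$perceptual, check = FALSE)
  if (attr(traj, "valid_until") < nrow(data)) return(-Inf)
  ll <- response_loglik(traj, data$c, data$y, pars$response)
  pm <- model_prior_moments(model_def)
  lp <- sum(dnorm(as.numeric(est), pm$mean, sqrt(pm$var), log = TRUE))
  ll + lp
}

# Input-surprise analogue of log_joint: Bernoulli likelihood of the inputs
# under the filter's own predictions, no response model involved.
input_log_joint <- function(est, u, free, priors, variant) {
  if (any(!is.finite(est))) return(-Inf)
  native <- try(to_native_space(setNames(as.numeric(est), free), priors),
                silent = TRUE)
  if (inherits(native, "try-error")) return(-Inf)
  fixed <- setNames(as.list(priors$native_mean[priors$fixed]),
                    priors$param[priors$fixed])
  all <- modifyList(fixed, native)
  pp <- try(perceptual_params(
    kappa2 = all$kappa2, omega2 = all$omega2, theta = all$theta,
    mu2_0 = all$mu2_0, sigma2_0 = all$sigma2_0,
    mu3_0 = all$mu3_0, sigma3_0 = all$sigma3_0,
    m3 = if (!is.null(all$m3)) all$m3 else 1,
    phi3 = if (!is.null(all$phi3)) all$phi3 else 0.1,
    variant = variant), silent = TRUE)
  if (inherits(pp, "try-error")) return(-Inf)
  traj <- hgf_filter(u, pp, check = FALSE)
  if (attr(traj, "valid_until") < length(u)) return(-Inf)
  p <- .clip_p(traj$muhat1)
  ll <- sum(u * log(p) + (1 - u) * log1p(-p))
  idx <- match(free, priors$param)
  mu <- vapply(idx, function(i)
    link_fun(priors$transform[i])(priors$native_mean[i]), numeric(1))
  ll + sum(dnorm(as.numeric(est), mu, sqrt(priors$est_var[idx]), log = TRUE))
}

# Multistart quasi-Newton maximisation of an objective over estimation
# space. Rejected parameter regions (objective -Inf) are presented to the
# optimiser as a large finite penalty so finite-difference gradients remain
# defined at the boundary; a start is only accepted if its optimum lies in
# the valid region. If every scheduled start fails, a few extra perturbed
# starts are tried before giving up.
multistart_optim <- function(objective, start, restarts, seed, reltol,
                             extra_starts = 5) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  d <- length(start)
  penalty <- 1e10
  obj_min <- function(x) {
    v <- objective(x)
    if (is.finite(v)) -v else penalty
  }
  starts <- c(list(start),
              lapply(seq_len(max(0, restarts - 1)),
                     function(i) start + rnorm(d)))
  best <- NULL; used <- 0L; failures <- 0L
  run_one <- function(s) {
    if (obj_min(s) >= penalty) return(NULL)
    fit <- try(optim(s, obj_min, method = "BFGS",
                     control = list(maxit = 500, reltol = reltol)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value) ||
        fit$value >= penalty / 2) return(NULL)
    fit
  }
  for (s in starts) {
    used <- used + 1L
    fit <- run_one(s)
    if (is.null(fit)) { failures <- failures + 1L; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  tries <- 0L
  while (is.null(best) && tries < extra_starts) {
    tries <- tries + 1L; used <- used + 1L
    fit <- run_one(start + rnorm(d, sd = 0.5 * tries))
    if (!is.null(fit)) best <- fit else failures <- failures + 1L
  }
  if (is.null(best))
    stop("all ", used, " optimisation starts failed", call. = FALSE)
  grad <- grad_central(obj_min, best$par)
  list(par = setNames(best$par, names(start)), value = -best$value,
       restarts_used = used, failed_starts = failures,
       grad_norm = sqrt(sum(grad^2)), convergence = best$convergence)
}

#' MAP estimation of a candidate model for one subject
#'
#' Maximises [log_joint()] with BFGS from the estimation-space prior mean
#' plus seeded Gaussian perturbations (sd 1), keeping the best optimum.
#'
#' @param data Subject data.frame with columns `u`, `c`, `y`.
#' @param model_def An [hgf_model()].
#' @param restarts Number of starts (1 = prior mean only).
#' @param seed Integer seed for the perturbed starts.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @return Object of class `hgf_fit`: MAP estimates in estimation
#'   (`est`) and native (`native`) space, the log joint at the optimum
#'   (`log_joint`), the Laplace log model evidence (`lme`, filled by
#'   [laplace_lme()], which this function calls), convergence diagnostics
#'   and the model identifier.
#' @export
fit_map <- function(data, model_def, restarts = 5, seed = 1,
                    reltol = 1e-10) {
  stopifnot(inherits(model_def, "hgf_model"))
  if (!nrow(data)) stop("need at least one trial", call. = FALSE)
  pm <- model_prior_moments(model_def)
  res <- multistart_optim(function(x) log_joint(x, data, model_def),
                          pm$mean, restarts, seed, reltol)
  fit <- structure(list(
    model = model_def$model, est = res$par,
    native = to_native_space(res$par, model_def$priors),
    log_joint = res$value, lme = NA_real_, hessian_pd = NA,
    restarts_used = res$restarts_used, failed_starts = res$failed_starts,
    grad_norm = res$grad_norm, convergence = res$convergence,
    model_def = model_def), class = "hgf_fit")
  laplace_lme(fit, data, model_def)
}

#' Laplace-approximated log model evidence
#'
#' `LME = log_joint(MAP) + (d/2) log(2*pi) - (1/2) log det(H)` with `H` the
#' central-difference Hessian of the negative log joint at the MAP. If `H`
#' is not positive definite it is projected to the nearest positive-definite
#' matrix (eigenvalue clamping) and the fit is flagged via `hessian_pd`.
#'
#' @param fit An `hgf_fit` (the `lme` field is filled in).
#' @param data Subject data used for the fit.
#' @param model_def The fitted [hgf_model()].
#' @return The fit with `lme` and `hessian_pd` set.
#' @export
laplace_lme <- function(fit, data, model_def) {
  d <- length(fit$est)
  if (d == 0) {
    fit$lme <- fit$log_joint
    fit$hessian_pd <- TRUE
    return(fit)
  }
  # evaluate rejected points as a large finite penalty so the Hessian is
  # defined when the MAP sits close to the validity boundary
  H <- hessian_central(function(x) {
    v <- log_joint(x, data, model_def)
    if (is.finite(v)) -v else 1e10
  }, as.numeric(fit$est))
  le <- laplace_evidence(fit$log_joint, H)
  fit$lme <- le$lme
  fit$hessian_pd <- le$pd
  fit
}

# Evidence from a log-joint maximum and the negative-log-joint Hessian.
laplace_evidence <- function(lj_max, H) {
  d <- nrow(H)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  pd <- all(ev > 0)
  if (!pd) ev <- pmax(ev, 1e-8)
  list(lme = lj_max + (d / 2) * log(2 * pi) - 0.5 * sum(log(ev)), pd = pd)
}

grad_central <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

hessian_central <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- rep(0, d); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    for (j in seq_len(d)[-seq_len(i)]) {
      ej <- rep(0, d); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Input-optimised ("Bayes optimal") perceptual parameters
#'
#' Maximises the Bernoulli likelihood of the input stream under the filter's
#' own one-step-ahead predictions, plus the estimation-space log-prior over
#' the free perceptual parameters — no responses are involved. Used to
#' freeze the perceptual block of the control models CI/CII.
#'
#' @param u Binary advice-accuracy sequence.
#' @param variant `"standard"` or `"mean_reverting"`.
#' @param restarts,seed,reltol As in [fit_map()].
#' @return Named list of native-space perceptual parameter values (free
#'   perceptual parameters only) with attributes `objective` (value at the
#'   optimum) and `est` (estimation-space vector).
#' @export
fit_bayes_optimal <- function(u, variant = c("standard", "mean_reverting"),
                              restarts = 5, seed = 1, reltol = 1e-10) {
  variant <- match.arg(variant)
  priors <- prior_spec(variant)
  free <- priors$param[!priors$fixed & priors$block == "perceptual"]
  idx <- match(free, priors$param)
  start <- setNames(vapply(idx, function(i)
    link_fun(priors$transform[i])(priors$native_mean[i]), numeric(1)), free)
  res <- multistart_optim(
    function(x) input_log_joint(x, u, free, priors, variant),
    start, restarts, seed, reltol)
  out <- to_native_space(res$par, priors)
  attr(out, "objective") <- res$value
  attr(out, "est") <- res$par
  out
}
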