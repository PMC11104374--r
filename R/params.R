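#' Perceptual parameters of the binary 3-level HGF
#'
#' Bundles the subject-specific quantities that govern hierarchical belief
#' updating: the coupling strength `kappa2` between the volatility level and
#' the tendency level, the tendency-level evolution rate `omega2`, the
#' meta-volatility `theta`, the initial beliefs `(mu2_0, sigma2_0)` and
#' `(mu3_0, sigma3_0)`, and — for the mean-reverting variant — the drift
#' equilibrium `m3` and drift rate `phi3` of the volatility level.
#'
#' @param kappa2 Coupling strength in `[0, 1]`.
#' @param omega2 Tendency-level evolution rate (unbounded).
#' @param theta Meta-volatility, `>= 0`. Fixed to 0.5 in the study design.
#' @param mu2_0,sigma2_0 Initial tendency-level mean (unbounded) and
#'   variance (`> 0`, fixed to 1).
#' @param mu3_0,sigma3_0 Initial volatility-level mean (unbounded) and
#'   variance (`> 0`, fixed to 1).
#' @param m3 Drift equilibrium of the volatility level (mean-reverting
#'   variant only). `m3 > mu3_0` means the agent comes to perceive the
#'   environment as increasingly volatile within the session.
#' @param phi3 Drift rate in `[0, 1]` (mean-reverting variant only; fixed
#'   to 0.1).
#' @param variant `"standard"` or `"mean_reverting"`.
#' @return An object of class `hgf_pparams` (named list).
#' @seealso [response_params()], [hgf_filter()]
#' @export
perceptual_params <- function(kappa2 = 0.5, omega2 = -2, theta = 0.5,
                              mu2_0 = 0, sigma2_0 = 1,
                              mu3_0 = 1, sigma3_0 = 1,
                              m3 = 1, phi3 = 0.1,
                              variant = c("standard", "mean_reverting")) {
  variant <- match.arg(variant)
  p <- list(kappa2 = kappa2, omega2 = omega2, theta = theta,
            mu2_0 = mu2_0, sigma2_0 = sigma2_0,
            mu3_0 = mu3_0, sigma3_0 = sigma3_0,
            m3 = m3, phi3 = phi3, variant = variant)
  validate_pparams(p)
  class(p) <- "hgf_pparams"
  p
}

validate_pparams <- function(p) {
  num <- p[setdiff(names(p), "variant")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1))))
    stop("all perceptual parameters must be finite scalars", call. = FALSE)
  if (p$kappa2 < 0 || p$kappa2 > 1) stop("kappa2 must lie in [0, 1]", call. = FALSE)
  if (p$phi3 < 0 || p$phi3 > 1) stop("phi3 must lie in [0, 1]", call. = FALSE)
  if (p$theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (p$sigma2_0 <= 0 || p$sigma3_0 <= 0)
    stop("initial variances must be > 0", call. = FALSE)
  invisible(p)
}

#' Response-model parameters
#'
#' @param zeta Advice weight in `[0, 1]`: how strongly the predicted advice
#'   accuracy is weighted against the non-social cue when forming the
#'   integrated belief.
#' @param nu Volatility-independent decision-noise parameter, `> 0`; larger
#'   values give more deterministic choices.
#' @return An object of class `hgf_rparams`.
#' @export
response_params <- function(zeta = 0.5, nu = 48) {
  if (!is.numeric(zeta) || zeta < 0 || zeta > 1)
    stop("zeta must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(nu) || nu <= 0) stop("nu must be > 0", call. = FALSE)
  structure(list(zeta = zeta, nu = nu), class = "hgf_rparams")
}

# ---------------------------------------------------------------------------
# Prior specification (empirical priors of the study design) and the four
# candidate models: HI (standard HGF), HII (mean-reverting HGF), and the
# control models CI/CII whose perceptual parameters are frozen at
# input-optimised ("Bayes optimal") values so that only the response model
# is free.
# ---------------------------------------------------------------------------

#' Empirical prior specification
#'
#' One row per model parameter: native-space prior mean, estimation-space
#' prior variance, the transformation linking native and estimation space
#' (`logit` for `[0,1]` parameters, `log` for positive ones, `identity`
#' otherwise), and whether the parameter is fixed (variance 0, excluded from
#' optimisation).
#'
#' @param variant `"standard"` or `"mean_reverting"`; the mean-reverting
#'   spec adds the drift parameters `m3` (free) and `phi3` (fixed).
#' @return A data.frame of class `hgf_priors` with columns `param`,
#'   `native_mean`, `est_var`, `transform`, `fixed`, `block`
#'   (`"perceptual"` or `"response"`).
#' @export
prior_spec <- function(variant = c("standard", "mean_reverting")) {
  variant <- match.arg(variant)
  tab <- data.frame(
    param = c("kappa2", "omega2", "theta", "mu2_0", "sigma2_0",
              "mu3_0", "sigma3_0", "zeta", "nu"),
    native_mean = c(0.5, -2, 0.5, 0, 1, 1, 1, 0.5, 48),
    est_var = c(1, 4, 0, 1, 0, 1, 0, 1, 1),
    transform = c("logit", "identity", "logit", "identity", "log",
                  "identity", "log", "logit", "log"),
    fixed = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    block = c(rep("perceptual", 7), "response", "response"),
    stringsAsFactors = FALSE
  )
  if (variant == "mean_reverting") {
    tab <- rbind(tab, data.frame(
      param = c("m3", "phi3"),
      native_mean = c(1, 0.1),
      est_var = c(1, 0),
      transform = c("identity", "logit"),
      fixed = c(FALSE, TRUE),
      block = "perceptual",
      stringsAsFactors = FALSE
    ))
  }
  class(tab) <- c("hgf_priors", "data.frame")
  tab
}

link_fun <- function(transform) {
  switch(transform,
         identity = identity,
         log = log,
         logit = function(x) log(x) - log1p(-x),
         stop("unknown transform: ", transform, call. = FALSE))
}

inv_link_fun <- function(transform) {
  switch(transform,
         identity = identity,
         log = exp,
         logit = function(x) 1 / (1 + exp(-x)),
         stop("unknown transform: ", transform, call. = FALSE))
}

#' Map native parameter values to estimation space (and back)
#'
#' Estimation space is where priors are Gaussian and the optimiser works:
#' logit for `[0,1]`-bounded parameters, log for positive ones, identity
#' otherwise. `to_estimation_space()` accepts a named list/vector of native
#' values and returns the estimation-space vector over the requested
#' parameters; `to_native_space()` inverts it.
#'
#' @param params Named list or vector of native-space values.
#' @param priors A [prior_spec()] table.
#' @param which Character vector of parameter names (default: the free
#'   parameters in `priors`).
#' @return Named numeric vector (estimation space), or named list (native).
#' @export
to_estimation_space <- function(params, priors, which = NULL) {
  if (is.null(which)) which <- priors$param[!priors$fixed]
  out <- vapply(which, function(nm) {
    row <- priors[priors$param == nm, ]
    if (nrow(row) != 1) stop("unknown parameter: ", nm, call. = FALSE)
    x <- params[[nm]]
    if (is.null(x)) stop("missing parameter: ", nm, call. = FALSE)
    if (row$transform == "log" && x <= 0)
      stop(nm, " must be > 0", call. = FALSE)
    if (row$transform == "logit" && (x <= 0 || x >= 1))
      stop(nm, " must lie strictly inside (0, 1)", call. = FALSE)
    link_fun(row$transform)(x)
  }, numeric(1))
  setNames(out, which)
}

#' @rdname to_estimation_space
#' @param est Named numeric vector in estimation space.
#' @export
to_native_space <- function(est, priors) {
  out <- lapply(names(est), function(nm) {
    row <- priors[priors$param == nm, ]
    if (nrow(row) != 1) stop("unknown parameter: ", nm, call. = FALSE)
    inv_link_fun(row$transform)(est[[nm]])
  })
  setNames(out, names(est))
}

#' Candidate model definitions
#'
#' Builds one of the four candidate models compared by the pipeline:
#' \describe{
#'   \item{HI}{standard 3-level HGF; 6 free parameters
#'     (`kappa2, omega2, mu2_0, mu3_0, zeta, nu`).}
#'   \item{HII}{mean-reverting HGF with a drift at the volatility level;
#'     7 free parameters (adds `m3`).}
#'   \item{CI, CII}{controls: the perceptual block is frozen at
#'     input-optimised values (see [fit_bayes_optimal()]) and only
#'     `zeta, nu` are free.}
#' }
#'
#' @param model One of `"HI"`, `"HII"`, `"CI"`, `"CII"`.
#' @param fixed_perceptual For CI/CII: named list of native-space perceptual
#'   values to freeze (typically from [fit_bayes_optimal()]); `NULL` freezes
#'   at the prior means.
#' @return An object of class `hgf_model`: list with `model`, `variant`,
#'   `priors`, `free` (free parameter names) and `fixed_native` (named list
#'   of all fixed native values).
#' @export
hgf_model <- function(model = c("HI", "HII", "CI", "CII"),
                      fixed_perceptual = NULL) {
  model <- match.arg(model)
  variant <- if (model %in% c("HII", "CII")) "mean_reverting" else "standard"
  priors <- prior_spec(variant)
  fixed <- priors$fixed
  if (model %in% c("CI", "CII")) fixed <- fixed | priors$block == "perceptual"
  free <- priors$param[!fixed]
  fixed_native <- setNames(as.list(priors$native_mean[fixed]),
                           priors$param[fixed])
  if (!is.null(fixed_perceptual)) {
    unknown <- setdiff(names(fixed_perceptual), priors$param)
    if (length(unknown))
      stop("unknown fixed parameters: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    fixed_native[names(fixed_perceptual)] <- fixed_perceptual
  }
  structure(list(model = model, variant = variant, priors = priors,
                 free = free, fixed_native = fixed_native),
            class = "hgf_model")
}

# Assemble full native parameter sets from an estimation-space vector of the
# model's free parameters plus its fixed values.
model_native_params <- function(est, model_def) {
  native <- to_native_space(setNames(as.numeric(est), model_def$free),
                            model_def$priors)
  all <- modifyList(model_def$fixed_native, native)
  pp <- perceptual_params(
    kappa2 = all$kappa2, omega2 = all$omega2, theta = all$theta,
    mu2_0 = all$mu2_0, sigma2_0 = all$sigma2_0,
    mu3_0 = all$mu3_0, sigma3_0 = all$sigma3_0,
    m3 = if (!is.null(all$m3)) all$m3 else 1,
    phi3 = if (!is.null(all$phi3)) all$phi3 else 0.1,
    variant = model_def$variant)
  rp <- response_params(zeta = all$zeta, nu = all$nu)
  list(perceptual = pp, response = rp)
}

# Estimation-space prior mean and variance vectors over the model's free set.
model_prior_moments <- function(model_def) {
  pr <- model_def$priors
  idx <- match(model_def$free, pr$param)
  mean_est <- vapply(idx, function(i)
    link_fun(pr$transform[i])(pr$native_mean[i]), numeric(1))
  list(mean = setNames(mean_est, model_def$free),
       var = setNames(pr$est_var[idx], model_def$free))
}
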