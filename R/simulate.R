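#' Simulate an agent on realised task inputs
#'
#' Runs the perceptual filter forward over the advice-accuracy stream,
#' computes per-trial choice probabilities from the response model, and
#' samples binary responses.
#'
#' @param records Data.frame from [realize_inputs()] (columns `u`, `c`).
#' @param pparams A [perceptual_params()] object.
#' @param rparams A [response_params()] object.
#' @param seed Integer seed for the response draws.
#' @return The records with `y` filled, plus attribute `trajectory` (the
#'   [hgf_filter()] output).
#' @export
simulate_agent <- function(records, pparams, rparams, seed = NULL) {
  traj <- hgf_filter(records$u, pparams)
  records$y <- sample_responses(traj, records$c, rparams, seed = seed)
  attr(records, "trajectory") <- traj
  records
}

#' Specify a synthetic cohort
#'
#' Groups of agents generated from a candidate model with group-specific
#' parameter distributions. Generative parameters are drawn as Gaussians in
#' estimation space (logit/log for bounded parameters), centred on the
#' group's native-space means — draws therefore always respect the native
#' bounds.
#'
#' @param groups Named list; each element a list with fields
#'   `n` (number of subjects), `model` (`"HI"` or `"HII"`), and optionally
#'   `mean` (named list of native-space means overriding the prior means)
#'   and `sd` (named list of estimation-space spreads overriding
#'   the per-parameter spreads).
#' @param spread_scale Multiplier on the default estimation-space spreads
#'   (the Table-1 prior standard deviations, with `m3` widened to sd 2 so
#'   that volatility-perception phenotypes are well separated).
#' @param schedule Task schedule shared by all subjects.
#' @return Object of class `hgf_cohort_spec`.
#' @export
cohort_spec <- function(groups, spread_scale = 1,
                        schedule = default_schedule()) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  for (g in groups) {
    if (is.null(g$n) || g$n < 0) stop("each group needs n >= 0", call. = FALSE)
    if (is.null(g$model) || !g$model %in% c("HI", "HII"))
      stop("each group needs model 'HI' or 'HII'", call. = FALSE)
  }
  structure(list(groups = groups, spread_scale = spread_scale,
                 schedule = schedule),
            class = "hgf_cohort_spec")
}

# Draw one subject's native parameters for a model, Gaussian in estimation
# space around the (possibly overridden) means. Default spreads are the
# Table-1 prior standard deviations scaled by `spread_scale`, except m3
# which defaults to a wide sd of 2 so that volatility-perception phenotypes
# span the clinically interesting range.
draw_subject_params <- function(model_def, mean_native = NULL, sd_est = NULL,
                                spread_scale = 1) {
  pm <- model_prior_moments(model_def)
  mu <- pm$mean
  if (!is.null(mean_native)) {
    for (nm in names(mean_native)) {
      if (nm %in% model_def$free) {
        row <- model_def$priors[model_def$priors$param == nm, ]
        mu[nm] <- link_fun(row$transform)(mean_native[[nm]])
      }
    }
  }
  sds <- sqrt(pm$var) * spread_scale
  if ("m3" %in% names(sds)) sds["m3"] <- 2 * spread_scale
  if (!is.null(sd_est))
    for (nm in intersect(names(sd_est), names(sds))) sds[nm] <- sd_est[[nm]]
  est <- rnorm(length(mu), mu, sds)
  setNames(est, names(mu))
}

#' Generate a labelled synthetic cohort
#'
#' For every subject: draw ground-truth parameters from the group's
#' distribution, realise the task inputs, and simulate responses. Ground
#' truth (native and estimation space) and the generating model are stored
#' for recovery analyses.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed; subject-level seeds are derived from it.
#' @return Object of class `hgf_cohort`: list with `trials` (long
#'   data.frame: `subject_id, group, trial, phase, u, c, y`), `truth` (one
#'   row per subject: group, generating model, estimation-space parameters),
#'   `truth_params` (list of per-subject parameter objects) and `schedule`.
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "hgf_cohort_spec"))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  trials <- list(); truth <- list(); tp <- list()
  sid <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    if (g$n == 0) next
    model_def <- hgf_model(g$model)
    for (i in seq_len(g$n)) {
      sid <- sid + 1L
      # reject-and-redraw: ground-truth agents must have valid trajectories
      for (attempt in seq_len(100)) {
        est <- draw_subject_params(model_def, g$mean, g$sd,
                                   spec$spread_scale)
        pars <- model_native_params(est, model_def)
        rec <- realize_inputs(spec$schedule)
        rec <- try(simulate_agent(rec, pars$perceptual, pars$response),
                   silent = TRUE)
        if (!inherits(rec, "try-error")) break
      }
      if (inherits(rec, "try-error"))
        stop("no valid parameter draw in 100 attempts", call. = FALSE)
      id <- sprintf("S%03d", sid)
      trials[[sid]] <- cbind(subject_id = id, group = gname,
                             rec[c("trial", "phase", "u", "c", "y")])
      truth[[sid]] <- data.frame(subject_id = id, group = gname,
                                 model = g$model, t(est))
      tp[[id]] <- pars
    }
  }
  if (sid == 0L)
    return(structure(list(trials = empty_trials(), truth = NULL,
                          truth_params = list(), schedule = spec$schedule),
                     class = "hgf_cohort"))
  allnames <- unique(unlist(lapply(truth, names)))
  truth_df <- do.call(rbind, lapply(truth, function(d) {
    for (m in setdiff(allnames, names(d))) d[[m]] <- NA_real_
    d[allnames]
  }))
  structure(list(trials = do.call(rbind, trials), truth = truth_df,
                 truth_params = tp, schedule = spec$schedule),
            class = "hgf_cohort")
}

empty_trials <- function() {
  data.frame(subject_id = character(0), group = character(0),
             trial = integer(0), phase = character(0),
             u = integer(0), c = numeric(0), y = integer(0),
             stringsAsFactors = FALSE)
}

#' Effect of the drift equilibrium on learning
#'
#' Sweeps the drift equilibrium `m3` over a grid with all other perceptual
#' parameters fixed (by default at input-optimised values, mirroring how
#' such simulations are conditioned on an ideal observer for the input at
#' hand) and summarises, per grid point, the average level-1 learning rate
#' and the mean absolute trial-to-trial change of the advice prediction in
#' the volatile phase. Grid points whose trajectory is rejected
#' (non-positive precision — the degenerate high-volatility regime) are
#' returned with `valid = FALSE`.
#'
#' @param records Realised inputs ([realize_inputs()] output).
#' @param m3_grid Grid of drift equilibria.
#' @param baseline Named list of perceptual parameters to hold fixed;
#'   `NULL` fits them to the input stream via [fit_bayes_optimal()].
#' @return Data.frame with columns `m3`, `mean_lr1`, `mean_volatile_update`,
#'   `valid`.
#' @export
m3_effect_curve <- function(records, m3_grid = -4:4, baseline = NULL) {
  if (is.null(baseline))
    baseline <- fit_bayes_optimal(records$u, "mean_reverting", restarts = 2)
  vol <- records$phase == "volatile"
  out <- data.frame(m3 = m3_grid, mean_lr1 = NA_real_,
                    mean_volatile_update = NA_real_, valid = FALSE)
  for (i in seq_along(m3_grid)) {
    p <- perceptual_params(kappa2 = baseline$kappa2,
                           omega2 = baseline$omega2,
                           mu2_0 = baseline$mu2_0, mu3_0 = baseline$mu3_0,
                           m3 = m3_grid[i], variant = "mean_reverting")
    tr <- try(hgf_filter(records$u, p), silent = TRUE)
    if (inherits(tr, "try-error")) next
    out$mean_lr1[i] <- mean(tr$lr1)
    out$mean_volatile_update[i] <- mean(abs(diff(tr$muhat1[vol])))
    out$valid[i] <- TRUE
  }
  out
}

#' Two-group study-design cohort
#'
#' Convenience wrapper for the design the simulation studies presuppose: a
#' control-like group generated from the standard HGF and a patient-like
#' group generated from the mean-reverting HGF with an elevated drift
#' equilibrium (`m3` centred at 3), so that the patient-like agents come to
#' perceive the adviser's intentions as increasingly volatile.
#'
#' @param n_per_group Subjects per group.
#' @param m3_patient Native-space mean of `m3` in the patient-like group.
#' @param seed Master seed.
#' @inheritParams cohort_spec
#' @return An `hgf_cohort`.
#' @export
study_cohort <- function(n_per_group = 10, m3_patient = 3, seed = 1,
                         schedule = default_schedule()) {
  spec <- cohort_spec(list(
    control_like = list(n = n_per_group, model = "HI"),
    patient_like = list(n = n_per_group, model = "HII",
                        mean = list(m3 = m3_patient))
  ), schedule = schedule)
  generate_cohort(spec, seed = seed)
}
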