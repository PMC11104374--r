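#' Enumerate the model-recovery simulation design
#'
#' Dry-run enumeration of the full factorial design: one simulation per
#' (generating model, subject, seed) cell. The full study design — 4 models,
#' 56 subjects, 20 seeds — enumerates 4480 simulations.
#'
#' @param models Character vector of generating models.
#' @param n_subjects Subjects per synthetic dataset.
#' @param n_seeds Simulation seeds.
#' @return Data.frame with columns `model`, `subject`, `seed`; its row
#'   count is the number of simulations.
#' @export
recovery_design <- function(models = c("HI", "HII", "CI", "CII"),
                            n_subjects = 56, n_seeds = 20) {
  expand.grid(model = models, subject = seq_len(n_subjects),
              seed = seq_len(n_seeds), stringsAsFactors = FALSE)
}

# Simulate one subject from a generating model (CI/CII simulate from the
# model's fixed perceptual block + drawn response parameters). Parameter
# draws whose filter trajectory is invalid on the realised inputs are
# rejected and redrawn: generative agents must have well-defined beliefs.
simulate_from_model <- function(model, schedule, spread_scale = 1,
                                mean_native = NULL, max_draws = 100) {
  gen_def <- hgf_model(model)
  for (i in seq_len(max_draws)) {
    est <- draw_subject_params(gen_def, mean_native = mean_native,
                               spread_scale = spread_scale)
    pars <- model_native_params(est, gen_def)
    rec <- realize_inputs(schedule)
    sim <- try(simulate_agent(rec, pars$perceptual, pars$response),
               silent = TRUE)
    if (!inherits(sim, "try-error"))
      return(list(records = sim, est = est, model = model))
  }
  stop("no valid parameter draw in ", max_draws, " attempts", call. = FALSE)
}

# Candidate-model definitions for one subject's input stream; CI/CII get
# their perceptual block frozen at input-optimised values.
candidate_defs <- function(models, u, bo_restarts = 1) {
  defs <- list()
  for (m in models) {
    defs[[m]] <- if (m %in% c("CI", "CII")) {
      variant <- if (m == "CII") "mean_reverting" else "standard"
      bo <- fit_bayes_optimal(u, variant, restarts = bo_restarts)
      hgf_model(m, fixed_perceptual = bo)
    } else hgf_model(m)
  }
  defs
}

#' Model recovery: seed-averaged protected-exceedance confusion matrix
#'
#' For every seed and generating model: simulate a synthetic dataset of
#' `n_subjects` agents (generative parameters drawn around the prior means,
#' with a wide spread on the drift equilibrium `m3`), re-invert every
#' candidate model on every subject, run random-effects model selection,
#' and record the protected exceedance probabilities. The confusion matrix
#' averages these over seeds; each row lies on the simplex.
#'
#' @param models Candidate (and generating) model set.
#' @param n_subjects Subjects per synthetic dataset (scaled-down default
#'   20; the full study design used 56).
#' @param n_seeds Number of simulation seeds (scaled-down default 5; full
#'   design 20).
#' @param schedule Task schedule.
#' @param seed Master seed from which per-cell seeds are derived.
#' @param restarts Optimisation restarts per fit (desk-scale default 2).
#' @param gen_mean Optional named list (by generating model) of native-space
#'   generative means overriding the prior means, e.g.
#'   `list(HII = list(m3 = 3))` for a patient-like volatility-perception
#'   cohort.
#' @param keep_fits Keep per-seed truth/estimate pairs (needed for
#'   [parameter_recovery()] on the same simulations).
#' @param progress Print per-cell progress.
#' @return Object of class `hgf_model_recovery`: `confusion` (generating x
#'   selected, mean protected exceedance probabilities), `per_seed` (array
#'   seeds x generating x selected), and if `keep_fits` a list `fits` of
#'   per-(seed, model) truth/estimate tables.
#' @export
model_recovery <- function(models = c("HI", "HII"), n_subjects = 20,
                           n_seeds = 5, schedule = default_schedule(),
                           seed = 1, restarts = 2, keep_fits = TRUE,
                           gen_mean = NULL, progress = FALSE) {
  K <- length(models)
  per_seed <- array(NA_real_, c(n_seeds, K, K),
                    dimnames = list(NULL, models, models))
  fits <- list()
  for (s in seq_len(n_seeds)) {
    for (gi in seq_along(models)) {
      gen <- models[gi]
      cell_seed <- (seed * 1000L + s * 37L + gi * 7L) %% .Machine$integer.max
      old <- local_seed(cell_seed)
      lme <- matrix(NA_real_, n_subjects, K, dimnames = list(NULL, models))
      truth <- matrix(NA_real_, n_subjects, 0)
      ests <- list()
      for (n in seq_len(n_subjects)) {
        sim <- simulate_from_model(gen, schedule,
                                   mean_native = gen_mean[[gen]])
        defs <- candidate_defs(models, sim$records$u)
        for (ci in seq_along(models)) {
          fit <- fit_map(sim$records, defs[[models[ci]]],
                         restarts = restarts,
                         seed = cell_seed + n * 101L + ci)
          lme[n, ci] <- fit$lme
          if (models[ci] == gen) ests[[n]] <- fit$est
        }
        if (n == 1) truth <- matrix(NA_real_, n_subjects, length(sim$est),
                                    dimnames = list(NULL, names(sim$est)))
        truth[n, ] <- sim$est
      }
      restore_seed(old)
      res <- bms(lme, seed = cell_seed)
      per_seed[s, gi, ] <- res$pxp
      if (keep_fits && gen %in% c("HI", "HII")) {
        est_mat <- do.call(rbind, ests)
        fits[[paste0(gen, "_seed", s)]] <-
          list(model = gen, seed = s, truth = truth, estimate = est_mat)
      }
      if (progress)
        message(sprintf("seed %d gen %s: pxp = %s", s, gen,
                        paste(round(res$pxp, 3), collapse = " ")))
    }
  }
  confusion <- apply(per_seed, c(2, 3), mean)
  structure(list(confusion = confusion, per_seed = per_seed, fits = fits),
            class = "hgf_model_recovery")
}

#' Cohen's f-squared from a correlation
#'
#' `f2 = r^2 / (1 - r^2)`; `f2 >= 0.35` is conventionally a large effect
#' and is the criterion for good parameter recovery. Returns `Inf` at
#' `|r| = 1`.
#'
#' @param r Pearson correlation(s).
#' @return f-squared value(s).
#' @export
cohen_f2 <- function(r) {
  out <- r^2 / (1 - r^2)
  out[abs(r) >= 1] <- Inf
  out
}

#' Parameter recovery: simulated vs recovered estimates
#'
#' Pearson correlation (with two-sided p-value) and Cohen's f-squared per
#' parameter between the generative ("simulated") and re-estimated
#' ("recovered") values, computed in estimation space where supports are
#' unbounded.
#'
#' @param truth Matrix/data.frame of generative estimation-space values,
#'   subjects in rows, parameters in columns.
#' @param estimate Matrix of recovered values, same shape.
#' @return Data.frame with columns `param`, `r`, `p`, `f2`, `n`.
#' @export
parameter_recovery <- function(truth, estimate) {
  truth <- as.matrix(truth); estimate <- as.matrix(estimate)
  if (!all(dim(truth) == dim(estimate)))
    stop("truth and estimate must have identical shape", call. = FALSE)
  if (nrow(truth) < 3) stop("need at least 3 subjects", call. = FALSE)
  params <- colnames(truth)
  out <- lapply(seq_along(params), function(j) {
    x <- truth[, j]; y <- estimate[, j]
    if (sd(x) == 0 || sd(y) == 0)
      stop("zero-variance vector for parameter ", params[j], call. = FALSE)
    ct <- cor.test(x, y)
    data.frame(param = params[j], r = unname(ct$estimate), p = ct$p.value,
               f2 = cohen_f2(unname(ct$estimate)), n = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parameter-recovery study for one model
#'
#' Runs the scaled-down simulate-and-refit design for a single candidate
#' model: per seed, draw `n_subjects` generative parameter sets, simulate,
#' re-invert the same model, and tabulate per-parameter recovery. The
#' per-seed fraction meeting the large-effect criterion `f2 >= 0.35` is the
#' headline recovery diagnostic.
#'
#' @inheritParams model_recovery
#' @param model The model to simulate from and re-fit (`"HI"` or `"HII"`).
#' @return Object of class `hgf_param_recovery`: `per_seed` (long
#'   data.frame of [parameter_recovery()] tables with a `seed` column),
#'   `criterion_rate` (per parameter, fraction of seeds with `f2 >= 0.35`),
#'   and `fits` (per-seed truth/estimate pairs).
#' @export
parameter_recovery_study <- function(model = "HII", n_subjects = 20,
                                     n_seeds = 5,
                                     schedule = default_schedule(),
                                     seed = 1, restarts = 2,
                                     progress = FALSE) {
  rec <- model_recovery(models = c("HI", "HII"), n_subjects = n_subjects,
                        n_seeds = n_seeds, schedule = schedule, seed = seed,
                        restarts = restarts, keep_fits = TRUE,
                        progress = progress)
  summarize_recovery_fits(rec$fits, model)
}

# Shared tail: turn per-seed truth/estimate pairs into recovery tables.
summarize_recovery_fits <- function(fits, model) {
  keep <- Filter(function(f) f$model == model, fits)
  if (!length(keep)) stop("no fits for model ", model, call. = FALSE)
  per_seed <- do.call(rbind, lapply(keep, function(f) {
    tab <- parameter_recovery(f$truth, f$estimate)
    tab$seed <- f$seed
    tab
  }))
  rownames(per_seed) <- NULL
  rate <- tapply(per_seed$f2 >= 0.35, per_seed$param, mean)
  structure(list(model = model, per_seed = per_seed,
                 criterion_rate = rate, fits = keep),
            class = "hgf_param_recovery")
}

#' Simulate-and-refit recovery for a single model without model comparison
#'
#' Lighter-weight path than [parameter_recovery_study()] when only one
#' model's parameter recovery is of interest: simulates from `model` and
#' re-inverts only `model`.
#'
#' @inheritParams parameter_recovery_study
#' @return An `hgf_param_recovery`.
#' @export
self_recovery <- function(model = "HII", n_subjects = 20, n_seeds = 5,
                          schedule = default_schedule(), seed = 1,
                          restarts = 2, progress = FALSE) {
  fits <- list()
  for (s in seq_len(n_seeds)) {
    cell_seed <- (seed * 1000L + s * 37L) %% .Machine$integer.max
    old <- local_seed(cell_seed)
    truth <- NULL; ests <- list()
    for (n in seq_len(n_subjects)) {
      sim <- simulate_from_model(model, schedule)
      fit <- fit_map(sim$records, hgf_model(model), restarts = restarts,
                     seed = cell_seed + n * 101L)
      ests[[n]] <- fit$est
      if (is.null(truth)) truth <- matrix(NA_real_, n_subjects,
                                          length(sim$est),
                                          dimnames = list(NULL, names(sim$est)))
      truth[n, ] <- sim$est
    }
    restore_seed(old)
    fits[[paste0(model, "_seed", s)]] <-
      list(model = model, seed = s, truth = truth,
           estimate = do.call(rbind, ests))
    if (progress) message("seed ", s, " done")
  }
  summarize_recovery_fits(fits, model)
}

#' Pairwise identifiability of estimated parameters
#'
#' Pearson correlation matrix between estimated parameters across subjects;
#' strong pairwise correlations (`|r| > 0.6`) indicate that two parameters
#' trade off against each other and are flagged.
#'
#' @param estimates Matrix of per-subject estimates (estimation space),
#'   subjects in rows, parameters in columns; `n >= 3`.
#' @param threshold Absolute-correlation flag threshold.
#' @return List with `correlation` (symmetric matrix, unit diagonal) and
#'   `flagged` (data.frame of parameter pairs exceeding the threshold).
#' @export
identifiability <- function(estimates, threshold = 0.6) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (any(apply(estimates, 2, sd) == 0))
    stop("degenerate (zero-variance) parameter column", call. = FALSE)
  R <- cor(estimates)
  idx <- which(abs(R) > threshold & upper.tri(R), arr.ind = TRUE)
  flagged <- data.frame(param1 = colnames(R)[idx[, 1]],
                        param2 = colnames(R)[idx[, 2]],
                        r = R[idx], stringsAsFactors = FALSE)
  list(correlation = R, flagged = flagged)
}
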