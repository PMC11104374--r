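#' Advice-taking frequency by phase
#'
#' The behavioural summary of the task: per subject and phase, the fraction
#' of trials on which the participant went with the advice
#' (`#trials with y = 1 / #phase trials`), plus the stable-minus-volatile
#' contrast per subject and group-level means.
#'
#' @param trials Long data.frame with columns `subject_id`, `group`
#'   (optional), `phase`, `y`.
#' @return Object of class `hgf_phase_summary`: `by_subject` (subject x
#'   phase frequencies and `contrast = stable - volatile`), `by_group`
#'   (group x phase mean and sd, if a `group` column is present).
#' @export
advice_taking_frequency <- function(trials) {
  req <- c("subject_id", "phase", "y")
  if (!all(req %in% names(trials)))
    stop("trials needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (any(is.na(trials$y))) stop("y must be defined on all trials", call. = FALSE)
  if (!all(trials$y %in% c(0, 1))) stop("y must be binary", call. = FALSE)
  has_group <- "group" %in% names(trials)
  agg <- aggregate(y ~ subject_id + phase, data = trials, FUN = mean,
                   drop = FALSE)
  if (any(is.na(agg$y))) stop("empty subject x phase cell", call. = FALSE)
  wide <- reshape(agg, idvar = "subject_id", timevar = "phase",
                  direction = "wide")
  names(wide) <- sub("^y\\.", "", names(wide))
  for (ph in c("stable", "volatile"))
    if (!ph %in% names(wide)) stop("missing phase: ", ph, call. = FALSE)
  wide$contrast <- wide$stable - wide$volatile
  if (has_group) {
    grp_map <- unique(trials[c("subject_id", "group")])
    wide <- merge(wide, grp_map, by = "subject_id")
  }
  by_group <- NULL
  if (has_group) {
    long <- merge(agg, unique(trials[c("subject_id", "group")]),
                  by = "subject_id")
    by_group <- aggregate(y ~ group + phase, data = long,
                          FUN = function(v) c(mean = mean(v), sd = sd(v)))
    by_group <- data.frame(group = by_group$group, phase = by_group$phase,
                           mean = by_group$y[, "mean"],
                           sd = by_group$y[, "sd"])
  }
  structure(list(by_subject = wide, by_group = by_group),
            class = "hgf_phase_summary")
}

#' Posterior predictive check of the advice-taking summary
#'
#' Simulates `n_reps` response sets per subject from fitted parameters on
#' the subject's own input stream and recomputes the phase summary for each
#' replicate, giving the model's predictive distribution of the behavioural
#' effect.
#'
#' @param fits Named list (by subject id) of `hgf_fit` objects.
#' @param trials Long trial data.frame (the data the fits were obtained
#'   on), columns `subject_id`, `group` (optional), `trial`, `phase`, `u`,
#'   `c`.
#' @param n_reps Number of predictive replicates.
#' @param seed Integer seed.
#' @return Object of class `hgf_ppc`: `ensemble` (long data.frame over
#'   reps of per-subject stable/volatile frequencies and contrasts) and
#'   `by_group` (group x phase predictive means, if groups present).
#' @export
posterior_predictive <- function(fits, trials, n_reps = 20, seed = 1) {
  if (n_reps == 0)
    return(structure(list(ensemble = NULL, by_group = NULL),
                     class = "hgf_ppc"))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  has_group <- "group" %in% names(trials)
  out <- list()
  for (rep in seq_len(n_reps)) {
    sim_trials <- lapply(names(fits), function(id) {
      sub <- trials[trials$subject_id == id, ]
      sub <- sub[order(sub$trial), ]
      pars <- model_native_params(fits[[id]]$est, fits[[id]]$model_def)
      sub$y <- {
        traj <- hgf_filter(sub$u, pars$perceptual)
        sample_responses(traj, sub$c, pars$response)
      }
      sub
    })
    summ <- advice_taking_frequency(do.call(rbind, sim_trials))
    bs <- summ$by_subject
    bs$rep <- rep
    out[[rep]] <- bs
  }
  ensemble <- do.call(rbind, out)
  by_group <- NULL
  if (has_group) {
    long <- rbind(
      data.frame(group = ensemble$group, phase = "stable",
                 y = ensemble$stable),
      data.frame(group = ensemble$group, phase = "volatile",
                 y = ensemble$volatile))
    by_group <- aggregate(y ~ group + phase, data = long, FUN = mean)
    names(by_group)[3] <- "mean"
  }
  structure(list(ensemble = ensemble, by_group = by_group),
            class = "hgf_ppc")
}
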