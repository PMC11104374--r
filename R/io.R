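.trial_cols <- c("subject_id", "group", "trial", "phase", "u", "c", "y")

#' Write / read trial tables
#'
#' Trial data travel as delimited text with the header
#' `subject_id, group, trial, phase, u, c, y`. Reading validates every row:
#' `u` and `y` binary (y may be NA), `c` strictly inside `(0, 1)`, `phase`
#' in `{stable, volatile}`.
#'
#' @param trials Long trial data.frame.
#' @param path File path (CSV).
#' @return `read_trials()` returns a named list of per-subject data.frames
#'   (ordered by trial); `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(.trial_cols, names(trials))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  write.csv(trials[.trial_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.trial_cols, names(raw))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  bad_u <- which(!raw$u %in% c(0, 1))
  if (length(bad_u))
    stop("non-binary u at row ", bad_u[1], call. = FALSE)
  bad_y <- which(!(is.na(raw$y) | raw$y %in% c(0, 1)))
  if (length(bad_y))
    stop("non-binary y at row ", bad_y[1], call. = FALSE)
  bad_c <- which(!(raw$c > 0 & raw$c < 1))
  if (length(bad_c))
    stop("cue probability outside (0, 1) at row ", bad_c[1], call. = FALSE)
  bad_p <- which(!raw$phase %in% c("stable", "volatile"))
  if (length(bad_p))
    stop("unknown phase label at row ", bad_p[1], call. = FALSE)
  split_ids <- unique(raw$subject_id)
  out <- lapply(split_ids, function(id) {
    sub <- raw[raw$subject_id == id, ]
    sub[order(sub$trial), ]
  })
  setNames(out, split_ids)
}

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in order — `simulate` (synthetic cohort),
#' `fit` (per-subject MAP for every candidate model), `compare`
#' (random-effects model selection, overall and per group), `recover`
#' (model + parameter recovery), `ppc` (posterior predictive of the phase
#' summary) — writing JSON/CSV artifacts to `out_dir`. A run is
#' reproducible from the config alone.
#'
#' @param config Named list:
#'   `seed` (integer), `stages` (subset of
#'   `c("simulate","fit","compare","recover","ppc")`),
#'   `n_per_group`, `m3_patient`, `models` (candidate set),
#'   `restarts`, `recovery` (list: `n_subjects`, `n_seeds`),
#'   `n_reps` (predictive replicates). Missing entries fall back to
#'   modest defaults.
#' @param out_dir Output directory (created if needed); `NULL` runs
#'   in-memory only.
#' @return Named list of stage results (invisibly writes artifacts).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- modifyList(list(
    seed = 1, stages = c("simulate", "fit", "compare", "ppc"),
    n_per_group = 8, m3_patient = 3, models = c("HI", "HII"),
    restarts = 2, recovery = list(n_subjects = 10, n_seeds = 2),
    n_reps = 10), config)
  unknown <- setdiff(cfg$models, c("HI", "HII", "CI", "CII"))
  if (length(unknown))
    stop("unknown model name: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bad_stage <- setdiff(cfg$stages,
                       c("simulate", "fit", "compare", "recover", "ppc"))
  if (length(bad_stage))
    stop("unknown stage: ", paste(bad_stage, collapse = ", "), call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_json <- function(x, name) {
    if (!is.null(out_dir))
      jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  }
  save_csv <- function(x, name) {
    if (!is.null(out_dir))
      write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  out <- list(config = cfg)
  save_json(cfg[setdiff(names(cfg), "stages")], "config.json")

  cohort <- NULL
  if ("simulate" %in% cfg$stages ||
      any(c("fit", "compare", "ppc") %in% cfg$stages)) {
    cohort <- study_cohort(n_per_group = cfg$n_per_group,
                           m3_patient = cfg$m3_patient, seed = cfg$seed)
    out$cohort <- cohort
    if (!is.null(out_dir)) {
      write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
      save_csv(cohort$truth, "ground_truth.csv")
    }
  }

  if (any(c("fit", "compare", "ppc") %in% cfg$stages)) {
    ids <- unique(cohort$trials$subject_id)
    fits <- list(); lme <- matrix(NA_real_, length(ids), length(cfg$models),
                                  dimnames = list(ids, cfg$models))
    for (i in seq_along(ids)) {
      sub <- cohort$trials[cohort$trials$subject_id == ids[i], ]
      defs <- candidate_defs(cfg$models, sub$u)
      subfits <- lapply(cfg$models, function(m)
        fit_map(sub, defs[[m]], restarts = cfg$restarts,
                seed = cfg$seed + i))
      names(subfits) <- cfg$models
      lme[i, ] <- vapply(subfits, function(f) f$lme, numeric(1))
      fits[[ids[i]]] <- subfits
    }
    out$fits <- fits
    out$lme <- lme
    # long format: models have different free-parameter sets
    fit_tab <- do.call(rbind, lapply(ids, function(id)
      do.call(rbind, lapply(cfg$models, function(m) {
        f <- fits[[id]][[m]]
        data.frame(subject_id = id, model = m, lme = f$lme,
                   param = names(f$est), estimate = as.numeric(f$est),
                   stringsAsFactors = FALSE)
      }))))
    save_csv(fit_tab, "fits.csv")
  }

  if ("compare" %in% cfg$stages) {
    overall <- bms(lme, seed = cfg$seed)
    groups <- unique(cohort$trials[c("subject_id", "group")])
    per_group <- lapply(split(groups$subject_id, groups$group), function(ids_g)
      bms(lme[ids_g, , drop = FALSE], seed = cfg$seed))
    out$bms <- list(overall = overall, per_group = per_group)
    save_json(list(
      overall = list(freq = as.list(overall$freq), xp = as.list(overall$xp),
                     bor = overall$bor, pxp = as.list(overall$pxp)),
      per_group = lapply(per_group, function(b)
        list(freq = as.list(b$freq), xp = as.list(b$xp), bor = b$bor,
             pxp = as.list(b$pxp)))), "bms.json")
  }

  if ("recover" %in% cfg$stages) {
    rec <- model_recovery(models = cfg$models,
                          n_subjects = cfg$recovery$n_subjects,
                          n_seeds = cfg$recovery$n_seeds, seed = cfg$seed,
                          restarts = cfg$restarts)
    out$recovery <- rec
    save_csv(as.data.frame(as.table(rec$confusion)), "model_confusion.csv")
  }

  if ("ppc" %in% cfg$stages) {
    # posterior predictive from the model favoured overall per subject
    best <- cfg$models[max.col(lme, ties.method = "first")]
    sel <- lapply(seq_along(ids), function(i) fits[[ids[i]]][[best[i]]])
    names(sel) <- ids
    ppc <- posterior_predictive(sel, cohort$trials, n_reps = cfg$n_reps,
                                seed = cfg$seed)
    out$ppc <- ppc
    save_csv(ppc$ensemble, "ppc_ensemble.csv")
  }
  out
}
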