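#!/usr/bin/env Rscript
# Stage 3: random-effects Bayesian model selection.
#
# Treats model identity as a random effect across subjects and infers
# Dirichlet-distributed model frequencies from the stage-2 log model
# evidences. Reports relative frequencies f, exceedance probabilities,
# the Bayesian omnibus risk, protected exceedance probabilities (PXP), and
# per-subject model attributions — overall and per group, since different
# groups may be governed by different learning mechanisms.

suppressPackageStartupMessages(library(advicehgf))

out_dir <- "results"
seed <- 1

lme_tab <- read.csv(file.path(out_dir, "lme.csv"), check.names = FALSE)
lme <- as.matrix(lme_tab[, -1])
rownames(lme) <- lme_tab$subject_id
groups <- unique(read.csv(file.path(out_dir, "trials.csv"))[
  c("subject_id", "group")])

report <- function(res, label) {
  cat("\n==", label, "==\n")
  print(res)
}

overall <- bms(lme, seed = seed)
report(overall, "all subjects")

per_group <- list()
for (g in unique(groups$group)) {
  ids <- groups$subject_id[groups$group == g]
  per_group[[g]] <- bms(lme[ids, , drop = FALSE], seed = seed)
  report(per_group[[g]], g)
}

to_list <- function(b) list(alpha = as.list(b$alpha),
                            freq = as.list(b$freq), xp = as.list(b$xp),
                            bor = b$bor, pxp = as.list(b$pxp))
jsonlite::write_json(
  c(list(overall = to_list(overall)), lapply(per_group, to_list)),
  file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

attr_tab <- data.frame(subject_id = rownames(overall$attribution),
                       overall$attribution, check.names = FALSE)
write.csv(attr_tab, file.path(out_dir, "attributions.csv"),
          row.names = FALSE)

cat("\nExpected pattern on the synthetic cohort: the patient-like group is",
    "attributed decisively to the mean-reverting model (HII). The",
    "control-like group is harder to call: a standard-HGF agent can be",
    "imitated by HII placing its equilibrium at the operating volatility",
    "level, so evidence differences stay small and the omnibus risk keeps",
    "the protected probabilities near chance. Pooling the groups dilutes",
    "the selection, which is why the per-group analysis matters.\n")
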