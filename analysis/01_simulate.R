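#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Builds a synthetic plains-zebra cohort matching the study design the
# downstream stages assume: 76 blood samples (ages 0.15-20.2 y) and 20
# biopsy samples (ages 0.16-24.8 y) profiled at 2000 CpGs (age-linear
# clock sites, pacemaker sites sharing one log trajectory, null sites),
# plus a 70-individual genotype panel with planted runs of homozygosity
# spanning F_ROH 0-0.37. Everything is written under results/data/ with
# the generating truth, so every later stage can be scored against it.

suppressMessages(library(equusage))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20210

ages_blood <- gen_ages(76, 0.15, 20.2, seed = seed + 1)
ages_biopsy <- gen_ages(20, 0.16, 24.8, seed = seed + 2)
ages <- c(ages_blood, ages_biopsy)
tissue <- rep(c("blood", "biopsy"), c(76, 20))
sex <- rep_len(c("F", "M"), 96)

sim <- gen_methylation(ages, n_sites = 2000, frac_clock = 0.04,
                       frac_pacemaker = 0.08, noise_sd = 0.02,
                       tissue_labels = tissue, sex = sex, seed = seed + 3)
sheet <- data.frame(sample_id = rownames(sim$beta), species = "plains_zebra",
                    tissue = tissue, sex = sex, age = ages,
                    stringsAsFactors = FALSE)
write_sample_sheet(sheet, "results/data/sample_sheet.csv")
write_beta_matrix(sim$beta, "results/data/beta.csv")
saveRDS(sim$truth, "results/data/methyl_truth.rds")

# related species for the transfer test (90% of sites conserved)
ages_rel <- gen_ages(50, 0.3, 22, seed = seed + 4)
rel <- gen_related_species(sim$truth, ages_rel, conserved_frac = 0.9,
                           shift_sd = 0.1, seed = seed + 5)
write_beta_matrix(rel$beta, "results/data/beta_related.csv")
write.csv(data.frame(sample_id = rownames(rel$beta), age = ages_rel),
          "results/data/related_ages.csv", row.names = FALSE)

# genotype panel: 70 individuals, inbreeding spread over the observed range
froh_targets <- c(rep(0, 20), seq(0.01, 0.37, length.out = 50))
geno <- gen_genotypes(70, 30000, target_froh = froh_targets, seed = seed + 6)
write_vcf_minimal(geno$table, "results/data/panel.vcf")
write.csv(geno$truth$runs, "results/data/planted_roh.csv", row.names = FALSE)
write.csv(data.frame(ind = names(geno$truth$target_froh),
                     target_froh = geno$truth$target_froh),
          "results/data/target_froh.csv", row.names = FALSE)

cat(sprintf("cohort: %d samples (%d blood, %d biopsy), %d CpGs\n",
            nrow(sim$beta), sum(tissue == "blood"), sum(tissue == "biopsy"),
            ncol(sim$beta)))
cat(sprintf("panel: %d individuals x %d SNPs, screened length %.2g bp\n",
            length(geno$table$ids), nrow(geno$table$sites),
            geno$truth$screened_length_bp))
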