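#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with known ground truth.
#
# Emulates the two experimental arms: a 4x4 nitrogen-by-water factorial on
# seedlings (48 RNA-seq samples, triplicate) and a 19-cultivar 2x2 field
# trial (228 samples), plus a 10-timepoint N-dose time course. Counts are
# negative binomial with log-means linear in the dose predictors; 60% of
# genes are null. Everything downstream reads the TSVs written here.

suppressPackageStartupMessages(library(nwdose))
seed <- 20260927L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

lab <- build_lab_design()
sim <- simulate_lab_counts(
  lab, 4000,
  class_proportions = c(N = 0.1, W = 0.1, NdivW = 0.1, NxW = 0.1,
                        null = 0.6),
  effect_size = 1, dispersion = 0.05, seed = seed
)
pheno <- simulate_phenotypes(lab, coef = c(intercept = 3, NxW = 0.5),
                             noise_sd = 0.1, seed = seed + 1L)

write_design(lab, "results/data/lab_design.tsv")
write_count_matrix(sim$counts, "results/data/lab_counts.tsv")
write_phenotypes(pheno, "results/data/lab_phenotypes.tsv")
utils::write.table(sim$truth, "results/data/lab_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

field <- build_field_design(sprintf("cv%02d", 1:19))
simf <- simulate_field_counts(
  field, 2000,
  class_proportions = c(N = 0.1, W = 0.1, NxW = 0.1, NdivW = 0.1,
                        null = 0.6),
  genotype_sd = 0.3, effect_size = 1, dispersion = 0.05, seed = seed + 2L
)
phf <- simulate_phenotypes(field, coef = c(intercept = 3, NxW = 0.5),
                           noise_sd = 0.1, seed = seed + 3L)

write_design(field, "results/data/field_design.tsv")
write_count_matrix(simf$counts, "results/data/field_counts.tsv")
write_phenotypes(phf, "results/data/field_phenotypes.tsv")
utils::write.table(simf$truth, "results/data/field_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

tc <- simulate_timecourse(n_genes = 2000, n_responders = 300,
                          fold = 4, dispersion = 0.05, seed = seed + 4L)
write_count_matrix(tc$treated, "results/data/timecourse_treated.tsv")
write_count_matrix(tc$control, "results/data/timecourse_control.tsv")
utils::write.table(data.frame(sample_id = colnames(tc$treated),
                              time = tc$col_times),
                   "results/data/timecourse_times.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(tc$truth, "results/data/timecourse_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tc$uptake, "results/data/timecourse_uptake.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("lab: ", nrow(sim$counts), " genes x ", ncol(sim$counts),
        " samples; field: ", nrow(simf$counts), " x ", ncol(simf$counts),
        "; time course: ", nrow(tc$treated), " x ", ncol(tc$treated),
        " per arm")
message("wrote results/data/*.tsv")
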