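#!/usr/bin/env Rscript
# Stage 6: eigengene-phenotype association with permutation nulls, and
# Monte-Carlo overlap of lab vs field gene classes.
#
# For each dose-response class recovered in the field, summarizes the
# class's expression as its first principal component (eigengene) and tests
# the association with each field trait against a null of eigengenes from
# random same-size gene sets. Overlaps between lab and field class
# memberships are tested against random draws from the shared background.

suppressPackageStartupMessages(library(nwdose))
seed <- 20260930L
n_perm <- 2000L  # permutations per test; study-scale analyses use 10000

field <- read_design("results/data/field_design.tsv")
counts <- read_count_matrix("results/data/field_counts.tsv")
pheno <- read_phenotypes("results/data/field_phenotypes.tsv")
fres <- utils::read.delim("results/field_gene_classes.tsv")
lab_cl <- utils::read.delim("results/lab_gene_classes.tsv")

kept <- filter_low_counts(counts)
sf <- size_factors(kept)
background <- rownames(kept)

traits <- list(shoot_biomass = log2(pheno$shoot_biomass),
               wue_delta13c = pheno$wue_delta13c)
rows <- list()
for (cls in c("N", "W", "NdivW", "NxW")) {
  gs <- intersect(fres$gene_id[fres$field_class == cls], background)
  if (length(gs) < 2) next
  for (trait in names(traits)) {
    a <- eigengene_assoc(gs, kept, traits[[trait]], sf = sf,
                         n_perm = n_perm, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      class = cls, trait = trait, n_genes = length(gs),
      r_abs = round(a$r_abs, 3), p_value = a$p_value,
      variance_proportion = round(a$variance_proportion, 3)
    )
  }
}
assoc <- do.call(rbind, rows)
utils::write.table(assoc, "results/eigengene_associations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("eigengene-trait associations (permutation p):")
for (i in seq_len(nrow(assoc))) {
  message(sprintf("  %-6s %-14s |r| = %.2f  p = %.4g  (PC1 var %.0f%%)",
                  assoc$class[i], assoc$trait[i], assoc$r_abs[i],
                  assoc$p_value[i], 100 * assoc$variance_proportion[i]))
}

# lab vs field class overlaps against the shared expressed background
shared_bg <- intersect(lab_cl$gene_id, background)
ov_list <- list()
for (cls in c("N", "W", "NdivW", "NxW")) {
  lab_set <- intersect(lab_cl$gene_id[lab_cl$model_class == cls], shared_bg)
  field_set <- intersect(fres$gene_id[fres$field_class == cls], shared_bg)
  if (!length(lab_set) || !length(field_set)) next
  ov_list[[cls]] <- monte_carlo_overlap(lab_set, field_set, shared_bg,
                                        n_perm = n_perm, seed = seed)
}
ovt <- adjust_overlaps(ov_list)
ovt$class <- names(ov_list)
utils::write.table(ovt, "results/lab_field_overlaps.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("lab-field class overlaps (Monte Carlo):")
for (i in seq_len(nrow(ovt))) {
  message(sprintf("  %-6s overlap %d of %d x %d  p = %.4g (adj %.4g)",
                  ovt$class[i], ovt$overlap[i], ovt$size_a[i],
                  ovt$size_b[i], ovt$p_value[i], ovt$padj[i]))
}
message("wrote results/eigengene_associations.tsv, results/lab_field_overlaps.tsv")
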