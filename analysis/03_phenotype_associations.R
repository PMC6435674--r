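#!/usr/bin/env Rscript
# Stage 3: gene-phenotype correlation screen per dose-response class.
#
# Correlates normalized expression of every classified gene with log2 shoot
# biomass, leaf N-content and water-use efficiency (delta-13C), BH-adjusted
# across genes, and tabulates the share of significant genes per class —
# the interaction classes are expected to track biomass, the N class
# N-content, the W class water-use efficiency. Also selects the phenotype
# model for shoot biomass by backward elimination.

suppressPackageStartupMessages(library(nwdose))

lab <- read_design("results/data/lab_design.tsv")
counts <- read_count_matrix("results/data/lab_counts.tsv")
pheno <- read_phenotypes("results/data/lab_phenotypes.tsv")
cl <- utils::read.delim("results/lab_gene_classes.tsv")

sel <- select_phenotype_model(pheno$shoot_biomass, lab)
message("biomass is best explained by: ",
        paste(sel$selected, collapse = " + "))

classified <- cl$gene_id[cl$model_class != "unclassified"]
sf <- size_factors(counts)
norm <- log2(sweep(counts[classified, , drop = FALSE], 2, sf, "/") + 1)

traits <- list(
  shoot_biomass = log2(pheno$shoot_biomass),
  n_content = pheno$n_content,
  wue_delta13c = pheno$wue_delta13c
)
rows <- list()
for (trait in names(traits)) {
  pf <- pearson_fdr(norm, traits[[trait]])
  hit <- pf$gene_id[pf$significant]
  for (cls in c("N", "W", "NdivW", "NxW")) {
    members <- cl$gene_id[cl$model_class == cls]
    rows[[length(rows) + 1]] <- data.frame(
      trait = trait, class = cls, n_genes = length(members),
      pct_correlated = round(100 * mean(members %in% hit), 1)
    )
  }
}
out <- do.call(rbind, rows)
utils::write.table(out, "results/class_trait_correlations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("share of genes correlated with each trait, by class:")
for (i in seq_len(nrow(out))) {
  message(sprintf("  %-14s %-6s %5.1f%%", out$trait[i], out$class[i],
                  out$pct_correlated[i]))
}
message("wrote results/class_trait_correlations.tsv")
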