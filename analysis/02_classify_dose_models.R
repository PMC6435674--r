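#!/usr/bin/env Rscript
# Stage 2: per-gene NB dose models and backward simplification.
#
# Filters weakly expressed genes, fits the four-term model (N, W, N/W,
# N-by-W) to every gene, simplifies each to the smallest form whose every
# term passes FDR 0.005, and computes the N vs N/W weight statistic for
# genes in the N / N/W / N+N/W classes. Reports recovery against the
# generating truth.

suppressPackageStartupMessages(library(nwdose))

lab <- read_design("results/data/lab_design.tsv")
counts <- read_count_matrix("results/data/lab_counts.tsv")
truth <- utils::read.delim("results/data/lab_truth.tsv")

kept <- filter_low_counts(counts)
message("count filter: ", nrow(counts), " -> ", nrow(kept), " genes")

cl <- classify_genes(kept, lab)
cl$trace <- NULL
utils::write.table(cl, "results/lab_gene_classes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

tab <- sort(table(cl$model_class), decreasing = TRUE)
message("model classes:")
for (nm in names(tab)) message(sprintf("  %-14s %d", nm, tab[[nm]]))

tr <- truth$true_class[match(cl$gene_id, truth$gene_id)]
single <- tr %in% c("N", "W", "NdivW", "NxW")
message(sprintf("single-term recovery: %.1f%% (%d genes)",
                100 * mean(cl$model_class[single] == tr[single]),
                sum(single)))
message(sprintf("null genes classified: %.1f%%",
                100 * mean(cl$model_class[tr == "null"] != "unclassified")))

w <- cl$n_weight[!is.na(cl$n_weight)]
message(sprintf(
  "N vs N/W weights: %d genes, %.1f%% within 10 points of 0 or 100",
  length(w), 100 * mean(w <= 10 | w >= 90)))
message("wrote results/lab_gene_classes.tsv")
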