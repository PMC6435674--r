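#' Gene-phenotype Pearson correlation screen with FDR control
#'
#' Correlates each gene's normalized expression with a per-sample phenotype
#' (Pearson, two-sided), adjusts across genes by Benjamini-Hochberg, and
#' flags genes passing `assoc_alpha`. Constant genes (or a constant
#' phenotype) have no defined correlation and are flagged not-significant
#' with a reason rather than erroring.
#'
#' @param expr numeric matrix of per-gene values (genes x samples), already
#'   normalized/transformed as desired.
#' @param phenotype numeric vector, one value per sample.
#' @param config an [nw_config()].
#' @return A tibble: `gene_id`, `r`, `p_value`, `padj`, `significant`,
#'   `reason` (NA unless the test was undefined).
#' @export
pearson_fdr <- function(expr, phenotype, config = nw_config()) {
  if (ncol(expr) != length(phenotype) || length(phenotype) < 3) {
    stop("phenotype must match expr columns (>= 3 samples)", call. = FALSE)
  }
  const_pheno <- stats::sd(phenotype) == 0
  res <- lapply(seq_len(nrow(expr)), function(g) {
    x <- expr[g, ]
    if (const_pheno || stats::sd(x) == 0) {
      return(list(r = NA_real_, p = NA_real_,
                  reason = if (const_pheno) "constant phenotype"
                  else "constant gene"))
    }
    ct <- stats::cor.test(x, phenotype, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, reason = NA_character_)
  })
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  padj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    gene_id = rownames(expr),
    r = r, p_value = p, padj = padj,
    significant = !is.na(padj) & padj < config$assoc_alpha,
    reason = vapply(res, `[[`, character(1), "reason")
  )
}

#' Monte-Carlo gene-set overlap test
#'
#' Significance of the overlap between two gene sets within a background:
#' `n_perm` random sets of size `|set_a|` are drawn uniformly without
#' replacement from the background and intersected with `set_b`;
#' `p = (1 + #{permutation overlap >= observed}) / (1 + n_perm)`.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of
#'   `background`.
#' @param background character vector of all eligible gene ids.
#' @param n_perm number of permutations.
#' @param seed integer seed (fixed seed gives a reproducible p).
#' @return A list: `size_a`, `size_b`, `background_size`, `overlap`,
#'   `p_value`.
#' @export
monte_carlo_overlap <- function(set_a, set_b, background,
                                n_perm = 10000, seed = 1L) {
  out_a <- setdiff(set_a, background)
  out_b <- setdiff(set_b, background)
  if (length(out_a) || length(out_b)) {
    stop("sets must be subsets of the background; offenders: ",
         paste(utils::head(c(out_a, out_b), 10), collapse = ", "),
         call. = FALSE)
  }
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  background <- unique(background)
  obs <- length(intersect(set_a, set_b))
  in_b <- background %in% set_b
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      sum(in_b[sample.int(length(background), length(set_a))]) >= obs
    }, numeric(1)))
  })
  list(
    size_a = length(set_a), size_b = length(set_b),
    background_size = length(background), overlap = obs,
    p_value = (1 + exceed) / (1 + n_perm)
  )
}

#' Adjust a family of overlap tests by Benjamini-Hochberg
#'
#' @param overlaps a list of [monte_carlo_overlap()] results.
#' @return A tibble with one row per test and a `padj` column.
#' @export
adjust_overlaps <- function(overlaps) {
  p <- vapply(overlaps, `[[`, numeric(1), "p_value")
  tibble::tibble(
    size_a = vapply(overlaps, `[[`, numeric(1), "size_a"),
    size_b = vapply(overlaps, `[[`, numeric(1), "size_b"),
    background_size = vapply(overlaps, `[[`, numeric(1), "background_size"),
    overlap = vapply(overlaps, `[[`, numeric(1), "overlap"),
    p_value = p,
    padj = stats::p.adjust(p, method = "BH")
  )
}

#' Build the eigengene (first principal component) of a gene set
#'
#' Expression is normalized by size factors, transformed to
#' `log2(x + 1)`, genes are centered, and the first principal component
#' across samples is extracted by singular value decomposition. Scores are
#' defined up to a global sign; the sign is fixed so the loading with the
#' largest magnitude is positive, making results reproducible.
#'
#' @param counts count matrix restricted to the gene set (>= 1 gene,
#'   >= 2 samples).
#' @param sf per-sample size factors (e.g. from [size_factors()] on the
#'   full matrix); defaults to 1 (counts already normalized).
#' @return A list: `scores` (one per sample), `variance_proportion`.
#' @export
build_eigengene <- function(counts, sf = rep(1, ncol(counts))) {
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (nrow(counts) < 1) stop("need >= 1 gene", call. = FALSE)
  y <- log2(sweep(counts, 2, sf, "/") + 1)
  eigengene_from_log <- function(ylog) {
    yc <- ylog - rowMeans(ylog)
    sv <- svd(t(yc), nu = 1, nv = 1)   # samples x genes
    scores <- sv$u[, 1] * sv$d[1]
    loading <- sv$v[, 1]
    flip <- sign(loading[which.max(abs(loading))])
    if (flip < 0) scores <- -scores
    tot <- sum(sv$d^2)
    list(scores = stats::setNames(scores, colnames(ylog)),
         variance_proportion = if (tot > 0) sv$d[1]^2 / tot else NA_real_)
  }
  eigengene_from_log(y)
}

#' Permutation test of an eigengene-phenotype association
#'
#' The statistic is the absolute Pearson correlation between the gene set's
#' eigengene scores and the phenotype (eigengene sign is arbitrary, so all
#' correlations are reported as positive). The null distribution is built
#' by drawing `n_perm` random gene sets of the same size (without
#' replacement) from the background expression matrix, computing each null
#' eigengene and its `|r|`; `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param gene_set character vector of gene ids (rows of
#'   `background_counts`).
#' @param background_counts count matrix of all eligible genes.
#' @param phenotype per-sample values (log2-transform upstream when
#'   appropriate).
#' @param sf per-sample size factors.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param config an [nw_config()].
#' @return A list: `r_abs`, `p_value`, `significant`,
#'   `variance_proportion`, `scores`, `reason` (non-NA when the test is
#'   undefined, e.g. constant phenotype).
#' @export
eigengene_assoc <- function(gene_set, background_counts, phenotype,
                            sf = rep(1, ncol(background_counts)),
                            n_perm = 10000, seed = 1L,
                            config = nw_config()) {
  missing_genes <- setdiff(gene_set, rownames(background_counts))
  if (length(missing_genes)) {
    stop("gene set members absent from background: ",
         paste(utils::head(missing_genes, 10), collapse = ", "),
         call. = FALSE)
  }
  if (length(phenotype) != ncol(background_counts)) {
    stop("phenotype must have one value per sample", call. = FALSE)
  }
  eg <- build_eigengene(
    background_counts[gene_set, , drop = FALSE], sf)
  if (stats::sd(phenotype) == 0) {
    return(list(r_abs = NA_real_, p_value = NA_real_, significant = FALSE,
                variance_proportion = eg$variance_proportion,
                scores = eg$scores, reason = "constant phenotype"))
  }
  # precompute the log2 normalized matrix once; null eigengenes reuse it
  ylog <- log2(sweep(background_counts, 2, sf, "/") + 1)
  abs_r_pc1 <- function(rows) {
    yc <- ylog[rows, , drop = FALSE]
    yc <- yc - rowMeans(yc)
    sv <- svd(t(yc), nu = 1, nv = 0)
    abs(stats::cor(sv$u[, 1], phenotype))
  }
  obs <- abs(stats::cor(eg$scores, phenotype))
  k <- length(unique(gene_set))
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      abs_r_pc1(sample.int(nrow(ylog), k))
    }, numeric(1))
  })
  p <- (1 + sum(null_r >= obs, na.rm = TRUE)) / (1 + n_perm)
  list(r_abs = obs, p_value = p, significant = p < 0.05,
       variance_proportion = eg$variance_proportion,
       scores = eg$scores, reason = NA_character_)
}

#' Rescale each gene's expression to the unit interval
#'
#' `(x - min) / (max - min)` per gene, so 1 marks the sample with maximal
#' expression. Constant genes map to all zeros by convention and are
#' flagged via the returned attribute `constant_genes`.
#'
#' @param expr numeric matrix, genes as rows.
#' @return A matrix of the same shape with values in \[0, 1\].
#' @export
normalize_unit_interval <- function(expr) {
  rng <- t(apply(expr, 1, range))
  span <- rng[, 2] - rng[, 1]
  const <- span == 0
  span[const] <- 1
  out <- (expr - rng[, 1]) / span
  out[const, ] <- 0
  attr(out, "constant_genes") <- rownames(expr)[const]
  out
}
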