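test_that("grain yield follows the moisture-normalized formula", {
  expect_equal(grain_yield(86, 14, 1), 86)
  expect_equal(grain_yield(123, 100, 2), 0)
  expect_equal(grain_yield(200, 20, 2), 200 * (80 / 86) / 2)

  # homogeneity: degree 1 in weight, degree -1 in area
  w <- c(50, 120); m <- c(12, 18); a <- c(1.5, 2)
  expect_equal(grain_yield(3 * w, m, a), 3 * grain_yield(w, m, a))
  expect_equal(grain_yield(w, m, 2 * a), grain_yield(w, m, a) / 2)

  expect_error(grain_yield(10, 14, 0), "sampling_area")
  expect_error(grain_yield(-1, 14, 1), "grain_weight")
  expect_error(grain_yield(10, 140, 1), "moisture")
})

test_that("field binning applies the significance and sign rules", {
  res <- tibble::tibble(
    gene_id = sprintf("g%d", 1:7),
    padj_N = c(0.01, 0.50, 0.01, 0.50, 0.50, 0.01, 0.50),
    padj_W = c(0.50, 0.01, 0.50, 0.50, 0.50, 0.01, 0.50),
    padj_NxW = c(0.50, 0.50, 0.01, 0.01, 0.01, 0.01, 0.50),
    log2fc_interaction = c(0.3, -0.2, 0.8, -0.8, 0.8, 0, 0.1)
  )
  b <- bin_field_genes(res)
  expect_identical(
    b$field_class,
    c("N",      # only N significant
      "W",      # only W significant
      "NxW",    # interaction significant, positive fold change
      "NdivW",  # interaction significant, negative fold change
      "NxW",    # interaction rules even without main effects
      "tie",    # significant interaction with exactly zero fold change
      "none")
  )
})

test_that("direction-conserved gene sets are exact intersections", {
  lab <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    class = c("N", "N", "NxW", "W"),
    direction = c("induced", "induced", "repressed", "induced")
  )
  fld <- tibble::tibble(
    gene_id = c("a", "b", "c", "e"),
    class = c("N", "N", "NxW", "W"),
    direction = c("induced", "repressed", "repressed", "induced")
  )
  kept <- conserved_direction(lab, fld)
  expect_setequal(kept$gene_id, c("a", "c"))  # b flips, d lab-only
})

test_that("the field model recovers classes and absorbs genotype", {
  # mostly-null composition: median-of-ratios normalization presumes the
  # bulk of the transcriptome is not differentially expressed
  fd <- build_field_design(sprintf("cv%02d", 1:19), replicates = 3)
  sim <- simulate_field_counts(
    fd, 150, class_proportions = c(N = 0.1, W = 0.1, NxW = 0.1,
                                   NdivW = 0.1, null = 0.6),
    genotype_sd = 0.4, effect_size = 1, seed = 47
  )
  fr <- bin_field_genes(fit_field_model(sim$counts, fd))
  tr <- sim$truth$true_class
  expect_gt(mean(fr$field_class[tr == "NxW"] == "NxW"), 0.8)
  expect_gt(mean(fr$field_class[tr == "NdivW"] == "NdivW"), 0.8)
  expect_gt(mean(fr$field_class[tr == "N"] == "N"), 0.7)
  # genes whose only structure is genotype offsets stay unclassified
  expect_gt(mean(fr$field_class[tr == "null"] == "none"), 0.8)

  bad <- sim$counts
  colnames(bad)[1] <- "rogue_sample"
  expect_error(fit_field_model(bad, fd), "rogue_sample")
})

test_that("per-cultivar offsets in the model leave dose inference unchanged", {
  fd <- field_design_small(n_cultivars = 5, replicates = 3)
  sim <- simulate_field_counts(
    fd, 30, class_proportions = c(NxW = 0.3, NdivW = 0.3, null = 0.4),
    genotype_sd = 0.3, effect_size = 1, seed = 53
  )
  base <- fit_field_model(sim$counts, fd)
  set.seed(99)
  shift <- rnorm(5, 0, 1)[match(fd$cultivar, unique(fd$cultivar))]
  shifted <- fit_field_model(sim$counts, fd, extra_log_offset = shift)
  expect_lt(max(abs(base$p_N - shifted$p_N), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(base$p_W - shifted$p_W), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(base$p_NxW - shifted$p_NxW), na.rm = TRUE), 1e-6)
  expect_identical(bin_field_genes(base)$field_class,
                   bin_field_genes(shifted)$field_class)
})

test_that("phenotype model selection finds the generating terms", {
  d <- lab_design_default()
  ph <- simulate_phenotypes(d, coef = c(intercept = 3, NxW = 0.5),
                            noise_sd = 0.1, seed = 59)
  sel <- select_phenotype_model(ph$shoot_biomass, d)
  expect_identical(sel$selected, "NxW")

  phN <- simulate_phenotypes(d, coef = c(intercept = 3, N = 0.6),
                             noise_sd = 0.1, seed = 61)
  selN <- select_phenotype_model(phN$shoot_biomass, d)
  expect_identical(selN$selected, "N")

  const <- select_phenotype_model(rep(5, nrow(d)), d)
  expect_length(const$selected, 0)

  # field variant reports the ANOVA interaction statistic
  fd <- field_design_small(n_cultivars = 6, replicates = 3)
  phf <- simulate_phenotypes(fd, coef = c(intercept = 3, NxW = 0.5),
                             noise_sd = 0.1, seed = 63)
  self <- select_phenotype_model(phf$shoot_biomass, fd)
  expect_identical(self$selected, "NxW")
  expect_gt(self$interaction_F, 10)
  expect_lt(self$interaction_p, 1e-4)
})
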