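test_that("simulation is reproducible and seed-sensitive", {
  d <- lab_design_default()
  a <- simulate_lab_counts(d, 50, seed = 7)
  b <- simulate_lab_counts(d, 50, seed = 7)
  c3 <- simulate_lab_counts(d, 50, seed = 8)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts, c3$counts))

  tc1 <- simulate_timecourse(n_genes = 30, n_responders = 5, seed = 3)
  tc2 <- simulate_timecourse(n_genes = 30, n_responders = 5, seed = 3)
  expect_identical(tc1$treated, tc2$treated)
  expect_identical(tc1$control, tc2$control)

  fd <- field_design_small()
  f1 <- simulate_field_counts(fd, 40, seed = 4)
  f2 <- simulate_field_counts(fd, 40, seed = 4)
  expect_identical(f1$counts, f2$counts)
})

test_that("zero effect size produces only null genes at the right baseline", {
  d <- lab_design_default()
  sim <- simulate_lab_counts(d, 200, effect_size = 0,
                             class_proportions = c(N = 0.5, NxW = 0.5),
                             dispersion = 0.05, seed = 21)
  expect_true(all(sim$truth$true_class == "null"))
  beta_cols <- grep("^beta_", names(sim$truth), value = TRUE)
  expect_true(all(as.matrix(sim$truth[, beta_cols]) == 0))

  # per-gene empirical mean within 3 Monte-Carlo SEs of exp(baseline)
  mu <- exp(sim$truth$baseline_log_mean)
  se <- sqrt((mu + 0.05 * mu^2) / ncol(sim$counts))
  dev <- abs(rowMeans(sim$counts) - mu) / se
  expect_lt(mean(dev > 3), 0.02)
})

test_that("counts obey the negative-binomial moment law", {
  # many replicates of each condition, modest gene count; constant baseline
  # so each gene has a single (mu, phi) per condition cell
  d <- build_lab_design(replicates = 25)
  phi <- 0.05
  sim <- simulate_lab_counts(d, 60, class_proportions = c(null = 1),
                             effect_size = 0, dispersion = phi,
                             baseline_log_mean_range = log(c(200, 200)),
                             seed = 31)
  mu <- 200
  v_theory <- mu + phi * mu^2
  v_emp <- apply(sim$counts, 1, var)
  # 3 MC standard errors of the mean of 60 per-gene variance estimates
  se <- sd(v_emp) / sqrt(length(v_emp))
  expect_lt(abs(mean(v_emp) - v_theory), 3 * se + 0.05 * v_theory)
  expect_gt(mean(v_emp), mu)  # clearly overdispersed relative to Poisson
})

test_that("truth tables are consistent with nonzero effects", {
  d <- lab_design_default()
  for (seed in c(1, 2, 3)) {
    sim <- simulate_lab_counts(
      d, 120,
      class_proportions = c(N = 0.2, W = 0.2, `N+NdivW` = 0.2, full = 0.2,
                            null = 0.2),
      seed = seed
    )
    tr <- sim$truth
    for (i in seq_len(nrow(tr))) {
      nz <- c("N", "W", "NdivW", "NxW")[
        c(tr$beta_N[i], tr$beta_W[i], tr$beta_NdivW[i], tr$beta_NxW[i]) != 0]
      lab <- if (length(nz) == 0) "null"
      else if (length(nz) == 4) "full"
      else paste(nz, collapse = "+")
      expect_identical(tr$true_class[i], lab)
    }
  }
})

test_that("phenotypes follow the dose model deterministically at zero noise", {
  d <- lab_design_default()
  ph0 <- simulate_phenotypes(d, coef = c(intercept = 2), noise_sd = 0,
                             seed = 1)
  expect_true(all(abs(ph0$shoot_biomass - 4) < 1e-12))

  ph1 <- simulate_phenotypes(d, coef = c(intercept = 1, NxW = 1),
                             noise_sd = 0, seed = 1)
  expect_equal(ph1$shoot_biomass, 2^(1 + d$n_std * d$w_std),
               tolerance = 1e-12)

  # monotone marginals: N-content in N dose, delta-13C falling in W volume
  n_means <- tapply(ph1$n_content, d$n_level, mean)
  expect_true(all(diff(n_means[order(as.numeric(names(n_means)))]) > 0))
  w_means <- tapply(ph1$wue_delta13c, d$w_level, mean)
  expect_true(all(diff(w_means[order(as.numeric(names(w_means)))]) < 0))
})

test_that("least squares recovers the phenotype interaction coefficient", {
  d <- lab_design_default()
  ph <- simulate_phenotypes(d, coef = c(intercept = 3, NxW = 0.5),
                            noise_sd = 0.1, seed = 11)
  fit <- lm(log2(ph$shoot_biomass) ~ d$n_std + d$w_std +
              I(d$n_std * d$w_std))
  expect_lt(abs(coef(fit)[["I(d$n_std * d$w_std)"]] - 0.5), 0.1)
})

test_that("time-course responders shift means only after onset", {
  tc <- simulate_timecourse(n_genes = 60, n_responders = 60, replicates = 12,
                            onset_minutes = 30, fold = 4,
                            directions = "up", dispersion = 0.02, seed = 13)
  on <- tc$col_times >= 30
  ratio <- rowMeans(tc$treated[, on]) / rowMeans(tc$control[, on])
  expect_gt(mean(ratio >= 3), 0.95)
  pre <- tc$col_times < 30
  ratio_pre <- rowMeans(tc$treated[, pre]) / rowMeans(tc$control[, pre])
  expect_lt(max(abs(log(ratio_pre))), log(1.5))

  expect_equal(tc$uptake$uptake[tc$uptake$time == 0], 0)
  expect_true(all(diff(tc$uptake$uptake) >= 0))

  expect_error(
    simulate_timecourse(n_genes = 10, n_responders = 2,
                        onset_minutes = 500, seed = 1),
    "onset"
  )
})

test_that("field interaction genes show the right contrast sign", {
  fd <- build_field_design(sprintf("cv%02d", 1:19))
  sim <- simulate_field_counts(
    fd, 60, class_proportions = c(NxW = 0.5, NdivW = 0.5),
    genotype_sd = 0.2, effect_size = 1, seed = 17
  )
  xN <- fd$n_level == max(fd$n_level)
  xW <- fd$w_level == max(fd$w_level)
  lg <- log2(sim$counts + 1)
  contrast <- rowMeans(lg[, xN & xW]) - rowMeans(lg[, xN & !xW]) -
    rowMeans(lg[, !xN & xW]) + rowMeans(lg[, !xN & !xW])
  expect_true(all(contrast[sim$truth$true_class == "NxW"] > 0))
  expect_true(all(contrast[sim$truth$true_class == "NdivW"] < 0))

  expect_error(simulate_field_counts(lab_design_default(), 10),
               "cultivar")
})

test_that("zero genotype spread reduces the field generator to a pure 2x2", {
  fd <- field_design_small(n_cultivars = 4, replicates = 6)
  sim <- simulate_field_counts(fd, 40, genotype_sd = 0,
                               class_proportions = c(null = 1),
                               effect_size = 0, seed = 23)
  # with no genotype offsets, per-cultivar means coincide within MC error
  for (g in sample(40, 5)) {
    cv_means <- tapply(sim$counts[g, ], fd$cultivar, mean)
    mu <- exp(sim$truth$baseline_log_mean[g])
    se <- sqrt((mu + 0.05 * mu^2) / 24)
    expect_true(all(abs(cv_means - mu) < 4 * se))
  }
})
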