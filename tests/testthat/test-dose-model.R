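test_that("size factors satisfy symmetry and scale equivariance", {
  m <- matrix(rep(c(10L, 20L, 30L), 4), nrow = 3,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4))

  m2 <- toy_counts(20, 6)
  m2 <- m2 + 1L  # ensure all positive
  doubled <- m2
  doubled[, 3] <- 2L * doubled[, 3]
  sf <- size_factors(doubled)
  expect_equal(sf[[3]] / sf[[1]],
               2 * size_factors(m2)[[3]] / size_factors(m2)[[1]],
               tolerance = 1e-12)

  zero_col <- m2
  zero_col[, 2] <- 0L
  expect_error(size_factors(zero_col), colnames(m2)[2])
})

test_that("size factors agree exactly with a brute-force oracle", {
  set.seed(55)
  for (i in 1:5) {
    m <- matrix(rnbinom(50 * 10, mu = 60, size = 5), 50,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("s%02d", 1:10)))
    storage.mode(m) <- "integer"
    expect_equal(unname(size_factors(m)), oracle_size_factors(m),
                 tolerance = 1e-14)
  }
})

test_that("model-form enumeration lists the 14 simplified forms", {
  forms <- enumerate_model_forms()
  expect_length(forms, 14)
  sizes <- lengths(forms)
  expect_equal(sum(sizes == 3), 4)
  expect_equal(sum(sizes == 2), 6)
  expect_equal(sum(sizes == 1), 4)
  expect_true(any(vapply(forms, function(f) identical(f, "NxW"),
                         logical(1))))
  labels <- vapply(forms, paste, character(1), collapse = "+")
  expect_false(anyDuplicated(labels) > 0)
})

test_that("N vs N/W weights follow the coefficient ratio", {
  expect_equal(compute_nw_weights(c(N = 0.8), "N"),
               list(n_weight = 100, ndivw_weight = 0))
  expect_equal(compute_nw_weights(c(NdivW = -1.2), "NdivW"),
               list(n_weight = 0, ndivw_weight = 100))
  w <- compute_nw_weights(c(N = 0.7, NdivW = -0.7), "N+NdivW")
  expect_equal(w$n_weight, 50)
  w2 <- compute_nw_weights(c(N = 1, NdivW = 3), "N+NdivW")
  expect_equal(w2$n_weight, 25)
  expect_equal(w2$ndivw_weight, 75)
  expect_error(compute_nw_weights(c(NxW = 1), "NxW"), "classes")
})

test_that("a flat gene shows no dose signal in the full model", {
  d <- lab_design_default()
  set.seed(3)
  filler <- matrix(rnbinom(30 * 48, mu = 100, size = 20), 30)
  m <- rbind(matrix(50L, 1, 48), filler)
  dimnames(m) <- list(sprintf("g%02d", 1:31), d$sample_id)
  storage.mode(m) <- "integer"
  ff <- fit_full_model(m, d)
  expect_lt(max(abs(unlist(ff[1, paste0("beta_", c("N", "W", "NdivW",
                                                   "NxW"))]))), 0.05)
  expect_true(all(ff[1, paste0("padj_", c("N", "W", "NdivW", "NxW"))] >
                    0.5))
})

test_that("the full model recovers a strong N effect", {
  d <- lab_design_default()
  sim <- simulate_lab_counts(d, 40,
                             class_proportions = c(N = 0.5, null = 0.5),
                             effect_size = 1, dispersion = 0.05, seed = 19)
  ff <- fit_full_model(sim$counts, d)
  ngenes <- sim$truth$true_class == "N"
  err <- abs(ff$beta_N[ngenes] - sim$truth$beta_N[ngenes])
  expect_lt(max(err), 0.25)
})

test_that("backward elimination accepts only models whose terms all pass", {
  d <- lab_design_default()
  sim <- simulate_lab_counts(
    d, 120, class_proportions = c(N = 0.2, NxW = 0.2, full = 0.1,
                                  null = 0.5),
    effect_size = 1, seed = 29
  )
  cl <- classify_genes(sim$counts, d)
  cfg <- nw_config()
  for (i in seq_len(nrow(cl))) {
    if (cl$model_class[i] == "unclassified") next
    final <- cl$trace[[i]][[length(cl$trace[[i]])]]
    expect_true(all(final$padj < cfg$model_alpha))
    want <- if (cl$model_class[i] == "full") c("N", "W", "NdivW", "NxW")
    else strsplit(cl$model_class[i], "+", fixed = TRUE)[[1]]
    expect_setequal(final$terms, want)
  }
  # strong four-term genes land in the full model, most nulls in none
  full_true <- sim$truth$true_class == "full"
  expect_gt(mean(cl$model_class[full_true] == "full"), 0.8)
  nulls <- sim$truth$true_class == "null"
  expect_gt(mean(cl$model_class[nulls] == "unclassified"), 0.85)
})

test_that("the weight statistic is bimodal for disjoint N and N/W genes", {
  d <- lab_design_default()
  sim <- simulate_lab_counts(
    d, 160, class_proportions = c(N = 0.3, NdivW = 0.3, null = 0.4),
    effect_size = 1, seed = 37
  )
  cl <- classify_genes(sim$counts, d)
  w <- cl$n_weight[!is.na(cl$n_weight)]
  expect_gt(length(w), 50)
  expect_gt(mean(w <= 10 | w >= 90), 0.9)
})
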