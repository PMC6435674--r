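test_that("per-gene Pearson screen matches the textbook formula", {
  set.seed(71)
  expr <- matrix(rnorm(30 * 12, 8), 30,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
  pheno <- rnorm(12)
  got <- pearson_fdr(expr, pheno)
  for (g in c(1, 7, 30)) {
    want <- oracle_pearson(expr[g, ], pheno)
    expect_equal(got$r[g], want$r, tolerance = 1e-12)
    expect_equal(got$p_value[g], want$p, tolerance = 1e-12)
  }

  # a gene identical to the phenotype is maximally significant
  expr2 <- rbind(expr, pheno_gene = pheno)
  got2 <- pearson_fdr(expr2, pheno)
  expect_equal(got2$r[got2$gene_id == "pheno_gene"], 1, tolerance = 1e-12)
  expect_true(got2$significant[got2$gene_id == "pheno_gene"])

  # constant genes are flagged, not errors
  expr3 <- rbind(expr, flat = rep(2, 12))
  got3 <- pearson_fdr(expr3, pheno)
  flat <- got3[got3$gene_id == "flat", ]
  expect_false(flat$significant)
  expect_identical(flat$reason, "constant gene")
})

test_that("null genes are almost never significant after BH", {
  set.seed(73)
  expr <- matrix(rnorm(500 * 20), 500,
                 dimnames = list(sprintf("g%03d", 1:500), NULL))
  got <- pearson_fdr(expr, rnorm(20))
  expect_lt(mean(got$significant), 0.01)
})

test_that("Monte-Carlo overlap p-values behave at the extremes", {
  bg <- sprintf("g%05d", 1:10000)
  same <- bg[1:20]
  r <- monte_carlo_overlap(same, same, bg, n_perm = 400, seed = 5)
  expect_equal(r$p_value, 1 / 401)
  expect_equal(r$overlap, 20)

  disj <- monte_carlo_overlap(bg[1:5], bg[101:105], bg, n_perm = 400,
                              seed = 5)
  expect_gt(disj$p_value, 0.9)

  expect_error(monte_carlo_overlap(c(same, "alien"), same, bg),
               "alien")
})

test_that("Monte-Carlo overlap agrees with the hypergeometric tail", {
  set.seed(77)
  n_perm <- 600
  bg <- sprintf("g%04d", 1:2000)
  for (i in 1:20) {
    na <- sample(30:80, 1)
    nb <- sample(40:120, 1)
    set_b <- sample(bg, nb)
    # draw set_a with some genuine overlap so tail probabilities vary
    k_forced <- sample(0:5, 1)
    set_a <- c(sample(set_b, k_forced), sample(setdiff(bg, set_b),
                                               na - k_forced))
    r <- monte_carlo_overlap(set_a, set_b, bg, n_perm = n_perm,
                             seed = 1000 + i)
    p_hyper <- phyper(r$overlap - 1, nb, 2000 - nb, na,
                      lower.tail = FALSE)
    se <- sqrt(p_hyper * (1 - p_hyper) / n_perm)
    expect_lt(abs(r$p_value - p_hyper), 3 * se + 2 / n_perm)
  }
})

test_that("eigengenes match a brute-force eigendecomposition", {
  set.seed(79)
  m <- matrix(rpois(50 * 20, 80), 50,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%02d", 1:20)))
  eg <- build_eigengene(m)
  y <- log2(m + 1)
  yc <- y - rowMeans(y)
  pc <- prcomp(t(yc), center = FALSE)
  expect_lt(max(abs(abs(eg$scores) - abs(unname(pc$x[, 1])))), 1e-8)
  expect_equal(eg$variance_proportion,
               pc$sdev[1]^2 / sum(pc$sdev^2), tolerance = 1e-10)

  # rank-1 cases
  single <- build_eigengene(m[1, , drop = FALSE])
  expect_equal(single$variance_proportion, 1)
  prof <- log2(m[1, ] + 1)
  cc <- abs(cor(single$scores, prof - mean(prof)))
  expect_equal(cc, 1, tolerance = 1e-10)

  # two identical rows are perfectly correlated
  two <- rbind(a = m[1, ], b = m[1, ])
  eg2 <- build_eigengene(two)
  expect_equal(eg2$variance_proportion, 1)

  expect_error(build_eigengene(m[, 1, drop = FALSE]), "2 samples")
})

test_that("eigengene association is sign-invariant with an add-one p", {
  set.seed(83)
  m <- matrix(rpois(200 * 24, 100), 200,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("s%02d", 1:24)))
  gs <- rownames(m)[1:15]
  eg <- build_eigengene(m[gs, ])
  r <- eigengene_assoc(gs, m, eg$scores, n_perm = 200, seed = 3)
  expect_equal(r$r_abs, 1, tolerance = 1e-10)
  expect_equal(r$p_value, 1 / 201)

  r_flip <- eigengene_assoc(gs, m, -eg$scores, n_perm = 200, seed = 3)
  expect_equal(r_flip$r_abs, r$r_abs, tolerance = 1e-12)
  expect_equal(r_flip$p_value, r$p_value)

  r_const <- eigengene_assoc(gs, m, rep(1, 24), n_perm = 50, seed = 3)
  expect_identical(r_const$reason, "constant phenotype")
  expect_false(r_const$significant)

  expect_error(eigengene_assoc(c(gs, "missing"), m, eg$scores),
               "missing")
})

test_that("unit-interval normalization is affine-invariant per gene", {
  x <- matrix(c(2, 4, 6,
                5, 5, 5,
                1, 0, 3), 3, byrow = TRUE,
              dimnames = list(c("rising", "flat", "mixed"), NULL))
  n <- normalize_unit_interval(x)
  expect_equal(unname(n["rising", ]), c(0, 0.5, 1))
  expect_equal(unname(n["flat", ]), c(0, 0, 0))
  expect_identical(attr(n, "constant_genes"), "flat")
  expect_equal(apply(n[c("rising", "mixed"), ], 1, max), c(rising = 1,
                                                           mixed = 1))

  n2 <- normalize_unit_interval(3 * x + 7)
  expect_equal(n2["rising", ], n["rising", ])
  expect_equal(n2["mixed", ], n["mixed", ])
})
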