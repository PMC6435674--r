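# shared small fixtures; heavier simulations are built inside the tests
# that need them so their cost is visible where it is paid

lab_design_default <- function() build_lab_design()

field_design_small <- function(n_cultivars = 6, replicates = 3) {
  build_field_design(sprintf("cv%02d", seq_len(n_cultivars)), replicates)
}

# tiny deterministic count matrix for I/O and size-factor unit tests
toy_counts <- function(n_genes = 5, n_samples = 4, seed = 101) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, 50), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# independent brute-force median-of-ratios, written against the definition
oracle_size_factors <- function(counts) {
  usable <- apply(counts, 1, function(r) all(r > 0))
  geo <- apply(counts[usable, , drop = FALSE], 1,
               function(r) exp(mean(log(r))))
  sapply(seq_len(ncol(counts)), function(j) {
    median(counts[usable, j] / geo)
  })
}

# textbook Pearson r and two-sided p, independent of cor.test
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

tmp_tsv <- function() tempfile(fileext = ".tsv")
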