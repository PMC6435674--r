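#' Synthetic data generators with known ground truth
#'
#' Every downstream stage of the pipeline is validated against simulated
#' data in which the class of each gene is known. Counts are drawn from a
#' negative binomial parameterized by mean and dispersion
#' (variance = mu + phi * mu^2), with log-means linear in the standardized
#' dose predictors — the generative inversion of the fitted model.
#'
#' @name simulate
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (all(dispersion <= 0)) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

resolve_class_terms <- function(class_name) {
  if (class_name %in% c("null", "none")) return(character(0))
  if (class_name == "full") return(nw_terms())
  terms <- strsplit(class_name, "+", fixed = TRUE)[[1]]
  bad <- setdiff(terms, nw_terms())
  if (length(bad)) {
    stop("unknown dose-model terms in class name: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  terms
}

class_label <- function(terms) {
  if (length(terms) == 0) return("null")
  if (length(terms) == 4) return("full")
  paste(nw_terms()[nw_terms() %in% terms], collapse = "+")
}

# deterministic class counts by largest remainder, so e.g. 2500 genes at
# proportions .2/.2/.2/.2/.2 gives exactly 500 per class
allocate_classes <- function(n_genes, class_proportions) {
  p <- class_proportions
  if (is.null(names(p)) || any(names(p) == "")) {
    stop("class_proportions must be a named vector", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  raw <- p * n_genes
  base <- floor(raw)
  left <- n_genes - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  rep(names(p), times = base)
}

#' Simulate a laboratory factorial count matrix with known gene classes
#'
#' Assigns each gene a response class (a subset of the terms N, W, N/W,
#' N-by-W, or `"null"`), draws a random direction (induced or repressed),
#' and generates negative-binomial counts whose log-mean is
#' `baseline + sum(beta * standardized predictor)`.
#'
#' @param design a lab design from [build_lab_design()].
#' @param n_genes number of genes to simulate.
#' @param class_proportions named vector of class proportions summing to 1;
#'   names are `"null"`, `"full"` or `+`-joined subsets of
#'   `N, W, NdivW, NxW`. Class counts are allocated deterministically
#'   (largest remainder).
#' @param effect_size absolute log-scale effect on each class term.
#' @param dispersion NB dispersion phi (scalar or per-gene vector);
#'   0 gives Poisson counts.
#' @param baseline_log_mean_range range (natural-log scale) from which
#'   per-gene baseline expression is drawn uniformly; the default spans
#'   mean counts of about 50 to 500.
#' @param seed integer seed; identical seeds give identical output.
#'
#' @return A list with `counts` (integer matrix) and `truth` (tibble:
#'   `gene_id`, `true_class`, `beta_N`, `beta_W`, `beta_NdivW`, `beta_NxW`,
#'   `baseline_log_mean`, `dispersion`, `direction`).
#' @export
simulate_lab_counts <- function(design, n_genes,
                                class_proportions = c(
                                  N = 0.1, W = 0.1, NdivW = 0.1, NxW = 0.1,
                                  null = 0.6
                                ),
                                effect_size = 1,
                                dispersion = 0.05,
                                baseline_log_mean_range = log(c(50, 500)),
                                seed = 1L) {
  if (n_genes <= 0) stop("n_genes must be positive", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  cols <- nw_term_columns()
  missing_cols <- setdiff(cols, names(design))
  if (length(missing_cols)) {
    stop("design lacks standardized predictors: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(design[, cols])
  colnames(X) <- nw_terms()
  simulate_from_predictors(X, design$sample_id, n_genes, class_proportions,
                           effect_size, dispersion, baseline_log_mean_range,
                           seed)
}

simulate_from_predictors <- function(X, sample_ids, n_genes,
                                     class_proportions, effect_size,
                                     dispersion, baseline_log_mean_range,
                                     seed, extra_offset = NULL) {
  classes <- allocate_classes(n_genes, class_proportions)
  phi <- rep_len(dispersion, n_genes)
  with_seed(seed, {
    classes <- sample(classes)  # shuffle class order across gene ids
    # induced/repressed split exactly 50/50 within each class, so a small
    # simulated panel has no net expression shift per condition (real
    # transcriptomes are large enough that an iid draw would balance out)
    sign_g <- rep(1, n_genes)
    for (cls in unique(classes)) {
      idx <- which(classes == cls)
      sign_g[idx] <- sample(rep_len(c(1, -1), length(idx)))
    }
    base_g <- stats::runif(n_genes, baseline_log_mean_range[1],
                           baseline_log_mean_range[2])
    betas <- matrix(0, n_genes, ncol(X),
                    dimnames = list(NULL, colnames(X)))
    for (g in seq_len(n_genes)) {
      terms <- resolve_class_terms(classes[g])
      terms <- intersect(terms, colnames(X))
      betas[g, terms] <- sign_g[g] * effect_size
    }
    log_mu <- base_g + betas %*% t(X)
    if (!is.null(extra_offset)) log_mu <- log_mu + extra_offset
    counts <- matrix(
      rnbinom_mu(length(log_mu), mu = exp(log_mu),
                 dispersion = rep(phi, times = ncol(log_mu))),
      nrow = n_genes,
      dimnames = list(sprintf("gene_%05d", seq_len(n_genes)), sample_ids)
    )
    true_class <- apply(betas != 0, 1, function(nz) {
      class_label(colnames(X)[nz])
    })
    truth <- tibble::tibble(
      gene_id = rownames(counts),
      true_class = true_class,
      baseline_log_mean = base_g,
      dispersion = phi,
      direction = ifelse(true_class == "null", NA_character_,
                         ifelse(sign_g > 0, "induced", "repressed"))
    )
    for (term in colnames(X)) truth[[paste0("beta_", term)]] <- betas[, term]
    list(counts = counts, truth = truth)
  })
}

#' Simulate per-sample phenotypes driven by the dose predictors
#'
#' Shoot biomass follows `log2(biomass) = intercept + coefficients on the
#' standardized predictors + Gaussian noise`, with the N-by-W column being
#' the raw product of the standardized main effects so a pure interaction
#' coefficient produces a multiplicative N-by-W effect on biomass. Leaf
#' N-content rises monotonically with the N dose and delta-13C falls
#' monotonically with the water volume (drought enriches 13C), mirroring
#' the qualitative trends of the assays they stand in for.
#'
#' @param design a treatment design tibble.
#' @param coef named vector over `intercept`, `N`, `W`, `NdivW`, `NxW`
#'   (missing entries default to 0) on the log2 biomass scale.
#' @param noise_sd standard deviation of the Gaussian noise on log2 biomass.
#' @param seed integer seed.
#' @return A phenotype tibble: `sample_id`, `shoot_biomass` (g),
#'   `n_content` (fraction of dry weight), `wue_delta13c` (per mil).
#' @export
simulate_phenotypes <- function(design,
                                coef = c(intercept = 1, NxW = 0.5),
                                noise_sd = 0.1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  full <- c(intercept = 0, N = 0, W = 0, NdivW = 0, NxW = 0)
  bad <- setdiff(names(coef), names(full))
  if (length(bad)) {
    stop("unknown coefficient names: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full[names(coef)] <- coef
  n <- nrow(design)
  ndivw <- if ("ndivw_std" %in% names(design)) design$ndivw_std else rep(0, n)
  lp <- full["intercept"] +
    full["N"] * design$n_std +
    full["W"] * design$w_std +
    full["NdivW"] * ndivw +
    full["NxW"] * design$n_std * design$w_std
  with_seed(seed, {
    log2_biomass <- lp + stats::rnorm(n, 0, noise_sd)
    n_content <- 0.02 + 0.01 * stats::plogis(design$n_std) +
      stats::rnorm(n, 0, noise_sd * 0.002)
    delta13c <- -28 - 1.5 * design$w_std + stats::rnorm(n, 0, noise_sd)
    tibble::tibble(
      sample_id = design$sample_id,
      shoot_biomass = 2^log2_biomass,
      n_content = n_content,
      wue_delta13c = delta13c
    )
  })
}

#' Simulate a paired treated/control N-dose time course
#'
#' Responder genes shift their log-mean by `log(fold)` (up or down, 50/50
#' unless directions are supplied) in the treated arm only, from their
#' onset time onward; the control arm is stationary. Nitrogen uptake
#' follows a saturating curve `uptake_max * (1 - exp(-t / tau))`.
#'
#' @param times time grid in minutes; must include 0. Defaults to the
#'   10-point grid 0, 5, 10, 15, 20, 30, 45, 60, 90, 120.
#' @param n_genes total genes; `n_responders` of them respond.
#' @param n_responders number of responder genes (first by shuffled id).
#' @param replicates biological replicates per arm and timepoint.
#' @param onset_minutes per-responder onset times; defaults to sampling
#'   from the grid between 5 and 30 minutes, the window in which rapid
#'   N-dose responses concentrate.
#' @param fold multiplicative expression shift in the treated arm.
#' @param dispersion NB dispersion phi.
#' @param baseline_log_mean_range uniform range of baseline log expression.
#' @param uptake_max,tau saturating-uptake parameters (tau in minutes).
#' @param directions optional vector `"up"`/`"down"` per responder.
#' @param seed integer seed.
#'
#' @return A list: `treated` and `control` count matrices (columns
#'   `t<min>_r<rep>`), `col_times` (time of each column), `times`, `truth`
#'   (gene_id, responder, onset, direction, fold), and `uptake` (tibble of
#'   time and uptake).
#' @export
simulate_timecourse <- function(times = c(0, 5, 10, 15, 20, 30, 45, 60, 90,
                                          120),
                                n_genes = 1000, n_responders = 100,
                                replicates = 3, onset_minutes = NULL,
                                fold = 4, dispersion = 0.05,
                                baseline_log_mean_range = log(c(50, 500)),
                                uptake_max = 1, tau = 30,
                                directions = NULL, seed = 1L) {
  if (!0 %in% times) stop("time grid must include 0", call. = FALSE)
  if (is.unsorted(times)) times <- sort(times)
  if (n_responders > n_genes) {
    stop("n_responders cannot exceed n_genes", call. = FALSE)
  }
  if (!is.null(onset_minutes) &&
      (any(onset_minutes <= 0) || any(onset_minutes > max(times)))) {
    stop("onset times must lie in (0, max(times)]", call. = FALSE)
  }
  col_times <- rep(times, each = replicates)
  sample_ids <- sprintf("t%g_r%d", col_times,
                        rep(seq_len(replicates), times = length(times)))
  n_cols <- length(sample_ids)
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))

  with_seed(seed, {
    responder <- rep(FALSE, n_genes)
    responder[sample(n_genes, n_responders)] <- TRUE
    onset <- rep(NA_real_, n_genes)
    dirn <- rep(NA_character_, n_genes)
    idx <- which(responder)
    if (length(idx)) {
      pool <- times[times >= 5 & times <= 30]
      if (!length(pool)) pool <- times[times > 0]
      onset[idx] <- if (is.null(onset_minutes)) {
        sample(pool, length(idx), replace = TRUE)
      } else rep_len(onset_minutes, length(idx))
      dirn[idx] <- if (is.null(directions)) {
        sample(rep_len(c("up", "down"), length(idx)))  # balanced 50/50
      } else rep_len(directions, length(idx))
    }
    base_g <- stats::runif(n_genes, baseline_log_mean_range[1],
                           baseline_log_mean_range[2])
    shift <- matrix(0, n_genes, n_cols)
    for (g in idx) {
      on <- col_times >= onset[g]
      shift[g, on] <- if (dirn[g] == "up") log(fold) else -log(fold)
    }
    mu_ctrl <- exp(matrix(base_g, n_genes, n_cols))
    mu_trt <- exp(matrix(base_g, n_genes, n_cols) + shift)
    control <- matrix(rnbinom_mu(length(mu_ctrl), mu_ctrl, dispersion),
                      n_genes, dimnames = list(gene_ids, sample_ids))
    treated <- matrix(rnbinom_mu(length(mu_trt), mu_trt, dispersion),
                      n_genes, dimnames = list(gene_ids, sample_ids))
    list(
      treated = treated, control = control,
      col_times = col_times, times = times,
      truth = tibble::tibble(gene_id = gene_ids, responder = responder,
                             onset = onset, direction = dirn, fold = fold),
      uptake = tibble::tibble(time = times,
                              uptake = uptake_max * (1 - exp(-times / tau)))
    )
  })
}

#' Simulate a field 2-by-2 count matrix across cultivars
#'
#' Effects act on 0/1 indicators of high N and replete W. N-by-W synergy
#' genes carry a positive interaction coefficient (expression driven by
#' high-N/high-W or low-N/low-W), N-molarity genes a negative one, matching
#' how the field analysis distinguishes the two from the interaction sign.
#' Per-cultivar, per-gene Gaussian offsets model genotype effects that the
#' genotype covariate must absorb.
#'
#' @param design a field design from [build_field_design()].
#' @param n_genes number of genes.
#' @param class_proportions named over `N`, `W`, `NxW`, `NdivW`, `null`.
#' @param genotype_sd sd of per-cultivar log-scale offsets.
#' @param effect_size absolute log-scale effect.
#' @param dispersion NB dispersion phi.
#' @param baseline_log_mean_range uniform range of baseline log expression.
#' @param seed integer seed.
#' @return A list with `counts` and `truth` (as in [simulate_lab_counts()],
#'   with betas on the 0/1 indicator coding and `beta_NxW` holding the
#'   interaction coefficient).
#' @export
simulate_field_counts <- function(design, n_genes,
                                  class_proportions = c(
                                    N = 0.1, W = 0.1, NxW = 0.1,
                                    NdivW = 0.1, null = 0.6
                                  ),
                                  genotype_sd = 0.3, effect_size = 1,
                                  dispersion = 0.05,
                                  baseline_log_mean_range = log(c(50, 500)),
                                  seed = 1L) {
  if (!"cultivar" %in% names(design)) {
    stop("field design must carry a cultivar column", call. = FALSE)
  }
  if (n_genes <= 0) stop("n_genes must be positive", call. = FALSE)
  classes <- allocate_classes(n_genes, class_proportions)
  xN <- as.numeric(design$n_level == max(design$n_level))
  xW <- as.numeric(design$w_level == max(design$w_level))
  cultivars <- unique(design$cultivar)
  cv_idx <- match(design$cultivar, cultivars)
  phi <- rep_len(dispersion, n_genes)
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))

  with_seed(seed, {
    classes <- sample(classes)
    sign_g <- rep(1, n_genes)
    for (cls in unique(classes)) {
      idx <- which(classes == cls)
      sign_g[idx] <- sample(rep_len(c(1, -1), length(idx)))
    }
    base_g <- stats::runif(n_genes, baseline_log_mean_range[1],
                           baseline_log_mean_range[2])
    bN <- bW <- bI <- numeric(n_genes)
    bN[classes == "N"] <- (sign_g * effect_size)[classes == "N"]
    bW[classes == "W"] <- (sign_g * effect_size)[classes == "W"]
    bI[classes == "NxW"] <- effect_size
    bI[classes == "NdivW"] <- -effect_size
    if (effect_size == 0) classes <- rep("null", n_genes)
    offsets <- matrix(stats::rnorm(n_genes * length(cultivars),
                                   0, genotype_sd),
                      n_genes, length(cultivars))
    log_mu <- base_g +
      outer(bN, xN) + outer(bW, xW) + outer(bI, xN * xW) +
      offsets[, cv_idx, drop = FALSE]
    counts <- matrix(
      rnbinom_mu(length(log_mu), exp(log_mu),
                 rep(phi, times = ncol(log_mu))),
      n_genes, dimnames = list(gene_ids, design$sample_id)
    )
    # direction = sign of the high-N/high-W vs low-N/low-W contrast
    hh_ll <- bN + bW + bI
    direction <- ifelse(classes == "null", NA_character_,
                        ifelse(hh_ll > 0, "induced",
                               ifelse(hh_ll < 0, "repressed",
                                      NA_character_)))
    truth <- tibble::tibble(
      gene_id = gene_ids, true_class = classes,
      beta_N = bN, beta_W = bW, beta_NxW = bI,
      baseline_log_mean = base_g, dispersion = phi,
      direction = direction
    )
    list(counts = counts, truth = truth)
  })
}
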