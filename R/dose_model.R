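#' Median-of-ratios size factors
#'
#' Per-sample normalization scalars correcting for sequencing depth: for
#' each sample, the median over genes (restricted to genes with all-positive
#' counts, i.e. a positive geometric mean) of the ratio of the sample's
#' count to the gene's geometric mean across samples.
#'
#' @param counts integer count matrix, genes as rows.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  all_zero <- colSums(counts) == 0
  if (any(all_zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[all_zero], collapse = ", "), call. = FALSE)
  }
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) {
    stop("no gene has positive counts in every sample; ",
         "size factors are undefined", call. = FALSE)
  }
  sub <- counts[usable, , drop = FALSE]
  geomean <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geomean, 2, stats::median)
  names(sf) <- colnames(counts)
  sf
}

#' Enumerate the simplified model forms
#'
#' All non-empty proper subsets of the four dose-model terms, ordered by
#' size (largest first) then lexicographically; with four terms this yields
#' the 14 simplified forms a gene can be binned into (the full model and
#' "unclassified" are handled separately).
#'
#' @return A list of character vectors of term names.
#' @export
enumerate_model_forms <- function() {
  terms <- nw_terms()
  k <- length(terms)
  forms <- list()
  for (size in seq(k - 1, 1)) {
    combos <- utils::combn(terms, size, simplify = FALSE)
    labels <- vapply(combos, paste, character(1), collapse = "+")
    forms <- c(forms, combos[order(labels)])
  }
  forms
}

# Fit one NB GLM: counts ~ given predictor columns with log size-factor
# offset. ML dispersion via glm.nb; when theta estimation fails, falls back
# to a fixed-theta fit at a method-of-moments dispersion estimate.
fit_nb_gene <- function(y, X, terms, log_sf) {
  df <- as.data.frame(X[, terms, drop = FALSE])
  names(df) <- terms
  df$y <- y
  df$.log_sf <- log_sf
  form <- stats::as.formula(
    paste("y ~", paste(c("1", terms, "offset(.log_sf)"), collapse = " + "))
  )
  fit <- tryCatch(
    suppressWarnings(
      MASS::glm.nb(form, data = df,
                   control = stats::glm.control(maxit = 50))
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    mu0 <- mean(y / exp(log_sf))
    v0 <- stats::var(y / exp(log_sf))
    phi_mom <- max((v0 - mu0) / max(mu0^2, 1e-8), 1e-8)
    fit <- tryCatch(
      suppressWarnings(
        stats::glm(form, data = df,
                   family = MASS::negative.binomial(theta = 1 / phi_mom),
                   control = stats::glm.control(maxit = 50))
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    fit$theta <- 1 / phi_mom
  }
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  want <- terms
  beta <- stats::setNames(rep(NA_real_, length(want)), want)
  pval <- stats::setNames(rep(NA_real_, length(want)), want)
  present <- intersect(want, rownames(co))
  beta[present] <- co[present, "Estimate"]
  # Wald statistics referenced against t(n - p): the ML dispersion is
  # estimated from the same few dozen samples, so the normal reference is
  # anti-conservative in small samples
  df_resid <- length(y) - nrow(co)
  zval <- co[present, "Estimate"] / co[present, "Std. Error"]
  pval[present] <- 2 * stats::pt(-abs(zval), df = max(df_resid, 1))
  if (anyNA(beta) || anyNA(pval)) return(NULL)
  list(
    alpha = co["(Intercept)", "Estimate"],
    beta = beta, p = pval,
    dispersion = max(1 / fit$theta, 1e-8),
    converged = isTRUE(fit$converged)
  )
}

#' Fit the full four-term NB dose model to every gene
#'
#' Per gene, a negative-binomial log-link GLM of counts on the four
#' standardized dose predictors (N, W, N/W, N-by-W) with a log size-factor
#' offset; per-term Wald p-values; Benjamini-Hochberg adjustment per term
#' across genes. Non-converging genes are flagged, never dropped silently.
#'
#' @param counts filtered count matrix (see [filter_low_counts()]).
#' @param design standardized lab design.
#' @param config an [nw_config()].
#' @return A tibble with one row per gene: `gene_id`, `alpha`, `beta_*`,
#'   `p_*`, `padj_*` for each term, `dispersion`, `converged`.
#' @export
fit_full_model <- function(counts, design, config = nw_config()) {
  check_counts_design(counts, design)
  counts <- counts[, design$sample_id, drop = FALSE]
  X <- as.matrix(design[, nw_term_columns()])
  colnames(X) <- nw_terms()
  log_sf <- log(size_factors(counts))
  terms <- nw_terms()

  rows <- lapply(seq_len(nrow(counts)), function(g) {
    fit <- fit_nb_gene(counts[g, ], X, terms, log_sf)
    if (is.null(fit)) {
      return(c(alpha = NA_real_,
               stats::setNames(rep(NA_real_, 4), paste0("beta_", terms)),
               stats::setNames(rep(NA_real_, 4), paste0("p_", terms)),
               dispersion = NA_real_, converged = 0))
    }
    c(alpha = fit$alpha,
      stats::setNames(fit$beta, paste0("beta_", terms)),
      stats::setNames(fit$p, paste0("p_", terms)),
      dispersion = fit$dispersion, converged = as.numeric(fit$converged))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- tibble::add_column(out, gene_id = rownames(counts), .before = 1)
  for (term in terms) {
    out[[paste0("padj_", term)]] <-
      stats::p.adjust(out[[paste0("p_", term)]], method = "BH")
  }
  out$converged <- out$converged == 1
  out
}

#' Classify genes by backward model simplification
#'
#' The central procedure: each gene starts at the full four-term NB model.
#' At each stage, per-term BH-adjusted p-values are computed across all
#' genes currently carrying that term; a gene whose every current term
#' passes `model_alpha` is accepted at its current model form; otherwise
#' its least significant term (largest adjusted p; ties broken by dropping
#' the later term in the order N, W, N/W, N-by-W) is removed and the gene
#' is refit. Genes failing even every one-term model are "unclassified"
#' and excluded downstream.
#'
#' @param counts filtered count matrix.
#' @param design standardized lab design.
#' @param config an [nw_config()].
#' @return A tibble per gene: `gene_id`, `model_class` (a `+`-joined term
#'   subset, `"full"`, or `"unclassified"`), accepted-stage coefficients
#'   `beta_*`, adjusted p-values `padj_*` (NA for terms absent from the
#'   accepted model), `dispersion`, `direction` (sign of the largest
#'   accepted coefficient), `n_weight` / `ndivw_weight` for genes whose
#'   class is within \{N, N/W\}, and `trace` (list-column of per-stage
#'   diagnostics).
#' @export
classify_genes <- function(counts, design, config = nw_config()) {
  check_counts_design(counts, design)
  counts <- counts[, design$sample_id, drop = FALSE]
  X <- as.matrix(design[, nw_term_columns()])
  colnames(X) <- nw_terms()
  log_sf <- log(size_factors(counts))
  terms_all <- nw_terms()
  n_genes <- nrow(counts)
  gene_ids <- rownames(counts)

  current_terms <- rep(list(terms_all), n_genes)
  active <- rep(TRUE, n_genes)
  result <- vector("list", n_genes)
  trace <- rep(list(list()), n_genes)

  for (stage in seq(length(terms_all), 1)) {
    idx <- which(active & lengths(current_terms) == stage)
    if (!length(idx)) next
    fits <- lapply(idx, function(g) {
      fit_nb_gene(counts[g, ], X, current_terms[[g]], log_sf)
    })
    failed <- vapply(fits, is.null, logical(1))
    for (j in which(failed)) {
      g <- idx[j]
      result[[g]] <- list(class = "unclassified", fit = NULL,
                          note = "fit failure")
      active[g] <- FALSE
    }
    idx <- idx[!failed]
    fits <- fits[!failed]
    if (!length(idx)) next

    # BH per term across the genes whose current model carries that term
    padj <- matrix(NA_real_, length(idx), length(terms_all),
                   dimnames = list(NULL, terms_all))
    for (term in terms_all) {
      has <- vapply(seq_along(idx), function(j) {
        term %in% current_terms[[idx[j]]]
      }, logical(1))
      if (!any(has)) next
      raw <- vapply(fits[has], function(f) f$p[[term]], numeric(1))
      padj[has, term] <- stats::p.adjust(raw, method = "BH")
    }

    for (j in seq_along(idx)) {
      g <- idx[j]
      terms_g <- current_terms[[g]]
      padj_g <- padj[j, terms_g]
      trace[[g]] <- c(trace[[g]], list(list(
        stage = stage, terms = terms_g, padj = padj_g
      )))
      if (all(padj_g < config$model_alpha)) {
        result[[g]] <- list(class = class_label_or_full(terms_g),
                            fit = fits[[j]], padj = padj_g)
        active[g] <- FALSE
      } else if (stage == 1) {
        result[[g]] <- list(class = "unclassified", fit = fits[[j]],
                            note = "no model form accepted")
        active[g] <- FALSE
      } else {
        worst <- max(padj_g)
        cand <- terms_g[padj_g == worst]
        # tie-break: drop the later term in the canonical order
        drop_term <- cand[which.max(match(cand, terms_all))]
        current_terms[[g]] <- setdiff(terms_g, drop_term)
      }
    }
  }

  out <- tibble::tibble(
    gene_id = gene_ids,
    model_class = vapply(result, function(r) r$class, character(1)),
    dispersion = vapply(result, function(r) {
      if (is.null(r$fit)) NA_real_ else r$fit$dispersion
    }, numeric(1))
  )
  for (term in terms_all) {
    out[[paste0("beta_", term)]] <- vapply(result, function(r) {
      if (is.null(r$fit) || !term %in% names(r$fit$beta)) NA_real_
      else r$fit$beta[[term]]
    }, numeric(1))
    out[[paste0("padj_", term)]] <- vapply(result, function(r) {
      if (is.null(r$padj) || !term %in% names(r$padj)) NA_real_
      else r$padj[[term]]
    }, numeric(1))
  }
  out$direction <- vapply(seq_len(n_genes), function(g) {
    r <- result[[g]]
    if (is.null(r$fit) || r$class == "unclassified") return(NA_character_)
    b <- r$fit$beta
    lead <- b[which.max(abs(b))]
    if (lead > 0) "induced" else "repressed"
  }, character(1))

  w <- t(vapply(seq_len(n_genes), function(g) {
    r <- result[[g]]
    cls <- r$class
    if (cls %in% c("N", "NdivW", "N+NdivW")) {
      unlist(compute_nw_weights(r$fit$beta, cls))
    } else c(n_weight = NA_real_, ndivw_weight = NA_real_)
  }, c(n_weight = 0, ndivw_weight = 0)))
  out$n_weight <- w[, "n_weight"]
  out$ndivw_weight <- w[, "ndivw_weight"]
  out$trace <- trace
  out
}

class_label_or_full <- function(terms) {
  if (length(terms) == length(nw_terms())) "full" else class_label(terms)
}

#' N-moles vs N-molarity weight statistic
#'
#' For genes explained by N, N/W, or both, the relative weight of the
#' N-moles coefficient: `100 * |beta_N| / (|beta_N| + |beta_NdivW|)`, with
#' an absent term contributing 0. A gene fit by the N model alone has an N
#' weight of 100% and an N/W weight of 0%. Coefficients are on standardized
#' predictors, which makes their magnitudes comparable; absolute values
#' give repressed genes well-defined weights.
#'
#' @param betas named numeric vector of accepted-model coefficients
#'   (containing `N` and/or `NdivW`).
#' @param model_class the accepted class; must be one of `"N"`, `"NdivW"`,
#'   `"N+NdivW"`.
#' @return A list with `n_weight` and `ndivw_weight` (percentages summing
#'   to 100).
#' @export
compute_nw_weights <- function(betas, model_class) {
  if (!model_class %in% c("N", "NdivW", "N+NdivW")) {
    stop("weights are defined only for classes N, NdivW, N+NdivW; got '",
         model_class, "'", call. = FALSE)
  }
  bn <- if ("N" %in% names(betas) && model_class != "NdivW")
    abs(betas[["N"]]) else 0
  bd <- if ("NdivW" %in% names(betas) && model_class != "N")
    abs(betas[["NdivW"]]) else 0
  nw <- 100 * bn / (bn + bd)
  list(n_weight = nw, ndivw_weight = 100 - nw)
}
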