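#' Field-side gene classification with a genotype covariate
#'
#' Per gene, a negative-binomial GLM of counts on categorical N dose,
#' categorical W regime, their interaction and a genotype (cultivar)
#' covariate, with a log size-factor offset. Term significance is assessed
#' by analysis of deviance against nested models at the full model's
#' dispersion (N and W are tested within the additive model, the
#' interaction against the full model), with the deviance difference
#' referenced against an F distribution scaled by the full model's
#' residual deviance — calibrated when the dispersion is estimated from
#' the same samples. BH adjustment is per term across genes. Genotype
#' controls cultivar effects and is never tested or used to subset.
#'
#' @param counts filtered count matrix.
#' @param field_design design from [build_field_design()] (must carry
#'   cultivars).
#' @param config an [nw_config()].
#' @param extra_log_offset optional per-sample vector added to the model's
#'   log offset, e.g. known per-cultivar expression shifts; because genotype
#'   is a covariate, any per-cultivar offset is absorbed and leaves the
#'   N/W/N-by-W inference unchanged.
#' @return A tibble per gene: `gene_id`, raw and BH-adjusted p for `N`,
#'   `W`, `NxW` terms, `log2fc_interaction` (interaction coefficient in
#'   log2 units), `direction` (`induced`/`repressed` by the
#'   high-N,high-W vs low-N,low-W normalized-mean contrast), `converged`.
#' @export
fit_field_model <- function(counts, field_design, config = nw_config(),
                            extra_log_offset = NULL) {
  if (!"cultivar" %in% names(field_design)) {
    stop("field design must carry a cultivar column", call. = FALSE)
  }
  check_counts_design(counts, field_design)
  counts <- counts[, field_design$sample_id, drop = FALSE]
  fN <- factor(field_design$n_level == max(field_design$n_level),
               levels = c(FALSE, TRUE), labels = c("low", "high"))
  fW <- factor(field_design$w_level == max(field_design$w_level),
               levels = c(FALSE, TRUE), labels = c("deplete", "replete"))
  geno <- factor(field_design$cultivar)
  log_sf <- log(size_factors(counts))
  if (!is.null(extra_log_offset)) {
    if (length(extra_log_offset) != ncol(counts)) {
      stop("extra_log_offset must have one value per sample", call. = FALSE)
    }
    log_sf <- log_sf + extra_log_offset
  }
  hh <- fN == "high" & fW == "replete"
  ll <- fN == "low" & fW == "deplete"
  norm <- sweep(counts, 2, exp(log_sf), "/")

  rows <- lapply(seq_len(nrow(counts)), function(g) {
    fit_field_gene(counts[g, ], fN, fW, geno, log_sf)
  })
  ok <- !vapply(rows, is.null, logical(1))
  grab <- function(f) vapply(seq_along(rows), function(i) {
    if (ok[i]) rows[[i]][[f]] else NA_real_
  }, numeric(1))

  out <- tibble::tibble(
    gene_id = rownames(counts),
    p_N = grab("p_N"), p_W = grab("p_W"), p_NxW = grab("p_NxW"),
    log2fc_interaction = grab("log2fc"),
    converged = ok
  )
  for (term in c("N", "W", "NxW")) {
    out[[paste0("padj_", term)]] <-
      stats::p.adjust(out[[paste0("p_", term)]], method = "BH")
  }
  out$direction <- vapply(seq_len(nrow(counts)), function(g) {
    d <- log2(mean(norm[g, hh]) + 1) - log2(mean(norm[g, ll]) + 1)
    if (is.na(d) || d == 0) NA_character_
    else if (d > 0) "induced" else "repressed"
  }, character(1))
  out
}

fit_field_gene <- function(y, fN, fW, geno, log_sf) {
  df <- data.frame(y = y, fN = fN, fW = fW, geno = geno, .log_sf = log_sf)
  full <- tryCatch(
    suppressWarnings(
      MASS::glm.nb(y ~ fN + fW + fN:fW + geno + offset(.log_sf), data = df,
                   control = stats::glm.control(maxit = 50))
    ),
    error = function(e) NULL
  )
  if (is.null(full)) return(NULL)
  theta <- max(full$theta, 1e-8)
  fam <- MASS::negative.binomial(theta = theta)
  refit <- function(form) {
    tryCatch(
      suppressWarnings(
        stats::glm(form, data = df, family = fam,
                   control = stats::glm.control(maxit = 50))
      ),
      error = function(e) NULL
    )
  }
  # deviances must be compared at one dispersion: refit the full model under
  # the fixed-theta family too
  m_full <- refit(y ~ fN + fW + fN:fW + geno + offset(.log_sf))
  m_add <- refit(y ~ fN + fW + geno + offset(.log_sf))
  m_noN <- refit(y ~ fW + geno + offset(.log_sf))
  m_noW <- refit(y ~ fN + geno + offset(.log_sf))
  if (is.null(m_full) || is.null(m_add) || is.null(m_noN) ||
      is.null(m_noW)) {
    return(NULL)
  }
  # deviance F-test: the likelihood-ratio statistic scaled by the full
  # model's residual deviance per df, referenced against F. The plain
  # chi-square reference is anti-conservative here because the dispersion
  # is estimated from the same data (quasi-likelihood-style correction)
  lrt <- function(reduced, larger) {
    dd <- reduced$deviance - larger$deviance
    df_diff <- reduced$df.residual - larger$df.residual
    if (df_diff <= 0 || m_full$df.residual <= 0) return(NA_real_)
    scale <- m_full$deviance / m_full$df.residual
    if (!is.finite(scale) || scale <= 0) return(NA_real_)
    f <- (max(dd, 0) / df_diff) / scale
    stats::pf(f, df_diff, m_full$df.residual, lower.tail = FALSE)
  }
  co <- stats::coef(m_full)
  ix <- grep(":", names(co), fixed = TRUE)
  list(
    p_N = lrt(m_noN, m_add),
    p_W = lrt(m_noW, m_add),
    p_NxW = lrt(m_add, m_full),
    log2fc = unname(co[ix][1]) / log(2)
  )
}

#' Bin field genes into dose-response classes by interaction sign
#'
#' A gene is `N` (resp. `W`) when that term is significant while the other
#' main term and the interaction are not; when the interaction is
#' significant, the sign of its log2 fold change decides: positive (driven
#' by high-N/high-W or low-N/low-W) is the synergistic class `NxW`,
#' negative (high-W/low-N or low-W/high-N) is the N-molarity class `NdivW`.
#' Everything else is `none`.
#'
#' @param results output of [fit_field_model()].
#' @param config an [nw_config()] (uses `assoc_alpha`).
#' @return `results` with a `field_class` column; a significant interaction
#'   with an exactly zero fold change is flagged `tie` (never silently
#'   assigned).
#' @export
bin_field_genes <- function(results, config = nw_config()) {
  a <- config$assoc_alpha
  sigN <- !is.na(results$padj_N) & results$padj_N < a
  sigW <- !is.na(results$padj_W) & results$padj_W < a
  sigI <- !is.na(results$padj_NxW) & results$padj_NxW < a
  fc <- results$log2fc_interaction
  cls <- rep("none", nrow(results))
  cls[sigI & fc > 0] <- "NxW"
  cls[sigI & fc < 0] <- "NdivW"
  cls[sigI & fc == 0] <- "tie"
  cls[sigN & !sigW & !sigI] <- "N"
  cls[sigW & !sigN & !sigI] <- "W"
  results$field_class <- cls
  results
}

#' Lab-field directionally conserved gene sets
#'
#' For each dose-response class, retains the genes assigned to the class in
#' both the laboratory and field analyses with the same regulation
#' direction (induced in both or repressed in both).
#'
#' @param lab_sets tibble with `gene_id`, `class`, `direction`.
#' @param field_sets tibble with the same columns.
#' @return A tibble of conserved `gene_id`, `class`, `direction` rows.
#' @export
conserved_direction <- function(lab_sets, field_sets) {
  need <- c("gene_id", "class", "direction")
  for (nm in list(lab_sets, field_sets)) {
    if (!all(need %in% names(nm))) {
      stop("inputs need columns gene_id, class, direction", call. = FALSE)
    }
  }
  key_lab <- paste(lab_sets$gene_id, lab_sets$class, lab_sets$direction)
  key_fld <- paste(field_sets$gene_id, field_sets$class,
                   field_sets$direction)
  keep <- lab_sets[key_lab %in% key_fld &
                     !is.na(lab_sets$direction), , drop = FALSE]
  tibble::as_tibble(keep)
}

#' Grain yield at standard moisture
#'
#' `yield = grain_weight * ((100 - moisture_content) / 86) / sampling_area`,
#' expressing yield in g per square metre normalized to the 14% moisture
#' reference (100 - 14 = 86).
#'
#' @param grain_weight harvested grain weight (g), >= 0.
#' @param moisture_content grain moisture percentage in \[0, 100\].
#' @param sampling_area harvested area (m^2), > 0.
#' @return Yield in g/m^2 (vectorized).
#' @export
grain_yield <- function(grain_weight, moisture_content, sampling_area) {
  if (any(grain_weight < 0)) {
    stop("grain_weight must be >= 0", call. = FALSE)
  }
  if (any(moisture_content < 0 | moisture_content > 100)) {
    stop("moisture_content must be within [0, 100]", call. = FALSE)
  }
  if (any(sampling_area <= 0)) {
    stop("sampling_area must be > 0", call. = FALSE)
  }
  grain_weight * ((100 - moisture_content) / 86) / sampling_area
}

#' Select the dose-model terms explaining a phenotype
#'
#' Backward elimination on a Gaussian linear model of log2 phenotype
#' against the standardized dose predictors (with a genotype covariate when
#' the design carries cultivars), mirroring the gene-level procedure: BH
#' adjustment across the current terms, accept when all pass `model_alpha`,
#' otherwise drop the worst and refit. For field designs the three-way
#' ANOVA interaction F statistic and p (categorical N-by-W with genotype)
#' are also reported.
#'
#' @param phenotype positive per-sample values aligned with `design` rows.
#' @param design treatment design tibble.
#' @param config an [nw_config()].
#' @return A list: `selected` (character vector of surviving terms, empty
#'   when nothing explains the phenotype), `stats` (tibble of the accepted
#'   stage: term, estimate, p, padj), and for field designs
#'   `interaction_F`, `interaction_p`.
#' @export
select_phenotype_model <- function(phenotype, design,
                                   config = nw_config()) {
  if (length(phenotype) != nrow(design)) {
    stop("phenotype length must match design rows", call. = FALSE)
  }
  if (stats::sd(phenotype) == 0) {
    return(list(selected = character(0),
                stats = tibble::tibble(term = character(0),
                                       estimate = numeric(0),
                                       p = numeric(0), padj = numeric(0))))
  }
  if (any(phenotype <= 0)) {
    stop("phenotype must be positive (log2 is taken internally)",
         call. = FALSE)
  }
  y <- log2(phenotype)
  cols <- nw_term_columns()
  avail <- nw_terms()[cols %in% names(design)]
  has_geno <- "cultivar" %in% names(design)
  Xg <- if (has_geno) {
    stats::model.matrix(~ factor(design$cultivar))[, -1, drop = FALSE]
  } else NULL

  terms <- avail
  accepted <- NULL
  while (length(terms) > 0) {
    X <- as.matrix(design[, cols[terms], drop = FALSE])
    colnames(X) <- terms
    dat <- data.frame(y = y, X, check.names = FALSE)
    form <- stats::as.formula(
      paste("y ~", paste(sprintf("`%s`", terms), collapse = " + "))
    )
    fit <- if (has_geno) {
      dat2 <- cbind(dat, as.data.frame(Xg))
      stats::lm(stats::as.formula(
        paste("y ~", paste(c(sprintf("`%s`", terms),
                             sprintf("`%s`", colnames(Xg))),
                           collapse = " + "))), data = dat2)
    } else {
      stats::lm(form, data = dat)
    }
    sm <- summary(fit)$coefficients
    pv <- sm[terms, "Pr(>|t|)"]
    est <- sm[terms, "Estimate"]
    padj <- stats::p.adjust(pv, method = "BH")
    if (all(padj < config$model_alpha)) {
      accepted <- tibble::tibble(term = terms, estimate = unname(est),
                                 p = unname(pv), padj = unname(padj))
      break
    }
    worst <- max(padj)
    cand <- terms[padj == worst]
    drop_term <- cand[which.max(match(cand, nw_terms()))]
    terms <- setdiff(terms, drop_term)
  }

  out <- list(
    selected = if (is.null(accepted)) character(0) else accepted$term,
    stats = if (is.null(accepted)) {
      tibble::tibble(term = character(0), estimate = numeric(0),
                     p = numeric(0), padj = numeric(0))
    } else accepted
  )
  if (has_geno) {
    fN <- factor(design$n_level)
    fW <- factor(design$w_level)
    av <- stats::anova(stats::lm(y ~ factor(design$cultivar) + fN * fW))
    ix <- grep(":", rownames(av))
    out$interaction_F <- av[ix, "F value"]
    out$interaction_p <- av[ix, "Pr(>F)"]
  }
  out
}
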