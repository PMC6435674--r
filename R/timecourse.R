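#' Spline-based time-course differential expression
#'
#' Fits each gene's log2 normalized expression jointly over the treated and
#' control arms with a cubic-spline time trend (interior knots at the 25/50/
#' 75% time quantiles) and tests whether the two arms share one curve: an
#' F-test of the arm shift plus arm-by-spline terms (5 numerator df with
#' the default 3-knot basis). A gene is differentially expressed when the
#' BH-adjusted p passes `assoc_alpha` and its combined read count across
#' all timepoints and both arms exceeds `timecourse_min_total`.
#'
#' Normalization uses median-of-ratios size factors computed jointly over
#' both arms; expression is `log2(count / size_factor + 1)`. Per-timepoint
#' fold changes are ratios of treated-arm mean normalized counts at time t
#' to the treated-arm mean at t = 0 (with a pseudocount of 1 on both means).
#'
#' @param treated,control count matrices sharing gene ids and column layout.
#' @param col_times time (minutes) of each column.
#' @param config an [nw_config()].
#' @return A tibble per gene: `gene_id`, `p_value`, `padj`, `total_count`,
#'   `de_flag`, plus a `fold_changes` list-column (named per timepoint,
#'   treated arm vs its t = 0 mean).
#' @export
fit_spline_de <- function(treated, control, col_times,
                          config = nw_config()) {
  validate_counts(treated)
  validate_counts(control)
  if (!identical(rownames(treated), rownames(control))) {
    stop("treated and control arms must share gene ids (same order)",
         call. = FALSE)
  }
  if (ncol(treated) != length(col_times) ||
      ncol(control) != length(col_times)) {
    stop("col_times must give one time per column of each arm",
         call. = FALSE)
  }
  times <- sort(unique(col_times))
  if (!0 %in% times) stop("time grid must include 0", call. = FALSE)

  sf <- size_factors(cbind(treated, control))
  n_s <- ncol(treated)
  norm_trt <- sweep(treated, 2, sf[seq_len(n_s)], "/")
  norm_ctl <- sweep(control, 2, sf[n_s + seq_len(n_s)], "/")
  y_all <- log2(cbind(norm_trt, norm_ctl) + 1)

  tt <- c(col_times, col_times)
  arm <- factor(rep(c("treated", "control"), each = n_s),
                levels = c("control", "treated"))
  basis <- spline_basis(tt, times, config$spline_knots)
  X_red <- cbind(1, basis)
  X_full <- cbind(X_red, arm == "treated",
                  basis * as.numeric(arm == "treated"))

  p <- vapply(seq_len(nrow(y_all)), function(g) {
    f_test_nested(y_all[g, ], X_red, X_full)
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  total <- unname(rowSums(treated) + rowSums(control))
  de <- !is.na(padj) & padj < config$assoc_alpha &
    total > config$timecourse_min_total

  t_pos <- times
  fc <- lapply(seq_len(nrow(treated)), function(g) {
    m <- vapply(t_pos, function(t0) {
      mean(norm_trt[g, col_times == t0])
    }, numeric(1))
    out <- (m + 1) / (m[t_pos == 0] + 1)
    names(out) <- as.character(t_pos)
    out
  })

  tibble::tibble(
    gene_id = rownames(treated),
    p_value = p, padj = padj,
    total_count = total, de_flag = de,
    fold_changes = fc
  )
}

# natural cubic spline basis with interior knots at time quantiles
spline_basis <- function(tt, times, n_knots) {
  probs <- seq_len(n_knots) / (n_knots + 1)
  knots <- stats::quantile(times, probs, names = FALSE, type = 7)
  splines::ns(tt, knots = knots, Boundary.knots = range(times))
}

f_test_nested <- function(y, X_red, X_full) {
  fit_red <- stats::lm.fit(X_red, y)
  fit_full <- stats::lm.fit(X_full, y)
  rss_red <- sum(fit_red$residuals^2)
  rss_full <- sum(fit_full$residuals^2)
  df1 <- fit_full$rank - fit_red$rank
  df2 <- length(y) - fit_full$rank
  if (df1 <= 0 || df2 <= 0) return(NA_real_)
  if (rss_full <= 0) return(if (rss_red > rss_full) 0 else NA_real_)
  f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Bin differentially expressed genes into timepoints by fold change
#'
#' A DE gene is "up" at a timepoint when its treated-arm mean normalized
#' expression ratio versus t = 0 strictly exceeds the fold-change threshold
#' and "down" when it is strictly below its reciprocal; a gene may occupy
#' several timepoints. Only t > 0 may be requested.
#'
#' @param results output of [fit_spline_de()] (only `de_flag` genes are
#'   binned).
#' @param config an [nw_config()] (uses `fc_threshold`).
#' @return A tibble: `gene_id`, `time`, `bin` (`"up"`/`"down"`), one row per
#'   gene-timepoint membership.
#' @export
bin_by_timepoint <- function(results, config = nw_config()) {
  de <- results[results$de_flag, , drop = FALSE]
  rows <- list()
  thr <- config$fc_threshold
  for (i in seq_len(nrow(de))) {
    fc <- de$fold_changes[[i]]
    tp <- as.numeric(names(fc))
    if (any(tp == 0)) {
      fc <- fc[tp != 0]
      tp <- tp[tp != 0]
    }
    up <- fc > thr
    down <- fc < 1 / thr
    if (any(up)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = de$gene_id[i], time = tp[up], bin = "up")
    }
    if (any(down)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = de$gene_id[i], time = tp[down], bin = "down")
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(gene_id = character(0), time = numeric(0),
                          bin = character(0)))
  }
  do.call(rbind, rows)
}

#' Correlate per-timepoint DE gene counts with nitrogen uptake
#'
#' Pearson correlation (with two-sided p) between the number of genes
#' differentially expressed at each timepoint and the measured N uptake at
#' that timepoint.
#'
#' @param de_counts integer vector, DE genes per timepoint.
#' @param uptake numeric vector, same length.
#' @return A list with `r` and `p_value`.
#' @export
correlate_uptake <- function(de_counts, uptake) {
  if (length(de_counts) != length(uptake) || length(de_counts) < 3) {
    stop("need >= 3 paired timepoints", call. = FALSE)
  }
  if (stats::sd(de_counts) == 0 || stats::sd(uptake) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(de_counts, uptake, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
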