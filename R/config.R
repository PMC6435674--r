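#' Analysis configuration
#'
#' Bundles the tunable thresholds shared across the pipeline. Defaults follow
#' the study design: a stringent FDR threshold of 0.005 for dose-model terms,
#' 0.05 for correlation/field significance, a total-count pre-filter of 128
#' reads, and 10,000 permutations for Monte-Carlo and eigengene nulls.
#'
#' @param model_alpha FDR threshold a model term must pass during backward
#'   model simplification (default 0.005).
#' @param assoc_alpha FDR threshold for gene-phenotype correlations, field
#'   differential expression and time-course DE (default 0.05).
#' @param min_total_count genes with total read count (summed over all
#'   samples) below this are removed before modelling (default 128).
#' @param min_median_count genes with median read count below this are
#'   removed; the default of 1 removes genes whose median count is zero.
#' @param spline_df degrees of freedom carried by the treatment-difference
#'   part of the time-course model (arm shift plus arm-by-spline terms).
#' @param spline_knots number of interior knots of the cubic spline basis,
#'   placed at time quantiles.
#' @param fc_threshold fold-change threshold for per-timepoint binning
#'   (strict inequality; default 1.25).
#' @param timecourse_min_total minimum combined read count across all
#'   timepoints for a gene to be eligible for time-course DE (default 100,
#'   strict inequality).
#' @param n_perm number of permutations for Monte-Carlo overlap and
#'   eigengene association nulls (default 10000).
#' @param seed integer seed used by stochastic operations.
#'
#' @return A list of class `nw_config`.
#' @export
nw_config <- function(model_alpha = 0.005,
                      assoc_alpha = 0.05,
                      min_total_count = 128,
                      min_median_count = 1,
                      spline_df = 5,
                      spline_knots = 3,
                      fc_threshold = 1.25,
                      timecourse_min_total = 100,
                      n_perm = 10000,
                      seed = 1L) {
  stopifnot(
    is.numeric(model_alpha), length(model_alpha) == 1,
    model_alpha > 0, model_alpha < 1,
    is.numeric(assoc_alpha), length(assoc_alpha) == 1,
    assoc_alpha > 0, assoc_alpha < 1
  )
  ints <- list(
    min_total_count = min_total_count,
    min_median_count = min_median_count,
    spline_df = spline_df, spline_knots = spline_knots,
    timecourse_min_total = timecourse_min_total, n_perm = n_perm
  )
  for (nm in names(ints)) {
    v <- ints[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v != round(v) || v <= 0) {
      stop(sprintf("`%s` must be a positive integer, got %s", nm,
                   paste(v, collapse = ",")), call. = FALSE)
    }
  }
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    stop("`fc_threshold` must exceed 1", call. = FALSE)
  }
  structure(
    list(
      model_alpha = model_alpha,
      assoc_alpha = assoc_alpha,
      min_total_count = as.integer(min_total_count),
      min_median_count = as.integer(min_median_count),
      spline_df = as.integer(spline_df),
      spline_knots = as.integer(spline_knots),
      fc_threshold = fc_threshold,
      timecourse_min_total = as.integer(timecourse_min_total),
      n_perm = as.integer(n_perm),
      seed = as.integer(seed)
    ),
    class = "nw_config"
  )
}

# canonical order of dose-model terms, used everywhere a tie must break
# deterministically and whenever classes are printed
nw_terms <- function() c("N", "W", "NdivW", "NxW")

# design columns carrying the standardized predictors, in nw_terms() order
nw_term_columns <- function() {
  c(N = "n_std", W = "w_std", NdivW = "ndivw_std", NxW = "nxw_std")
}
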