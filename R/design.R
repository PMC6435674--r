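#' Build the laboratory 4-by-4 nitrogen-by-water factorial design
#'
#' Constructs the full factorial treatment design crossing four nitrogen
#' doses with four water volumes. Nitrogen is supplied as a concentration
#' (mM) in a fixed saturating feed volume of 130 mL, so the absolute
#' amount of N in mmol is `concentration * 0.130`. Water volumes are in mL,
#' hence the N-molarity predictor `n_over_w = n_level / w_level` is in
#' mmol/mL = mol/L; predictors enter every model standardized, so the unit
#' convention does not affect any fit.
#'
#' @param n_conc_mM four distinct positive NH4NO3 concentrations (mM);
#'   defaults to the dose series 0.625, 1.25, 2.5, 5.
#' @param w_volumes_mL four distinct positive water volumes (mL); defaults
#'   to 16.25, 32.5, 65, 130.
#' @param replicates number of replicates per condition (>= 1).
#'
#' @return A tibble with one row per sample: `sample_id`, `n_level` (mmol N),
#'   `w_level` (mL), `n_over_w`, `n_times_w` (product of the standardized
#'   main-effect columns), `replicate`, and standardized predictor columns
#'   `n_std`, `w_std`, `ndivw_std`, `nxw_std` (mean 0, unit variance).
#' @export
#'
#' @examples
#' d <- build_lab_design()
#' nrow(d) # 48 samples: 16 conditions in triplicate
build_lab_design <- function(n_conc_mM = c(0.625, 1.25, 2.5, 5),
                             w_volumes_mL = c(16.25, 32.5, 65, 130),
                             replicates = 3L) {
  check_levels(n_conc_mM, 4L, "n_conc_mM")
  check_levels(w_volumes_mL, 4L, "w_volumes_mL")
  if (!is.numeric(replicates) || length(replicates) != 1 || replicates < 1 ||
      replicates != round(replicates)) {
    stop("`replicates` must be a single integer >= 1", call. = FALSE)
  }
  replicates <- as.integer(replicates)

  grid <- expand.grid(
    replicate = seq_len(replicates),
    w_conc = w_volumes_mL,
    n_conc = n_conc_mM,
    KEEP.OUT.ATTRS = FALSE
  )
  n_level <- grid$n_conc * 0.130  # mmol N in the 130 mL saturating feed
  w_level <- grid$w_conc
  d <- tibble::tibble(
    sample_id = sprintf("N%g_W%g_r%d", grid$n_conc, grid$w_conc,
                        grid$replicate),
    n_level = n_level,
    w_level = w_level,
    n_over_w = n_level / w_level,
    replicate = as.integer(grid$replicate)
  )
  standardize_design(d)
}

#' Build the field 2-by-2 nitrogen-by-water design across cultivars
#'
#' Field trials cross two nitrogen fertilizer doses (0 vs 150 kg/ha) with
#' two categorical water regimes (0 = deplete/drought, 1 = replete) for a
#' panel of cultivars. Unlike the lab design there is no meaningful
#' N-molarity predictor; N-molarity-type responses are identified from the
#' sign of the N-by-W interaction instead, so `n_over_w` is `NA`.
#'
#' @param cultivars character vector of distinct cultivar names (>= 1).
#' @param replicates replicates per cultivar-by-condition cell (>= 1).
#' @param n_doses two fertilizer doses in kg/ha, default `c(0, 150)`.
#'
#' @return A tibble with columns `sample_id`, `cultivar`, `n_level` (kg/ha),
#'   `w_level` (0/1), `n_over_w` (NA), `n_times_w`, `replicate`, and the
#'   standardized predictor columns `n_std`, `w_std`, `nxw_std`.
#' @export
#'
#' @examples
#' d <- build_field_design(paste0("cv", 1:19))
#' nrow(d) # 19 cultivars x 2 N x 2 W x 3 replicates = 228
build_field_design <- function(cultivars, replicates = 3L,
                               n_doses = c(0, 150)) {
  if (length(cultivars) < 1) stop("need at least one cultivar", call. = FALSE)
  if (anyDuplicated(cultivars)) {
    stop("duplicate cultivar names: ",
         paste(unique(cultivars[duplicated(cultivars)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(n_doses) != 2 || n_doses[1] == n_doses[2]) {
    stop("`n_doses` must be two distinct fertilizer doses", call. = FALSE)
  }
  if (!is.numeric(replicates) || length(replicates) != 1 || replicates < 1 ||
      replicates != round(replicates)) {
    stop("`replicates` must be a single integer >= 1", call. = FALSE)
  }
  replicates <- as.integer(replicates)

  grid <- expand.grid(
    replicate = seq_len(replicates),
    w_level = c(0, 1),
    n_level = sort(n_doses),
    cultivar = as.character(cultivars),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  d <- tibble::tibble(
    sample_id = sprintf("%s_N%g_W%d_r%d", grid$cultivar, grid$n_level,
                        grid$w_level, grid$replicate),
    cultivar = grid$cultivar,
    n_level = grid$n_level,
    w_level = grid$w_level,
    n_over_w = NA_real_,
    replicate = as.integer(grid$replicate)
  )
  standardize_design(d)
}

#' (Re)compute standardized predictor columns of a treatment design
#'
#' Centers and scales `n_level`, `w_level` and (when defined) `n_over_w` to
#' mean 0 / unit variance, forms the interaction predictor as the product of
#' the standardized main effects, and standardizes that product too. The
#' operation is idempotent: it always recomputes from the raw dose columns.
#'
#' @param design a tibble carrying `n_level`, `w_level` and optionally
#'   `n_over_w`.
#' @return The design with columns `n_times_w`, `n_std`, `w_std`,
#'   `ndivw_std` (lab only) and `nxw_std` refreshed.
#' @export
standardize_design <- function(design) {
  need <- c("sample_id", "n_level", "w_level")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols)) {
    stop("design lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  design$n_std <- standardize(design$n_level)
  design$w_std <- standardize(design$w_level)
  design$n_times_w <- design$n_std * design$w_std
  design$nxw_std <- standardize(design$n_times_w)
  if ("n_over_w" %in% names(design) && !all(is.na(design$n_over_w))) {
    design$ndivw_std <- standardize(design$n_over_w)
  }
  tibble::as_tibble(design)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant predictor", call. = FALSE)
  }
  (x - mean(x)) / s
}

check_levels <- function(x, n, name) {
  if (length(x) != n || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be %d finite positive values", name, n),
         call. = FALSE)
  }
  if (anyDuplicated(x)) {
    stop(sprintf("`%s` contains duplicate levels", name), call. = FALSE)
  }
  invisible(x)
}
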