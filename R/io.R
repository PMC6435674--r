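#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a tab-separated file whose header starts with `gene_id` followed
#' by sample ids; every remaining cell must parse as a non-negative integer.
#' Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @return An integer matrix with gene ids as rownames, sample ids as
#'   colnames.
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty counts file: ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (header[1] != "gene_id") {
    stop("counts header must start with 'gene_id', got '", header[1], "'",
         call. = FALSE)
  }
  ncol_exp <- length(header)
  widths <- lengths(cells)
  bad <- which(widths != ncol_exp)
  if (length(bad)) {
    stop("ragged rows in ", path, " at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  body <- cells[-1]
  gene_ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  raw <- unlist(lapply(body, `[`, -1), use.names = FALSE)
  num <- suppressWarnings(as.numeric(raw))
  bad_cell <- which(is.na(num) | num < 0 | num != round(num))
  if (length(bad_cell)) {
    line_no <- 1 + ((bad_cell[1] - 1) %/% (ncol_exp - 1)) + 1
    stop(sprintf("non-integer or negative count '%s' at line %d of %s",
                 raw[bad_cell[1]], line_no, path), call. = FALSE)
  }
  m <- matrix(as.integer(num), nrow = length(body), ncol = ncol_exp - 1,
              byrow = TRUE, dimnames = list(gene_ids, header[-1]))
  m
}

#' Write a count matrix to TSV
#'
#' @param counts integer matrix, genes as rows.
#' @param path output file path.
#' @export
write_count_matrix <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a treatment design table
#'
#' Designs round-trip through plain TSV. On read, the standardized predictor
#' columns are recomputed from the raw dose columns so a hand-edited design
#' is always internally consistent.
#'
#' @param path file path.
#' @return A design tibble (see [build_lab_design()]).
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "n_level", "w_level", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("design file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  if (is.null(df$n_over_w)) df$n_over_w <- NA_real_
  standardize_design(tibble::as_tibble(df))
}

#' @rdname read_design
#' @param design design tibble to serialize.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a per-sample phenotype table
#'
#' @param path file path.
#' @return A tibble with a `sample_id` column plus numeric trait columns
#'   (e.g. `shoot_biomass`, `n_content`, `wue_delta13c`, `grain_yield`).
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("phenotype file lacks 'sample_id' column", call. = FALSE)
  }
  if ("shoot_biomass" %in% names(df)) {
    bad <- which(!is.na(df$shoot_biomass) & df$shoot_biomass <= 0)
    if (length(bad)) {
      stop("non-positive shoot_biomass at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' @rdname read_phenotypes
#' @param phenotypes phenotype tibble to serialize.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Check that a count matrix and a design describe the same samples
#'
#' @param counts integer count matrix.
#' @param design design tibble.
#' @return Invisibly `TRUE`; errors name any sample present on one side only.
#' @export
check_counts_design <- function(counts, design) {
  validate_counts(counts)
  missing_in_counts <- setdiff(design$sample_id, colnames(counts))
  missing_in_design <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_in_counts) || length(missing_in_design)) {
    stop("sample mismatch between counts and design; ",
         "absent from counts: [",
         paste(missing_in_counts, collapse = ", "),
         "]; absent from design: [",
         paste(missing_in_design, collapse = ", "), "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Remove weakly expressed genes before modelling
#'
#' Retains genes whose total read count across all samples is at least
#' `min_total_count` and whose median count is at least `min_median_count`.
#' The default configuration removes genes totalling fewer than 128 reads or
#' with a median count of zero.
#'
#' @param counts integer count matrix, genes as rows.
#' @param config an [nw_config()] list.
#' @return The filtered matrix, row order preserved. Warns (rather than
#'   errors) when nothing survives.
#' @export
filter_low_counts <- function(counts, config = nw_config()) {
  validate_counts(counts)
  keep <- rowSums(counts) >= config$min_total_count &
    apply(counts, 1, stats::median) >= config$min_median_count
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no genes survive the count filter", call. = FALSE)
  }
  out
}

validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids in counts", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(TRUE)
}
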