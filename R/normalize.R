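#' RPKM: reads per kilobase per million mapped reads
#'
#' `rpkm = r * 1e9 / (R * L)` — the count scaled by transcript length in kb
#' and library depth in millions. Vectorized over all three arguments.
#'
#' @param r Mapped read count(s), non-negative.
#' @param R Total mapped reads in the library, >= 1.
#' @param L CDS length(s) in bp, >= 1.
#' @return Non-negative numeric vector.
#' @examples
#' rpkm(100, 1e6, 1000) # 100
#' @export
rpkm <- function(r, R, L) {
  if (any(R < 1) || any(L < 1)) abort("R and L must be >= 1", class = "duoseq_domain_error")
  if (any(r < 0)) abort("r must be >= 0", class = "duoseq_domain_error")
  r * 1e9 / (R * L)
}

#' TPM: transcripts per million
#'
#' Length-normalized read rates `r_i / L_i` rescaled so the library sums to
#' one million: `tpm_i = 1e6 * (r_i/L_i) / sum_j(r_j/L_j)`. Unlike RPKM, TPM
#' is a composition — it is comparable across libraries of different depth
#' and length distribution, which is why heatmaps are drawn from it.
#'
#' @param counts Non-negative read counts.
#' @param lengths CDS lengths in bp, >= 1, same length as `counts`.
#' @return Numeric vector summing to 1e6, or all zeros (with a warning) when
#'   every count is zero.
#' @export
tpm_vector <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    abort_validation("counts and lengths must have the same length")
  }
  if (any(lengths < 1)) abort("lengths must be >= 1", class = "duoseq_domain_error")
  if (any(counts < 0)) abort("counts must be >= 0", class = "duoseq_domain_error")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) {
    warn("all counts are zero; TPM vector is all zeros")
    return(rep(0, length(counts)))
  }
  1e6 * rate / tot
}

#' Expression index: counts scaled to 100 at the most-read CDS
#'
#' `index_i = 100 * r_i / max_j(r_j)`. A within-library rank-free measure of
#' how close each CDS is to the library's most heavily mapped CDS.
#'
#' @param counts Non-negative read counts with at least one positive entry.
#' @return Numeric vector in \[0, 100\] with maximum exactly 100.
#' @export
expression_index <- function(counts) {
  if (any(counts < 0)) abort("counts must be >= 0", class = "duoseq_domain_error")
  m <- max(counts)
  if (length(counts) == 0 || m == 0) {
    abort("no mapped reads: all counts are zero", class = "duoseq_domain_error")
  }
  100 * counts / m
}

#' Row-wise z-score matrix
#'
#' Standardizes each row (CDS) of an expression matrix to mean 0 and sample
#' standard deviation 1 (`n - 1` denominator, the default of the common R
#' heatmap tools). Rows with zero variance are mapped to all zeros, with a
#' warning, so downstream clustering stays defined.
#'
#' @param values Numeric matrix, CDS in rows, libraries (>= 2) in columns.
#' @return Matrix of the same shape and dimnames.
#' @export
zscore_matrix <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) abort("need >= 2 libraries (columns)", class = "duoseq_domain_error")
  if (any(!is.finite(values))) abort_validation("matrix has non-finite entries")
  mu <- rowMeans(values)
  s <- apply(values, 1, sd)
  flat <- s == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance rows set to 0", sum(flat)))
    s[flat] <- 1
  }
  z <- (values - mu) / s
  z[flat, ] <- 0
  z
}

#' Per-library normalization table
#'
#' Computes RPKM, TPM and the expression index for every CDS in every
#' library of a dataset. RPKM uses each library's `total_mapped` as depth;
#' TPM and the expression index are computed within each library.
#'
#' @param dataset A `duoseq_dataset` from [validate_dataset()].
#' @return A long tibble `(cds_id, library, condition, count, rpkm, tpm,
#'   expression_index)`, ordered by library then `cds_id`.
#' @examples
#' sim <- simulate_dataset(synthetic_config(n_cds = 50, depth_per_library = 1e4, seed = 1))
#' normalize_libraries(sim$dataset)
#' @export
normalize_libraries <- function(dataset) {
  dataset <- validate_dataset(dataset)
  dataset_long(dataset) |>
    dplyr::group_by(.data$library) |>
    dplyr::mutate(
      rpkm = rpkm(.data$count, .data$total_mapped, .data$length_bp),
      tpm = tpm_vector(.data$count, .data$length_bp),
      expression_index = if (max(.data$count) > 0) expression_index(.data$count) else NA_real_
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "cds_id", "library", "condition", "count", "rpkm", "tpm", "expression_index"
    ) |>
    dplyr::arrange(.data$library, .data$cds_id)
}

#' TPM z-score matrix of a dataset
#'
#' Builds the CDS x library TPM matrix and standardizes each row with
#' [zscore_matrix()]; this is the matrix the expression heatmap displays.
#'
#' @inheritParams normalize_libraries
#' @param ids Optional subset of cds_ids (rows); defaults to all.
#' @return Numeric matrix, rows named by `cds_id`, columns by library.
#' @export
tpm_zscore_matrix <- function(dataset, ids = NULL) {
  norm <- normalize_libraries(dataset)
  wide <- tidyr::pivot_wider(
    norm[, c("cds_id", "library", "tpm")],
    names_from = "library", values_from = "tpm"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$cds_id
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, rownames(mat))
    if (length(missing_ids) > 0) {
      abort_validation(sprintf(
        "ids not in dataset: %s", paste(head(missing_ids, 5), collapse = ", ")
      ))
    }
    mat <- mat[ids, , drop = FALSE]
  }
  zscore_matrix(mat)
}

#' Write a normalization table as TSV
#'
#' @param norm A tibble from [normalize_libraries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized_table <- function(norm, path) {
  readr::write_tsv(norm, path)
  invisible(path)
}
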