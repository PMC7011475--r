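#' Pseudocounted normalized read rates
#'
#' The two-library fold statistic used to rank differential expression when
#' each condition has a single deeply sequenced library:
#' \deqn{n_1 = r_1 R_2 / (R_1 (r_2 + 1)), \quad n_2 = r_2 R_1 / (R_2 (r_1 + 1))}
#' where \eqn{r_1, r_2} are the reads mapping to a CDS and \eqn{R_1, R_2}
#' the total mapped reads of each library. One unit is added to the opposing
#' count to avoid division by zero, so `n1` is a depth-normalized ratio of
#' library-1 to (pseudocounted) library-2 expression; `n1 >= 8` reads as "at
#' least eight-fold higher in library 1". Vectorized.
#'
#' @param r1,r2 Per-CDS mapped read counts, non-negative.
#' @param R1,R2 Total mapped reads per library, >= 1.
#' @return A tibble with columns `n1`, `n2`.
#' @examples
#' normalized_read_rate(10, 0, 1e6, 1e6) # n1 = 10, n2 = 0
#' @export
normalized_read_rate <- function(r1, r2, R1, R2) {
  if (any(R1 < 1) || any(R2 < 1)) {
    abort("R1 and R2 must be >= 1", class = "duoseq_domain_error")
  }
  if (any(r1 < 0) || any(r2 < 0)) {
    abort("counts must be >= 0", class = "duoseq_domain_error")
  }
  r1 <- as.numeric(r1); r2 <- as.numeric(r2)
  R1 <- as.numeric(R1); R2 <- as.numeric(R2)
  tibble::tibble(
    n1 = r1 * R2 / (R1 * (r2 + 1)),
    n2 = r2 * R1 / (R2 * (r1 + 1))
  )
}

#' Per-CDS two-library chi-squared test
#'
#' Pearson chi-squared test (1 df, no continuity correction) of the 2x2
#' contingency table contrasting a CDS's reads against all other mapped
#' reads in each library:
#' \tabular{lll}{
#'           \tab CDS reads \tab other reads \cr
#'   library 1 \tab `r1` \tab `R1 - r1` \cr
#'   library 2 \tab `r2` \tab `R2 - r2`
#' }
#' This asks whether the CDS occupies a different fraction of the two
#' libraries than expected under a common proportion. A CDS with
#' `r1 = r2 = 0` returns `(stat = 0, p = 1)` by convention. Vectorized.
#'
#' @inheritParams normalized_read_rate
#' @return A tibble with columns `stat` (chi-squared statistic) and `p`
#'   (upper-tail p-value from the chi-squared distribution with 1 df).
#' @examples
#' chi2_two_library(30, 10, 1e4, 1e4) # stat ~ 10.02, p ~ 1.55e-3
#' @export
chi2_two_library <- function(r1, r2, R1, R2) {
  if (any(R1 < 1) || any(R2 < 1)) {
    abort("R1 and R2 must be >= 1", class = "duoseq_domain_error")
  }
  if (any(r1 < 0) || any(r2 < 0)) {
    abort("counts must be >= 0", class = "duoseq_domain_error")
  }
  if (any(r1 > R1) || any(r2 > R2)) {
    abort_validation("per-CDS count exceeds library total")
  }
  a <- as.numeric(r1); b <- as.numeric(R1) - a
  c_ <- as.numeric(r2); d <- as.numeric(R2) - c_
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(denom == 0, 0, n * (a * d - b * c_)^2 / denom)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  zero <- (a + c_) == 0
  stat[zero] <- 0
  p[zero] <- 1
  tibble::tibble(stat = stat, p = p)
}

check_pvalues <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
}

#' Bonferroni family-wise error correction
#'
#' `p_adj_i = min(1, m * p_i)` for `m` tests; a thin, validated wrapper
#' around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bonferroni <- function(p_values) {
  check_pvalues(p_values)
  p.adjust(p_values, method = "bonferroni")
}

#' Benjamini-Hochberg step-up FDR
#'
#' Step-up q-values: on ascending-sorted p, `q_(i) = min_{j >= i} min(1,
#' m p_(j) / j)`, mapped back to input order; a validated wrapper around
#' [stats::p.adjust()].
#'
#' @inheritParams bonferroni
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  check_pvalues(p_values)
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed coding sequences between two libraries
#'
#' For every CDS, computes the pseudocounted normalized read rates
#' ([normalized_read_rate()]), the per-CDS 2x2 chi-squared test
#' ([chi2_two_library()]), Bonferroni and BH-adjusted p-values over the
#' whole catalog, and a DEG call: `lib1_up` when `n1 >= fold_threshold` and
#' the chosen corrected p-value is `<= alpha`; `lib2_up` symmetrically;
#' `none` otherwise. Defaults follow the study design: at least eight-fold
#' and Bonferroni-corrected p <= 0.05.
#'
#' @param dataset A `duoseq_dataset`.
#' @param lib1,lib2 Names of the two libraries to compare (e.g. the virgin
#'   and inseminated spermatheca libraries).
#' @param alpha Significance level on the corrected p-value (default 0.05).
#' @param fold_threshold Minimum normalized read rate (default 8).
#' @param correction Which corrected p-value gates the call:
#'   `"bonferroni"` (default) or `"bh"`.
#' @return A tibble of class `duoseq_de` with columns `cds_id, r1, r2, n1,
#'   n2, chi2, p, p_bonferroni, q_bh, deg_call`, sorted by `q_bh` then
#'   `cds_id`. Attributes record the library names and thresholds.
#' @examples
#' sim <- simulate_dataset(synthetic_config(n_cds = 200, depth_per_library = 2e5, seed = 1))
#' de <- call_degs(sim$dataset, "virgin", "inseminated")
#' dplyr::count(de, deg_call)
#' @export
call_degs <- function(dataset, lib1, lib2, alpha = 0.05, fold_threshold = 8,
                      correction = c("bonferroni", "bh")) {
  dataset <- validate_dataset(dataset)
  correction <- match.arg(correction)
  if (alpha < 0 || fold_threshold <= 0) {
    abort_validation("alpha must be >= 0 and fold_threshold > 0")
  }
  l1 <- library_counts(dataset, lib1)
  l2 <- library_counts(dataset, lib2)
  rates <- normalized_read_rate(l1$counts, l2$counts, l1$total, l2$total)
  test <- chi2_two_library(l1$counts, l2$counts, l1$total, l2$total)
  res <- tibble::tibble(
    cds_id = dataset$counts$cds_id,
    r1 = l1$counts, r2 = l2$counts,
    n1 = rates$n1, n2 = rates$n2,
    chi2 = test$stat, p = test$p,
    p_bonferroni = bonferroni(test$p),
    q_bh = bh_fdr(test$p)
  )
  # alpha = 0 disables calling outright (underflowed p-values are still 0)
  p_adj <- if (correction == "bonferroni") res$p_bonferroni else res$q_bh
  p_gate <- if (alpha > 0) p_adj else rep(Inf, nrow(res))
  res$deg_call <- dplyr::case_when(
    res$n1 >= fold_threshold & p_gate <= alpha ~ "lib1_up",
    res$n2 >= fold_threshold & p_gate <= alpha ~ "lib2_up",
    .default = "none"
  )
  res <- dplyr::arrange(res, .data$q_bh, .data$cds_id)
  structure(res,
    class = c("duoseq_de", class(res)),
    lib1 = lib1, lib2 = lib2, alpha = alpha,
    fold_threshold = fold_threshold, correction = correction
  )
}

#' @describeIn call_degs Returns the DE table as a plain tibble (already
#'   tidy; provided for broom-style workflows).
#' @param x A `duoseq_de` table.
#' @param ... Unused.
#' @export
tidy.duoseq_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn call_degs One-row summary: libraries compared, thresholds,
#'   and DEG counts in each direction.
#' @export
glance.duoseq_de <- function(x, ...) {
  tibble::tibble(
    lib1 = attr(x, "lib1"), lib2 = attr(x, "lib2"),
    n_cds = nrow(x),
    n_deg = sum(x$deg_call != "none"),
    n_lib1_up = sum(x$deg_call == "lib1_up"),
    n_lib2_up = sum(x$deg_call == "lib2_up"),
    alpha = attr(x, "alpha"),
    fold_threshold = attr(x, "fold_threshold"),
    correction = attr(x, "correction")
  )
}

#' @describeIn call_degs Fold-significance plot: log2 of the larger
#'   normalized read rate (signed by direction) against -log10 corrected p,
#'   colored by call.
#' @param object A `duoseq_de` table.
#' @export
autoplot.duoseq_de <- function(object, ...) {
  corr <- attr(object, "correction")
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    signed_fold = ifelse(.data$n1 >= .data$n2, log2(.data$n1 + 1e-9), -log2(.data$n2 + 1e-9)),
    p_adj = if (corr == "bonferroni") .data$p_bonferroni else .data$q_bh
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$signed_fold, y = -log10(pmax(.data$p_adj, 1e-300)),
    colour = .data$deg_call
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * log2(attr(object, "fold_threshold")),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "alpha")),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_colour_manual(
      values = c(lib1_up = "#D55E00", lib2_up = "#0072B2", none = "grey70")
    ) +
    ggplot2::labs(
      x = sprintf("signed log2 normalized read rate (%s vs %s)",
                  attr(object, "lib1"), attr(object, "lib2")),
      y = sprintf("-log10 %s-adjusted p", corr),
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' Write a DE table as TSV
#'
#' @param de A `duoseq_de` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(tibble::as_tibble(de), path)
  invisible(path)
}
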