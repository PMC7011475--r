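#' Construct a qPCR Ct table
#'
#' Holds threshold-cycle (Ct) measurements for relative quantification: one
#' row per (gene, sample group, technical replicate), together with the
#' endogenous reference gene (here the ribosomal protein S7 transcript is
#' the usual choice) and the calibrator group all fold changes are anchored
#' to (the virgin-spermathecae control group in this study design).
#'
#' @param records A data frame with columns `gene`, `group`, `replicate`,
#'   `ct` (cycles, finite).
#' @param reference_gene Name of the endogenous reference gene; must be
#'   measured in every group.
#' @param calibrator_group Name of the calibrator group; must be present.
#' @return A tibble of class `duoseq_qpcr` carrying `reference_gene` and
#'   `calibrator_group` as attributes.
#' @export
qpcr_table <- function(records, reference_gene, calibrator_group) {
  records <- tibble::as_tibble(records)
  need <- c("gene", "group", "replicate", "ct")
  if (!all(need %in% names(records))) {
    abort_validation("records need columns gene, group, replicate, ct")
  }
  records <- dplyr::select(records, dplyr::all_of(need))
  if (anyNA(records$ct) || any(!is.finite(records$ct))) {
    abort_validation("all Ct values must be finite")
  }
  groups <- unique(records$group)
  if (!calibrator_group %in% groups) {
    abort_validation(sprintf("calibrator group '%s' not present", calibrator_group))
  }
  if (!reference_gene %in% records$gene) {
    abort_validation(sprintf("reference gene '%s' not present", reference_gene))
  }
  ref_groups <- unique(records$group[records$gene == reference_gene])
  missing_ref <- setdiff(groups, ref_groups)
  if (length(missing_ref) > 0) {
    abort_validation(sprintf(
      "reference gene '%s' missing from group(s): %s",
      reference_gene, paste(missing_ref, collapse = ", ")
    ))
  }
  structure(records,
    class = c("duoseq_qpcr", class(records)),
    reference_gene = reference_gene, calibrator_group = calibrator_group
  )
}

#' Read a qPCR Ct table from TSV
#'
#' Four tab-separated columns: `gene`, `group`, `replicate`, `ct`.
#'
#' @param path Path to the TSV file.
#' @inheritParams qpcr_table
#' @return A `duoseq_qpcr` tibble.
#' @export
read_qpcr_table <- function(path, reference_gene, calibrator_group) {
  mat <- read_tsv_fields(path, 4, c("gene", "target"))
  ct <- suppressWarnings(as.numeric(mat[, 4]))
  if (anyNA(ct)) abort_parse(sprintf("non-numeric Ct value in %s", path))
  qpcr_table(
    tibble::tibble(
      gene = mat[, 1], group = mat[, 2],
      replicate = suppressWarnings(as.integer(mat[, 3])), ct = ct
    ),
    reference_gene, calibrator_group
  )
}

mean_ct <- function(table, gene, group) {
  ct <- table$ct[table$gene == gene & table$group == group]
  if (length(ct) == 0) {
    abort_validation(sprintf("no Ct for gene '%s' in group '%s'", gene, group))
  }
  mean(ct)
}

#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification: replicate Ct values are averaged, then
#' \deqn{\Delta Ct(g) = \bar{Ct}_{gene,g} - \bar{Ct}_{ref,g}}
#' \deqn{\Delta\Delta Ct = \Delta Ct(group) - \Delta Ct(calibrator)}
#' and the fold change relative to the calibrator group is
#' \eqn{2^{-\Delta\Delta Ct}}. The double difference cancels both loading
#' (via the reference gene) and any global Ct shift.
#'
#' @param table A `duoseq_qpcr` table.
#' @param gene Target gene (not the reference gene).
#' @param group Sample group.
#' @return A single fold change; 1 for the calibrator group by construction.
#' @examples
#' tab <- qpcr_table(
#'   data.frame(
#'     gene = c("gld", "s7", "gld", "s7"),
#'     group = c("ins", "ins", "vir", "vir"),
#'     replicate = 1, ct = c(20, 18, 22, 18)
#'   ),
#'   reference_gene = "s7", calibrator_group = "vir"
#' )
#' delta_delta_ct(tab, "gld", "ins") # 4
#' @export
delta_delta_ct <- function(table, gene, group) {
  ref <- attr(table, "reference_gene")
  calib <- attr(table, "calibrator_group")
  if (gene == ref) abort_validation("gene must differ from the reference gene")
  dct_group <- mean_ct(table, gene, group) - mean_ct(table, ref, group)
  dct_calib <- mean_ct(table, gene, calib) - mean_ct(table, ref, calib)
  2^(-(dct_group - dct_calib))
}

#' Full relative-quantification report
#'
#' Computes [delta_delta_ct()] for every non-reference gene in every group,
#' with dispersion bounds from the replicate Ct spread: the ddCt standard
#' deviation is taken as \eqn{s = \sqrt{s_{gene}^2 + s_{ref}^2}} within the
#' sample group, and the bounds are \eqn{2^{-(\Delta\Delta Ct \pm s)}}.
#' Single-replicate measurements get `NA` bounds.
#'
#' @param table A `duoseq_qpcr` table.
#' @return A tibble `(gene, group, n_replicates, rel_expr, lower, upper)`,
#'   one row per gene x group, sorted by gene then group; empty when the
#'   table holds only the reference gene.
#' @export
relquant_report <- function(table) {
  ref <- attr(table, "reference_gene")
  genes <- sort(setdiff(unique(table$gene), ref))
  groups <- sort(unique(table$group))
  if (length(genes) == 0) {
    return(tibble::tibble(
      gene = character(), group = character(), n_replicates = integer(),
      rel_expr = numeric(), lower = numeric(), upper = numeric()
    ))
  }
  grid <- tidyr::expand_grid(gene = genes, group = groups)
  purrr::pmap(grid, function(gene, group) {
    ct_g <- table$ct[table$gene == gene & table$group == group]
    ct_r <- table$ct[table$gene == ref & table$group == group]
    fold <- delta_delta_ct(table, gene, group)
    ddct <- -log2(fold)
    s <- sqrt(sd(ct_g)^2 + sd(ct_r)^2) # NA for single replicates
    tibble::tibble(
      gene = gene, group = group, n_replicates = length(ct_g),
      rel_expr = fold, lower = 2^(-(ddct + s)), upper = 2^(-(ddct - s))
    )
  }) |>
    purrr::list_rbind()
}

#' Fold-change bar chart of a relative-quantification report
#'
#' @param report A tibble from [relquant_report()].
#' @return A ggplot object: bars of fold change per group, faceted by gene,
#'   with error bars where replicate spread is available.
#' @export
plot_relquant <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$group, y = .data$rel_expr)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.25, na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fold change vs calibrator (2^-ddCt)") +
    ggplot2::theme_minimal()
}
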