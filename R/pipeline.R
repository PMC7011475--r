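#' Hierarchical clustering of an expression matrix
#'
#' Agglomerative clustering of heatmap rows (CDS) and columns (libraries)
#' with Euclidean distance and complete linkage — the defaults of the
#' common R heatmap tools — via [stats::dist()] and [stats::hclust()].
#' Ties are broken deterministically by input order.
#'
#' @param zmatrix Numeric matrix (e.g. from [tpm_zscore_matrix()]), >= 2
#'   rows, finite entries.
#' @param distance Distance measure for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A list of class `duoseq_clustering`: `row_order` and `col_order`
#'   (permutations of rownames / colnames) and the two `hclust` trees
#'   (`row_hclust`, `col_hclust`; the latter `NULL` for a single column).
#' @export
hierarchical_cluster <- function(zmatrix, distance = "euclidean", linkage = "complete") {
  zmatrix <- as.matrix(zmatrix)
  if (nrow(zmatrix) < 2) abort("need >= 2 rows to cluster", class = "duoseq_domain_error")
  if (any(!is.finite(zmatrix))) abort_validation("matrix has non-finite entries")
  hr <- hclust(dist(zmatrix, method = distance), method = linkage)
  hc <- if (ncol(zmatrix) >= 2) {
    hclust(dist(t(zmatrix), method = distance), method = linkage)
  }
  structure(
    list(
      row_order = rownames(zmatrix)[hr$order],
      col_order = if (is.null(hc)) colnames(zmatrix) else colnames(zmatrix)[hc$order],
      row_hclust = hr, col_hclust = hc
    ),
    class = "duoseq_clustering"
  )
}

#' @export
print.duoseq_clustering <- function(x, ...) {
  cat(sprintf(
    "<duoseq_clustering> %d rows x %d columns (%s)\n",
    length(x$row_order), length(x$col_order), x$row_hclust$method
  ))
  invisible(x)
}

#' @describeIn hierarchical_cluster Row and column orders as a two-column
#'   tibble `(dimension, position, label)`.
#' @param x A `duoseq_clustering`.
#' @param ... Unused.
#' @export
tidy.duoseq_clustering <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(dimension = "row", position = seq_along(x$row_order), label = x$row_order),
    tibble::tibble(dimension = "column", position = seq_along(x$col_order), label = x$col_order)
  )
}

#' Expression heatmap of a z-score matrix
#'
#' Draws the clustered CDS x library z-score matrix as a tile plot, rows
#' and columns in dendrogram order.
#'
#' @param zmatrix Matrix from [tpm_zscore_matrix()] (or any z-score matrix).
#' @param clustering Optional `duoseq_clustering`; computed if missing.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(zmatrix, clustering = NULL) {
  clustering <- clustering %||% hierarchical_cluster(zmatrix)
  df <- tibble::as_tibble(as.data.frame(zmatrix), rownames = "cds_id") |>
    tidyr::pivot_longer(-"cds_id", names_to = "library", values_to = "z") |>
    dplyr::mutate(
      cds_id = factor(.data$cds_id, levels = clustering$row_order),
      library = factor(.data$library, levels = clustering$col_order)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$library, .data$cds_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#0072B2", mid = "grey95", high = "#D55E00", midpoint = 0
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Run the full comparison pipeline
#'
#' Orchestrates the whole analysis on either in-memory objects or files:
#' dataset validation, per-library normalization, the two-library DEG call,
#' tissue-enrichment filtering, candidate selection, functional
#' classification of the DEG sets, the z-score matrix with hierarchical
#' clustering, and (optionally) qPCR relative quantification. All tables
#' are written as TSV into `out_dir` together with a JSON run manifest
#' (package version, configuration echo, input checksums, headline counts).
#' Identical inputs and configuration yield byte-identical outputs.
#'
#' @param dataset A `duoseq_dataset`, or `NULL` to read from files.
#' @param catalog_path,count_paths When `dataset` is `NULL`: path to the
#'   catalog, and a named character vector of count-table paths whose names
#'   are taken as library names and (when one of [library_conditions])
#'   conditions.
#' @param out_dir Output directory, created if needed.
#' @param lib1,lib2 The two libraries compared by [call_degs()] (defaults:
#'   the `virgin` and `inseminated` conditions).
#' @param alpha,fold_threshold,correction DEG-call settings, see [call_degs()].
#' @param floor,min_relative,min_fold_vs_female_body Enrichment settings,
#'   see [enrichment_table()] and [flag_enriched()].
#' @param min_fold_vs_body Candidate threshold, see [select_candidates()].
#' @param vocabulary Vocabulary tibble for [classify_annotations()].
#' @param qpcr Optional `duoseq_qpcr` table; adds a relative-quantification
#'   report to the outputs.
#' @param quiet Suppress progress messages.
#' @return The manifest as a list, invisibly. Side effect: files
#'   `normalized.tsv`, `de.tsv`, `enrichment.tsv`, `candidates.txt`,
#'   `class_summary_lib1_up.tsv`, `class_summary_lib2_up.tsv`,
#'   `zscore_matrix.tsv`, `cluster_order.tsv`, optionally `qpcr_report.tsv`,
#'   and `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(dataset = NULL, catalog_path = NULL, count_paths = NULL,
                         out_dir, lib1 = NULL, lib2 = NULL,
                         alpha = 0.05, fold_threshold = 8,
                         correction = c("bonferroni", "bh"),
                         floor = 1, min_relative = 1,
                         min_fold_vs_female_body = 2, min_fold_vs_body = 30,
                         vocabulary = default_vocabulary(), qpcr = NULL,
                         quiet = FALSE) {
  correction <- match.arg(correction)
  say <- function(...) if (!quiet) message(sprintf(...))
  checksums <- NULL
  if (is.null(dataset)) {
    paths <- c(catalog = catalog_path, count_paths)
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files) > 0) {
      abort_validation(sprintf(
        "input file(s) not found: %s", paste(missing_files, collapse = ", ")
      ))
    }
    checksums <- as.list(tools::md5sum(paths))
    say("reading catalog %s and %d count tables", catalog_path, length(count_paths))
    catalog <- read_cds_catalog(catalog_path)
    libs <- purrr::imap(count_paths, function(p, nm) {
      cond <- if (nm %in% library_conditions) nm else "other"
      read_count_table(p, name = nm, condition = cond)
    })
    dataset <- validate_dataset(catalog, libs)
  } else {
    dataset <- validate_dataset(dataset)
  }
  pick_cond <- function(nm, cond) {
    nm %||% dataset$libraries$library[dataset$libraries$condition == cond][1]
  }
  lib1 <- pick_cond(lib1, "virgin")
  lib2 <- pick_cond(lib2, "inseminated")
  if (is.na(lib1) || is.na(lib2)) {
    abort_validation("cannot determine the two comparison libraries; pass lib1/lib2")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)

  say("normalizing %d libraries", nrow(dataset$libraries))
  norm <- normalize_libraries(dataset)
  write_normalized_table(norm, out("normalized.tsv"))

  say("calling DEGs: %s vs %s", lib1, lib2)
  de <- call_degs(dataset, lib1, lib2, alpha = alpha,
                  fold_threshold = fold_threshold, correction = correction)
  write_de_table(de, out("de.tsv"))

  has_bodies <- all(c("body_female", "body_male") %in% dataset$libraries$condition)
  candidates <- character()
  if (has_bodies) {
    say("computing whole-body enrichment")
    enr <- enrichment_table(dataset, virgin = lib1, inseminated = lib2, floor = floor) |>
      flag_enriched(min_relative = min_relative,
                    min_fold_vs_female_body = min_fold_vs_female_body)
    candidates <- select_candidates(de, enr, min_fold_de = fold_threshold,
                                    min_fold_vs_body = min_fold_vs_body)
    enr$candidate <- enr$cds_id %in% candidates
    write_enrichment_table(enr, out("enrichment.tsv"))
    writeLines(candidates, out("candidates.txt"))
  } else {
    say("no body_female/body_male libraries: skipping enrichment stage")
  }

  say("classifying annotations")
  classified <- classify_annotations(dataset$catalog, vocabulary)
  for (side in c("lib1_up", "lib2_up")) {
    ids <- de$cds_id[de$deg_call == side]
    readr::write_tsv(summarize_classes(ids, classified),
                     out(sprintf("class_summary_%s.tsv", side)))
  }

  deg_ids <- de$cds_id[de$deg_call != "none"]
  zscore_ids <- if (length(deg_ids) >= 2) sort(deg_ids) else NULL
  zmat <- tpm_zscore_matrix(dataset, ids = zscore_ids)
  readr::write_tsv(
    tibble::as_tibble(as.data.frame(zmat), rownames = "cds_id"),
    out("zscore_matrix.tsv")
  )
  clust <- hierarchical_cluster(zmat)
  readr::write_tsv(tidy(clust), out("cluster_order.tsv"))

  if (!is.null(qpcr)) {
    say("computing qPCR relative quantification")
    readr::write_tsv(relquant_report(qpcr), out("qpcr_report.tsv"))
  }

  manifest <- list(
    package = "duoseq",
    version = as.character(utils::packageVersion("duoseq")),
    libraries = as.list(setNames(dataset$libraries$condition, dataset$libraries$library)),
    comparison = list(lib1 = lib1, lib2 = lib2),
    config = list(
      alpha = alpha, fold_threshold = fold_threshold, correction = correction,
      floor = floor, min_relative = min_relative,
      min_fold_vs_female_body = min_fold_vs_female_body,
      min_fold_vs_body = min_fold_vs_body
    ),
    input_md5 = checksums,
    n_cds = nrow(dataset$catalog),
    n_deg = sum(de$deg_call != "none"),
    n_lib1_up = sum(de$deg_call == "lib1_up"),
    n_lib2_up = sum(de$deg_call == "lib2_up"),
    n_candidates = length(candidates),
    outputs = setdiff(list.files(out_dir), "manifest.json")
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %d DEG (%d %s-up, %d %s-up), %d candidates",
      manifest$n_deg, manifest$n_lib1_up, lib1, manifest$n_lib2_up, lib2,
      manifest$n_candidates)
  invisible(manifest)
}
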