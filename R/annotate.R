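#' Default keyword vocabulary
#'
#' A compact keyword-to-functional-class vocabulary covering the classes
#' recurrent in insect organ transcriptome catalogs (secreted, energy
#' metabolism, signal transduction, extracellular matrix / cell adhesion,
#' proteolysis, immunity, transport, chitin-associated, transcription
#' machinery, ...). Keywords are matched as lowercase substrings of the CDS
#' annotation; the priority (defaulting to keyword length, so longer — more
#' specific — keywords win) orders tied matches. Users are expected to
#' extend or replace it via [read_vocabulary()].
#'
#' @return A tibble `(keyword, class_label, priority)`.
#' @export
default_vocabulary <- function() {
  v <- tibble::tribble(
    ~keyword, ~class_label,
    "glucose dehydrogenase", "metabolism",
    "dehydrogenase", "metabolism",
    "cytochrome", "metabolism",
    "oxidase", "metabolism",
    "reductase", "metabolism",
    "atp synthase", "metabolism",
    "glycolytic", "metabolism",
    "lipase", "metabolism",
    "kinase", "signal transduction",
    "phosphatase", "signal transduction",
    "receptor", "signal transduction",
    "g-protein", "signal transduction",
    "hormone", "signal transduction",
    "nuclear receptor", "signal transduction",
    "juvenile hormone", "signal transduction",
    "odorant binding", "signal transduction",
    "collagen", "extracellular matrix/cell adhesion",
    "laminin", "extracellular matrix/cell adhesion",
    "cadherin", "extracellular matrix/cell adhesion",
    "integrin", "extracellular matrix/cell adhesion",
    "mucin", "extracellular matrix/cell adhesion",
    "adhesion", "extracellular matrix/cell adhesion",
    "chitin", "chitin associated",
    "chitinase", "chitin associated",
    "cuticle", "chitin associated",
    "protease", "proteolysis",
    "peptidase", "proteolysis",
    "trypsin", "proteolysis",
    "protease inhibitor", "protease inhibitor",
    "serpin", "protease inhibitor",
    "kazal", "protease inhibitor",
    "antimicrobial", "immunity",
    "defensin", "immunity",
    "cecropin", "immunity",
    "lysozyme", "immunity",
    "immune", "immunity",
    "transporter", "transport",
    "channel", "transport",
    "exchanger", "transport",
    "sodium/calcium exchanger", "transport",
    "transcription factor", "transcription machinery",
    "zinc finger", "transcription machinery",
    "atrophin", "transcription machinery",
    "ribosomal protein", "protein synthesis",
    "ribosomal", "protein synthesis",
    "elongation factor", "protein synthesis",
    "heat shock", "protein modification",
    "ubiquitin", "protein modification",
    "glycosyltransferase", "protein modification",
    "galnt", "protein modification",
    "secreted", "secreted",
    "signal peptide", "secreted",
    "salivary", "secreted",
    "transposable element", "transposable element",
    "transposase", "transposable element"
  )
  v$priority <- nchar(v$keyword)
  v
}

validate_vocabulary <- function(vocab) {
  vocab <- tibble::as_tibble(vocab)
  if (!all(c("keyword", "class_label", "priority") %in% names(vocab))) {
    abort_validation("vocabulary needs columns keyword, class_label, priority")
  }
  if (nrow(vocab) == 0) abort_validation("vocabulary is empty")
  if (any(!nzchar(vocab$keyword))) abort_validation("vocabulary keywords must be non-empty")
  vocab$keyword <- tolower(vocab$keyword)
  vocab
}

#' Read a keyword vocabulary from TSV
#'
#' Three tab-separated columns: `keyword`, `class_label`, `priority`
#' (integer; larger wins ties). `#` comments and a header row are accepted.
#'
#' @param path Path to the TSV file.
#' @return A tibble `(keyword, class_label, priority)` in file order.
#' @export
read_vocabulary <- function(path) {
  mat <- read_tsv_fields(path, 3, c("keyword", "word"))
  pr <- suppressWarnings(as.numeric(mat[, 3]))
  if (anyNA(pr)) {
    abort_parse(sprintf("non-numeric priority in %s", path))
  }
  validate_vocabulary(tibble::tibble(
    keyword = mat[, 1], class_label = mat[, 2], priority = pr
  ))
}

#' Classify CDS annotations with a keyword vocabulary
#'
#' Assigns one functional class per CDS by lowercase substring match of the
#' vocabulary keywords against the annotation text. Among matching
#' keywords, the highest priority wins; ties are broken by earliest
#' vocabulary position, making classification deterministic and independent
#' of catalog order. A CDS with no keyword match is labelled `"secreted"`
#' when it carries a predicted signal peptide (a protein with a secretion
#' signal but no informative annotation is presumed released to the organ
#' lumen), and `"unknown/conserved"` otherwise.
#'
#' @param catalog A catalog tibble (see [read_cds_catalog()]).
#' @param vocab A vocabulary tibble (default [default_vocabulary()]).
#' @return The catalog with a `functional_class` column added.
#' @examples
#' cat <- cds_catalog("g1", 900, "glucose dehydrogenase")
#' classify_annotations(cat)$functional_class # "metabolism"
#' @export
classify_annotations <- function(catalog, vocab = default_vocabulary()) {
  vocab <- validate_vocabulary(vocab)
  ann <- tolower(catalog$annotation)
  best_class <- character(length(ann))
  best_prio <- rep(-Inf, length(ann))
  # iterate the vocabulary in order so earlier entries win priority ties
  for (i in seq_len(nrow(vocab))) {
    hit <- stringr::str_detect(ann, stringr::fixed(vocab$keyword[i]))
    take <- hit & vocab$priority[i] > best_prio
    best_class[take] <- vocab$class_label[i]
    best_prio[take] <- vocab$priority[i]
  }
  none <- !is.finite(best_prio)
  best_class[none] <- ifelse(catalog$has_signal_peptide[none], "secreted", "unknown/conserved")
  dplyr::mutate(catalog, functional_class = best_class)
}

#' Summarize functional classes over a set of CDS
#'
#' Per-class counts and percentages for a chosen id list (e.g. a DEG set),
#' ordered by descending count then label.
#'
#' @param ids Character vector of `cds_id`s to summarize.
#' @param catalog A classified catalog from [classify_annotations()].
#' @return A tibble `(class_label, count, percent)`; empty for empty `ids`.
#' @export
summarize_classes <- function(ids, catalog) {
  if (!"functional_class" %in% names(catalog)) {
    abort_validation("catalog is not classified; run classify_annotations() first")
  }
  if (length(ids) == 0) {
    return(tibble::tibble(class_label = character(), count = integer(), percent = numeric()))
  }
  missing_ids <- setdiff(ids, catalog$cds_id)
  if (length(missing_ids) > 0) {
    abort_validation(sprintf(
      "unclassified ids: %s", paste(head(missing_ids, 5), collapse = ", ")
    ))
  }
  sub <- catalog[match(ids, catalog$cds_id), ]
  dplyr::count(sub, class_label = .data$functional_class, name = "count") |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$class_label)
}

#' Class-composition bar chart
#'
#' @param summary A tibble from [summarize_classes()].
#' @return A ggplot object.
#' @export
plot_class_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = stats::reorder(.data$class_label, .data$count),
    y = .data$percent
  )) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of classified CDS") +
    ggplot2::theme_minimal()
}
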