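#' Library conditions recognised by the pipeline
#'
#' The four library roles of the study design — two sperm-storage-organ
#' (spermatheca) libraries taken before and after insemination, and two
#' whole-body baseline libraries — plus `"other"` for anything else.
#'
#' @export
library_conditions <- c("virgin", "inseminated", "body_female", "body_male", "other")

abort_validation <- function(msg) abort(msg, class = "duoseq_validation_error")
abort_parse <- function(msg) abort(msg, class = "duoseq_parse_error")

#' Construct a count library
#'
#' A count library is one sequencing library's mapped reads per coding
#' sequence (CDS): a tibble with columns `cds_id` and `count`, carrying the
#' library `name`, its `condition` and its `total_mapped` read count as
#' attributes. `total_mapped` is the total number of reads mapped over all
#' identified coding sequences; it defaults to the column sum but can be
#' supplied explicitly, because a filtered table may cover only a subset of
#' the CDS the library was mapped against.
#'
#' @param counts A data frame with columns `cds_id` (character) and `count`
#'   (non-negative integers), or a named numeric vector of counts.
#' @param name Library name (string).
#' @param condition One of [library_conditions].
#' @param total_mapped Total mapped reads over all CDS. Defaults to
#'   `sum(counts$count)`.
#' @return A tibble of class `duoseq_library`.
#' @examples
#' count_library(c(g1 = 10, g2 = 0), "vir", "virgin")
#' @export
count_library <- function(counts, name, condition = "other", total_mapped = NULL) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble::tibble(cds_id = names(counts), count = unname(counts))
  }
  counts <- tibble::as_tibble(counts)
  if (!all(c("cds_id", "count") %in% names(counts))) {
    abort_validation("`counts` must have columns `cds_id` and `count`")
  }
  counts <- dplyr::select(counts, "cds_id", "count")
  condition <- match.arg(condition, library_conditions)
  if (anyNA(counts$count) || any(counts$count < 0)) {
    abort_validation(sprintf("library '%s': counts must be non-negative", name))
  }
  if (any(counts$count != floor(counts$count))) {
    abort_validation(sprintf("library '%s': counts must be integers", name))
  }
  dup <- unique(counts$cds_id[duplicated(counts$cds_id)])
  if (length(dup) > 0) {
    abort_validation(sprintf(
      "library '%s': duplicate cds_id: %s", name, paste(head(dup, 5), collapse = ", ")
    ))
  }
  if (is.null(total_mapped)) total_mapped <- sum(counts$count)
  if (length(total_mapped) != 1 || is.na(total_mapped) || total_mapped < 0) {
    abort_validation("`total_mapped` must be a single non-negative number")
  }
  counts <- dplyr::arrange(counts, .data$cds_id)
  structure(counts,
    class = c("duoseq_library", class(counts)),
    name = name, condition = condition, total_mapped = as.numeric(total_mapped)
  )
}

#' @export
print.duoseq_library <- function(x, ...) {
  cat(sprintf(
    "<duoseq_library> '%s' (%s): %d CDS, %s total mapped reads\n",
    attr(x, "name"), attr(x, "condition"), nrow(x),
    format(attr(x, "total_mapped"), big.mark = ",")
  ))
  NextMethod()
}

# Read a whitespace-tolerant TSV with '#' comments and an optional header.
# Returns a character matrix of fields; attribute "line" maps rows to file lines.
read_tsv_fields <- function(path, n_fields, header_names) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort_parse(sprintf("no records in %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < n_fields)
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "malformed line %d in %s: expected %d tab-separated fields",
      lineno[bad[1]], path, n_fields
    ))
  }
  mat <- do.call(rbind, lapply(fields, function(f) f[seq_len(n_fields)]))
  # optional header: first row repeats known column names
  if (tolower(mat[1, 1]) %in% header_names) {
    mat <- mat[-1, , drop = FALSE]
    lineno <- lineno[-1]
    if (nrow(mat) == 0) abort_parse(sprintf("no records in %s", path))
  }
  attr(mat, "line") <- lineno
  mat
}

#' Read a per-CDS count table
#'
#' Reads a two-column tab-separated table (`cds_id`, `count`) into a
#' [count_library()]. Lines starting with `#` are comments; a header row is
#' detected and skipped.
#'
#' @inheritParams count_library
#' @param path Path to the tab-separated file.
#' @return A `duoseq_library` tibble.
#' @export
read_count_table <- function(path, name, condition = "other", total_mapped = NULL) {
  mat <- read_tsv_fields(path, 2, c("cds_id", "id", "gene"))
  counts <- suppressWarnings(as.numeric(mat[, 2]))
  bad <- which(is.na(counts) | counts < 0)
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "line %d in %s: count '%s' is not a non-negative integer",
      attr(mat, "line")[bad[1]], path, mat[bad[1], 2]
    ))
  }
  count_library(
    tibble::tibble(cds_id = mat[, 1], count = counts),
    name = name, condition = condition, total_mapped = total_mapped
  )
}

#' Write a count library as TSV
#'
#' @param lib A `duoseq_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(lib, path) {
  readr::write_tsv(tibble::as_tibble(lib)[, c("cds_id", "count")], path)
  invisible(path)
}

#' Read a CDS catalog
#'
#' A catalog describes every coding sequence: its id, length in bp, free-text
#' annotation and whether a signal peptide was predicted. Two formats are
#' accepted: a tab-separated table `(cds_id, length_bp, annotation,
#' signal_peptide)` with the flag coded 0/1, or a FASTA file, in which case
#' `length_bp` is the sequence length, the annotation is the description
#' line after the id, and the signal-peptide flag defaults to `FALSE`.
#'
#' @param path Path to a TSV or FASTA file.
#' @param format `"auto"` (sniff a leading `>`), `"tsv"` or `"fasta"`.
#' @return A tibble with columns `cds_id`, `length_bp`, `annotation`,
#'   `has_signal_peptide`, sorted by `cds_id`.
#' @export
read_cds_catalog <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readr::read_lines(path, n_max = 50)
    first <- first[!grepl("^\\s*(#|$)", first)]
    format <- if (length(first) > 0 && startsWith(first[1], ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    hdr <- names(seqs)
    ids <- sub("\\s.*$", "", hdr)
    ann <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
    cat <- tibble::tibble(
      cds_id = ids, length_bp = Biostrings::width(seqs),
      annotation = ann, has_signal_peptide = FALSE
    )
  } else {
    mat <- read_tsv_fields(path, 4, c("cds_id", "id"))
    len <- suppressWarnings(as.numeric(mat[, 2]))
    bad <- which(is.na(len) | len < 1 | len != floor(len))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "line %d in %s: length_bp '%s' must be a positive integer",
        attr(mat, "line")[bad[1]], path, mat[bad[1], 2]
      ))
    }
    flag <- mat[, 4]
    if (!all(flag %in% c("0", "1", "TRUE", "FALSE"))) {
      abort_validation(sprintf("signal_peptide flags in %s must be 0/1", path))
    }
    cat <- tibble::tibble(
      cds_id = mat[, 1], length_bp = as.integer(len),
      annotation = mat[, 3], has_signal_peptide = flag %in% c("1", "TRUE")
    )
  }
  dup <- unique(cat$cds_id[duplicated(cat$cds_id)])
  if (length(dup) > 0) {
    abort_validation(sprintf(
      "duplicate cds_id in catalog: %s", paste(head(dup, 5), collapse = ", ")
    ))
  }
  if (any(cat$length_bp < 1)) abort_validation("length_bp must be >= 1")
  dplyr::arrange(cat, .data$cds_id)
}

#' Construct a CDS catalog from vectors
#'
#' @param cds_id Character ids, unique.
#' @param length_bp Positive integer lengths (bp).
#' @param annotation Free-text annotations (recycled if length 1).
#' @param has_signal_peptide Logical flags (recycled if length 1).
#' @return A catalog tibble sorted by `cds_id`.
#' @export
cds_catalog <- function(cds_id, length_bp, annotation = "", has_signal_peptide = FALSE) {
  cat <- tibble::tibble(
    cds_id = as.character(cds_id), length_bp = as.integer(length_bp),
    annotation = annotation, has_signal_peptide = has_signal_peptide
  )
  if (anyDuplicated(cat$cds_id)) abort_validation("cds_id must be unique")
  if (anyNA(cat$length_bp) || any(cat$length_bp < 1)) {
    abort_validation("length_bp must be >= 1")
  }
  dplyr::arrange(cat, .data$cds_id)
}

#' Validate and align a dataset
#'
#' Aligns a set of count libraries on the catalog's id universe. Every
#' library must only count ids present in the catalog; ids a library does not
#' report are imputed as count 0 (with one warning per library), since a
#' transcript can legitimately be absent from one condition. Ids are ordered
#' lexicographically throughout, which makes all downstream output
#' deterministic.
#'
#' @param catalog A catalog tibble from [read_cds_catalog()] or
#'   [cds_catalog()], or an existing `duoseq_dataset` (returned unchanged —
#'   validation is idempotent).
#' @param libraries A list of [count_library()] objects (at least 2).
#' @return A `duoseq_dataset`: a list with elements
#'   \describe{
#'     \item{catalog}{the catalog tibble, sorted by `cds_id`;}
#'     \item{counts}{a wide tibble, `cds_id` plus one count column per library;}
#'     \item{libraries}{a tibble `(library, condition, total_mapped)`.}
#'   }
#' @export
validate_dataset <- function(catalog, libraries) {
  if (inherits(catalog, "duoseq_dataset")) {
    if (!missing(libraries)) {
      abort_validation("pass either a dataset or (catalog, libraries), not both")
    }
    return(catalog)
  }
  if (length(libraries) < 2) abort_validation("need at least 2 libraries")
  catalog <- dplyr::arrange(tibble::as_tibble(catalog), .data$cds_id)
  ids <- catalog$cds_id
  nm <- unname(vapply(libraries, function(l) attr(l, "name"), character(1)))
  if (anyDuplicated(nm)) abort_validation("library names must be unique")
  counts <- tibble::tibble(cds_id = ids)
  for (lib in libraries) {
    unknown <- setdiff(lib$cds_id, ids)
    if (length(unknown) > 0) {
      abort_validation(sprintf(
        "library '%s' counts ids missing from catalog: %s",
        attr(lib, "name"), paste(head(unknown, 5), collapse = ", ")
      ))
    }
    v <- setNames(rep(0, length(ids)), ids)
    v[lib$cds_id] <- lib$count
    n_missing <- length(ids) - nrow(lib)
    if (n_missing > 0) {
      warn(sprintf(
        "library '%s': %d catalog ids absent, imputed as count 0",
        attr(lib, "name"), n_missing
      ))
    }
    counts[[attr(lib, "name")]] <- unname(v)
  }
  meta <- tibble::tibble(
    library = nm,
    condition = unname(vapply(libraries, function(l) attr(l, "condition"), character(1))),
    total_mapped = unname(vapply(libraries, function(l) attr(l, "total_mapped"), numeric(1)))
  )
  structure(
    list(catalog = catalog, counts = counts, libraries = meta),
    class = "duoseq_dataset"
  )
}

#' @export
print.duoseq_dataset <- function(x, ...) {
  cat(sprintf(
    "<duoseq_dataset> %d CDS x %d libraries\n", nrow(x$catalog), nrow(x$libraries)
  ))
  print(x$libraries)
  invisible(x)
}

#' @describeIn validate_dataset One-line dataset summary as a tibble.
#' @param x A `duoseq_dataset`.
#' @param ... Unused.
#' @export
glance.duoseq_dataset <- function(x, ...) {
  tibble::tibble(
    n_cds = nrow(x$catalog),
    n_libraries = nrow(x$libraries),
    total_mapped = sum(x$libraries$total_mapped),
    median_length_bp = stats::median(x$catalog$length_bp)
  )
}

# Long (cds_id, library, condition, count, total_mapped, length_bp) view.
dataset_long <- function(dataset) {
  tidyr::pivot_longer(dataset$counts, -"cds_id",
    names_to = "library", values_to = "count"
  ) |>
    dplyr::left_join(dataset$libraries, by = "library") |>
    dplyr::left_join(dataset$catalog[, c("cds_id", "length_bp")], by = "cds_id")
}

# Fetch one library's counts aligned to the catalog order, plus its total.
library_counts <- function(dataset, name) {
  if (!name %in% dataset$libraries$library) {
    abort_validation(sprintf("unknown library '%s'", name))
  }
  list(
    counts = dataset$counts[[name]],
    total = dataset$libraries$total_mapped[dataset$libraries$library == name]
  )
}
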