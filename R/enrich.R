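#' Relative RPKM against the whole-body baseline
#'
#' Expression of a CDS in the tissue of interest relative to its
#' constitutive whole-body expression:
#' `rpkm_sp / max(rpkm_body_female, rpkm_body_male, floor)`.
#' An RPKM of 1 is taken as the constitutive whole-body reference level, so
#' the baseline is floored at `floor = 1`; this both encodes that reference
#' and guards against division by zero for transcripts the bodies do not
#' express. Using the larger of the two body libraries is the conservative
#' choice: enrichment must beat both bodies. Vectorized.
#'
#' @param rpkm_sp Tissue (spermathecal) RPKM, >= 0.
#' @param rpkm_body_f,rpkm_body_m Whole-body female and male RPKM, >= 0.
#' @param floor Baseline floor, > 0 (default 1).
#' @return Non-negative numeric vector.
#' @examples
#' relative_rpkm(30, 2, 1) # 15
#' relative_rpkm(5, 0, 0)  # 5: floored baseline
#' @export
relative_rpkm <- function(rpkm_sp, rpkm_body_f, rpkm_body_m, floor = 1.0) {
  if (length(floor) != 1 || is.na(floor) || floor <= 0) {
    abort("`floor` must be a single positive number", class = "duoseq_config_error")
  }
  if (any(rpkm_sp < 0) || any(rpkm_body_f < 0) || any(rpkm_body_m < 0)) {
    abort("RPKM inputs must be >= 0", class = "duoseq_domain_error")
  }
  rpkm_sp / pmax(rpkm_body_f, rpkm_body_m, floor)
}

#' Build the per-CDS enrichment table
#'
#' Computes RPKM for the two tissue libraries and the two whole-body
#' baseline libraries, the relative RPKM of each tissue library against the
#' body baseline ([relative_rpkm()]), and their maximum over the two tissue
#' conditions (`max_relative_rpkm`, the "maximum relative RPKM" used to
#' judge tissue enrichment: values > 1 exceed constitutive whole-body
#' expression).
#'
#' @param dataset A `duoseq_dataset` containing the four libraries.
#' @param virgin,inseminated,body_female,body_male Library names; by default
#'   the library whose condition matches each role.
#' @param floor Baseline floor passed to [relative_rpkm()].
#' @return A tibble `(cds_id, rpkm_sp_virgin, rpkm_sp_inseminated,
#'   rpkm_body_female, rpkm_body_male, relative_rpkm_virgin,
#'   relative_rpkm_inseminated, max_relative_rpkm)`, sorted by `cds_id`.
#' @export
enrichment_table <- function(dataset, virgin = NULL, inseminated = NULL,
                             body_female = NULL, body_male = NULL, floor = 1.0) {
  dataset <- validate_dataset(dataset)
  pick <- function(name, cond) {
    if (!is.null(name)) return(name)
    hit <- dataset$libraries$library[dataset$libraries$condition == cond]
    if (length(hit) != 1) {
      abort_validation(sprintf(
        "expected exactly one library with condition '%s'; pass its name explicitly", cond
      ))
    }
    hit
  }
  libs <- list(
    sp_virgin = pick(virgin, "virgin"),
    sp_inseminated = pick(inseminated, "inseminated"),
    body_female = pick(body_female, "body_female"),
    body_male = pick(body_male, "body_male")
  )
  len <- dataset$catalog$length_bp
  rp <- lapply(libs, function(nm) {
    l <- library_counts(dataset, nm)
    rpkm(l$counts, l$total, len)
  })
  tibble::tibble(
    cds_id = dataset$counts$cds_id,
    rpkm_sp_virgin = rp$sp_virgin,
    rpkm_sp_inseminated = rp$sp_inseminated,
    rpkm_body_female = rp$body_female,
    rpkm_body_male = rp$body_male,
    relative_rpkm_virgin =
      relative_rpkm(rp$sp_virgin, rp$body_female, rp$body_male, floor),
    relative_rpkm_inseminated =
      relative_rpkm(rp$sp_inseminated, rp$body_female, rp$body_male, floor),
    max_relative_rpkm =
      pmax(relative_rpkm(rp$sp_virgin, rp$body_female, rp$body_male, floor),
           relative_rpkm(rp$sp_inseminated, rp$body_female, rp$body_male, floor))
  ) |>
    dplyr::arrange(.data$cds_id) |>
    structure(floor = floor)
}

#' Flag tissue-enriched coding sequences
#'
#' A CDS is enriched when (a) its maximum relative RPKM exceeds
#' `min_relative` — i.e. it is expressed above the constitutive whole-body
#' level — and (b) its larger tissue RPKM is at least
#' `min_fold_vs_female_body` times the female-body RPKM (floored at the
#' table's baseline floor). The defaults encode "relative RPKM > 1" and "at
#' least double the whole-female-body expression".
#'
#' @param table An enrichment tibble from [enrichment_table()].
#' @param min_relative Enrichment threshold on `max_relative_rpkm`
#'   (strict >, default 1).
#' @param min_fold_vs_female_body Minimum fold over the female body
#'   (default 2).
#' @return The input tibble with a logical `enriched` column added.
#' @export
flag_enriched <- function(table, min_relative = 1.0, min_fold_vs_female_body = 2.0) {
  floor <- attr(table, "floor") %||% 1.0
  sp_max <- pmax(table$rpkm_sp_virgin, table$rpkm_sp_inseminated)
  dplyr::mutate(
    table,
    enriched = .data$max_relative_rpkm > min_relative &
      sp_max >= min_fold_vs_female_body * pmax(.data$rpkm_body_female, floor)
  )
}

#' Select candidate transcripts for follow-up
#'
#' The candidate cascade applied to pick transcripts for experimental
#' validation: differentially expressed between the two tissue conditions
#' with at least `min_fold_de` normalized read rate, and at least
#' `min_fold_vs_body`-fold above constitutive whole-body expression.
#' (A functional-group criterion is applied downstream by the caller using
#' [classify_annotations()] labels.)
#'
#' @param de A `duoseq_de` table from [call_degs()].
#' @param enr An enrichment tibble from [enrichment_table()].
#' @param min_fold_de Minimum normalized read rate in the up direction
#'   (default 8).
#' @param min_fold_vs_body Minimum `max_relative_rpkm` (default 30).
#' @return Character vector of candidate `cds_id`s, sorted.
#' @export
select_candidates <- function(de, enr, min_fold_de = 8, min_fold_vs_body = 30) {
  if (!setequal(de$cds_id, enr$cds_id)) {
    abort_validation("DE and enrichment tables must share the same cds_id universe")
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(de)[, c("cds_id", "n1", "n2", "deg_call")],
    enr[, c("cds_id", "max_relative_rpkm")],
    by = "cds_id"
  )
  hit <- joined$deg_call != "none" &
    pmax(joined$n1, joined$n2) >= min_fold_de &
    joined$max_relative_rpkm >= min_fold_vs_body
  sort(joined$cds_id[hit])
}

#' Write an enrichment table as TSV
#'
#' @param enr Enrichment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(enr, path) {
  readr::write_tsv(tibble::as_tibble(enr), path)
  invisible(path)
}
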