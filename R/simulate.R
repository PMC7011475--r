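#' Configuration for the synthetic dataset generator
#'
#' Describes the simulated study: a catalog of `n_cds` coding sequences and
#' four count libraries (virgin and inseminated tissue, female and male
#' whole body), each sequenced to about `depth_per_library` mapped reads.
#' Baseline per-CDS expression is drawn log-uniformly over four orders of
#' magnitude — the dynamic range of a deep transcriptome, which exercises
#' the pseudocount behaviour at low counts. A fraction `frac_de` of CDS is
#' planted as differentially expressed between the two tissue conditions at
#' `de_fold` (split between directions by `de_skew`), and a fraction
#' `frac_enriched` as tissue-enriched, with whole-body expression divided
#' by `enriched_fold_vs_body`; the two sets are drawn independently. Counts
#' are negative-binomial with dispersion `nb_dispersion` (0 gives Poisson),
#' since real libraries are overdispersed.
#'
#' @param n_cds Number of coding sequences.
#' @param depth_per_library Expected total mapped reads per library.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); >= 0.
#' @param frac_de Fraction of CDS planted as DE between conditions.
#' @param de_fold Planted expression fold between conditions, > 1.
#' @param de_skew Fraction of planted DE that is up in the virgin library.
#' @param frac_enriched Fraction of CDS planted as tissue-enriched.
#' @param enriched_fold_vs_body Fold by which body expression of enriched
#'   CDS is reduced, > 1.
#' @param length_range CDS length range in bp, `c(min, max)`.
#' @param frac_signal_peptide Fraction of CDS flagged with a signal peptide.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated list of class `duoseq_config`.
#' @export
synthetic_config <- function(n_cds = 2000, depth_per_library = 2e6,
                             nb_dispersion = 0.1, frac_de = 0.05, de_fold = 8,
                             de_skew = 0.5, frac_enriched = 0.05,
                             enriched_fold_vs_body = 30,
                             length_range = c(300, 3000),
                             frac_signal_peptide = 0.15, seed = 1) {
  cfg <- list(
    n_cds = n_cds, depth_per_library = depth_per_library,
    nb_dispersion = nb_dispersion, frac_de = frac_de, de_fold = de_fold,
    de_skew = de_skew, frac_enriched = frac_enriched,
    enriched_fold_vs_body = enriched_fold_vs_body,
    length_range = length_range, frac_signal_peptide = frac_signal_peptide,
    seed = seed
  )
  bad_frac <- function(x) x < 0 || x > 1
  if (n_cds < 1 || depth_per_library < 1 || nb_dispersion < 0 ||
      bad_frac(frac_de) || bad_frac(frac_enriched) || bad_frac(de_skew) ||
      bad_frac(frac_signal_peptide) || de_fold <= 1 ||
      enriched_fold_vs_body <= 1 || length(length_range) != 2 ||
      length_range[1] < 1 || length_range[2] < length_range[1]) {
    abort("invalid synthetic configuration", class = "duoseq_config_error")
  }
  structure(cfg, class = "duoseq_config")
}

nb_counts <- function(mu, dispersion) {
  if (dispersion == 0) {
    stats::rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
}

# Annotation phrases the default vocabulary recognises (plus opaque ones),
# so classification is exercised end to end.
annotation_pool <- c(
  "glucose dehydrogenase", "cytochrome p450", "serine protease",
  "chitin binding protein", "protease inhibitor kazal-type",
  "sodium/calcium exchanger", "zinc finger transcription factor",
  "odorant binding protein", "ribosomal protein s7", "collagen alpha chain",
  "defensin precursor", "abc transporter", "receptor tyrosine kinase",
  "hypothetical protein", "conserved hypothetical protein", "uncharacterized protein"
)

#' Simulate a four-library dataset with planted ground truth
#'
#' Generates a CDS catalog and the four count libraries of the study design
#' (see [synthetic_config()]) together with the planted truth, so that
#' error rates and power of the downstream calls can be measured against a
#' known answer.
#'
#' @param config A `duoseq_config`.
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{a `duoseq_dataset` (libraries `virgin`, `inseminated`,
#'       `body_female`, `body_male`);}
#'     \item{truth}{a list: `de_lib1_up`, `de_lib2_up`, `enriched` (cds_id
#'       character vectors) and `baseline_means` (named numeric).}
#'   }
#' @examples
#' sim <- simulate_dataset(synthetic_config(n_cds = 100, depth_per_library = 1e5, seed = 7))
#' sim$dataset
#' length(sim$truth$de_lib1_up)
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "duoseq_config")) {
    abort("`config` must come from synthetic_config()", class = "duoseq_config_error")
  }
  withr::local_seed(config$seed)
  n <- config$n_cds
  ids <- sprintf("cds%05d", seq_len(n))
  lengths <- sample(seq(config$length_range[1], config$length_range[2]), n, replace = TRUE)
  catalog <- cds_catalog(
    ids, lengths,
    annotation = sample(annotation_pool, n, replace = TRUE),
    has_signal_peptide = runif(n) < config$frac_signal_peptide
  )

  baseline <- 10^runif(n, 0, 4) # relative abundance over 4 orders of magnitude
  n_de <- round(config$frac_de * n)
  de_ids <- sample(ids, n_de)
  n_up1 <- round(config$de_skew * n_de)
  de1 <- sort(de_ids[seq_len(n_up1)])
  de2 <- sort(setdiff(de_ids, de1))
  # tissue-enriched transcripts are planted among abundant CDS: enrichment is
  # defined relative to the constitutive whole-body reference (RPKM ~ 1), so a
  # transcript expressed below that floor everywhere cannot carry the label
  eligible <- ids[baseline > stats::median(baseline)]
  enr <- sort(sample(eligible, min(length(eligible), round(config$frac_enriched * n))))

  w <- setNames(baseline, ids)
  mu_base <- config$depth_per_library * w / sum(w)
  mult <- function(up_ids, fold) ifelse(ids %in% up_ids, fold, 1)
  mu <- list(
    virgin = mu_base * mult(de1, config$de_fold),
    inseminated = mu_base * mult(de2, config$de_fold),
    body_female = mu_base / mult(enr, config$enriched_fold_vs_body),
    body_male = mu_base / mult(enr, config$enriched_fold_vs_body)
  )
  conds <- c(virgin = "virgin", inseminated = "inseminated",
             body_female = "body_female", body_male = "body_male")
  libs <- purrr::imap(mu, function(m, nm) {
    count_library(setNames(nb_counts(m, config$nb_dispersion), ids),
                  name = nm, condition = conds[[nm]])
  })
  dataset <- validate_dataset(catalog, libs)
  truth <- list(
    de_lib1_up = de1, de_lib2_up = de2, enriched = enr,
    baseline_means = mu_base
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate a null dataset (no planted effects)
#'
#' The same generator with `frac_de = frac_enriched = 0`: every apparent
#' difference between libraries is sampling noise, which is what family-wise
#' error simulations need.
#'
#' @inheritParams simulate_dataset
#' @return A `duoseq_dataset`.
#' @export
simulate_null_dataset <- function(config = synthetic_config()) {
  cfg <- unclass(config)
  cfg$frac_de <- 0
  cfg$frac_enriched <- 0
  simulate_dataset(do.call(synthetic_config, cfg))$dataset
}

#' Simulate a qPCR Ct fixture with known fold changes
#'
#' Builds a replicate-level Ct table whose underlying truth is given fold
#' changes relative to a calibrator group: each gene's Ct in a group is
#' `base_ct - log2(fold) + noise`, the reference gene has fold 1 in every
#' group, and Gaussian noise of `ct_noise_sd` cycles models technical
#' replicate scatter. With zero noise, [delta_delta_ct()] inverts the
#' construction exactly.
#'
#' @param true_folds A data frame `(gene, group, fold)` of target-gene fold
#'   changes relative to the calibrator group (folds > 0; the calibrator
#'   rows should be 1 for exact recovery).
#' @param calibrator_group Calibrator group; defaults to the first group.
#' @param reference_gene Name for the endogenous reference (default `"S7"`);
#'   must not collide with a target gene.
#' @param n_replicates Technical replicates per (gene, group).
#' @param ct_noise_sd Gaussian Ct noise, cycles.
#' @param seed Integer seed.
#' @return A list: `table` (a `duoseq_qpcr`) and `truth` (the fold tibble).
#' @export
simulate_qpcr_fixture <- function(true_folds, calibrator_group = NULL,
                                  reference_gene = "S7", n_replicates = 3,
                                  ct_noise_sd = 0.2, seed = 1) {
  true_folds <- tibble::as_tibble(true_folds)
  if (!all(c("gene", "group", "fold") %in% names(true_folds))) {
    abort("`true_folds` needs columns gene, group, fold", class = "duoseq_config_error")
  }
  if (any(true_folds$fold <= 0)) {
    abort("folds must be > 0", class = "duoseq_config_error")
  }
  if (reference_gene %in% true_folds$gene) {
    abort("reference gene name collides with a target gene", class = "duoseq_config_error")
  }
  withr::local_seed(seed)
  groups <- unique(true_folds$group)
  calibrator_group <- calibrator_group %||% groups[1]
  all_folds <- dplyr::bind_rows(
    true_folds,
    tibble::tibble(gene = reference_gene, group = groups, fold = 1)
  )
  genes <- unique(all_folds$gene)
  base_ct <- setNames(runif(length(genes), 18, 28), genes)
  records <- tidyr::expand_grid(
    all_folds, replicate = seq_len(n_replicates)
  ) |>
    dplyr::mutate(
      ct = base_ct[.data$gene] - log2(.data$fold) +
        rnorm(dplyr::n(), 0, ct_noise_sd)
    ) |>
    dplyr::select("gene", "group", "replicate", "ct")
  list(
    table = qpcr_table(records, reference_gene, calibrator_group),
    truth = true_folds
  )
}

#' Write a simulated dataset's libraries, catalog and truth to disk
#'
#' Emits the same TSV formats the readers consume (one count table per
#' library, a catalog TSV) plus the truth as JSON, so file-based round
#' trips can be tested without shipping data.
#'
#' @param sim A list from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset
  paths <- c(catalog = file.path(dir, "catalog.tsv"))
  readr::write_tsv(
    dplyr::mutate(ds$catalog, has_signal_peptide = as.integer(.data$has_signal_peptide)),
    paths["catalog"]
  )
  for (nm in ds$libraries$library) {
    p <- file.path(dir, paste0(nm, "_counts.tsv"))
    readr::write_tsv(
      tibble::tibble(cds_id = ds$counts$cds_id, count = ds$counts[[nm]]), p
    )
    paths[nm] <- p
  }
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}
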