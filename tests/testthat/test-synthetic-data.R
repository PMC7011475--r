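test_that("generation is reproducible from the seed and sensitive to it", {
  cfg <- synthetic_config(n_cds = 120, depth_per_library = 5e4, seed = 17)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  c_ <- simulate_dataset(synthetic_config(n_cds = 120, depth_per_library = 5e4, seed = 18))
  expect_false(identical(a$dataset$counts, c_$dataset$counts))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(frac_de = 1.2), class = "duoseq_config_error")
  expect_error(synthetic_config(de_fold = 1), class = "duoseq_config_error")
  expect_error(synthetic_config(nb_dispersion = -0.1), class = "duoseq_config_error")
  expect_error(synthetic_config(length_range = c(500, 100)), class = "duoseq_config_error")
  expect_error(simulate_dataset(list(n_cds = 10)), class = "duoseq_config_error")
})

test_that("planted truth matches the configuration", {
  sim <- simulate_dataset(synthetic_config(
    n_cds = 200, depth_per_library = 1e5, frac_de = 0.1, de_skew = 0.5,
    frac_enriched = 0.05, seed = 2
  ))
  tr <- sim$truth
  ids <- sim$dataset$catalog$cds_id
  expect_length(c(tr$de_lib1_up, tr$de_lib2_up), 20)
  expect_length(tr$de_lib1_up, 10)
  expect_length(tr$enriched, 10)
  expect_true(all(c(tr$de_lib1_up, tr$de_lib2_up, tr$enriched) %in% ids))

  # null configuration gives empty truth and is what simulate_null_dataset uses
  null_sim <- simulate_dataset(synthetic_config(
    n_cds = 100, depth_per_library = 1e4, frac_de = 0, frac_enriched = 0, seed = 3
  ))
  expect_length(null_sim$truth$de_lib1_up, 0)
  expect_length(null_sim$truth$enriched, 0)
})

test_that("null libraries still satisfy normalization invariants", {
  ds <- simulate_null_dataset(synthetic_config(n_cds = 100, depth_per_library = 5e4, seed = 4))
  norm <- normalize_libraries(ds)
  per_lib <- dplyr::summarise(dplyr::group_by(norm, library),
                              max_idx = max(expression_index), .groups = "drop")
  expect_equal(per_lib$max_idx, rep(100, 4))
})

test_that("the planted fold is realized: depth-normalized DE ratios center near de_fold", {
  meds <- vapply(1:10, function(s) {
    sim <- simulate_dataset(synthetic_config(seed = 100 + s))
    ds <- sim$dataset
    tr <- sim$truth
    R <- setNames(ds$libraries$total_mapped, ds$libraries$library)
    i1 <- match(tr$de_lib1_up, ds$counts$cds_id)
    i2 <- match(tr$de_lib2_up, ds$counts$cds_id)
    ratio <- c(
      (ds$counts$virgin[i1] / R[["virgin"]]) / (ds$counts$inseminated[i1] / R[["inseminated"]]),
      (ds$counts$inseminated[i2] / R[["inseminated"]]) / (ds$counts$virgin[i2] / R[["virgin"]])
    )
    stats::median(ratio)
  }, numeric(1))
  expect_true(all(meds >= 6 & meds <= 10.7))
})

test_that("DE is recovered with headroom over the fold gate, with controlled FDR", {
  # planted fold at twice the calling threshold: the statistic n1 ~ fold * mu/(mu+1)
  # shrinks below the planted fold, so recovery needs headroom
  perf <- t(vapply(1:5, function(s) {
    sim <- simulate_dataset(synthetic_config(de_fold = 16, seed = 200 + s))
    de <- call_degs(sim$dataset, "virgin", "inseminated")
    tr <- sim$truth
    up1 <- de$cds_id[de$deg_call == "lib1_up"]
    up2 <- de$cds_id[de$deg_call == "lib2_up"]
    tp <- sum(up1 %in% tr$de_lib1_up) + sum(up2 %in% tr$de_lib2_up)
    called <- length(up1) + length(up2)
    c(sens = tp / (length(tr$de_lib1_up) + length(tr$de_lib2_up)),
      fdr = if (called > 0) 1 - tp / called else 0)
  }, c(sens = 0, fdr = 0)))
  expect_true(mean(perf[, "sens"]) >= 0.80)
  expect_true(mean(perf[, "fdr"]) <= 0.05)
})

test_that("the family-wise error rate is controlled in the Poisson limit", {
  # the chi-squared test models sequencing (binomial) noise only, so nominal
  # FWER control holds when counts are Poisson; overdispersion inflates it
  any_sig <- vapply(1:60, function(s) {
    ds <- simulate_null_dataset(synthetic_config(
      n_cds = 1000, depth_per_library = 1e6, nb_dispersion = 0, seed = 300 + s
    ))
    de <- call_degs(ds, "virgin", "inseminated")
    any(de$p_bonferroni <= 0.05)
  }, logical(1))
  expect_true(mean(any_sig) <= 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("noisy qPCR fixtures recover folds within the noise envelope", {
  truth <- tibble::tibble(gene = "a", group = c("vir", "ins"), fold = c(1, 4))
  hits <- vapply(1:40, function(s) {
    fix <- simulate_qpcr_fixture(truth, ct_noise_sd = 0.2, n_replicates = 3, seed = s)
    est <- delta_delta_ct(fix$table, "a", "ins")
    abs(log2(est) - 2) <= 3 * 0.2
  }, logical(1))
  expect_true(mean(hits) >= 0.90)
})

test_that("simulated datasets write the formats the readers consume", {
  sim <- simulate_dataset(synthetic_config(n_cds = 40, depth_per_library = 1e4, seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir)
  cat2 <- read_cds_catalog(paths[["catalog"]])
  expect_equal(cat2$cds_id, sim$dataset$catalog$cds_id)
  expect_equal(cat2$has_signal_peptide, sim$dataset$catalog$has_signal_peptide)
  lib <- read_count_table(paths[["virgin"]], "virgin", "virgin")
  expect_equal(lib$count, sim$dataset$counts$virgin)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$de_lib1_up, sim$truth$de_lib1_up)
})
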