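test_that("rpkm follows r * 1e9 / (R * L) and rejects degenerate depth/length", {
  expect_equal(rpkm(100, 1e6, 1000), 100)
  expect_equal(rpkm(0, 123, 456), 0)
  expect_equal(rpkm(1, 1e6, 500), 2)
  expect_error(rpkm(1, 0, 10), class = "duoseq_domain_error")
  expect_error(rpkm(1, 10, 0), class = "duoseq_domain_error")
  expect_error(rpkm(-1, 10, 10), class = "duoseq_domain_error")

  # linear in r, inverse in R and L
  withr::with_seed(11, {
    for (i in 1:50) {
      r <- sample(0:1000, 1); R <- as.numeric(sample(1e3:1e6, 1))
      L <- as.numeric(sample(100:5000, 1)); k <- sample(2:9, 1)
      expect_equal(rpkm(k * r, R, L), k * rpkm(r, R, L))
      expect_equal(rpkm(r, k * R, L), rpkm(r, R, L) / k)
      expect_equal(rpkm(r, R, k * L), rpkm(r, R, L) / k)
    }
  })
})

test_that("tpm is proportional to length-normalized rates and sums to 1e6", {
  expect_equal(tpm_vector(c(10, 10), c(1000, 2000)),
               c(2, 1) / 3 * 1e6, tolerance = 1e-9)
  expect_equal(tpm_vector(5, 700), 1e6)
  expect_warning(z <- tpm_vector(c(0, 0), c(10, 10)), "all zeros")
  expect_equal(z, c(0, 0))

  withr::with_seed(12, {
    for (i in 1:25) {
      n <- sample(2:200, 1)
      counts <- stats::rpois(n, 30)
      counts[1] <- counts[1] + 1 # non-degenerate
      lens <- sample(100:5000, n, replace = TRUE)
      expect_equal(sum(tpm_vector(counts, lens)) / 1e6, 1, tolerance = 1e-9)
    }
  })
})

test_that("expression index peaks at 100 and is scale-invariant", {
  expect_equal(expression_index(c(50, 100, 25)), c(50, 100, 25))
  expect_equal(expression_index(7), 100)
  expect_error(expression_index(c(0, 0)), "no mapped reads",
               class = "duoseq_domain_error")

  withr::with_seed(13, {
    for (i in 1:25) {
      counts <- stats::rpois(sample(2:100, 1), 20) + 1
      expect_equal(max(expression_index(counts)), 100)
      k <- stats::runif(1, 0.1, 50)
      expect_equal(expression_index(k * counts), expression_index(counts))
    }
  })
})

test_that("z-score rows are standardized with sample sd, zero-variance rows zeroed", {
  # independent mean/sd recomputation on a worked row
  expect_equal(zscore_matrix(matrix(c(1, 3), 1))[1, ],
               c(-1, 3 - 2) / stats::sd(c(1, 3)), tolerance = 1e-12)
  expect_equal(unname(zscore_matrix(matrix(c(1, 3), 1))[1, ]),
               c(-0.70710678, 0.70710678), tolerance = 1e-7)
  # already standardized rows are fixed points
  expect_equal(unname(zscore_matrix(matrix(c(-1, 0, 1), 1))[1, ]), c(-1, 0, 1))
  expect_warning(z <- zscore_matrix(matrix(5, 1, 3)), "zero-variance")
  expect_equal(unname(z[1, ]), c(0, 0, 0))
  expect_error(zscore_matrix(matrix(1:5, 5, 1)), class = "duoseq_domain_error")
  expect_error(zscore_matrix(matrix(c(1, NA, 3, 4), 2)),
               class = "duoseq_validation_error")

  withr::with_seed(14, {
    m <- matrix(stats::rnorm(40 * 4, 10, 4), 40, 4)
    z <- zscore_matrix(m)
    expect_equal(unname(rowMeans(z)), rep(0, 40), tolerance = 1e-12)
    expect_equal(unname(apply(z, 1, stats::sd)), rep(1, 40), tolerance = 1e-12)
    # agrees with base scale() applied row-wise
    expect_equal(unname(z), unname(t(scale(t(m)))), tolerance = 1e-12,
                 ignore_attr = TRUE)
  })
})

test_that("normalize_libraries carries the per-library invariants", {
  sim <- simulate_dataset(synthetic_config(n_cds = 150, depth_per_library = 5e4, seed = 3))
  norm <- normalize_libraries(sim$dataset)
  per_lib <- dplyr::summarise(
    dplyr::group_by(norm, library),
    tpm_sum = sum(tpm), max_idx = max(expression_index),
    .groups = "drop"
  )
  expect_equal(per_lib$tpm_sum / 1e6, rep(1, 4), tolerance = 1e-9)
  expect_equal(per_lib$max_idx, rep(100, 4))
  # RPKM recomputes from the raw ingredients
  one <- norm[norm$library == "virgin", ]
  ds <- sim$dataset
  R <- ds$libraries$total_mapped[ds$libraries$library == "virgin"]
  expect_equal(one$rpkm, one$count * 1e9 / (R * ds$catalog$length_bp))
})

test_that("tpm_zscore_matrix subsets rows and standardizes them", {
  sim <- simulate_dataset(synthetic_config(n_cds = 60, depth_per_library = 5e4, seed = 4))
  ids <- sim$dataset$catalog$cds_id[1:10]
  z <- tpm_zscore_matrix(sim$dataset, ids = ids)
  expect_equal(rownames(z), ids)
  expect_equal(ncol(z), 4)
  expect_equal(unname(rowMeans(z)), rep(0, 10), tolerance = 1e-12)
  expect_error(tpm_zscore_matrix(sim$dataset, ids = "nope"),
               class = "duoseq_validation_error")
})
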