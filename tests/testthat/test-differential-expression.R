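test_that("normalized read rate matches its defining expression", {
  nr <- normalized_read_rate(10, 0, 1e6, 1e6)
  expect_equal(nr$n1, 10)
  expect_equal(nr$n2, 0)
  nr <- normalized_read_rate(10, 10, 1e6, 1e6)
  expect_equal(nr$n1, 10 / 11)
  expect_equal(nr$n2, 10 / 11)
  nr <- normalized_read_rate(0, 0, 5e5, 1e6)
  expect_equal(c(nr$n1, nr$n2), c(0, 0))
  expect_error(normalized_read_rate(1, 1, 0, 10), class = "duoseq_domain_error")

  # independently coded expression over random tuples
  withr::with_seed(21, {
    r1 <- as.numeric(sample(0:5000, 1000, replace = TRUE))
    r2 <- as.numeric(sample(0:5000, 1000, replace = TRUE))
    R1 <- as.numeric(sample(1e4:1e7, 1000, replace = TRUE))
    R2 <- as.numeric(sample(1e4:1e7, 1000, replace = TRUE))
    nr <- normalized_read_rate(r1, r2, R1, R2)
    expect_equal(nr$n1, r1 * R2 / (R1 * (r2 + 1)))
    expect_equal(nr$n2, r2 * R1 / (R2 * (r1 + 1)))
  })
})

test_that("two-library chi-squared equals the brute-force Pearson computation", {
  # worked example, frozen from the expected-count oracle
  res <- chi2_two_library(30, 10, 1e4, 1e4)
  expect_equal(res$stat, 10.02004, tolerance = 1e-6)
  expect_equal(res$p, 1.548461e-3, tolerance = 1e-6)

  # equal proportions: no signal
  res <- chi2_two_library(25, 25, 2e5, 2e5)
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)

  # zero-zero convention
  res <- chi2_two_library(0, 0, 1e4, 2e4)
  expect_equal(c(res$stat, res$p), c(0, 1))

  # exchangeability of the 2x2 test
  a <- chi2_two_library(40, 3, 1e5, 3e5)
  b <- chi2_two_library(3, 40, 3e5, 1e5)
  expect_equal(a, b)

  expect_error(chi2_two_library(11, 1, 10, 10), class = "duoseq_validation_error")

  # oracle equivalence over random tables: expected-count brute force and
  # stats::chisq.test as a second, independent implementation
  withr::with_seed(22, {
    for (i in 1:300) {
      R1 <- sample(1e3:1e6, 1); R2 <- sample(1e3:1e6, 1)
      r1 <- sample(0:min(R1, 2000), 1); r2 <- sample(0:min(R2, 2000), 1)
      if (r1 + r2 == 0) next
      got <- chi2_two_library(r1, r2, R1, R2)
      ora <- oracle_chi2(r1, r2, R1, R2)
      expect_equal(got$stat, unname(ora["stat"]), tolerance = 1e-10)
      expect_equal(got$p, unname(ora["p"]), tolerance = 1e-10)
      ct <- suppressWarnings(stats::chisq.test(
        matrix(c(r1, R1 - r1, r2, R2 - r2), 2, byrow = TRUE), correct = FALSE
      ))
      expect_equal(got$stat, unname(ct$statistic), tolerance = 1e-8)
    }
  })
})

test_that("multiple-testing corrections match hand-computed values and dominate correctly", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroni(c(0.6, 0.9)), c(1, 1))
  expect_error(bonferroni(c(0.5, 1.2)), class = "duoseq_validation_error")

  # hand step-up: all four share min(4 * 0.04/4, 4*0.03/3, ...) = 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_error(bh_fdr(c(-0.1)), class = "duoseq_validation_error")

  withr::with_seed(23, {
    for (i in 1:25) {
      p <- stats::runif(sample(1:100, 1))
      q <- bh_fdr(p)
      expect_true(all(q <= bonferroni(p) + 1e-15))
      # BH preserves the ranking of p
      expect_true(all(diff(q[order(p)]) >= -1e-15))
      expect_true(all(q >= p - 1e-15))
    }
  })
})

test_that("call_degs applies fold and significance gates and sorts deterministically", {
  ds <- tiny_dataset(c1 = c(g1 = 80, g2 = 10, g3 = 10),
                     c2 = c(g1 = 0, g2 = 10, g3 = 10))
  de <- call_degs(ds, "vir", "ins")
  g1 <- de[de$cds_id == "g1", ]
  expect_equal(g1$n1, 80)
  expect_equal(g1$deg_call, "lib1_up")
  expect_true(g1$p_bonferroni <= 0.05)
  # equal counts are never DE: n = 10/11 < 8
  expect_equal(de$deg_call[de$cds_id != "g1"], c("none", "none"))
  # sorted by q then id
  expect_equal(de$cds_id, de$cds_id[order(de$q_bh, de$cds_id)])
  # invariant chain on adjusted p-values
  expect_true(all(de$p_bonferroni >= de$p))
  expect_true(all(de$q_bh <= de$p_bonferroni))

  expect_error(call_degs(ds, "vir", "nope"), "unknown library",
               class = "duoseq_validation_error")
})

test_that("relabeling the two libraries swaps calls and keeps p-values", {
  sim <- simulate_dataset(synthetic_config(n_cds = 300, depth_per_library = 3e5, seed = 5))
  a <- call_degs(sim$dataset, "virgin", "inseminated")
  b <- call_degs(sim$dataset, "inseminated", "virgin")
  a <- dplyr::arrange(tibble::as_tibble(a), cds_id)
  b <- dplyr::arrange(tibble::as_tibble(b), cds_id)
  expect_equal(a$p, b$p)
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$n1, b$n2)
  expect_equal(a$n2, b$n1)
  swap <- c(lib1_up = "lib2_up", lib2_up = "lib1_up", none = "none")
  expect_equal(unname(swap[a$deg_call]), b$deg_call)
})

test_that("the DEG set shrinks as thresholds tighten", {
  sim <- simulate_dataset(synthetic_config(n_cds = 400, depth_per_library = 4e5, seed = 6))
  n_deg <- function(alpha, fold) {
    de <- call_degs(sim$dataset, "virgin", "inseminated",
                    alpha = alpha, fold_threshold = fold)
    sum(de$deg_call != "none")
  }
  expect_true(n_deg(0.05, 16) <= n_deg(0.05, 8))
  expect_true(n_deg(0.01, 8) <= n_deg(0.05, 8))
  expect_equal(n_deg(0, 8), 0)
})

test_that("glance on a DE table reports the comparison and counts", {
  ds <- tiny_dataset()
  g <- glance(call_degs(ds, "vir", "ins"))
  expect_equal(g$n_cds, 3L)
  expect_equal(g$n_deg, g$n_lib1_up + g$n_lib2_up)
  expect_equal(g$correction, "bonferroni")
})
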