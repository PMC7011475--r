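# Small in-code fixtures shared across test files.

tiny_catalog <- function() {
  cds_catalog(
    cds_id = c("g1", "g2", "g3"),
    length_bp = c(1000, 500, 2000),
    annotation = c("glucose dehydrogenase", "hypothetical protein", "chitin binding protein"),
    has_signal_peptide = c(FALSE, TRUE, FALSE)
  )
}

# Two-library dataset with explicit totals so DE arithmetic is exact.
tiny_dataset <- function(c1 = c(g1 = 80, g2 = 10, g3 = 10),
                         c2 = c(g1 = 0, g2 = 10, g3 = 10),
                         R1 = 1e6, R2 = 1e6) {
  validate_dataset(tiny_catalog(), list(
    count_library(c1, "vir", "virgin", total_mapped = R1),
    count_library(c2, "ins", "inseminated", total_mapped = R2)
  ))
}

# Four-library dataset for enrichment tests.
quad_dataset <- function(vir = c(g1 = 300, g2 = 40, g3 = 10),
                         ins = c(g1 = 250, g2 = 30, g3 = 10),
                         bf = c(g1 = 2, g2 = 40, g3 = 10),
                         bm = c(g1 = 1, g2 = 40, g3 = 10),
                         R = 1e5) {
  validate_dataset(tiny_catalog(), list(
    count_library(vir, "virgin", "virgin", total_mapped = R),
    count_library(ins, "inseminated", "inseminated", total_mapped = R),
    count_library(bf, "body_female", "body_female", total_mapped = R),
    count_library(bm, "body_male", "body_male", total_mapped = R)
  ))
}

# Independent brute-force Pearson chi-squared on [[r1, R1-r1], [r2, R2-r2]],
# computed from expected counts E = row * col / grand total.
oracle_chi2 <- function(r1, r2, R1, R2) {
  obs <- matrix(c(r1, R1 - r1, r2, R2 - r2), nrow = 2, byrow = TRUE)
  grand <- sum(obs)
  expect <- outer(rowSums(obs), colSums(obs)) / grand
  stat <- sum((obs - expect)^2 / expect)
  c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

ct_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], group = r[[2]], replicate = as.integer(r[[3]]),
               ct = as.numeric(r[[4]]))
  }))
}
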