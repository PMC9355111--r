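table1 <- lp_estimates_table()
strict <- as.matrix(table1[, c("LP1_strict", "LP2_strict", "LP3_strict")])
gestalt <- as.matrix(table1[, c("LP1_gestalt", "LP2_gestalt", "LP3_gestalt")])

test_that("identical raters give ICC 1 and constant tables are rejected", {
  x <- cbind(a = c(1, 5, 9, 3), b = c(1, 5, 9, 3), c = c(1, 5, 9, 3))
  res <- icc_two_way(x)
  expect_equal(res$icc, 1)
  expect_equal(res$ci_low, 1)
  expect_error(icc_two_way(matrix(7, 4, 3)), "undefined")
  expect_error(icc_two_way(rbind(strict, c(1, NA, 3))), "missing|complete")
})

test_that("both ICC variants match the ANOVA-based reference values", {
  # reference values computed independently from the same published table
  # with the standard two-way mean-square formulas
  cons <- icc_two_way(strict, "consistency")
  expect_equal(cons$icc, 0.651022, tolerance = 1e-5)
  expect_lt(abs(cons$ci_low - 0.29), 0.005)
  expect_lt(abs(cons$ci_high - 0.89), 0.005)
  abs_ <- icc_two_way(strict, "absolute")
  expect_equal(abs_$icc, 0.437214, tolerance = 1e-5)
  expect_lt(abs(abs_$ci_low - 0.04), 0.005)
  expect_lt(abs(abs_$ci_high - 0.79), 0.005)
  g <- icc_two_way(gestalt, "consistency")
  expect_equal(g$icc, 0.723390, tolerance = 1e-5)
})

test_that("consistency ICC ignores a constant rater shift, absolute does not", {
  set.seed(101)
  for (i in 1:10) {
    x <- matrix(runif(24, 0, 50), 8, 3) +
      matrix(runif(8, 0, 30), 8, 3)  # add subject effects
    shifted <- x; shifted[, 2] <- shifted[, 2] + 12
    expect_equal(icc_two_way(shifted, "consistency")$icc,
                 icc_two_way(x, "consistency")$icc, tolerance = 1e-10)
    # the absolute variant is sensitive to the shift (in either direction,
    # depending on whether the shift widens or narrows the rater means)
    expect_false(isTRUE(all.equal(icc_two_way(shifted, "absolute")$icc,
                                  icc_two_way(x, "absolute")$icc,
                                  tolerance = 1e-8)))
  }
})

test_that("added noise degrades the ICC in expectation", {
  set.seed(55)
  subject <- runif(12, 0, 60)
  base <- matrix(subject, 12, 3) + matrix(rnorm(36, 0, 2), 12, 3)
  mean_icc <- function(noise_sd) {
    mean(vapply(1:30, function(i) {
      icc_two_way(base + matrix(rnorm(36, 0, noise_sd), 12, 3))$icc
    }, numeric(1)))
  }
  iccs <- vapply(c(0, 5, 15, 40), mean_icc, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("Pearson correlation is symmetric, bounded, and exact on affine data", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(pearson_correlation(a, b)$r, pearson_correlation(b, a)$r)
    expect_lte(abs(pearson_correlation(a, b)$r), 1)
  }
  expect_error(pearson_correlation(rep(1, 5), c(1, 2, 3, 4, 5)), "constant")

  # hand-computed product-moment value on the published pairs
  r <- pearson_correlation(table1$algorithm, table1$LP2_strict)
  x1 <- table1$algorithm; y1 <- table1$LP2_strict
  hand <- sum((x1 - mean(x1)) * (y1 - mean(y1))) /
    sqrt(sum((x1 - mean(x1))^2) * sum((y1 - mean(y1))^2))
  expect_equal(r$r, hand, tolerance = 1e-12)
})

test_that("least squares matches analytic fits and ties r-squared to Pearson", {
  x <- c(0, 1, 2, 3)
  fit <- linear_fit(x, 3 * x)
  expect_equal(fit$slope, 3)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(linear_fit(x, rep(2, 4))$slope, 0)
  expect_equal(linear_fit(x, rep(2, 4))$r_squared, 0)
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(linear_fit(a, b)$r_squared, pearson_correlation(a, b)$r^2,
                 tolerance = 1e-12)
  }
})

test_that("threshold disagreement counts subjects straddling the cutoff", {
  low <- matrix(c(10, 20, 5, 25, 29, 30), 3, 2)
  expect_equal(threshold_disagreement_count(low, 30), 0)
  expect_equal(threshold_disagreement_count(rbind(c(25, 35)), 30), 1)
  # brute-force enumeration over the published strict rows
  brute <- sum(vapply(seq_len(nrow(strict)), function(i) {
    any(strict[i, ] > 30) && any(strict[i, ] <= 30)
  }, logical(1)))
  expect_equal(threshold_disagreement_count(strict, 30), brute)
  expect_equal(threshold_disagreement_count(strict, 30), 6)
})

test_that("rater CSVs round-trip and report missing cells by name", {
  td <- withr::local_tempdir()
  f <- file.path(td, "raters.csv")
  write.csv(data.frame(image = 1:3, A = c(1, 2, 3), B = c(2, 3, 4)), f,
            row.names = FALSE)
  m <- read_rater_table(f)
  expect_equal(dim(m), c(3L, 2L))
  write.csv(data.frame(image = 1:3, A = c(1, NA, 3), B = c(2, 3, 4)), f,
            row.names = FALSE)
  expect_error(read_rater_table(f), "subject '2' rater 'A'")
})
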