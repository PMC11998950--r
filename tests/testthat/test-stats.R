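# Explicit sums-of-squares oracle for the two-way subjects x measurements
# grid, written as raw loops so it shares nothing with the implementation.
oracle_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- sum(m) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (sum(m[i, ]) / k - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(m[, j]) / n - g)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - g)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = (sst - ssr - ssc) / ((n - 1) * (k - 1)))
}

test_that("Bland-Altman reproduces direct arithmetic", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)   # differences 1, 2, 3
  ba <- bland_altman(x, y)
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)
  expect_false(ba$good_agreement)  # |2| exceeds the 1.2 point rule
  same <- bland_altman(c(40, 42), c(40, 42))
  expect_equal(same$mean_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  expect_true(same$good_agreement)
})

test_that("the 1.2 point rule splits good from poor agreement on |mean difference|", {
  poor <- bland_altman(c(43.3, 44.3, 45.3), c(42, 43, 44))  # mean diff 1.3
  expect_false(poor$good_agreement)
  neg <- bland_altman(c(42, 43, 44), c(43.3, 44.3, 45.3))   # mean diff -1.3
  expect_false(neg$good_agreement)
  ok <- bland_altman(c(43.1, 44.1, 45.1), c(42, 43, 44))    # mean diff 1.1
  expect_true(ok$good_agreement)
})

test_that("Bland-Altman is antisymmetric and equivariant under shifts", {
  withr::local_seed(23)
  for (i in 1:20) {
    x <- runif(8, 35, 50); y <- runif(8, 35, 50)
    ab <- bland_altman(x, y); ba <- bland_altman(y, x)
    expect_equal(ab$mean_diff, -ba$mean_diff, tolerance = 1e-12)
    expect_equal(ab$loa_low, -ba$loa_high, tolerance = 1e-12)
    expect_equal(ab$loa_high, -ba$loa_low, tolerance = 1e-12)
    cshift <- runif(1, -5, 5)
    sh <- bland_altman(x, y + cshift)
    expect_equal(sh$mean_diff, ab$mean_diff - cshift, tolerance = 1e-9)
    expect_equal(sh$sd_diff, ab$sd_diff, tolerance = 1e-9)
  }
  expect_error(bland_altman(1:3, 1:4), class = "microhct_insufficient_data")
  expect_error(bland_altman(1, 1), class = "microhct_insufficient_data")
})

test_that("ICC matches the explicit mean-squares oracle", {
  tt <- simulate_trial_table(n_samples = 5, trials = 3, seed = 11)
  r <- icc(tt, design = "intra")
  m <- matrix(tt$hct_pct[order(tt$sample_id, tt$trial)], nrow = 5, byrow = TRUE)
  ms <- oracle_ms(m)
  n <- 5; k <- 3
  expected <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k / n * (ms$msc - ms$mse))
  expect_equal(r$icc, expected, tolerance = 1e-9)
  expect_equal(r$ms$msr, ms$msr, tolerance = 1e-9)
  # consistency and one-way forms against their defining formulas
  rc <- icc(tt, design = "intra", type = "consistency")
  expect_equal(rc$icc, (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse),
               tolerance = 1e-9)
  ro <- icc(tt, design = "intra", type = "oneway")
  msw <- ((ms$msc * (k - 1)) + ms$mse * (n - 1) * (k - 1)) / (n * (k - 1))
  expect_equal(ro$icc, (ms$msr - msw) / (ms$msr + (k - 1) * msw),
               tolerance = 1e-9)
})

test_that("ICC handles degenerate and duplicated-measurement tables", {
  flat <- trial_table(tidyr::expand_grid(
    sample_id = c("a", "b", "c"), rater = "r1", method = "app",
    trial = 1:3) |> dplyr::mutate(hct_pct = 44))
  r <- icc(flat, design = "intra")
  expect_true(r$degenerate)
  expect_true(is.na(r$icc))
  expect_equal(r$typical_error, 0)
  # duplicated rater: identical columns with real between-subject variance
  base <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         hct_pct = c(40, 43, 46, 49))
  dup <- trial_table(dplyr::bind_rows(
    dplyr::mutate(base, rater = "r1", method = "app", trial = 1),
    dplyr::mutate(base, rater = "r2", method = "app", trial = 1)))
  r2 <- icc(dup, design = "inter")
  expect_equal(r2$icc, 1)
  expect_equal(r2$typical_error, 0)
})

test_that("ICC is shift invariant and typical error ignores subject offsets", {
  tt <- simulate_trial_table(n_samples = 8, trials = 3, seed = 5)
  r1 <- icc(tt, design = "intra")
  tt2 <- tt
  tt2$hct_pct <- tt2$hct_pct + 3
  r2 <- icc(tt2, design = "intra")
  expect_equal(r1$icc, r2$icc, tolerance = 1e-9)
  expect_equal(r1$typical_error, r2$typical_error, tolerance = 1e-9)
  # subject-specific constants change ICC but not typical error
  tt3 <- tt
  tt3$hct_pct <- tt3$hct_pct + 2 * as.integer(factor(tt3$sample_id))
  r3 <- icc(tt3, design = "intra")
  expect_equal(r1$typical_error, r3$typical_error, tolerance = 1e-9)
})

test_that("unbalanced reliability designs are rejected", {
  tt <- simulate_trial_table(n_samples = 4, trials = 3, seed = 2)
  expect_error(icc(tt[-1, ], design = "intra"), class = "microhct_design_error")
  expect_error(icc(tt, design = "inter"), class = "microhct_design_error")
})

test_that("Pearson correlation matches direct covariance arithmetic", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1)
  withr::local_seed(3)
  x <- runif(6, 38, 48); y <- runif(6, 38, 48)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- pearson_r(x, y)
  expect_equal(r$r, direct, tolerance = 1e-12)
  tstat <- direct * sqrt(4 / (1 - direct^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), 1:3), class = "microhct_undefined_correlation")
})

test_that("repeated-measures ANOVA matches an explicit sums-of-squares oracle", {
  grid <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    condition = rep(c("a", "b"), 3),
    hct_pct = c(42, 43.5, 44, 44.4, 40.8, 42.1)
  )
  res <- rm_anova(grid)
  m <- matrix(grid$hct_pct, nrow = 3, byrow = TRUE)
  ms <- oracle_ms(m)  # rows = subjects, cols = conditions
  ss_eff <- ms$msc * 1
  ss_err <- ms$mse * 2
  expect_equal(res$statistic, ms$msc / ms$mse, tolerance = 1e-9)
  expect_equal(res$partial_eta_sq, ss_eff / (ss_eff + ss_err), tolerance = 1e-9)
  expect_equal(res$p_value, pf(ms$msc / ms$mse, 1, 2, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("identical conditions give zero effect and eta squared stays in [0,1]", {
  flat <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3", "s4"), each = 3),
    condition = rep(c("a", "b", "c"), 4),
    hct_pct = rep(c(42, 44, 46, 41), each = 3)
  )
  res <- rm_anova(flat)
  expect_equal(res$partial_eta_sq, 0)
  withr::local_seed(29)
  for (i in 1:100) {
    g <- tidyr::expand_grid(sample_id = paste0("s", 1:4),
                            condition = c("a", "b", "c"))
    g$hct_pct <- runif(12, 38, 48)
    e <- rm_anova(g)$partial_eta_sq
    expect_true(e >= 0 && e <= 1)
  }
  expect_error(rm_anova(flat[-1, ]), class = "microhct_design_error")
})

test_that("Bonferroni paired t tests adjust and cap p-values", {
  g <- tidyr::expand_grid(sample_id = paste0("s", 1:6),
                          condition = c("a", "b", "c", "d", "e"))
  withr::local_seed(13)
  g$hct_pct <- runif(nrow(g), 40, 46)
  single <- paired_t_bonferroni(g, comparisons = list(c("a", "b")))
  expect_equal(single$p_adjusted, single$p_value)
  multi <- paired_t_bonferroni(g, comparisons = list(c("a", "b"), c("a", "c"),
                                                     c("a", "d"), c("a", "e")))
  expect_equal(multi$p_adjusted, pmin(1, multi$p_value * 4))
  expect_true(all(multi$p_adjusted <= 1))
  # identical conditions: t = 0, adjusted p capped at 1
  g2 <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("s", 1:5), condition = "a",
                   hct_pct = c(40, 42, 44, 46, 48)),
    tibble::tibble(sample_id = paste0("s", 1:5), condition = "b",
                   hct_pct = c(40, 42, 44, 46, 48)))
  same <- paired_t_bonferroni(g2, comparisons = list(c("a", "b")))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_adjusted, 1)
})

test_that("Cohen's d follows the pooled-SD formula with interpretation bands", {
  d <- cohens_d(c(0, 2), c(2, 4))
  expect_equal(d$cohens_d, -2 / sqrt(2), tolerance = 1e-12)
  expect_equal(d$band, "large")
  eq <- cohens_d(c(1, 3), c(3, 1))
  expect_equal(eq$cohens_d, 0)
  expect_error(cohens_d(c(2, 2), c(2, 2)), class = "microhct_undefined_effect")
  withr::local_seed(41)
  for (i in 1:20) {
    a <- runif(6, 38, 48); b <- runif(6, 38, 48)
    expect_equal(cohens_d(a, b)$cohens_d, -cohens_d(b, a)$cohens_d,
                 tolerance = 1e-12)
    k <- runif(1, 0.1, 5)
    expect_equal(cohens_d(k * a, k * b)$cohens_d, cohens_d(a, b)$cohens_d,
                 tolerance = 1e-9)
  }
})

test_that("effect-size bands use the published thresholds", {
  expect_equal(cohens_d(c(0, 1, 2), c(0.3, 1.3, 2.3))$band, "small")  # |d| = 0.3
  bands <- vapply(c(0.01, 0.05, 0.2, 0.25, 0.79, 0.9),
                  function(e) microhct:::band_eta(e), character(1))
  expect_identical(bands, c("negligible", "small", "medium", "medium",
                            "large", "large"))
  dd <- vapply(c(0.1, 0.2, 0.49, 0.5, 0.8, -1.2),
               function(x) microhct:::band_d(x), character(1))
  expect_identical(dd, c("negligible", "small", "small", "medium",
                         "large", "large"))
})

test_that("trial tables validate their invariants", {
  good <- simulate_trial_table(n_samples = 3, trials = 2, seed = 1)
  expect_s3_class(good, "trial_table")
  expect_error(trial_table(good[c(1, 1), ]), class = "microhct_invalid_table")
  bad <- good
  bad$hct_pct[1] <- 150
  expect_error(trial_table(bad), class = "microhct_invalid_table")
  expect_error(trial_table(data.frame(x = 1)), class = "microhct_invalid_table")
})
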