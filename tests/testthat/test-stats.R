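test_that("correlations are exact for perfect linear and monotone data", {
  x <- c(1.3, 2.1, 4.8, 7.2, 9.9, 12.4)
  r1 <- correlation_analysis(x, 2 * x + 1)
  expect_equal(r1$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r1$spearman_rho, 1, tolerance = 1e-12)
  expect_identical(unname(r1$verdicts["pearson"]), "significant")
  r2 <- correlation_analysis(x, exp(-x))
  expect_equal(r2$spearman_rho, -1, tolerance = 1e-12)
  expect_lt(abs(r2$pearson_r), 1)
  ## report invariants
  expect_true(abs(r1$pearson_r) <= 1 && abs(r1$spearman_rho) <= 1)
  expect_true(r1$pearson_p >= 0 && r1$pearson_p <= 1)
})

test_that("spearman matches the brute-force rank formula without ties", {
  set.seed(31)
  for (k in 1:5) {
    x <- sample(seq(1, 50, by = 0.7), 5)
    y <- sample(seq(2, 60, by = 0.9), 5)
    ## exhaustive-sort rank oracle
    rank_of <- function(v) vapply(v, function(vi) sum(v <= vi), numeric(1))
    d <- rank_of(x) - rank_of(y)
    rho_formula <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
    rep <- correlation_analysis(x, y)
    expect_equal(rep$spearman_rho, rho_formula, tolerance = 1e-12)
  }
})

test_that("spearman equals pearson applied to ranks when untied", {
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20)
  rep <- correlation_analysis(x, y)
  expect_equal(rep$spearman_rho, cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("correlation is invariant under affine / monotone transforms", {
  set.seed(12)
  x <- rnorm(15); y <- x + rnorm(15, sd = 0.5)
  base <- correlation_analysis(x, y)
  aff <- correlation_analysis(3 * x - 7, -2 * y + 1)
  expect_equal(abs(aff$pearson_r), abs(base$pearson_r), tolerance = 1e-12)
  expect_equal(aff$pearson_r, -base$pearson_r, tolerance = 1e-12)
  mono <- correlation_analysis(x, exp(y))
  expect_equal(mono$spearman_rho, base$spearman_rho, tolerance = 1e-12)
})

test_that("degenerate correlation inputs are flagged, not computed", {
  expect_error(correlation_analysis(1:3, 1:4), "equal length")
  expect_error(correlation_analysis(c(1, 2), c(2, 3)), "at least 3")
  expect_error(correlation_analysis(c(1, 2, NA), c(1, 2, 3)), "finite")
  flagged <- correlation_analysis(rep(1, 5), rnorm(5))
  expect_match(flagged$flag, "constant")
  expect_true(is.na(flagged$pearson_r))
})

test_that("normality screening reports Shapiro-Wilk per variable", {
  set.seed(2)
  x <- rnorm(30); y <- runif(30)
  rep <- correlation_analysis(x, y)
  expect_length(rep$shapiro, 2)
  expect_equal(rep$shapiro[[1]][["W"]],
               unname(shapiro.test(x)$statistic), tolerance = 1e-12)
  expect_equal(rep$shapiro[[2]][["p"]], shapiro.test(y)$p.value,
               tolerance = 1e-12)
})

test_that("grid study reporting orders levels and flags failures", {
  runner <- function(level) {
    vals <- c(coarse = 6.0, medium = 5.5, fine = 5.4, very_fine = 5.39)
    list(icp = vals[[level]], converged = TRUE)
  }
  rep <- grid_independence(runner = runner)
  expect_equal(rep$levels$icp_cmH2O, c(6.0, 5.5, 5.4, 5.39))
  expect_length(rep$successive_diff_pct, 3)
  expect_true(all(diff(rep$successive_diff_pct) <= 0))
  ## identical values at two levels -> 0% difference
  rep0 <- grid_independence(levels = c("fine", "very_fine"),
                            runner = function(l) list(icp = 5.4,
                                                      converged = TRUE))
  expect_equal(rep0$successive_diff_pct, 0)
  ## a non-converged level is excluded with a warning
  expect_warning(
    rep_bad <- grid_independence(runner = function(l)
      list(icp = 5, converged = l != "medium")),
    "non-converged")
  expect_equal(sum(rep_bad$levels$converged), 3)
  expect_error(grid_independence(levels = "coarse", runner = runner),
               "at least 2")
})

test_that("validation comparison reports percent differences and r", {
  calc <- c(18, 22, 26, 30, 34)
  same <- validation_compare(calc, calc)
  expect_equal(same$max_diff_pct, 0)
  expect_equal(same$correlation$pearson_r, 1, tolerance = 1e-12)
  ## single pair: difference defined, correlation flagged
  single <- validation_compare(20, 21)
  expect_equal(single$diff_pct, 100 / 21, tolerance = 1e-9)
  expect_identical(single$correlation, "insufficient-n")
  ## zero measured value flagged, excluded
  z <- validation_compare(c(10, 20, 30, 40), c(0, 21, 29, 41))
  expect_equal(z$n_flagged, 1)
  expect_true(is.na(z$diff_pct[1]))
})

test_that("figures are written as image files", {
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  rep <- correlation_analysis(x, y)
  p1 <- tempfile(fileext = ".png")
  save_correlation_plot(x, y, rep, p1)
  expect_gt(file.size(p1), 1000)
  gs <- grid_independence(runner = function(l)
    list(icp = 5 + 0.01 * runif(1), converged = TRUE))
  p2 <- tempfile(fileext = ".png")
  save_grid_study_plot(gs, p2)
  expect_gt(file.size(p2), 1000)
})

test_that("2% multiplicative noise keeps validation errors small, r high", {
  ok_diff <- 0; ok_r <- 0; n_rep <- 50
  for (s in seq_len(n_rep)) {
    truth <- seq(15, 35, length.out = 10)        # spans > 2x range
    m <- generate_monitored_icp(truth, 0.02, seed = s)
    vc <- validation_compare(truth, m$readings)
    if (vc$max_diff_pct < 6) ok_diff <- ok_diff + 1
    if (vc$correlation$pearson_r > 0.9) ok_r <- ok_r + 1
  }
  expect_gte(ok_diff / n_rep, 0.9)
  expect_gte(ok_r / n_rep, 0.95)
})
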