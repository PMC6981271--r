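# frozen from textbook Welch formulas with numerical integration of the
# t density (rel.tol 1e-13); pt() agrees to 8 digits independently
welch_123_456 <- list(t = -3.674234614174767, df = 4,
                      p = 0.021311641128757)

test_that("welch_t_test reproduces the textbook worked example", {
  res <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t_stat, welch_123_456$t, tolerance = 1e-12)
  expect_equal(res$df, welch_123_456$df, tolerance = 1e-12)
  expect_equal(res$p_value, welch_123_456$p, tolerance = 1e-10)
})

test_that("welch_t_test handles identical and degenerate groups", {
  g <- c(0.1, 0.2, 0.3)
  same <- welch_t_test(g, g)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  # both variances zero, equal means: no evidence, p = 1
  flat <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$p_value, 1)
  expect_false(flat$floored)

  # both variances zero, unequal means: maximal evidence at the floor
  sep <- welch_t_test(c(2, 2, 2), c(3, 3, 3))
  expect_equal(sep$p_value, 1e-300)
  expect_true(sep$floored)
  expect_equal(sep$t_stat, -Inf)

  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("welch_t_test is antisymmetric and agrees with stats::t.test", {
  set.seed(101)
  for (i in 1:50) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    g1 <- rnorm(n1, sd = runif(1, 0.5, 2))
    g2 <- rnorm(n2, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    mine <- welch_t_test(g1, g2)
    flipped <- welch_t_test(g2, g1)
    expect_identical(flipped$t_stat, -mine$t_stat)
    expect_identical(flipped$p_value, mine$p_value)
    ref <- stats::t.test(g1, g2, var.equal = FALSE)
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("differential table: null and two-fold proteins behave as expected", {
  design <- toy_design()
  # synthetic matrix: protein A identical in every sample, protein B with an
  # exact 2:1 ratio of condition means
  mat <- rbind(A = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),
               B = c(0.4, 0.5, 0.3, 0.25, 0.1, 0.25))
  colnames(mat) <- design$sample_id
  d <- differential_table(mat, design)
  expect_equal(d$a[d$accession == "B"], 1)     # mean 0.4 vs 0.2
  expect_equal(d$a[d$accession == "A"], 0)
  expect_equal(d$p_value[d$accession == "A"], 1)
  expect_equal(d$b[d$accession == "A"], 0)
  expect_equal(d$accession, sort(d$accession))
})

test_that("differential table matches an independent straight-line oracle", {
  sim <- simulate_pulldown(simulation_config(n_background = 5L,
                                             n_spiked_P = 0L,
                                             n_spiked_NP = 0L, seed = 3L))
  nsaf <- compute_nsaf(sim$records, sim$design)
  got <- differential_table(nsaf, sim$design)

  # straight-line recomputation sharing no package code
  p_cols <- c("P1", "P2", "P3"); np_cols <- c("NP1", "NP2", "NP3")
  for (acc in rownames(nsaf)) {
    x <- nsaf[acc, p_cols]; y <- nsaf[acc, np_cols]
    mp <- sum(x) / 3; mn <- sum(y) / 3
    vx <- sum((x - mp)^2) / 2; vy <- sum((y - mn)^2) / 2
    tt <- (mp - mn) / sqrt(vx / 3 + vy / 3)
    dfree <- (vx / 3 + vy / 3)^2 / ((vx / 3)^2 / 2 + (vy / 3)^2 / 2)
    pp <- 2 * stats::pt(abs(tt), dfree, lower.tail = FALSE)
    row <- got[got$accession == acc, ]
    expect_equal(row$a, log2(mp / mn), tolerance = 1e-10)
    expect_equal(row$t_stat, tt, tolerance = 1e-10)
    expect_equal(row$df, dfree, tolerance = 1e-10)
    expect_equal(row$p_value, pp, tolerance = 1e-10)
    expect_equal(row$b, -10 * log10(pp), tolerance = 1e-10)
  }
})

test_that("b is a monotone decreasing transform of p, with a working floor", {
  p <- sort(runif(100, 1e-6, 1))
  b <- -10 * log10(p)
  expect_true(all(diff(b) <= 0))

  design <- toy_design()
  mat <- rbind(A = c(1, 1, 1, 2, 2, 2) / 9)  # zero variance, unequal means
  colnames(mat) <- design$sample_id
  d <- differential_table(mat, design, p_floor = 1e-50)
  expect_equal(d$p_value, 1e-50)
  expect_true(d$p_floored)
  expect_equal(d$b, 500)
  # configurable log base for the significance axis
  d2 <- differential_table(mat, design, p_floor = 1e-50, log_base = exp(1))
  expect_equal(d2$b, -10 * log(1e-50))
})

test_that("null p-values are near-uniform at realistic coverage", {
  # both conditions from the same count model, at the per-protein coverage
  # of real identification lists (~15 expected counts per reported protein),
  # where the t-test's calibration is meaningfully testable
  cfg <- simulation_config(n_background = 2000L, n_spiked_P = 0L,
                           n_spiked_NP = 0L, depth_mean = 30000,
                           seed = 601L)
  sim <- simulate_pulldown(cfg)
  nsaf <- compute_nsaf(sim$records, sim$design)
  d <- differential_table(nsaf, sim$design)
  ks <- suppressWarnings(stats::ks.test(d$p_value, "punif")$statistic)
  expect_lt(unname(ks), 0.1)
})
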