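test_that("stochastic operations are bit-reproducible from their seed", {
  gp <- planted_cohort(n = 200, amplitude = 0.2, seed = 30)
  a <- shift_null(gp$seqs, n_iter = 20, seed = 77)
  b <- shift_null(gp$seqs, n_iter = 20, seed = 77)
  expect_identical(a$values, b$values)
  c1 <- bootstrap_magnitudes(gp$seqs, sample_size = 100, n_boot = 15,
                             seed = 78)
  c2 <- bootstrap_magnitudes(gp$seqs, sample_size = 100, n_boot = 15,
                             seed = 78)
  expect_identical(c1$values, c2$values)
  expect_false(identical(a$values,
                         shift_null(gp$seqs, n_iter = 20, seed = 78)$values))
})

test_that("the shift null rejects a strong plant and accepts a null cohort", {
  gp <- planted_cohort(n = 600, amplitude = 0.25, seed = 31)
  obs <- periodicity_stat(gp$seqs)$magnitude10
  nd <- shift_null(gp$seqs, n_iter = 300, seed = 32)
  expect_gt(obs, max(nd$values))

  g0 <- planted_cohort(n = 600, amplitude = 0, seed = 33)
  obs0 <- periodicity_stat(g0$seqs)$magnitude10
  nd0 <- shift_null(g0$seqs, n_iter = 300, seed = 34)
  expect_gt(obs0, quantile(nd0$values, 0.0025))
  expect_lt(obs0, quantile(nd0$values, 0.9975))
})

test_that("shifting randomizes phase: a small plant is abolished below a quarter of observed", {
  ## 1-9 bp shifts leave a coherent residual of amplitude a/9, so complete
  ## abolition (to sampling-noise level) is the regime where that residual
  ## is below the noise floor.
  ratios <- vapply(1:5, function(r) {
    gp <- planted_cohort(n = 1000, amplitude = 0.05, seed = 400 + r)
    obs <- periodicity_stat(gp$seqs)$magnitude10
    nd <- shift_null(gp$seqs, n_iter = 60, seed = 500 + r)
    median(nd$values) / obs
  }, numeric(1))
  expect_true(all(ratios < 0.25))
})

test_that("zero shifts are rejected as null draws", {
  gp <- planted_cohort(n = 150, amplitude = 0, seed = 35)
  expect_error(shift_null(gp$seqs, shift_min = 0, n_iter = 5, seed = 1),
               "shift_min")
})

test_that("a global per-iteration shift preserves the magnitude (phase invariance)", {
  gp <- planted_cohort(n = 500, amplitude = 0.25, seed = 36)
  obs <- periodicity_stat(gp$seqs)$magnitude10
  ndg <- shift_null(gp$seqs, n_iter = 30, seed = 37, per_sequence = FALSE)
  expect_gt(min(ndg$values), 0.8 * obs)
})

test_that("bootstrap magnitudes separate planted groups and honor contracts", {
  hi <- planted_cohort(n = 400, amplitude = 0.2, seed = 38)
  lo <- planted_cohort(n = 400, amplitude = 0, seed = 39)
  bh <- bootstrap_magnitudes(hi$seqs, sample_size = 200, n_boot = 300,
                             seed = 40)
  bl <- bootstrap_magnitudes(lo$seqs, sample_size = 200, n_boot = 300,
                             seed = 41)
  expect_lt(compare_groups(bl, bh, alternative = "less"), 1e-10)

  ## single draw and sample_size == population are valid
  expect_length(bootstrap_magnitudes(hi$seqs, sample_size = 400, n_boot = 1,
                                     seed = 42)$values, 1L)
  full <- bootstrap_magnitudes(hi$seqs, sample_size = 400, n_boot = 50,
                               seed = 43)
  expect_gt(stats::sd(full$values), 0)
  expect_error(bootstrap_magnitudes(hi$seqs, sample_size = 10, n_boot = 2,
                                    seed = 1), "sample_size")
})

test_that("bootstrap mean approaches the full-set magnitude as samples grow", {
  gp <- planted_cohort(n = 800, amplitude = 0.1, seed = 44)
  target <- periodicity_stat(gp$seqs)$magnitude10
  bias <- vapply(c(250L, 500L, 1000L), function(m) {
    abs(mean(bootstrap_magnitudes(gp$seqs, sample_size = m, n_boot = 150,
                                  seed = 45)$values) - target)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("normality diagnostic accepts normal draws and rejects uniform ones", {
  set.seed(46)
  ok <- 0L
  for (r in 1:50) {
    d <- rotasig:::new_null_distribution(rnorm(500), "bootstrap", r)
    if (normality_check(d)$p_value > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 45L)  # calibration: ~1% nominal rejection
  unif <- rotasig:::new_null_distribution(runif(5000), "bootstrap", 1)
  expect_lt(normality_check(unif)$p_value, 1e-5)
  const <- rotasig:::new_null_distribution(rep(1, 200), "bootstrap", 1)
  expect_error(normality_check(const), "degenerate")
  expect_error(normality_check(rnorm(50)), "100")
})

test_that("rank-sum comparison is calibrated and detects separation", {
  set.seed(47)
  ps <- replicate(200, compare_groups(rnorm(40), rnorm(40)))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(compare_groups(rnorm(100), rnorm(100) + 50), 1e-15)
  ## power monotone in shift
  pw <- vapply(c(0.2, 0.5, 1), function(d) {
    mean(replicate(50, compare_groups(rnorm(30), rnorm(30) + d,
                                      alternative = "less") < 0.05))
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("label association test finds nested labels and stays calibrated", {
  set.seed(48)
  n <- 2000
  a <- rbinom(n, 1, 0.1) == 1
  b <- a | (rbinom(n, 1, 0.05) == 1)  # every a=1 has b=1
  res <- label_association_test(a, b, n_perm = 500, seed = 49)
  expect_equal(res$p_value, 1 / 501)

  ident <- label_association_test(a, a, n_perm = 200, seed = 50)
  expect_equal(ident$statistic, sum(a))
  expect_equal(ident$p_value, 1 / 201)

  ps <- replicate(100, {
    x <- rbinom(300, 1, 0.4) == 1
    y <- rbinom(300, 1, 0.4) == 1
    label_association_test(x, y, n_perm = 99,
                           seed = sample.int(1e6, 1))$p_value
  })
  ## roughly uniform under independence
  expect_gt(mean(ps < 0.2), 0.1)
  expect_lt(mean(ps < 0.2), 0.35)

  expect_error(label_association_test(rep(TRUE, 10), rbinom(10, 1, 0.5)),
               "both classes")
})
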