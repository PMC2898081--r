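test_that("TRANSFAC-style PWM blocks round-trip through write/read", {
  pw <- example_pwm()
  path <- withr::local_tempfile(fileext = ".txt")
  write_pwm(pw, path)
  back <- read_pwm(path)
  expect_equal(back$counts, pw$counts)
  expect_equal(back$prob, pw$prob)
  expect_equal(back$width, 7L)
  ## columns sum to 1 after load
  expect_equal(unname(colSums(back$prob)), rep(1, 7), tolerance = 1e-9)
})

test_that("PWM construction validates shape and handles zero pseudocount", {
  expect_error(pwm(matrix(1, 3, 5)), "4 rows")
  expect_error(pwm(matrix(1, 4, 1)), "width")
  m <- matrix(5, 4, 5); m[2, 3] <- 0
  expect_warning(p0 <- pwm(m, pseudocount = 0), "hard-zero")
  expect_equal(unname(p0$prob[2, 3]), 0)
})

test_that("a parser rejects ragged matrices and honors base order", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ID toy", "P0  T  G  C  A",
               "01  10  0  0  0", "02  0  10  0  0",
               "03  0  0  10  0", "04  0  0  0  10"), path)
  pw <- suppressWarnings(read_pwm(path, pseudocount = 0))
  ## consensus follows the declared T,G,C,A order
  expect_equal(unname(pw$prob["T", 1]), 1)
  expect_equal(unname(pw$prob["G", 2]), 1)
  expect_equal(unname(pw$prob["A", 4]), 1)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("P0 A C G T", "01 1 2 x 4"), bad)
  expect_error(read_pwm(bad), "ragged|non-numeric")
})

test_that("point-mass and uniform PWMs give the expected score series", {
  polyA <- pwm(rbind(rep(100, 7), 0, 0, 0), pseudocount = 0, id = "polyA") |>
    suppressWarnings()
  seq <- paste0(strrep("C", 10), strrep("A", 7), strrep("C", 10))
  sc <- scan_local_probability(seq, polyA)
  expect_equal(sc$values, c(rep(0, 10), 1, rep(0, 10)))

  unif <- pwm(matrix(1, 4, 7))
  scu <- scan_local_probability(strrep("ACGT", 10), unif)
  expect_equal(scu$values, rep(0.25^7, 34), tolerance = 1e-12)
  ## constant series: no offset exceeds the regional mean -> zero matches
  al <- aligned_seq_set(strrep("ACGT", 60), 100L)
  expect_equal(nrow(call_matches(al, unif, c(-50L, 80L), c(0L, 40L))), 0L)
})

test_that("hand-computed product scores match on a 2-column toy matrix", {
  toy <- pwm(matrix(c(0.9, 0.1, 0, 0,
                      0, 0, 0.8, 0.2), 4, 2), pseudocount = 0) |>
    suppressWarnings()
  sc <- scan_local_probability("AGAT", toy)
  ## windows AG, GA, AT: 0.9*0.8, 0.1*0, 0.9*0.2
  expect_equal(sc$values, c(0.72, 0, 0.18))
})

test_that("vectorized scan equals the brute-force window-product oracle", {
  set.seed(60)
  pw <- example_pwm(70)
  for (r in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 120, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    got <- scan_local_probability(s, pw)$values
    want <- oracle_pwm_scores(s, pw$prob)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("match calling finds a planted consensus and enforces uniqueness", {
  set.seed(61)
  pw <- example_pwm(90)
  cfg <- synth_config(n_promoters = 200, upstream = 100, downstream = 150,
                      motif = list(pwm = example_pwm(98), offset = 20L,
                                   fraction = 1), seed = 62)
  gp <- generate_promoters(cfg)
  mm <- call_matches(gp$seqs, pw, scan_region = c(-100L, 149L),
                     match_region = c(0L, 40L))
  expect_gt(nrow(mm), 150)
  expect_true(all(mm$local_prob > mm$regional_mean))
  off_mode <- as.integer(names(which.max(table(mm$offset))))
  expect_equal(off_mode, 20L)

  ## two planted copies break uniqueness
  two <- gp$seqs
  seq1 <- two$sequences[1]
  ins <- substr(seq1, two$offset_of_tss + 21L, two$offset_of_tss + 27L)
  substr(seq1, two$offset_of_tss + 6L, two$offset_of_tss + 12L) <- ins
  two$sequences[1] <- seq1
  mm1 <- call_matches(aligned_seq_set(seq1, two$offset_of_tss, "dup"), pw,
                      c(-100L, 149L), c(0L, 40L), require_unique = TRUE)
  expect_equal(nrow(mm1), 0L)
  mm2 <- call_matches(aligned_seq_set(seq1, two$offset_of_tss, "dup"), pw,
                      c(-100L, 149L), c(0L, 40L), require_unique = FALSE)
  expect_gte(nrow(mm2), 2L)
  expect_true(all(!mm2$unique_in_window))
})

test_that("background promoters produce few spurious unique matches", {
  ## the regional-arithmetic-mean threshold admits some background
  ## exceedances; the discriminative property is that unplanted cohorts sit
  ## far below planted recovery (cf. the shuffle-control test)
  cfg <- synth_config(n_promoters = 400, upstream = 500, downstream = 510,
                      seed = 63)
  gp <- generate_promoters(cfg)
  mm <- call_matches(gp$seqs, example_pwm(85), c(-500L, 500L), c(0L, 40L))
  expect_lt(nrow(mm) / 400, 0.25)
})

test_that("column shuffling preserves column content and exposes planted motifs", {
  pw <- example_pwm(90)
  cfg <- synth_config(n_promoters = 150, upstream = 100, downstream = 150,
                      motif = list(pwm = example_pwm(98), offset = 15L,
                                   fraction = 0.8), seed = 64)
  gp <- generate_promoters(cfg)
  ctrl <- column_shuffle_control(gp$seqs, pw, n_shuffles = 30, seed = 65,
                                 scan_region = c(-100L, 149L))
  expect_gt(ctrl$params$observed, max(ctrl$values))
  expect_lte(ctrl$params$p_value, 1 / 31)

  ## determinism
  ctrl2 <- column_shuffle_control(gp$seqs, pw, n_shuffles = 30, seed = 65,
                                  scan_region = c(-100L, 149L))
  expect_identical(ctrl$values, ctrl2$values)

  ## a column-constant PWM is invariant under shuffling
  unifish <- pwm(matrix(c(40, 20, 20, 20), 4, 7))
  ctrl3 <- column_shuffle_control(gp$seqs, unifish, n_shuffles = 10,
                                  seed = 66, scan_region = c(-100L, 149L))
  expect_true(all(ctrl3$values == ctrl3$params$observed))
  expect_equal(ctrl3$params$p_value, 1)
})

test_that("match sets are invariant to per-column count rescaling", {
  counts <- example_pwm(80)$counts
  scaled <- sweep(counts, 2, c(1, 10, 2, 5, 1, 3, 7), "*")
  cfg <- synth_config(n_promoters = 100, upstream = 100, downstream = 150,
                      motif = list(pwm = example_pwm(98), offset = 10L,
                                   fraction = 0.5), seed = 67)
  gp <- generate_promoters(cfg)
  m1 <- call_matches(gp$seqs, pwm(counts, pseudocount = 0) |>
                       suppressWarnings(), c(-100L, 149L), c(0L, 40L))
  m2 <- call_matches(gp$seqs, pwm(scaled, pseudocount = 0) |>
                       suppressWarnings(), c(-100L, 149L), c(0L, 40L))
  expect_equal(m1$tss_id, m2$tss_id)
  expect_equal(m1$offset, m2$offset)
})
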