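test_that("a single tag smears into a 1/70 plateau under the sliding window", {
  ts <- tss_set("t1", "chr1", 1000L, "+", 5L)
  tg <- tag_set("chr1", 1060L, "+")  # offset +60
  prof <- tag_density_profile(tg, ts, window = c(-200L, 200L))
  df <- as.data.frame(prof)
  inwin <- df$offset >= 25 & df$offset <= 94
  expect_equal(df$value[inwin], rep(1 / 70, 70))
  expect_equal(sum(df$value[!inwin] > 1 / 70 + 1e-12), 0)
})

test_that("reverse tags never leak into the forward profile", {
  ts <- tss_set("t1", "chr1", 1000L, "+", 5L)
  tg <- tag_set(c("chr1", "chr1"), c(1060L, 1070L), c("+", "-"))
  fwd <- tag_density_profile(tg, ts, window = c(-100L, 100L),
                             strand = "forward", smooth_bp = 1L)
  rev <- tag_density_profile(tg, ts, window = c(-100L, 100L),
                             strand = "reverse", smooth_bp = 1L)
  expect_equal(sum(fwd$values), 1)
  expect_equal(sum(rev$values), 1)
  expect_equal(which(fwd$values > 0) - 101L, 60L)
  expect_equal(which(rev$values > 0) - 101L, 70L)
})

test_that("per-TSS averaging makes a duplicated TSS a no-op", {
  tg <- tag_set(rep("chr1", 3), c(1050L, 1080L, 1120L), rep("+", 3))
  one <- tss_set("a", "chr1", 1000L, "+", 5L)
  two <- tss_set(c("a", "b"), c("chr1", "chr1"), c(1000L, 1000L),
                 c("+", "+"), c(5L, 5L))
  p1 <- tag_density_profile(tg, one, window = c(-200L, 200L))
  p2 <- tag_density_profile(tg, two, window = c(-200L, 200L))
  expect_equal(p1$values, p2$values)
})

test_that("unsmoothed counts conserve the number of in-window tags", {
  set.seed(70)
  ts <- tss_set(c("a", "b"), c("chr1", "chr2"), c(5000L, 3000L), c("+", "-"),
                c(5L, 5L))
  tg <- tag_set(sample(c("chr1", "chr2"), 200, replace = TRUE),
                sample(2500:5500, 200, replace = TRUE),
                sample(c("+", "-"), 200, replace = TRUE))
  pf <- tag_density_profile(tg, ts, window = c(-300L, 300L),
                            strand = "forward", smooth_bp = 1L,
                            per_tss = FALSE)
  pr <- tag_density_profile(tg, ts, window = c(-300L, 300L),
                            strand = "reverse", smooth_bp = 1L,
                            per_tss = FALSE)
  rel <- rotasig:::tags_relative_to_tss(tg, ts, c(-300L, 300L))
  expect_equal(sum(pf$values) + sum(pr$values), nrow(rel))
  ## smoothing preserves total area up to edge shrinkage
  pfs <- tag_density_profile(tg, ts, window = c(-300L, 300L),
                             strand = "forward", smooth_bp = 71L,
                             per_tss = FALSE)
  expect_equal(sum(pfs$values), sum(pf$values), tolerance = 0.15)
})

test_that("minus-strand TSSs mirror offsets and swap tag strands", {
  ## tag upstream in genome coordinates is downstream in transcript
  ## coordinates for a minus-strand TSS
  ts <- tss_set("m", "chr1", 1000L, "-", 5L)
  tg <- tag_set("chr1", 940L, "-")  # transcript offset +60, reads as forward
  counts <- region_tag_counts(tg, ts, region = c(40L, 200L))
  expect_equal(counts$score, 1L)
  fwd <- tag_density_profile(tg, ts, window = c(-100L, 100L),
                             strand = "forward", smooth_bp = 1L)
  expect_equal(which(fwd$values > 0) - 101L, 60L)

  ## mirror symmetry: flipping all strands and TSS orientation leaves the
  ## transcription-oriented profile unchanged
  ts_p <- tss_set("p", "chr1", 1000L, "+", 5L)
  tg_p <- tag_set("chr1", 1060L, "+")
  fwd_p <- tag_density_profile(tg_p, ts_p, window = c(-100L, 100L),
                               strand = "forward", smooth_bp = 1L)
  expect_equal(fwd$values, fwd_p$values)
})

test_that("region tag counts use closed bounds and brute-force containment", {
  ts <- tss_set("t", "chr1", 1000L, "+", 5L)
  tg <- tag_set(rep("chr1", 4), c(1040L, 1100L, 1200L, 1201L),
                rep("+", 4))
  expect_equal(region_tag_counts(tg, ts, c(40L, 200L))$score, 3L)
  expect_equal(region_tag_counts(tag_set(character(), integer(),
                                         character()), ts)$score, 0L)
})

test_that("quantile partition sizes and tie handling are deterministic", {
  sc <- data.frame(tss_id = sprintf("t%02d", 1:8), score = 8:1)
  qp <- quantile_partition(sc, 4L)
  expect_equal(unname(table(qp$group)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(qp$group[qp$score <= 2], c(1L, 1L))

  sc10 <- data.frame(tss_id = sprintf("t%02d", 1:10), score = runif(10))
  expect_equal(as.integer(table(quantile_partition(sc10, 3L)$group)),
               c(4L, 3L, 3L))

  tied <- data.frame(tss_id = sprintf("t%02d", 1:6), score = rep(1, 6))
  q1 <- quantile_partition(tied, 3L)
  q2 <- quantile_partition(tied[sample(6), ], 3L)
  expect_equal(q1$group[order(q1$tss_id)], q2$group[order(q2$tss_id)])
})

test_that("group periodicity recovers an intensity-coupled amplitude gradient", {
  groups <- data.frame(label = c("L", "M", "H"), fraction = rep(1 / 3, 3),
                       amplitude = c(0.02, 0.10, 0.25))
  cfg <- synth_config(n_promoters = 600, upstream = 20, downstream = 220,
                      groups = groups, seed = 71)
  gp <- generate_promoters(cfg)
  ## simulated mark score increases with the planted amplitude group
  score <- as.numeric(factor(gp$truth$group, levels = c("L", "M", "H"))) * 10
  part <- data.frame(tss_id = names(gp$truth$group), score = score,
                     group = as.integer(score / 10))
  res <- periodicity_by_group(gp$seqs, part, sample_size = 150,
                              n_boot = 200, seed = 72)
  expect_gt(res$trend$estimate, 0)
  expect_lt(res$trend$p_value, 1e-6)
  expect_true(all(res$pairwise < 1e-4))
  expect_true(all(diff(res$group_magnitude[as.character(1:3)]) > 0))

  expect_error(periodicity_by_group(gp$seqs, part[part$group == 1, ]),
               "2 groups")
  small <- part[c(1:50, 201:400), ]
  expect_error(periodicity_by_group(gp$seqs, small, sample_size = 150,
                                    n_boot = 50, seed = 1), "fewer than 100")
})

test_that("amplitude-constant groups show no systematic trend", {
  cfg <- synth_config(n_promoters = 400, upstream = 20, downstream = 220,
                      amplitude = 0.1, seed = 73)
  gp <- generate_promoters(cfg)
  rs <- vapply(1:6, function(r) {
    set.seed(500 + r)
    part <- data.frame(tss_id = gp$seqs$source_ids,
                       score = runif(400),
                       group = sample(rep(1:2, each = 200)))
    periodicity_by_group(gp$seqs, part, sample_size = 120, n_boot = 100,
                         seed = 600 + r)$trend$estimate
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.5)
})

test_that("tag BED ingestion maps 5' ends per strand", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t125\ttag1\t0\t+", "chr1\t99\t125\ttag2\t0\t-"),
             path)
  tg <- read_tags_bed(path)
  expect_equal(tg$pos, c(100L, 125L))
})
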