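# Control-region sampling, conservation statistics, cutoff calibration
# and the rank-sum test.

test_that("control regions are length-matched, intergenic and reproducible", {
  sim <- default_sim()
  nc <- sim$truth$cand_info[present == TRUE & conserved == TRUE, cand_id]
  cand <- annotation(sim$truth$cand_exons)
  ctrl <- sample_control_regions(sim$reference, subset_annotation(cand, nc),
                                 sim$truth$chrom_sizes, seed = 9L)
  tx <- subset_annotation(cand, nc)$transcripts
  expect_equal(ctrl$end - ctrl$start,
               tx[match(ctrl$transcript_id, transcript_id), spliced_length])
  spans <- sim$reference$transcripts
  for (i in seq_len(nrow(ctrl))) {
    hit <- spans[chrom == ctrl$chrom[i] & start < ctrl$end[i] &
                   end > ctrl$start[i]]
    expect_equal(nrow(hit), 0L)
  }
  ctrl2 <- sample_control_regions(sim$reference, subset_annotation(cand, nc),
                                  sim$truth$chrom_sizes, seed = 9L)
  expect_identical(ctrl, ctrl2)
})

test_that("conservation statistics match constant and step-track expectations", {
  flat <- signal_track(data.table::data.table(chrom = "c", start = 0L,
                                              end = 1000L, value = 1))
  region <- data.table::data.table(chrom = "c", start = 0L, end = 600L)
  st <- conservation_stats(flat, flat, region, base_cutoff = 0.972)
  expect_equal(st$fraction_conserved, 1)
  expect_equal(st$max_window_mean, 1)       # constant track
  step <- signal_track(data.table::data.table(
    chrom = "c", start = c(0L, 200L), end = c(200L, 1000L), value = c(0.9, 0.1)))
  st2 <- conservation_stats(flat, step, region, base_cutoff = 0.5)
  expect_equal(st2$max_window_mean, 0.9)    # best 200-bp window is the head
  # brute-force all-windows oracle on a random track
  set.seed(4)
  rnd <- signal_track(data.table::data.table(
    chrom = "c", start = seq(0L, 950L, 50L), end = seq(50L, 1000L, 50L),
    value = runif(20)))
  st3 <- conservation_stats(flat, rnd, region, base_cutoff = 0.5, window = 200L)
  v <- track_base_values(rnd, "c", 0L, 600L)
  wm <- max(vapply(1:(600 - 200 + 1), function(i) mean(v[i:(i + 199)]), 0))
  expect_equal(st3$max_window_mean, wm)
  # regions shorter than the window use the whole-region mean
  st4 <- conservation_stats(flat, rnd,
                            data.table::data.table(chrom = "c", start = 0L,
                                                   end = 100L),
                            base_cutoff = 0.5)
  expect_equal(st4$max_window_mean, mean(v[1:100]))
  expect_error(conservation_stats(flat, flat,
                                  data.table::data.table(chrom = "c",
                                                         start = integer(),
                                                         end = integer()),
                                  0.5), "empty region")
})

test_that("the calibrated base cutoff is the quantile of pooled control bases", {
  # uniform values on [0,1] -> 95th percentile ~ 0.95
  set.seed(12)
  runs <- data.table::data.table(chrom = "c", start = seq(0L, 9999L, 1L),
                                 end = seq(1L, 10000L, 1L), value = runif(10000))
  tr <- signal_track(runs)
  ctrl <- data.table::data.table(transcript_id = sprintf("t%d", 1:50),
                                 chrom = "c", start = seq(0L, 9800L, 200L)[1:50])
  ctrl[, end := start + 200L]
  cut <- calibrate_cutoffs(ctrl, tr, tr)
  expect_equal(cut$base_cutoff, 0.95, tolerance = 0.02)
  expect_error(calibrate_cutoffs(ctrl[1:5], tr, tr), "at least")
})

test_that("rank-sum p-values match enumeration and the normal approximation", {
  # frozen example: complete separation of 3 vs 3 gives p = 0.1
  expect_equal(rank_sum_test(1:3, 4:6)$p_value, 0.1)
  expect_equal(rank_sum_test(1:3, 4:6)$statistic, 0)
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  # bitmask-enumeration oracle incl. ties, small pooled sizes
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:5, 1L); m <- sample(2:5, 1L)
    a <- sample(1:6, n, replace = TRUE); b <- sample(1:6, m, replace = TRUE)
    expect_equal(rank_sum_test(a, b)$p_value, oracle_rank_sum_p(a, b))
  }
  # tie-free exact agrees with the closed-form distribution in wilcox.test
  for (i in 1:20) {
    n <- sample(2:8, 1L); m <- sample(2:8, 1L)
    a <- rnorm(n); b <- rnorm(m)
    expect_equal(rank_sum_test(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # large samples: normal approximation with continuity correction
  a <- rnorm(30); b <- rnorm(40, 1)
  expect_equal(rank_sum_test(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(rank_sum_test(rnorm(50), rnorm(50, 5))$p_value, 1e-6)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})
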