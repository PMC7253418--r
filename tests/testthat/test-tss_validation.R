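# TSS grouping, promoter metaprofiles, peak overlap and CAGE support.

test_that("TSS groups follow category and the +/-300 bp annotated interval", {
  ref <- make_ann(make_tx("r1", "g1", list(c(1000, 1200), c(1500, 1700),
                                           c(2000, 2200))))
  q <- make_ann(
    # novel isoform (novel junction + shared one), TSS 250 bp upstream
    make_tx("ni_close", "x", list(c(750, 1100), c(1300, 1700), c(2000, 2100))),
    # novel isoform with TSS 600 bp away from every annotated TSS
    make_tx("ni_far", "x", list(c(400, 500), c(1500, 1700), c(2000, 2100))),
    make_tx("ng", "y", list(c(8000, 8400))),
    make_tx("ex", "x", list(c(1000, 1200), c(1500, 1700), c(2000, 2150))))
  cmp <- classify_transcripts(q, ref)
  tss <- categorize_tss(cmp, q, ref)
  g <- setNames(tss$group, tss$transcript_id)
  expect_equal(unname(g["ni_close"]), "classic")   # 250 bp from annotated TSS
  expect_equal(unname(g["ni_far"]), "novel")       # 600 bp away
  expect_equal(unname(g["ng"]), "novel_gene")
  expect_equal(unname(g["ex"]), "annotated")
  # partition: classic + novel = novel_isoform count
  expect_equal(sum(g %in% c("classic", "novel")),
               sum(cmp$category == "novel_isoform"))
})

test_that("promoter profiles have 161 bins, centre on the TSS and reverse on minus", {
  flat <- signal_track(data.table::data.table(chrom = "c", start = 0L,
                                              end = 100000L, value = 2.5))
  p <- promoter_profile(flat, "c", 50000L, "+")
  expect_length(p, 161L)
  expect_true(all(p == 2.5))
  # single bump 1 kb upstream of a minus-strand TSS appears on the 5' side
  bump <- signal_track(data.table::data.table(chrom = "c", start = 50950L,
                                              end = 51050L, value = 10))
  pp <- promoter_profile(bump, "c", 50000L, "+")
  pm <- promoter_profile(bump, "c", 50000L, "-")
  expect_equal(rev(pp), pm)
  # genomically downstream is 5' for a minus-strand transcript, so the
  # bump sits in the first half of the oriented profile
  expect_gt(which.max(pp), 81L)
  expect_lt(which.max(pm), 81L)
})

test_that("profile bin means match per-base brute-force averaging", {
  sim <- default_sim()
  tr <- sim$tracks$h3k4me3
  info <- sim$truth$cand_info[present == TRUE & hc_tss == TRUE]
  set.seed(2)
  pick <- info[sample(.N, min(5L, .N))]
  for (i in seq_len(nrow(pick))) {
    p <- promoter_profile(tr, pick$chrom[i], pick$tss[i], pick$strand[i])
    starts <- pick$tss[i] - 4000L - 50L + 50L * (0:160)
    want <- vapply(starts, function(s) oracle_track_mean(tr, pick$chrom[i],
                                                         s, s + 100L), 0)
    if (pick$strand[i] == "-") want <- rev(want)
    expect_equal(p, want)
  }
})

test_that("high-confidence TSS calls honour the +/-500 bp window over merged peaks", {
  tss <- data.table::data.table(transcript_id = c("a", "b", "c"),
                                chrom = "c", tss = c(1000L, 3000L, 5000L))
  peaks <- list(data.table::data.table(chrom = "c", start = 950L, end = 1050L),
                data.table::data.table(chrom = "c", start = 2400L, end = 2499L))
  hc <- high_confidence_tss(tss, peaks)
  expect_equal(hc, c(TRUE, FALSE, FALSE))   # b's nearest peak ends 501 bp away
  # a peak present in only one stage file still confers confidence
  peaks2 <- c(peaks, list(data.table::data.table(chrom = "c", start = 4600L,
                                                 end = 4700L)))
  expect_equal(high_confidence_tss(tss, peaks2), c(TRUE, FALSE, TRUE))
})

test_that("CAGE support unions nonzero intervals across samples", {
  tss <- data.table::data.table(transcript_id = c("a", "b"),
                                chrom = "c", tss = c(1000L, 5000L))
  t1 <- signal_track(data.table::data.table(chrom = "c", start = 900L,
                                            end = 950L, value = 3))
  t0 <- signal_track(data.table::data.table(chrom = "c", start = 4000L,
                                            end = 4400L, value = 0))
  expect_equal(cage_supported(tss, list(t1, t0)), c(TRUE, FALSE))
  expect_equal(cage_supported(tss, list(t0)), c(FALSE, FALSE))  # zero runs
  # a nonzero run 600 bp away does not count
  t2 <- signal_track(data.table::data.table(chrom = "c", start = 5601L,
                                            end = 5700L, value = 1))
  expect_equal(cage_supported(tss, list(t2)), c(FALSE, FALSE))
})

test_that("mean H3K4me3 profile over marked promoters is bimodal around the TSS", {
  sim <- default_sim()
  info <- sim$truth$cand_info[present == TRUE & hc_tss == TRUE]
  pr <- promoter_profiles(sim$tracks$h3k4me3,
                          info[, .(transcript_id = cand_id, chrom, tss, strand)])
  mp <- colMeans(pr)
  centre <- mp[81L]
  left_peak <- max(mp[60:75])
  right_peak <- max(mp[87:102])
  expect_gt(left_peak, centre)
  expect_gt(right_peak, centre)
})
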