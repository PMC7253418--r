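# Exon-chain classification, merging, stage dynamics and saturation.

test_that("class codes follow the stated rules on hand-built cases", {
  ref <- make_ann(make_tx("r1", "g1", list(c(100, 200), c(300, 400), c(500, 600))),
                  make_tx("r2", "g2", list(c(5000, 5800))))
  # identical intron chain with different ends -> "="
  q <- make_ann(make_tx("q1", "x", list(c(150, 200), c(300, 400), c(500, 550))))
  expect_equal(classify_transcripts(q, ref)$code, "=")
  # contiguous sub-chain within the span -> "c"
  q <- make_ann(make_tx("q2", "x", list(c(320, 400), c(500, 580))))
  expect_equal(classify_transcripts(q, ref)$code, "c")
  # shares one junction, has a novel one -> "j"
  q <- make_ann(make_tx("q3", "x", list(c(150, 200), c(300, 350), c(450, 550))))
  cmp <- classify_transcripts(q, ref)
  expect_equal(cmp$code, "j")
  expect_equal(cmp$category, "novel_isoform")
  expect_equal(cmp$best_ref, "r1")
  # exon running >= 10 bp into an intron without splicing there -> "e"
  q <- make_ann(make_tx("q4", "x", list(c(150, 250))))
  expect_equal(classify_transcripts(q, ref)$code, "e")
  # no overlap with any reference -> "u"
  q <- make_ann(make_tx("q5", "x", list(c(9000, 9500))))
  cmp <- classify_transcripts(q, ref)
  expect_equal(cmp$code, "u")
  expect_equal(cmp$category, "novel_gene")
  expect_true(is.na(cmp$best_ref))
  # antisense and intronic fall into "other"
  q <- make_ann(make_tx("q6", "x", list(c(150, 250)), strand = "-"))
  cmp <- classify_transcripts(q, ref)
  expect_equal(cmp$code, "other")
  expect_equal(cmp$sub_label, "antisense")
  q <- make_ann(make_tx("q7", "x", list(c(210, 290))))
  cmp <- classify_transcripts(q, ref)
  expect_equal(cmp$sub_label, "intronic")
})

test_that("mono-exon equality needs 50% reciprocal overlap", {
  ref <- make_ann(make_tx("r", "g", list(c(1000, 2000))))
  q <- make_ann(make_tx("q", "x", list(c(1400, 2400))))   # 600/1000 both ways
  expect_equal(classify_transcripts(q, ref)$code, "=")
  q <- make_ann(make_tx("q", "x", list(c(1800, 3000))))   # 200/1200 fails
  expect_false(classify_transcripts(q, ref)$code == "=")
  # contained within one reference exon -> "c"
  q <- make_ann(make_tx("q", "x", list(c(1200, 1400))))
  expect_equal(classify_transcripts(q, ref)$code, "c")
})

test_that("classification matches the exhaustive oracle on random small annotations", {
  cfg <- sim_config(seed = 23L, n_genes = 9L, n_chroms = 1L, n_das = 0L,
                    stages = c("Oo", "1C"), transcripts_per_stage = 20L)
  ref <- simulate_reference(cfg)
  cand <- annotation(ref$truth$cand_exons)
  got <- classify_transcripts(cand, ref$reference)
  want <- oracle_classify(cand, ref$reference)
  m <- merge(got[, .(query_id, code)], want, by = "query_id")
  expect_equal(m$code.x, m$code.y)
})

test_that("merging collapses identical intron chains to extreme ends with provenance", {
  s1 <- make_ann(make_tx("a", "g", list(c(100, 200), c(300, 400))))
  s2 <- make_ann(make_tx("b", "g", list(c(50, 200), c(300, 480))))
  m <- merge_transcriptomes(list(st1 = s1, st2 = s2))
  expect_equal(nrow(m$annotation$transcripts), 1L)
  ex <- m$annotation$exons
  expect_equal(ex$start, c(50L, 300L))
  expect_equal(ex$end, c(200L, 480L))
  expect_equal(m$provenance$stages, "st1,st2")
  # disjoint sets concatenate
  s3 <- make_ann(make_tx("c", "g2", list(c(5000, 5100), c(5200, 5300))))
  m2 <- merge_transcriptomes(list(st1 = s1, st3 = s3))
  expect_equal(nrow(m2$annotation$transcripts), 2L)
  # mono-exon same-strand overlap collapses to the union span
  s4 <- make_ann(make_tx("d", "g3", list(c(9000, 9400))))
  s5 <- make_ann(make_tx("e", "g3", list(c(9300, 9800))))
  m3 <- merge_transcriptomes(list(a = s4, b = s5))
  expect_equal(m3$annotation$exons$start, 9000L)
  expect_equal(m3$annotation$exons$end, 9800L)
})

test_that("merging is idempotent", {
  sim <- default_sim()
  m1 <- merge_transcriptomes(sim$stage_sets)
  m2 <- merge_transcriptomes(list(again = m1$annotation))
  expect_equal(
    m1$annotation$exons[order(chrom, start, end), .(chrom, strand, start, end)],
    m2$annotation$exons[order(chrom, start, end), .(chrom, strand, start, end)])
})

test_that("merged category percentages sum to 100", {
  sim <- default_sim()
  m <- merge_transcriptomes(sim$stage_sets)
  cs <- category_summary(classify_transcripts(m$annotation, sim$reference))
  expect_equal(sum(cs$pct), 100, tolerance = 0.1)
})

test_that("stage dynamics counts gains against the later and losses against the earlier stage", {
  a <- make_ann(make_tx("A", "g", list(c(100, 200), c(300, 400))))
  ab <- make_ann(make_tx("A2", "g", list(c(100, 200), c(300, 400))),
                 make_tx("B", "h", list(c(9000, 9100), c(9200, 9300))))
  d <- stage_dynamics(a, ab)
  expect_equal(sort(d$gained), "B")
  expect_equal(d$gain_pct, 50)
  expect_equal(length(d$lost), 0L)
  d2 <- stage_dynamics(ab, a)
  expect_equal(sort(d2$lost), "B")
  expect_equal(d2$loss_pct, 50)
  # identical sets share everything
  d3 <- stage_dynamics(ab, ab)
  expect_equal(length(d3$gained), 0L)
  expect_equal(length(d3$lost), 0L)
})

test_that("saturation is monotone, order-invariant at the union and deterministic", {
  sim <- default_sim()
  sets <- sim$stage_sets[c("Oo", "1C", "2C")]
  s1 <- saturation_curve(sets, sim$reference, reps = 10L, seed = 42L)
  s2 <- saturation_curve(sets, sim$reference, reps = 10L, seed = 42L)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(apply(s1$counts, 1L, function(x) all(diff(x) >= 0))))
  expect_equal(length(unique(s1$counts[, 3L])), 1L)   # full union, any order
  expect_true(all(s1$lower <= s1$mean & s1$mean <= s1$upper))
  expect_error(saturation_curve(sets, sim$reference, reps = 1L), "reps")
})
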