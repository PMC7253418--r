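# Synthetic data generator: determinism, planted proportions, motif
# construction, ZGA/junction planting, file emission.

test_that("generation is deterministic under the seed and changes with it", {
  cfg <- sim_config(seed = 7L, n_genes = 9L, n_chroms = 1L, n_das = 2L,
                    transcripts_per_stage = 20L, stages = c("Oo", "1C", "2C"))
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$reference$exons, b$reference$exons)
  expect_identical(a$truth$junctions, b$truth$junctions)
  c_ <- simulate_reference(sim_config(seed = 8L, n_genes = 9L, n_chroms = 1L,
                                      transcripts_per_stage = 20L, n_das = 2L,
                                      stages = c("Oo", "1C", "2C")))
  expect_false(identical(as.character(a$genome), as.character(c_$genome)))
})

test_that("category proportions are apportioned exactly per stage", {
  expect_equal(isoatlas:::.apportion(c(0.6, 0.1, 0.2, 0.07, 0.03), 100L),
               c(60L, 10L, 20L, 7L, 3L))
  sim <- default_sim()
  members <- sim$truth$stage_members
  info <- sim$truth$cand_info
  das_ids <- c(sim$truth$das$incl_id, sim$truth$das$excl_id)
  for (s in sim$config$stages) {
    ids <- setdiff(members[stage == s, cand_id], das_ids)
    cats <- info[match(ids, cand_id), category]
    n_cat <- isoatlas:::.apportion(unname(sim$config$category_props),
                                   sim$config$transcripts_per_stage)
    # DAS-forced exacts aside, each category matches its apportioned count
    expect_gte(sum(cats == "exact"), n_cat[1L] - length(das_ids))
    expect_equal(sum(cats == "contained"), n_cat[2L])
    expect_equal(sum(cats == "novel_isoform"), n_cat[3L])
    expect_equal(sum(cats == "novel_gene"), n_cat[4L])
    expect_equal(sum(cats == "other"), n_cat[5L])
  }
})

test_that("forcing canonical_fraction = 1 makes every junction GT..AG", {
  cfg <- sim_config(seed = 3L, n_genes = 9L, n_chroms = 1L, n_das = 0L,
                    canonical_fraction = 1, stages = c("Oo", "1C"),
                    transcripts_per_stage = 20L)
  ref <- simulate_reference(cfg)
  expect_true(all(ref$truth$junctions$canonical))
  jn <- extract_junctions(ref$reference, ref$genome)
  expect_true(all(jn$motif5 == "GT" & jn$motif3 == "AG"))
})

test_that("planted canonical share lands inside binomial bounds of the rate", {
  sim <- default_sim()
  tru <- sim$truth$junctions
  bounds <- binom_bounds(nrow(tru), sim$config$canonical_fraction)
  expect_gte(mean(tru$canonical), bounds[1L])
  expect_lte(mean(tru$canonical), bounds[2L])
})

test_that("novel-gene candidates never touch reference exons", {
  sim <- default_sim()
  ng <- sim$truth$cand_info[category == "novel_gene", cand_id]
  ngex <- sim$truth$cand_exons[transcript_id %in% ng]
  rex <- sim$reference$exons
  for (i in seq_len(nrow(ngex))) {
    hits <- rex[chrom == ngex$chrom[i] & start < ngex$end[i] &
                  end > ngex$start[i]]
    expect_equal(nrow(hits), 0L)
  }
})

test_that("share_fraction = 1 yields identical consecutive stages", {
  cfg <- sim_config(seed = 5L, n_genes = 9L, n_chroms = 1L,
                    share_fraction = 1, stages = c("Oo", "1C", "2C"),
                    transcripts_per_stage = 20L, n_das = 0L)
  ref <- simulate_reference(cfg)
  stg <- simulate_stage_transcriptomes(ref$reference, ref$truth, cfg)
  m <- stg$truth$stage_members
  expect_identical(m[stage == "Oo", sort(cand_id)], m[stage == "1C", sort(cand_id)])
  expect_identical(m[stage == "1C", sort(cand_id)], m[stage == "2C", sort(cand_id)])
})

test_that("planted ZGA transcripts satisfy the rule by construction, others never", {
  sim <- default_sim()
  sm <- stage_means(sim$tpm)
  zga_ids <- sim$truth$cand_info[zga == TRUE, cand_id]
  expect_true(all(sm[zga_ids, "Oo"] <= 1))
  expect_true(all(sm[zga_ids, "1C"] > 1))
  expect_true(all(sm[zga_ids, "2C"] > 2 * sm[zga_ids, "1C"]))
})

test_that("planted unsupported junctions stay below ten reads in every sample", {
  sim <- default_sim()
  jn <- sim$truth$junction_support_truth
  sup <- sim$junction_support
  agg <- sup[, .(mx = max(count)), by = .(chrom, donor, acceptor, strand)]
  m <- merge(jn, agg, by = c("chrom", "donor", "acceptor", "strand"))
  expect_true(all(m[supported == FALSE, mx] <= 9L))
  expect_true(all(m[supported == TRUE, mx] >= 10L))
})

test_that("emitted files parse cleanly back through the readers", {
  sim <- default_sim()
  dir <- tempfile()
  write_dataset(sim, dir)
  ref <- read_gtf(file.path(dir, "reference.gtf"))
  expect_equal(nrow(ref$transcripts), nrow(sim$reference$transcripts))
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_equal(unname(Biostrings::width(g)), unname(sim$truth$chrom_sizes))
  tr <- read_bedgraph(file.path(dir, "phylop.bedgraph"))
  expect_equal(nrow(tr$runs), nrow(sim$tracks$phylop$runs))
  tpm <- read_expression_tsv(file.path(dir, "tpm.tsv"), "TPM")
  expect_equal(dim(tpm), dim(sim$tpm))
  expect_equal(max(abs(tpm - sim$tpm)), 0, tolerance = 1e-6)
  sup <- read_junction_tsv(file.path(dir, "junctions.tsv"))
  expect_equal(nrow(sup), nrow(sim$junction_support))
})
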