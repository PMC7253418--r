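# Junction motifs and validation, AS event enumeration, PSI,
# differential splicing, event dynamics.

test_that("junction motifs are read on the sense strand", {
  # forward gene: intron [103, 197) with GT..AG
  seqs <- rep("A", 300)
  seqs[104:105] <- c("G", "T"); seqs[196:197] <- c("A", "G")
  g <- Biostrings::DNAStringSet(c(chr1 = paste(seqs, collapse = "")))
  ann <- make_ann(make_tx("t", "g", list(c(50, 103), c(197, 250))))
  jn <- extract_junctions(ann, g)
  expect_equal(jn$motif5, "GT")
  expect_true(jn$canonical)
  # minus-strand gene: genomic CT..AC reads GT..AG in sense
  seqs2 <- rep("A", 300)
  seqs2[104:105] <- c("C", "T"); seqs2[196:197] <- c("A", "C")
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste(seqs2, collapse = "")))
  ann2 <- make_ann(make_tx("t", "g", list(c(50, 103), c(197, 250)),
                           strand = "-"))
  jn2 <- extract_junctions(ann2, g2)
  expect_equal(jn2$motif5, "GT")
  expect_equal(jn2$motif3, "AG")
  expect_true(jn2$canonical)
  # GC..AG is noncanonical
  seqs[104:105] <- c("G", "C")
  g3 <- Biostrings::DNAStringSet(c(chr1 = paste(seqs, collapse = "")))
  expect_false(extract_junctions(ann, g3)$canonical)
})

test_that("junction validation keeps >= 10 reads in at least one sample", {
  jn <- data.table::data.table(chrom = "c", donor = c(100L, 200L, 300L),
                               acceptor = c(150L, 250L, 350L), strand = "+")
  sup <- data.table::data.table(
    chrom = "c", donor = c(100L, 100L, 200L, 200L),
    acceptor = c(150L, 150L, 250L, 250L), strand = "+",
    sample_id = c("s1", "s2", "s1", "s2"), count = c(12L, 0L, 9L, 9L))
  v <- validate_junctions(jn, sup)
  expect_equal(v$validated, c(TRUE, FALSE, FALSE))  # absent junction drops too
  expect_equal(v$max_support, c(12L, 9L, 0L))
})

test_that("each of the seven AS types is found exactly once in the fixture", {
  ev <- enumerate_as_events(as_fixture("+"))
  expect_equal(nrow(ev), 7L)
  expect_setequal(ev$type, c("SE", "A5", "A3", "RI", "MX", "AF", "AL"))
  # each gene produced exactly its own event type, no cross-type calls
  expect_equal(ev[order(gene_id), gene_id],
               paste0("g", sort(c("SE", "A5", "A3", "RI", "MX", "AF", "AL"))))
  expect_equal(ev[gene_id == "gSE", type], "SE")
  expect_equal(ev[gene_id == "gRI", type], "RI")
  expect_equal(ev[gene_id == "gMX", type], "MX")
  # inclusion/exclusion sets are disjoint and correct for SE and RI
  se <- ev[type == "SE"]
  expect_equal(se$inclusion[[1L]], "gSE.1")
  expect_equal(se$exclusion[[1L]], "gSE.2")
  ri <- ev[type == "RI"]
  expect_equal(ri$inclusion[[1L]], "gRI.2")   # retention is inclusion
  expect_equal(ri$exclusion[[1L]], "gRI.1")
  expect_equal(attr(ev, "as_genes"), sort(unique(ev$gene_id)))
})

test_that("5'/3' and first/last assignments swap on the minus strand", {
  evp <- enumerate_as_events(as_fixture("+"))
  evm <- enumerate_as_events(as_fixture("-"))
  swap <- c(SE = "SE", RI = "RI", MX = "MX", A5 = "A3", A3 = "A5",
            AF = "AL", AL = "AF")
  tp <- setNames(evp$type, evp$gene_id)
  tm <- setNames(evm$type, evm$gene_id)
  expect_equal(unname(swap[tp[names(tm)]]), unname(tm))
})

test_that("single-isoform genes yield no events and duplicates collapse", {
  one <- make_ann(make_tx("t1", "g", list(c(0, 100), c(200, 300))))
  expect_equal(nrow(enumerate_as_events(one)), 0L)
  # three isoforms sharing the same skipped exon report the event once
  tri <- make_ann(
    make_tx("a", "g", list(c(0, 100), c(200, 300), c(400, 500))),
    make_tx("b", "g", list(c(0, 100), c(400, 500))),
    make_tx("c", "g", list(c(0, 100), c(200, 300), c(400, 520))))
  ev <- enumerate_as_events(tri)
  se <- ev[type == "SE"]
  expect_equal(nrow(se), 1L)
  expect_setequal(se$inclusion[[1L]], c("a", "c"))
  expect_equal(se$exclusion[[1L]], "b")
})

test_that("PSI is the inclusion share of expression and scale-invariant", {
  ev <- enumerate_as_events(as_fixture("+"))[type == "SE"]
  m <- matrix(c(3, 1, 6, 2), nrow = 2L,
              dimnames = list(c("gSE.1", "gSE.2"), c("s1_1", "s2_1")))
  tpm <- expression_matrix(m, "TPM")
  psi <- compute_psi(ev, tpm)
  expect_equal(unname(psi[1L, ]), c(0.75, 0.75))
  tpm10 <- expression_matrix(m * 10, "TPM")
  expect_equal(compute_psi(ev, tpm10), psi)       # scaling invariance
  m0 <- m; m0[, 2L] <- 0
  psi0 <- compute_psi(ev, expression_matrix(m0, "TPM"))
  expect_true(is.na(psi0[1L, 2L]))                # zero denominator
  expect_error(compute_psi(ev, expression_matrix(
    matrix(1, 1, 1, dimnames = list("gSE.1", "s")), "TPM")), "missing")
})

test_that("differential splicing classifies planted shifts and handles NAs", {
  ps <- simulate_psi_replicates(40L, reps = 5L, delta = 0.4, noise_sd = 0.02,
                                seed = 3L)
  res <- diff_splice(ps$psi_a, ps$psi_b, seed = 5L)
  expect_true(all(res$class == "up"))
  res2 <- diff_splice(ps$psi_b, ps$psi_a, seed = 5L)
  expect_true(all(res2$class == "down"))
  # identical replicates: delta 0, never significant
  same <- matrix(rep(c(0.4, 0.5, 0.6), 3L), nrow = 3L)
  r0 <- diff_splice(same, same, seed = 1L)
  expect_equal(r0$delta_psi, rep(0, 3L))
  expect_equal(r0$class, rep("none", 3L))
  # a condition with no defined PSI is skipped
  rna <- diff_splice(c(NA, NA), c(0.2, 0.3), seed = 1L)
  expect_true(is.na(rna$class))
})

test_that("event dynamics difference sets per type with later/earlier percentages", {
  e1 <- enumerate_as_events(as_fixture("+"))
  d0 <- event_dynamics(e1, e1)
  expect_equal(sum(d0$n_gained), 0L)
  expect_equal(sum(d0$n_lost), 0L)
  e_prev <- e1[type %in% c("SE", "A5")]
  d <- event_dynamics(e_prev, e1)
  expect_equal(d[type == "RI", n_gained], 1L)
  expect_equal(d[type == "RI", gain_pct], 100)
  expect_equal(d[type == "SE", n_gained], 0L)
  d2 <- event_dynamics(e1, e_prev)
  expect_equal(d2[type == "RI", n_lost], 1L)
})

test_that("planted canonical junction share is recovered from the genome", {
  sim <- default_sim()
  jn <- extract_junctions(union_ann(sim), sim$genome)
  jd <- unique(jn[, .(chrom, strand, donor, acceptor, canonical)])
  tru <- sim$truth$junctions
  m <- merge(jd, tru, by = c("chrom", "strand", "donor", "acceptor"))
  expect_equal(nrow(m), nrow(jd))
  expect_equal(m$canonical.x, m$canonical.y)  # exact motif-truth agreement
})
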