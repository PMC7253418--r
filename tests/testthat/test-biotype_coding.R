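# Biotype split, ORF extraction, homology significance, expression tiers.

test_that("novel transcripts split on the coding cutoff and lncRNA length rule", {
  res <- classify_biotype(
    c("n1", "n2", "n3"), rep("novel_gene", 3L),
    coding_scores = c(n1 = 0.45, n2 = 0.30, n3 = 0.30),
    spliced_lengths = c(n1 = 1000L, n2 = 500L, n3 = 150L))
  expect_equal(res$class, c("protein_coding", "lncRNA", "else"))
  expect_equal(res$basis, rep("coding_score", 3L))
  # boundary: exactly 0.44 is not protein coding
  res2 <- classify_biotype("n", "novel_isoform",
                           coding_scores = c(n = 0.44),
                           spliced_lengths = c(n = 300L))
  expect_equal(res2$class, "lncRNA")
  expect_error(classify_biotype("n", "novel_isoform"),
               "without a coding score")
})

test_that("annotated transcripts map from the reference biotype", {
  res <- classify_biotype(
    c("a1", "a2", "a3"), c("exact_match", "contained", "exact_match"),
    ref_biotypes = c(a1 = "protein_coding", a2 = "lincRNA",
                     a3 = "processed_pseudogene"))
  expect_equal(res$class, c("protein_coding", "lncRNA", "else"))
  expect_equal(res$basis, rep("reference_biotype", 3L))
})

test_that("ORF extraction honours the 300 bp floor and scans all frames", {
  orf303 <- paste0("ATG", paste(rep("GCT", 99L), collapse = ""), "TAA")
  expect_equal(nchar(orf303), 303L)
  res <- find_orfs(orf303)
  expect_equal(nrow(res), 1L)
  expect_equal(res$length, 303L)
  expect_equal(substr(res$peptide, 1L, 2L), "MA")
  # one codon shorter fails the floor
  expect_equal(nrow(find_orfs(paste0("ATG", paste(rep("GCT", 97L), collapse = ""),
                                     "TAA"))), 0L)
  expect_equal(nrow(find_orfs("CCCCCCTAACCC", min_len = 3L)), 0L)  # no ATG
  expect_error(find_orfs("ATGXXX"), "non-ACGTN")
  # 3'-incomplete ORFs only when requested
  open_orf <- paste0("ATG", paste(rep("GCT", 120L), collapse = ""))
  expect_equal(nrow(find_orfs(open_orf)), 0L)
  expect_equal(nrow(find_orfs(open_orf, allow_incomplete = TRUE)), 1L)
})

test_that("ORF extraction equals a brute-force all-frames scan on random sequences", {
  brute <- function(s, min_len) {
    n <- nchar(s); out <- list(); stops <- c("TAA", "TAG", "TGA")
    for (p in seq_len(max(n - 2L, 0L))) {
      if (substr(s, p, p + 2L) != "ATG") next
      q <- p
      while (q + 2L <= n) {
        if (substr(s, q, q + 2L) %in% stops) {
          if (q + 2L - p + 1L >= min_len)
            out[[length(out) + 1L]] <- c(p - 1L, q + 2L)
          break
        }
        q <- q + 3L
      }
    }
    if (!length(out)) return(data.table::data.table(start = integer(),
                                                    end = integer()))
    d <- data.table::as.data.table(do.call(rbind, out))
    data.table::setnames(d, c("start", "end"))
    d[order(start, end)]
  }
  set.seed(91)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(200:2500, 1L),
                      replace = TRUE), collapse = "")
    got <- find_orfs(s, min_len = 30L)[order(start, end), .(start, end)]
    expect_equal(as.data.frame(got), as.data.frame(brute(s, 30L)),
                 ignore_attr = TRUE)
  }
})

test_that("homology significance uses strict log10(e) < -5 per source", {
  expect_equal(homology_significance(1e-6, 1e-7), "both")
  expect_equal(homology_significance(1e-4, NA), "none")
  expect_equal(homology_significance(1e-5, NA), "none")      # boundary strict
  expect_equal(homology_significance(1e-6, NA), "blast_only")
  expect_equal(homology_significance(NA, 1e-8), "pfam_only")
  expect_error(homology_significance(-1, NA), "> 0")
})

test_that("expression tiers split at TPM 1 and 10", {
  expect_equal(expression_tier(c(0.5, 1, 5, 10, 50)),
               c("not_detected", "not_detected", "expressed", "expressed", "high"))
  expect_error(expression_tier(-1), "negative")
})
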