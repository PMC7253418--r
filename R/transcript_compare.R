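# Exon-chain comparison of assembled transcripts against a reference
# annotation: class codes, five-way categories, cross-stage merging,
# gain/loss dynamics and saturation of novel-transcript discovery.
#
# Class codes follow the comparison vocabulary used for long-read
# transcript annotation:
#   "="  exact match of the intron chain (mono-exon: >= 50% reciprocal
#        span overlap with a mono-exon reference)
#   "c"  contiguous sub-chain of a reference chain with the query span
#        inside the reference span (mono-exon: query inside one
#        reference exon)
#   "j"  shares >= 1 splice junction with a reference transcript but is
#        neither "=" nor "c"
#   "e"  overlaps a reference exon and extends >= 10 bp into an adjacent
#        reference intron without splicing there
#   other: antisense / intronic / unclassified overlap
#   "u"  no overlap with the reference on either strand (intergenic)
# Categories: "=" exact_match, "c" contained, "j"/"e" novel_isoform,
# "u" novel_gene, rest other.  {=, c} form the "annotated" set and
# {j, e, u} the "novel" set.

CODE_CATEGORY <- c("=" = "exact_match", "c" = "contained",
                   "j" = "novel_isoform", "e" = "novel_isoform",
                   "u" = "novel_gene", "other" = "other")
CODE_SET <- c("=" = "annotated", "c" = "annotated", "j" = "novel",
              "e" = "novel", "u" = "novel", "other" = "other")

# all same-strand exonic-overlap base counts between two exon tables
.exon_overlap_pairs <- function(qex, rex, same_strand = TRUE) {
  if (!nrow(qex) || !nrow(rex))
    return(data.table(qid = character(), rid = character(), overlap_bp = integer()))
  a <- qex[, .(qid = transcript_id, chrom, strand, start, end)]
  b <- rex[, .(rid = transcript_id, chrom, rstrand = strand, start, end)]
  setkey(b, chrom, start, end)
  ov <- foverlaps(a, b, by.x = c("chrom", "start", "end"), nomatch = NULL)
  ov[, olen := pmin(i.end, end) - pmax(i.start, start)]
  ov <- ov[olen > 0L]
  if (same_strand) ov <- ov[strand == rstrand] else ov <- ov[strand != rstrand]
  ov[, .(overlap_bp = sum(olen)), by = .(qid, rid)]
}

#' Classify query transcripts against a reference annotation
#'
#' Assigns each query transcript a class code by the first matching rule
#' in priority order `=` > `c` > `j` > `e` > other > `u`, together with
#' the best-matching reference transcript (ties broken by number of
#' shared junctions, then exonic overlap, then lexicographic id) and the
#' five-way category used throughout the package.
#'
#' @param query annotation of query transcript models
#' @param reference reference annotation
#' @param min_intron_overlap minimum bases a query exon must extend into
#'   a reference intron for code "e" (default 10)
#' @param mono_reciprocal minimum reciprocal span overlap for mono-exon
#'   "=" (default 0.5)
#' @return data.table with one row per query transcript: `query_id`,
#'   `code`, `sub_label` (for code "other": antisense / intronic /
#'   unclassified, else NA), `category`, `set` (annotated / novel /
#'   other), `best_ref` (NA for "u" and "other"), `n_shared_junctions`.
#' @export
classify_transcripts <- function(query, reference,
                                 min_intron_overlap = 10L,
                                 mono_reciprocal = 0.5) {
  stopifnot(is_annotation(query), is_annotation(reference))
  qtx <- query$transcripts
  rtx <- reference$transcripts
  qir <- introns(query);  rir <- introns(reference)
  qch <- intron_chain_strings(query)
  rch <- intron_chain_strings(reference)

  # shared-junction counts per (qid, rid)
  shared <- if (nrow(qir) && nrow(rir)) {
    merge(qir[, .(qid = transcript_id, chrom, strand, donor, acceptor)],
          rir[, .(rid = transcript_id, chrom, strand, donor, acceptor)],
          by = c("chrom", "strand", "donor", "acceptor"),
          allow.cartesian = TRUE)[, .(n_shared = .N), by = .(qid, rid)]
  } else data.table(qid = character(), rid = character(), n_shared = integer())

  ov_same <- .exon_overlap_pairs(query$exons, reference$exons, TRUE)
  ov_anti <- .exon_overlap_pairs(query$exons, reference$exons, FALSE)

  # candidate pairs per code level -----------------------------------------
  # "=" multi-exon: identical intron chain
  eq_multi <- merge(qch[, .(qid = transcript_id, chrom, strand, chain)],
                    rch[, .(rid = transcript_id, chrom, strand, chain)],
                    by = c("chrom", "strand", "chain"),
                    allow.cartesian = TRUE)[, .(qid, rid)]
  # "=" mono-exon: reciprocal span overlap
  qmono <- qtx[n_exons == 1L, .(qid = transcript_id, chrom, strand, start, end,
                                qlen = end - start)]
  rmono <- rtx[n_exons == 1L, .(rid = transcript_id, chrom, strand, start, end,
                                rlen = end - start)]
  eq_mono <- if (nrow(qmono) && nrow(rmono)) {
    setkey(rmono, chrom, start, end)
    m <- foverlaps(qmono, rmono, by.x = c("chrom", "start", "end"), nomatch = NULL)
    m <- m[strand == i.strand]
    m[, olen := pmin(i.end, end) - pmax(i.start, start)]
    m[olen > 0 & olen >= mono_reciprocal * qlen & olen >= mono_reciprocal * rlen,
      .(qid, rid)]
  } else data.table(qid = character(), rid = character())
  eq <- unique(rbind(eq_multi, eq_mono))

  # "c" multi-exon: contiguous sub-chain + span containment
  c_multi <- if (nrow(shared)) {
    cand <- merge(shared, qch[, .(qid = transcript_id, qchain = chain)], by = "qid")
    cand <- merge(cand, rch[, .(rid = transcript_id, rchain = chain)], by = "rid")
    cand <- merge(cand, qtx[, .(qid = transcript_id, qs = start, qe = end)], by = "qid")
    cand <- merge(cand, rtx[, .(rid = transcript_id, rs = start, re = end)], by = "rid")
    cand[mapply(grepl, qchain, rchain, MoreArgs = list(fixed = TRUE)) &
           qs >= rs & qe <= re, .(qid, rid)]
  } else data.table(qid = character(), rid = character())
  # "c" mono-exon: query span inside one reference exon, same strand
  c_mono <- if (nrow(qmono) && nrow(reference$exons)) {
    rex <- reference$exons[, .(rid = transcript_id, chrom, rstrand = strand,
                               start, end)]
    setkey(rex, chrom, start, end)
    m <- foverlaps(qmono, rex, by.x = c("chrom", "start", "end"), nomatch = NULL)
    m[strand == rstrand & i.start >= start & i.end <= end, .(qid, rid)]
  } else data.table(qid = character(), rid = character())
  ctn <- unique(rbind(c_multi, c_mono))

  jj <- shared[, .(qid, rid)]

  # "e": same-strand exon overlap + >= min_intron_overlap into an intron
  ee <- if (nrow(ov_same) && nrow(rir)) {
    ri <- rir[, .(rid = transcript_id, chrom, strand, start = donor, end = acceptor)]
    setkey(ri, chrom, start, end)
    qe <- query$exons[, .(qid = transcript_id, chrom, strand, start, end)]
    m <- foverlaps(qe, ri, by.x = c("chrom", "start", "end"), nomatch = NULL)
    m <- m[strand == i.strand]
    m[, olen := pmin(i.end, end) - pmax(i.start, start)]
    iov <- m[olen >= min_intron_overlap, unique(.SD), .SDcols = c("qid", "rid")]
    merge(iov, ov_same[, .(qid, rid)], by = c("qid", "rid"))
  } else data.table(qid = character(), rid = character())

  # intronic: query span fully inside a reference intron (either strand)
  intr <- if (nrow(rir)) {
    ri <- rir[, .(rid = transcript_id, chrom, start = donor, end = acceptor)]
    setkey(ri, chrom, start, end)
    qs <- qtx[, .(qid = transcript_id, chrom, start, end)]
    m <- foverlaps(qs, ri, by.x = c("chrom", "start", "end"), nomatch = NULL)
    m[i.start >= start & i.end <= end, .(qid, rid)]
  } else data.table(qid = character(), rid = character())

  # assign codes by priority ------------------------------------------------
  res <- data.table(query_id = qtx$transcript_id)
  res[, `:=`(code = NA_character_, sub_label = NA_character_,
             best_ref = NA_character_, n_shared_junctions = 0L)]

  pick_best <- function(cands) {
    # cands: dt(qid, rid); returns best rid + shared count per qid
    x <- merge(cands, shared, by = c("qid", "rid"), all.x = TRUE)
    x[is.na(n_shared), n_shared := 0L]
    x <- merge(x, ov_same, by = c("qid", "rid"), all.x = TRUE)
    x[is.na(overlap_bp), overlap_bp := 0L]
    setorder(x, qid, -n_shared, -overlap_bp, rid)
    x[, .SD[1L], by = qid]
  }
  assign_code <- function(cands, code_chr) {
    cands <- cands[qid %in% res[is.na(code), query_id]]
    if (!nrow(cands)) return(invisible())
    best <- pick_best(cands)
    res[best, `:=`(code = code_chr, best_ref = i.rid,
                   n_shared_junctions = i.n_shared),
        on = c(query_id = "qid")]
    invisible()
  }
  assign_code(eq, "=")
  assign_code(ctn, "c")
  assign_code(jj, "j")
  assign_code(ee, "e")

  open_ids <- res[is.na(code), query_id]
  if (length(open_ids)) {
    same_ids <- intersect(open_ids, unique(ov_same$qid))
    res[query_id %in% same_ids, `:=`(code = "other", sub_label = "unclassified")]
    open_ids <- setdiff(open_ids, same_ids)
    anti_ids <- intersect(open_ids, unique(ov_anti$qid))
    res[query_id %in% anti_ids, `:=`(code = "other", sub_label = "antisense")]
    open_ids <- setdiff(open_ids, anti_ids)
    intr_ids <- intersect(open_ids, unique(intr$qid))
    res[query_id %in% intr_ids, `:=`(code = "other", sub_label = "intronic")]
    open_ids <- setdiff(open_ids, intr_ids)
    res[query_id %in% open_ids, code := "u"]
  }
  res[, category := CODE_CATEGORY[code]]
  res[, set := CODE_SET[code]]
  res[code %in% c("u", "other"), best_ref := NA_character_]
  setcolorder(res, c("query_id", "code", "sub_label", "category", "set",
                     "best_ref", "n_shared_junctions"))
  res[]
}

#' Per-category counts and percentages of a classification table
#' @param comparison result of [classify_transcripts()]
#' @return data.table(category, n, pct) over all five categories
#' @export
category_summary <- function(comparison) {
  cats <- c("exact_match", "contained", "novel_isoform", "novel_gene", "other")
  out <- data.table(category = cats)
  cnt <- comparison[, .N, by = category]
  out <- merge(out, cnt, by = "category", all.x = TRUE, sort = FALSE)
  out[is.na(N), N := 0L]
  setnames(out, "N", "n")
  out[, pct := 100 * n / max(sum(n), 1L)]
  out[]
}

#' Merge stage transcriptomes into a non-redundant transcript set
#'
#' Multi-exon transcripts with identical (chrom, strand, intron chain)
#' collapse to one model whose terminal exons take the extreme observed
#' 5'/3' ends; mono-exon transcripts collapse by same-strand overlap to
#' their union span.  Merged transcripts are grouped into loci
#' (gene ids `XLOC_...`) by same-strand span overlap.
#'
#' @param stage_sets named list of annotations (names = stage labels)
#' @return list with elements `annotation` (the merged annotation,
#'   transcript ids `MT_...`), `provenance` (data.table merged_id,
#'   stages, source_ids) and `n_input`
#' @export
merge_transcriptomes <- function(stage_sets) {
  if (is.null(names(stage_sets)))
    names(stage_sets) <- paste0("set", seq_along(stage_sets))
  ex_all <- rbindlist(lapply(names(stage_sets), function(s) {
    ann <- stage_sets[[s]]
    cbind(ann$exons, stage = s)
  }))
  if (!nrow(ex_all))
    return(list(annotation = annotation(data.table(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer())),
      provenance = data.table(merged_id = character(), stages = character(),
                              source_ids = character()),
      n_input = 0L))
  ex_all[, skey := paste(stage, transcript_id, sep = "\r")]
  tx_all <- ex_all[, .(chrom = chrom[1L], strand = strand[1L],
                       start = min(start), end = max(end), n_exons = .N,
                       stage = stage[1L], transcript_id = transcript_id[1L]),
                   by = skey]
  ir <- ex_all[order(skey, start),
               if (.N > 1L) .(donor = end[-.N], acceptor = start[-1L]), by = skey]
  chains <- if (nrow(ir)) ir[, .(chain = paste0(
    "|", paste(donor, acceptor, sep = ":", collapse = "|"), "|")), by = skey]
  else data.table(skey = character(), chain = character())
  tx_all <- merge(tx_all, chains, by = "skey", all.x = TRUE)

  merged <- list()
  # multi-exon groups
  multi <- tx_all[!is.na(chain)]
  if (nrow(multi)) {
    grp <- multi[, .(start = min(start), end = max(end),
                     stages = paste(sort(unique(stage)), collapse = ","),
                     source_ids = paste(sort(unique(transcript_id)), collapse = ",")),
                 by = .(chrom, strand, chain)]
    # rebuild exons from chain + extreme ends
    grp[, gid := .I]
    mex <- grp[, {
      parts <- strsplit(gsub("^\\||\\|$", "", chain), "|", fixed = TRUE)[[1L]]
      da <- do.call(rbind, lapply(strsplit(parts, ":", fixed = TRUE), as.integer))
      .(estart = c(start, da[, 2L]), eend = c(da[, 1L], end))
    }, by = .(gid, chrom, strand, stages, source_ids)]
    merged$multi <- mex
  }
  # mono-exon clusters
  mono <- tx_all[is.na(chain)]
  if (nrow(mono)) {
    mono_cl <- mono[, {
      ir2 <- IRanges::IRanges(start + 1L, end)
      red <- IRanges::reduce(ir2, with.revmap = TRUE)
      rv <- S4Vectors::mcols(red)$revmap
      .(estart = IRanges::start(red) - 1L, eend = IRanges::end(red),
        stages = vapply(rv, function(i) paste(sort(unique(stage[i])), collapse = ","), ""),
        source_ids = vapply(rv, function(i) paste(sort(unique(transcript_id[i])), collapse = ","), ""))
    }, by = .(chrom, strand)]
    mono_cl[, gid := .I + 1e9]
    merged$mono <- mono_cl[, .(gid, chrom, strand, stages, source_ids,
                               estart, eend)]
  }
  mex <- rbindlist(merged, use.names = TRUE)
  # deterministic merged ids ordered by genomic position
  ord <- mex[, .(start = min(estart), end = max(eend)),
             by = .(gid, chrom, strand, stages, source_ids)]
  setorder(ord, chrom, start, end, strand, source_ids)
  ord[, merged_id := sprintf("MT_%05d", .I)]
  # loci by same-strand span overlap
  ord[, locus := {
    ir2 <- IRanges::IRanges(start + 1L, end)
    red <- IRanges::reduce(ir2, with.revmap = TRUE)
    lab <- integer(.N)
    rv <- S4Vectors::mcols(red)$revmap
    for (k in seq_along(rv)) lab[rv[[k]]] <- k
    paste(chrom, strand, lab, sep = "_")
  }, by = .(chrom, strand)]
  lmap <- unique(ord[, .(locus)])[, gene_id := sprintf("XLOC_%05d", .I)]
  ord <- merge(ord, lmap, by = "locus")
  mex <- merge(mex, ord[, .(gid, merged_id, gene_id)], by = "gid")
  ann <- annotation(mex[, .(transcript_id = merged_id, gene_id, chrom, strand,
                            start = estart, end = eend)])
  prov <- ord[, .(merged_id, stages, source_ids)][order(merged_id)]
  list(annotation = ann, provenance = prov, n_input = nrow(tx_all))
}

#' Transcript gain/loss between consecutive stages
#'
#' A transcript of the later stage classifying as "=" or "c" against the
#' earlier stage is shared; other codes make it gained.  Symmetrically,
#' earlier-stage transcripts not "="/"c" against the later stage are
#' lost.  Percentages follow the convention of reporting gains relative
#' to the later stage's total and losses relative to the earlier
#' stage's.
#'
#' @param previous annotation of the earlier stage
#' @param current annotation of the later stage
#' @return list(shared, gained, lost, gain_pct, loss_pct,
#'   n_previous, n_current)
#' @export
stage_dynamics <- function(previous, current) {
  fwd <- classify_transcripts(current, previous)
  rev <- classify_transcripts(previous, current)
  gained <- fwd[!code %in% c("=", "c"), query_id]
  shared <- fwd[code %in% c("=", "c"), query_id]
  lost <- rev[!code %in% c("=", "c"), query_id]
  list(shared = shared, gained = gained, lost = lost,
       gain_pct = 100 * length(gained) / max(nrow(fwd), 1L),
       loss_pct = 100 * length(lost) / max(nrow(rev), 1L),
       n_previous = nrow(rev), n_current = nrow(fwd))
}

#' Saturation of novel-transcript discovery
#'
#' Repeatedly permutes the stage order at random; at each step the
#' stage sets seen so far are merged and the merged transcripts are
#' classified against the reference, counting those with novel codes
#' (j, e, u).  Reports the per-step mean and an empirical-percentile
#' confidence interval over repetitions.  When `long_read_sets` is
#' supplied, each stage's set is first merged with its long-read set
#' before entering the procedure.
#'
#' @param stage_sets named list of annotations, one per stage
#' @param reference reference annotation
#' @param reps number of random stage orders (default 100)
#' @param ci confidence level for the percentile interval (default 0.99)
#' @param seed integer seed; the curve is deterministic given the seed
#' @param long_read_sets optional named list of annotations merged into
#'   the matching stage set first
#' @return list(step, mean, lower, upper, reps, counts) where counts is
#'   the reps x steps matrix of novel-transcript counts
#' @export
saturation_curve <- function(stage_sets, reference, reps = 100L, ci = 0.99,
                             seed = 1L, long_read_sets = NULL) {
  if (reps < 2L) stop("reps must be >= 2 for a confidence interval")
  if (!is.null(long_read_sets)) {
    stopifnot(all(names(stage_sets) %in% c(names(long_read_sets), NA)) ||
                length(long_read_sets) == length(stage_sets))
    stage_sets <- lapply(names(stage_sets), function(s) {
      lr <- long_read_sets[[s]]
      if (is.null(lr)) stage_sets[[s]]
      else merge_transcriptomes(list(sr = stage_sets[[s]], lr = lr))$annotation
    })
    names(stage_sets) <- names(long_read_sets)[seq_along(stage_sets)]
  }
  n <- length(stage_sets)
  counts <- matrix(NA_real_, nrow = reps, ncol = n)
  # the novel count after a step depends only on the set of stages merged
  # so far, not their order: memoize per subset
  cache <- new.env(parent = emptyenv())
  novel_count <- function(sel) {
    key <- paste(sort(sel), collapse = ",")
    if (is.null(cache[[key]])) {
      merged <- merge_transcriptomes(stage_sets[sel])$annotation
      cmp <- classify_transcripts(merged, reference)
      cache[[key]] <- sum(cmp$code %in% c("j", "e", "u"))
    }
    cache[[key]]
  }
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      ordr <- sample.int(n)
      for (k in seq_len(n)) counts[r, k] <- novel_count(ordr[seq_len(k)])
    }
  })
  alpha <- (1 - ci) / 2
  list(step = seq_len(n),
       mean = colMeans(counts),
       lower = apply(counts, 2L, quantile, probs = alpha),
       upper = apply(counts, 2L, quantile, probs = 1 - alpha),
       reps = reps, counts = counts)
}
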