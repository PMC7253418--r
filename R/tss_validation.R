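# TSS categorisation of classified transcripts, promoter H3K4me3
# metaprofiles, high-confidence TSS calls by peak overlap, and CAGE
# support.

#' Categorise transcription start sites
#'
#' Annotated TSS intervals are the +/- `halfwidth` bp around each
#' reference transcript's TSS (same strand required).  Novel-gene
#' transcripts get group "novel_gene"; novel isoforms whose TSS falls in
#' an annotated TSS interval are "classic", the remaining novel-isoform
#' TSSs are "novel"; exact matches are "annotated".  Contained and
#' "other" transcripts get NA.
#'
#' @param comparison classification table from [classify_transcripts()]
#' @param query annotation of the classified transcripts
#' @param reference reference annotation
#' @param halfwidth half-width of the annotated TSS interval
#'   (default 300)
#' @return data.table(transcript_id, tss, strand, group)
#' @export
categorize_tss <- function(comparison, query, reference, halfwidth = 300L) {
  cmp <- as.data.table(comparison)
  if (anyNA(cmp$category)) stop("unclassified transcript in comparison table")
  tx <- query$transcripts[, .(transcript_id, chrom, strand, tss)]
  out <- merge(tx, cmp[, .(transcript_id = query_id, category)],
               by = "transcript_id")
  rt <- reference$transcripts[, .(chrom, strand, rt_lo = tss - halfwidth,
                                  rt_hi = tss + halfwidth)]
  in_annot <- vapply(seq_len(nrow(out)), function(i) {
    rt[chrom == out$chrom[i] & strand == out$strand[i] &
         out$tss[i] >= rt_lo & out$tss[i] <= rt_hi, .N] > 0L
  }, TRUE)
  out[, group := NA_character_]
  out[category == "novel_gene", group := "novel_gene"]
  idx <- which(out$category == "novel_isoform")
  if (length(idx))
    out[idx, group := ifelse(in_annot[idx], "classic", "novel")]
  out[category == "exact_match", group := "annotated"]
  out[, .(transcript_id, tss, strand, group)]
}

#' Promoter signal metaprofile
#'
#' Averages a signal track in 161 bins of width `bin_width` laid at
#' `bin_step` steps across the +/- `span` promoter around the TSS.  The
#' first bin starts at `tss - span - bin_width/2` so that the middle bin
#' (81st of 161) is centred on the TSS; bins are ordered 5' to 3'
#' relative to the transcript, i.e. minus-strand profiles are reversed.
#' Bases beyond chromosome bounds score the track default.
#'
#' @param track signal_track (e.g. H3K4me3)
#' @param chrom chromosome
#' @param tss 0-based TSS position
#' @param strand "+" or "-"
#' @param span promoter half-width (default 4000)
#' @param bin_width bin width (default 100)
#' @param bin_step step between bin starts (default 50)
#' @return numeric vector of `2*span/bin_step + 1` bin means (161 for
#'   the defaults)
#' @export
promoter_profile <- function(track, chrom, tss, strand = "+", span = 4000L,
                             bin_width = 100L, bin_step = 50L) {
  n_bins <- as.integer(2L * span / bin_step + 1L)
  starts <- as.integer(tss - span - bin_width %/% 2L + bin_step * (seq_len(n_bins) - 1L))
  st <- track_region_stats(track, data.table(chrom = chrom, start = starts,
                                             end = starts + bin_width))
  v <- st$mean
  if (strand == "-") v <- rev(v)
  v
}

#' Promoter profile matrix for a set of TSSs
#' @param track signal_track
#' @param tss_table data.table(transcript_id, chrom, tss, strand)
#' @param ... passed to [promoter_profile()]
#' @return matrix transcripts x bins
#' @export
promoter_profiles <- function(track, tss_table, ...) {
  tt <- as.data.table(tss_table)
  m <- t(vapply(seq_len(nrow(tt)), function(i)
    promoter_profile(track, tt$chrom[i], tt$tss[i], tt$strand[i], ...),
    promoter_profile(track, tt$chrom[1L], tt$tss[1L], tt$strand[1L], ...) * 0))
  rownames(m) <- tt$transcript_id
  m
}

#' High-confidence TSS call by merged-peak overlap
#'
#' Peaks from the supplied stage files are merged by interval union; a
#' TSS is high-confidence iff a merged peak intersects
#' `[tss - halfwidth, tss + halfwidth]`.
#'
#' @param tss_table data.table(transcript_id, chrom, tss)
#' @param peak_sets list of peak interval tables (chrom, start, end),
#'   e.g. one per stage
#' @param halfwidth window half-width around the TSS (default 500)
#' @return logical vector in `tss_table` row order
#' @export
high_confidence_tss <- function(tss_table, peak_sets, halfwidth = 500L) {
  tt <- as.data.table(tss_table)
  peaks <- merge_intervals(rbindlist(lapply(peak_sets, function(p)
    as.data.table(p)[, .(chrom, start, end)])))
  vapply(seq_len(nrow(tt)), function(i) {
    w_lo <- tt$tss[i] - halfwidth; w_hi <- tt$tss[i] + halfwidth
    peaks[chrom == tt$chrom[i] & start <= w_hi & end - 1L >= w_lo, .N] > 0L
  }, TRUE)
}

#' CAGE support of a TSS
#'
#' Support intervals are the union of bases with nonzero signal in any
#' CAGE sample; a TSS is supported iff a support interval intersects
#' `[tss - halfwidth, tss + halfwidth]`.
#'
#' @param tss_table data.table(transcript_id, chrom, tss)
#' @param cage_tracks list of signal_track objects, one per sample
#' @param halfwidth window half-width (default 500)
#' @return logical vector in `tss_table` row order
#' @export
cage_supported <- function(tss_table, cage_tracks, halfwidth = 500L) {
  runs <- rbindlist(lapply(cage_tracks, function(tr)
    tr$runs[value != 0, .(chrom, start, end)]))
  if (!nrow(runs))
    return(rep(FALSE, nrow(as.data.table(tss_table))))
  support <- merge_intervals(runs)
  tt <- as.data.table(tss_table)
  vapply(seq_len(nrow(tt)), function(i) {
    w_lo <- tt$tss[i] - halfwidth; w_hi <- tt$tss[i] + halfwidth
    support[chrom == tt$chrom[i] & start <= w_hi & end - 1L >= w_lo, .N] > 0L
  }, TRUE)
}
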