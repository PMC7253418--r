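# Conservation scoring of novel non-coding transcripts against
# length-matched intergenic control regions, with cutoffs calibrated as
# the 95th percentile of the control distribution.  Per-base conservation
# (phyloP-style) enters as the fraction of bases above a base-level
# cutoff; element conservation (phastCons-style) as the maximal 200-bp
# sliding-window mean over the spliced sequence.

#' Sample length-matched intergenic control regions
#'
#' Places one uniformly chosen intergenic interval per transcript whose
#' length equals that transcript's spliced length.  Intergenic space is
#' the complement of all reference transcript spans (either strand), so
#' controls overlap no reference exon.  Sampling weights every feasible
#' start position equally across all gaps, making placement exact (no
#' rejection loop) and deterministic under the seed.
#'
#' @param reference reference annotation
#' @param transcripts annotation (or transcript table) of the
#'   transcripts to match; spliced lengths are used
#' @param chrom_sizes named integer vector of chromosome lengths
#' @param seed integer seed
#' @param margin bases to keep clear of reference spans (default 0)
#' @return data.table(transcript_id, chrom, start, end) with
#'   end - start = matched spliced length
#' @export
sample_control_regions <- function(reference, transcripts, chrom_sizes,
                                   seed = 1L, margin = 0L) {
  tx <- if (is_annotation(transcripts)) transcripts$transcripts
        else as.data.table(transcripts)
  spans <- reference$transcripts[, .(chrom, start = pmax(start - margin, 0L),
                                     end = end + margin)]
  gaps <- rbindlist(lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    s <- spans[chrom == ch]
    if (!nrow(s)) return(data.table(chrom = ch, start = 0L, end = as.integer(L)))
    red <- IRanges::reduce(IRanges::IRanges(s$start + 1L, pmin(s$end, L)))
    gp <- IRanges::gaps(red, start = 1L, end = L)
    data.table(chrom = ch, start = IRanges::start(gp) - 1L, end = IRanges::end(gp))
  }))
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(tx)), function(i) {
      L <- tx$spliced_length[i]
      g <- gaps[end - start >= L]
      if (!nrow(g))
        stop("no intergenic gap can host a control of length ", L)
      npos <- g$end - g$start - L + 1L
      gi <- sample.int(nrow(g), 1L, prob = npos)
      s0 <- g$start[gi] + sample.int(npos[gi], 1L) - 1L
      data.table(transcript_id = tx$transcript_id[i], chrom = g$chrom[gi],
                 start = s0, end = s0 + L)
    })
  })
  rbindlist(out)
}

#' Conservation statistics of a region set
#'
#' For the spliced (exon-concatenated) sequence of a transcript — or any
#' plain interval — computes the fraction of bases whose per-base
#' conservation exceeds `base_cutoff` and the maximum mean of the
#' element-conservation track over all `window`-bp sliding windows of
#' the spliced sequence (whole-region mean when shorter than `window`).
#'
#' @param phylop per-base conservation signal_track
#' @param phastcons element conservation signal_track
#' @param region data.table of exon intervals (chrom, start, end) in
#'   genomic order; a single-row table for an unspliced control region
#' @param base_cutoff per-base cutoff for the conserved-base fraction
#' @param window sliding-window width in bp (default 200)
#' @return list(fraction_conserved, max_window_mean, length)
#' @export
conservation_stats <- function(phylop, phastcons, region,
                               base_cutoff, window = 200L) {
  region <- as.data.table(region)[order(start)]
  if (!nrow(region) || sum(region$end - region$start) < 1L)
    stop("empty region")
  pv <- unlist(lapply(seq_len(nrow(region)), function(i)
    track_base_values(phylop, region$chrom[i], region$start[i], region$end[i])))
  cv <- unlist(lapply(seq_len(nrow(region)), function(i)
    track_base_values(phastcons, region$chrom[i], region$start[i], region$end[i])))
  L <- length(pv)
  frac <- mean(pv > base_cutoff)
  if (L < window) {
    wmax <- mean(cv)
  } else {
    cs <- cumsum(c(0, cv))
    wmax <- max(cs[(window + 1L):(L + 1L)] - cs[1L:(L - window + 1L)]) / window
  }
  list(fraction_conserved = frac, max_window_mean = wmax, length = L)
}

#' Calibrate conservation cutoffs from control regions
#'
#' The base-level cutoff is the `percentile`-th linear-interpolation
#' quantile of all per-base phyloP-style values pooled over the
#' controls; the fraction and window cutoffs are the same percentile of
#' the per-control statistics computed with that base cutoff.
#'
#' @param controls control region table from [sample_control_regions()]
#' @param phylop,phastcons signal tracks
#' @param percentile calibration percentile (default 95)
#' @param window sliding-window width (default 200)
#' @param min_controls minimum number of control regions (default 20)
#' @return list(base_cutoff, fraction_cutoff, window_cutoff, percentile,
#'   control_stats) where control_stats holds the per-control statistics
#' @export
calibrate_cutoffs <- function(controls, phylop, phastcons, percentile = 95,
                              window = 200L, min_controls = 20L) {
  controls <- as.data.table(controls)
  if (nrow(controls) < min_controls)
    stop("need at least ", min_controls, " control regions to calibrate")
  base_vals <- unlist(lapply(seq_len(nrow(controls)), function(i)
    track_base_values(phylop, controls$chrom[i], controls$start[i],
                      controls$end[i])))
  base_cutoff <- unname(quantile(base_vals, percentile / 100, type = 7))
  st <- lapply(seq_len(nrow(controls)), function(i)
    conservation_stats(phylop, phastcons, controls[i, .(chrom, start, end)],
                       base_cutoff = base_cutoff, window = window))
  cs <- data.table(transcript_id = controls$transcript_id,
                   fraction_conserved = vapply(st, `[[`, 0, "fraction_conserved"),
                   max_window_mean = vapply(st, `[[`, 0, "max_window_mean"))
  list(base_cutoff = base_cutoff,
       fraction_cutoff = unname(quantile(cs$fraction_conserved,
                                         percentile / 100, type = 7)),
       window_cutoff = unname(quantile(cs$max_window_mean,
                                       percentile / 100, type = 7)),
       percentile = percentile, control_stats = cs)
}

#' Score transcripts against conservation cutoffs
#'
#' @param ann annotation containing the transcripts
#' @param ids transcript ids to score
#' @param phylop,phastcons signal tracks
#' @param cutoffs list with base_cutoff, fraction_cutoff, window_cutoff
#'   (from [calibrate_cutoffs()] or fixed values)
#' @param window sliding-window width (default 200)
#' @return data.table(transcript_id, fraction_conserved, max_window_mean,
#'   phylop_significant, phastcons_significant, both)
#' @export
conservation_scores <- function(ann, ids, phylop, phastcons, cutoffs,
                                window = 200L) {
  out <- rbindlist(lapply(ids, function(id) {
    ex <- ann$exons[transcript_id == id, .(chrom, start, end)]
    st <- conservation_stats(phylop, phastcons, ex,
                             base_cutoff = cutoffs$base_cutoff, window = window)
    data.table(transcript_id = id,
               fraction_conserved = st$fraction_conserved,
               max_window_mean = st$max_window_mean)
  }))
  out[, phylop_significant := fraction_conserved > cutoffs$fraction_cutoff]
  out[, phastcons_significant := max_window_mean > cutoffs$window_cutoff]
  out[, both := phylop_significant & phastcons_significant]
  out[]
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration of all group assignments with mid-rank ties when
#' `n + m <= exact_max`; otherwise the normal approximation with tie and
#' continuity correction.  The exact two-sided p-value is twice the
#' smaller tail probability of the U statistic, capped at 1.
#'
#' @param group_a,group_b numeric vectors (both non-empty)
#' @param exact_max largest pooled size for exact enumeration
#'   (default 16)
#' @return list(statistic = U of group_a, p_value, method)
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 16L) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)          # mid-ranks
  U_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= exact_max) {
    idx <- combn(n + m, n)
    Us <- colSums(matrix(rk[idx], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p_lo <- mean(Us <= U_obs + eps)
    p_hi <- mean(Us >= U_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    N <- n + m
    mu <- n * m / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n * m / 12 * ((N^3 - N - tie_term) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = U_obs, p_value = 1,
                                 method = "normal approximation"))
    z <- (U_obs - mu - sign(U_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = U_obs, p_value = p, method = method)
}
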