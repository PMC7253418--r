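# Shared fixtures and independent oracles.  The default simulated
# dataset is built once per session and reused across test files.

.fx_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fx_cache$sim)) .fx_cache$sim <- simulate_dataset(sim_config())
  .fx_cache$sim
}

# five-replicate variant used for differential-splicing recovery
das_sim <- function() {
  if (is.null(.fx_cache$das))
    .fx_cache$das <- simulate_dataset(sim_config(replicates = 5L))
  .fx_cache$das
}

union_ann <- function(sim) isoatlas:::.union_annotation(sim$stage_sets)

# quick transcript builder: ex = list of c(start, end)
make_tx <- function(tid, gid, ex, strand = "+", chrom = "chr1") {
  data.table::data.table(transcript_id = tid, gene_id = gid, chrom = chrom,
                         strand = strand,
                         start = vapply(ex, `[`, 0, 1L),
                         end = vapply(ex, `[`, 0, 2L))
}

make_ann <- function(...) annotation(data.table::rbindlist(list(...)))

# hand-built seven-gene fixture: exactly one AS event of each type (+)
as_fixture <- function(strand = "+") {
  mk <- function(g, t, ex) make_tx(paste0(g, ".", t), g, ex, strand, "chrT")
  make_ann(
    mk("gSE", "1", list(c(0, 100), c(200, 300), c(400, 500))),
    mk("gSE", "2", list(c(0, 100), c(400, 500))),
    mk("gA5", "1", list(c(1000, 1100), c(1300, 1400))),
    mk("gA5", "2", list(c(1000, 1150), c(1300, 1400))),
    mk("gA3", "1", list(c(2000, 2100), c(2200, 2400))),
    mk("gA3", "2", list(c(2000, 2100), c(2250, 2400))),
    mk("gRI", "1", list(c(3000, 3100), c(3200, 3300))),
    mk("gRI", "2", list(c(3000, 3300))),
    mk("gMX", "1", list(c(4000, 4100), c(4200, 4300), c(4500, 4600))),
    mk("gMX", "2", list(c(4000, 4100), c(4350, 4450), c(4500, 4600))),
    mk("gAF", "1", list(c(5000, 5100), c(5500, 5600))),
    mk("gAF", "2", list(c(5200, 5300), c(5500, 5600))),
    mk("gAL", "1", list(c(6000, 6100), c(6200, 6300))),
    mk("gAL", "2", list(c(6000, 6100), c(6400, 6500))))
}

# ---------------------------------------------------------------------------
# Independent exhaustive classification oracle: plain loops over every
# query x reference pair, checking each rule directly on integer exon
# and intron matrices (no chain strings, no joins).
oracle_classify <- function(query, reference, min_intron_overlap = 10L,
                            mono_reciprocal = 0.5) {
  get_in <- function(ex) if (nrow(ex) > 1L)
    cbind(ex$end[-nrow(ex)], ex$start[-1L]) else matrix(0L, 0L, 2L)
  prep <- function(ann) lapply(ann$transcripts$transcript_id, function(id) {
    ex <- ann$exons[transcript_id == id][order(start)]
    list(id = id, chrom = ex$chrom[1L], strand = ex$strand[1L], ex = ex,
         im = get_in(ex), s = min(ex$start), e = max(ex$end))
  })
  refs <- prep(reference)
  code_of <- c("=", "c", "j", "e", "other", "other", "other", "u")
  out <- lapply(prep(query), function(q) {
    best <- 8L
    for (r in refs) {
      if (r$chrom != q$chrom) next
      ov <- 0L
      for (a in seq_len(nrow(q$ex))) for (b in seq_len(nrow(r$ex)))
        ov <- ov + max(0L, min(q$ex$end[a], r$ex$end[b]) -
                         max(q$ex$start[a], r$ex$start[b]))
      lvl <- 8L
      if (r$strand == q$strand) {
        if (nrow(q$im) > 0L && nrow(q$im) == nrow(r$im) && all(q$im == r$im)) {
          lvl <- 1L
        } else if (nrow(q$im) == 0L && nrow(r$im) == 0L) {
          o <- max(0L, min(q$e, r$e) - max(q$s, r$s))
          if (o >= mono_reciprocal * (q$e - q$s) &&
              o >= mono_reciprocal * (r$e - r$s)) lvl <- 1L
        }
        if (lvl > 1L) {
          contained <- FALSE
          if (nrow(q$im) > 0L && nrow(r$im) >= nrow(q$im) &&
              q$s >= r$s && q$e <= r$e) {
            for (off in 0L:(nrow(r$im) - nrow(q$im)))
              if (all(r$im[(off + 1L):(off + nrow(q$im)), , drop = FALSE] ==
                      q$im)) contained <- TRUE
          }
          if (nrow(q$im) == 0L)
            for (b in seq_len(nrow(r$ex)))
              if (q$s >= r$ex$start[b] && q$e <= r$ex$end[b]) contained <- TRUE
          if (contained) lvl <- 2L
        }
        if (lvl > 2L && nrow(q$im) && nrow(r$im)) {
          for (a in seq_len(nrow(q$im))) for (b in seq_len(nrow(r$im)))
            if (all(q$im[a, ] == r$im[b, ])) lvl <- min(lvl, 3L)
        }
        if (lvl > 3L && ov > 0L && nrow(r$im)) {
          for (a in seq_len(nrow(q$ex))) for (b in seq_len(nrow(r$im)))
            if (min(q$ex$end[a], r$im[b, 2L]) -
                max(q$ex$start[a], r$im[b, 1L]) >= min_intron_overlap)
              lvl <- min(lvl, 4L)
        }
        if (lvl > 4L && ov > 0L) lvl <- 5L                 # other/unclassified
      } else if (ov > 0L) {
        lvl <- 6L                                          # other/antisense
      }
      if (lvl > 6L && nrow(r$im)) {                        # other/intronic
        for (b in seq_len(nrow(r$im)))
          if (q$s >= r$im[b, 1L] && q$e <= r$im[b, 2L]) lvl <- min(lvl, 7L)
      }
      best <- min(best, lvl)
    }
    data.table::data.table(query_id = q$id, code = code_of[best])
  })
  data.table::rbindlist(out)
}

# per-base brute-force mean of a track over [s, e): expands the window
# to one value per base, independent of the overlap-join arithmetic
# used by track_region_stats
oracle_track_mean <- function(track, chrom, s, e) {
  v <- rep(track$default, e - s)
  r <- track$runs
  keep <- which(r$chrom == chrom & r$end > s & r$start < e)
  for (k in keep) {
    for (p in seq.int(max(s, r$start[k]), min(e, r$end[k]) - 1L))
      v[p - s + 1L] <- r$value[k]
  }
  mean(v)
}

# bitmask-enumeration oracle for the exact two-sided rank-sum p-value
oracle_rank_sum_p <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  rk <- rank(c(a, b))
  U_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  us <- c()
  for (mask in 0:(2^N - 1)) {
    if (sum(bitwAnd(mask, 2^(0:(N - 1))) > 0) != n) next
    sel <- which(bitwAnd(mask, 2^(0:(N - 1))) > 0)
    us <- c(us, sum(rk[sel]) - n * (n + 1) / 2)
  }
  min(1, 2 * min(mean(us <= U_obs + 1e-9), mean(us >= U_obs - 1e-9)))
}

binom_bounds <- function(n, p, conf = 0.99) {
  alpha <- (1 - conf) / 2
  c(qbinom(alpha, n, p), qbinom(1 - alpha, n, p)) / n
}
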