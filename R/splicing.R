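# Splice-junction extraction and motif classing, short-read junction
# validation, seven-type alternative-splicing event enumeration
# (SE, A5, A3, RI, MX, AF, AL), PSI computation, permutation-based
# differential splicing and event stage dynamics.

.revcomp2 <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), ""))
}

#' Extract splice junctions with donor/acceptor motifs
#'
#' One record per intron of every multi-exon transcript; the motif is
#' the first and last intron dinucleotide read on the transcript's sense
#' strand (reverse-complemented genomic sequence for minus-strand
#' transcripts).  A junction is canonical iff its sense motif is GT..AG.
#'
#' @param ann annotation
#' @param genome DNAStringSet from [read_genome()]
#' @return data.table(transcript_id, gene_id, chrom, strand, donor,
#'   acceptor, motif5, motif3, motif, canonical)
#' @export
extract_junctions <- function(ann, genome) {
  ir <- introns(ann)
  if (!nrow(ir)) {
    ir[, `:=`(motif5 = character(), motif3 = character(), motif = character(),
              canonical = logical())]
    return(ir[])
  }
  seqs <- lapply(unique(ir$chrom), function(ch) {
    if (!ch %in% names(genome)) stop("unknown chromosome: ", ch)
    toupper(as.character(genome[[ch]]))
  })
  names(seqs) <- unique(ir$chrom)
  lens <- vapply(seqs, nchar, 0L)
  if (any(ir$acceptor > lens[ir$chrom] | ir$donor < 0L))
    stop("intron outside genome bounds")
  left <- substr(rep(NA_character_, nrow(ir)), 1, 1)
  left <- vapply(seq_len(nrow(ir)), function(i)
    substr(seqs[[ir$chrom[i]]], ir$donor[i] + 1L, ir$donor[i] + 2L), "")
  right <- vapply(seq_len(nrow(ir)), function(i)
    substr(seqs[[ir$chrom[i]]], ir$acceptor[i] - 1L, ir$acceptor[i]), "")
  ir[, motif5 := ifelse(strand == "+", left, .revcomp2(right))]
  ir[, motif3 := ifelse(strand == "+", right, .revcomp2(left))]
  ir[, motif := paste0(motif5, "-", motif3)]
  ir[, canonical := motif5 == "GT" & motif3 == "AG"]
  ir[]
}

#' Validate junctions against short-read support
#'
#' Keeps a junction iff its maximum per-sample short-read count reaches
#' `min_reads` in at least one sample; junctions absent from the table
#' count as unsupported.
#'
#' @param junctions data.table with chrom, donor, acceptor, strand (one
#'   row per distinct junction or per transcript intron)
#' @param support long-format support table from [read_junction_tsv()]
#' @param min_reads minimum reads in at least one sample (default 10)
#' @return `junctions` with added columns `max_support` and `validated`
#' @export
validate_junctions <- function(junctions, support, min_reads = 10L) {
  jn <- as.data.table(junctions)
  agg <- as.data.table(support)[, .(max_support = max(count)),
                                by = .(chrom, donor, acceptor, strand)]
  out <- merge(jn, agg, by = c("chrom", "donor", "acceptor", "strand"),
               all.x = TRUE, sort = FALSE)
  out[is.na(max_support), max_support := 0L]
  out[, validated := max_support >= min_reads]
  out[]
}

# per-isoform structural view used by the event enumerator
.iso_view <- function(ex) {
  ex <- ex[order(start)]
  n <- nrow(ex)
  im <- if (n > 1L) cbind(d = ex$end[-n], a = ex$start[-1L]) else
    matrix(integer(), ncol = 2L, dimnames = list(NULL, c("d", "a")))
  list(ex = cbind(s = ex$start, e = ex$end), im = im,
       jk = if (nrow(im)) paste(im[, 1L], im[, 2L]) else character())
}

.has_j <- function(v, d, a) any(v$im[, 1L] == d & v$im[, 2L] == a)
.has_exon_cover <- function(v, d, a) any(v$ex[, "s"] <= d & v$ex[, "e"] >= a)

#' Enumerate alternative-splicing events within genes
#'
#' Pairwise comparison of the isoforms of each gene following local-event
#' conventions: SE (exon present in one isoform, removed by a single
#' intron with shared flanking junctions in another), A5/A3 (two introns
#' sharing one boundary, alternative boundary exons overlapping;
#' 5'/3' assigned strand-aware), RI (an intron of one isoform fully
#' exonic in another with shared outer boundaries), MX (two exons each
#' included exclusively between identical outer junctions), AF/AL
#' (non-overlapping alternative first/last exons with distinct TSS/TES
#' sharing the inner junction boundary).  Duplicate events (same type and
#' coordinates) are reported once; inclusion/exclusion isoform sets are
#' collected over all isoforms of the gene.
#'
#' @param ann annotation (all genes are scanned) or exon table of a
#'   single gene
#' @return data.table(event_id, gene_id, type, chrom, strand, coords,
#'   inclusion, exclusion) with list columns for the isoform sets, plus
#'   attribute `as_genes` (character vector of genes with >= 1 event)
#' @export
enumerate_as_events <- function(ann) {
  ex_all <- if (is_annotation(ann)) ann$exons else as.data.table(ann)
  if (uniqueN(ex_all$gene_id) == 0L) stop("no genes to scan")
  events <- list()
  for (g in unique(ex_all$gene_id)) {
    gex <- ex_all[gene_id == g]
    if (uniqueN(gex$chrom) > 1L || uniqueN(gex$strand) > 1L)
      stop("gene ", g, " mixes chrom/strand")
    tids <- unique(gex$transcript_id)
    if (length(tids) < 2L) next
    strand <- gex$strand[1L]; chrom <- gex$chrom[1L]
    iso <- lapply(tids, function(t) .iso_view(gex[transcript_id == t]))
    names(iso) <- tids
    ev <- .pairwise_events(iso, tids, chrom, strand)
    if (nrow(ev)) { ev[, gene_id := g]; events[[g]] <- ev }
  }
  out <- if (length(events)) rbindlist(events) else
    data.table(type = character(), coords = character(), chrom = character(),
               strand = character(), inclusion = list(), exclusion = list(),
               gene_id = character())
  out <- out[!duplicated(paste(gene_id, type, chrom, strand, coords))]
  out[, event_id := paste0(gene_id, ";", type, ":", chrom, ":", coords, ":", strand)]
  setcolorder(out, c("event_id", "gene_id", "type", "chrom", "strand",
                     "coords", "inclusion", "exclusion"))
  setattr(out, "as_genes", unique(out$gene_id))
  out[]
}

# core pairwise detector; iso = named list of .iso_view structures
.pairwise_events <- function(iso, tids, chrom, strand) {
  res <- list()
  add <- function(type, coords, incl, excl) {
    if (!length(incl) || !length(excl)) return(invisible())
    res[[length(res) + 1L]] <<- data.table(
      type = type, coords = coords, chrom = chrom, strand = strand,
      inclusion = list(sort(incl)), exclusion = list(sort(excl)))
  }
  members <- function(pred) tids[vapply(iso[tids], pred, TRUE)]
  nt <- length(tids)
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    for (ord in list(c(i, j), c(j, i))) {
      v1 <- iso[[ord[1L]]]; v2 <- iso[[ord[2L]]]
      # SE: consecutive introns (d,s),(e,a) in v1 vs single intron (d,a) in v2
      if (nrow(v1$im) >= 2L && nrow(v2$im) >= 1L) {
        for (k in seq_len(nrow(v1$im) - 1L)) {
          d <- v1$im[k, 1L]; s <- v1$im[k, 2L]
          e <- v1$im[k + 1L, 1L]; a <- v1$im[k + 1L, 2L]
          if (.has_j(v2, d, a)) {
            add("SE", paste(d, s, e, a, sep = "-"),
                members(function(v) .has_j(v, d, s) && .has_j(v, e, a)),
                members(function(v) .has_j(v, d, a)))
          }
        }
      }
      # RI: intron (d,a) of v1 with exact flanking boundaries exonic in v2
      if (nrow(v1$im) >= 1L) {
        for (k in seq_len(nrow(v1$im))) {
          d <- v1$im[k, 1L]; a <- v1$im[k, 2L]
          x1 <- v1$ex[k, "s"]; x2 <- v1$ex[k + 1L, "e"]
          if (any(v2$ex[, "s"] == x1 & v2$ex[, "e"] == x2)) {
            add("RI", paste(x1, d, a, x2, sep = "-"),
                members(function(v) .has_exon_cover(v, d, a)),
                members(function(v) .has_j(v, d, a)))
          }
        }
      }
      if (ord[1L] != i) next   # symmetric detectors below run once per pair
      # A5/A3: introns sharing exactly one boundary, alt-boundary exons overlap
      if (nrow(v1$im) && nrow(v2$im)) {
        for (k1 in seq_len(nrow(v1$im))) for (k2 in seq_len(nrow(v2$im))) {
          d1 <- v1$im[k1, 1L]; a1 <- v1$im[k1, 2L]
          d2 <- v2$im[k2, 1L]; a2 <- v2$im[k2, 2L]
          if (a1 == a2 && d1 != d2) {
            e1 <- v1$ex[k1, ]; e2 <- v2$ex[k2, ]          # exons ending at d1/d2
            if (max(e1["s"], e2["s"]) < min(e1["e"], e2["e"])) {
              type <- if (strand == "+") "A5" else "A3"
              dl <- max(d1, d2)                            # shorter intron donor
              ds <- min(d1, d2)
              add(type, paste(ds, dl, a1, sep = "-"),
                  members(function(v) .has_j(v, dl, a1)),
                  members(function(v) .has_j(v, ds, a1)))
            }
          }
          if (d1 == d2 && a1 != a2) {
            e1 <- v1$ex[k1 + 1L, ]; e2 <- v2$ex[k2 + 1L, ] # exons starting at a1/a2
            if (max(e1["s"], e2["s"]) < min(e1["e"], e2["e"])) {
              type <- if (strand == "+") "A3" else "A5"
              as_ <- min(a1, a2)                           # shorter intron acceptor is max
              al <- max(a1, a2)
              add(type, paste(d1, as_, al, sep = "-"),
                  members(function(v) .has_j(v, d1, as_)),
                  members(function(v) .has_j(v, d1, al)))
            }
          }
        }
      }
      # MX: consecutive intron pairs sharing outer (d, a), middle exons disjoint
      if (nrow(v1$im) >= 2L && nrow(v2$im) >= 2L) {
        for (k1 in seq_len(nrow(v1$im) - 1L)) for (k2 in seq_len(nrow(v2$im) - 1L)) {
          d <- v1$im[k1, 1L]; a <- v1$im[k1 + 1L, 2L]
          if (v2$im[k2, 1L] != d || v2$im[k2 + 1L, 2L] != a) next
          A <- c(v1$im[k1, 2L], v1$im[k1 + 1L, 1L])        # middle exon of v1
          B <- c(v2$im[k2, 2L], v2$im[k2 + 1L, 1L])
          if (identical(A, B)) next
          if (A[2L] <= B[1L] || B[2L] <= A[1L]) {          # disjoint
            left <- if (A[1L] < B[1L]) A else B
            right <- if (A[1L] < B[1L]) B else A
            five <- if (strand == "+") left else right     # 5'-proximal exon
            three <- if (strand == "+") right else left
            add("MX", paste(d, left[1L], left[2L], right[1L], right[2L], a, sep = "-"),
                members(function(v) .has_j(v, d, five[1L]) && .has_j(v, five[2L], a)),
                members(function(v) .has_j(v, d, three[1L]) && .has_j(v, three[2L], a)))
          }
        }
      }
      # AF/AL: alternative terminal exons
      if (nrow(v1$im) && nrow(v2$im)) {
        f1 <- v1$ex[1L, ]; f2 <- v2$ex[1L, ]               # genomic-left exons
        l1 <- v1$ex[nrow(v1$ex), ]; l2 <- v2$ex[nrow(v2$ex), ]
        # left ends: first exons on +, last exons on -
        if ((f1["e"] <= f2["s"] || f2["e"] <= f1["s"]) &&
            v1$im[1L, 2L] == v2$im[1L, 2L] && f1["e"] != f2["e"]) {
          a <- v1$im[1L, 2L]
          type <- if (strand == "+") "AF" else "AL"
          dist <- if (f1["s"] < f2["s"]) f1 else f2        # genomic-left terminal exon
          prox <- if (f1["s"] < f2["s"]) f2 else f1
          incl_ex <- dist   # distal TSS (AF, +) / distal TES (AL, -) side
          excl_ex <- prox
          add(type, paste(min(f1["s"], f2["s"]), dist["e"], prox["e"], a, sep = "-"),
              members(function(v) nrow(v$im) >= 1L && v$ex[1L, "e"] == incl_ex["e"] &&
                        .has_j(v, incl_ex["e"], a)),
              members(function(v) nrow(v$im) >= 1L && v$ex[1L, "e"] == excl_ex["e"] &&
                        .has_j(v, excl_ex["e"], a)))
        }
        # right ends: last exons on +, first exons on -
        if ((l1["e"] <= l2["s"] || l2["e"] <= l1["s"]) &&
            v1$im[nrow(v1$im), 1L] == v2$im[nrow(v2$im), 1L] && l1["s"] != l2["s"]) {
          d <- v1$im[nrow(v1$im), 1L]
          type <- if (strand == "+") "AL" else "AF"
          dist <- if (l1["e"] > l2["e"]) l1 else l2        # genomic-right terminal exon
          prox <- if (l1["e"] > l2["e"]) l2 else l1
          incl_ex <- dist   # distal TES (AL, +) / distal TSS (AF, -) side
          excl_ex <- prox
          add(type, paste(d, prox["s"], dist["s"], max(l1["e"], l2["e"]), sep = "-"),
              members(function(v) nrow(v$im) >= 1L &&
                        v$ex[nrow(v$ex), "s"] == incl_ex["s"] &&
                        .has_j(v, d, incl_ex["s"])),
              members(function(v) nrow(v$im) >= 1L &&
                        v$ex[nrow(v$ex), "s"] == excl_ex["s"] &&
                        .has_j(v, d, excl_ex["s"])))
        }
      }
    }
  }
  if (!length(res))
    return(data.table(type = character(), coords = character(),
                      chrom = character(), strand = character(),
                      inclusion = list(), exclusion = list()))
  rbindlist(res)
}

#' Percent spliced-in (PSI) of events across samples
#'
#' PSI = sum TPM(inclusion isoforms) / (sum TPM(inclusion) +
#' sum TPM(exclusion)); NA when the denominator is zero.
#'
#' @param events event table from [enumerate_as_events()]
#' @param tpm expr_matrix of transcript TPMs covering all member
#'   isoforms
#' @return numeric matrix events x samples (rownames = event ids)
#' @export
compute_psi <- function(events, tpm) {
  ev <- as.data.table(events)
  need <- unique(unlist(c(ev$inclusion, ev$exclusion)))
  miss <- setdiff(need, rownames(tpm))
  if (length(miss))
    stop("isoform(s) missing from the expression matrix: ",
         paste(head(miss, 3L), collapse = ", "))
  m <- matrix(NA_real_, nrow = nrow(ev), ncol = ncol(tpm),
              dimnames = list(ev$event_id, colnames(tpm)))
  for (i in seq_len(nrow(ev))) {
    inc <- colSums(tpm[ev$inclusion[[i]], , drop = FALSE])
    exc <- colSums(tpm[ev$exclusion[[i]], , drop = FALSE])
    tot <- inc + exc
    m[i, ] <- ifelse(tot > 0, inc / tot, NA_real_)
  }
  m
}

#' Differential splicing between two conditions
#'
#' For each event, `delta_psi` is the mean replicate PSI of condition B
#' minus condition A; the two-sided p-value comes from a permutation
#' test on the replicate labels (difference of means statistic), using
#' exact enumeration of all label arrangements when their number does
#' not exceed `exact_max` and Monte-Carlo sampling of `n_perm`
#' permutations otherwise.  Events are classed `up` (delta > 0,
#' p < alpha), `down` (delta < 0, p < alpha) or `none`; events with no
#' defined PSI in a condition are skipped (class NA).
#'
#' @param psi_a,psi_b numeric vectors (one event) or matrices
#'   (events x replicates) of PSI values; NAs are dropped per event
#' @param n_perm Monte-Carlo permutations (default 1000)
#' @param seed integer seed
#' @param alpha significance level (default 0.05)
#' @param exact_max exact-enumeration bound on the arrangement count
#' @return data.table(event_id, delta_psi, p_value, class)
#' @export
diff_splice <- function(psi_a, psi_b, n_perm = 1000L, seed = 1L,
                        alpha = 0.05, exact_max = 5000L) {
  if (is.vector(psi_a)) psi_a <- matrix(psi_a, nrow = 1L)
  if (is.vector(psi_b)) psi_b <- matrix(psi_b, nrow = 1L)
  stopifnot(nrow(psi_a) == nrow(psi_b))
  ids <- rownames(psi_a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(psi_a)))
  combo_cache <- new.env(parent = emptyenv())
  out <- withr::with_seed(seed, {
    rbindlist(lapply(seq_len(nrow(psi_a)), function(i) {
      a <- psi_a[i, ]; a <- a[!is.na(a)]
      b <- psi_b[i, ]; b <- b[!is.na(b)]
      if (!length(a) || !length(b))
        return(data.table(event_id = ids[i], delta_psi = NA_real_,
                          p_value = NA_real_, class = NA_character_))
      delta <- mean(b) - mean(a)
      pooled <- c(a, b)
      nA <- length(a); N <- length(pooled)
      n_arr <- choose(N, nA)
      if (n_arr <= exact_max) {
        key <- paste(N, nA)
        if (is.null(combo_cache[[key]])) combo_cache[[key]] <- combn(N, nA)
        idx <- combo_cache[[key]]
        sumA <- colSums(matrix(pooled[idx], nrow = nA))
        deltas <- (sum(pooled) - sumA) / (N - nA) - sumA / nA
        p <- mean(abs(deltas) >= abs(delta) - 1e-12)
      } else {
        extreme <- 0L
        for (r in seq_len(n_perm)) {
          sel <- sample.int(N, nA)
          d <- mean(pooled[-sel]) - mean(pooled[sel])
          if (abs(d) >= abs(delta) - 1e-12) extreme <- extreme + 1L
        }
        p <- (1 + extreme) / (1 + n_perm)
      }
      cls <- if (p < alpha && delta > 0) "up"
             else if (p < alpha && delta < 0) "down" else "none"
      data.table(event_id = ids[i], delta_psi = delta, p_value = p, class = cls)
    }))
  })
  out[]
}

#' Gained and lost AS events between consecutive stages
#'
#' Events are identified by (type, coordinates, strand); duplicates
#' collapse before set differencing.  Gains are reported relative to
#' the later stage's per-type totals and losses relative to the earlier
#' stage's.
#'
#' @param events_prev,events_curr event tables from
#'   [enumerate_as_events()]
#' @return data.table(type, n_prev, n_curr, n_gained, n_lost, gain_pct,
#'   loss_pct) over the seven event types
#' @export
event_dynamics <- function(events_prev, events_curr) {
  key <- function(ev) unique(as.data.table(ev)[, .(type, chrom, strand, coords)])
  p <- key(events_prev); c_ <- key(events_curr)
  types <- c("SE", "A5", "A3", "RI", "MX", "AF", "AL")
  rbindlist(lapply(types, function(t) {
    ps <- p[type == t, paste(chrom, strand, coords)]
    cs <- c_[type == t, paste(chrom, strand, coords)]
    g <- setdiff(cs, ps); l <- setdiff(ps, cs)
    data.table(type = t, n_prev = length(ps), n_curr = length(cs),
               n_gained = length(g), n_lost = length(l),
               gain_pct = if (length(cs)) 100 * length(g) / length(cs) else 0,
               loss_pct = if (length(ps)) 100 * length(l) / length(ps) else 0)
  }))
}
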