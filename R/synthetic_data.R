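# Synthetic multi-chromosome dataset with known ground truth for every
# downstream analysis: a reference annotation with multi-isoform genes,
# seven stage transcriptomes containing planted exact / contained /
# novel-isoform / novel-gene / other transcripts, promoter H3K4me3 with
# called peaks, CAGE support, conservation tracks with a planted
# conserved subset, TPM/FPKM matrices with planted ZGA genes and
# differential-splicing shifts, and a short-read junction support table
# consistent with the planted splice motifs.
#
# Everything is deterministic under (seed, config); each generation
# stage draws from a seed derived from config$seed with a fixed offset.

#' Simulation configuration
#'
#' Defaults describe a small three-chromosome genome hosting two dozen
#' multi-isoform genes, seven developmental stages (sperm to blastocyst)
#' with two replicates each, 97% canonical GT/AG junctions, and modest
#' log-normal expression noise.
#'
#' @param seed integer master seed
#' @param n_chroms,chrom_length genome shape
#' @param n_genes number of reference genes
#' @param isoforms_per_gene inclusive range of reference isoform counts
#' @param canonical_fraction Bernoulli probability that a distinct
#'   junction is canonical (GT..AG)
#' @param category_props named proportions of the five planted
#'   categories per stage (must sum to 1)
#' @param stages ordered stage labels
#' @param replicates replicates per stage
#' @param transcripts_per_stage planted transcripts per stage
#' @param share_fraction fraction of a stage's members kept from the
#'   preceding stage (per category)
#' @param n_zga,n_conserved,n_sf,n_das planted feature counts
#' @param tpm_sdlog log-normal TPM noise scale
#' @param frac_hc_tss,frac_cage fractions of present-candidate TSSs
#'   given an H3K4me3 peak / CAGE signal
#' @param frac_unsupported_junctions fraction of junctions left without
#'   short-read support
#' @param psi_shift planted differential-splicing delta-PSI magnitude
#' @param das_pair the consecutive stage pair carrying the PSI shift
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_chroms = 3L, chrom_length = 300000L,
                       n_genes = 24L, isoforms_per_gene = c(1L, 3L),
                       canonical_fraction = 0.97,
                       category_props = c(exact = 0.6, contained = 0.1,
                                          novel_isoform = 0.2,
                                          novel_gene = 0.07, other = 0.03),
                       stages = c("sperm", "Oo", "1C", "2C", "4C", "8C", "BL"),
                       replicates = 2L, transcripts_per_stage = 60L,
                       share_fraction = 0.7, n_zga = 12L, n_conserved = 12L,
                       n_sf = 6L, n_das = 6L, tpm_sdlog = 0.15,
                       frac_hc_tss = 0.6, frac_cage = 0.5,
                       frac_unsupported_junctions = 0.05,
                       psi_shift = 0.4, das_pair = c("1C", "2C")) {
  cfg <- as.list(environment())
  if (abs(sum(category_props) - 1) > 1e-9)
    stop("category_props must sum to 1")
  if (!all(names(category_props) == c("exact", "contained", "novel_isoform",
                                      "novel_gene", "other")))
    stop("category_props must be named exact/contained/novel_isoform/novel_gene/other")
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  # worst-case per-gene footprint: margins + 8 exons/7 introns + novel slot
  if (genes_per_chrom * 23000L > 0.95 * chrom_length)
    stop("chrom_length too small to host ", genes_per_chrom,
         " genes per chromosome with >= 30% intergenic space")
  if (n_das > 0L && !all(das_pair %in% stages))
    stop("das_pair must name two stages when DAS events are planted")
  structure(cfg, class = "sim_config")
}

# largest-remainder apportionment of n into proportions p (sums to n)
.apportion <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1L
  }
  as.integer(k)
}

#' Simulate the reference genome, annotation and candidate pool
#'
#' Lays out multi-exon genes with intergenic novel-gene slots, builds
#' the reference isoforms, constructs the full pool of candidate
#' transcripts for the five planted categories, assigns splice-site
#' motifs per distinct junction (canonical GT..AG with probability
#' `canonical_fraction`, otherwise GC..AG or AT..AC subject to
#' shared-site consistency), and emits the genome sequence carrying
#' those motifs.
#'
#' @param config sim_config
#' @return list(genome, reference, truth); truth carries the candidate
#'   exon table, candidate info (category, coding score, planted
#'   biotype), junction motif truth and chromosome sizes
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 101L, .simulate_reference_impl(config))
}

.simulate_reference_impl <- function(config) {
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(as.integer(config$chrom_length),
                              config$n_chroms), chroms)
  ref_ex <- list(); cand_ex <- list(); cand_info <- list()
  gene_meta <- list()
  gene_chrom <- rep(chroms, length.out = config$n_genes)
  cursor <- setNames(rep(3000L, config$n_chroms), chroms)
  biotype_pool <- c("protein_coding", "lincRNA", "processed_pseudogene")

  for (g in seq_len(config$n_genes)) {
    ch <- gene_chrom[g]
    gid <- sprintf("G%03d", g)
    strand <- sample(c("+", "-"), 1L)
    gbt <- sample(biotype_pool, 1L, prob = c(0.6, 0.25, 0.15))
    cursor[ch] <- cursor[ch] + 1500L          # upstream margin (AF exon)
    gstart <- cursor[ch]
    n_ex <- sample(5:8, 1L)
    elens <- sample(seq(120L, 360L, 4L), n_ex, replace = TRUE)
    ilens <- sample(seq(400L, 1500L, 4L), n_ex - 1L, replace = TRUE)
    estarts <- gstart + cumsum(c(0L, head(elens, -1L) + ilens))
    eends <- estarts + elens
    gend <- eends[n_ex]
    # reference isoforms: full skeleton + single-exon-skip variants
    k_iso <- sample(seq(config$isoforms_per_gene[1L],
                        config$isoforms_per_gene[2L]), 1L)
    skips <- if (k_iso > 1L) sample(2:(n_ex - 1L), k_iso - 1L) else integer()
    iso_exsets <- c(list(seq_len(n_ex)),
                    lapply(skips, function(s) setdiff(seq_len(n_ex), s)))
    for (i in seq_along(iso_exsets)) {
      tid <- sprintf("%s.T%d", gid, i)
      sel <- iso_exsets[[i]]
      ref_ex[[tid]] <- data.table(transcript_id = tid, gene_id = gid,
                                  chrom = ch, strand = strand,
                                  start = estarts[sel], end = eends[sel],
                                  biotype = gbt)
    }
    add_cand <- function(id, category, sub_type, starts, ends,
                         cstrand = strand, cgene = gid) {
      cand_ex[[id]] <<- data.table(transcript_id = id, gene_id = cgene,
                                   chrom = ch, strand = cstrand,
                                   start = as.integer(starts),
                                   end = as.integer(ends))
      cand_info[[id]] <<- data.table(cand_id = id, gene_id = cgene,
                                     category = category, sub_type = sub_type)
    }
    # exact candidates: one per reference isoform, ends trimmed
    for (i in seq_along(iso_exsets)) {
      sel <- iso_exsets[[i]]
      s <- estarts[sel]; e <- eends[sel]
      s[1L] <- s[1L] + sample(0:40, 1L)
      e[length(e)] <- e[length(e)] - sample(0:40, 1L)
      add_cand(sprintf("EX_%s_%d", gid, i), "exact", "exact", s, e)
    }
    # contained: interior exons (drop first and last of the skeleton)
    add_cand(sprintf("CT_%s", gid), "contained", "interior",
             estarts[2:(n_ex - 1L)], eends[2:(n_ex - 1L)])
    # novel isoforms: double skip, retained intron, shifted donor, alt first exon
    sel <- setdiff(seq_len(n_ex), c(2L, 3L))
    add_cand(sprintf("NIskip_%s", gid), "novel_isoform", "double_skip",
             estarts[sel], eends[sel])
    kri <- max(3L, n_ex %/% 2L)               # keep clear of the skipped pair
    s <- estarts[-(kri + 1L)]; e <- eends[-(kri + 1L)]
    e[kri] <- eends[kri + 1L]                 # merge exons kri, kri+1
    add_cand(sprintf("NIri_%s", gid), "novel_isoform", "retained_intron", s, e)
    ka <- n_ex - 1L                           # shift donor of intron ka by 60
    s <- estarts; e <- eends
    e[ka] <- e[ka] + 60L
    add_cand(sprintf("NIalt_%s", gid), "novel_isoform", "shifted_donor", s, e)
    s <- estarts; e <- eends
    s[1L] <- gstart - 1400L; e[1L] <- gstart - 1200L
    add_cand(sprintf("NIaf_%s", gid), "novel_isoform", "alt_first_exon", s, e)
    # other: antisense mono-exon over exons 2-3, or intronic mono-exon
    if (g %% 2L == 0L) {
      add_cand(sprintf("OTanti_%s", gid), "other", "antisense",
               estarts[2L] + 10L, eends[3L] - 10L,
               cstrand = if (strand == "+") "-" else "+",
               cgene = sprintf("OTanti_%s", gid))
    } else {
      add_cand(sprintf("OTintr_%s", gid), "other", "intronic",
               eends[1L] + 100L, eends[1L] + 300L,
               cgene = sprintf("OTintr_%s", gid))
    }
    cursor[ch] <- gend + 1200L
    # intergenic novel-gene slot
    slot <- cursor[ch]
    ngid <- sprintf("NG_%03d", g)
    nstrand <- sample(c("+", "-"), 1L)
    if (g %% 3L == 0L) {                      # mono-exon novel gene
      L <- if (g %% 6L == 0L) 150L else sample(seq(300L, 800L, 4L), 1L)
      add_cand(ngid, "novel_gene", "mono", slot, slot + L,
               cstrand = nstrand, cgene = ngid)
    } else {
      nel <- sample(seq(150L, 300L, 4L), 3L, replace = TRUE)
      nil <- sample(seq(400L, 700L, 4L), 2L, replace = TRUE)
      ns <- slot + cumsum(c(0L, head(nel, -1L) + nil))
      add_cand(ngid, "novel_gene", "multi", ns, ns + nel,
               cstrand = nstrand, cgene = ngid)
    }
    cursor[ch] <- slot + 4200L + 1500L
    gene_meta[[gid]] <- data.table(gene_id = gid, chrom = ch, strand = strand,
                                   n_isoforms = length(iso_exsets),
                                   biotype = gbt)
  }
  if (any(cursor > chrom_sizes[names(cursor)] - 2000L))
    stop("genome too small to place all genes")

  reference <- annotation(rbindlist(ref_ex))
  cand_exons <- rbindlist(cand_ex)
  cand_ann <- annotation(cand_exons)
  info <- rbindlist(cand_info)
  info <- merge(info, cand_ann$transcripts[, .(cand_id = transcript_id, chrom,
                                               strand, tss, spliced_length,
                                               n_exons)],
                by = "cand_id", sort = FALSE)
  # planted coding potential and biotype class for novel candidates
  info[, coding_score := NA_real_]
  nov <- info$category %in% c("novel_isoform", "novel_gene")
  p_code <- ifelse(info$category == "novel_isoform", 0.6, 0.3)
  is_coding <- nov & runif(nrow(info)) < p_code
  info[is_coding, coding_score := runif(sum(is_coding), 0.5, 0.95)]
  info[nov & !is_coding, coding_score := runif(sum(nov & !is_coding), 0.05, 0.35)]
  info[, biotype_class := NA_character_]
  info[nov, biotype_class := ifelse(coding_score > 0.44, "protein_coding",
                                    ifelse(spliced_length > 200L, "lncRNA", "else"))]

  # junction motif truth over the union of reference and candidate junctions
  all_ir <- rbind(introns(reference)[, .(chrom, strand, donor, acceptor)],
                  introns(cand_ann)[, .(chrom, strand, donor, acceptor)])
  jdt <- unique(all_ir)
  setorder(jdt, chrom, donor, acceptor, strand)
  jdt[, want_canonical := runif(.N) < config$canonical_fraction]
  # per-site sense motifs with shared-site consistency; on the minus
  # strand the sense-donor site sits at the genomic acceptor end
  jdt[, dkey := paste(chrom, strand, ifelse(strand == "+", donor, acceptor))]
  jdt[, akey := paste(chrom, strand, ifelse(strand == "+", acceptor, donor))]
  donor_can <- jdt[, any(want_canonical), by = dkey]
  acc_can <- jdt[, any(want_canonical), by = akey]
  dmotif <- setNames(rep("GT", nrow(donor_can)), donor_can$dkey)
  amotif <- setNames(rep("AG", nrow(acc_can)), acc_can$akey)
  donor_free <- setNames(!donor_can$V1, donor_can$dkey)
  acc_free <- setNames(!acc_can$V1, acc_can$akey)
  for (i in which(!jdt$want_canonical)) {
    dk <- jdt$dkey[i]; ak <- jdt$akey[i]
    if (donor_free[dk] && acc_free[ak] && runif(1) < 0.5) {
      dmotif[dk] <- "AT"; amotif[ak] <- "AC"      # AT..AC
    } else if (donor_free[dk] && amotif[ak] == "AG") {
      dmotif[dk] <- "GC"                          # GC..AG
    }                                             # else forced canonical
  }
  jdt[, motif5 := dmotif[dkey]]
  jdt[, motif3 := amotif[akey]]
  jdt[, canonical := motif5 == "GT" & motif3 == "AG"]
  jdt[, c("dkey", "akey", "want_canonical") := NULL]

  # genome sequence with motifs written at every splice site
  seqs <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), chrom_sizes[[ch]], replace = TRUE))
  names(seqs) <- chroms
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(jdt))) {
    ch <- jdt$chrom[i]; d <- jdt$donor[i]; a <- jdt$acceptor[i]
    m5 <- strsplit(jdt$motif5[i], "")[[1L]]
    m3 <- strsplit(jdt$motif3[i], "")[[1L]]
    if (jdt$strand[i] == "+") {
      seqs[[ch]][(d + 1L):(d + 2L)] <- m5
      seqs[[ch]][(a - 1L):a] <- m3
    } else {                                     # sense motifs on the - strand
      seqs[[ch]][(a - 1L):a] <- rev(rc[m5])
      seqs[[ch]][(d + 1L):(d + 2L)] <- rev(rc[m3])
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chroms

  truth <- list(cand_exons = cand_exons, cand_info = info,
                junctions = jdt, gene_meta = rbindlist(gene_meta),
                chrom_sizes = chrom_sizes)
  list(genome = genome, reference = reference, truth = truth)
}

#' Simulate per-stage transcript sets
#'
#' Samples stage memberships from the candidate pool so that every
#' stage realises the configured category proportions exactly (largest
#' remainder apportionment) and consecutive stages share the configured
#' fraction per category.  Also fixes the planted differential-splicing
#' genes, ZGA candidates and conserved non-coding candidates among the
#' candidates present in at least one stage.
#'
#' @param reference reference annotation (from [simulate_reference()])
#' @param truth truth list (updated and returned)
#' @param config sim_config
#' @return list(stage_sets = named list of annotations, truth)
#' @export
simulate_stage_transcriptomes <- function(reference, truth, config) {
  withr::with_seed(config$seed + 202L, {
    info <- truth$cand_info
    cats <- c("exact", "contained", "novel_isoform", "novel_gene", "other")
    n_cat <- setNames(.apportion(unname(config$category_props[cats]),
                                 config$transcripts_per_stage), cats)
    pools <- lapply(cats, function(cc) info[category == cc, cand_id])
    names(pools) <- cats
    short <- n_cat > vapply(pools, length, 0L)
    if (any(short))
      stop("candidate pool too small for category ", cats[short][1L])

    # planted DAS genes: need >= 2 reference isoforms (inclusion/exclusion pair)
    das_genes <- truth$gene_meta[n_isoforms >= 2L][
      seq_len(min(config$n_das, .N)), gene_id]
    das <- data.table(gene_id = das_genes,
                      incl_id = sprintf("EX_%s_1", das_genes),
                      excl_id = sprintf("EX_%s_2", das_genes),
                      direction = rep_len(c(1, -1), length(das_genes)))

    members <- list(); prev <- NULL
    for (s in config$stages) {
      cur <- lapply(cats, function(cc) {
        n <- n_cat[[cc]]
        if (n == 0L) return(character())
        keep <- character()
        if (!is.null(prev)) {
          pv <- intersect(prev, pools[[cc]])
          keep <- sample(pv, min(round(config$share_fraction * n), length(pv)))
        }
        fresh <- sample(setdiff(pools[[cc]], keep), n - length(keep))
        c(keep, fresh)
      })
      cur <- unlist(cur)
      # DAS event isoforms must be quantifiable in every stage
      cur <- union(cur, c(das$incl_id, das$excl_id))
      members[[s]] <- sort(cur)
      prev <- cur
    }
    member_dt <- rbindlist(lapply(config$stages, function(s)
      data.table(stage = s, cand_id = members[[s]])))
    present <- unique(member_dt$cand_id)
    info[, present := cand_id %in% present]

    # ZGA candidates: present, outside DAS genes
    zga_pool <- info[present == TRUE & !gene_id %in% das$gene_id, cand_id]
    info[, zga := cand_id %in% sample(zga_pool, min(config$n_zga,
                                                    length(zga_pool)))]
    # conserved candidates: present non-coding novel genes only — novel
    # genes occupy disjoint intergenic slots, so elevated conservation
    # signal never bleeds into the exons of unrelated candidates
    cons_pool <- info[present == TRUE & category == "novel_gene" &
                        biotype_class %in% c("lncRNA", "else"), cand_id]
    info[, conserved := cand_id %in% sample(cons_pool,
                                            min(config$n_conserved,
                                                length(cons_pool)))]
    truth$cand_info <- info
    truth$stage_members <- member_dt
    truth$das <- das
    cand_ann <- annotation(truth$cand_exons)
    stage_sets <- lapply(config$stages, function(s)
      subset_annotation(cand_ann, members[[s]]))
    names(stage_sets) <- config$stages
    list(stage_sets = stage_sets, truth = truth)
  })
}

# genome-wide track on a fixed bin grid; values drawn by value_fun(n)
.grid_track <- function(chrom_sizes, binsize, value_fun) {
  rbindlist(lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    starts <- seq(0L, L - 1L, by = binsize)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + binsize, L), value = value_fun(length(starts)))
  }))
}

# overwrite grid bins overlapping the given regions
.override_bins <- function(grid, regions, binsize, value_fun) {
  for (i in seq_len(nrow(regions))) {
    sel <- grid$chrom == regions$chrom[i] &
      grid$end > regions$start[i] & grid$start < regions$end[i]
    grid[sel, value := value_fun(sum(sel))]
  }
  grid
}

#' Simulate chromatin, CAGE and conservation tracks
#'
#' High-confidence TSSs receive a bimodal H3K4me3 bump (two flanks at
#' +/-500 bp) plus a called peak in one of three stage peak sets; a
#' CAGE run is placed at a configured subset of TSSs in one of two
#' samples; conserved candidates get elevated phyloP/phastCons over
#' their exons against a genome-wide background.  The realised
#' high-confidence and CAGE flags (any TSS within +/-500 bp of a peak /
#' nonzero CAGE interval, including incidental neighbours) are written
#' back into the truth.
#'
#' @param reference reference annotation
#' @param truth truth list (after [simulate_stage_transcriptomes()])
#' @param config sim_config
#' @return list(h3k4me3, peak_sets, cage_tracks, phylop, phastcons,
#'   truth)
#' @export
simulate_tracks <- function(reference, truth, config) {
  withr::with_seed(config$seed + 303L, {
    info <- truth$cand_info
    sizes <- truth$chrom_sizes
    pres <- info[present == TRUE]
    # choose promoter-marked and CAGE-marked TSSs among present candidates
    hc_sel <- pres[runif(.N) < config$frac_hc_tss, cand_id]
    cage_sel <- pres[runif(.N) < config$frac_cage, cand_id]

    # H3K4me3: additive bimodal bumps on a 50-bp grid
    binsize <- 50L
    bump_tss <- pres[cand_id %in% hc_sel, .(cand_id, chrom, tss)]
    bins <- rbindlist(lapply(seq_len(nrow(bump_tss)), function(i) {
      tss <- bump_tss$tss[i]
      bs <- seq(((tss - 2000L) %/% binsize) * binsize,
                ((tss + 2000L) %/% binsize) * binsize, by = binsize)
      x <- bs + binsize / 2 - tss
      amp <- runif(1L, 8, 15)
      data.table(chrom = bump_tss$chrom[i], start = bs,
                 value = amp * (exp(-(x + 500)^2 / (2 * 250^2)) +
                                  exp(-(x - 500)^2 / (2 * 250^2))))
    }))
    h3k <- if (nrow(bins)) {
      agg <- bins[, .(value = sum(value)), by = .(chrom, start)]
      agg <- agg[start >= 0L]
      agg[, end := start + binsize]
      signal_track(agg[value > 1e-4], default = 0)
    } else signal_track(data.table(chrom = character(), start = integer(),
                                   end = integer(), value = numeric()))
    # peaks: each marked TSS contributes a peak to one of three stage sets
    peak_dt <- pres[cand_id %in% hc_sel,
                    .(chrom, start = pmax(tss - 300L, 0L), end = tss + 300L)]
    peak_sets <- lapply(1:3, function(k)
      if (nrow(peak_dt)) peak_dt[seq_len(.N) %% 3L == (k - 1L)] else peak_dt)
    names(peak_sets) <- c("2C", "4C", "8C")

    # CAGE: two samples, nonzero run at selected TSSs
    cage_dt <- pres[cand_id %in% cage_sel,
                    .(chrom, start = pmax(tss - 100L, 0L), end = tss + 100L,
                      smp = seq_len(.N) %% 2L + 1L)]
    cage_tracks <- lapply(1:2, function(k) {
      d <- cage_dt[smp == k, .(chrom, start, end)]
      if (!nrow(d))
        return(signal_track(data.table(chrom = character(), start = integer(),
                                       end = integer(), value = numeric())))
      m <- merge_intervals(d)
      m[, value := runif(.N, 1, 5)]
      signal_track(m, default = 0)
    })

    # conservation: genome-wide background, elevated over conserved exons
    cons_ex <- merge(truth$cand_exons, info[conserved == TRUE, .(cand_id)],
                     by.x = "transcript_id", by.y = "cand_id")
    phylop_grid <- .grid_track(sizes, 100L, function(n) rnorm(n, 0, 0.3))
    phylop_grid <- .override_bins(phylop_grid, cons_ex, 100L,
                                  function(n) rnorm(n, 1.5, 0.2))
    phast_grid <- .grid_track(sizes, 100L,
                              function(n) pmin(pmax(rnorm(n, 0.10, 0.05), 0), 1))
    phast_grid <- .override_bins(phast_grid, cons_ex, 100L,
                                 function(n) pmin(rnorm(n, 0.9, 0.03), 1))
    phylop <- signal_track(phylop_grid, default = 0)
    phastcons <- signal_track(phast_grid, default = 0)

    # realised truth flags (incidental overlaps included)
    tssdt <- pres[, .(transcript_id = cand_id, chrom, tss)]
    info[, hc_tss := FALSE]
    info[cand_id %in% tssdt$transcript_id,
         hc_tss := high_confidence_tss(tssdt, peak_sets)]
    info[, cage := FALSE]
    info[cand_id %in% tssdt$transcript_id,
         cage := cage_supported(tssdt, cage_tracks)]
    truth$cand_info <- info
    list(h3k4me3 = h3k, peak_sets = peak_sets, cage_tracks = cage_tracks,
         phylop = phylop, phastcons = phastcons, truth = truth)
  })
}

#' Simulate expression matrices and the junction support table
#'
#' Builds the transcript TPM matrix over all candidates present in any
#' stage (log-normal replicate noise around planted stage means), the
#' gene FPKM matrix, a short-read junction support table giving every
#' junction at least ten reads in one sample unless planted
#' unsupported, two mapped-read count tables differing by more than the
#' quantification-change threshold for a planted subset, and per-stage
#' AS-event counts with splicing-factor genes whose expression is
#' linearly coupled (planted sign) to those counts.
#'
#' Planted expression patterns keep wide margins around the ZGA
#' thresholds: ZGA candidates are off in the oocyte, on from the 1-cell
#' stage and more than doubled at the 2-cell stage; all other
#' candidates are either maternally expressed, uniformly expressed, or
#' off until after the 2-cell stage.
#'
#' @param reference reference annotation
#' @param truth truth list (after tracks)
#' @param config sim_config
#' @return list(tpm, fpkm, junction_support, counts_ref_a, counts_ref_b,
#'   as_counts, truth)
#' @export
simulate_quantification <- function(reference, truth, config) {
  withr::with_seed(config$seed + 404L, {
    info <- truth$cand_info
    stages <- config$stages
    reps <- config$replicates
    samples <- as.vector(t(outer(stages, seq_len(reps), paste, sep = "_")))
    pres <- info[present == TRUE]
    das <- truth$das

    # planted per-stage mean TPM per present candidate
    mu <- matrix(0.05, nrow = nrow(pres), ncol = length(stages),
                 dimnames = list(pres$cand_id, stages))
    pat <- sample(c("maternal", "uniform", "late"), nrow(pres),
                  replace = TRUE, prob = c(0.3, 0.5, 0.2))
    for (i in seq_len(nrow(pres))) {
      mu[i, ] <- switch(pat[i],
        maternal = c(runif(1, 5, 30), runif(1, 5, 30),
                     runif(length(stages) - 2L, 2, 30)),
        uniform = rep(runif(1, 3, 30), length(stages)),
        late = {
          v <- rep(0.05, length(stages))
          i2c <- match("2C", stages)
          if (!is.na(i2c) && i2c < length(stages))
            v[(i2c + 1L):length(stages)] <- runif(length(stages) - i2c, 3, 20)
          v
        })
    }
    # ZGA pattern: off in oocyte, on at 1C, >2x at 2C
    zga_ids <- pres[cand_id %in% info[zga == TRUE, cand_id], cand_id]
    for (id in zga_ids) {
      v <- rep(0.05, length(stages)); names(v) <- stages
      v["Oo"] <- 0.05; v["1C"] <- 8; v["2C"] <- 40
      later <- which(seq_along(stages) > match("2C", stages))
      v[later] <- runif(length(later), 5, 30)
      mu[id, ] <- v
    }
    # DAS genes: only the planted pair expressed; PSI shifts at das_pair
    i_hi <- match(config$das_pair[2L], stages)
    for (k in seq_len(nrow(das))) {
      others <- info[gene_id == das$gene_id[k] & present == TRUE &
                       !cand_id %in% c(das$incl_id[k], das$excl_id[k]), cand_id]
      others <- intersect(others, rownames(mu))
      if (length(others)) mu[others, ] <- 0.05
      psi_lo <- if (das$direction[k] > 0) 0.25 else 0.25 + config$psi_shift
      psi_hi <- psi_lo + das$direction[k] * config$psi_shift
      psi <- ifelse(seq_along(stages) >= i_hi, psi_hi, psi_lo)
      total <- 30
      mu[das$incl_id[k], ] <- psi * total
      mu[das$excl_id[k], ] <- (1 - psi) * total
    }
    tpm_vals <- matrix(0, nrow = nrow(pres), ncol = length(samples),
                       dimnames = list(pres$cand_id, samples))
    for (j in seq_along(samples)) {
      st <- sub("_[^_]*$", "", samples[j])
      tpm_vals[, j] <- mu[, st] * rlnorm(nrow(pres), 0, config$tpm_sdlog)
    }
    tpm <- expression_matrix(tpm_vals, unit = "TPM")

    # per-stage AS event counts (from the stage annotations) and SF genes
    cand_ann <- annotation(truth$cand_exons)
    as_counts <- vapply(stages, function(s) {
      ids <- truth$stage_members[stage == s, cand_id]
      nrow(enumerate_as_events(subset_annotation(cand_ann, ids)))
    }, 0L)
    sf_pool <- truth$gene_meta[!gene_id %in% das$gene_id, gene_id]
    sf_genes <- sample(sf_pool, min(config$n_sf, length(sf_pool)))
    sf <- data.table(gene_id = sf_genes,
                     direction = rep_len(c(1, -1), length(sf_genes)))
    gmu <- matrix(rlnorm(nrow(truth$gene_meta) * length(stages),
                         log(10), 0.5),
                  nrow = nrow(truth$gene_meta),
                  dimnames = list(truth$gene_meta$gene_id, stages))
    for (k in seq_len(nrow(sf))) {
      gmu[sf$gene_id[k], ] <- 100 + sf$direction[k] * 2 *
        (as_counts - min(as_counts))
    }
    fpkm_vals <- matrix(0, nrow = nrow(gmu), ncol = length(samples),
                        dimnames = list(rownames(gmu), samples))
    for (j in seq_along(samples)) {
      st <- sub("_[^_]*$", "", samples[j])
      fpkm_vals[, j] <- gmu[, st] * rlnorm(nrow(gmu), 0, 0.02)
    }
    fpkm <- expression_matrix(fpkm_vals, unit = "FPKM")

    # junction support: >= 10 reads in one sample unless planted unsupported
    pres_ann <- subset_annotation(cand_ann, pres$cand_id)
    jn <- unique(introns(pres_ann)[, .(chrom, strand, donor, acceptor)])
    jn[, supported := runif(.N) >= config$frac_unsupported_junctions]
    support <- rbindlist(lapply(seq_len(nrow(jn)), function(i) {
      cnt <- if (jn$supported[i]) {
        hi <- sample(seq_along(samples), 1L)
        v <- sample(0:8, length(samples), replace = TRUE)
        v[hi] <- sample(15:80, 1L)
        v
      } else sample(0:5, length(samples), replace = TRUE)
      data.table(chrom = jn$chrom[i], donor = jn$donor[i],
                 acceptor = jn$acceptor[i], strand = jn$strand[i],
                 sample_id = samples, count = cnt)
    }))
    truth$junction_support_truth <- jn

    # quantification-change count tables over reference transcripts
    rt <- reference$transcripts$transcript_id
    base <- matrix(rlnorm(length(rt) * length(stages), log(200), 0.4),
                   nrow = length(rt), dimnames = list(rt, stages))
    counts_a <- round(base)
    counts_b <- counts_a
    flagged <- sample(rt, max(1L, round(0.1 * length(rt))))
    for (id in flagged) {
      st <- sample(stages, 1L)
      counts_b[id, st] <- counts_a[id, st] * sample(6:12, 1L)
    }
    truth$quant_flagged <- flagged
    truth$sf <- sf
    truth$as_counts <- as_counts
    truth$cand_info <- info
    list(tpm = tpm, fpkm = fpkm, junction_support = support,
         counts_ref_a = counts_a, counts_ref_b = counts_b,
         as_counts = as_counts, truth = truth)
  })
}

#' Simulate a complete dataset
#'
#' Runs [simulate_reference()], [simulate_stage_transcriptomes()],
#' [simulate_tracks()] and [simulate_quantification()] in order and
#' returns all pieces plus the accumulated truth labels.
#'
#' @param config sim_config
#' @return list(genome, reference, stage_sets, tracks, tpm, fpkm,
#'   junction_support, counts_ref_a, counts_ref_b, as_counts, truth,
#'   config)
#' @export
simulate_dataset <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  stg <- simulate_stage_transcriptomes(ref$reference, ref$truth, config)
  trk <- simulate_tracks(ref$reference, stg$truth, config)
  qnt <- simulate_quantification(ref$reference, trk$truth, config)
  list(genome = ref$genome, reference = ref$reference,
       stage_sets = stg$stage_sets,
       tracks = trk[c("h3k4me3", "peak_sets", "cage_tracks",
                      "phylop", "phastcons")],
       tpm = qnt$tpm, fpkm = qnt$fpkm,
       junction_support = qnt$junction_support,
       counts_ref_a = qnt$counts_ref_a, counts_ref_b = qnt$counts_ref_b,
       as_counts = qnt$as_counts, truth = qnt$truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits genome.fa, reference.gtf, stage_<s>.gtf, h3k4me3.bedgraph,
#' peaks_<s>.bed, cage_<k>.bedgraph, phylop.bedgraph,
#' phastcons.bedgraph, tpm.tsv, fpkm.tsv, junctions.tsv,
#' coding_scores.tsv and truth_transcripts.tsv.
#'
#' @param sim result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_genome(sim$genome, fp("genome.fa"))
  write_gtf(sim$reference, fp("reference.gtf"))
  for (s in names(sim$stage_sets))
    write_gtf(sim$stage_sets[[s]], fp(sprintf("stage_%s.gtf", s)))
  write_bedgraph(sim$tracks$h3k4me3, fp("h3k4me3.bedgraph"))
  for (s in names(sim$tracks$peak_sets))
    write_bed(sim$tracks$peak_sets[[s]], fp(sprintf("peaks_%s.bed", s)))
  for (k in seq_along(sim$tracks$cage_tracks))
    write_bedgraph(sim$tracks$cage_tracks[[k]], fp(sprintf("cage_%d.bedgraph", k)))
  write_bedgraph(sim$tracks$phylop, fp("phylop.bedgraph"))
  write_bedgraph(sim$tracks$phastcons, fp("phastcons.bedgraph"))
  write_expression_tsv(sim$tpm, fp("tpm.tsv"), id_col = "transcript_id")
  write_expression_tsv(sim$fpkm, fp("fpkm.tsv"), id_col = "gene_id")
  write_junction_tsv(sim$junction_support, fp("junctions.tsv"))
  fwrite(sim$truth$cand_info[present == TRUE,
                             .(transcript_id = cand_id, coding_score)],
         fp("coding_scores.tsv"), sep = "\t")
  fwrite(sim$truth$cand_info, fp("truth_transcripts.tsv"), sep = "\t")
  invisible(dir)
}

#' Simulate replicate PSI values for differential-splicing calibration
#'
#' Generates per-event replicate PSI values in two conditions with a
#' planted mean shift, clipped to [0, 1].
#'
#' @param n_events number of events
#' @param reps replicates per condition (default 5)
#' @param delta planted mean shift (condition B minus A; default 0)
#' @param noise_sd replicate noise standard deviation (default 0.05)
#' @param seed integer seed
#' @return list(psi_a, psi_b) matrices of dimension n_events x reps
#' @export
simulate_psi_replicates <- function(n_events, reps = 5L, delta = 0,
                                    noise_sd = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    base <- runif(n_events, 0.2, 0.55)
    clip <- function(x) pmin(pmax(x, 0), 1)
    psi_a <- clip(matrix(rnorm(n_events * reps, base, noise_sd),
                         nrow = n_events))
    psi_b <- clip(matrix(rnorm(n_events * reps, base + delta, noise_sd),
                         nrow = n_events))
    list(psi_a = psi_a, psi_b = psi_b)
  })
}
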