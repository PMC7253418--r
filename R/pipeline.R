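# End-to-end orchestration: classify -> merge -> biotype -> conservation
# -> TSS validation -> splicing -> stage dynamics -> ZGA, from a single
# flat configuration, producing the augmented annotation and a
# structured report whose counts cross-foot with the per-record tables.

#' Default pipeline thresholds
#'
#' Every analysis threshold with its default, overridable through the
#' pipeline configuration: coding-potential cutoff 0.44, lncRNA minimum
#' length 200 bp, annotated-TSS half-width 300 bp, peak/CAGE window
#' half-width 500 bp, minimum short-read junction support 10,
#' expression on/off threshold 1, conservation calibration percentile
#' 95 with 200-bp windows, differential-splicing alpha 0.05, and
#' quantification-change delta threshold 5.
#'
#' @return named list of defaults
#' @export
pipeline_defaults <- function() {
  list(coding_cutoff = 0.44, lnc_min_length = 200L, tss_halfwidth = 300L,
       peak_halfwidth = 500L, min_junction_reads = 10L, off_threshold = 1,
       conservation_percentile = 95, conservation_window = 200L,
       psi_alpha = 0.05, n_perm = 1000L, delta_threshold = 5)
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  thr <- pipeline_defaults()
  for (k in names(thr)) if (!is.null(config[[k]])) thr[[k]] <- config[[k]]
  config$thresholds <- thr
  config
}

.validate_paths <- function(config) {
  need <- c("reference_gtf", "genome_fasta", "tpm_tsv", "junctions_tsv",
            "h3k4me3_bedgraph", "phylop_bedgraph", "phastcons_bedgraph",
            "coding_scores_tsv")
  for (k in need) {
    if (is.null(config[[k]])) stop("pipeline config missing field: ", k)
    if (!file.exists(config[[k]])) stop("missing input file for ", k, ": ",
                                        config[[k]])
  }
  for (p in unlist(config$stage_gtfs))
    if (!file.exists(p)) stop("missing stage GTF: ", p)
  for (p in unlist(c(config$peak_beds, config$cage_bedgraphs)))
    if (!file.exists(p)) stop("missing track file: ", p)
  invisible(config)
}

# union of the stage sets at transcript-id level (identical ids dedupe)
.union_annotation <- function(stage_sets) {
  ex <- unique(rbindlist(lapply(stage_sets, function(a) a$exons)),
               by = c("transcript_id", "start", "end"))
  annotation(ex)
}

#' Run the full analysis pipeline
#'
#' Executes classification of every stage set against the reference,
#' cross-stage merging, biotype classification of the merged
#' transcripts, conservation scoring of the novel non-coding ones
#' against calibrated intergenic controls, TSS categorisation and
#' validation (H3K4me3 peaks, CAGE), junction extraction/validation and
#' seven-type AS-event analysis with PSI and differential splicing over
#' consecutive stages, transcript gain/loss dynamics, and ZGA calls.
#' Writes the augmented annotation (reference plus novel isoforms and
#' novel genes) and all per-record tables to `outdir`.
#'
#' @param config path to a flat YAML file or an equivalent named list
#'   with fields: reference_gtf, genome_fasta, stage_gtfs (named list
#'   stage -> path, in stage order), tpm_tsv, fpkm_tsv (optional),
#'   junctions_tsv, h3k4me3_bedgraph, peak_beds (list),
#'   cage_bedgraphs (list), phylop_bedgraph, phastcons_bedgraph,
#'   coding_scores_tsv, seed, outdir, plus any threshold from
#'   [pipeline_defaults()]
#' @return the report: a named list of summary tables; per-record
#'   tables are written under `outdir`
#' @export
run_pipeline <- function(config) {
  config <- .read_config(config)
  .validate_paths(config)
  thr <- config$thresholds
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- if (is.null(config$outdir)) stop("config needs an outdir") else
    config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- list()
  log_step <- function(step, n_in, n_out)
    log_lines[[length(log_lines) + 1L]] <<- data.table(
      step = step, n_in = n_in, n_out = n_out)

  reference <- read_gtf(config$reference_gtf)
  genome <- read_genome(config$genome_fasta)
  stages <- names(config$stage_gtfs)
  stage_sets <- lapply(config$stage_gtfs, read_gtf)
  tpm <- read_expression_tsv(config$tpm_tsv, unit = "TPM")
  scores_dt <- fread(config$coding_scores_tsv, sep = "\t")
  coding_scores <- setNames(scores_dt[[2L]], scores_dt[[1L]])

  # 1. per-stage classification ------------------------------------------
  per_stage <- lapply(stages, function(s) {
    cmp <- classify_transcripts(stage_sets[[s]], reference)
    log_step(paste0("classify_", s), nrow(stage_sets[[s]]$transcripts), nrow(cmp))
    cmp
  })
  names(per_stage) <- stages
  stage_categories <- rbindlist(lapply(stages, function(s)
    cbind(stage = s, category_summary(per_stage[[s]]))))

  # 2. merge + merged classification --------------------------------------
  merged <- merge_transcriptomes(stage_sets)
  union_ann <- .union_annotation(stage_sets)
  merged_cmp <- classify_transcripts(merged$annotation, reference)
  log_step("merge", merged$n_input, nrow(merged$annotation$transcripts))
  merged_categories <- category_summary(merged_cmp)

  # union-level classification drives per-transcript analyses (ids match
  # the expression matrix and score tables)
  union_cmp <- classify_transcripts(union_ann, reference)
  novel_ids <- union_cmp[category %in% c("novel_isoform", "novel_gene"), query_id]

  # augmented annotation: reference + novel transcripts
  aug <- annotation(rbind(reference$exons,
                          union_ann$exons[transcript_id %in% novel_ids]))
  write_gtf(aug, file.path(outdir, "augmented.gtf"))
  log_step("augment", nrow(reference$transcripts), nrow(aug$transcripts))

  # 3. biotype -------------------------------------------------------------
  ref_bt <- setNames(reference$transcripts$biotype,
                     reference$transcripts$transcript_id)
  best_bt <- ref_bt[union_cmp$best_ref]
  names(best_bt) <- union_cmp$query_id
  biotype <- classify_biotype(
    union_cmp$query_id, union_cmp$category,
    coding_scores = coding_scores,
    spliced_lengths = setNames(union_ann$transcripts$spliced_length,
                               union_ann$transcripts$transcript_id),
    ref_biotypes = best_bt,
    cutoff = thr$coding_cutoff, min_lnc_length = thr$lnc_min_length)
  biotype <- merge(biotype, union_cmp[, .(transcript_id = query_id, set)],
                   by = "transcript_id")
  biotype_summary <- biotype[set %in% c("annotated", "novel"),
                             .N, by = .(set, class)]
  log_step("biotype", nrow(union_cmp), nrow(biotype))

  # 4. expression tiers ----------------------------------------------------
  sm <- stage_means(tpm)
  tier_tbl <- rbindlist(lapply(colnames(sm), function(s) {
    ids <- intersect(rownames(sm), union_cmp$query_id)
    data.table(stage = s, tier = expression_tier(sm[ids, s]))[, .N, by = .(stage, tier)]
  }))

  # 5. conservation of novel non-coding transcripts ------------------------
  chrom_sizes <- setNames(Biostrings::width(genome), names(genome))
  noncoding_novel <- biotype[transcript_id %in% novel_ids &
                               class %in% c("lncRNA", "else"), transcript_id]
  conservation <- NULL
  cutoffs <- NULL
  if (length(noncoding_novel) >= 5L) {
    phylop <- read_bedgraph(config$phylop_bedgraph)
    phastcons <- read_bedgraph(config$phastcons_bedgraph)
    controls <- sample_control_regions(aug,
                                       subset_annotation(union_ann, noncoding_novel),
                                       chrom_sizes, seed = seed)
    cutoffs <- calibrate_cutoffs(controls, phylop, phastcons,
                                 percentile = thr$conservation_percentile,
                                 window = thr$conservation_window,
                                 min_controls = min(20L, length(noncoding_novel)))
    conservation <- conservation_scores(union_ann, noncoding_novel,
                                        phylop, phastcons, cutoffs,
                                        window = thr$conservation_window)
    fwrite(conservation, file.path(outdir, "conservation.tsv"), sep = "\t")
    log_step("conservation", length(noncoding_novel), nrow(conservation))
  }

  # 6. TSS validation ------------------------------------------------------
  tss_tbl <- categorize_tss(union_cmp, union_ann, reference,
                            halfwidth = thr$tss_halfwidth)
  tss_tbl <- merge(tss_tbl,
                   union_ann$transcripts[, .(transcript_id, chrom)],
                   by = "transcript_id")
  peak_sets <- lapply(config$peak_beds, read_bed)
  cage_tracks <- lapply(config$cage_bedgraphs, read_bedgraph)
  novel_tss <- tss_tbl[group %in% c("classic", "novel", "novel_gene")]
  novel_tss[, high_confidence := high_confidence_tss(novel_tss, peak_sets,
                                                     halfwidth = thr$peak_halfwidth)]
  novel_tss[, cage_supported := cage_supported(novel_tss, cage_tracks,
                                               halfwidth = thr$peak_halfwidth)]
  h3k <- read_bedgraph(config$h3k4me3_bedgraph)
  profiles <- promoter_profiles(h3k, novel_tss)
  fwrite(data.table(transcript_id = rownames(profiles), profiles),
         file.path(outdir, "promoter_profiles.tsv"), sep = "\t")
  fwrite(novel_tss, file.path(outdir, "tss.tsv"), sep = "\t")
  log_step("tss", nrow(tss_tbl), nrow(novel_tss))
  tss_summary <- novel_tss[, .N, by = .(group, high_confidence)]

  # 7. splicing ------------------------------------------------------------
  junctions <- extract_junctions(union_ann, genome)
  jn_distinct <- unique(junctions[, .(chrom, strand, donor, acceptor, canonical)])
  support <- read_junction_tsv(config$junctions_tsv)
  validated <- validate_junctions(jn_distinct, support,
                                  min_reads = thr$min_junction_reads)
  events <- enumerate_as_events(union_ann)
  psi <- compute_psi(events, tpm)
  fwrite(data.table(event_id = rownames(psi), psi),
         file.path(outdir, "psi.tsv"), sep = "\t")
  log_step("as_events", nrow(union_ann$transcripts), nrow(events))
  # per-stage events and event dynamics
  stage_events <- lapply(stages, function(s)
    enumerate_as_events(stage_sets[[s]]))
  names(stage_events) <- stages
  event_counts <- data.table(stage = stages,
                             n_events = vapply(stage_events, nrow, 0L))
  ev_dyn <- rbindlist(lapply(seq_len(length(stages) - 1L), function(i)
    cbind(pair = paste(stages[i], stages[i + 1L], sep = "->"),
          event_dynamics(stage_events[[i]], stage_events[[i + 1L]]))))
  # differential splicing over consecutive stages from the oocyte on
  das_stages <- setdiff(stages, "sperm")
  st_of <- sample_stages(tpm)
  das <- rbindlist(lapply(seq_len(length(das_stages) - 1L), function(i) {
    a <- das_stages[i]; b <- das_stages[i + 1L]
    res <- diff_splice(psi[, st_of == a, drop = FALSE],
                       psi[, st_of == b, drop = FALSE],
                       n_perm = thr$n_perm, seed = seed + i,
                       alpha = thr$psi_alpha)
    cbind(pair = paste(a, b, sep = "->"), res)
  }))
  fwrite(das, file.path(outdir, "das.tsv"), sep = "\t")
  das_summary <- das[!is.na(class), .N, by = .(pair, class)]

  # 8. transcript dynamics -------------------------------------------------
  dyn <- rbindlist(lapply(seq_len(length(stages) - 1L), function(i) {
    d <- stage_dynamics(stage_sets[[i]], stage_sets[[i + 1L]])
    data.table(pair = paste(stages[i], stages[i + 1L], sep = "->"),
               n_gained = length(d$gained), n_lost = length(d$lost),
               gain_pct = d$gain_pct, loss_pct = d$loss_pct)
  }))

  # 9. ZGA -----------------------------------------------------------------
  zga <- call_zga(tpm, off_threshold = thr$off_threshold)
  fwrite(zga, file.path(outdir, "zga.tsv"), sep = "\t")
  zga_genes <- if (!is.null(config$fpkm_tsv) && file.exists(config$fpkm_tsv))
    call_zga(read_expression_tsv(config$fpkm_tsv, unit = "FPKM"),
             off_threshold = thr$off_threshold) else NULL
  log_step("zga", nrow(zga), sum(zga$is_zga))

  fwrite(rbindlist(lapply(per_stage, identity), idcol = "stage"),
         file.path(outdir, "comparison_per_stage.tsv"), sep = "\t")
  fwrite(merged_cmp, file.path(outdir, "comparison_merged.tsv"), sep = "\t")
  fwrite(biotype, file.path(outdir, "biotype.tsv"), sep = "\t")
  fwrite(validated, file.path(outdir, "junctions_validated.tsv"), sep = "\t")
  fwrite(rbindlist(log_lines), file.path(outdir, "log.tsv"), sep = "\t")

  report <- list(
    stage_categories = stage_categories,
    merged_categories = merged_categories,
    n_merged = nrow(merged$annotation$transcripts),
    n_augmented = nrow(aug$transcripts),
    n_reference = nrow(reference$transcripts),
    n_novel = length(novel_ids),
    biotype_summary = biotype_summary,
    expression_tiers = tier_tbl,
    conservation_cutoffs = if (!is.null(cutoffs))
      cutoffs[c("base_cutoff", "fraction_cutoff", "window_cutoff")] else NULL,
    n_conserved_both = if (!is.null(conservation)) sum(conservation$both) else NA,
    tss_summary = tss_summary,
    junction_canonical_pct = 100 * mean(jn_distinct$canonical),
    junction_validated_pct = 100 * mean(validated$validated),
    event_counts = event_counts,
    event_dynamics = ev_dyn,
    das_summary = das_summary,
    transcript_dynamics = dyn,
    n_zga_transcripts = sum(zga$is_zga),
    n_zga_genes = if (!is.null(zga_genes)) sum(zga_genes$is_zga) else NA,
    thresholds = thr, seed = seed)
  yaml::write_yaml(report[c("n_merged", "n_augmented", "n_reference",
                            "n_novel", "junction_canonical_pct",
                            "n_zga_transcripts", "thresholds", "seed")],
                   file.path(outdir, "report.yaml"))
  report
}
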