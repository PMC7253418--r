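# Biotype assignment (protein_coding / lncRNA / else), ORF extraction,
# homology-hit significance classes and expression tiers.

# reference biotype label -> three-way class
.REF_BIOTYPE_MAP <- list(
  protein_coding = "protein_coding",
  lncRNA = c("lncRNA", "lincRNA", "antisense", "antisense_RNA",
             "processed_transcript", "sense_intronic", "sense_overlapping",
             "bidirectional_promoter_lncRNA", "3prime_overlapping_ncRNA")
)

#' Three-way biotype classification
#'
#' Annotated transcripts (categories exact_match / contained) are mapped
#' from their reference biotype; novel transcripts (novel_isoform /
#' novel_gene) are classified from their coding-potential score:
#' protein_coding when `score > cutoff`, lncRNA when `score <= cutoff`
#' and the spliced length exceeds `min_lnc_length`, else otherwise.
#'
#' @param transcript_ids character vector
#' @param categories five-way category per transcript (from
#'   [classify_transcripts()])
#' @param coding_scores named numeric vector in [0,1] covering every
#'   novel transcript (coding-potential scores are consumed, not
#'   computed)
#' @param spliced_lengths named integer vector of spliced lengths
#' @param ref_biotypes named character vector of reference biotype
#'   labels for annotated transcripts
#' @param cutoff coding-potential cutoff (default 0.44)
#' @param min_lnc_length minimum spliced length for lncRNA (default 200)
#' @return data.table(transcript_id, class, basis, coding_score)
#' @export
classify_biotype <- function(transcript_ids, categories, coding_scores = NULL,
                             spliced_lengths = NULL, ref_biotypes = NULL,
                             cutoff = 0.44, min_lnc_length = 200L) {
  stopifnot(length(transcript_ids) == length(categories))
  out <- data.table(transcript_id = transcript_ids, category = categories,
                    class = NA_character_, basis = NA_character_,
                    coding_score = NA_real_)
  annotated <- out$category %in% c("exact_match", "contained")
  novel <- out$category %in% c("novel_isoform", "novel_gene")
  if (any(annotated)) {
    bt <- ref_biotypes[out$transcript_id[annotated]]
    cls <- rep("else", sum(annotated))
    cls[bt %in% .REF_BIOTYPE_MAP$protein_coding] <- "protein_coding"
    cls[bt %in% .REF_BIOTYPE_MAP$lncRNA] <- "lncRNA"
    out[annotated, `:=`(class = cls, basis = "reference_biotype")]
  }
  if (any(novel)) {
    sc <- if (is.null(coding_scores)) rep(NA_real_, sum(novel)) else
      coding_scores[out$transcript_id[novel]]
    if (anyNA(sc))
      stop("novel transcript without a coding score: ",
           out$transcript_id[novel][which(is.na(sc))[1L]])
    sl <- spliced_lengths[out$transcript_id[novel]]
    cls <- ifelse(sc > cutoff, "protein_coding",
                  ifelse(sl > min_lnc_length, "lncRNA", "else"))
    out[novel, `:=`(class = cls, basis = "coding_score",
                    coding_score = as.numeric(sc))]
  }
  out[, category := NULL]
  out[]
}

#' Find ATG-initiated open reading frames
#'
#' Scans the three forward frames of a sense-strand spliced transcript
#' sequence and reports every ATG-initiated ORF terminated by a stop
#' codon (optionally also ORFs running off the 3' end) of at least
#' `min_len` nucleotides, sorted by length descending.
#'
#' @param sequence nucleotide string (ACGTN)
#' @param min_len minimum ORF length in bp including the stop codon
#'   (default 300)
#' @param allow_incomplete also report 3'-incomplete ORFs that reach the
#'   transcript end without a stop (default FALSE)
#' @return data.table(frame, start, end, length, peptide); start/end are
#'   0-based half-open nucleotide positions within the transcript, and
#'   the peptide excludes the stop codon
#' @export
find_orfs <- function(sequence, min_len = 300L, allow_incomplete = FALSE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains non-ACGTN characters")
  n <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    cod_start <- frame + 3L * (seq_len(ncod) - 1L)       # 0-based
    codons <- substring(sequence, cod_start + 1L, cod_start + 3L)
    atg_i <- which(codons == "ATG")
    stop_i <- which(codons %in% stops)
    for (ai in atg_i) {
      si <- stop_i[stop_i >= ai]
      if (length(si)) {
        si <- si[1L]
        if (si == ai) next                                # ATG cannot be a stop, defensive
        s0 <- cod_start[ai]; e0 <- cod_start[si] + 3L
        if (e0 - s0 >= min_len)
          res[[length(res) + 1L]] <- data.table(
            frame = frame, start = s0, end = e0, length = e0 - s0,
            complete = TRUE)
      } else if (allow_incomplete) {
        s0 <- cod_start[ai]; e0 <- cod_start[ncod] + 3L
        if (e0 - s0 >= min_len)
          res[[length(res) + 1L]] <- data.table(
            frame = frame, start = s0, end = e0, length = e0 - s0,
            complete = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.table(frame = integer(), start = integer(), end = integer(),
                      length = integer(), complete = logical(),
                      peptide = character()))
  out <- rbindlist(res)
  setorder(out, -length, frame, start)
  out[, peptide := vapply(seq_len(.N), function(i) {
    cds <- substr(sequence, start[i] + 1L, end[i])
    if (complete[i]) cds <- substr(cds, 1L, nchar(cds) - 3L)
    if (!nchar(cds)) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       if.fuzzy.codon = "X"))
  }, "")]
  out[]
}

#' Homology-hit significance class
#'
#' A hit is significant when `log10(e-value) < -5`.  Classes: both /
#' blast_only / pfam_only / none.
#'
#' @param blast_evalue best BLASTP e-value (NA when no hit)
#' @param pfam_evalue best Pfam domain e-value (NA when no hit)
#' @param log10_cutoff significance cutoff on log10(e) (default -5,
#'   strict inequality)
#' @return character vector of classes (vectorized over inputs)
#' @export
homology_significance <- function(blast_evalue = NA_real_,
                                  pfam_evalue = NA_real_,
                                  log10_cutoff = -5) {
  k <- max(length(blast_evalue), length(pfam_evalue))
  b <- rep_len(as.numeric(blast_evalue), k)
  p <- rep_len(as.numeric(pfam_evalue), k)
  if (any(b <= 0, na.rm = TRUE) || any(p <= 0, na.rm = TRUE))
    stop("e-values must be > 0")
  bs <- !is.na(b) & log10(b) < log10_cutoff
  ps <- !is.na(p) & log10(p) < log10_cutoff
  ifelse(bs & ps, "both",
         ifelse(bs, "blast_only", ifelse(ps, "pfam_only", "none")))
}

#' Expression tier of a TPM value
#'
#' not_detected (TPM <= 1), expressed (1 < TPM <= 10), high (TPM > 10).
#'
#' @param tpm non-negative numeric vector
#' @return character vector of tiers
#' @export
expression_tier <- function(tpm) {
  if (any(tpm < 0)) stop("negative TPM")
  ifelse(tpm > 10, "high", ifelse(tpm > 1, "expressed", "not_detected"))
}
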