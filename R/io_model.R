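# Core genomic data model: annotations (exon chains), signal tracks,
# genome sequences, expression matrices and junction support tables.
# Conventions: coordinates are 0-based half-open everywhere internally;
# GTF (1-based closed) and BED/bedGraph (0-based half-open) are converted
# at the I/O boundary.  Transcript strand must be "+" or "-".

#' Build an annotation from an exon table
#'
#' The annotation is the container for a set of transcript models: a
#' validated exon table plus a per-transcript summary (span, exon count,
#' spliced length, strand-aware TSS).
#'
#' @param exons data.frame/data.table with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand` ("+" or "-"), `start`, `end`
#'   (0-based half-open exon coordinates) and optionally `biotype`.
#' @return An object of class `annotation`: a list with elements
#'   `exons` (one row per exon, sorted) and `transcripts` (one row per
#'   transcript with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `n_exons`, `spliced_length`, `tss`,
#'   `biotype`).
#' @export
annotation <- function(exons) {
  ex <- as.data.table(exons)
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(ex))
  if (length(miss))
    stop("exon table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"biotype" %in% names(ex)) ex[, biotype := NA_character_]
  ex <- ex[, c(req, "biotype"), with = FALSE]
  ex[, `:=`(start = as.integer(start), end = as.integer(end),
            transcript_id = as.character(transcript_id),
            gene_id = as.character(gene_id),
            chrom = as.character(chrom), strand = as.character(strand))]
  if (nrow(ex)) {
    if (any(!ex$strand %in% c("+", "-")))
      stop("unstranded or invalid strand in exon table; transcripts must be '+' or '-'")
    if (any(ex$end <= ex$start))
      stop("exon with end <= start (0-based half-open coordinates required)")
    if (any(ex$start < 0L)) stop("negative exon start")
    bad <- ex[, .(n_chrom = uniqueN(chrom), n_strand = uniqueN(strand),
                  n_gene = uniqueN(gene_id)), by = transcript_id]
    if (any(bad$n_chrom > 1L) || any(bad$n_strand > 1L))
      stop("transcript with exons on mixed chrom/strand: ",
           bad[n_chrom > 1L | n_strand > 1L, transcript_id][1L])
    if (any(bad$n_gene > 1L))
      stop("transcript assigned to multiple gene_ids: ",
           bad[n_gene > 1L, transcript_id][1L])
  }
  setorder(ex, chrom, transcript_id, start)
  # exons of one transcript must be disjoint with >= 1 bp gaps
  if (nrow(ex)) {
    ex[, exon_rank := seq_len(.N), by = transcript_id]
    gap_bad <- ex[, if (.N > 1L) any(start[-1L] <= end[-.N]) else FALSE,
                  by = transcript_id]
    if (any(gap_bad$V1))
      stop("overlapping or abutting exons within transcript: ",
           gap_bad[V1 == TRUE, transcript_id][1L])
  } else ex[, exon_rank := integer()]
  tx <- ex[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
               start = min(start), end = max(end), n_exons = .N,
               spliced_length = sum(end - start),
               biotype = biotype[1L]), by = transcript_id]
  tx[, tss := ifelse(strand == "+", start, end - 1L)]
  setorder(tx, chrom, start, transcript_id)
  structure(list(exons = ex[], transcripts = tx[]), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d transcripts, %d genes, %d exons on %d sequence(s)\n",
              nrow(x$transcripts), uniqueN(x$transcripts$gene_id),
              nrow(x$exons), uniqueN(x$exons$chrom)))
  invisible(x)
}

#' @rdname annotation
#' @param x object to test
#' @export
is_annotation <- function(x) inherits(x, "annotation")

#' Subset an annotation by transcript ids
#' @param ann annotation
#' @param ids character vector of transcript ids to keep
#' @return annotation restricted to `ids`
#' @export
subset_annotation <- function(ann, ids) {
  annotation(ann$exons[transcript_id %in% ids])
}

#' Intron table of an annotation
#'
#' One row per intron with `donor` (intron start, the base after the
#' upstream exon) and `acceptor` (intron end, exclusive) in genomic
#' coordinates; donor < acceptor regardless of strand.
#'
#' @param ann annotation
#' @return data.table with columns transcript_id, gene_id, chrom, strand,
#'   donor, acceptor, intron_rank (genomic order)
#' @export
introns <- function(ann) {
  ex <- ann$exons[order(transcript_id, start)]
  ir <- ex[, if (.N > 1L)
    .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
      donor = end[-.N], acceptor = start[-1L]), by = transcript_id]
  if (is.null(ir) || !nrow(ir))
    return(data.table(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      donor = integer(), acceptor = integer(),
                      intron_rank = integer()))
  ir[, intron_rank := seq_len(.N), by = transcript_id]
  ir[]
}

#' Intron-chain strings
#'
#' Canonical string form of a transcript's ordered intron chain, used for
#' exact-match and containment tests.  Multi-exon transcripts only.
#'
#' @param ann annotation
#' @return data.table(transcript_id, chrom, strand, chain) where chain is
#'   "|d1:a1|d2:a2|...|"
#' @export
intron_chain_strings <- function(ann) {
  ir <- introns(ann)
  if (!nrow(ir))
    return(data.table(transcript_id = character(), chrom = character(),
                      strand = character(), chain = character()))
  ir[, .(chrom = chrom[1L], strand = strand[1L],
         chain = paste0("|", paste(donor, acceptor, sep = ":", collapse = "|"), "|")),
     by = transcript_id]
}

# ---------------------------------------------------------------------------
# GTF

#' Read transcript models from a GTF file
#'
#' Parses exon features (1-based closed coordinates) into an
#' [annotation()] with 0-based half-open coordinates.  Lines are
#' pre-validated so that malformed records are reported with their line
#' number.  Exons lacking a strand are rejected: strand drives TSS,
#' splice-motif and AS logic downstream.
#'
#' @param path GTF file path
#' @return annotation
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) return(annotation(data.table(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer())))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                 idx[which(nf < 9L)[1L]], nf[which(nf < 9L)[1L]]))
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  is_exon <- m[, 3L] == "exon"
  if (!any(is_exon)) stop("GTF contains no exon features: ", path)
  ln <- idx[is_exon]
  s1 <- suppressWarnings(as.integer(m[is_exon, 4L]))
  e1 <- suppressWarnings(as.integer(m[is_exon, 5L]))
  if (anyNA(s1) || anyNA(e1))
    stop(sprintf("malformed GTF line %d: non-numeric coordinate",
                 ln[which(is.na(s1) | is.na(e1))[1L]]))
  if (any(e1 < s1))
    stop(sprintf("invalid GTF line %d: end < start", ln[which(e1 < s1)[1L]]))
  strand <- m[is_exon, 7L]
  if (any(!strand %in% c("+", "-")))
    stop(sprintf("invalid GTF line %d: unstranded exon ('%s'); stranded models required",
                 ln[which(!strand %in% c("+", "-"))[1L]],
                 strand[which(!strand %in% c("+", "-"))[1L]]))
  attrs <- m[is_exon, 9L]
  get_attr <- function(key) {
    re <- paste0(key, "\\s+\"([^\"]*)\"")
    mm <- regmatches(attrs, regexpr(re, attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- grepl(re, attrs)
    out[hit] <- sub(re, "\\1", regmatches(attrs, regexpr(re, attrs)))
    out
  }
  gid <- get_attr("gene_id")
  tid <- get_attr("transcript_id")
  if (anyNA(gid) || anyNA(tid))
    stop(sprintf("malformed GTF line %d: missing gene_id/transcript_id attribute",
                 ln[which(is.na(gid) | is.na(tid))[1L]]))
  bt <- get_attr("transcript_biotype")
  annotation(data.table(transcript_id = tid, gene_id = gid,
                        chrom = m[is_exon, 1L], strand = strand,
                        start = s1 - 1L, end = e1, biotype = bt))
}

#' Write an annotation as GTF
#'
#' Emits exon features with 1-based closed coordinates, attributes in
#' fixed order (gene_id then transcript_id, then transcript_biotype when
#' present) and deterministic record order, so that
#' `read_gtf(write_gtf(ann))` reproduces `ann` field by field.
#'
#' @param ann annotation
#' @param path output path
#' @param source source field (column 2)
#' @return `path`, invisibly
#' @export
write_gtf <- function(ann, path, source = "isoatlas") {
  ex <- ann$exons[order(chrom, transcript_id, start)]
  attr_str <- ifelse(is.na(ex$biotype),
    sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id, ex$transcript_id),
    sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
            ex$gene_id, ex$transcript_id, ex$biotype))
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, source, ex$start + 1L, ex$end, ex$strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Signal tracks (bedGraph-backed run-length numeric tracks)

#' Construct a per-base signal track from interval runs
#'
#' @param runs data.frame/data.table with columns chrom, start, end
#'   (0-based half-open) and value.  Runs must be disjoint per chromosome.
#' @param default value returned for uncovered bases (default 0, matching
#'   the treatment of uncovered bases as 0 when averaging over a fixed
#'   denominator)
#' @return object of class `signal_track`
#' @export
signal_track <- function(runs, default = 0) {
  rt <- as.data.table(runs)[, .(chrom = as.character(chrom),
                                start = as.integer(start),
                                end = as.integer(end),
                                value = as.numeric(value))]
  if (anyNA(rt$value)) stop("non-numeric value in signal runs")
  if (nrow(rt) && any(rt$end <= rt$start)) stop("signal run with end <= start")
  setorder(rt, chrom, start)
  if (nrow(rt)) {
    bad <- rt[, if (.N > 1L) any(start[-1L] < end[-.N]) else FALSE, by = chrom]
    if (any(bad$V1))
      stop("overlapping signal runs on chromosome ", bad[V1 == TRUE, chrom][1L])
  }
  structure(list(runs = rt[], default = as.numeric(default)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d runs on %d sequence(s), default %g\n",
              nrow(x$runs), uniqueN(x$runs$chrom), x$default))
  invisible(x)
}

#' Read a 4-column bedGraph into a signal track
#' @param path bedGraph path (chrom, 0-based start, end, value)
#' @param default value for uncovered bases
#' @return signal_track
#' @export
read_bedgraph <- function(path, default = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t",
          col.names = c("chrom", "start", "end", "value"),
          colClasses = list(character = 1L)),
    error = function(e) stop("failed to parse bedGraph ", path, ": ",
                             conditionMessage(e)))
  if (ncol(dt) != 4L) stop("bedGraph must have 4 columns: ", path)
  if (!is.numeric(dt$value))
    stop("non-numeric value column in bedGraph: ", path)
  signal_track(dt, default = default)
}

#' Write a signal track as bedGraph
#' @param track signal_track
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, path) {
  r <- track$runs
  writeLines(sprintf("%s\t%d\t%d\t%s", r$chrom, r$start, r$end,
                     formatC(r$value, format = "g", digits = 10)), path)
  invisible(path)
}

#' Per-base track lookup
#' @param track signal_track
#' @param chrom chromosome
#' @param pos integer vector of 0-based base positions
#' @return numeric vector of values (default where uncovered)
#' @export
track_value <- function(track, chrom, pos) {
  .ch <- chrom
  r <- track$runs[chrom == .ch]
  out <- rep(track$default, length(pos))
  if (!nrow(r)) return(out)
  i <- findInterval(pos, r$start)
  hit <- i >= 1L & pos < r$end[pmax(i, 1L)]
  out[hit] <- r$value[i[hit]]
  out
}

#' Interval statistics over a signal track
#'
#' For each query interval returns the covered base count, the sum of
#' per-base values over covered bases, and the mean over the full
#' interval length with uncovered bases scoring the track default.
#'
#' @param track signal_track
#' @param regions data.frame/data.table with chrom, start, end (0-based
#'   half-open)
#' @return data.table with columns chrom, start, end, len, covered, sum,
#'   mean, in input row order
#' @export
track_region_stats <- function(track, regions) {
  q <- as.data.table(regions)[, .(chrom = as.character(chrom),
                                  start = as.integer(start),
                                  end = as.integer(end))]
  q[, `:=`(len = end - start, qrow = .I)]
  r <- copy(track$runs)
  if (!nrow(r)) {
    q[, `:=`(covered = 0L, sum = 0)]
  } else {
    setkey(r, chrom, start, end)
    ov <- foverlaps(q, r, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
    # foverlaps treats intervals as closed; half-open abutting pairs
    # ([a,b) vs [b,c)) appear as matches with zero overlap and drop out
    ov[, olen := pmin(i.end, end) - pmax(i.start, start)]
    ov <- ov[olen > 0L]
    agg <- ov[, .(covered = sum(olen), sum = sum(olen * value)), by = qrow]
    q[, `:=`(covered = 0L, sum = 0)]
    q[agg, `:=`(covered = i.covered, sum = i.sum), on = "qrow"]
  }
  q[, mean := (sum + track$default * (len - covered)) / len]
  q[, qrow := NULL]
  q[]
}

#' Expand a track to per-base values over one interval
#' @param track signal_track
#' @param chrom chromosome
#' @param start,end 0-based half-open interval
#' @return numeric vector of length `end - start`
#' @export
track_base_values <- function(track, chrom, start, end) {
  if (end <= start) stop("empty interval")
  .ch <- chrom; .s <- start; .e <- end
  r <- track$runs[chrom == .ch & end > .s & start < .e]
  out <- rep(track$default, end - start)
  if (nrow(r)) {
    for (k in seq_len(nrow(r))) {
      a <- max(r$start[k], start); b <- min(r$end[k], end)
      out[(a - start + 1L):(b - start)] <- r$value[k]
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Genome sequences

#' Read a genome FASTA
#' @param path FASTA path
#' @return named `Biostrings::DNAStringSet`
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome named DNAStringSet
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Fetch a genomic subsequence
#'
#' Returns the uppercase sequence of `[start, end)` on `chrom`; for
#' `strand = "-"` the reverse complement is returned.
#'
#' @param genome DNAStringSet as returned by [read_genome()]
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @param strand "+" or "-"
#' @return character scalar
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  n <- length(genome[[chrom]])
  if (start < 0 || end > n || end <= start)
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, n))
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Spliced (exon-concatenated) transcript sequence
#' @param genome DNAStringSet
#' @param ann annotation
#' @param transcript transcript id
#' @return sense-strand spliced sequence, character scalar
#' @export
transcript_sequence <- function(genome, ann, transcript) {
  ex <- ann$exons[transcript_id == transcript][order(start)]
  if (!nrow(ex)) stop("unknown transcript: ", transcript)
  parts <- vapply(seq_len(nrow(ex)), function(i)
    fetch_sequence(genome, ex$chrom[i], ex$start[i], ex$end[i], "+"), "")
  s <- paste(parts, collapse = "")
  if (ex$strand[1L] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# ---------------------------------------------------------------------------
# BED (peaks / support intervals)

#' Read a BED3/BED6 file
#' @param path BED path
#' @return data.table(chrom, start, end[, name, score, strand]) 0-based
#'   half-open
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1L))
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, nm[seq_len(min(ncol(dt), 6L))])
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (any(dt$end <= dt$start)) stop("BED interval with end <= start: ", path)
  setorder(dt, chrom, start)
  dt[]
}

#' Write intervals as BED
#' @param dt data.table with chrom, start, end (and optionally name)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(dt, path) {
  dt <- as.data.table(dt)
  if ("name" %in% names(dt))
    writeLines(sprintf("%s\t%d\t%d\t%s", dt$chrom, dt$start, dt$end, dt$name), path)
  else
    writeLines(sprintf("%s\t%d\t%d", dt$chrom, dt$start, dt$end), path)
  invisible(path)
}

#' Merge (union) intervals
#' @param dt data.table with chrom, start, end; optional strand column is
#'   honoured when `by_strand = TRUE`
#' @param by_strand merge separately per strand
#' @return data.table of disjoint merged intervals
#' @export
merge_intervals <- function(dt, by_strand = FALSE) {
  dt <- as.data.table(dt)
  if (!nrow(dt)) return(dt)
  grp <- if (by_strand && "strand" %in% names(dt)) c("chrom", "strand") else "chrom"
  out <- dt[, {
    ir <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    .(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }, by = grp]
  setorder(out, chrom, start)
  out[]
}

# ---------------------------------------------------------------------------
# Expression matrices

#' Construct an expression matrix
#'
#' A numeric matrix of non-negative expression values with transcripts or
#' genes as rows and stage/replicate samples as columns.  Column names
#' follow `"<stage>_<replicate>"`; the stage label is everything before
#' the final underscore.
#'
#' @param values numeric matrix, rownames = feature ids, colnames =
#'   sample labels
#' @param unit "TPM" or "FPKM"
#' @return object of class `expr_matrix` (a matrix with `unit` attribute)
#' @export
expression_matrix <- function(values, unit = c("TPM", "FPKM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row and column names")
  if (anyDuplicated(colnames(values))) stop("duplicate sample labels")
  if (any(values < 0)) stop("negative expression values")
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' Stage label of each sample column
#' @param m expr_matrix
#' @return character vector, one stage per column
#' @export
sample_stages <- function(m) sub("_[^_]*$", "", colnames(m))

#' Average replicate columns per stage
#' @param m expr_matrix
#' @return plain matrix, one column per stage (column order = first
#'   appearance)
#' @export
stage_means <- function(m) {
  st <- sample_stages(m)
  u <- unique(st)
  out <- vapply(u, function(s) rowMeans(m[, st == s, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(m), u))
  out
}

#' Read an expression TSV (features x samples, header row)
#' @param path TSV path; first column feature id
#' @param unit "TPM" or "FPKM"
#' @return expr_matrix
#' @export
read_expression_tsv <- function(path, unit = c("TPM", "FPKM")) {
  dt <- fread(path, header = TRUE, sep = "\t")
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- ids
  expression_matrix(m, unit = match.arg(unit))
}

#' Write an expression matrix as TSV
#' @param m expr_matrix
#' @param path output path
#' @param id_col name of the id column
#' @return `path`, invisibly
#' @export
write_expression_tsv <- function(m, path, id_col = "feature_id") {
  dt <- data.table(id = rownames(m))
  setnames(dt, "id", id_col)
  out <- cbind(dt, as.data.table(unclass(m)))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Junction support tables

#' Read a short-read splice-junction support table
#'
#' Long-format TSV with header `chrom donor acceptor strand sample count`:
#' per-sample short-read counts for each junction (donor = intron start,
#' acceptor = intron end, 0-based half-open; donor < acceptor).
#'
#' @param path TSV path
#' @return data.table(chrom, donor, acceptor, strand, sample_id, count)
#' @export
read_junction_tsv <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t",
              colClasses = list(character = "chrom"))
  setnames(dt, c("chrom", "donor", "acceptor", "strand", "sample_id", "count"))
  dt[, `:=`(donor = as.integer(donor), acceptor = as.integer(acceptor),
            count = as.integer(count))]
  if (any(dt$donor >= dt$acceptor)) stop("junction with donor >= acceptor")
  if (any(dt$count < 0L)) stop("negative junction support count")
  dt[]
}

#' Write a junction support table
#' @param dt junction support data.table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_junction_tsv <- function(dt, path) {
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
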