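# ZGA transcript/gene calls, splicing-factor/AS-count correlation,
# stage-specificity z-scores, and quantification-change flags between
# two annotation references.

#' Call ZGA (zygotic genome activation) transcripts or genes
#'
#' A feature is ZGA when it is not expressed in the oocyte
#' (value <= `off_threshold`), expressed in both 1-cell and 2-cell
#' (value > `off_threshold`), and the 2-cell value exceeds twice the
#' 1-cell value.  Replicate columns are averaged per stage before the
#' clauses are evaluated.
#'
#' @param expr expr_matrix containing the three stages
#' @param oocyte,one_cell,two_cell stage labels (defaults "Oo", "1C",
#'   "2C")
#' @param off_threshold expression threshold separating off from on
#'   (default 1)
#' @return data.table(feature_id, oocyte, one_cell, two_cell, is_zga)
#' @export
call_zga <- function(expr, oocyte = "Oo", one_cell = "1C", two_cell = "2C",
                     off_threshold = 1) {
  sm <- stage_means(expr)
  need <- c(oocyte, one_cell, two_cell)
  miss <- setdiff(need, colnames(sm))
  if (length(miss)) stop("missing stage column(s): ", paste(miss, collapse = ", "))
  dt <- data.table(feature_id = rownames(sm),
                   oocyte = sm[, oocyte], one_cell = sm[, one_cell],
                   two_cell = sm[, two_cell])
  dt[, is_zga := oocyte <= off_threshold & one_cell > off_threshold &
        two_cell > off_threshold & two_cell > 2 * one_cell]
  dt[]
}

#' Correlation of splicing-factor expression with AS-event counts
#'
#' Pearson correlation between each factor's per-stage expression and
#' the per-stage number of AS events, over the same ordered stages.
#'
#' @param sf_expr numeric matrix factors x stages (rownames = factor
#'   ids), or expr_matrix whose columns are averaged per stage first
#' @param as_counts named numeric vector of AS-event totals per stage
#' @return data.table(factor_id, r, n_stages); r is NA when either
#'   vector has zero variance
#' @export
sf_as_correlation <- function(sf_expr, as_counts) {
  m <- if (inherits(sf_expr, "expr_matrix")) stage_means(sf_expr) else
    as.matrix(sf_expr)
  stages <- intersect(colnames(m), names(as_counts))
  if (length(stages) < 3L) stop("need >= 3 paired stage observations")
  x <- as_counts[stages]
  rbindlist(lapply(rownames(m), function(f) {
    y <- m[f, stages]
    r <- if (sd(y) == 0 || sd(x) == 0) NA_real_ else cor(x, y)
    data.table(factor_id = f, r = r, n_stages = length(stages))
  }))
}

#' Row-wise z-scores of an expression matrix
#'
#' Per row: (x - mean) / sd; rows with zero standard deviation emit
#' zeros.
#'
#' @param expr numeric matrix (or expr_matrix) with >= 2 columns
#' @return matrix of the same shape
#' @export
stage_zscore <- function(expr) {
  m <- unclass(as.matrix(expr))
  attr(m, "unit") <- NULL
  if (ncol(m) < 2L) stop("z-scores need >= 2 samples per row")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s == 0, Inf, s)
  z
}

#' Flag transcripts whose quantification changes between two references
#'
#' Compares per-stage mapped-read counts of each transcript quantified
#' against reference A and reference B.  With the default ratio
#' definition, delta = max(a+1, b+1) / min(a+1, b+1); the
#' absolute-difference variant |a - b| is available via
#' `delta = "difference"`.  A transcript is flagged when delta exceeds
#' `threshold` in at least one stage.
#'
#' @param counts_a,counts_b numeric matrices transcripts x stages with
#'   identical dimnames
#' @param threshold flag threshold on delta (default 5)
#' @param delta "ratio" (default) or "difference"
#' @return data.table(transcript_id, max_delta, flagged)
#' @export
quant_change_flags <- function(counts_a, counts_b, threshold = 5,
                               delta = c("ratio", "difference")) {
  delta <- match.arg(delta)
  a <- as.matrix(counts_a); b <- as.matrix(counts_b)
  if (!identical(dimnames(a), dimnames(b)))
    stop("count matrices must share transcript ids and stage columns")
  d <- if (delta == "ratio") pmax(a + 1, b + 1) / pmin(a + 1, b + 1) else abs(a - b)
  md <- apply(d, 1L, max)
  data.table(transcript_id = rownames(a), max_delta = md,
             flagged = md > threshold)
}
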