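# Methylation-expression integration: sliding-window gene-body mCH versus
# expression, enhancer methylation deltas, and the per-gene max-normalised
# transcription-factor panel.

#' Sliding-window gene-body mCH versus expression profile
#'
#' Genes with both a methylation and an expression value are ordered by
#' descending TPM and averaged in windows of `window` genes with step 1
#' (`N - window + 1` windows). The expression axis is `log10(TPM + 1)`. The
#' Spearman rank correlation of the unwindowed (mCH, TPM) pairs is reported
#' alongside, plus a linear fit of windowed mean mCH on windowed mean
#' log-expression (fit on the smoothed means, labelled as such).
#'
#' @param gene_mch named numeric vector (or `data.frame(gene, mch)`) of
#'   gene-body mCH levels.
#' @param expression expression table with columns `gene`, `tpm`.
#' @param window window size in genes (default 20).
#' @return list with `windows` (`data.table`: window index, mean mCH, mean
#'   log10(TPM+1)), `rho` (unwindowed Spearman; `NA` with a reason when
#'   undefined), `n_genes` and `fit` (intercept/slope of the linear fit on
#'   windowed means).
#' @export
sliding_window_profile <- function(gene_mch, expression, window = 20) {
  if (is.data.frame(gene_mch)) {
    v <- gene_mch[[2L]]
    names(v) <- gene_mch[[1L]]
    gene_mch <- v
  }
  expression <- data.table::as.data.table(expression)
  dt <- expression[gene %in% names(gene_mch)]
  dt[, mch := gene_mch[gene]]
  dt <- dt[is.finite(mch) & is.finite(tpm)]
  if (nrow(dt) < window)
    stop(sprintf("need at least %d genes with both values, have %d",
                 window, nrow(dt)))
  data.table::setorder(dt, -tpm, gene)
  logex <- log10(dt$tpm + 1)
  n_win <- nrow(dt) - window + 1L
  csm <- cumsum(c(0, dt$mch))
  cse <- cumsum(c(0, logex))
  windows <- data.table::data.table(
    window = seq_len(n_win),
    mean_mch = (csm[seq_len(n_win) + window] - csm[seq_len(n_win)]) / window,
    mean_log_tpm = (cse[seq_len(n_win) + window] - cse[seq_len(n_win)]) / window)
  rho <- if (stats::var(dt$mch) == 0 || stats::var(dt$tpm) == 0) NA_real_
  else suppressWarnings(stats::cor(dt$mch, dt$tpm, method = "spearman"))
  fit <- stats::coef(stats::lm(mean_mch ~ mean_log_tpm, data = windows))
  list(windows = windows, rho = rho,
       rho_reason = if (is.na(rho)) "constant input: rank correlation undefined"
       else NA_character_,
       n_genes = nrow(dt),
       fit = c(intercept = unname(fit[1L]), slope = unname(fit[2L])))
}

#' Per-enhancer methylation deltas and hypermethylated fraction
#'
#' Corrected levels per enhancer in both samples,
#' `delta = level(sample_a) - level(sample_b)` (in vitro minus in vivo by
#' convention), and the fraction of covered enhancers with
#' `delta > flag_threshold`. Enhancers below `min_calls` in either sample are
#' excluded from the denominator.
#'
#' @param enhancers enhancer feature table.
#' @param sample_a,sample_b [methylome_sample()] objects.
#' @param context methylation context (default CG).
#' @param flag_threshold hypermethylation flag threshold on delta
#'   (default 0.5).
#' @param min_calls per-enhancer coverage floor (default 20).
#' @return list with `deltas` (per-enhancer table with `flagged`),
#'   `flagged_fraction` and `n_covered`.
#' @export
enhancer_deltas <- function(enhancers, sample_a, sample_b, context = "CG",
                            flag_threshold = 0.5, min_calls = 20) {
  enhancers <- data.table::as.data.table(enhancers)
  if (nrow(enhancers) == 0L) stop("no enhancers supplied")
  agg_a <- aggregate_by_feature(sample_a, enhancers, context,
                                min_calls = min_calls)
  agg_b <- aggregate_by_feature(sample_b, enhancers, context,
                                min_calls = min_calls)
  dt <- data.table::data.table(
    name = agg_a$name, chrom = agg_a$chrom, start = agg_a$start,
    end = agg_a$end, level_a = agg_a$corrected_level,
    level_b = agg_b$corrected_level)
  dt[, delta := level_a - level_b]
  covered <- dt[is.finite(delta)]
  if (nrow(covered) == 0L) stop("zero covered enhancers")
  dt[, flagged := is.finite(delta) & delta > flag_threshold]
  list(deltas = dt[],
       flagged_fraction = mean(covered$delta > flag_threshold),
       n_covered = nrow(covered))
}

#' Transcription-factor expression/methylation panel
#'
#' For each gene in the panel, expression and gene-body mCH are normalised
#' per gene to the larger of the two samples' values, so the higher sample is
#' exactly 1 and the other lies in `[0, 1]`. A gene with zero reads in a
#' sample is missing for that cell; when both samples are zero the pair is
#' missing entirely. Genes are ordered by the difference in gene-body mCH
#' (sample_a minus sample_b, descending; ties by name).
#'
#' @param genes character vector of panel gene names.
#' @param expression_a,expression_b expression tables (`gene`, `tpm`).
#' @param mch_a,mch_b named numeric vectors of gene-body mCH.
#' @return `data.table`: one row per gene with normalised expression and mCH
#'   for both samples, the mCH difference used for ordering, and rows sorted
#'   by it.
#' @export
tf_panel <- function(genes, expression_a, expression_b, mch_a, mch_b) {
  if (length(genes) == 0L) stop("gene panel is empty")
  ex_a <- data.table::as.data.table(expression_a)
  ex_b <- data.table::as.data.table(expression_b)
  val <- function(tbl, g) {
    i <- match(g, tbl$gene)
    ifelse(is.na(i), NA_real_, tbl$tpm[i])
  }
  # zero_missing: expression cells with zero reads (TPM 0) are missing; a
  # methylation level of exactly 0 is a valid value if covered.
  norm_pair <- function(a, b, zero_missing = FALSE) {
    hi <- pmax(ifelse(is.finite(a), a, 0), ifelse(is.finite(b), b, 0))
    na_a <- !is.finite(a) | hi == 0 | (zero_missing & a == 0)
    na_b <- !is.finite(b) | hi == 0 | (zero_missing & b == 0)
    cbind(a = ifelse(na_a, NA_real_, a / hi),
          b = ifelse(na_b, NA_real_, b / hi))
  }
  e <- norm_pair(val(ex_a, genes), val(ex_b, genes), zero_missing = TRUE)
  m <- norm_pair(unname(mch_a[genes]), unname(mch_b[genes]))
  out <- data.table::data.table(
    gene = genes,
    expression_a = e[, "a"], expression_b = e[, "b"],
    mch_a = m[, "a"], mch_b = m[, "b"],
    mch_delta = unname(mch_a[genes]) - unname(mch_b[genes]))
  out[order(-mch_delta, gene, method = "radix")]
}
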