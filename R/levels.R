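# Weighted methylation levels with spike-in nonconversion correction, and
# their aggregation over features, feature classes and metagene profiles.
#
# The weighted methylation level of a scope is the pooled count of methylated
# basecalls divided by the pooled total basecalls at reference cytosines of
# the requested context inside the scope -- never a mean of per-site or
# per-part levels. The pooled CH level pools CA+CC+CT counts before division.
# The sample- and context-specific nonconversion rate (apparent methylation
# of the fully unmethylated spike-in) is subtracted from the raw level and
# the result clipped at zero.

#' Estimate per-context bisulfite nonconversion rates from a spike-in
#'
#' The nonconversion rate of a context is the fraction of methylated
#' basecalls among all basecalls at spike-in cytosines of that context --
#' the apparent methylation of a genome known to be unmethylated. Rates are
#' computed individually for CG, CA, CC and CT, plus the pooled CH rate used
#' when correcting pooled-CH levels.
#'
#' @param spikein_records cytosine records of the unmethylated control
#'   genome.
#' @return list with `rates` (named vector over CG, CA, CC, CT, CH) and
#'   `calls_used` (total basecalls per context).
#' @export
estimate_nonconversion <- function(spikein_records) {
  spikein_records <- data.table::as.data.table(spikein_records)
  validate_records(spikein_records, "spike-in records")
  rates <- numeric(0)
  calls <- numeric(0)
  for (cx in .ALL_CONTEXTS) {
    sub <- spikein_records[context %in% expand_context(cx)]
    tot <- sum(sub$count_total)
    if (tot == 0)
      stop(sprintf("spike-in has zero total calls in context %s", cx))
    rates[cx] <- sum(sub$count_m) / tot
    calls[cx] <- tot
  }
  if (any(rates > 0.1))
    warning(sprintf("nonconversion rate above 0.1 in context(s): %s",
                    paste(names(rates)[rates > 0.1], collapse = ", ")))
  list(rates = rates, calls_used = calls)
}

#' Weighted methylation level of a context within an optional region
#'
#' @param records cytosine records (or a [methylome_sample()], whose own
#'   nonconversion rates are then used).
#' @param context `"CG"`, `"CA"`, `"CC"`, `"CT"` or pooled `"CH"`.
#' @param nonconversion nonconversion rates as returned by
#'   [estimate_nonconversion()] (or a named vector); `NULL` means no
#'   correction.
#' @param region optional single interval (`list`/one-row `data.frame` with
#'   `chrom`, `start`, `end`, 0-based half-open); only cytosines with
#'   `start <= pos < end` on that chromosome are used.
#' @return one-row `data.table` with `context`, `m_calls`, `total_calls`,
#'   `n_cytosines`, `raw_level`, `corrected_level` and `reason` (`NA` unless
#'   the value is missing). Zero total calls in scope give a missing value
#'   (`NA` levels), not zero.
#' @export
weighted_level <- function(records, context, nonconversion = NULL,
                           region = NULL) {
  if (inherits(records, "methylome_sample")) {
    if (is.null(nonconversion)) nonconversion <- records$nonconversion
    records <- records$records
  }
  context <- match.arg(context, .ALL_CONTEXTS)
  ctx_set <- expand_context(context)
  keep <- records$context %in% ctx_set
  sub <- records[keep, ]
  if (!is.null(region)) {
    sub <- sub[sub$chrom == region$chrom & sub$pos >= region$start &
                 sub$pos < region$end, ]
  }
  m <- sum(sub$count_m)
  tot <- sum(sub$count_total)
  if (tot == 0) {
    return(data.table::data.table(context = context, m_calls = 0,
                                  total_calls = 0, n_cytosines = nrow(sub),
                                  raw_level = NA_real_,
                                  corrected_level = NA_real_,
                                  reason = "no calls in scope"))
  }
  raw <- m / tot
  corrected <- max(0, raw - nc_rate(nonconversion, context))
  data.table::data.table(context = context, m_calls = m, total_calls = tot,
                         n_cytosines = nrow(sub), raw_level = raw,
                         corrected_level = corrected, reason = NA_character_)
}

# Pool counts of one sample's records over a feature table; one output row
# per feature. A cytosine overlapping two features contributes to both.
pool_by_feature <- function(records, features, context) {
  ctx_set <- expand_context(context)
  keep <- records$context %in% ctx_set
  sub <- records[keep, ]
  out <- data.table::data.table(name = features$name,
                                m_calls = 0, total_calls = 0,
                                n_cytosines = 0L)
  if (nrow(sub) > 0L && nrow(features) > 0L) {
    q <- GenomicRanges::GRanges(sub$chrom,
                                IRanges::IRanges(sub$pos + 1L, sub$pos + 1L))
    s <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start + 1L,
                                                 features$end))
    # differing sequence sets between query and features are expected
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
    if (length(hits) > 0L) {
      dt <- data.table::data.table(fi = S4Vectors::subjectHits(hits),
                                   m = sub$count_m[S4Vectors::queryHits(hits)],
                                   t = sub$count_total[S4Vectors::queryHits(hits)])
      agg <- dt[, list(m = sum(m), t = sum(t), n = .N), by = fi]
      out[agg$fi, `:=`(m_calls = agg$m, total_calls = agg$t,
                       n_cytosines = agg$n)]
    }
  }
  out
}

#' Aggregate weighted methylation over a feature table
#'
#' One pooled, nonconversion-corrected weighted level per feature. Features
#' whose total calls fall below `min_calls` are flagged missing (`NA`
#' levels), never zero-filled. A cytosine overlapping two features
#' contributes to both.
#'
#' @param sample a [methylome_sample()] (or a record table, in which case
#'   pass `nonconversion` explicitly).
#' @param features feature table (columns `chrom`, `start`, `end`, `name`,
#'   and optionally `feature_type`).
#' @param context `"CG"`, `"CA"`, `"CC"`, `"CT"` or `"CH"`.
#' @param min_calls coverage floor per feature (total basecalls); default 20.
#' @param nonconversion optional override of the sample's rates.
#' @return `data.table` with one row per feature: counts, `raw_level`,
#'   `corrected_level` (`NA` below `min_calls` or when uncovered) and
#'   `reason`.
#' @export
aggregate_by_feature <- function(sample, features, context, min_calls = 20,
                                 nonconversion = NULL) {
  if (min_calls < 1) stop("min_calls must be >= 1")
  if (inherits(sample, "methylome_sample")) {
    if (is.null(nonconversion)) nonconversion <- sample$nonconversion
    records <- sample$records
  } else records <- sample
  features <- data.table::as.data.table(features)
  context <- match.arg(context, .ALL_CONTEXTS)
  absent <- setdiff(unique(features$chrom), unique(records$chrom))
  if (length(absent) > 0L)
    warning(sprintf("feature chromosome(s) absent from sample: %s",
                    paste(absent, collapse = ", ")))
  pooled <- pool_by_feature(records, features, context)
  nc <- nc_rate(nonconversion, context)
  out <- data.table::data.table(
    name = features$name, chrom = features$chrom, start = features$start,
    end = features$end,
    feature_type = if ("feature_type" %in% names(features))
      features$feature_type else "feature",
    context = context, n_cytosines = pooled$n_cytosines,
    m_calls = pooled$m_calls, total_calls = pooled$total_calls)
  out[, raw_level := ifelse(total_calls >= min_calls,
                            m_calls / pmax(total_calls, 1), NA_real_)]
  out[, corrected_level := pmax(0, raw_level - nc)]
  out[, reason := data.table::fcase(
    total_calls == 0, "no calls in scope",
    total_calls < min_calls, sprintf("below min_calls (%d)", min_calls),
    default = NA_character_)]
  out[]
}

#' Gene x sample x context methylation matrix
#'
#' Long-format table of corrected weighted gene-body levels (full TSS-to-TES
#' span) with coverage counts; entries below the coverage floor are flagged
#' missing, never zero-filled.
#'
#' @param samples named list of [methylome_sample()] objects.
#' @param genes gene feature table.
#' @param contexts contexts to tabulate (default CG and pooled CH).
#' @param min_calls coverage floor per gene and context; default 20.
#' @return `data.table` with columns `gene`, `sample`, `context`,
#'   `corrected_level`, `raw_level`, `total_calls`, `n_cytosines`, `reason`.
#' @export
gene_methylation_matrix <- function(samples, genes,
                                    contexts = c("CG", "CH"),
                                    min_calls = 20) {
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, `[[`, "", "name")
  rows <- lapply(names(samples), function(sn) {
    data.table::rbindlist(lapply(contexts, function(cx) {
      agg <- aggregate_by_feature(samples[[sn]], genes, cx,
                                  min_calls = min_calls)
      data.table::data.table(gene = agg$name, sample = sn, context = cx,
                             corrected_level = agg$corrected_level,
                             raw_level = agg$raw_level,
                             total_calls = agg$total_calls,
                             n_cytosines = agg$n_cytosines,
                             reason = agg$reason)
    }))
  })
  data.table::rbindlist(rows)
}

#' Metagene methylation profile with flanking regions
#'
#' Each gene body is scaled to `n_body_bins` bins; the `flank_bp` regions
#' upstream of the TSS and downstream of the TES are cut into `n_flank_bins`
#' fixed-width bins each. Minus-strand genes are reversed so bins always run
#' TSS to TES. Per bin, counts are pooled across genes and the corrected
#' weighted level computed (pooled counts, not a mean of gene profiles).
#'
#' @param samples named list of [methylome_sample()] objects.
#' @param genes stranded gene feature table.
#' @param context methylation context.
#' @param flank_bp flank width in bp (default 10000).
#' @param n_body_bins,n_flank_bins bin counts for body and each flank.
#' @return `data.table`: `sample`, `bin` (1..`2*n_flank_bins+n_body_bins`),
#'   `zone` (upstream/body/downstream), pooled counts and levels.
#' @export
metagene_profile <- function(samples, genes, context, flank_bp = 10000,
                             n_body_bins = 60, n_flank_bins = 20) {
  if (flank_bp <= 0) stop("flank_bp must be > 0")
  genes <- data.table::as.data.table(genes)
  if (any(!genes$strand %in% c("+", "-")))
    stop("metagene_profile needs stranded genes")
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, `[[`, "", "name")
  n_bins <- 2L * n_flank_bins + n_body_bins
  flank_w <- flank_bp / n_flank_bins

  ctx_set <- expand_context(context)
  profile_one <- function(sample) {
    recs <- sample$records[sample$records$context %in% ctx_set, ]
    q <- GenomicRanges::GRanges(recs$chrom,
                                IRanges::IRanges(recs$pos + 1L, recs$pos + 1L))
    win <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start - flank_bp + 1L,
                                                   genes$end + flank_bp))
    hits <- GenomicRanges::findOverlaps(q, win)
    gi <- S4Vectors::subjectHits(hits)
    pos <- recs$pos[S4Vectors::queryHits(hits)]
    gs <- genes$start[gi]; ge <- genes$end[gi]; minus <- genes$strand[gi] == "-"
    # bin index on the plus-strand layout, then mirror minus-strand genes
    bin <- integer(length(pos))
    up <- pos < gs
    down <- pos >= ge
    body <- !up & !down
    bin[up] <- 1L + pmin(floor((pos[up] - (gs[up] - flank_bp)) / flank_w),
                         n_flank_bins - 1L)
    bin[body] <- n_flank_bins + 1L +
      pmin(floor((pos[body] - gs[body]) / (ge[body] - gs[body]) * n_body_bins),
           n_body_bins - 1L)
    bin[down] <- n_flank_bins + n_body_bins + 1L +
      pmin(floor((pos[down] - ge[down]) / flank_w), n_flank_bins - 1L)
    bin[minus] <- n_bins + 1L - bin[minus]
    dt <- data.table::data.table(
      bin = bin, m = recs$count_m[S4Vectors::queryHits(hits)],
      t = recs$count_total[S4Vectors::queryHits(hits)])
    agg <- dt[, list(m_calls = sum(m), total_calls = sum(t), n = .N), by = bin]
    out <- data.table::data.table(bin = seq_len(n_bins), m_calls = 0,
                                  total_calls = 0, n_cytosines = 0L)
    out[agg$bin, `:=`(m_calls = agg$m_calls, total_calls = agg$total_calls,
                      n_cytosines = agg$n)]
    nc <- nc_rate(sample$nonconversion, context)
    out[, raw_level := ifelse(total_calls > 0, m_calls / pmax(total_calls, 1),
                              NA_real_)]
    out[, corrected_level := pmax(0, raw_level - nc)]
    out[, zone := rep(c("upstream", "body", "downstream"),
                      c(n_flank_bins, n_body_bins, n_flank_bins))]
    out
  }
  data.table::rbindlist(lapply(names(samples), function(sn)
    cbind(sample = sn, profile_one(samples[[sn]]))))
}

#' Weighted levels per genomic feature class
#'
#' Corrected weighted level of the whole genome, intergenic regions, introns,
#' exons, CpG islands and the 1 kb TSS windows, with counts pooled across all
#' features of a class.
#'
#' @param sample a [methylome_sample()].
#' @param annotation a `genome_annotation` (or any feature table containing
#'   the six classes).
#' @param context methylation context.
#' @return `data.table` with one row per class.
#' @export
feature_class_summary <- function(sample, annotation, context) {
  features <- if (inherits(annotation, "genome_annotation"))
    annotation$features else data.table::as.data.table(annotation)
  classes <- c("intergenic", "intron", "exon", "CGI", "TSS_window")
  missing_cls <- setdiff(classes, unique(features$feature_type))
  if (length(missing_cls) > 0L)
    stop(sprintf("annotation lacks feature class(es): %s",
                 paste(missing_cls, collapse = ", ")))
  nc <- nc_rate(sample$nonconversion, context)
  rows <- lapply(classes, function(cl) {
    pooled <- pool_by_feature(sample$records, features[feature_type == cl],
                              context)
    m <- sum(pooled$m_calls); tot <- sum(pooled$total_calls)
    data.table::data.table(class = cl, m_calls = m, total_calls = tot,
                           raw_level = if (tot > 0) m / tot else NA_real_)
  })
  genome <- weighted_level(sample$records, context,
                           nonconversion = sample$nonconversion)
  rows <- c(list(data.table::data.table(class = "whole_genome",
                                        m_calls = genome$m_calls,
                                        total_calls = genome$total_calls,
                                        raw_level = genome$raw_level)), rows)
  out <- data.table::rbindlist(rows)
  out[, corrected_level := pmax(0, raw_level - nc)]
  out[, context := context]
  out[]
}
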