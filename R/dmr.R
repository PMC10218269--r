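# Differentially methylated regions: a same-sign-run candidate caller (a
# declared stand-in for an external segmentation tool; externally produced
# candidate intervals can be fed straight into the filter), the study's DMR
# filters (site count, per-sample coverage, cytosine density, effect size),
# genomic-feature enrichment by the observed/expected rule, and
# developmental-DMR methylation status.

# Shared covered sites of a context between two samples, with per-site raw
# levels and their difference (a - b).
shared_sites <- function(sample_a, sample_b, context) {
  ctx <- expand_context(context)
  keep_a <- sample_a$records$context %in% ctx & sample_a$records$count_total > 0L
  keep_b <- sample_b$records$context %in% ctx & sample_b$records$count_total > 0L
  a <- sample_a$records[keep_a, ]
  b <- sample_b$records[keep_b, ]
  m <- merge(a[, list(chrom, pos, m_a = count_m, t_a = count_total)],
             b[, list(chrom, pos, m_b = count_m, t_b = count_total)],
             by = c("chrom", "pos"))
  if (nrow(m) == 0L) stop("no shared covered sites between the two samples")
  m[, diff := m_a / t_a - m_b / t_b]
  data.table::setkey(m, chrom, pos)
  m[]
}

#' Candidate differential regions from same-sign site runs
#'
#' At every site covered in both samples the per-site methylation difference
#' is computed and smoothed with a running mean over `smooth_k` consecutive
#' shared sites (complete windows only; smoothing suppresses isolated
#' single-site noise). Runs of consecutive sites whose smoothed difference
#' has the same sign and magnitude at least `site_delta_min`, with inter-site
#' gaps at most `max_gap_bp`, are merged; runs with at least `min_sites`
#' sites become candidate intervals. This is deliberately simple plumbing:
#' the scientifically meaningful step is the downstream filtering in
#' [filter_dmrs()], which also accepts intervals from any external caller.
#'
#' @param sample_a,sample_b [methylome_sample()] objects on the same
#'   reference layout.
#' @param context methylation context (`"CH"` pools CA/CC/CT).
#' @param site_delta_min minimum smoothed per-site |difference| (default 0.1).
#' @param max_gap_bp maximum gap between consecutive qualifying sites.
#' @param min_sites minimum qualifying sites per candidate (default 3).
#' @param smooth_k running-mean window in sites (odd; 1 disables smoothing).
#' @return `data.table` of candidate intervals (`chrom`, `start`, `end`,
#'   `n_sites`, `sign`).
#' @export
candidate_regions <- function(sample_a, sample_b, context,
                              site_delta_min = 0.1, max_gap_bp = 500,
                              min_sites = 3, smooth_k = 3) {
  if (smooth_k %% 2L != 1L) stop("smooth_k must be odd")
  m <- shared_sites(sample_a, sample_b, context)
  if (smooth_k > 1L) {
    half <- (smooth_k - 1L) %/% 2L
    m[, sdiff := {
      if (.N < smooth_k) rep(NA_real_, .N) else {
        cs <- cumsum(c(0, diff))
        sm <- (cs[(smooth_k + 1L):(.N + 1L)] - cs[seq_len(.N - smooth_k + 1L)]) /
          smooth_k
        c(rep(NA_real_, half), sm, rep(NA_real_, half))
      }
    }, by = chrom]
  } else m[, sdiff := diff]
  q <- m[!is.na(sdiff) & abs(sdiff) >= site_delta_min]
  if (nrow(q) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_sites = integer(),
                                  sign = integer()))
  q[, s := sign(sdiff)]
  q[, run := cumsum(c(1L, (s[-1L] != s[-.N]) |
                        (pos[-1L] - pos[-.N] > max_gap_bp))), by = chrom]
  cand <- q[, list(start = min(pos), end = max(pos) + 1L, n_sites = .N,
                   sign = s[1L]), by = list(chrom, run)]
  cand <- cand[n_sites >= min_sites]
  cand[, run := NULL]
  data.table::setkey(cand, chrom, start)
  cand[]
}

#' Filter candidate regions into DMRs
#'
#' A candidate passes when (i) it spans at least `min_sites` cytosines each
#' covered by at least `min_cov` calls in *both* samples (strict per-cytosine
#' reading; `cov_rule = "region_mean"` instead requires the mean per-sample
#' coverage over shared sites to reach `min_cov`), (ii) the retained
#' cytosines are denser than `min_density` per 100 bp (strict inequality)
#' over the retained span, and (iii) the pooled-level difference between the
#' samples is at least `min_delta` in magnitude. Direction is the sign of
#' `delta = level(sample_a) - level(sample_b)`, i.e. `hyper_in_vitro` when
#' sample_a is the in vitro sample and delta > 0.
#'
#' @param candidates interval table (`chrom`, `start`, `end`) from
#'   [candidate_regions()] or an external caller.
#' @param sample_a,sample_b the two [methylome_sample()] objects.
#' @param context methylation context.
#' @param min_sites minimum retained cytosines (default 3).
#' @param min_cov minimum per-cytosine coverage per sample (default 5).
#' @param min_density minimum cytosines per 100 bp, strict (default 3).
#' @param min_delta minimum |pooled delta| (default 0.2).
#' @param cov_rule `"per_cytosine"` (default) or `"region_mean"`.
#' @return `data.table` of DMRs: coordinates (retained-site span), `context`,
#'   `n_cytosines`, per-sample coverage minima and pooled levels, `delta`,
#'   `direction`, `density` (cytosines per 100 bp), `name`, `score`
#'   (`1000 * |delta|`, BED-style).
#' @export
filter_dmrs <- function(candidates, sample_a, sample_b, context,
                        min_sites = 3, min_cov = 5, min_density = 3,
                        min_delta = 0.2,
                        cov_rule = c("per_cytosine", "region_mean")) {
  cov_rule <- match.arg(cov_rule)
  candidates <- data.table::as.data.table(candidates)
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    context = character(), n_cytosines = integer(), min_cov_a = integer(),
    min_cov_b = integer(), level_a = numeric(), level_b = numeric(),
    delta = numeric(), direction = character(), density = numeric(),
    name = character(), score = numeric())
  if (nrow(candidates) == 0L) return(empty)
  m <- shared_sites(sample_a, sample_b, context)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    sub <- m[chrom == candidates$chrom[i] & pos >= candidates$start[i] &
               pos < candidates$end[i]]
    if (nrow(sub) == 0L) return(NULL)
    keep <- if (cov_rule == "per_cytosine")
      sub$t_a >= min_cov & sub$t_b >= min_cov
    else rep(mean(sub$t_a) >= min_cov & mean(sub$t_b) >= min_cov, nrow(sub))
    sub <- sub[keep]
    if (nrow(sub) < min_sites) return(NULL)
    span <- max(sub$pos) + 1L - min(sub$pos)
    density <- nrow(sub) / (span / 100)
    if (density <= min_density) return(NULL)
    level_a <- sum(sub$m_a) / sum(sub$t_a)
    level_b <- sum(sub$m_b) / sum(sub$t_b)
    delta <- level_a - level_b
    if (abs(delta) < min_delta) return(NULL)
    data.table::data.table(
      chrom = candidates$chrom[i], start = min(sub$pos),
      end = max(sub$pos) + 1L, context = context, n_cytosines = nrow(sub),
      min_cov_a = min(sub$t_a), min_cov_b = min(sub$t_b),
      level_a = level_a, level_b = level_b, delta = delta,
      direction = if (delta > 0) "hyper_in_vitro" else "hypo_in_vitro",
      density = density, score = round(1000 * abs(delta), 1))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- data.table::rbindlist(rows)
  out[, name := sprintf("dmr_%03d_%s", seq_len(.N), direction)]
  data.table::setkey(out, chrom, start)
  out[]
}

#' Independent validity check of emitted DMRs
#'
#' Recomputes the filter conditions for every DMR directly from the two
#' samples and reports violations; used to assert that every emitted region
#' satisfies all invariants.
#'
#' @param dmrs output of [filter_dmrs()].
#' @param sample_a,sample_b the samples the DMRs were called from.
#' @param min_sites,min_cov,min_density,min_delta the filter parameters used.
#' @return logical vector, `TRUE` for every valid DMR.
#' @export
validate_dmrs <- function(dmrs, sample_a, sample_b, min_sites = 3,
                          min_cov = 5, min_density = 3, min_delta = 0.2) {
  if (nrow(dmrs) == 0L) return(logical(0))
  vapply(seq_len(nrow(dmrs)), function(i) {
    m <- shared_sites(sample_a, sample_b, dmrs$context[i])
    sub <- m[chrom == dmrs$chrom[i] & pos >= dmrs$start[i] &
               pos < dmrs$end[i]]
    sub <- sub[t_a >= min_cov & t_b >= min_cov]
    n <- nrow(sub)
    if (n < min_sites) return(FALSE)
    span <- max(sub$pos) + 1L - min(sub$pos)
    delta <- sum(sub$m_a) / sum(sub$t_a) - sum(sub$m_b) / sum(sub$t_b)
    n / (span / 100) > min_density && abs(delta) >= min_delta
  }, TRUE)
}

#' Genomic-feature enrichment of DMRs
#'
#' A DMR is assigned to a feature class when its midpoint falls inside any
#' feature of the class (the midpoint rule gives a clean partition for
#' partitioning annotations). The expected count is the total DMR count times
#' the class's share of the genome (union length of its features over total
#' genome length); enrichment is observed/expected.
#'
#' @param dmrs DMR table from [filter_dmrs()] (any interval table with a
#'   `direction` column works; direction split is reported when present).
#' @param annotation `genome_annotation` or feature table.
#' @param genome_length total genome length; taken from the annotation when
#'   available.
#' @param classes feature classes to test (default: all in the annotation).
#' @return `data.table`: `class`, `observed`, `expected`, `enrichment`,
#'   `class_length`, plus hyper/hypo counts.
#' @export
feature_enrichment <- function(dmrs, annotation, genome_length = NULL,
                               classes = NULL) {
  features <- if (inherits(annotation, "genome_annotation"))
    annotation$features else data.table::as.data.table(annotation)
  if (is.null(genome_length)) {
    if (!inherits(annotation, "genome_annotation"))
      stop("genome_length required when annotation is a plain feature table")
    genome_length <- sum(annotation$chrom_lengths)
  }
  if (is.null(classes)) classes <- unique(features$feature_type)
  dmrs <- data.table::as.data.table(dmrs)
  n_dmr <- nrow(dmrs)
  if (n_dmr == 0L) stop("no DMRs supplied")
  mid <- GenomicRanges::GRanges(
    dmrs$chrom,
    IRanges::IRanges((dmrs$start + dmrs$end) %/% 2 + 1L, width = 1L))
  has_dir <- "direction" %in% names(dmrs)
  rows <- lapply(classes, function(cl) {
    f <- features[feature_type == cl]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      f$chrom, IRanges::IRanges(f$start + 1L, f$end)))
    len <- sum(GenomicRanges::width(gr))
    if (len == 0) {
      warning(sprintf("feature class '%s' has zero length: omitted", cl))
      return(NULL)
    }
    inside <- IRanges::overlapsAny(mid, gr)
    expected <- n_dmr * len / genome_length
    data.table::data.table(
      class = cl, observed = sum(inside), expected = expected,
      enrichment = sum(inside) / expected, class_length = len,
      n_hyper = if (has_dir) sum(inside & dmrs$direction == "hyper_in_vitro")
      else NA_integer_,
      n_hypo = if (has_dir) sum(inside & dmrs$direction == "hypo_in_vitro")
      else NA_integer_)
  })
  data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
}

#' Methylation status of developmental DMRs in a query sample
#'
#' Developmental DMRs gain (adult set) or lose (fetal set) methylation over
#' in vivo maturation. Each region's corrected level in the query sample is
#' classified `low` (< `hypo_lo`), `high` (> `hyper_hi`) or `intermediate`;
#' regions without covered cytosines are `missing`. The summary reports, per
#' developmental class, the fraction of non-missing regions in each state --
#' e.g. the fraction of adult DMRs already in a high-methylation state versus
#' still fetal-like low.
#'
#' @param sample query [methylome_sample()].
#' @param dev_dmrs feature table whose `feature_type` is `dev_DMR_fetal` or
#'   `dev_DMR_adult`.
#' @param context methylation context.
#' @param hypo_lo,hyper_hi classification cut points (defaults 1/3 and 2/3).
#' @param min_calls coverage floor per region (default 1).
#' @return list with `regions` (per-region status) and `summary` (fractions
#'   per developmental class).
#' @export
developmental_dmr_status <- function(sample, dev_dmrs, context,
                                     hypo_lo = 1 / 3, hyper_hi = 2 / 3,
                                     min_calls = 1) {
  dev_dmrs <- data.table::as.data.table(dev_dmrs)
  bad <- setdiff(unique(dev_dmrs$feature_type),
                 c("dev_DMR_fetal", "dev_DMR_adult"))
  if (length(bad) > 0L)
    stop(sprintf("dev_dmrs must be labelled dev_DMR_fetal/dev_DMR_adult, got: %s",
                 paste(bad, collapse = ", ")))
  agg <- aggregate_by_feature(sample, dev_dmrs, context,
                              min_calls = min_calls)
  status <- data.table::fcase(
    is.na(agg$corrected_level), "missing",
    agg$corrected_level < hypo_lo, "low",
    agg$corrected_level > hyper_hi, "high",
    default = "intermediate")
  regions <- data.table::data.table(
    name = agg$name, dev_class = dev_dmrs$feature_type,
    level = agg$corrected_level, status = status)
  ok <- regions[status != "missing"]
  if (nrow(ok) == 0L) {
    warning("all developmental DMRs uncovered; empty summary")
    return(list(regions = regions,
                summary = data.table::data.table(dev_class = character(),
                                                 fraction_low = numeric(),
                                                 fraction_intermediate = numeric(),
                                                 fraction_high = numeric(),
                                                 n = integer())))
  }
  summary <- ok[, list(fraction_low = mean(status == "low"),
                       fraction_intermediate = mean(status == "intermediate"),
                       fraction_high = mean(status == "high"), n = .N),
                by = dev_class]
  list(regions = regions, summary = summary)
}
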