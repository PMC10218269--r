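# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (explicit loops, no count pooling tricks) so they stay
# independent of the implementation paths they check.

# Small, fast simulation configuration for unit tests.
tiny_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_chrom = 1L, chrom_length = 4e5, n_genes = 30L,
               spike_length = 4e4, n_enhancers = 20L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Configuration with no regional structure: every site of a context class has
# exactly the set-point probability, so analytic binomial SEs apply.
flat_config <- function(seed = 11, ...) {
  args <- list(seed = seed, regional_sd = c(CG = 0, CH = 0))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(tiny_config, args)
}

# Quick record-table constructor.
records_dt <- function(chrom, pos, strand = "+", context, count_m,
                       count_total) {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, context = context,
                         count_m = as.integer(count_m),
                         count_total = as.integer(count_total))
}

# Independent weighted-level oracle: explicit per-record loop.
brute_weighted_level <- function(records, context, nc = 0, region = NULL) {
  ctx <- if (context == "CH") c("CA", "CC", "CT") else context
  m <- 0; tot <- 0
  for (i in seq_len(nrow(records))) {
    if (!(records$context[i] %in% ctx)) next
    if (!is.null(region)) {
      if (records$chrom[i] != region$chrom) next
      if (records$pos[i] < region$start || records$pos[i] >= region$end) next
    }
    m <- m + records$count_m[i]
    tot <- tot + records$count_total[i]
  }
  if (tot == 0) return(NA_real_)
  max(0, m / tot - nc)
}

# Independent enrichment-score oracle: full O(N) running-sum walk.
brute_es <- function(scores, in_set, p = 1) {
  n <- length(scores)
  w <- abs(scores)^p
  sw <- sum(w[in_set])
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      running <- running + (if (sw > 0) w[i] / sw else 1 / sum(in_set))
    } else {
      running <- running - 1 / (n - sum(in_set))
    }
    if (abs(running) > abs(best)) best <- running
    else if (abs(running) == abs(best) && running > best) best <- running
  }
  best
}

# Binomial SE of a corrected weighted level: sampling noise of the raw level
# plus sampling noise of the spike-in nonconversion estimate subtracted from
# it.
corrected_level_se <- function(p, n_calls, nc = 0, n_spike_calls = Inf) {
  sqrt(p * (1 - p) / n_calls + nc * (1 - nc) / n_spike_calls)
}
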