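# Neuron-similarity gene score and a from-scratch preranked GSEA: weighted
# Kolmogorov-Smirnov running-sum enrichment score, permutation null,
# NES (ES normalised to the mean enrichment of same-size random samples of
# matching sign) and add-one permutation p-values.

#' Per-gene neuron similarity score
#'
#' For each gene, `y = |level_invitro - level_invivo|` is the methylation
#' difference between the two neuron samples and `s_neuron = |y - 1|` its
#' similarity rescaling (1 = identical state). `s_distinct` is the absolute
#' difference between the neuron mean and the non-neuron (glia/fetal) mean.
#' Both components are averaged and the combined score rescaled over all
#' scored genes to `[0, 1]` (`rescale = "minmax"`, the default) or left as
#' the plain average, which already lies in `[0, 1]`
#' (`rescale = "half"`). Genes with any missing level are excluded.
#'
#' @param level_invivo,level_invitro,level_glia,level_fetal named numeric
#'   vectors of per-gene corrected levels in `[0, 1]`.
#' @param rescale `"minmax"` or `"half"` (see above).
#' @return `data.table` with `gene`, `s_neuron`, `s_distinct`,
#'   `combined_raw` (pre-rescale) and `combined`.
#' @export
similarity_score <- function(level_invivo, level_invitro, level_glia,
                             level_fetal, rescale = c("minmax", "half")) {
  rescale <- match.arg(rescale)
  genes <- Reduce(intersect, list(names(level_invivo), names(level_invitro),
                                  names(level_glia), names(level_fetal)))
  lv <- cbind(invivo = level_invivo[genes], invitro = level_invitro[genes],
              glia = level_glia[genes], fetal = level_fetal[genes])
  ok <- stats::complete.cases(lv)
  if (sum(!ok) > 0L)
    message(sprintf("similarity_score: %d gene(s) excluded for missing levels",
                    sum(!ok)))
  lv <- lv[ok, , drop = FALSE]
  genes <- genes[ok]
  if (length(genes) == 0L) stop("zero genes with all four levels")
  if (any(lv < 0 | lv > 1)) stop("levels must lie in [0, 1]")
  y <- abs(lv[, "invitro"] - lv[, "invivo"])
  s_neuron <- abs(y - 1)
  s_distinct <- abs((lv[, "invivo"] + lv[, "invitro"]) / 2 -
                      (lv[, "glia"] + lv[, "fetal"]) / 2)
  combined_raw <- (s_neuron + s_distinct) / 2
  combined <- if (rescale == "minmax" &&
                  diff(range(combined_raw)) > 0) {
    (combined_raw - min(combined_raw)) / diff(range(combined_raw))
  } else combined_raw
  data.table::data.table(gene = genes, s_neuron = unname(s_neuron),
                         s_distinct = unname(s_distinct),
                         combined_raw = unname(combined_raw),
                         combined = unname(combined))
}

#' Rank genes by a score
#'
#' Stable descending (or ascending) sort; ties are broken lexicographically
#' by gene name so the ranking is invariant to input order.
#'
#' @param values named numeric vector (or `data.frame(gene, value)`).
#' @param descending rank highest score first (default).
#' @return `data.table` with `gene`, `score` and `rank` (1..N).
#' @export
rank_genes <- function(values, descending = TRUE) {
  if (is.data.frame(values)) {
    v <- values[[2L]]
    names(v) <- values[[1L]]
    values <- v
  }
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be named with unique gene names")
  if (any(!is.finite(values))) stop("scores must be finite")
  ord <- if (descending)
    order(-values, names(values), method = "radix")
  else order(values, names(values), method = "radix")
  data.table::data.table(gene = names(values)[ord],
                         score = unname(values)[ord],
                         rank = seq_along(values))
}

# ES of one gene set from its (unsorted) positions in the ranked list.
# Hits increment the running sum by |score|^p normalised over the set; each
# miss decrements by 1/(N - n_set). ES is the signed extremum of the walk,
# attained either right after a hit (maximum) or just before one (minimum).
es_walk <- function(positions, scores, n_total, weight_exponent = 1) {
  k <- length(positions)
  idx <- sort.int(positions)
  w <- abs(scores[idx])^weight_exponent
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep(1 / k, k)
  miss <- 1 / (n_total - k)
  cw <- cumsum(w)
  before <- c(0, cw[-k]) - miss * (idx - seq_len(k))
  after <- cw - miss * (idx - seq_len(k))
  i_max <- which.max(after)
  i_min <- which.min(before)
  pos_ex <- after[i_max]
  neg_ex <- before[i_min]
  if (pos_ex >= -neg_ex)
    list(es = pos_ex, position = idx[i_max], hits = idx)
  else
    list(es = neg_ex, position = idx[i_min] - 1L, hits = idx)
}

#' Enrichment score of a gene set against a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov walk down the ranked list: a gene in
#' the set increments the running sum by `|score|^weight_exponent`
#' (normalised so the in-set increments total 1), every other gene decrements
#' it by `1/(N - n_set)`. The enrichment score is the signed maximum
#' deviation of the running sum from zero.
#'
#' @param ranked output of [rank_genes()].
#' @param gene_set character vector of gene names.
#' @param weight_exponent score weighting exponent (default 1).
#' @return list with `es`, `position` (1-based index in the ranked list where
#'   the extremum is attained), `n_hits` and `leading_edge` (genes up to the
#'   extremum for positive ES, after it for negative ES).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  ranked <- data.table::as.data.table(ranked)
  n <- nrow(ranked)
  pos <- which(ranked$gene %in% gene_set)
  if (length(pos) == 0L) stop("gene set has empty intersection with the ranked list")
  if (length(pos) == n)
    stop("gene set covers the entire ranked list: miss decrement undefined")
  walk <- es_walk(pos, ranked$score, n, weight_exponent)
  le <- if (walk$es >= 0) walk$hits[walk$hits <= walk$position]
  else walk$hits[walk$hits > walk$position]
  list(es = walk$es, position = walk$position, n_hits = length(pos),
       leading_edge = ranked$gene[le])
}

#' Preranked GSEA with permutation NES and p-values
#'
#' For every gene set (after intersection with the ranked list and size
#' filtering), the enrichment score is compared to `n_perm` null scores from
#' random same-size gene samples drawn from the list. `NES = ES / mean(|null
#' ES| of matching sign)` and the add-one permutation p-value is
#' `(1 + #{same-sign null at least as extreme}) / (1 + #{null of that
#' sign})`, so p is never 0. Sets with `p < p_filter` are returned, sorted by
#' decreasing NES. Deterministic for a fixed seed (one substream per set, so
#' collection order is irrelevant).
#'
#' @param ranked output of [rank_genes()].
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm permutations per set (default 1000).
#' @param seed RNG seed.
#' @param weight_exponent score weighting exponent (default 1).
#' @param min_size,max_size set size bounds after intersection.
#' @param p_filter retain sets with `p < p_filter` (default 0.05; use 1 to
#'   keep everything).
#' @return `data.table`: `set`, `es`, `nes`, `p_value`, `size`,
#'   `n_null_same_sign` (permutations matching the observed sign, the
#'   denominator base of the p-value) and `leading_edge` (list column),
#'   sorted by decreasing NES.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, seed = 1L,
                           weight_exponent = 1, min_size = 5, max_size = 500,
                           p_filter = 0.05) {
  ranked <- data.table::as.data.table(ranked)
  n <- nrow(ranked)
  sizes <- vapply(collection, function(g) sum(ranked$gene %in% g), 0L)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep)) stop("no gene set passes the size filter")
  collection <- collection[keep]
  scores <- ranked$score
  rows <- lapply(names(collection), function(set_name) {
    obs <- enrichment_score(ranked, collection[[set_name]], weight_exponent)
    k <- obs$n_hits
    null_es <- with_seed(derive_seed(seed, "gsea", set_name), {
      vapply(seq_len(n_perm), function(i)
        es_walk(sample.int(n, k), scores, n, weight_exponent)$es, 0)
    })
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same) > 0) obs$es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    data.table::data.table(set = set_name, es = obs$es, nes = nes,
                           p_value = p, size = k,
                           n_null_same_sign = length(same),
                           leading_edge = list(obs$leading_edge))
  })
  out <- data.table::rbindlist(rows)
  out <- out[p_value < p_filter]
  out[order(-nes)]
}
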