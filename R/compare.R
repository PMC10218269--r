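# In vitro vs in vivo methylome comparison: per-gene deltas, hyper/hypo
# classification, heatmap ordering, normalisation to the global level,
# 100 kb bin matrices and Spearman correlation clustering, and the
# cross-context correlation of per-gene deltas.

#' Per-gene methylation difference between two samples
#'
#' `delta = level(sample_a) - level(sample_b)` on corrected gene-body levels;
#' a gene with either level missing gets a missing delta.
#'
#' @param matrix long gene methylation matrix from
#'   [gene_methylation_matrix()].
#' @param sample_a,sample_b sample names (conventionally in vitro and
#'   in vivo, so positive delta means hypermethylated in vitro).
#' @param context methylation context present in the matrix.
#' @return `data.table` with `gene`, `level_a`, `level_b`, `delta`.
#' @export
gene_deltas <- function(matrix, sample_a, sample_b, context) {
  matrix <- data.table::as.data.table(matrix)
  for (s in c(sample_a, sample_b))
    if (!s %in% matrix$sample) stop(sprintf("unknown sample '%s'", s))
  ctx <- context
  a <- matrix[sample == sample_a & matrix$context == ctx,
              list(gene, level_a = corrected_level)]
  b <- matrix[sample == sample_b & matrix$context == ctx,
              list(gene, level_b = corrected_level)]
  out <- merge(a, b, by = "gene", all = FALSE)
  out[, delta := level_a - level_b]
  out[]
}

#' Classify genes as hyper- or hypomethylated from their deltas
#'
#' A gene is hypermethylated when `delta > threshold` and hypomethylated when
#' `delta < -threshold`. Fractions are computed over genes with a
#' non-missing delta. Default thresholds follow the study: 0.1 for CG,
#' 0.01 for CH.
#'
#' @param deltas output of [gene_deltas()].
#' @param threshold positive classification threshold.
#' @return list with `classes` (per-gene table, class in hyper/hypo/neither/
#'   missing), `fractions` (named vector over non-missing genes) and
#'   `n_classified`.
#' @export
classify_hyper_hypo <- function(deltas, threshold = 0.1) {
  if (threshold <= 0) stop("threshold must be > 0")
  deltas <- data.table::as.data.table(deltas)
  cls <- data.table::fcase(
    is.na(deltas$delta), "missing",
    deltas$delta > threshold, "hyper",
    deltas$delta < -threshold, "hypo",
    default = "neither")
  ok <- cls != "missing"
  if (!any(ok)) stop("no genes with non-missing delta")
  fractions <- c(hyper = mean(cls[ok] == "hyper"),
                 hypo = mean(cls[ok] == "hypo"),
                 neither = mean(cls[ok] == "neither"))
  list(classes = data.table::data.table(gene = deltas$gene,
                                        delta = deltas$delta, class = cls),
       fractions = fractions, n_classified = sum(ok))
}

#' Gene ordering for delta-sorted heatmaps
#'
#' Descending by delta; ties broken lexicographically by gene name, so the
#' ordering is stable under permutation of the input.
#'
#' @param deltas output of [gene_deltas()]; missing deltas are dropped.
#' @return character vector of gene names.
#' @export
order_for_heatmap <- function(deltas) {
  deltas <- data.table::as.data.table(deltas)
  deltas <- deltas[!is.na(delta)]
  deltas$gene[order(-deltas$delta, deltas$gene, method = "radix")]
}

#' Normalise per-gene levels to the sample's global level
#'
#' `normalized(gene) = level(gene) / global_level(sample, context)`, used to
#' compare methylation patterning between samples whose overall levels
#' differ.
#'
#' @param matrix long gene methylation matrix.
#' @param sample sample name.
#' @param context methylation context.
#' @param global_level the sample's corrected global weighted level (must be
#'   > 0); pass the value from [weighted_level()] on the whole sample.
#' @return `data.table` with `gene`, `level`, `normalized`.
#' @export
normalize_to_global <- function(matrix, sample, context, global_level) {
  if (!is.finite(global_level) || global_level <= 0)
    stop("global level must be a positive number")
  matrix <- data.table::as.data.table(matrix)
  ctx <- context; sn <- sample
  sub <- matrix[matrix$sample == sn & matrix$context == ctx]
  if (nrow(sub) == 0L) stop(sprintf("unknown sample '%s'", sn))
  sub[, list(gene, level = corrected_level,
             normalized = corrected_level / global_level)]
}

#' Corrected methylation levels on a genome tiling
#'
#' Tiles every non-excluded chromosome into `bin_size` bins (the last bin of
#' a chromosome may be short), pools counts per bin and sample, and corrects
#' with each sample's nonconversion rate. Bins below `min_calls` in a sample
#' are masked (`NA`) for that sample.
#'
#' @param samples named list of [methylome_sample()] objects.
#' @param annotation a `genome_annotation` or named vector of chromosome
#'   lengths.
#' @param context methylation context.
#' @param bin_size tile width in bp (default 100 kb as in the study).
#' @param exclude chromosomes left out (default chrX and chrY).
#' @param min_calls per-bin coverage floor (total calls), default 20.
#' @return list with `levels` (bins x samples matrix of corrected levels,
#'   masked entries `NA`), `bins` (the tiling) and `context`.
#' @export
bin_genome <- function(samples, annotation, context, bin_size = 1e5,
                       exclude = c("chrX", "chrY"), min_calls = 20) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  chrom_lengths <- if (inherits(annotation, "genome_annotation"))
    annotation$chrom_lengths else annotation
  chrom_lengths <- chrom_lengths[!names(chrom_lengths) %in% exclude]
  if (length(chrom_lengths) == 0L) stop("all chromosomes excluded")
  bins <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0L, chrom_lengths[[ch]] - 1L, by = bin_size)
    data.table::data.table(chrom = ch, start = as.integer(starts),
                           end = as.integer(pmin(starts + bin_size,
                                                 chrom_lengths[[ch]])))
  }))
  bins[, name := sprintf("%s:%d-%d", chrom, start, end)]
  bins[, feature_type := "bin"]
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, `[[`, "", "name")
  lev <- vapply(names(samples), function(sn) {
    agg <- aggregate_by_feature(samples[[sn]], bins, context,
                                min_calls = min_calls)
    agg$corrected_level
  }, numeric(nrow(bins)))
  rownames(lev) <- bins$name
  if (all(is.na(lev))) stop("all bins masked: coverage below min_calls")
  list(levels = lev, bins = bins[, list(chrom, start, end, name)],
       context = context)
}

#' Spearman correlation clustering of binned methylation
#'
#' Pairwise Spearman correlation over the unmasked bins common to each sample
#' pair, distance `1 - rho`, agglomerative clustering with average linkage
#' (configurable). Output is deterministic and invariant to sample and bin
#' order.
#'
#' @param bin_matrix output of [bin_genome()] (or a bins x samples numeric
#'   matrix).
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `correlation` (samples x samples Spearman rho),
#'   `hclust`, `newick` (dendrogram as a Newick string) and `n_bins_used`
#'   (pairwise bin counts).
#' @export
correlation_clustering <- function(bin_matrix, linkage = "average") {
  lev <- if (is.list(bin_matrix) && !is.null(bin_matrix$levels))
    bin_matrix$levels else bin_matrix
  if (ncol(lev) < 2L) stop("need at least 2 samples")
  lev <- lev[order(rownames(lev)), sort(colnames(lev)), drop = FALSE]
  n_used <- crossprod(!is.na(lev))
  if (min(n_used) < 3L)
    stop("need at least 3 unmasked bins common to every sample pair")
  for (sn in colnames(lev)) {
    v <- lev[!is.na(lev[, sn]), sn]
    if (length(v) > 0L && stats::var(v) == 0)
      stop(sprintf("sample '%s' is constant over unmasked bins: Spearman correlation undefined", sn))
  }
  rho <- stats::cor(lev, method = "spearman", use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(correlation = rho, hclust = hc, newick = newick, n_bins_used = n_used)
}

#' Pearson correlation of per-gene deltas across two contexts
#'
#' Measures whether genes gaining (or losing) methylation in one context do
#' so in the other; the study reports a very low correlation between CG and
#' CH deltas.
#'
#' @param deltas_cg,deltas_ch outputs of [gene_deltas()] for the two
#'   contexts.
#' @return list with `r` (Pearson correlation over shared genes with both
#'   deltas non-missing) and `n` (number of gene pairs).
#' @export
cross_context_correlation <- function(deltas_cg, deltas_ch) {
  a <- data.table::as.data.table(deltas_cg)[, list(gene, d_cg = delta)]
  b <- data.table::as.data.table(deltas_ch)[, list(gene, d_ch = delta)]
  m <- merge(a, b, by = "gene")
  m <- m[is.finite(d_cg) & is.finite(d_ch)]
  if (nrow(m) < 3L) stop("need at least 3 shared genes with both deltas")
  if (stats::var(m$d_cg) == 0 || stats::var(m$d_ch) == 0)
    stop("zero variance in one delta vector: Pearson correlation undefined")
  list(r = stats::cor(m$d_cg, m$d_ch, method = "pearson"), n = nrow(m))
}
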