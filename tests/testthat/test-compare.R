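# Gene deltas, hyper/hypo classification, ordering, normalisation, genome
# binning and Spearman correlation clustering.

# small hand-built gene matrix helper
toy_matrix <- function(levels_a, levels_b, context = "CG") {
  genes <- names(levels_a)
  data.table::rbindlist(list(
    data.table::data.table(gene = genes, sample = "a", context = context,
                           corrected_level = unname(levels_a),
                           raw_level = unname(levels_a),
                           total_calls = 100, n_cytosines = 10,
                           reason = NA_character_),
    data.table::data.table(gene = genes, sample = "b", context = context,
                           corrected_level = unname(levels_b),
                           raw_level = unname(levels_b),
                           total_calls = 100, n_cytosines = 10,
                           reason = NA_character_)))
}

test_that("gene deltas subtract levels and propagate missingness", {
  m <- toy_matrix(c(g1 = 0.9, g2 = 0.5, g3 = NA),
                  c(g1 = 0.7, g2 = 0.5, g3 = 0.2))
  d <- gene_deltas(m, "a", "b", "CG")
  expect_equal(d$delta[d$gene == "g1"], 0.2)
  expect_equal(d$delta[d$gene == "g2"], 0)
  expect_true(is.na(d$delta[d$gene == "g3"]))
  expect_error(gene_deltas(m, "a", "nope", "CG"), "unknown sample")

  # identical samples -> all deltas zero
  d0 <- gene_deltas(toy_matrix(c(g1 = 0.4, g2 = 0.8),
                               c(g1 = 0.4, g2 = 0.8)), "a", "b", "CG")
  expect_true(all(d0$delta == 0))

  # oracle: deltas recomputed from raw records agree
  cfg <- flat_config(seed = 201, chrom_length = 2e5, n_genes = 8L)
  ann <- simulate_annotation(cfg)
  sa <- simulate_methylome(cfg, ann, "neuron_invitro", "vitro")
  sb <- simulate_methylome(cfg, ann, "neuron_invivo", "vivo")
  genes <- ann$features[ann$features$feature_type == "gene"]
  mat <- gene_methylation_matrix(list(vitro = sa, vivo = sb), genes)
  d <- gene_deltas(mat, "vitro", "vivo", "CH")
  for (g in d$gene[c(1, 4, 8)]) {
    reg <- list(chrom = genes$chrom[genes$name == g],
                start = genes$start[genes$name == g],
                end = genes$end[genes$name == g])
    expected <- brute_weighted_level(sa$records, "CH",
                                     sa$nonconversion$rates[["CH"]], reg) -
      brute_weighted_level(sb$records, "CH",
                           sb$nonconversion$rates[["CH"]], reg)
    expect_equal(d$delta[d$gene == g], expected, tolerance = 1e-12)
  }
})

test_that("hyper/hypo classification fractions behave and are monotone", {
  d <- data.table::data.table(gene = c("g1", "g2", "g3"),
                              delta = c(0.2, -0.2, 0.05))
  cl <- classify_hyper_hypo(d, threshold = 0.1)
  expect_equal(unname(cl$fractions["hyper"]), 1 / 3)
  expect_equal(unname(cl$fractions["hypo"]), 1 / 3)
  expect_equal(sum(cl$fractions), 1)

  d0 <- data.table::data.table(gene = c("g1", "g2"), delta = c(0, 0))
  cl0 <- classify_hyper_hypo(d0, 0.1)
  expect_equal(unname(cl0$fractions["hyper"]), 0)
  expect_equal(unname(cl0$fractions["hypo"]), 0)

  expect_error(classify_hyper_hypo(
    data.table::data.table(gene = "g", delta = NA_real_), 0.1), "non-missing")

  # raising the threshold never adds hyper or hypo genes
  set.seed(3)
  dr <- data.table::data.table(gene = sprintf("g%03d", 1:200),
                               delta = stats::rnorm(200, 0, 0.1))
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2), function(th) {
    cl <- classify_hyper_hypo(dr, th)
    c(sum(cl$classes$class == "hyper"), sum(cl$classes$class == "hypo"))
  }, c(0, 0))
  expect_true(all(diff(counts[1L, ]) <= 0))
  expect_true(all(diff(counts[2L, ]) <= 0))
})

test_that("a planted shift on 30% of genes is classified as hyper", {
  cfg <- flat_config(seed = 211, chrom_length = 1e6, n_genes = 60L)
  ann <- simulate_annotation(cfg)
  sa <- simulate_methylome(cfg, ann, "neuron_invivo", "vitro")
  sb <- simulate_methylome(cfg, ann, "neuron_invivo", "vivo")
  genes <- ann$features[ann$features$feature_type == "gene"]
  planted <- genes[seq_len(18L)]  # 30% of 60
  plan <- data.table::data.table(chrom = planted$chrom,
                                 start = planted$start, end = planted$end,
                                 context = "CG", delta = 0.15)
  pl <- plant_dmrs(list(a = sb, b = sa), plan, cfg)
  mat <- gene_methylation_matrix(list(vitro = pl$b, vivo = sb), genes,
                                 contexts = "CG")
  d <- gene_deltas(mat, "vitro", "vivo", "CG")
  cl <- classify_hyper_hypo(d, threshold = 0.1)
  se <- sqrt(0.3 * 0.7 / 60)
  expect_lt(abs(cl$fractions[["hyper"]] - 0.3), 3 * se)
  expect_lt(cl$fractions[["hypo"]], 0.05)
})

test_that("heatmap ordering is descending, tie-stable and order-invariant", {
  d <- data.table::data.table(gene = c("b", "a", "c", "d"),
                              delta = c(0.5, 0.5, 0.9, NA))
  expect_equal(order_for_heatmap(d), c("c", "a", "b"))
  perm <- d[c(3, 1, 4, 2)]
  expect_equal(order_for_heatmap(perm), order_for_heatmap(d))
})

test_that("normalisation to the global level is a plain ratio", {
  m <- toy_matrix(c(g1 = 0.04, g2 = 0.02), c(g1 = 0.04, g2 = 0.02))
  nz <- normalize_to_global(m, "a", "CG", global_level = 0.04)
  expect_equal(nz$normalized, c(1, 0.5))
  expect_error(normalize_to_global(m, "a", "CG", global_level = 0),
               "positive")

  # count-weighted mean of normalised levels is ~1 when genes tile the scope
  cfg <- flat_config(seed = 221, chrom_length = 2e5, n_genes = 6L,
                     nonconversion = 0)
  ann <- simulate_annotation(cfg)
  s <- simulate_methylome(cfg, ann, "neuron_invivo")
  genes <- ann$features[ann$features$feature_type == "gene"]
  mat <- gene_methylation_matrix(list(x = s), genes, contexts = "CH")
  # global level over the union of gene bodies
  pooled <- aggregate_by_feature(
    s, data.table::data.table(chrom = genes$chrom,
                              start = min(genes$start),
                              end = max(genes$end), name = "span",
                              feature_type = "span", strand = ".")[1L],
    "CH")
  nz <- normalize_to_global(mat, "x", "CH",
                            global_level = pooled$corrected_level)
  w <- mat$total_calls[mat$sample == "x"]
  wmean <- sum(nz$normalized * w) / sum(w)
  expect_lt(abs(wmean - 1), 0.02)
})

test_that("genome binning tiles autosomes and matches feature aggregation", {
  cfg <- flat_config(seed = 231, chrom_length = 1e6, n_genes = 20L)
  ann <- simulate_annotation(cfg)
  s1 <- simulate_methylome(cfg, ann, "neuron_invivo", "s1")
  s2 <- simulate_methylome(cfg, ann, "glia", "s2")
  bm <- bin_genome(list(s1 = s1, s2 = s2), ann, "CG", bin_size = 1e5)
  expect_equal(nrow(bm$bins), 10L)  # 1 Mb / 100 kb
  expect_equal(ncol(bm$levels), 2L)

  # excluded chromosomes contribute no bins
  lens <- c(chr1 = 1e6, chrX = 5e5)
  bmx <- bin_genome(list(s1 = s1), lens, "CG", bin_size = 1e5)
  expect_false(any(grepl("chrX", rownames(bmx$levels))))

  # bin levels equal aggregate_by_feature on the same intervals
  agg <- aggregate_by_feature(s1, cbind(bm$bins, feature_type = "bin"),
                              "CG", min_calls = 20)
  expect_equal(unname(bm$levels[, "s1"]), agg$corrected_level)
})

test_that("correlation clustering reproduces planted relationships", {
  set.seed(9)
  base <- stats::runif(40, 0.2, 0.8)
  lev <- cbind(a = base + stats::rnorm(40, 0, 0.01),
               b = base + stats::rnorm(40, 0, 0.01),
               c = stats::runif(40, 0.2, 0.8))
  lev2 <- cbind(lev, a2 = lev[, "a"])  # duplicated sample
  rownames(lev2) <- sprintf("bin%02d", 1:40)
  cl <- correlation_clustering(lev2)
  expect_equal(cl$correlation["a", "a2"], 1)
  # first merge joins the duplicates
  first <- cl$hclust$merge[1L, ]
  expect_true(all(first < 0))
  expect_setequal(cl$hclust$labels[-first], c("a", "a2"))

  # rank-reversed copy correlates at exactly -1
  lev3 <- cbind(x = base, y = rev(sort(base))[rank(base)])
  rownames(lev3) <- sprintf("bin%02d", 1:40)
  cl3 <- correlation_clustering(lev3)
  expect_equal(cl3$correlation["x", "y"], -1)

  # constant sample is an error naming the sample
  lev4 <- cbind(a = base, flat = rep(0.5, 40))
  rownames(lev4) <- sprintf("bin%02d", 1:40)
  expect_error(correlation_clustering(lev4), "flat")

  # invariance to sample order and bin order
  cl_perm <- correlation_clustering(lev2[sample(40), c(3, 1, 4, 2)])
  expect_equal(cl_perm$correlation, cl$correlation)
  expect_equal(cl_perm$newick, cl$newick)
})

test_that("cross-context correlation is Pearson with affine invariance", {
  d_cg <- data.table::data.table(gene = sprintf("g%d", 1:50),
                                 delta = seq(-0.5, 0.5, length.out = 50))
  d_ch <- data.table::data.table(gene = sprintf("g%d", 1:50),
                                 delta = 2 * seq(-0.5, 0.5, length.out = 50))
  cc <- cross_context_correlation(d_cg, d_ch)
  expect_equal(cc$r, 1)
  expect_equal(cc$n, 50L)

  # affine rescaling of either vector leaves r unchanged
  d_ch2 <- data.table::copy(d_ch)
  d_ch2$delta <- -3 * d_ch2$delta + 0.1
  expect_equal(abs(cross_context_correlation(d_cg, d_ch2)$r), 1)

  # independent deltas at n = 5000 are uncorrelated within the null envelope
  set.seed(12)
  di <- data.table::data.table(gene = sprintf("g%d", 1:5000),
                               delta = stats::rnorm(5000))
  dj <- data.table::data.table(gene = sprintf("g%d", 1:5000),
                               delta = stats::rnorm(5000))
  expect_lt(abs(cross_context_correlation(di, dj)$r), 3 / sqrt(5000))

  dz <- data.table::data.table(gene = sprintf("g%d", 1:10),
                               delta = rep(0.3, 10))
  expect_error(cross_context_correlation(d_cg[1:10], dz), "zero variance")
})
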