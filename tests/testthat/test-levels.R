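# Weighted levels, nonconversion estimation and feature aggregation.

test_that("nonconversion rates are per-context call fractions", {
  sp <- records_dt("lambda", c(0, 10, 20, 30), "+",
                   c("CG", "CA", "CC", "CT"), c(0, 0, 0, 0), c(10, 10, 10, 10))
  nc0 <- estimate_nonconversion(sp)
  expect_true(all(nc0$rates == 0))

  # CA: 5 methylated of 1000 calls -> 0.005
  sp2 <- records_dt("lambda", seq(0, 90, 10), "+",
                    c(rep("CA", 7), "CG", "CC", "CT"),
                    c(2, 3, 0, 0, 0, 0, 0, 1, 0, 0),
                    c(200, 200, 200, 200, 100, 50, 50, 100, 100, 100))
  nc <- estimate_nonconversion(sp2)
  expect_equal(unname(nc$rates["CA"]), 0.005)
  expect_equal(unname(nc$calls_used["CA"]), 1000)
  # pooled CH rate pools CA+CC+CT calls
  expect_equal(unname(nc$rates["CH"]), 5 / 1200)

  # a context without calls is an error naming the context
  sp3 <- sp2[sp2$context != "CT", ]
  expect_error(estimate_nonconversion(sp3), "context CT")

  # recovery on simulated spike-in within 3 binomial SE
  cfg <- flat_config(seed = 71, nonconversion = 0.004, spike_length = 1.2e5)
  ann <- simulate_annotation(cfg)
  s <- simulate_methylome(cfg, ann, "esc")
  est <- s$nonconversion
  for (cx in c("CG", "CA", "CH")) {
    se <- sqrt(0.004 * 0.996 / est$calls_used[cx])
    expect_lt(abs(est$rates[cx] - 0.004), 3 * se)
  }
})

test_that("weighted level pools counts, corrects and clips", {
  # pooled-count definition: (3+1)/(4+6) = 0.4, not mean of 0.75 and 1/6
  recs <- records_dt("chr1", c(100, 200), "+", "CA", c(3, 1), c(4, 6))
  wl <- weighted_level(recs, "CA")
  expect_equal(wl$raw_level, 0.4)
  expect_equal(wl$corrected_level, 0.4)

  # clipping: raw 0.007, nonconversion 0.010 -> corrected 0
  recs2 <- records_dt("chr1", 1, "+", "CG", 7, 1000)
  wl2 <- weighted_level(recs2, "CG", nonconversion = c(CG = 0.010))
  expect_equal(wl2$raw_level, 0.007)
  expect_equal(wl2$corrected_level, 0)

  # zero calls in scope -> missing value with reason, not zero
  wl3 <- weighted_level(recs, "CG")
  expect_true(is.na(wl3$raw_level))
  expect_equal(wl3$reason, "no calls in scope")

  # CH pools CA+CC+CT counts before division
  recs4 <- records_dt("chr1", c(1, 2, 3, 4), "+",
                      c("CA", "CC", "CT", "CG"), c(1, 2, 3, 9),
                      c(10, 10, 10, 10))
  wl4 <- weighted_level(recs4, "CH")
  expect_equal(wl4$m_calls, 6)
  expect_equal(wl4$total_calls, 30)
  expect_equal(wl4$raw_level, 0.2)
})

test_that("weighted level matches the brute-force oracle exactly", {
  cfg <- flat_config(seed = 81, chrom_length = 2e5, n_genes = 10L)
  ann <- simulate_annotation(cfg)
  s <- simulate_methylome(cfg, ann, "neuron_invitro")
  recs <- s$records
  nc <- s$nonconversion
  for (cx in c("CG", "CA", "CC", "CT", "CH")) {
    expect_equal(weighted_level(recs, cx, nc)$corrected_level,
                 brute_weighted_level(recs, cx, nc$rates[[cx]]),
                 tolerance = 1e-12)
  }
  region <- list(chrom = "chr1", start = 50000L, end = 120000L)
  for (cx in c("CG", "CH")) {
    expect_equal(weighted_level(recs, cx, nc, region)$corrected_level,
                 brute_weighted_level(recs, cx, nc$rates[[cx]], region),
                 tolerance = 1e-12)
  }
})

test_that("pooling property: union of disjoint regions pools counts", {
  recs <- records_dt("chr1", c(10, 1010, 1020, 1030), "+", "CG",
                     c(9, 0, 1, 0), c(10, 10, 10, 10))
  r1 <- list(chrom = "chr1", start = 0L, end = 100L)
  r2 <- list(chrom = "chr1", start = 1000L, end = 1100L)
  whole <- list(chrom = "chr1", start = 0L, end = 1100L)
  w1 <- weighted_level(recs, "CG", region = r1)
  w2 <- weighted_level(recs, "CG", region = r2)
  wu <- weighted_level(recs, "CG", region = whole)
  pooled <- (w1$m_calls + w2$m_calls) / (w1$total_calls + w2$total_calls)
  expect_equal(wu$raw_level, pooled)
  # and it is NOT the mean of the part levels
  expect_false(isTRUE(all.equal(wu$raw_level,
                                mean(c(w1$raw_level, w2$raw_level)))))
})

test_that("correction is monotone in the nonconversion rate", {
  recs <- records_dt("chr1", c(1, 2, 3), "+", "CA", c(2, 3, 1), c(10, 10, 10))
  lev <- vapply(seq(0, 0.2, by = 0.02), function(nc)
    weighted_level(recs, "CA", nonconversion = c(CA = nc))$corrected_level, 0)
  expect_true(all(diff(lev) <= 0))
  expect_equal(lev[1L],
               weighted_level(recs, "CA")$raw_level)  # nc = 0 equals raw
})

test_that("feature aggregation matches per-feature brute force", {
  cfg <- flat_config(seed = 91, chrom_length = 2e5, n_genes = 10L)
  ann <- simulate_annotation(cfg)
  s <- simulate_methylome(cfg, ann, "esc")
  set.seed(17)
  starts <- sort(sample.int(190000L, 100L))
  feats <- data.table::data.table(
    chrom = "chr1", start = starts,
    end = starts + sample(500:5000, 100, replace = TRUE),
    name = sprintf("f%03d", 1:100), feature_type = "feature", strand = ".")
  agg <- aggregate_by_feature(s, feats, "CH", min_calls = 1)
  nc <- s$nonconversion$rates[["CH"]]
  for (i in seq(1, 100, by = 7)) {
    expect_equal(agg$corrected_level[i],
                 brute_weighted_level(s$records, "CH", nc,
                                      list(chrom = "chr1",
                                           start = feats$start[i],
                                           end = feats$end[i])),
                 tolerance = 1e-12)
  }

  # a feature covering no cytosines is missing, not zero
  none <- data.table::data.table(chrom = "chr9", start = 0L, end = 100L,
                                 name = "nothing", feature_type = "f",
                                 strand = ".")
  expect_warning(agg0 <- aggregate_by_feature(s, none, "CG"), "absent")
  expect_true(is.na(agg0$corrected_level))
  expect_equal(agg0$reason, "no calls in scope")

  # a single feature spanning the whole chromosome equals the genome level
  whole <- data.table::data.table(chrom = "chr1", start = 0L,
                                  end = cfg$chrom_length, name = "all",
                                  feature_type = "f", strand = ".")
  aggw <- aggregate_by_feature(s, whole, "CG")
  expect_equal(aggw$corrected_level,
               weighted_level(s, "CG")$corrected_level)

  # min_calls flags low-coverage features as missing
  aggm <- aggregate_by_feature(s, feats[1L], "CG", min_calls = 1e9)
  expect_true(is.na(aggm$corrected_level))
  expect_match(aggm$reason, "below min_calls")
})

test_that("gene matrix flags missing entries and never zero-fills", {
  cfg <- flat_config(seed = 95, chrom_length = 2e5, n_genes = 8L)
  ann <- simulate_annotation(cfg)
  s <- simulate_methylome(cfg, ann, "glia")
  genes <- ann$features[ann$features$feature_type == "gene"]
  mat <- gene_methylation_matrix(list(glia = s), genes, min_calls = 1e9)
  expect_true(all(is.na(mat$corrected_level)))
  expect_true(all(mat$total_calls > 0))  # counts kept, levels missing
  mat2 <- gene_methylation_matrix(list(glia = s), genes)
  expect_true(all(!is.na(mat2$corrected_level)))
  expect_equal(sort(unique(mat2$context)), c("CG", "CH"))
})

test_that("metagene profile is flat for uniform methylation and strand-symmetric", {
  # deterministic records: depth 10, exactly 3 methylated everywhere
  pos <- seq(0L, 39980L, by = 20L)
  recs <- records_dt("chr1", pos, "+", rep(c("CG", "CA"), length(pos) / 2),
                     3L, 10L)
  s <- methylome_sample("u", "u", recs)
  genes <- data.table::data.table(chrom = "chr1", start = 15000L,
                                  end = 25000L, name = "g1",
                                  feature_type = "gene", strand = "+")
  prof <- metagene_profile(list(u = s), genes, "CG", flank_bp = 2000,
                           n_body_bins = 10, n_flank_bins = 4)
  expect_true(all(abs(prof$raw_level - 0.3) < 1e-12))

  # a minus-strand gene with mirrored methylation gives the same profile
  recs_m <- data.table::copy(recs)
  recs_m$pos <- 40000L - recs_m$pos
  recs_m <- recs_m[order(recs_m$pos), ]
  s_m <- methylome_sample("m", "m", recs_m)
  genes_m <- data.table::data.table(chrom = "chr1", start = 15000L,
                                    end = 25000L, name = "g1",
                                    feature_type = "gene", strand = "-")
  # make the plus-strand methylation asymmetric, mirror it for the minus gene
  recs2 <- data.table::copy(recs)
  recs2$count_m <- ifelse(recs2$pos < 20000L, 1L, 8L)
  recs2_m <- data.table::copy(recs2)
  recs2_m$pos <- 39999L - recs2_m$pos
  recs2_m <- recs2_m[order(recs2_m$pos), ]
  p_plus <- metagene_profile(list(x = methylome_sample("x", "x", recs2)),
                             genes, "CG", flank_bp = 2000,
                             n_body_bins = 10, n_flank_bins = 4)
  p_minus <- metagene_profile(list(x = methylome_sample("x", "x", recs2_m)),
                              genes_m, "CG", flank_bp = 2000,
                              n_body_bins = 10, n_flank_bins = 4)
  expect_equal(p_plus$raw_level, p_minus$raw_level)

  # brute-force per-bin pooling oracle on simulated genes
  cfg <- flat_config(seed = 99, chrom_length = 2e5, n_genes = 10L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_methylome(cfg, ann, "neuron_invivo")
  genes10 <- ann$features[ann$features$feature_type == "gene"]
  pr <- metagene_profile(list(a = sim), genes10, "CG", flank_bp = 1000,
                         n_body_bins = 5, n_flank_bins = 2)
  # oracle: loop genes x sites, assign bins naively
  nb <- 5L; nf <- 2L; fw <- 1000 / nf
  m <- numeric(nb + 2L * nf); tot <- numeric(nb + 2L * nf)
  rcg <- sim$records[sim$records$context == "CG", ]
  for (gi in seq_len(nrow(genes10))) {
    gs <- genes10$start[gi]; ge <- genes10$end[gi]
    sub <- rcg[rcg$pos >= gs - 1000 & rcg$pos < ge + 1000, ]
    for (ri in seq_len(nrow(sub))) {
      p <- sub$pos[ri]
      b <- if (p < gs) 1L + min(floor((p - (gs - 1000)) / fw), nf - 1L)
      else if (p >= ge) nf + nb + 1L + min(floor((p - ge) / fw), nf - 1L)
      else nf + 1L + min(floor((p - gs) / (ge - gs) * nb), nb - 1L)
      if (genes10$strand[gi] == "-") b <- (nb + 2L * nf) + 1L - b
      m[b] <- m[b] + sub$count_m[ri]
      tot[b] <- tot[b] + sub$count_total[ri]
    }
  }
  expect_equal(pr$raw_level, m / tot, tolerance = 1e-12)
})

test_that("feature class summary covers the six classes and recovers set-points", {
  cfg <- flat_config(seed = 101)
  ann <- simulate_annotation(cfg)
  s <- simulate_methylome(cfg, ann, "esc")
  fcs <- feature_class_summary(s, ann, "CG")
  expect_setequal(fcs$class, c("whole_genome", "intergenic", "intron",
                               "exon", "CGI", "TSS_window"))
  expect_equal(fcs$raw_level[fcs$class == "whole_genome"],
               weighted_level(s, "CG")$raw_level)
  # CGI CG level near its set-point (the subtraction correction estimates
  # p * (1 - nc)), distinct from the gene-body level. A single 3-SE draw
  # fails ~1% of seeds, so the bias is tested on the mean standardised error
  # over six seeds.
  z <- vapply(101:106, function(sd) {
    cfg_i <- flat_config(seed = sd)
    ann_i <- simulate_annotation(cfg_i)
    s_i <- simulate_methylome(cfg_i, ann_i, "esc")
    fcs_i <- feature_class_summary(s_i, ann_i, "CG")
    cgi <- fcs_i[fcs_i$class == "CGI", ]
    se <- corrected_level_se(0.10, cgi$total_calls, nc = 0.005,
                             n_spike_calls = s_i$nonconversion$calls_used[["CG"]])
    (cgi$corrected_level - 0.10 * (1 - 0.005)) / se
  }, 0)
  expect_lt(abs(mean(z)), 3 / sqrt(6))
  expect_gt(fcs$corrected_level[fcs$class == "intergenic"], 0.7)

  # missing classes are reported by name
  slim <- ann$features[ann$features$feature_type %in% c("gene", "exon")]
  expect_error(feature_class_summary(s, slim, "CG"), "intergenic")

  # an annotation where exons tile all DNA equals the genome level
  allex <- data.table::rbindlist(list(
    ann$features[ann$features$feature_type %in%
                   c("intergenic", "intron", "CGI", "TSS_window")],
    data.table::data.table(chrom = "chr1", start = 0L,
                           end = cfg$chrom_length, name = "bigexon",
                           feature_type = "exon", strand = "+")))
  fcs2 <- feature_class_summary(s, allex, "CH")
  expect_equal(fcs2$raw_level[fcs2$class == "exon"],
               fcs2$raw_level[fcs2$class == "whole_genome"])
})
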