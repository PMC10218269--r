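# Seeded synthetic-methylome generator. It emulates the statistical structure
# of the study design: six sample groups (ESC, NPC, in vitro neuron, in vivo
# neuron, glia, fetal cortex) sequenced at ~30x mean coverage per cytosine,
# with a fully unmethylated lambda-like spike-in, context-specific methylation
# set-points, bin-scale regional methylation structure shared between related
# groups, optional planted DMRs, and expression anticorrelated with gene-body
# mCH. Counts only; no reads or sequence are simulated.

# Dinucleotide layout repeated along every chromosome. Per 10 sites:
# 2x CG, 4x CA, 2x CC, 2x CT, so 20% of sites are CG and, among CH sites,
# CA:CC:CT = 2:1:1 (mCA dominates mCH as in neuronal genomes).
.SITE_PATTERN <- c("CG", "CA", "CC", "CT", "CA", "CG", "CA", "CT", "CC", "CA")

#' Methylation set-points for one sample group
#'
#' True (pre-nonconversion) methylation probabilities: `mCG_gene_body` for CG
#' sites outside CpG islands, `mCG_CGI` for CG sites in CpG islands,
#' `mCH_global` for the genome-wide weighted CH level and `mCA_share` for the
#' fraction of CH methylation carried by CA sites. With the fixed site layout
#' (CA = half of CH sites) the per-context probabilities are
#' `p_CA = 2 * mCA_share * mCH_global` and
#' `p_CC = p_CT = 2 * (1 - mCA_share) * mCH_global`.
#'
#' Regional structure: every group modulates its site probabilities by a
#' smooth bin-scale multiplier built from a latent profile shared within its
#' class (`ch_class` for CH; one genome-wide latent profile for CG) mixed
#' with an idiosyncratic profile; `w_cg`/`w_ch` in `[0,1]` are the
#' idiosyncratic variance weights (0 = fully shared regional pattern).
#' Multipliers are renormalised to a site-weighted mean of one so global
#' set-points are preserved.
#'
#' @param mCG_gene_body,mCG_CGI,mCH_global,mCA_share probabilities in `[0,1]`.
#' @param ch_class latent-profile class label for CH regional structure.
#' @param w_cg,w_ch idiosyncratic variance weights in `[0,1]`.
#' @return a `group_profile` list.
#' @export
group_profile <- function(mCG_gene_body, mCG_CGI, mCH_global, mCA_share,
                          ch_class = "other", w_cg = 0.3, w_ch = 0.3) {
  p <- c(mCG_gene_body = mCG_gene_body, mCG_CGI = mCG_CGI,
         mCH_global = mCH_global, mCA_share = mCA_share,
         w_cg = w_cg, w_ch = w_ch)
  if (any(p < 0 | p > 1))
    stop("group_profile values must lie in [0, 1]")
  if (2 * mCA_share * mCH_global > 1 || 2 * (1 - mCA_share) * mCH_global > 1)
    stop("mCH_global / mCA_share imply a per-context probability > 1")
  structure(list(mCG_gene_body = mCG_gene_body, mCG_CGI = mCG_CGI,
                 mCH_global = mCH_global, mCA_share = mCA_share,
                 ch_class = ch_class, w_cg = w_cg, w_ch = w_ch),
            class = "group_profile")
}

#' Default group set-points for the six study groups
#'
#' CH set-points are chosen so the global weighted mCA levels equal the
#' study's printed values: in vitro neurons 5.3% (day 38), in vivo adult
#' neurons slightly below, ESC 1.25%, NPC intermediate-low, glia and fetal
#' cortex below 0.1%. CG levels place the in vitro neuron ~8% above the in
#' vivo neuron (genome-wide CG hypermethylation) with lowly methylated CpG
#' islands throughout. The two neuron groups share the CH regional profile;
#' the in vitro neuron's CG regional profile is mostly idiosyncratic
#' (regionally uneven hypermethylation), glia intermediate, fetal and in vivo
#' neuron almost fully shared.
#'
#' @return named list of [group_profile()] objects.
#' @export
default_group_profiles <- function() {
  list(
    esc = group_profile(0.80, 0.10, 0.0125 / (2 * 0.8), 0.8,
                        ch_class = "other", w_cg = 0.30, w_ch = 0.30),
    npc = group_profile(0.78, 0.08, 0.0040 / (2 * 0.8), 0.8,
                        ch_class = "other", w_cg = 0.30, w_ch = 0.30),
    neuron_invitro = group_profile(0.86, 0.06, 0.053 / (2 * 0.8), 0.8,
                                   ch_class = "neuron", w_cg = 0.90,
                                   w_ch = 0.05),
    neuron_invivo = group_profile(0.78, 0.05, 0.045 / (2 * 0.8), 0.8,
                                  ch_class = "neuron", w_cg = 0.05,
                                  w_ch = 0.05),
    glia = group_profile(0.80, 0.05, 0.0005, 0.8,
                         ch_class = "nonneuronal", w_cg = 0.50, w_ch = 0.20),
    fetal = group_profile(0.77, 0.05, 0.0005, 0.8,
                          ch_class = "nonneuronal", w_cg = 0.05, w_ch = 0.20)
  )
}

#' Simulation configuration
#'
#' @param seed master seed; every stream (layout, annotation, each
#'   sample x chromosome, planting, expression) derives its own substream
#'   from it, so generation order never matters.
#' @param n_chrom,chrom_length number and length (bp) of autosome-like
#'   chromosomes (`chr1`, `chr2`, ...).
#' @param n_genes,exons_per_gene gene count and exons per gene.
#' @param depth_mean mean sequencing depth per cytosine (Poisson), default 30
#'   as in the study.
#' @param nonconversion bisulfite nonconversion (false-methylation) rate in
#'   `[0, 0.05]`; a scalar applied to every context or a vector named by
#'   context. Default 0.005.
#' @param group_profiles named list of [group_profile()] set-points.
#' @param site_spacing mean spacing between simulated cytosines (bp); the
#'   8 bp default approximates real dinucleotide densities (roughly one CA
#'   site per 20 bp across both strands), which the DMR density filter
#'   presumes.
#' @param spike_length length of the unmethylated spike-in contig (bp).
#' @param cgi_fraction fraction of TSSs carrying a CpG island.
#' @param n_enhancers intergenic enhancer count.
#' @param regional_scale bin size (bp) of the latent regional methylation
#'   profiles.
#' @param regional_sd named vector, log-scale SD of the regional multiplier
#'   for `CG` and `CH`.
#' @param overdispersion beta-binomial overdispersion rho in `[0,1)`;
#'   0 (default) gives pure binomial counts with analytic SEs.
#' @param expression_model list `a` (intercept), `b` (slope, must be < 0) and
#'   `sd` (noise SD) of `log(TPM + 1) = a + b * mCH + N(0, sd)`.
#' @param dmr_plant optional `data.table(chrom, start, end, context, delta)`
#'   of regions to plant in comparisons (see [plant_dmrs()]).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 2.5e6,
                       n_genes = 300L,
                       exons_per_gene = 5L,
                       depth_mean = 30,
                       nonconversion = 0.005,
                       group_profiles = default_group_profiles(),
                       site_spacing = 8L,
                       spike_length = 1.2e5,
                       cgi_fraction = 0.6,
                       n_enhancers = 100L,
                       regional_scale = 1e5,
                       regional_sd = c(CG = 0.04, CH = 0.40),
                       overdispersion = 0,
                       expression_model = list(a = 2.5, b = -30, sd = 0.4),
                       dmr_plant = NULL) {
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (any(nonconversion < 0) || any(nonconversion > 0.05))
    stop("nonconversion must lie in [0, 0.05]")
  if (!is.null(expression_model) && expression_model$b >= 0)
    stop("expression_model slope b must be < 0")
  if (overdispersion < 0 || overdispersion >= 1)
    stop("overdispersion must lie in [0, 1)")
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 depth_mean = depth_mean, nonconversion = nonconversion,
                 group_profiles = group_profiles,
                 site_spacing = as.integer(site_spacing),
                 spike_length = as.integer(spike_length),
                 cgi_fraction = cgi_fraction,
                 n_enhancers = as.integer(n_enhancers),
                 regional_scale = as.integer(regional_scale),
                 regional_sd = regional_sd,
                 overdispersion = overdispersion,
                 expression_model = expression_model,
                 dmr_plant = dmr_plant),
            class = "sim_config")
}

# Nonconversion rate for one base context from the config (scalar or named).
config_nc <- function(config, context) {
  nc <- config$nonconversion
  if (length(nc) == 1L && is.null(names(nc))) return(unname(nc))
  if (!context %in% names(nc))
    stop(sprintf("config$nonconversion lacks context %s", context))
  unname(nc[[context]])
}

# Deterministic cytosine layout for one contig: jittered positions at
# site_spacing intervals with the cyclic context pattern and random strand.
layout_sites <- function(chrom, length_bp, spacing, stream_seed) {
  n <- (length_bp %/% spacing)
  with_seed(stream_seed, {
    jitter <- sample.int(spacing, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    data.table::data.table(
      chrom = chrom,
      pos = as.integer(seq_len(n) - 1L) * spacing + jitter,
      strand = strand,
      context = rep_len(.SITE_PATTERN, n))
  })
}

#' Simulate a genome annotation
#'
#' Places non-overlapping genes (each with `exons_per_gene` exons and the
#' intervening introns), 1 kb TSS windows (500 bp each side of the TSS), CpG
#' islands at a fraction of TSSs, intergenic enhancers, the intergenic
#' complement, and the fixed cytosine site layout shared by all simulated
#' samples. Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return `genome_annotation` list with elements `chrom_lengths`, `features`
#'   (all typed intervals), `sites` (genome cytosine layout with CGI/gene
#'   membership flags) and `spike_sites` (spike-in layout).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  margin <- 11000L  # metagene flanks + TSS windows stay inside bounds
  min_len <- 3000L
  min_gap <- 1500L
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1L)))
  span <- config$chrom_length - 2L * margin
  if (any(per_chrom * (min_len + min_gap) > span))
    stop("n_genes infeasible for the configured genome size")

  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  chrom_lengths <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                                   chroms)

  feats <- with_seed(derive_seed(config$seed, "annotation"), {
    out <- vector("list", config$n_chrom)
    for (ci in seq_len(config$n_chrom)) {
      ng <- per_chrom[ci]
      if (ng == 0L) { out[[ci]] <- NULL; next }
      lens <- pmin(pmax(round(stats::rlnorm(ng, log(8000), 0.35)),
                        min_len), 20000L)
      slack <- span - sum(lens) - ng * min_gap
      if (slack < 0) stop("n_genes infeasible for the configured genome size")
      w <- stats::runif(ng + 1L)
      gaps <- min_gap + floor(slack * w / sum(w))[seq_len(ng)]
      starts <- margin + cumsum(gaps) + cumsum(c(0L, lens[-ng]))
      ends <- starts + lens
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      gene_id <- sprintf("gene_%s_%03d", chroms[ci], seq_len(ng))
      genes <- data.table::data.table(chrom = chroms[ci],
                                      start = as.integer(starts),
                                      end = as.integer(ends),
                                      name = gene_id, feature_type = "gene",
                                      strand = strand)
      # exon/intron structure: k exons pinned to the gene ends
      k <- config$exons_per_gene
      ex <- lapply(seq_len(ng), function(i) {
        len <- lens[i]
        w_ex <- min(300L, len %/% (2L * k))
        anchors <- floor((len - w_ex) * (seq_len(k) - 1L) / (k - 1L))
        data.table::data.table(chrom = chroms[ci],
                               start = as.integer(starts[i] + anchors),
                               end = as.integer(starts[i] + anchors + w_ex),
                               name = sprintf("%s_ex%d", gene_id[i], seq_len(k)),
                               feature_type = "exon", strand = strand[i])
      })
      ex <- data.table::rbindlist(ex)
      intr <- ex[, {
        s <- end[-.N]; e <- start[-1L]
        list(start = s, end = e,
             name = sprintf("%s_in%d", name[1L], seq_len(.N - 1L)),
             strand = strand[1L])
      }, by = list(chrom, gene = sub("_ex\\d+$", "", name))]
      introns <- intr[end > start,
                      list(chrom, start, end, name, feature_type = "intron",
                           strand)]
      tss <- ifelse(strand == "+", starts, ends - 1L)
      tssw <- data.table::data.table(chrom = chroms[ci],
                                     start = as.integer(tss - 500L),
                                     end = as.integer(tss + 500L),
                                     name = sprintf("%s_tss", gene_id),
                                     feature_type = "TSS_window",
                                     strand = strand)
      has_cgi <- stats::runif(ng) < config$cgi_fraction
      cgi <- data.table::data.table(chrom = chroms[ci],
                                    start = as.integer(tss[has_cgi] - 400L),
                                    end = as.integer(tss[has_cgi] + 400L),
                                    name = sprintf("%s_cgi", gene_id[has_cgi]),
                                    feature_type = "CGI",
                                    strand = rep(".", sum(has_cgi)))
      out[[ci]] <- data.table::rbindlist(list(genes, ex, introns, tssw, cgi))
    }
    feats <- data.table::rbindlist(out)

    # intergenic complement of the gene set, per chromosome
    genes_all <- feats[feature_type == "gene"]
    inter <- genes_all[, {
      s <- c(0L, end); e <- c(start, chrom_lengths[[chrom[1L]]])
      keep <- e > s
      list(start = s[keep], end = e[keep])
    }, by = chrom]
    inter[, `:=`(name = sprintf("intergenic_%s_%03d", chrom, seq_len(.N)),
                 feature_type = "intergenic", strand = "."), by = chrom]

    # enhancers: 500 bp, in 700 bp slots inside intergenic gaps, 200 bp off
    # gene borders; multiple slots per gap so large counts fit small genomes
    gaps <- inter[(end - start) >= 900L]
    slots <- gaps[, {
      k <- (end - start - 400L) %/% 700L
      list(slot_start = start + 200L + 700L * (seq_len(k) - 1L))
    }, by = list(chrom, gap_start = start)]
    if (nrow(slots) < config$n_enhancers)
      stop("n_enhancers infeasible: not enough intergenic space")
    take <- slots[sample.int(.N, config$n_enhancers)]
    off <- floor(stats::runif(nrow(take)) * 200L)
    enh <- take[, list(chrom, start = as.integer(slot_start + off),
                       end = as.integer(slot_start + off + 500L),
                       name = sprintf("enhancer_%03d", seq_len(.N)),
                       feature_type = "enhancer", strand = ".")]
    data.table::setorder(enh, chrom, start)
    enh[, name := sprintf("enhancer_%03d", seq_len(.N))]
    data.table::rbindlist(list(feats,
                               inter[, list(chrom, start, end, name,
                                            feature_type, strand)],
                               enh))
  })
  data.table::setkey(feats, chrom, start, end)

  sites <- data.table::rbindlist(lapply(chroms, function(ch)
    layout_sites(ch, chrom_lengths[[ch]], config$site_spacing,
                 derive_seed(config$seed, "layout", ch))))
  # membership flags used by the group set-points
  sites[, in_cgi := overlaps_any(sites, feats[feature_type == "CGI"])]
  sites[, in_gene := overlaps_any(sites, feats[feature_type == "gene"])]
  sites[, bin := paste0(chrom, ":", pos %/% config$regional_scale)]

  spike_sites <- layout_sites("lambda_spike", config$spike_length,
                              config$site_spacing,
                              derive_seed(config$seed, "layout", "lambda"))

  structure(list(chrom_lengths = chrom_lengths, features = feats,
                 sites = sites, spike_sites = spike_sites, config = config),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d chromosome(s), %s bp; %d sites\n",
              length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ","), nrow(x$sites)))
  print(x$features[, .N, by = feature_type])
  invisible(x)
}

# TRUE for sites whose position falls inside any feature interval.
overlaps_any <- function(sites, features) {
  if (nrow(features) == 0L) return(rep(FALSE, nrow(sites)))
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  s <- GenomicRanges::GRanges(features$chrom,
                              IRanges::IRanges(features$start + 1L,
                                               features$end))
  IRanges::overlapsAny(q, s)
}

# Regional multiplier per (bin, context class) for one group: lognormal in a
# latent z mixing a class-shared and a group-own profile, renormalised to a
# site-weighted mean of one so global set-points are preserved exactly.
regional_multiplier <- function(config, sites, context_class, share_label,
                                group, w_own) {
  sdlog <- unname(config$regional_sd[[context_class]])
  bins <- sort(unique(sites$bin))
  if (is.na(sdlog) || sdlog == 0 || length(bins) < 2L)
    return(stats::setNames(rep(1, length(bins)), bins))
  z_shared <- with_seed(derive_seed(config$seed, "regional", context_class,
                                    "shared", share_label),
                        stats::rnorm(length(bins)))
  z_own <- with_seed(derive_seed(config$seed, "regional", context_class,
                                 "own", group),
                     stats::rnorm(length(bins)))
  z <- sqrt(1 - w_own) * z_shared + sqrt(w_own) * z_own
  m <- exp(sdlog * z)
  ctx <- if (context_class == "CG") "CG" else .CH_CONTEXTS
  w <- sites[context %in% ctx, .N, by = bin]
  wt <- stats::setNames(rep(0, length(bins)), bins)
  wt[w$bin] <- w$N
  m <- m * sum(wt) / sum(wt * m)
  stats::setNames(m, bins)
}

# True per-site methylation probabilities for one group over the shared layout.
true_site_probs <- function(config, annotation, group) {
  prof <- config$group_profiles[[group]]
  if (is.null(prof))
    stop(sprintf("unknown group '%s': not in config$group_profiles", group))
  sites <- data.table::copy(annotation$sites)
  p_ch <- c(CA = 2 * prof$mCA_share * prof$mCH_global,
            CC = 2 * (1 - prof$mCA_share) * prof$mCH_global,
            CT = 2 * (1 - prof$mCA_share) * prof$mCH_global)
  base <- numeric(nrow(sites))
  is_cg <- sites$context == "CG"
  base[is_cg] <- ifelse(sites$in_cgi[is_cg], prof$mCG_CGI, prof$mCG_gene_body)
  base[!is_cg] <- p_ch[sites$context[!is_cg]]
  m_cg <- regional_multiplier(config, sites, "CG", "genome", group, prof$w_cg)
  m_ch <- regional_multiplier(config, sites, "CH", prof$ch_class, group,
                              prof$w_ch)
  mult <- ifelse(is_cg, m_cg[sites$bin], m_ch[sites$bin])
  sites[, p_true := pmin(pmax(base * mult, 0), 1)]
  sites
}

# Draw observed counts at given true probabilities: depth ~ Poisson, methylated
# calls ~ Binomial(depth, p_obs) with p_obs = p + (1 - p) * nonconversion
# (optionally beta-binomial when overdispersion > 0).
draw_counts <- function(sites, config, stream_seed) {
  with_seed(stream_seed, {
    n <- nrow(sites)
    depth <- stats::rpois(n, config$depth_mean)
    nc_by_ctx <- vapply(.BASE_CONTEXTS, function(cx) config_nc(config, cx), 0)
    nc <- nc_by_ctx[sites$context]
    p_obs <- sites$p_true + (1 - sites$p_true) * nc
    if (config$overdispersion > 0) {
      rho <- config$overdispersion
      shp <- (1 - rho) / rho
      inner <- p_obs > 0 & p_obs < 1
      p_obs[inner] <- stats::rbeta(sum(inner), p_obs[inner] * shp,
                                   (1 - p_obs[inner]) * shp)
    }
    count_m <- stats::rbinom(n, depth, p_obs)
    sites[, `:=`(count_m = count_m, count_total = depth)]
  })
  sites
}

#' Simulate one sample's methylome plus its spike-in
#'
#' Uses the fixed cytosine layout from the annotation, the group's
#' methylation set-points with regional modulation, Poisson depth at
#' `depth_mean`, and binomial methylated counts at
#' `p_obs = p_true + (1 - p_true) * nonconversion`. The spike-in contig has
#' `p_true = 0` everywhere, so its apparent methylation estimates the
#' nonconversion rate. Deterministic for fixed seed, with one stream per
#' (sample, chromosome).
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()].
#' @param group group name present in `config$group_profiles`.
#' @param sample_name sample label (defaults to the group name); distinct
#'   labels give independent replicate draws of the same group.
#' @return a [methylome_sample()] whose `records` carry an extra `p_true`
#'   column (simulation truth; dropped on write).
#' @export
simulate_methylome <- function(config, annotation, group,
                               sample_name = group) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "genome_annotation"))
  sites <- true_site_probs(config, annotation, group)
  recs <- data.table::rbindlist(lapply(split(sites, sites$chrom), function(s)
    draw_counts(data.table::copy(s), config,
                derive_seed(config$seed, "counts", sample_name, s$chrom[1L]))))
  recs <- recs[, list(chrom, pos, strand, context, count_m, count_total,
                      p_true)]
  data.table::setkey(recs, chrom, pos)
  spike <- data.table::copy(annotation$spike_sites)
  spike[, p_true := 0]
  spike <- draw_counts(spike, config,
                       derive_seed(config$seed, "counts", sample_name,
                                   "lambda_spike"))
  spike <- spike[, list(chrom, pos, strand, context, count_m, count_total)]
  methylome_sample(sample_name, group, recs, spikein = spike)
}

#' Plant differentially methylated regions into one sample of a pair
#'
#' Inside each planted region the true methylation of sample `b` is shifted
#' by `delta` (clipped to `[0,1]`) at the region's context and the observed
#' methylated counts are redrawn at the same depths. Regions must not
#' overlap. Returns the modified sample and the truth intervals (a BED-ready
#' feature table).
#'
#' @param pair list of two [methylome_sample()] objects named `a` and `b`;
#'   records must carry the simulation `p_true` column.
#' @param dmr_plant `data.frame(chrom, start, end, context, delta)`; context
#'   `"CH"` targets all of CA/CC/CT.
#' @param config the [sim_config()] used to generate the pair.
#' @return list with `a` (untouched), `b` (modified), `truth` (feature table,
#'   `feature_type = "DMR"`).
#' @export
plant_dmrs <- function(pair, dmr_plant, config) {
  stopifnot(all(c("a", "b") %in% names(pair)))
  dmr_plant <- data.table::as.data.table(dmr_plant)
  if (nrow(dmr_plant) == 0L)
    return(list(a = pair$a, b = pair$b, truth = dmr_plant))
  if (!"p_true" %in% names(pair$b$records))
    stop("plant_dmrs needs simulated records carrying p_true")
  gr <- GenomicRanges::GRanges(dmr_plant$chrom,
                               IRanges::IRanges(dmr_plant$start + 1L,
                                                dmr_plant$end))
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    stop("planted regions overlap")
  recs <- data.table::copy(pair$b$records)
  for (i in seq_len(nrow(dmr_plant))) {
    ctx <- expand_context(dmr_plant$context[i])
    idx <- which(recs$chrom == dmr_plant$chrom[i] &
                   recs$pos >= dmr_plant$start[i] &
                   recs$pos < dmr_plant$end[i] &
                   recs$context %in% ctx)
    if (length(idx) == 0L) next
    p_new <- pmin(pmax(recs$p_true[idx] + dmr_plant$delta[i], 0), 1)
    nc <- vapply(recs$context[idx], function(cx) config_nc(config, cx), 0)
    p_obs <- p_new + (1 - p_new) * nc
    cm <- with_seed(derive_seed(config$seed, "plant", i),
                    stats::rbinom(length(idx), recs$count_total[idx], p_obs))
    recs[idx, `:=`(count_m = cm, p_true = p_new)]
  }
  truth <- dmr_plant[, list(chrom, start = as.integer(start),
                            end = as.integer(end),
                            name = sprintf("planted_dmr_%03d", seq_len(.N)),
                            feature_type = "DMR", strand = ".")]
  b <- methylome_sample(pair$b$name, pair$b$group, recs,
                        spikein = pair$b$spikein,
                        nonconversion = pair$b$nonconversion)
  list(a = pair$a, b = b, truth = truth)
}

#' Simulate expression anticorrelated with gene-body mCH
#'
#' `log(TPM + 1) = a + b * mCH + Normal(0, sd)` with `b < 0`; TPM is clipped
#' at zero. Genes without an mCH value are omitted with a warning.
#'
#' @param gene_mch `data.frame(gene, mch)` or a named numeric vector of
#'   gene-body mCH levels.
#' @param expression_model list with `a`, `b` (<= 0; the study design uses a
#'   strictly negative slope) and `sd`.
#' @param seed RNG seed for the noise term.
#' @return expression `data.table` with columns `gene`, `tpm`.
#' @export
simulate_expression <- function(gene_mch, expression_model, seed = 1L) {
  if (is.numeric(gene_mch))
    gene_mch <- data.table::data.table(gene = names(gene_mch),
                                       mch = unname(gene_mch))
  gene_mch <- data.table::as.data.table(gene_mch)
  # b = 0 is allowed here for null checks; the study configuration itself
  # (sim_config) requires a strictly negative slope.
  if (expression_model$b > 0) stop("expression_model slope b must be <= 0")
  drop <- !is.finite(gene_mch$mch)
  if (any(drop)) {
    warning(sprintf("%d gene(s) without mCH omitted from expression", sum(drop)))
    gene_mch <- gene_mch[!drop]
  }
  lt <- with_seed(derive_seed(seed, "expression"),
                  expression_model$a + expression_model$b * gene_mch$mch +
                    stats::rnorm(nrow(gene_mch), 0, expression_model$sd))
  data.table::data.table(gene = gene_mch$gene,
                         tpm = pmax(exp(lt) - 1, 0))
}

#' Simulate the full study design
#'
#' Convenience wrapper: annotation plus one methylome per configured group,
#' and expression tables for the two neuron groups derived from their true
#' gene-body mCH.
#'
#' @param config a [sim_config()].
#' @param groups group names to simulate (default: all configured).
#' @param expression_for groups for which to simulate expression.
#' @return list with `config`, `annotation`, `samples` (named list of
#'   [methylome_sample()]) and `expression` (named list of TPM tables).
#' @export
simulate_study <- function(config = sim_config(),
                           groups = names(config$group_profiles),
                           expression_for = intersect(
                             c("neuron_invitro", "neuron_invivo"), groups)) {
  annotation <- simulate_annotation(config)
  samples <- lapply(groups, function(g) simulate_methylome(config, annotation, g))
  names(samples) <- groups
  genes <- annotation$features[feature_type == "gene"]
  expression <- lapply(expression_for, function(g) {
    mch <- true_gene_mch(samples[[g]], genes)
    simulate_expression(mch, config$expression_model,
                        seed = derive_seed(config$seed, "expr", g))
  })
  names(expression) <- expression_for
  list(config = config, annotation = annotation, samples = samples,
       expression = expression)
}

# True (noise-free) gene-body mCH per gene from the simulation truth column.
true_gene_mch <- function(sample, genes) {
  recs <- sample$records[context %in% .CH_CONTEXTS]
  q <- GenomicRanges::GRanges(recs$chrom,
                              IRanges::IRanges(recs$pos + 1L, recs$pos + 1L))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  dt <- data.table::data.table(gene = genes$name[S4Vectors::subjectHits(hits)],
                               p = recs$p_true[S4Vectors::queryHits(hits)])
  out <- dt[, list(mch = mean(p)), by = gene]
  stats::setNames(out$mch, out$gene)
}
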