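#!/usr/bin/env Rscript
# In vitro vs in vivo methylome comparison: per-gene deltas and hyper/hypo
# fractions, heatmap gene ordering, metagene profiles, cross-context
# correlation of deltas, and Spearman correlation clustering of 100 kb bins
# in both contexts.

source("analysis/00_common.R")

study <- get_study()
ann <- study$annotation
genes <- ann$features[feature_type == "gene"]
mat <- gene_methylation_matrix(study$samples[neuron_samples], genes)
fwrite(mat, file.path(results_dir, "gene_methylation_matrix.tsv"), sep = "\t")

d_cg <- gene_deltas(mat, "neuron_invitro", "neuron_invivo", "CG")
d_ch <- gene_deltas(mat, "neuron_invitro", "neuron_invivo", "CH")
cl_cg <- classify_hyper_hypo(d_cg, threshold = 0.1)
cl_ch <- classify_hyper_hypo(d_ch, threshold = 0.01)
fr <- list(cg = as.list(cl_cg$fractions), ch = as.list(cl_ch$fractions),
           n_genes = cl_cg$n_classified)
jsonlite::write_json(fr, file.path(results_dir, "hyper_hypo_fractions.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("gene-body fractions: CG hyper %.1f%% / hypo %.1f%% (|delta| > 0.1), CH hyper %.1f%% / hypo %.1f%% (|delta| > 0.01)\n",
            100 * cl_cg$fractions["hyper"], 100 * cl_cg$fractions["hypo"],
            100 * cl_ch$fractions["hyper"], 100 * cl_ch$fractions["hypo"]))

ord <- order_for_heatmap(d_cg)
writeLines(ord, file.path(results_dir, "heatmap_gene_order_cg.txt"))

cc <- cross_context_correlation(d_cg, d_ch)
cat(sprintf("cross-context Pearson r of per-gene deltas: %.4f over %d genes (near zero: contexts change independently)\n",
            cc$r, cc$n))

prof <- metagene_profile(study$samples[neuron_samples], genes, "CG")
prof_ch <- metagene_profile(study$samples[neuron_samples], genes, "CH")
fwrite(rbind(cbind(context = "CG", prof), cbind(context = "CH", prof_ch)),
       file.path(results_dir, "metagene_profiles.tsv"), sep = "\t")

for (cx in c("CG", "CH")) {
  bm <- bin_genome(study$samples[neuron_samples], ann, cx)
  cl <- correlation_clustering(bm)
  writeLines(cl$newick, file.path(results_dir,
                                  sprintf("clustering_%s.nwk", cx)))
  fwrite(data.table(bin = rownames(bm$levels), bm$levels),
         file.path(results_dir, sprintf("bin_levels_%s.tsv", cx)), sep = "\t")
  cat(sprintf("%s 100 kb-bin tree: %s\n", cx, cl$newick))
}
cat("wrote gene_methylation_matrix.tsv, hyper_hypo_fractions.json, heatmap_gene_order_cg.txt, metagene_profiles.tsv, bin_levels_*.tsv, clustering_*.nwk\n")
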