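#!/usr/bin/env Rscript
# Neuron-similarity gene score and preranked GSEA. Genes are scored for
# having the same methylation state in both neuron samples while differing
# from glia/fetal, then a gene-set collection is tested against the ranking:
# a planted "neuron-similar" set drawn from the top decile of the score, plus
# size-matched random sets as negative controls.

source("analysis/00_common.R")

study <- get_study()
genes <- study$annotation$features[feature_type == "gene"]
mat <- gene_methylation_matrix(study$samples[neuron_samples], genes,
                               contexts = "CH")
lv <- function(g) {
  x <- mat[sample == g]
  stats::setNames(x$corrected_level, x$gene)
}
sc <- similarity_score(lv("neuron_invivo"), lv("neuron_invitro"),
                       lv("glia"), lv("fetal"))
fwrite(sc, file.path(results_dir, "similarity_scores_ch.tsv"), sep = "\t")
ranked <- rank_genes(stats::setNames(sc$combined, sc$gene))

set.seed(analysis_seed)
planted <- sample(ranked$gene[seq_len(ceiling(0.1 * nrow(ranked)))], 20)
coll <- c(list(neuron_similar_planted = planted),
          stats::setNames(lapply(1:25, function(i) sample(ranked$gene, 20)),
                          sprintf("random_%02d", 1:25)))
write_gmt(coll, file.path(results_dir, "gene_sets.gmt"))

res <- gsea_preranked(ranked, coll, n_perm = 1000, seed = analysis_seed,
                      p_filter = 1)
out <- res[, .(set, es, nes, p_value, size,
               leading_edge = vapply(leading_edge, paste, "",
                                     collapse = ","))]
fwrite(out, file.path(results_dir, "gsea_similarity_ch.tsv"), sep = "\t")

hit <- res[set == "neuron_similar_planted"]
cat(sprintf("planted neuron-similar set: ES %.3f, NES %.2f, p %.4g\n",
            hit$es, hit$nes, hit$p_value))
cat(sprintf("random sets significant at p < 0.05: %d of 25 (false positives)\n",
            nrow(res[set != "neuron_similar_planted" & p_value < 0.05])))
cat("wrote similarity_scores_ch.tsv, gene_sets.gmt, gsea_similarity_ch.tsv\n")
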