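#!/usr/bin/env Rscript
# Step 4 — structure among the nine PAMPA membranes.
#
# UPGMA dendrogram of the D' matrix and covariance PCA of the
# (e,s,a,b,v) coefficient vectors; exports the tree as Newick and the
# loadings/scores/explained variance as CSV.

library(pampalfer)
dir.create("results", showWarnings = FALSE)

sys <- pampa_systems()
nine <- sys[sys$category == "pampa", ]
m <- dprime_matrix(nine)

h <- hierarchical_cluster(m, linkage = "upgma")
writeLines(dendrogram_newick(h), "results/04_dendrogram.nwk")
merges <- data.frame(step = seq_along(h$height), height = h$height)
cat("UPGMA merge heights:\n"); print(round(h$height, 3))
cat(sprintf("first merge: systems %d and %d at D' = %.3f\n",
            -h$merge[1, 1], -h$merge[1, 2], h$height[1]))

p <- pca_coefficients(nine, k = 2)
print(p)
utils::write.csv(data.frame(coefficient = rownames(p$loadings),
                            p$loadings),
                 "results/04_pca_loadings.csv", row.names = FALSE)
utils::write.csv(data.frame(system_id = rownames(p$scores), p$scores),
                 "results/04_pca_scores.csv", row.names = FALSE)
utils::write.csv(data.frame(component = c("PC1", "PC2"),
                            explained_fraction =
                              p$explained_variance_fraction),
                 "results/04_pca_variance.csv", row.names = FALSE)
utils::write.csv(radial_plot_data(nine), "results/04_radial_plot_data.csv",
                 row.names = FALSE)
cat(sprintf("PC1+PC2 explain %.2f%% of the coefficient variance\n",
            100 * sum(p$explained_variance_fraction)))
cat("wrote results/04_dendrogram.nwk and PCA/radial CSVs\n")
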