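#!/usr/bin/env Rscript
# Step 5 — which PAMPA membranes can emulate which biological process?
#
# Scores PAMPA systems 1-8 against the five biological reference
# processes (skin permeation, water-skin partition, intestinal
# absorption, blood-brain partition, saline-brain permeation); pairs at
# D' <= 1 are flagged as able to emulate.  The poorly-correlated
# hexadecane P16 membrane (system 9) is excluded as in the compilation.
# Bundles the whole analysis into one JSON report.

library(pampalfer)
dir.create("results", showWarnings = FALSE)

sys <- pampa_systems()
pampa <- sys[sys$category == "pampa" & sys$system_id != "9", ]
bio <- sys[sys$category == "biological", ]

flags <- compare_to_biological(pampa, bio, threshold = 1.0)
utils::write.csv(flags, "results/05_emulation_flags.csv", row.names = FALSE)
cat("pairs flagged as emulating (D' <= 1):\n")
print(flags[flags$emulates, ], row.names = FALSE)

m <- dprime_matrix(sys)
nine <- sys[sys$category == "pampa", ]
report <- list(systems = sys[, c("system_id", "name", "category",
                                 "e", "s", "a", "b", "v")],
               dprime = m,
               dendrogram_newick =
                 dendrogram_newick(hierarchical_cluster(dprime_matrix(nine))),
               pca = pca_coefficients(nine, k = 2),
               flags = flags,
               threshold = 1.0)
write_report(report, "results/05_analysis_report.json")
cat("wrote results/05_emulation_flags.csv, results/05_analysis_report.json\n")
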