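#!/usr/bin/env Rscript

# Step 6: effective connectivity.
#
# Reads the afferent and efferent connectivity-probability matrices,
# keeps edges at or above the 0.5 probability cut, clusters each matrix's
# region probability patterns into a hierarchical binary tree (exported
# as Newick), cuts at k = 4, and compares the two directions.

suppressPackageStartupMessages(library(faceseeg))

dataset <- "results/dataset"
cfg <- analysis_config()
aff <- read_connectivity(file.path(dataset, "connectivity_afferent.csv"),
                         "afferent")
eff <- read_connectivity(file.path(dataset, "connectivity_efferent.csv"),
                         "efferent")

for (cm in list(aff, eff)) {
  edges <- threshold_edges(cm, cfg)
  utils::write.table(edges,
                     sprintf("results/edges_%s.tsv", cm$direction),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tree <- cluster_regions(cm)
  write_tree_newick(tree, sprintf("results/tree_%s.nwk", cm$direction))
  part <- cut_regions(tree, 4)
  message(sprintf("%s: %d edges >= %.2f; k=4 clusters: %s",
                  cm$direction, nrow(edges), cfg$conn_threshold,
                  paste(vapply(split(names(part), part), paste,
                               character(1), collapse = "+"),
                        collapse = " | ")))
}

cmp <- compare_directions(aff, eff, cfg)
print(cmp)
utils::write.table(
  data.frame(correlation = cmp$correlation,
             edge_agreement = cmp$edge_agreement,
             same_partition_k4 = cmp$same_partition),
  "results/direction_comparison.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message("wrote results/edges_*.tsv, results/tree_*.nwk, results/direction_comparison.tsv")
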