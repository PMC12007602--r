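#!/usr/bin/env Rscript

# Step 3: continuous cortical surface maps.
#
# Builds the three geodesic-disk, logistic-kernel maps from the per-lead
# results: sampling density (leads/cm^2), overall responsiveness (% of
# explored, masked below 10%) and relative responsiveness (% of
# responding, masked below 10%).  Per-node values go to TSV and a GIFTI
# functional overlay.

suppressPackageStartupMessages(library(faceseeg))

dataset <- "results/dataset"
mesh <- read_mesh(file.path(dataset, "mesh.off"))
assignment <- utils::read.table(file.path(dataset, "lead_nodes.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
res <- utils::read.table("results/lead_results.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
cfg <- analysis_config()
flags <- map_flags(res)

for (kind in c("density", "overall", "relative")) {
  map <- compute_map(kind, mesh, assignment, flags, cfg)
  write_surface_map(map, sprintf("results/map_%s.tsv", kind))
  write_surface_map_gifti(map, sprintf("results/map_%s.gii", kind))
  shown <- map$values[map$mask]
  unit <- if (kind == "density") "leads/cm^2" else "%"
  message(sprintf("%s map: %d/%d nodes displayable, range %.2f-%.2f %s",
                  kind, sum(map$mask), length(map$mask),
                  if (length(shown)) min(shown) else NA,
                  if (length(shown)) max(shown) else NA, unit))
}
message("wrote results/map_{density,overall,relative}.{tsv,gii}")
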