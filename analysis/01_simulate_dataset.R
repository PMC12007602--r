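#!/usr/bin/env Rscript

# Step 1: generate the synthetic study dataset.
#
# Builds a spherical cortical mesh, scatters SEEG leads over it, plants
# per-lead evoked responses (a subset of leads responds to faces, a subset
# of those discriminates emotional from neutral expressions, with peak
# latencies spread over the 100-500 ms classes), simulates epoched trials
# at the study conditions (54 trials per condition, 1000 Hz, -200..700 ms
# epochs), draws a nearest-seed parcellation, and writes block-structured
# afferent/efferent connectivity matrices.  All downstream steps read
# these files only.

suppressPackageStartupMessages(library(faceseeg))

out_dir <- "results/dataset"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- analysis_config()
seed <- cfg$rng_seed

## geometry --------------------------------------------------------------
mesh <- make_mesh("sphere", n_nodes = 642, spacing_mm = 3, seed = seed)
n_nodes <- nrow(mesh$node_positions)
write_mesh_off(mesh, file.path(out_dir, "mesh.off"))
write_mesh_gifti(mesh, file.path(out_dir, "mesh.gii"))

placement <- make_leads(mesh, n_leads = 60, seed = seed)
write_leads_table(placement$leads, file.path(out_dir, "leads.tsv"))
utils::write.table(placement$assignment,
                   file.path(out_dir, "lead_nodes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## nearest-seed parcellation (synthetic stand-in for an atlas) -----------
set.seed(seed)
n_regions <- 12
seeds <- sample.int(n_nodes, n_regions)
d2 <- vapply(seeds, function(s)
  colSums((t(mesh$node_positions) - mesh$node_positions[s, ])^2),
  numeric(n_nodes))
labels <- sprintf("parc_%02d", max.col(-d2))
utils::write.table(
  data.frame(node_index = seq_len(n_nodes), region = labels,
             hemisphere = mesh$hemisphere),
  file.path(out_dir, "parcellation.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

## planted evoked structure ----------------------------------------------
# Selectivity follows the parcellation: leads whose majority parcel is
# parc_01..parc_03 discriminate emotional from neutral (amplitude gap
# >= 5 noise SD), leads in parc_04..parc_05 respond equally to every
# condition, the rest are silent.  Latency classes cycle over 100..500 ms.
parc <- parcellation(labels)
labelled <- assign_regions(placement$leads, mesh, placement$assignment,
                           parc)
lead_region <- match(labelled$region, sprintf("parc_%02d", 1:n_regions))
specs <- lapply(seq_len(nrow(labelled)), function(l) {
  lat <- c(100, 200, 300, 400, 500)[(l - 1) %% 5 + 1]
  reg <- lead_region[l]
  if (!is.na(reg) && reg <= 3) {
    list(smiling = evoked_spec(6, lat, 120),
         fearful = evoked_spec(5, lat, 120),
         neutral = evoked_spec(1, lat, 120))
  } else if (!is.na(reg) && reg <= 5) {
    list(smiling = evoked_spec(5, lat, 120),
         fearful = evoked_spec(5, lat, 120),
         neutral = evoked_spec(5, lat, 120))
  } else {
    list(smiling = NULL, fearful = NULL, neutral = NULL)
  }
})
n_selective_planted <- sum(lead_region <= 3, na.rm = TRUE)
n_responsive_planted <- sum(lead_region <= 5, na.rm = TRUE)
rec <- simulate_epochs(placement, specs, noise_spec(1),
                       n_trials_per_condition = 54, config = cfg,
                       seed = seed + 2)
write_epochs(rec, file.path(out_dir, "epochs"))

## connectivity: four planted clusters over nine regions of interest -----
regions <- c("vmPFC", "rACC", "cACC", "latOFC1", "latOFC2",
             "IFGpt", "AI", "RO", "IFJ")
blocks <- list(cingulate = 1:3, orbitofrontal = 4:5,
               lateral_prefrontal = 6:7, premotor = 8:9)
aff <- simulate_connectivity(regions, blocks, p_within = 0.8,
                             p_between = 0.1, noise_sd = 0.02,
                             seed = seed + 3, direction = "afferent")
eff <- simulate_connectivity(regions, blocks, p_within = 0.8,
                             p_between = 0.1, noise_sd = 0.02,
                             seed = seed + 4, direction = "efferent")
write_connectivity(aff, file.path(out_dir, "connectivity_afferent.csv"))
write_connectivity(eff, file.path(out_dir, "connectivity_efferent.csv"))

message(sprintf("dataset: %d-node mesh, %d leads (%d responsive, %d selective planted), %d trials",
                n_nodes, 60, n_responsive_planted, n_selective_planted,
                dim(rec$data)[2]))
message("wrote ", out_dir)
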