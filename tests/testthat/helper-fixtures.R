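# Shared builders for small in-code fixtures.

# lead_set of n leads at given x positions on a line
line_leads <- function(n, x = seq_len(n), hemisphere = rep("R", n),
                       grey = rep(TRUE, n)) {
  faceseeg:::as_lead_set(data.frame(
    lead_id = sprintf("L%02d", seq_len(n)),
    x = x, y = 0, z = 0,
    hemisphere = hemisphere, grey_matter = grey,
    stringsAsFactors = FALSE))
}

# epoched recording built from an explicit per-condition trial generator:
# gen(condition, trial) must return a numeric vector of n_samp samples
build_recording <- function(conditions, n_trials, gen,
                            n_leads = 1L, sampling_rate = 1000,
                            epoch_window = c(-200, 700)) {
  n_samp <- diff(epoch_window) * sampling_rate / 1000
  trial_cond <- rep(conditions, each = n_trials)
  data <- array(NA_real_, dim = c(n_leads, length(trial_cond), n_samp))
  for (l in seq_len(n_leads)) {
    for (tr in seq_along(trial_cond)) {
      data[l, tr, ] <- gen(trial_cond[tr], tr)
    }
  }
  epoched_recording(data, lead_ids = sprintf("L%02d", seq_len(n_leads)),
                    conditions = trial_cond,
                    sampling_rate = sampling_rate,
                    epoch_window = epoch_window)
}

# Gaussian bump on the epoch time axis, zero before onset
bump_waveform <- function(times, amplitude, peak_ms, width_ms = 100) {
  sdms <- width_ms / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(times - peak_ms)^2 / (2 * sdms^2)) * (times >= 0)
}

default_times <- function(epoch_window = c(-200, 700)) {
  seq(epoch_window[1], epoch_window[2] - 1)
}

# brute-force shortest path by DFS over all simple paths (small meshes only)
brute_force_geodesic <- function(mesh, from, to) {
  tr <- mesh$triangles
  e <- unique(t(apply(rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)]), 1, sort)))
  elen <- sqrt(rowSums((mesh$node_positions[e[, 1], , drop = FALSE] -
                          mesh$node_positions[e[, 2], , drop = FALSE])^2))
  n <- nrow(mesh$node_positions)
  adj <- lapply(seq_len(n), function(i) {
    hit <- which(e[, 1] == i | e[, 2] == i)
    data.frame(node = ifelse(e[hit, 1] == i, e[hit, 2], e[hit, 1]),
               len = elen[hit])
  })
  best <- Inf
  dfs <- function(node, visited, acc) {
    if (acc >= best) return()
    if (node == to) { best <<- acc; return() }
    nb <- adj[[node]]
    for (k in seq_len(nrow(nb))) {
      if (!visited[nb$node[k]]) {
        v <- visited; v[nb$node[k]] <- TRUE
        dfs(nb$node[k], v, acc + nb$len[k])
      }
    }
  }
  visited <- rep(FALSE, n); visited[from] <- TRUE
  dfs(from, visited, 0)
  best
}

# leads tiling a strip: k leads of 7 consecutive nodes each
tiled_strip_assignment <- function(n_leads) {
  data.frame(lead_id = rep(sprintf("L%d", seq_len(n_leads)), each = 7),
             node = seq_len(7 * n_leads))
}
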