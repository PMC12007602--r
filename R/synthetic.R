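#' Generate a synthetic triangulated mesh
#'
#' Three geometries, all deterministic for a given seed:
#' * `"strip"` — `n_nodes` collinear nodes at `spacing_mm`, triangulated by
#'   consecutive triples. The skip-edges this produces have length
#'   `2 * spacing_mm` and cannot shorten chain paths, so the geodesic
#'   distance between nodes `i` and `j` is exactly `|i - j| * spacing_mm`.
#' * `"grid"` — a near-square planar lattice with unit-cell triangles.
#' * `"sphere"` — a subdivided icosahedron scaled so the mean edge length
#'   is approximately `spacing_mm`, with at least `n_nodes` nodes.
#'
#' Meshes are centred on the origin so that both hemispheres (x < 0 vs
#' x >= 0) are populated.
#'
#' @param kind `"strip"`, `"grid"` or `"sphere"`.
#' @param n_nodes requested number of nodes (>= 3; the sphere rounds up to
#'   the next icosahedral subdivision).
#' @param spacing_mm nominal edge length in mm.
#' @param seed integer seed (kept for interface symmetry; the geometries
#'   are deterministic).
#' @return A `cortical_mesh`.
#' @export
make_mesh <- function(kind = c("strip", "grid", "sphere"),
                      n_nodes = 100L, spacing_mm = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (n_nodes < 3L) stop("n_nodes must be at least 3")
  stopifnot(spacing_mm > 0)
  switch(kind,
         strip = make_mesh_strip(n_nodes, spacing_mm),
         grid = make_mesh_grid(n_nodes, spacing_mm),
         sphere = make_mesh_sphere(n_nodes, spacing_mm))
}

make_mesh_strip <- function(n, spacing) {
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  pos <- cbind(x = x, y = 0, z = 0)
  tris <- if (n >= 3) cbind(1:(n - 2), 2:(n - 1), 3:n) else
    matrix(integer(0), ncol = 3)
  cortical_mesh(pos, tris)
}

make_mesh_grid <- function(n, spacing) {
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  pos <- cbind(x = (ij$j - (nc + 1) / 2) * spacing,
               y = (ij$i - (nr + 1) / 2) * spacing,
               z = 0)
  idx <- function(i, j) (j - 1L) * nr + i
  tris <- NULL
  for (j in seq_len(nc - 1)) {
    for (i in seq_len(nr - 1)) {
      tris <- rbind(tris,
                    c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                    c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  cortical_mesh(pos, tris)
}

make_mesh_sphere <- function(n, spacing) {
  # icosahedron
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  while (nrow(v) < n) {
    # subdivide each triangle into 4, deduplicating midpoints
    key <- function(a, b) paste(min(a, b), max(a, b))
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid_cache[[k]])) return(mid_cache[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[k]] <- nrow(v)
      nrow(v)
    }
    newf <- NULL
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  # scale so the mean edge length is about spacing
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  elen <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  cortical_mesh(v * spacing / mean(elen), f)
}

#' Place synthetic leads on a mesh
#'
#' Lead positions are mesh nodes chosen by greedy farthest-point sampling
#' from a seeded random start, which keeps leads well separated. Each lead
#' is then represented by its `nodes_per_lead` (default 7) nearest mesh
#' nodes; nodes are claimed greedily in lead order so assignments are
#' disjoint. With a single lead the assignment is exactly its 7 nearest
#' nodes.
#'
#' @param mesh a `cortical_mesh`.
#' @param n_leads number of leads (>= 1).
#' @param seed integer seed for the placement.
#' @param nodes_per_lead nodes representing one lead (default 7).
#' @param p_white proportion of leads marked as white matter (excluded by
#'   the grey-matter view); default 0.
#' @return A list of class `"lead_placement"`: `leads` (a `lead_set`) and
#'   `assignment` (data.frame `lead_id`, `node` with `nodes_per_lead` rows
#'   per lead, disjoint across leads).
#' @export
make_leads <- function(mesh, n_leads, seed = 1L, nodes_per_lead = 7L,
                       p_white = 0) {
  stopifnot(inherits(mesh, "cortical_mesh"), n_leads >= 1,
            p_white >= 0, p_white < 1)
  n <- nrow(mesh$node_positions)
  if (n_leads > floor(n / nodes_per_lead)) {
    stop("too many leads: ", n_leads, " leads need ",
         n_leads * nodes_per_lead, " nodes but the mesh has ", n)
  }
  set.seed(seed)
  pos <- mesh$node_positions
  centre <- integer(n_leads)
  centre[1] <- sample.int(n, 1L)
  if (n_leads > 1) {
    d2min <- colSums((t(pos) - pos[centre[1], ])^2)
    for (k in 2:n_leads) {
      centre[k] <- which.max(d2min)
      d2min <- pmin(d2min, colSums((t(pos) - pos[centre[k], ])^2))
    }
  }
  lead_id <- sprintf("lead%03d", seq_len(n_leads))
  taken <- rep(FALSE, n)
  assign_rows <- vector("list", n_leads)
  for (k in seq_len(n_leads)) {
    d2 <- colSums((t(pos) - pos[centre[k], ])^2)
    ord <- order(d2, seq_len(n))  # ties by node index
    picked <- ord[!taken[ord]][seq_len(nodes_per_lead)]
    taken[picked] <- TRUE
    assign_rows[[k]] <- data.frame(lead_id = lead_id[k], node = picked,
                                   stringsAsFactors = FALSE)
  }
  grey <- rep(TRUE, n_leads)
  if (p_white > 0) {
    grey[sample.int(n_leads, round(p_white * n_leads))] <- FALSE
  }
  leads <- as_lead_set(data.frame(
    lead_id = lead_id,
    x = pos[centre, 1], y = pos[centre, 2], z = pos[centre, 3],
    hemisphere = mesh$hemisphere[centre],
    grey_matter = grey,
    stringsAsFactors = FALSE))
  structure(list(leads = leads,
                 assignment = do.call(rbind, assign_rows)),
            class = "lead_placement")
}

#' Evoked-response specification
#'
#' A Gaussian-bump evoked waveform: `amplitude * polarity *
#' exp(-(t - peak)^2 / (2 * sd^2))` for t >= 0, where `sd` is derived from
#' the full-width-at-half-maximum `width_ms`. The bump is zero before
#' stimulus onset so the baseline segment carries noise only.
#'
#' @param amplitude peak amplitude, arbitrary (microvolt-like) units, >= 0.
#' @param peak_latency_ms peak latency in (0, 700].
#' @param width_ms FWHM of the bump in ms.
#' @param polarity `+1` or `-1`.
#' @return A list of class `"evoked_spec"`.
#' @export
evoked_spec <- function(amplitude, peak_latency_ms, width_ms = 100,
                        polarity = 1) {
  stopifnot(amplitude >= 0, width_ms > 0, polarity %in% c(-1, 1))
  structure(list(amplitude = amplitude,
                 peak_latency_ms = peak_latency_ms,
                 width_ms = width_ms,
                 polarity = polarity),
            class = "evoked_spec")
}

#' Noise specification
#'
#' White Gaussian noise plus an optional 1/f ("pink") component synthesized
#' by spectral shaping, giving EEG-like autocorrelation.
#'
#' @param white_sd standard deviation of the white component (>= 0).
#' @param pink_sd standard deviation of the 1/f component (>= 0).
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(white_sd = 1, pink_sd = 0) {
  stopifnot(white_sd >= 0, pink_sd >= 0)
  structure(list(white_sd = white_sd, pink_sd = pink_sd),
            class = "noise_spec")
}

# one trial of pink noise with unit SD via 1/sqrt(f) spectral shaping
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Simulate epoched recordings
#'
#' Each trial is noise plus the condition's Gaussian-bump evoked waveform
#' (see [evoked_spec()]); the pre-stimulus baseline carries no evoked
#' component. Deterministic for a given seed.
#'
#' @param leads a `lead_set` or `lead_placement` (its leads are used).
#' @param evoked either a named list `condition -> evoked_spec` applied to
#'   every lead, or a list of such lists (one per lead). `NULL` entries or
#'   missing conditions get no evoked component.
#' @param noise a `noise_spec`.
#' @param n_trials_per_condition trials per condition (>= 2), default 54
#'   presentations per stimulus condition.
#' @param config an [analysis_config()]; supplies the epoch window check.
#' @param seed integer seed.
#' @param sampling_rate Hz.
#' @param epoch_window epoch window in ms, half-open.
#' @return An `epoched_recording` with trials grouped by condition.
#' @export
simulate_epochs <- function(leads, evoked, noise = noise_spec(),
                            n_trials_per_condition = 54L,
                            config = NULL, seed = 1L,
                            sampling_rate = 1000,
                            epoch_window = c(-200, 700)) {
  config <- as_config(config)
  if (inherits(leads, "lead_placement")) leads <- leads$leads
  stopifnot(inherits(leads, "lead_set"), inherits(noise, "noise_spec"))
  if (n_trials_per_condition < 2) {
    stop("need at least 2 trials per condition")
  }
  n_leads <- nrow(leads)
  is_spec_map <- function(m) {
    is.list(m) && length(m) > 0 && !is.null(names(m)) &&
      all(vapply(m, function(e) is.null(e) || inherits(e, "evoked_spec"),
                 logical(1)))
  }
  per_lead <- if (is_spec_map(evoked)) {
    rep(list(evoked), n_leads)
  } else {
    if (length(evoked) != n_leads) {
      stop("evoked must be one condition->evoked_spec map, ",
           "or a list with one map per lead")
    }
    evoked
  }
  conditions <- unique(unlist(lapply(per_lead, names)))
  if (is.null(conditions)) {
    stop("evoked specs must be named by condition")
  }
  for (m in per_lead) {
    for (cond in names(m)) {
      sp <- m[[cond]]
      if (is.null(sp)) next
      if (sp$peak_latency_ms <= config$analysis_window[1] ||
          sp$peak_latency_ms > config$analysis_window[2]) {
        stop("evoked peak latency ", sp$peak_latency_ms,
             " ms is outside the analysis window (",
             config$analysis_window[1], ", ",
             config$analysis_window[2], "]")
      }
    }
  }
  step <- 1000 / sampling_rate
  times <- seq(epoch_window[1], epoch_window[2] - step, by = step)
  n_samp <- length(times)
  n_trials <- n_trials_per_condition * length(conditions)
  trial_cond <- rep(conditions, each = n_trials_per_condition)

  set.seed(seed)
  data <- array(0, dim = c(n_leads, n_trials, n_samp))
  for (l in seq_len(n_leads)) {
    bumps <- lapply(conditions, function(cond) {
      sp <- per_lead[[l]][[cond]]
      if (is.null(sp)) return(numeric(n_samp))
      sdms <- sp$width_ms / (2 * sqrt(2 * log(2)))
      sp$amplitude * sp$polarity *
        exp(-(times - sp$peak_latency_ms)^2 / (2 * sdms^2)) * (times >= 0)
    })
    names(bumps) <- conditions
    for (tr in seq_len(n_trials)) {
      x <- stats::rnorm(n_samp, sd = noise$white_sd)
      if (noise$pink_sd > 0) {
        x <- x + noise$pink_sd * pink_noise(n_samp)
      }
      data[l, tr, ] <- x + bumps[[trial_cond[tr]]]
    }
  }
  epoched_recording(data, lead_ids = leads$lead_id,
                    conditions = trial_cond,
                    sampling_rate = sampling_rate,
                    epoch_window = epoch_window)
}

#' Simulate a block-structured connectivity-probability matrix
#'
#' Planted-partition generator: entries within a block are centred on
#' `p_within`, entries across blocks on `p_between`, with independent
#' Gaussian noise, clipped to `[0, 1]`.
#'
#' @param regions character vector of region names.
#' @param blocks list of integer/character vectors partitioning `regions`.
#' @param p_within within-block probability (> `p_between`).
#' @param p_between between-block probability.
#' @param noise_sd SD of the additive noise.
#' @param seed integer seed.
#' @param direction `"afferent"` or `"efferent"`.
#' @return A `connectivity_matrix`.
#' @export
simulate_connectivity <- function(regions, blocks, p_within = 0.8,
                                  p_between = 0.1, noise_sd = 0.02,
                                  seed = 1L,
                                  direction = c("afferent", "efferent")) {
  direction <- match.arg(direction)
  stopifnot(p_within > p_between, p_within >= 0, p_within <= 1,
            p_between >= 0, p_between <= 1, noise_sd >= 0)
  r <- length(regions)
  idx_blocks <- lapply(blocks, function(b) {
    if (is.character(b)) match(b, regions) else as.integer(b)
  })
  flat <- unlist(idx_blocks)
  if (anyDuplicated(flat)) stop("blocks overlap")
  if (!setequal(flat, seq_len(r))) stop("blocks must partition the regions")
  member <- integer(r)
  for (k in seq_along(idx_blocks)) member[idx_blocks[[k]]] <- k
  base <- ifelse(outer(member, member, "=="), p_within, p_between)
  set.seed(seed)
  m <- base + matrix(stats::rnorm(r * r, sd = noise_sd), r, r)
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(regions, regions)
  connectivity_matrix(m, direction)
}

#' Block membership implied by a block list
#'
#' Convenience for comparing a planted partition with a recovered one.
#'
#' @param regions character vector of region names.
#' @param blocks list of vectors partitioning `regions` (names or indices).
#' @return Integer vector of block ids named by region.
#' @export
block_membership <- function(regions, blocks) {
  member <- integer(length(regions))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    idx <- if (is.character(b)) match(b, regions) else as.integer(b)
    member[idx] <- k
  }
  names(member) <- regions
  member
}
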