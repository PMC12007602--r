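---
title: "Mapping intracranial responses to emotional facial expressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intracranial responses to emotional facial expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceseeg)
```

## The problem

Stereo-electroencephalography (SEEG) records local field potentials from
depth electrodes implanted in patients undergoing presurgical epilepsy
evaluation. When such patients passively watch static images of smiling,
fearful and neutral faces, some recording leads show an intracranial
event-related potential (iERP), and a subset of those discriminate
emotional from neutral expressions. `faceseeg` implements the full
statistical chain that turns epoched multi-channel recordings into

1. per-lead responsiveness and selectivity calls,
2. continuous cortical surface maps of sampling density and
   responsiveness,
3. parcellation-level regional summaries with lateralization tests,
4. tabulated high-frequency stimulation (HF-ES) outcomes, and
5. thresholded, clustered cortico-cortical evoked-potential (CCEP)
   connectivity summaries.

Because clinical SEEG recordings cannot be redistributed, the package
ships a synthetic-data module that generates meshes, lead placements,
epoched recordings and connectivity matrices with exactly the
statistical structure the analyses assume; every stage is exercised and
validated against that generator.

## Per-lead statistics

**Epochs and baseline.** Trials are epoched in a half-open
[-200, 700) ms window around stimulus onset at 1000 Hz. Each trial's
mean over the pre-stimulus baseline [-200, 0) is subtracted from the
whole trial (subtractive baseline correction); the iERP is the mean of
the corrected trials of one condition. Correction is idempotent and a
constant trial maps to an identically zero waveform.

**Responsiveness.** The 0-700 ms window is divided into 35 adjacent
20-ms bins. For each bin, a two-sided paired t-test across trials
compares the trial's bin mean with its own baseline mean (α = 0.05). A
lead is *responsive* if at least four consecutive bins are significant.
The run-length rule is the multiplicity control: for 35 independent
Bernoulli(0.05) bins the exact probability of a run of four or more —
computed by the dynamic program in `runlength_null_prob()` — is about
1.9·10⁻⁴, almost three orders of magnitude below the per-bin rate. In
simulation the empirical flag rate on pure-noise leads sits at this
level (the shared baseline mean induces a weak positive correlation of
about 1/11 between bins, which can push the empirical rate slightly
above the independent-bin value; the calibration test uses an exact
binomial comparison to allow for Monte-Carlo error). A pooled variant
of the bin test (bin sample versus baseline sample, unpaired) is
available through `baseline_mode = "pooled"`; the paired reading is the
default.

**Selectivity.** For each responsive lead, a two-way ANOVA on per-trial
bin means crosses Condition (emotional versus neutral) with Time
(35 bins). Smiling, fearful and neutral trials are distinct trials, so
Condition cannot be a within-unit factor at the trial level: we treat
trials as the random unit, Condition as a between-trial factor and Time
as repeated within trials, i.e. a split-plot design fitted by `aov`
with an `Error(trial)` stratum. The decision rule is unchanged from the
two-within-factor reading: a lead is *selective* when the
Condition-by-Time interaction is significant **and** at least one main
effect is significant. Tests verify the resulting F statistics against
a from-scratch sums-of-squares computation to 10⁻⁸. No sphericity
correction is applied by default (a Greenhouse–Geisser option exists,
`sphericity_correction = TRUE`); selective leads get planned per-bin
contrasts (two-sample t-tests, uncorrected, in keeping with the
planned-comparison frame).

**Gating.** Selectivity is only evaluated on leads responsive in at
least one emotional condition, so selective leads are a subset of
responsive leads by construction — `analyze_leads()` enforces this
ordering.

**Peak latency.** The peak is the argmax of |waveform| over (0, 700]
(polarity-free, because iERP polarity depends on the recording
reference; ties go to the earliest sample). Latency classes are the
half-open 100-ms bins [c − 50, c + 50) around 100...500 ms, with the
extremes absorbing everything below 50 ms and at or above 550 ms.

## Continuous surface maps

Cortical geometry is a triangulated mesh; geodesic distance is the
shortest path on the triangle edge graph with Euclidean edge weights.
Edge-graph paths slightly overestimate exact polyhedral geodesics
(typically a few percent), which the distance kernel makes immaterial;
an exact-geodesic backend could be swapped in behind
`geodesic_distances()` without touching the map definitions.

Each lead is represented by a fixed number of mesh nodes (7 by
default), here the 7 nodes nearest to the lead position — the
image-based node assignment of a clinical pipeline is out of scope. For
every node, the nodes within a 1-cm geodesic disk contribute with a
logistic weight

w(d) = 1 / (1 + exp(s·(d − m))),  s = 2 mm⁻¹, m = 7.5 mm,

so nodes within 5 mm are near-maximally weighted and weights fade
towards the 10-mm rim, avoiding edge effects. The steepness is read as
per-millimetre; with that reading w(5 mm) ≈ 0.993 and w(10 mm) ≈ 0.0067,
matching the intended 5-mm plateau / 10-mm cut-off behaviour. Three
maps are defined per node:

* **density** = (weighted explored nodes / 7) / disk area — leads/cm²;
* **overall** = 100 · weighted responsive / weighted explored — the
  percentage of responding tissue among explored tissue;
* **relative** = 100 · weighted selective / weighted responsive — the
  selectivity topography among responding sites.

Overall and relative maps are masked below 10% to suppress sparsely
responsive territory; nodes with no explored (respectively responsive)
weight in their disk are masked too. The disk area uses the nominal
Euclidean πr² with r = 1 cm. The density normalisation radius is
configurable (`map_radius_mm`): descriptions of sampling-density
figures sometimes use a 2-cm disk, and the parameter surfaces that
choice rather than resolving it.

## Regional summaries

A parcellation labels mesh nodes with region names (the study-scale
template splits the brain into 129 structures; any node-label table
works). A lead inherits the majority region of its 7 nodes, ties broken
by the node nearest the lead; leads with no labelled node stay in the
lead-level and map stages but drop out of regional tables. Per region
and hemisphere we report explored leads, significant leads, the exact
percentage (display tables round half-away-from-zero to integer), and
the selection flag: at least 10% of the region's recording leads
significant, evaluated on at least 4 significant leads. The "four
leads" clause is read as a minimum on the significant count — the
published table marks a 43% cell with three significant leads as not
selected, which fixes that reading. Hemispheric lateralization is
tested by a 2×2 chi-squared on (significant, non-significant) × (L, R);
Yates correction is off by default (the reported significance pattern
reproduces either way on the published counts, e.g. χ² = 3.82,
p = 0.051 for 75/176 versus 84/252 and χ² = 6.07, p = 0.014 for 5/35
versus 1/61).

## Stimulation outcomes

HF-ES outcomes use a closed six-category vocabulary (sensorimotor,
interoceptive, emotional, language, unspecific subjective,
unresponsive); sensorimotor outcomes additionally carry a body district
(face/mouth, eye/neck, hand/arm). Tabulation counts categories and
districts by hemisphere; the headline unresponsive percentage is
derived as stimulated minus responsive over stimulated. On the
published counting scheme (273 stimulated, 103 responsive) this yields
62%; note the source's own unresponsive count (171) is internally
inconsistent with those two numbers by one site, so the derived count
(170) is used.

## Effective connectivity

Region-by-region CCEP connection probabilities (afferent and efferent)
are thresholded at probability 0.5 — inclusive boundary by default,
since the figure-level description uses "≥ 50%" while the text uses
"> 0.5"; `strict_gt = TRUE` restores the strict reading. Self-
connections are excluded. Each matrix row (a region's probability
pattern) is clustered agglomeratively into a hierarchical binary tree:
the distance between two regions is the Euclidean distance between
their rows with both mutual entries masked out, and linkage is average.
Neither distance nor linkage is prescribed by the study design; these
defaults are standard for probability patterns, and validation rests on
planted-structure recovery rather than one linkage's idiosyncrasies
(single and complete linkage recover the same planted partitions at the
tested noise levels). Trees export to Newick; cutting at k = 4 yields
the cluster-level partition, and `compare_directions()` reports the
off-diagonal correlation, thresholded-edge Jaccard agreement and
whether afferent and efferent trees induce the same k = 4 partition.

## The synthetic generator

`make_mesh()` builds strips (collinear chains with exactly known
geodesics — the skip edges of the collinear triangulation cannot
shorten chain paths), planar grids, and subdivided-icosahedron spheres.
`make_leads()` places leads by farthest-point sampling and assigns each
its 7 nearest unclaimed nodes. `simulate_epochs()` adds a Gaussian-bump
evoked waveform (amplitude, peak latency, FWHM width, polarity; zero
before onset) to white noise plus an optional 1/f component synthesised
by spectral shaping — the 1/f option exists precisely to stress the
bin-independence assumption of the responsiveness test with EEG-like
autocorrelation. `simulate_connectivity()` draws planted-partition
matrices (within/between-block probabilities, additive noise, clipped
to [0, 1]).

Defaults mirror the study conditions: 54 trials per condition
(the presentation count is stated per stimulus; whether it applies per
image or per condition is ambiguous in the source, so the trial count
is a parameter with 54 as default), unit noise SD, evoked amplitudes
quoted in noise-SD units, latencies in the 100-500 ms classes. What the
generator does **not** emulate: volume-conduction physics, epileptiform
or pathological high-frequency activity, artefacts, inter-patient
variability, or spatially correlated noise across leads. Passing the
validation suite therefore demonstrates the statistical machinery is
correct and calibrated under the stated noise model — not that the
pipeline is robust to every pathology of clinical data.

## Numerical choices and problem sizes

* Epoch windows and time bins are half-open; bin edges at
  0, 20, ..., 700 ms; a 900-sample epoch at 1000 Hz.
* Argmax ties take the earliest sample; region-majority ties take the
  nearest node's region; hclust ties resolve deterministically for a
  given input order.
* Degenerate inputs error early: fewer than 2 trials, constant
  waveforms, zero expected chi-squared cells, out-of-range triangle
  indices, connectivity values outside [0, 1].
* Validation problem sizes were chosen as the smallest that make the
  Monte-Carlo bounds sharp: 2000 null leads for criterion calibration,
  100 replicates for power/latency recovery and for planted-partition
  recovery, 30-60 replicates for secondary property tests. The
  end-to-end demonstration dataset uses a 642-node sphere, 60 leads and
  12 parcels.
* The epoch container is a flat little-endian float64 array with a JSON
  sidecar — language-neutral, bit-exact on round trip, and inspectable
  without special tooling. Vendor raw-recording formats are
  deliberately out of scope; epochs are the pipeline's entry point.

## Known limitations

* The whole-sheet smiling selectivity percentage printed in the source
  results (25.5%) disagrees with its own counts (427 of 1691 = 25.25%);
  the package reproduces the counts, and the acceptance check against
  the printed figure documents the discrepancy rather than hiding it.
* The ANOVA treats bins as exchangeable repeated measures; with strong
  temporal autocorrelation and no sphericity correction the
  interaction test is anticonservative, which is why the
  Greenhouse-Geisser option exists.
* Edge-graph geodesics, nearest-node lead assignment and the nominal
  disk area are desk-scale approximations of an imaging pipeline.
* Pooling leads across patient-level groupings (e.g. merging subfields
  of one functional territory) is supported only by relabelling
  regions before `regional_summary()`; no canonical grouping is
  encoded.
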