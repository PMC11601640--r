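---
title: "Models and methods behind cycleflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cycleflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cycleflow)
```

# Overview

`cycleflow` reimplements, as tested and reusable code, the computational
stages of a single-cell study of cell-cycle progression under kinase
inhibition in head-and-neck squamous cell carcinoma cells, together with
the cohort-level and pharmacology analyses that surround it:

1. **Imaging** — quantify CDK2 activity from two-channel time-lapse movies
   (a nuclear marker such as H2B-mTurquoise and a DHB-mVenus-style
   translocation sensor) via illumination-bias correction, nuclear
   segmentation, and a perinuclear cytoplasmic ring.
2. **Tracking and fate** — link nuclei into lineages, call anaphases by the
   45–55% daughter-size rule, and classify each post-mitotic cell as
   immediately re-entering the cycle, transiently quiescent (G0), or in
   prolonged G0; call G2 arrest when no second mitosis follows the first
   within 30 hours.
3. **Cytometry gating** — EdU/DNA-content bivariate phase gating.
4. **Copy-number consensus** — per-gene, per-PDX-model categorical status
   (diploid / gain / amplification) by majority vote over samples, with
   model-level mean FPKM and a one-way ANOVA of expression across classes.
5. **Non-compartmental PK** — trapezoidal AUC, terminal rate constant by
   log-linear tail regression, AUC extrapolation, half-life.
6. **TMT proteomics filtering** — decoy/contaminant cleanup, completeness
   and peptide-count filters, per-channel median normalisation, Student's
   t-tests, and |Log2FC| ≥ 1 / −log10 p ≥ 2 classification.

Every stage can be exercised on synthetic inputs with recorded ground
truth; the generators are first-class, tested code.

# The CDK2 sensor model

The translocation sensor leaves the nucleus as CDK2 activity rises, so
activity is read as the ratio

\[ A = \frac{\mathrm{median}(\text{cytoplasmic sensor})}
           {\mathrm{median}(\text{nuclear sensor})} \]

on the background-subtracted scale. Conventions adopted where the source
procedure is silent:

* **Ratio direction.** The cytoplasmic/nuclear direction follows the
  sensor construct (activity rises as the sensor exits the nucleus); the
  classification thresholds (0.6) are on this scale.
* **Nuclear statistic.** The median is specified only for the cytoplasm;
  we use the median for the nucleus too, for robustness and symmetry.
* **Background indistinguishability.** Ring pixels with corrected
  intensity ≤ *k*·(robust background sd) are excluded from the cytoplasmic
  median; *k* defaults to 2. No threshold is stated in the source; this is
  a recorded convention.

## Imaging procedure

* **Illumination bias** is fit empirically: cell-free pixels (below an
  Otsu split, eroded 5 px away from foreground) are sampled across frames
  and a degree-2 polynomial surface is fit and normalised to mean 1.
  Images are corrected as `image / surface − background`, clipped at 0.
* **Segmentation** is intensity thresholding (Otsu by default) plus
  8-connected labelling; components larger than `split_above_um2`
  (default 150 µm², ~1.7 nuclei) are split in two by a deterministic
  two-means on pixel coordinates seeded at the principal-axis extremes.
  Any algorithm meeting the synthetic recall/precision ≥ 0.95 property is
  conformant; this one is chosen for having no tunable learned parts.
* **Sub-pixel areas.** Nuclear areas are refined by flux integration:
  blurring conserves the integrated intensity of a uniform-brightness
  nucleus, so area = (integrated intensity within 3 px of the mask,
  contested pixels going to the nearer nucleus) / (plateau intensity from
  the eroded interior). Pixel counting is available (`subpixel = FALSE`).
  This matters because the mitosis rule tests area *fractions* against a
  band only 10 percentage points wide.
* **Cytoplasmic ring**: pixels whose Euclidean distance to the parent
  nuclear mask lies in (2, 10] µm, excluding all nuclear masks and any
  pixel within 10 µm of another nucleus. Distances are computed with an
  exact Euclidean distance transform on the pixel grid and converted by
  the pixel size; the band is half-open as written. A crowded-out (empty)
  ring yields a flagged missing value, never a zero.

# Tracking and fate rules

* **Tracking** is greedy nearest-neighbour linking gated by a maximum step
  (10 µm/frame default) and a maximum relative area change (35% default).
  The area gate is what makes anaphase visible to the tracker: a
  half-sized daughter cannot continue the mother's track, so the mother
  track ends and two daughter tracks begin.
* **Mitosis calling**: a track ending at frame *f* with two tracks
  starting at *f*+1 within 20 µm is a candidate; it is accepted iff both
  daughter/mother area fractions lie in **[0.45, 0.55]**, both ends
  inclusive ("approximately 45–55%" — inclusivity is our recorded
  convention). Rejected candidates are kept with their fractions.
* **Fate at anaphase + 2 h**: activity strictly greater than **0.6** means
  immediate re-entry; otherwise the cell is transient G0 if activity
  later exceeds 0.6 within the viewing time, else prolonged G0. Exactly
  0.6 counts as low (the rule says "greater than 0.6"). The 2-hour
  readout uses the single nearest frame (≤ 6 min error at the 12-min
  cadence); a 3-frame median is selectable.
* **G2 arrest**: a lineage with no second mitosis for more than **30 h**
  after the first is arrested; a second mitosis within 30 h means
  cycling; a movie ending earlier censors the call. "Second mitosis"
  means a division of either daughter lineage. The observation horizon
  is the movie end (synthetic cells are essentially never lost).

# The synthetic world

The movie generator states a world; its defaults are fixed and not tuned
to test outcomes:

* two channels, 12-min cadence, 0.65 µm pixels (20× objective class);
* nuclei are anti-aliased ellipses (~85 µm², mild 0.9–1.12 aspect) whose
  coverage-weighted rendering gives sub-pixel control of areas — the
  scheduled daughter fractions are honoured to ≪1%, which the band tests
  require; a σ = 1 px Gaussian blur smooths all edges;
* the sensor channel is partitioned so that (cytoplasmic − background) /
  (nuclear − background) equals the prescribed activity; the rendered
  cytoplasm reaches 10 µm from the nucleus, covering the measurement ring
  (ring exclusion still guarantees an admissible pixel never contains a
  neighbour's cytoplasm);
* prescribed activities are piecewise trajectories: post-anaphase baseline
  0.3, pre-mitotic peak 1.0 (consistent with the published dynamic range
  without reading figures as ground truth), re-entry rise 0.25 h⁻¹,
  transient-G0 crossing at 6 h by default, prolonged G0 capped below 0.5,
  G2-arrest plateau 0.9. The source describes no numeric sensor dynamics;
  these shapes are module conventions, not claims.
* motion is a bounded random walk: a tethered (Ornstein–Uhlenbeck-style)
  step of sd 2 px/frame with pairwise repulsion so nuclei never overlap.
  Without repulsion, colliding nuclei merge and re-split, which the
  tracker would see as spurious "divisions"; overlap-free motion is part
  of the stated world, and real-data merge behaviour is out of its scope.
* division places daughters symmetrically with a clean ~7 px boundary gap;
  near the field margin, clamping and repulsion alternate so the pair is
  never collapsed onto the border;
* death (used only for end-reason accounting) shrinks the nucleus by
  ~50% over two frames before removal.

A green end-to-end test therefore establishes that the pipeline recovers
a *known, overlap-free, uniformly lit, modestly noisy* world — not that
it handles debris, focus drift, apoptotic fragmentation, or dense
confluent cultures.

Table generators follow the same philosophy. The PDX cohort defaults
mirror the published cohort composition for the amplicon gene (58 models;
22 diploid / 31 gain / 5 amplified, i.e. class probabilities 0.38 / 0.53 /
0.09) with ≥ 4 samples per model; the perturbed-sample minority never
outvotes the latent class. PK profiles default to the published 8-point
sampling design (0.083–24 h) with n = 3 animals per time point and
lognormal noise; below-LLOQ records keep their true value plus a flag so
handling policies can be tested against truth. The TMT generator spikes
known up/down sets and assigns flags, missing values and peptide counts
for the filters.

# Numerical and statistical choices

* **CN thresholds**, literally: CN = 2 (to 1e−9) is diploid, (2, 5) is
  gain, ≥ 5 is amplification. Values below 2 fall outside the published
  three-class scheme: they map to a flagged `loss` class and leave the
  consensus denominator. Note the source's Results speak of amplification
  "at least 4 copies" while its Methods define ≥ 5; the Methods rule is
  implemented and the discrepancy is only surfaced here.
* **Consensus ties** break toward the more severe class and are flagged;
  the tie rule is exercised against an exhaustive brute-force mode
  computation over all 3⁶ vote vectors.
* **ANOVA** is fixed-effects one-way via `lm`/`anova`; the test suite
  checks it against an independent sum-of-squares oracle and the F = t²
  two-group identity, and calibrates null p-values (KS test) on 1000
  replicates.
* **NCA**: linear trapezoidal AUC; terminal λ by OLS of ln C on t over the
  best-adjusted-r² suffix (length ≥ 3, excluding Tmax) or a user tail;
  AUC0-∞ = AUC0-t + C_last/λ; **t½ = 0.693/λ with the printed constant**,
  not ln 2 — a 0.0147% difference, kept so outputs match the stated
  formula. Destructive sampling (n = 3 per time point) admits no
  per-animal profiles, so concentrations are naively pooled by nominal
  time. Below-LLOQ policy (configurable): zero before Tmax, excluded
  after, profile ends at the last quantifiable point.
* **TMT tests** are equal-variance Student's t (Welch by flag), raw
  p-values by design (no multiple-testing correction, matching the stated
  procedure; BH available), thresholds inclusive at |Log2FC| = 1.0 and
  −log10 p = 2.0, Log2FC = treated − control (the volcano orientation
  implies but does not state this; recorded here).
* **EdU gating**: the negative mode is the lowest density mode carrying
  ≥ 5% mass; its sd comes from the left half-distribution (robust to the
  positive tail); threshold = mode + 3 sd. EdU positivity takes precedence
  over DNA content (a 4N EdU+ cell is late-S); EdU-negative cells split at
  3N (the figure's boxes are graphical only; the midpoint is the
  symmetric default). Without units a "unimodal high" population cannot
  be distinguished from a unimodal low one; `max_mode` lets the caller
  state a bound, otherwise a unimodal population is treated as negative —
  the all-negative case must gate every cell EdU−.

# Degenerate inputs and tie-breaks

* Empty frames segment to empty detection sets; blank frames are detected
  by a contrast guard on the Otsu split.
* A zero-variance EdU or DNA channel anchors on the single value.
* t-tests with zero variance in both groups: p = 1 when means are equal
  (and the protein is `unchanged`), p = 0 with infinite t when they
  differ.
* λ ≤ 0 (non-decaying tails) is flagged not-reportable and propagates
  missing AUC0-∞ and t½.
* Two-means splitting initialises at the principal-axis extreme pixels,
  making the split deterministic (no RNG in the measurement path).

# Configuration surface

The command-line layer (`run_stage()`, `cf_main()`) accepts JSON
configuration (the YAML surface was dropped: no YAML parser is available
in the supported dependency set) and echoes a frozen parameter snapshot
next to every output. All stages are deterministic given `seed`; movies
can be streamed frame by frame (`stream_movie()`) so length is bounded by
disk, not memory. Movies are exchanged as plain-text frame pages plus a
JSON sidecar carrying pixel size, cadence, channel roles and ground truth
(no TIFF codec is available in the supported set; the in-memory array is
the primary interface).

# Known limitations

* The synthetic world omits photobleaching, focus drift, camera-specific
  noise, apoptotic morphology and dense confluence; conclusions about the
  pipeline's robustness are bounded accordingly.
* Death calling is a programmatic surrogate (area collapse without a
  split) for what the source assessed visually.
* The G2-arrest observation horizon is the movie end; lineages lost early
  are censored conservatively.
* Loess smoothing of amplification frequency uses `stats::loess`
  (local linear, tricube weights) with span 0.3 by default; the published
  figure names its smoother ambiguously ("loss method", read as loess).
* Real deposited proteomics tables can be read with
  `read_protein_groups()`, but no test or report depends on downloads.
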