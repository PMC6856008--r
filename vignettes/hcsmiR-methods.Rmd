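---
title: "Methods: phenotypic miRNA HCS analysis with hcsmiR"
author: "hcsmiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic miRNA HCS analysis with hcsmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcsmiR)
```

# Overview

hcsmiR implements a complete image-based high-content screening (HCS)
analysis for miRNA mimic libraries. The biological setting is a 96-well
screen in which each well is transfected with one miR mimic (plus a
negative-control mimic, here called PMC), stained with a nuclear dye
(DAPI channel), an anti-Snail/Slug immunostain (FITC channel) and a
whole-cell dye (Cy5 channel), and imaged at 9 fields per well. The
pipeline proceeds in five stages:

1. **Segmentation** — nuclei from DAPI, cell bodies grown from nucleus
   seeds over Cy5, cytoplasm as the per-object set difference.
2. **Morphometry** — per-cell area, eccentricity, solidity, neighbour
   count, percent intercellular contact, and nuclear/cytoplasmic median
   channel intensities.
3. **Profiles** — per-field medians, per-well values, and the
   percent-change-versus-control (PMC) profile matrix.
4. **Clustering and classification** — hierarchical clustering of miR
   profiles and a survival/EMT phenotype call per group.
5. **Targets** — group consensus predicted targets, opposite-group
   exclusion, hypergeometric/EASE pathway enrichment, and the
   regulatory-network export.

A migration module quantifies exclusion-zone migration assays, and a
synthetic-data module generates every input with planted ground truth,
so each stage is testable end to end without any external data.

# Synthetic data: what it emulates, and what it does not

`generateField()` renders cells as rasterized ellipses with sinusoidal
boundary jitter; each nucleus is a concentric ellipse with area ratio
0.25. Epithelial-style cells are placed in Gaussian clusters around
Poisson-distributed centres (`clusteringStrength` is the inverse
cluster spread; 0 means uniform placement); mesenchymal-style cells are
elongated (eccentricity 0.70–0.92) and dispersed. Channel rendering is
flat: the FITC intensity inside the nucleus and cytoplasm equals the
spec means exactly before noise, noise is additive Gaussian clipped to
the 16-bit range, and a constant background autofluorescence of 200
units is added everywhere. All randomness derives from one explicit
seed; per-well and per-field streams are split deterministically from
it, so a screen is reproducible bit for bit.

Default control-condition values (free parameters of the generator,
chosen once as plausible for a TNF-α-primed epithelial carcinoma line
at sub-confluent density; no published control distributions exist to
calibrate against): 50 cells per 512×512 field, mean cell area 400 px²,
per-cell eccentricity uniform on [0.45, 0.65] (an intermediate
morphology with headroom for planted effects in both directions),
nuclear:cytoplasmic Snail/Slug levels 3000:1500, DAPI 30000, Cy5 15000,
noise SD 50, boundary jitter 5%.

The generator does **not** emulate a point-spread function, shading,
channel bleed-through, debris, mitotic figures, or intensity gradients
within compartments. Consequently, passing tests demonstrate the
correctness of the *computation* (operators, aggregation, statistics),
not robustness to real microscopy artefacts — segmentation performance
on real images will depend on settings the synthetic benchmark cannot
probe.

`generateScreen()` derives each well's scene from the control spec by
scaling the four classification parameters by (1 + effect/100); the
planted per-well values are returned as a ground-truth table.
`generateTargetTable()` plants consensus genes that pass the
max(N − 2, 4) rule by construction, genes shared between designated
group pairs (to exercise exclusion), and i.i.d. background edges; the
analytic union bound on background-born false consensus genes is
attached to the result. `generateMigrationPair()` builds exclusion-zone
mask pairs whose occupied areas are exact distance-quantiles, so the
end/start ratio matches the requested growth factor to within one
pixel.

# Segmentation

Settings are deliberately classical because the original toolchain's
parameters are unpublished: Otsu threshold on a Gaussian-smoothed
channel (default sigma 2 px; a `fixed` threshold is available),
hole-filling, and optional declumping by distance-transform watershed.
Objects outside the nucleus area band (defaults 20–5000 px²) are
removed, border-touching nuclei are discarded when
`excludeBorderObjects` is TRUE (default, the usual convention to avoid
truncated morphometry), and surviving labels are renumbered 1..K in
raster-scan order of their first pixel so outputs are order-stable.

Cell bodies are grown from nucleus seeds by seeded propagation
(`EBImage::propagate`, the same constrained region-growing used by
CellProfiler's secondary-object identification) over the smoothed Cy5
channel, constrained to the Cy5 foreground united with the nucleus
pixels; this guarantees one cell per nucleus and nucleus ⊆ cell. The
cytoplasm map is cell minus nucleus, an identity tested per object.

A practical note on the Otsu + smoothing interaction: with a heavy
background class, the Otsu cut sits below the half-maximum of small
bright objects, so strong smoothing dilates them slightly (at sigma
2 px, planted nuclei of ~100 px² are recovered at IoU ≈ 0.85; at sigma
1 px recovery is pixel-exact on noise-free scenes). The default stays
at sigma 2 for robustness to noise; users segmenting small objects at
low noise may prefer sigma 1.

# Morphometry conventions

All conventions are fixed so that results are bit-stable:

* **Eccentricity** comes from the eigenvalues λ₁ ≥ λ₂ of the second
  central moment matrix of the pixel centres, as
  sqrt(1 − λ₂/λ₁), with 1/12 — the variance of a unit pixel — added to
  both diagonal moments (the MATLAB-regionprops ellipse). The
  correction makes a single pixel exactly 0, keeps every mask strictly
  below 1 (a bare pixel-centre formula returns 1 for any collinear
  mask), and changes nothing measurable for realistic objects: a
  rasterized 20×10-semi-axis ellipse still measures within 0.02 of the
  analytic sqrt(0.75) ≈ 0.866.
* **Solidity** is area divided by the number of pixel centres inside or
  on the convex hull of the object's pixel centres (the "convex image"
  count). Counting hull pixels rather than polygon area keeps solidity
  ≤ 1 for discs (a polygon over centres is smaller than the pixelated
  object) while remaining exactly reproducible by brute-force
  enumeration, which the tests do.
* **Neighbours**: two cells are neighbours iff their labels, expanded
  by `expansionPx` (default 1 px, 8-connectivity, ties to the lower
  label), contain an 8-adjacent pixel pair. **Percent touching** is
  measured on the *un*-expanded map: 100 × boundary pixels 8-adjacent
  to another label / total boundary pixels. The two measures use
  different maps on purpose, mirroring the distinction between
  neighbour detection distance and literal membrane contact.
* **Medians** over an even number of pixels are the midpoint of the two
  central order statistics (the R default), e.g. {10, 20, 30, 40} → 25.
  Cells with an empty cytoplasm keep their nuclear features and are
  flagged, never silently NA-propagated.

# Profiles and QC

Per-field values are medians over the field's (non-excluded) cells;
`count nuclei` is the cell count. Per-well values are medians across
the field medians, with counts summed. Wells with fewer than
`minCellsQc` cells (default 50) fail QC and are dropped with a logged
reason. The PMC value for treatment t and parameter p is

100 × (mean over t's passing wells − mean over control wells) / (mean over control wells).

The replicate combiner is the mean (configurable to median) — the
conventional percent-of-control choice; the control reference is the
mean across all passing control wells of the plate, which avoids
cross-plate drift when several plates are normalized separately.
Parameters whose control reference is 0 cannot be expressed as percent
change and are dropped with a warning (this happens naturally for
neighbour counts in sparse synthetic wells). Every dropped well and
column appears in the QC log.

# Clustering and the survival/EMT classification

Profiles are z-scored per column (parameters have incommensurate
scales), then clustered by average-linkage agglomeration on
1 − uncentered Pearson correlation. The uncentered (cosine) form is
the deliberate default: after column z-scoring, a profile that moves
all four parameters in the same direction is a near-constant row, and
*centred* correlation — which subtracts the row mean — erases exactly
the up-versus-down distinction that separates phenotype blocks;
uncentered correlation keeps the sign. Centred Pearson and Euclidean
remain available. The dendrogram is cut into `kMain` groups (the cut
level is a required user choice; no automatic rule is imposed),
labelled G1..Gk in leaf order. Optionally, any group whose members
disagree in the sign of their `count nuclei` change beyond `splitTol`
(default 10 points) is split into an "a" (positive) and "b" (negative)
survival subgroup, reproducing the G1 → G1a/G1b subdivision logic;
in-band members follow their raw sign, ties going to "a".

The phenotype call per group uses the four classification parameters
and a threshold `tau` (default 10 points, roughly the PMC noise floor
of the synthetic screens; configurable):

* survival direction = sign of mean `count nuclei` change where
  |mean| > tau, otherwise the group is *unclassified*;
* EMT direction = sign of the mean of the `cells eccentricity` and
  nuclear Snail/Slug changes where |mean| > tau;
* the EMT half of the label is attached **only** when the EMT direction
  is opposite the density confound: sparse wells (anti-survival) look
  mesenchymal and dense wells (pro-survival) look epithelial for purely
  physical reasons, so a pro-EMT signature in an anti-survival group
  (or anti-EMT in a pro-survival group) is treated as a density
  by-product and the group is labelled by survival alone.

Enumerating all sign patterns yields exactly five outcomes —
pro-survival/EMT, anti-survival/EMT, pro-survival, anti-survival,
unclassified — which the tests verify exhaustively. One naming caveat
is recorded for users of the historical group labels: source figure
text occasionally writes "G4" where the surrounding results use "G3";
the package treats these as the same third main group.

# Consensus targets, exclusion, enrichment

A gene is a consensus target of a group of N miRs when at least
max(N − 2, 4) distinct members are predicted to target it. miR identity
is matched case-insensitively after stripping the "hsa-" prefix;
TargetScan-style family rows are expanded to mature miRs only through
an explicit family-membership table, never by string heuristics.
Members absent from the table are reported but still count in N (the
threshold reflects group size, not table coverage). Whether transcripts
should be collapsed to genes before counting is unknowable from the
published method; the package counts the gene symbols of the table.

For each pair of opposite-phenotype groups, genes reaching consensus in
both are moved to the excluded set of *both* groups; filtered =
consensus − excluded. Enrichment of the filtered set is the one-sided
hypergeometric upper tail, with two conservative variants reported
alongside: the EASE score (the same tail with the overlap reduced by
one, floor 0 — the "modified Fisher exact" of the DAVID tool) and
Benjamini–Hochberg adjustment across tested pathways. The default
universe is all genes of the target table; it is an explicit, exposed
argument because the original analysis tool's background is
unpublished, and no attempt is made to reproduce any specific
enriched-pathway list (those depend on prediction-database and
annotation versions). Pathways arrive as GMT files; the regulatory
network (miR → gene → pathway, genes annotated with supporter counts)
exports to SIF and GraphML.

# Migration

The migration index is M = (Ae/As × 100) − 100 with As the occupied
area after seeding and Ae at endpoint; it is scale-invariant and may be
negative (contraction), which is flagged. Binary masks are measured
exactly. Grayscale (phase-contrast-like) images are segmented by
texture: a local-variance map (15 px window) thresholded by Otsu and
morphologically closed — phase-contrast cells differ from background in
texture, not mean brightness, and the original recipe is unpublished,
so this documented choice stands in.

# Numerical and degenerate-input policy

* Determinism everywhere: identical inputs and seeds give identical
  outputs, including watershed/propagation label assignment and
  raster-scan label renumbering.
* Empty cases are values, not errors, where the science allows: a blank
  field segments to zero nuclei; an empty field summary has count 0 and
  missing medians; an empty filtered set yields an empty network (with
  a warning). Hard errors are reserved for contract violations: missing
  channels, shape mismatches, As ≤ 0, k_main > n, self-pairs,
  infeasible growth, overcrowded fields.
* Profile rows with missing values are rejected rather than imputed.
* Tolerances in the test suite: morphometry agrees with brute-force
  oracles to 1e-9; hypergeometric tails agree with direct combinatorial
  sums to 1e-12 over all universes up to 60; planted screen effects are
  recovered within 2 percentage points (rasterization plus sampling) at
  the reference problem size below.

# Problem sizes used by the tests and acceptance script

The reference synthetic screen is 8 treatments × 3 wells plus 3 control
wells, 9 fields per well (243 fields of 512×512 px, 50 cells nominal
per control field, zero intensity noise) — large enough that per-well
medians estimate planted values to well under a percentage point for
counts and intensities, with eccentricity the noisiest readout (its
per-cell sampling width dominates). The consensus oracle runs 200
random tables up to 12 miRs × 300 genes; enrichment is verified
exhaustively for every (universe ≤ 60, pathway, query, overlap)
configuration; migration uses 512×512 masks. These sizes are the
package's reference conditions and are stated here so results are
interpretable, not tuned per run.

# Known limitations

* Synthetic realism limits noted above; no plate-spatial effects
  (row/column gradients, edge effects) are simulated or corrected —
  B-score-style normalization is out of scope.
* The classification rule is a formalization of a verbal convention;
  `tau` and `splitTol` defaults are package choices, and groups near
  the thresholds are sensitive to them.
* Bootstrap or consensus clustering stability is not assessed.
* TargetScan context++ scores are not modelled; the synthetic target
  tables are structural (who targets whom), not quantitative.

# A worked mini-run

```{r mini, eval = FALSE}
design <- screenDesign(list(
  `miR-x` = setNames(c(-40, -25, -30, -20), clusteringParameters())),
  replicates = 3, fieldsPerWell = 9)
base <- sceneSpec(nCells = 50, noiseSd = 0, seed = 7)
scr <- generateScreen(design, base)
fs <- fieldSummaries(scr$cells, fields = screenFields(design))
pm <- percentChangeMatrix(aggregateWells(fs), scr$layout, "PMC")
profileValues(pm)["miR-x", clusteringParameters()]
```
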