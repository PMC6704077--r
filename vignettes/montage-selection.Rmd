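---
title: "Selecting tDCS montages from simulated current-density fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting tDCS montages from simulated current-density fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscope)
```

## The problem

Transcranial direct current stimulation (tDCS) passes a weak current between
two scalp electrodes (an anode and a cathode, one configuration being a
*montage*). When a cognitive function involves two cortical pathways lying
close together — for reading, a dorsal grapho-phonological route around the
supramarginal gyrus and a ventral lexico-semantic route along the
middle/inferior temporal gyri — an experiment that wants to stimulate one
pathway per session needs a montage *pair* whose current distributions
overlap as little as possible.

Field simulators output, per montage, a cloud of cortical nodes with a scalar
magnitude of current density (MCD) at each node. `mscope` implements the
post-processing that turns several such fields into a montage choice, using
three principles applied in order:

1. **Lobe selectivity configuration.** For each montage, nodes are grouped by
   the 12 (hemisphere, lobe) categories of the anatomical labelling. Writing
   $\bar{m}_c$ for the mean MCD of category $c$, the montage's profile
   consists of the category with maximum mean (`max_MCD`), the unweighted
   average of category means (`avg_MCD`,
   $\mathrm{avg} = \tfrac{1}{|C|}\sum_c \bar{m}_c$), the percent exceedance
   $100(\bar{m}_c - \mathrm{avg})/\mathrm{avg}$ of every category above the
   average, and the *spread count* (non-maximum categories above the
   average). A montage passes when `max_MCD` sits in the pathway's target
   lobe; survivors are ranked by minimal spread.
2. **Thresholded overlap.** Each field is thresholded at 50% of its maximum;
   for a dorsal–ventral pair, $p = N_{\mathrm{overlap}} / N_{>\mathrm{thresh}}$
   relates the overlapping above-threshold nodes to the dorsal montage's
   count, and two pairs are contrasted by
   $r = |p_1 - p_2| / (p_1 + p_2) \in [0, 1]$. The pair with the fewest
   overlapping nodes wins.
3. **Gyrus clusters.** Above-threshold nodes are grouped by (hemisphere,
   gyrus); each cluster's CMCD is the *sum* of its members' values (so extent
   and intensity both count). The winning montages are verified by requiring
   a target gyrus among the top-$k$ clusters (default $k = 5$).

The final pair is the principle-2 winner when both members survive
principle 1 and pass principle 3.

## Design choices in the selection procedure

Several points are under-determined by the procedure's informal description;
the package resolves them as follows.

* `avg_MCD` is the **unweighted** mean of the category means, not the
  node-weighted grand mean, and categories without labelled nodes are
  omitted rather than counted as zero. Both hemispheres and the
  limbic/sublobar categories participate.
* Thresholding uses **strict** inequality (`value > 0.5 * max`), ties at the
  threshold are excluded, and the maximum is taken over labelled nodes only,
  so thresholding and the lobe statistics see the same support. Fraction-of-max
  thresholding makes every principle-2 and principle-3 statistic invariant
  under global field scaling, which is what makes the intensity sensitivity
  analysis exact (below).
* A montage whose maximum is *shared* between two lobes (relative tolerance
  `1e-6`) is excluded by principle 1 — it would comparably stimulate both —
  and survivor ties are broken by the total exceedance mass of non-target
  lobes, then alphabetically.
* Principle 2's default scope (`pairScope = "winnerRow"`) fixes the dorsal
  side to the top principle-1 survivor and compares every ventral montage
  against it: settle the dorsal montage first, then pick the ventral partner
  with least overlap. This mirrors how the procedure is applied in practice;
  `"survivors"` (all survivor pairs) and `"all"` (the full matrix, e.g. all
  25 pairs of 5 dorsal and 5 ventral montages) are available when the wider
  matrix is the object of interest. If the two principles disagree outright —
  the overlap winner fails the selectivity screen — the report says so and
  returns no pair rather than silently preferring one principle.
* `p = 0` is returned (with a note) rather than an error; $r$ errors only
  when $p_1 + p_2 = 0$. Reported $p$ and $r$ keep full precision; round to
  two decimals only for table-style display.
* The node-level ANOVA (`anovaAcrossLobes()`) treats nodes as independent
  observations, as is conventional for simulator output. Node values are
  spatially autocorrelated, so these F statistics replicate that convention
  rather than constitute spatially corrected inference; the package reports
  them with that caveat rather than endorsing them.

## The synthetic head model and field generator

The analysis consumes per-node scalars; it does not need a finite-element
solver to be exercised end to end. `buildHeadModel()` and `simulateField()`
therefore generate data with the statistical structure such solvers produce,
not their physics:

* **Head model.** A quasi-uniform Fibonacci lattice over a spherical cap
  reaching 40° below the equator (so lateral-inferior temporal and
  posterior-inferior occipital territory exists), on two shells: a cortical
  shell at 0.82 of the 85 mm scalp radius and an inner shell at 0.35 carrying
  the sublobar label. A small seeded tangential jitter (1.5 mm sd)
  de-regularises the lattice. A fixed angular partition assigns hemisphere
  (left is $x \le 0$; the $x = 0$ tie-break is deterministic and
  measure-zero), lobe (medial limbic band; anterior-superior frontal;
  posterior-superior parietal; lateral-inferior temporal;
  posterior-inferior occipital; inner-shell sublobar) and, within each lobe,
  2–5 named gyri by azimuth/elevation bands. The boundaries were chosen once
  so that the cortical projections of CP5 and TP7 fall squarely in the
  supramarginal and middle-temporal bands, as they do anatomically.
* **Electrodes.** A proportional 10-10 layout on the scalp sphere (equatorial
  ring at 18° steps, interpolated parasagittal arcs). The extracephalic
  return sites have no physical counterpart on a sphere; they are fixed
  synthetic directions below the equator (right maxilla at polar angle 100°,
  nape of the neck at 165°, nearly antipodal so that its current path leaves
  the cortical cap quickly, as a neck return does).
* **Fields.** Per node,
  $v_i = \frac{I}{2}\, g(A) \left[ e^{-d_a^2 / 2\sigma(A)^2} +
  \lambda\, e^{-d_p^2 / 2\sigma_p^2} \right] + \varepsilon_i$, clipped at
  zero: a Gaussian source centred on the cortical projection of the anode
  plus a leak ridge along the anode-to-cathode great circle (sampled on the
  scalp every 2°, projected radially to the cortical shell; $d_a$, $d_p$ are
  Euclidean distances, adequate on a convex model). Electrode area $A$
  controls the size laws $g(A) = (25/A)^{0.5}$ and
  $\sigma(A) = \sigma_0 (A/25)^{0.5}$: smaller electrodes give a higher,
  tighter peak. Defaults: $\sigma_0 = 35$ mm, $\lambda = 0.35$,
  $\sigma_p = 25$ mm, $\varepsilon = 0$ (noise off), current $I = 2$ mA.
  The field is strictly linear in $I$ when noise is off, and deterministic
  given the seed.

These defaults *are* the study conditions of the synthetic experiment: under
them the ten-montage, 5 × 5 cm² run (10,000 nodes, head seed 1) selects the
(CP5→CZ, TP7→neck) pair through all three principles, the CP5_CZ row of the
overlap table attains its minimum at the TP7_Neck column, and the
supramarginal and middle/inferior temporal gyri carry top-5 CMCD clusters of
the respective winners — the qualitative structure a full solver produces.
What the generator does **not** emulate: absolute MCD magnitudes (which are
head-model specific), tissue conductivities and layers, sulcal geometry,
field directionality, or realistic inter-subject variability. Passing tests
therefore demonstrate that the *analysis* is correct and that its conclusions
are stable under the stated perturbations, not that any particular montage is
optimal on a real head.

## Sensitivity analyses

* **Intensity.** Halving the current (2 mA → 1 mA) with noise off halves
  every per-lobe mean exactly (linearity) and leaves threshold sets, $p$,
  $r$, cluster ranks and the `max_MCD` lobe unchanged (scale invariance) —
  the package asserts both. With noise on, `intensitySensitivity()` repeats
  the simulation over seeds and reports a paired t-test on per-(lobe, seed)
  means; the test's direction is the interesting output, and the test choice
  is reported alongside the raw deltas rather than hidden.
* **Displacement.** `perturbElectrode()` moves a site 10 mm geodesically
  along the local superior–inferior and anterior–posterior tangent
  directions ("1 cm up/down in the coronal plane, left/right in the axial
  plane", read as tangent-plane displacements re-projected to the scalp; at
  the vertex a fixed fallback frame is used). `displacementSensitivity()`
  simulates the 8 variants (4 directions × both electrodes) and reports
  per-lobe deltas and whether the `max_MCD` lobe ever changes. Under default
  parameters it does not; a deliberately sharp source ($\sigma_0 = 5$ mm)
  placed on a lobe boundary does flip, and the report flags it.

## Numerical and interface conventions

* Coordinates are RAS millimetres with the origin at the sphere centre
  standing in for the anterior commissure; all tables are UTF-8,
  tab-delimited, with a header row and `.` decimals. Numeric columns are
  written at `%.17g`, so write → read round-trips are bit exact and pipeline
  reruns are byte identical.
* Node identity: fields simulated on one head share node identifiers, and
  overlap is computed by identifier intersection. Mapping into atlas space
  (`mapToAtlasSpace()`) applies a 4 × 4 affine and drops nodes outside an
  axis-aligned bounding box — a stand-in for the unlabelled-node reduction a
  real atlas lookup produces (the criterion by which a Talairach daemon
  rejects nodes is not recoverable from published tables); dropped counts
  are reported.
* MCD units follow the source tables, which print "mA" where current density
  is dimensionally current/area; the synthetic fields therefore carry
  unlabelled field units, and nothing downstream depends on the unit.
* Problem sizes: tests run the full experiment at 10,000 nodes (the
  selection outcome is unchanged from 5,000 to the full 35,057-node scale,
  and across head seeds 1–4); oracle-equivalence tests use 100 random
  instances of up to 1,000 nodes.

## A worked run

```{r, eval = FALSE}
head <- buildHeadModel(10000, seed = 1)
layout <- layoutElectrodes(85)
fields <- lapply(enumerateStandardMontages(5, 5), simulateField,
                 cloud = head$cloud, layout = layout,
                 params = SimulationParams())
report <- selectMontages(fields[grep("^CP5", names(fields))],
                         fields[grep("^TP7", names(fields))],
                         head$labels)
finalPair(report)
#> [1] "CP5_CZ_5_5"   "TP7_Neck_5_5"
```

`runMontageExperiment()` wraps this (plus electrode sizes 3 × 3 and 5 × 7 and
the sensitivity analyses) and writes every artifact — node tables, fields,
per-montage lobe profiles, the overlap table, the selection report — under an
output directory, stamped with a configuration fingerprint; reruns are byte
identical. This package is a library: the exported functions and this
vignette are its interface, and `scripts/acceptance.R` in the source
repository recomputes the headline overlap-ratio statistics from the
published counts.

## Known limitations

* The spherical two-shell head has no sulci, no tissue layers and no
  conductivity model; absolute field values are meaningless and only
  order/ratio statements carry information.
* The per-node ANOVA inherits the field's spatial autocorrelation (degrees
  of freedom in the thousands); treat its p-values as descriptive.
* Gyrus "clusters" are anatomical label groups, not connected components; a
  gyrus stimulated at two disjoint patches forms one cluster.
* The 10-10 layout is proportional-ideal; real cap placements deviate by
  roughly the 1 cm the displacement sensitivity analysis probes.
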