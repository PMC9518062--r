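---
title: "Ecological security patterns from importance, sensitivity and connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological security patterns from importance, sensitivity and connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espattern)
```

# The model

An ecological security pattern (ESP) is a spatial network of **sources**
(patches that supply high-level ecosystem function), **corridors**
(least-resistance channels between sources) and **nodes** (points on
corridors that deserve targeted protection).  `espattern` implements the
full construction chain on gridded landscapes, organised around a
three-axis evaluation of per-cell ecological security:

1. **Importance of ecosystem services** — four service layers fused into a
   five-level surface:
   * water conservation $WC = NPP \cdot F_{sic} \cdot F_{pre} \cdot (1 - F_{slo})$,
   * soil conservation $SC = NPP \cdot (1 - K) \cdot (1 - F_{slo})$ with $K$
     min–max normalised,
   * carbon sequestration $CS = \frac{NPP}{0.45}(1.2 + 1.63)$ — carbon is
     taken as 45 % of dry matter, each gram of which fixes 1.63 g CO$_2$
     and releases 1.2 g O$_2$ (the source expression is typeset ambiguously;
     this reading is consistent with its own constants note, and both
     constants are arguments),
   * habitat quality $Q = H_j\left(1 - \frac{D^2}{D^2 + k^2}\right)$, the
     InVEST-style half-saturation decay of suitability $H_j$ under
     accumulated threat $D$.
2. **Eco-environmental sensitivity** — RUSLE soil erosion fused with
   certainty-factor (CF) geohazard susceptibility.
3. **Landscape connectivity** — Conefor-style patch indices (IIC, PC and
   their leave-one-out importances dIIC, dPC, PI) rasterised onto the
   habitat patches.

The three five-level surfaces combine per cell as

$$s = w_1\,n(\text{imp}) + w_2\,(1 - n(\text{sens})) + w_3\,n(\text{conn}),
\qquad n(r) = \tfrac{r-1}{K-1},$$

with equal default weights (the source study states none), sensitivity
entering with reversed polarity.  Sources are connected components of the
top two security classes above an area threshold; corridors are
minimum-cumulative-resistance (MCR) paths,
$MCR = f\min\sum D_{ij} R_i$ with $f$ the identity, over a land-use
resistance surface corrected by nightlight and elevation ratios,
$R_i = \frac{NL_i}{NL_a}R$ and $R_j = \frac{DEM_i}{DEM_a}R_i$, where the
subscript $a$ denotes the mean over the cell's land-use class.  Nodes are
typed by what a corridor crosses: resistance-surface ridge lines
(strategic), roads/rivers (breaking), valley lines (respite).

# Key formulas and their numerical treatment

**Rainfall erosivity (monthly estimator).**
$R = 0.1833\,\bigl[\frac{1}{N}\sum_i \frac{\sum_j P_{ij}^2}{\sum_j P_{ij}}\bigr]^{1.9957}$
over $N$ years of monthly rainfall $P_{ij}$ (mm).  Cells with zero annual
rainfall contribute 0 (the ratio is defined as 0), so deserts do not
produce NaN.

**Soil erodibility (EPIC).** The Williams texture/organic-carbon formula
with $\beta = 1 - W_g/100$.  The transcription in the source prints
$\exp[+0.0256\,W_g(1-W_p/100)]$; the formula it cites (and physical
plausibility of K for sandy soils) requires the minus sign, which this
package uses.  The implementation is tested against an independent literal
transcription.

**LS factor.** The source does not state its LS form.  Adopted the
McCool/Moore raster construction common in mountainous RUSLE mapping:
slope from Horn's 3×3 finite differences, slope length
$\lambda = (\text{flow accumulation} + 1)\cdot \text{cell}$ capped at
300 m, $L = (\lambda/22.13)^m$ with $m \in \{0.2, 0.3, 0.4, 0.5\}$ by
slope band, and the steep-slope $S$ ($10.8\sin\theta + 0.03$ below 5°,
$16.8\sin\theta - 0.5$ to 10°, $21.9\sin\theta - 0.96$ above).  All
constants are arguments.  Soil loss $A = R\,K\,LS\,C\,P$ is computed in
t/(hm² a) and multiplied by 100 to the t/(km² a) scale on which the
six-class intensity grading (0–500–2500–5000–8000–15000–∞) operates.

**Certainty factor.**
$CF = \frac{P_a - P_s}{P_a(1 - P_s)}$ if $P_a \ge P_s$, else
$\frac{P_a - P_s}{P_s(1 - P_a)}$.  Eq-level the probabilities must lie in
$[0,1]$; a per-km² point density does not (a 400 km² scene with 2000
points has prior 5 km⁻²).  `cf_factor()` therefore estimates $P_a$ as
points per *cell* in the bin (the same density scaled by cell area, capped
at 1), which preserves the branch structure, the sign, and the $[-1,1]$
range on any grid.  Continuous factors are binned into quantile bins
(default 8); categorical factors use their native classes.  Factor CFs
combine by unweighted sum (the source states no combination rule).

**Connectivity indices.**
$IIC = \sum_{ij} \frac{a_i a_j}{1 + l_{ij}} / A_L^2$ and
$PC = \sum_{ij} a_i a_j p^*_{ij} / A_L^2$ with self terms
($l_{ii} = 0$, $p^*_{ii} = 1$) included and disconnected pairs
contributing 0 — standard Conefor semantics.  Links join patches whose
edge-to-edge (minimum boundary-cell) distance is below a threshold;
$p_{ij} = e^{-kd}$ with $k$ calibrated from a (median distance,
probability) pair, default $p = 0.5$ at half the threshold; $p^*$ is the
maximum product over paths, computed as a shortest path on $-\log p$.
dIIC/dPC are exact leave-one-out recomputations (paths through the removed
patch disappear), $PI = (dIIC + dPC)/2$.

**Cost distance.** The 8-neighbour grid graph with step cost
$\frac{R_u + R_v}{2} \cdot \ell$, $\ell$ the step length
($\sqrt2\,$cell on diagonals) — the discretisation used by GIS
cost-distance tools.  Multi-source accumulation uses one Dijkstra run from
a zero-cost virtual source.  Corridor pairing: every primary–primary pair,
each secondary point to its nearest-by-cost neighbour of any level, then
near-duplicate routes (> 80 % shared cells) are dropped, cheapest first.

**Classification.** Graded surfaces with continuous scores (importance,
geohazard, connectivity) use Fisher–Jenks natural breaks (exact dynamic
programme on a ≤ 1500-value quantile thinning), with a quantile option.
The combined-sensitivity and security scores are weighted means of a few
normalised class ranks and take only a handful of distinct values, where
Jenks breaks collapse; these two use fixed equal intervals on $[0,1]$.
All interval gradings are left-closed right-open with a closed top class,
so printed touching bounds like "0–500 / 500–2500" are deterministic.

**Node detection.** Ridge (valley) lines are the cells with zero D8
upstream contribution on the (sign-inverted) resistance surface — the
hydrological reading of "ridge line of the resistance surface".  An
8-connected least-cost path can cross a diagonal line of river cells
without sharing a cell with it, so breaking points are found by exact
segment–segment intersection of corridor polylines with road/river
polylines; adjacent intersection cells merge into one node.

# The synthetic scene

No geodata ships with the package; `generate_scene()` produces a complete,
aligned, seeded stack that *emulates the statistical structure the
analysis assumes*: a fractal (diamond-square) DEM with ~3000 m relief;
rivers as D8 flow-accumulation exceedances (hydrologically consistent with
the DEM by construction); land use claimed by class-specific suitability
rules (construction/farmland on low, river-accessible, gentle cells;
unutilized rock/ice high and steep; forest as matrix) with exact class
targets on the non-water domain; monsoonal monthly rainfall with
orographic enhancement; NPP/NDVI fields correlated with elevation;
nightlight decaying exponentially from construction; soil texture via a
softmax of Gaussian random fields (so fractions sum to 100); and a hazard
inventory drawn per cell from
$\mathrm{logit}^{-1}(b_0 + w_s z_{slope} - w_r z_{riverdist})$ with the
intercept calibrated to an expected 2000 points and the ground-truth
coefficients stored for recovery tests.

Defaults (200×200 cells of 0.1 km, 5 years of rainfall, $w_s = 1.2$,
$w_r = 0.8$) describe a desk-scale alpine-valley scene: large enough for
patch/corridor structure, generated in seconds.  What a green test on this
scene establishes is that the *machinery* is correct (formula fixed
points, oracle agreement, parameter recovery, partition invariants); it
does not establish climate realism, land-use transition realism, or any
study-area-specific number — the published per-class areas and corridor
counts depend on unavailable rasters and are deliberately treated as
descriptive, with only their internal arithmetic reproduced.

# Choices at genuinely open points

* **Habitat threat construction ($D_{xj}$):** undefined in the source;
  the standard half-saturation construction is used — threats are
  construction (3 km reach, weight 1) and farmland (1.5 km, 0.6), linear
  decay, sensitivity 1 for natural classes and 0 for source classes, all
  in `habitat_model()`.
* **$F_{sic}$, $F_{pre}$:** derived from a land-use infiltration lookup
  and min–max normalised annual rainfall; both may be supplied directly.
* **Importance/security weights:** equal; arguments.
* **Habitat classes for patches:** forest + grassland; argument.
* **Dispersal kernel calibration and link threshold:** unreported in the
  source; exposed as arguments with the defaults above.
* **Pipeline source-area threshold:** the stand-alone
  `identify_sources()` default (10 km²) suits prefecture-scale domains;
  the pipeline passes 0.5 % of the domain area so the desk-scale scene
  retains sources.
* **Eq (6) guard:** an unlit land-use class has $NL_a = 0$ and the ratio
  is undefined; the base coefficient is kept.

# Limitations

Single-band rasters only, no CRS transformation or reprojection;
corridors are 1-cell least-cost lines (no width, no circuit-theory current
maps); lithology/fault factors enter only as user-supplied categorical
rasters; the GeoTIFF codec is a minimal uncompressed baseline
implementation intended for interchange, not a general TIFF reader.

# A worked run

```{r pipeline, eval = FALSE}
scene <- generate_scene(scene_config(seed = 1))
result <- esp_pipeline(scene)
result$tables$sources
result$tables$corridors
result$tables$nodes
write_esp_result(result, "esp_out")
```
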