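---
title: "Image-based NUE screening: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based NUE screening: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryeNUE)
options(ryeNUE.quiet = TRUE)
```

`ryeNUE` analyses automated greenhouse screens of nitrogen use efficiency
(NUE) in perennial ryegrass: multi-view RGB images of potted plants, taken
twice a week across repeated defoliation/regrowth cycles, are segmented and
reduced to silhouette features; projected area serves as a non-destructive
biomass proxy; destructive harvests at the end of each regrowth phase anchor
the biomass scale; and a linear mixed model turns pot-level traits into
genotype-level estimates. This vignette documents the scientific model
behind each stage, the conventions the implementation fixes, and the choices
made where the design was genuinely open.

## The trial

The reference design screens 76 genotypes under two nitrogen levels (0.5 and
5 mM N in half-strength nutrient solution) with four replicates — a
randomized complete block design of 608 pots in 16 greenhouse rows of 38.
Each replicate occupies a contiguous band of rows; treatments alternate
between rows within the band (irrigation lines are per-row, so a row carries
one treatment); genotypes are randomized within their treatment's rows.
`generate_design()` reproduces exactly this layout and generalizes it; when
the genotype count does not divide the row capacity, rows fill left to right
and the last row of a treatment block runs short.

Three defoliation cuts at roughly four-week intervals split the trial into
an acclimation phase (AP) and two experimental phases (EP-1, EP-2). The AP
exists because perennial grasses remobilize nitrogen stored in roots and
crown after cutting: until that reserve is consumed, growth does not reflect
the applied treatments. Phase labels use half-open intervals anchored at the
cuts — `[start, cut1)` is AP, `[cut1, cut2)` is EP-1, and so on — so a
timestamp falling exactly on a cut belongs to the phase that begins there
(the plant has just been cut back to stubble). Observations at or after the
final cut are labelled out-of-study rather than silently dropped.

## The synthetic-trial generator

No public imagery exists for trials of this kind, so the generator is a
first-class module: it produces design tables, growth trajectories,
harvest records and rendered imagery with known ground truth, which is what
makes every downstream stage testable.

**Growth law.** Within each phase, true projected area regrows logistically
from the residual area left by cutting to 5 cm stubble:

$$A(t) = \frac{K A_0}{A_0 + (K - A_0)\,e^{-rt}}$$

The logistic is chosen because its absolute growth rate is unimodal (rising
in the first week after defoliation, then declining) and its relative growth
rate decays monotonically — the temporal pattern regrowing forage grasses
show. Defaults, chosen once to match the reference trial's scale:
$A_0 = 8000$ px (stubble silhouette), $r = 0.22\,d^{-1}$, and asymptotes
$K = 80{,}000$ px at 0.5 mM vs $160{,}000$ px at 5 mM. These give
phase-level area growth rates near 2,500 and 5,000 px d⁻¹ for the two
treatments and, through the harvest coupling below, phase dry matter near
1.3 g and 2.6 g — the magnitudes a real screen of this design reports.
During the AP the treatment effect on $K$ is suppressed (all pots share the
mean asymptote): the acclimation-phase equivalence of the two N levels is a
property of the biology the generator must emulate, not something the
analysis should discover.

**Effect structure.** Genotype multipliers on $K$ are log-normal with log-SD
0.30 (between-genotype CV ≈ 30%, the spread a breeding population shows);
genotype × treatment interaction multipliers use log-SD 0.08; replicate
blocks add a ±3,000 px (SD) shift to $K$. All log-normal draws are centred
to mean 1 so they scale around, rather than inflate, the yield level.

**Observation and coupling noise.** Each imaged view area carries
multiplicative log-normal noise (log-SD 0.05 — segmentation and pose
variation). Fresh biomass is proportional to end-of-phase area gain
($9\times10^{-5}$ g px⁻¹) with log-SD 0.13 coupling noise; dry matter
applies a dry-matter fraction of 0.20 with log-SD 0.05. The coupling SD is
the one deliberately *calibrated* parameter: it was tuned once, over a small
seed grid, so the realized Pearson correlation between end-of-phase MPPA
and FM across a full trial is ≈ 0.95 — the strength of the area–biomass
relationship this class of platform achieves — and then frozen. Setting any
noise SD to zero degenerates the generator exactly (trajectories equal the
closed-form logistic; FM becomes an exact linear map of area gain), which
the test suite exploits.

**Imaging schedule.** Twice-weekly imaging is encoded as one date every
3.5 days, eight per 28-day phase, with the first date of each phase at the
cut itself (area $A_0$). The generator does not emulate: root physiology or
N uptake, evapotranspiration and watering-by-weight, within-genotype clonal
variation (a single residual SD covers it), diurnal or positional lighting
effects, or leaf-level architecture beyond what the renderer draws. Passing
tests therefore demonstrate correctness of the *analysis* under a plausible
generative model, not performance on real imagery.

**Renderer.** Tillers are tapered, drooping blades radiating from a crown,
rasterized by stamping discs along each blade's 3D centerline projected to
the requested view; the 90° side view is the 0° geometry rotated about the
vertical axis. Plant pixels are green-dominant by construction
(G ≥ R + 30 and G ≥ B + 30 on the 0–255 scale) against a neutral cabinet
and white pot, which guarantees segmentability; photorealism is explicitly
not the goal. A plant whose projection would leave the frame raises an
overflow error — silhouettes are never silently cropped, because a cropped
silhouette corrupts every feature downstream. When the pipeline renders
imagery for simulated pots, the target silhouette area is the trajectory
area divided by 25: display frames are small (192 px default), and the
fixed scale factor keeps rendered plants inside them while preserving
relative areas.

## Segmentation

Foreground is selected on the excess-green index ExG = 2G − R − B, either at
a fixed threshold or by Otsu's method on the ExG channel. Otsu always finds
*some* split, so a floor (`min_exg`, default 20 on the 0–255 ExG scale)
prevents it from shredding plant-free frames into noise; frames with nothing
above the floor return an empty-flagged mask — deliberately not an error,
so a batch records a missing observation and continues. Morphological
opening and closing with disc structuring elements are available but default
to radius 0: grass blades project at 2–3 px width at screening resolution,
and radius-1 opening erases them outright while closing bridges neighbouring
blades into false area. Isolated noise is removed instead by dropping
connected components below `min_size` (15 px); all surviving components
together form the plant, since each frame holds exactly one plant whose
blades separate in projection. A rectangular exclusion zone is available for
real imagery where pot or carrier pixels pass the colour test.

## Shape features and the corner-point convention

All seven features are pixel-unit quantities (no camera calibration is
assumed, so no mm conversion is offered). The implementation fixes one
convention exactly: hull-based features are computed over the **four corner
points of every foreground pixel's unit square**, not pixel centers. The
corner hull contains all foreground pixel area, so

$$\text{compactness} = \frac{\text{area}}{\text{convex hull area}} \in (0, 1]$$

holds for every mask, with equality exactly for "convex" pixel sets such as
filled rectangles; center-point hulls violate the upper bound on thin
shapes, making the ratio meaningless. The cost of the convention is a small
outward bias: the corner hull circumscribes the silhouette by about half a
pixel, so a digital disk of radius $r$ has compactness
$\approx (1 + 0.55/r)^{-2}$ — about 0.97 at $r = 30$ — approaching 1 only
for large shapes. Caliper length is the hull diameter by rotating calipers;
hull area and circumference are the polygon shoelace area and perimeter
(vertices from `grDevices::chull`, collinear vertices dropped so the
calipers never stall). Width and height are the axis-aligned bounding-box
extents in the camera frame, in whole pixels. The test suite verifies the
caliper, hull area and perimeter against independent brute-force oracles
(all-pairs distances, gift-wrapping hull) on dozens of random masks.

## Derived traits

MPPA is the mean of the two side-view areas. The three digital volumes are
$V = A_{s.0} + A_{s.90} + A_t$,
$V_{lemnatec} = A_{s.0} \times A_{s.90} \times A_t$, and
$V_{keygene} = A_{s.0} + A_{s.90} + 3\ln A_t$. The `V_keygene` logarithm is
read as the natural log of the cubed top area — natural because the growth
analysis defines RGR with natural logs; a base-10 alternative is selectable
(`log_base = "10"`), and the choice is immaterial to correlation-based use
of the trait.

Phase-level growth rates use the first and last imaging date within the
phase as $(t_1, t_2)$ — the trait tables carry those dates so the choice is
auditable — and per-interval rates between consecutive imaging dates are
always emitted alongside, since temporal profiles need them and it is not
obvious a priori which convention a given collaborator expects. For an
exactly exponential series the phase-level RGR recovers the generating rate
regardless of which interior dates exist, a property the tests assert to
1e-12. `AGR_dm` divides the phase-end harvest DM by the *actual* days
between consecutive cuts read from the schedule, not a fixed 28.

Supplied nitrogen uses the elemental-N molar mass (14.007 g/mol): the
treatment concentrations are N levels, not nitrate mass. The standard
schedule — seven 100 ml applications per phase — supplies 4.9 mg and 49 mg N
per pot per phase at 0.5 and 5 mM. NUE = DM/Ns is only defined for the
experimental phases; the AP consumes unmeasured residual N, so its NUE is
reported missing. Because Ns is constant within a treatment × phase group,
NUE within such a group is DM rescaled: group CVs of NUE and DM are
identical to machine precision, and a tenfold dose divides NUE exactly by
ten — both are regression tests.

## Trial statistics

The trial model fits N treatment, genotype and their interaction as fixed
effects and replicate as a random intercept, by REML (`lme4`), per phase.
Cell estimates (BLUEs) and standard errors come from the fixed-effect
design matrix and covariance; Wald χ² tests (`car::Anova`, type III with
sum-to-zero contrasts) cover the three fixed terms with numerator df
$G-1$, $T-1$, $(G-1)(T-1)$. On a balanced complete design the cell BLUEs
equal arithmetic cell means — the exact oracle the tests use at tolerance
1e-8. Degenerate inputs degrade explicitly: a single replicate falls back
to fixed-effects least squares with a logged warning (and no Wald tests,
since the cell-mean model is saturated); boundary (zero) block-variance
fits are logged but their estimates remain valid. A per-treatment variant
(genotype-only model within each N level) is available because genotype
rankings are sometimes wanted conditional on management; the joint model is
the default as it matches the trial's factorial structure. Missing
observations (empty masks, unreadable files) propagate as missing traits
and are handled pairwise-complete in correlations; nothing is imputed.

`recover_parameters()` closes the loop on synthetic trials: it correlates
estimated genotype BLUEs with the generator's true multipliers (per
treatment and averaged) and reports top-decile overlap — the quantity that
matters for selection. At the default settings (76 genotypes, 4 replicates,
calibrated noise) the treatment-averaged Spearman correlation sits near
0.95.

## Reproducibility and problem sizes

Every stochastic operation is a pure function of its arguments and a seed;
the pipeline derives per-stage seeds from one master seed and the stage
name, and writes a manifest with an MD5 checksum per artifact, so an
identical configuration and seed reproduce identical checksums. The test
suite runs full-size (608-pot) trials for the statistical checks — a trial
simulates in well under a second — and uses 176–192 px frames with 8–13
tillers for the imaging checks, where silhouettes are a few thousand pixels
and geometry oracles stay exact; image counts per test (≈ 50–100) keep the
suite fast while exercising every view.

## Known limitations

The renderer draws silhouettes, not photographs: no shadows, specular pot
highlights, soil, moss, or neighbouring-plant intrusion, which are the
failure modes of real ExG segmentation. Biomass coupling is phase-local and
linear in area gain; real canopies saturate (side-view area under-counts
dense tillering), which is why real feature–biomass correlations fall with
canopy density while synthetic ones do not. The generator exposes a single
residual SD rather than separating clonal from measurement variance. And
NUE here is agronomic (yield per N supplied): without tissue-N assays the
pipeline cannot partition uptake from utilization efficiency.
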