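---
title: "Methods: simulating and analyzing smAFM unfolding of a multidomain adhesion protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing smAFM unfolding of a multidomain adhesion protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmunfold)
```

## The system and the measurement

Contactin-4 (CNTN4) is a neuronal cell-adhesion molecule whose ectodomain is
a chain of six immunoglobulin C2-type (IgC2) domains followed by four
fibronectin type III (FnIII) domains. In single-molecule force spectroscopy
(smAFM) the molecule is tethered between a glass surface and an AFM
cantilever tip and stretched at constant piezo velocity; each domain that
unfolds releases hidden contour length, producing one tooth of a saw-tooth
force-extension curve. Two structural facts drive the expected signal:

* each IgC2 domain carries one internal disulfide bridge that clamps roughly
  half of its chain, so an IgC2 tooth releases only the unprotected part
  (around 10-18 nm of contour);
* FnIII domains have no clamp and unfold completely (around 30 nm),
  sometimes through a partially unfolded intermediate.

The pipeline in this package extracts, for every tooth, the contour-length
increment `dL` and the rupture force `Fmax`, and decomposes their population
distributions into Gaussian components whose means identify the two domain
classes. A companion elastic-network module estimates per-residue mechanical
stiffness from C-alpha coordinates.

## Worm-like chain model

Branch elasticity uses the Marko-Siggia interpolation for a worm-like chain,

$$F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4\,(1-x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right],$$

with persistence length $L_p$ (nm), contour length $L_c$ (nm) and thermal
energy $k_B T$ (4.142 pN nm at the default 300 K, from the physical
Boltzmann constant). The model is evaluated by `wlc_force()`, inverted by
bracketed bisection (`wlc_extension()`, tolerance $10^{-6}$ pN), and fitted
per branch by least squares over $L_c$ (`fit_wlc_segment()`).

$L_p$ is fixed at 0.4 nm during fitting. Unfolded polypeptide is
conventionally modelled with $L_p \approx 0.4$ nm, and fixing it makes
contour-length increments comparable across branches of the same curve,
which is what the increment histogram requires; a free-$L_p$ mode exists for
diagnostic use. The per-residue contour gain `l_aa` defaults to 0.38 nm per
amino acid (the conventional 0.36-0.40 nm band).

## Domain architecture table

`cntn4_architecture()` loads a ten-row table (6 IgC2 + 4 FnIII) giving each
domain's residue count, the residue span sheltered by the disulfide bridge,
the linker length to the next module, and a folded N-to-C span `d_fold`
(default 4.5 nm) that is subtracted when converting stretched contour to a
predicted unfolding length:

* FnIII: `n_res * l_aa - d_fold`;
* IgC2: `(n_res - n_protected) * l_aa - d_fold`, floored at zero.

`d_fold` is not measurable from the force curves themselves; 4.5 nm is the
typical folded end-to-end span of Ig/FnIII beta-sandwich domains and is what
reconciles residue counts with stretched lengths of 29-33 nm (FnIII) and
10-18 nm (IgC2). The residue partitions in the packaged table are synthetic
placeholders chosen once to be consistent with those ranges and with a
~1000-residue ectodomain (the published per-domain counts exist only as a
figure image); the table file documents this per row.

## The synthetic-data generator

`synthesize_dataset()` emulates a constant-velocity pulling experiment at
0.5 um/s with a 0.02 N/m cantilever (loading rate $k_c v = 10^4$ pN/s),
sampling 10 points per nm of piezo travel with 5 pN Gaussian force noise
(the noise magnitude and sampling rate are package choices; the instrument
parameters are the emulated experiment's). Each curve is built in three
steps.

**Event scripting** (`draw_event_sequence()`). Each engaged domain draws an
increment and a rupture force from class-conditional Gaussian mixtures whose
defaults are the measured population parameters: IgC2 increments
9.5 +/- 3.3 and 17.4 +/- 3.3 nm (equal weights), FnIII increments
30.6 +/- 3.7 nm; IgC2 forces 61.0 +/- 12.9 / 95.0 +/- 26.4 pN and FnIII
forces 79.4 +/- 21.5 / 145.0 +/- 48.6 pN (component weights within a class
are not published and default to equal). Draws are truncated at +/- 3 sd
and at the hard physical ceiling implied by the architecture (the largest
unprotected contour of the class at 0.40 nm/aa). Event order is a
force-biased random interleaving: rank = drawn rupture force + N(0, 20 pN)
jitter. This reproduces the predominantly short-before-long saw-tooth
sequences seen experimentally while still producing non-sequential
interleavings; a uniform shuffle is also physically wrong here, because a
weak (60 pN) tooth occurring late, at long contour length, relaxes by less
than any drop threshold and would be invisible to any detector.

**Tip pickup.** The tip adsorbs the molecule at random positions, so by
default each curve engages a random contiguous span of 4-10 domains
(`pickup = "span"`), reproducing the experimental spread of 4-10 clear
peaks per selected trace; `junk_fraction` curves engage 0-3 domains and
fail downstream selection. The final detachment force grows with the number
of engaged domains (N(60 + 18 n, 35) pN, floored at 30), so fully engaged
molecules detach under high stress - the basis of the strong-attachment
subset.

**Mechanics** (`synthesize_curve()`). At every piezo position $z$ the
tip-sample separation solves the quasi-static force balance
$k_c (z - x) = F_{WLC}(x; L_c)$ (vectorised bisection, 60 iterations; the
noiseless branch reproduces the WLC through cantilever compliance to better
than $10^{-3}$ pN). Ruptures occur at the scripted force
(phenomenological mode, used for population round trips) or by integrating
the Bell-Evans hazard $k(F) = k_0 e^{F \Delta x / k_B T}$ along the ramp
(kinetic mode; defaults $k_0 = 10^{-4}$ s$^{-1}$, $\Delta x = 0.4$ nm put
ruptures in the 50-150 pN decade at the nominal loading rate). On rupture
the contour grows by the scripted increment. Noise is added to the force
channel only, so separations remain strictly increasing (enforced; a
violation is a simulation error).

Three optional spectral features are scripted:

* **Two-stage FnIII intermediates** ("humps", probability `p_hump`): the
  event splits into a 13-18 nm stage rupturing at 0.5-0.8 of the full force,
  then the remainder.
* **Partial first-FnIII events** (`p_partial`): the first FnIII module
  contributes a 23.1-24.4 nm event placed after every IgC2 event, so at
  most three full FnIII teeth follow it.
* **Horseshoe plateaus** (`p_horseshoe`): the bent "horseshoe" arrangement
  of the N-terminal IgC2 modules peels open at a weak ~20 pN interdomain
  interaction, rendered as a near-constant-force shelf (slight 0.08 pN/nm
  tilt - the feature is "not completely flat") spanning 35-45 nm of
  extension. Because 20 pN is far below any domain's rupture force, the
  quasi-static threshold picture opens the horseshoe at the first crossing
  of 20 pN, before any tooth; the shelf is therefore placed at the front of
  the script (published curves showing teeth before plateaus reflect
  adsorption geometries this quasi-static model does not capture). Contour
  is released during the shelf keeping $x/L_c$ constant, which keeps the
  force on the shelf and the post-shelf branch continuous. A shelf overtaken
  by a taut chain releases instantly and is recorded as such in the truth
  table.

The default feature probabilities are 0.03 each. The calibration argument:
the published 2,804-peak increment histogram is cleanly described by the
three Gaussians above, and every two-stage or compound feature injects
increments *between* those modes; more than a few percent of such teeth
would produce a population inconsistent with the printed decomposition.
Feature-focused analyses enable them explicitly (probability 1).

**What the generator does not emulate**: thermal drift, baseline slopes,
tip-chemistry artifacts, refolding, multiple molecules in parallel, force
dependence of noise, finite camera/deflection bandwidth, and dynamic
(non-quasi-static) force rebalancing after a rupture. Passing round-trip
tests shows the inference chain is correct and unbiased *for this data
model*, not that it is robust to everything a real instrument produces.

## The inference pipeline

`preprocess()` subtracts the force baseline (median of the final 10% of
samples) and can median-smooth. `detect_ruptures()` reports local maxima of
the lightly smoothed force that exceed `min_peak_force` (30 pN) and fall by
at least `min_drop` within 2 nm of piezo travel. Two details matter:

* Lookahead windows are measured in piezo travel (reconstructed from the
  median sampling step), not separation: the separation axis compresses on
  steep branches and jumps by $\Delta F / k_c$ across a rupture.
* `min_drop` defaults to 10 pN. With 5 pN force noise the median-smoothed
  detection statistic has a standard deviation near 2.3 pN, so 10 pN is a
  >4-sigma event (no false peaks in 100 featureless noise curves in the
  test suite); a stricter 20 pN threshold measurably censors small-increment
  teeth, whose post-rupture relaxation shrinks as contour length grows, and
  that censoring is class-asymmetric (it erases the smallest IgC2
  increments preferentially and merges them into compound increments).

`extract_events()` fits a WLC branch from each preceding valley (+10 pN) to
each peak, takes `Fmax` as the model force at the peak separation (the
fitted value is far less noise-biased than the raw peak sample), and forms
increments as forward differences of successive branch contour lengths,
`dL_i = Lc_(i+1) - Lc_i`. The forward difference pairs the increment a
rupture released with the force at which that same rupture happened - the
pairing class-conditional force statistics require - and leaves the
unanchored quantity as the absolute first-branch contour (pickup geometry),
not any increment. The final detected peak is treated as tip detachment: it
contributes the last branch and the detachment force but is not an
unfolding event. Peaks whose branch contours differ by less than 1.5 nm are
duplicate detections of one rupture and are collapsed. `filter_curves()`
applies the selection rules: at least 4 peaks; the strong-attachment subset
has 7-10 peaks and detachment force >= 150 pN (the published criterion is
qualitative - "high stress at the final stage" - so the threshold is a
package choice).

## Population statistics

`fit_gaussian_mixture()` offers maximum-likelihood EM (mclust; the default)
and histogram least-squares, the traditional smAFM presentation (1 nm bins
for increments, 10 pN for forces; Levenberg-Marquardt from deterministic
quantile- and histogram-mode-based starts). The two agree on well-separated
mixtures (tested); on strongly overlapping components unweighted least
squares on binned counts is biased by about 1 nm for the IgC2 pair, which
is why EM is the default everywhere results are reported.

`population_analysis()` is the canonical chain: increments are restricted to
a 3-45 nm analysis window (real single-domain increments live well inside
it; values outside are compound segmentation artifacts), the 3-component
increment mixture is fitted with a shared component width (the published
widths, 3.3/3.3/3.7 nm, are effectively equal; with free variances the
spare component turns into a broad absorber of the few compound
increments) plus a uniform background component on 15-45 nm with a free
weight - the robust-mixture treatment of the remaining compound increments,
which are sums of two single-domain releases and therefore live between the
population modes - events are labeled by posterior responsibility (components 1-2
IgC2, component 3 FnIII; ties break toward FnIII; a hard 24 nm cut is
available as a fallback), and 2-component force mixtures are fitted per
class with free variances (the published force widths differ by factors of
2).

### Feature detectors

* `detect_long_plateau()` finds windows where the smoothed force stays in a
  +/- 10 pN band around a level in 10-40 pN over >= 30 nm of separation,
  recovering about four of five simulated shelves at a ~2-4% false-window
  rate on feature-free curves (undetected weak teeth leave flat low-force
  valleys that are genuine morphological confusables at 5 pN noise),
  with two guards: the least-squares slope must stay below 0.2 pN/nm (a true shelf rises at ~0.1 pN/nm)
  (excludes slowly rising WLC branches that drift through the band) and a
  window may not contain a detected rupture peak (excludes smoothing-
  flattened small teeth). The validity flag records whether the plateau
  precedes every FnIII-labeled event, ignoring FnIII labels on compound
  increments above 38 nm - typically the event whose measured increment
  swallowed the plateau span itself.
* `detect_intermediate_hump()` flags consecutive event pairs with a first
  increment of 11-18 nm, a summed increment of 26-36 nm, and an
  intermediate force below 0.85 of the completion force;
  `merge_hump_events()` collapses flagged pairs into single FnIII events.
  There is an inherent specificity limit: the published IgC2 component at
  17.4 +/- 3.3 nm populates the 11-18 nm window, so consecutive IgC2 pairs
  can mimic the signature; the force-ratio guard suppresses but cannot
  eliminate mimics, and the test suite pins the achievable operating point
  rather than a nominal one.
* `detect_partial_fniii()` flags events with increments in 23.1-24.4 nm
  (+/- 0.6 nm fit-noise pad) occurring after every IgC2-labeled event with
  at most three FnIII-labeled events following. Its mimics are
  undetected-rupture merges of IgC2 pairs that happen to sum into the
  window; they are rarer (a few percent of curves) than the hump mimics.

## Mechanical stiffness (ANM)

`build_anm()` assembles the standard anisotropic-network Hessian from
C-alpha coordinates (uniform springs, default cutoff 15 A - the
conventional C-alpha choice - and gamma = 1) and eigendecomposes it; a
connected three-dimensional structure must show exactly 6 numerically zero
modes (tolerance $10^{-8}$ relative to the largest eigenvalue), and a
disconnected contact graph is an error naming the components.
`effective_stiffness()` computes the pairwise effective spring constant as
the inverse of the directional compliance summed over non-zero modes,

$$k_{ij}^{\mathrm{eff}} = \left[\sum_k \lambda_k^{-1}
\big((\mathbf u_{k,j}-\mathbf u_{k,i})\cdot \hat r_{ij}\big)^2\right]^{-1},$$

verified in the tests against an independent full-Hessian pseudo-inverse
oracle to $10^{-6}$ relative. `stiffness_profile()` reduces the pair matrix
to a per-residue scalar (mean over all partners; a package convention - the
reference analysis does not state one) and reports, per domain, the
fractions of unmasked residues in three ranges (k < 12, 12 <= k < 15,
k >= 15, configurable); disulfide-protected IgC2 residues are excluded via
the mask, and a fully masked domain is flagged rather than zeroed. Note the
bin thresholds are in model units that scale with gamma and with the
averaging convention, so they are only meaningful relative to a stated
convention (recorded in the profile's `units` field). Two caveats
established during development and enforced in tests: the
"raising the cutoff never softens a pair" monotonicity holds only for
mechanism-free networks (exactly 6 zero modes) - an internal floppy mode
re-enters the compliance sum with a huge term once extra contacts barely
stiffen it - and collinear chains legitimately show more than 6 zero modes.
The published homology-model coordinates are not deposited, so the shipped
analysis (`analysis/05_mechstiff.R`) runs on a synthetic bead model with
the CNTN4 domain layout, and figure-derived per-domain bar heights are not
treated as reference values.

## Problem sizes and runtime choices

The packaged analyses use 150 curves; the acceptance script
(`scripts/acceptance.R`) uses two 500-curve runs (about 3,200 measured
increments each, matching the published >2,800-event scale) plus a
100-curve horseshoe run, and completes in well under a minute per run. Test
fixtures use 2-100-bead networks and 15-120-curve batches. These sizes were
chosen so the full population structure (including the minority components)
is identifiable while any single analysis stays interactive.

## Known limitations

* Cascaded ruptures (a scripted force below the current post-rupture force)
  fire instantly and merge increments; they are real physics of the
  quasi-static model and the main loss channel for the partial-FnIII
  detector.
* The hump detector's specificity is bounded by the IgC2/intermediate
  window overlap discussed above.
* The architecture table's residue partitions are consistent placeholders,
  not transcriptions; analyses that depend on per-domain identity beyond
  the class level should treat them accordingly.
* The event model draws forces independently of increments within a class;
  any true correlation between domain size and strength is not emulated.
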