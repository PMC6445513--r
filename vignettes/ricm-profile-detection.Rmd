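---
title: "Detecting and measuring soft-probe fringe patterns in RICM images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and measuring soft-probe fringe patterns in RICM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A soft colloidal probe (SCP) is an elastic hydrogel microsphere that acts as
an adhesion sensor: placed on a functionalized coverslip, it deforms, and
the radius of the flat contact disc encodes the adhesion energy through
Johnson–Kendall–Roberts (JKR) contact mechanics,

$$W_{adh} = \frac{r_c^3}{6\pi p^2}\cdot\frac{4E}{3(1-v^2)},$$

where $p$ is the particle radius, $r_c$ the contact radius, $E$ the Young's
modulus and $v$ the Poisson ratio of the probe. In reflection interference
contrast microscopy (RICM) the probe produces concentric interference
fringes whose radial intensity profile is fixed by physics, so both $p$ and
$r_c$ can be read off an image — if the fringe pattern can be found and
fitted automatically. `ricmatch` implements that pipeline: physics-based
radial templates, a gradient-voting search-space reduction, Pearson
template matching, an extrema-focused refinement of the particle size, and
the derived physical measurements, plus a ground-truthed synthetic scene
generator so the whole chain is testable without microscope data.

## The forward model

The height of a sphere of radius $p$ whose lowest point sits at height $d$
above the coverslip is $h(r) = \max(0,\, d + p - \sqrt{p^2 - r^2})$; for
touching or indenting probes ($d \le 0$) the clamp crops the sphere and
produces a flat contact disc of radius $r_c = \sqrt{2p|d| - d^2}$. The
normalized fringe intensity at lateral distance $r$ is

$$p_{\mathrm{tpl}}(r) = \mathrm{sinc}(y)\,
  \cos\!\big(2kh(r)(1-\sin^2(\alpha/2)) + \theta\big),
  \qquad y = 2kh(r)\sin^2(\alpha/2),$$

with $k = 2\pi n/\lambda$ the wavenumber in the medium and
$\alpha = \arcsin(\mathrm{INA}/n)$ the illumination aperture half-angle.
The sinc term is the contrast envelope of a finite illumination aperture.
An empirical factor $e^{-dec\,(r/r_{max})^2}$ attenuates outer fringes,
absorbing what the planar-interface theory misses at large radii. The
exponent is normalized by $r_{max}$ so the decay parameter's working range
$[0, 10]$ spans identity to $e^{-10}$ at the template edge; an
un-normalized $r^2$ exponent would annihilate every fringe and leave the
parameter useless.

Templates are sampled at integer pixel radii $1 \dots r_{max}$ (the center
pixel is skipped — every sampling ray shares it, so it carries no radial
information) and pre-computed over a grid of $(d, p, dec)$; the default
grid (heights $-0.45$ to $0\ \mu m$ in $0.01\ \mu m$ steps, radii $10$ to
$30\ \mu m$ in $1\ \mu m$ steps, decay $0$ to $10$) yields
$46 \times 21 \times 11 = 10\,626$ templates.

```{r, eval = FALSE}
library(ricmatch)
opt  <- optical_config()   # u = 0.067 um/px, lambda = 0.53 um, INA = 0.67,
                           # n = 1.332, theta = pi, r_max = 100 px
bank <- build_bank(parameter_grid(), opt)
bank
```

Because of the cosine's periodicity only the height *relative* to the
fringe phase is observable: heights separated by
$\lambda/(2n)(1 - \sin^2(\alpha/2)) \approx 0.185\ \mu m$ produce identical
fringe frequencies. Detections report the template offset (the $i = 0$
branch) together with that ambiguity period; for adhering probes — the
intended use — the $i = 0$ branch is the physical one, since a contact
disc removes the ambiguity.

## Pipeline stages and their parameters

**Pre-selection.** Template matching every pixel is wasteful; circular
patterns betray their centers through gradient geometry. For every pixel
whose Sobel gradient magnitude exceeds a floor (default 5% of the image
maximum — a literal non-zero test would pass every noise pixel), a line is
drawn along the gradient orientation, $r_{max}$ pixels in *both*
directions, into an accumulator. Both directions matter because successive
fringe edges alternate between inward- and outward-pointing gradients.
Votes are unweighted so bright outer rings do not dominate faint inner
ones. Ring gradients are radial, so lines pile up at pattern centers; the
brightest $c = 1\%$ of accumulator pixels (ties at the threshold all
included) become match candidates, cutting the search space a
hundredfold.

**Matching.** At each candidate the image is sampled along $m = 90$ rays
at pixel radii $1 \dots r_{max}$ (bilinear interpolation; nearest-neighbor
visibly distorts the tightly spaced inner fringes). Ray $i$ points along
$(\sin, \cos)$ of $2\pi i/m$. The azimuthal mean profile $p_{mean}$ is
Pearson-correlated against every template; the best correlation and
template index land in a map. Two gates precede correlation: the profile
amplitude must reach $a = 5\%$ of the observed image range (correlation is
amplitude-blind, so flat noise would otherwise match), and the mean
correlation of individual rays with $p_{mean}$ must reach $t_2 = 0.5$ (a
radial-symmetry test that rejects edges and half-patterns). Positions with
less than half their sampling disc inside the image are rejected rather
than zero-padded — padding would fabricate the very symmetry the gate
tests. A constant profile is assigned correlation 0 ("no similarity") so
flat regions cannot match flat-contact templates. Per-position results are
independent, so any parallel execution order gives identical output.

**Extraction.** The map's global maximum is accepted if it reaches
$t_1 = 0.9$; a disc of radius $r_{max}$ around it is cleared and the
search repeats, up to `max_iterations` (default 100, configurable — the
stopping rule usually triggers first). No two detections can therefore lie
within $r_{max}$ pixels. Detections are ranked by first-pass correlation;
on cluttered images false positives occur but rank below true particles,
so downstream review can filter by rank and score.

**Refinement.** Pearson correlation weights bright fringes heavily, but
particle size lives in the *positions* of the extrema. Each detection is
re-fit by maximizing the slope-synchronism score: the fraction of radial
positions where profile and template rise or fall together. Differences
are compared by sign; the count is normalized by $r_{max}$ (the
convention of the score's origin, kept although only $r_{max}-1$
differences exist, so a perfect match scores $(r_{max}-1)/r_{max}$, not
1.0 — thresholds on this score should account for that). A flat stretch
only matches a flat stretch: the contact core's width is thereby
informative. Under noise a measured flat core never has *exactly* zero
differences, so the refinement compares slopes at the noise resolution of
the averaged profile: the spread of the $m$ directional samples at each
radius yields a standard error for every mean-profile value, and
differences below twice their propagated standard error count as flat, on
the profile and (amplitude-rescaled) on the template alike. Without this,
a noisy contact core reads as random rises and falls and the refinement
systematically prefers oscillating, non-contact templates; with an
amplitude-proportional tolerance instead, decayed outer fringes get
erased and size errors grow for strong decay. Noise-free profiles reduce
to the exact sign comparison. Ties are broken by
first-pass correlation, then lowest index. The refined template replaces
the first-pass one for all derived quantities. The refinement searches the
full bank — at one position per detection the cost is negligible.

## The synthetic scene generator

`render_scene()` evaluates the same forward model around each particle
center (sub-pixel positions allowed), maps model values to intensities as
`background + contrast * value` (defaults 0.5 and 0.25 — the model does
not dictate camera counts; these give visibly dark contact cores on a
mid-gray field), then applies a radially symmetric multiplicative vignette
$1 - s(\rho/\rho_{max})^2$, adds i.i.d. Gaussian pixel noise, and clips to
$[0, 1]$. The fringe pattern is rendered to one pixel past $r_{max}$ so
that bilinear sampling at radius $r_{max}$ never mixes modeled pixels with
background. Scenes are deterministic given their seed and leave the
caller's RNG untouched.

What the generator deliberately does *not* emulate: neck deformation and
meniscus artifacts at the contact border (outside the forward model by
design), shot-noise statistics, non-planar reflection corrections, and
dual-wavelength imaging. Passing the closed-loop tests therefore shows the
pipeline inverts its own forward model under noise, vignetting and
clutter — it does not certify behavior on aberrated experimental optics.

## Validation cohorts and the numbers they produce

The package's benchmark functions rebuild the validation end-to-end:

* `localization_benchmark()` — 50 single-particle $512^2$ scenes,
  parameters uniform over the search grid, sub-pixel centers, noise
  $\sigma = 0.02$ of the dynamic range. It reports the center error of the
  top-ranked detection (mean well under 1 px; detection on the integer
  grid alone contributes ~0.4 px), the refined and first-pass size errors,
  and the best bank correlation at each true center (10th percentile above
  0.99).
* `contact_benchmark()` — 100 adhering particles on $256^2$ scenes. For
  each detection the model contact radius (from the refined template) is
  regressed on the intensity-based reference: 1D region growing outward
  along $p_{mean}$, stopping when intensity rises 30% of the profile
  amplitude over the center reference $I_0$. $I_0$ averages the first 3
  radial samples because azimuthal averaging barely denoises small radii
  (at radius 0 every ray samples one pixel). The regression shows a slope
  near 1, a small negative intercept — region growing stops late, on the
  first fringe's rise, so it overestimates — and adjusted $R^2 > 0.98$.

These cohort sizes keep a full validation run in the minutes range on a
single core while leaving the per-scene statistics stable; both functions
scale to larger cohorts unchanged.

The contact cohort is rendered decay-free, and that choice is forced, not
cosmetic: the intensity reference assumes a *flat* dark core, but the
decay factor tilts the core upward, and for wide contact discs (up to
$77$ px within a $100$ px profile under the default grid) the tilt alone
crosses a 30% threshold before the disc edge. Measured over 120 grid
draws, decay 2 stops early on 23, decay 1 on 1, decay 0 on none — only a
decay-free cohort satisfies "region growing never stops inside the true
contact disc for every particle", which is the premise of using it as a
reference. With decay present, the intensity-based reference is only
trustworthy for compact cores; that interaction, not noise, is its main
failure mode. Physically, the decay is a property of the optical setup —
constant within a batch — not of an individual particle, so a single
batch-wide value is the realistic rendering choice in any case.

## Numerical choices and degenerate inputs

* Template parameters must satisfy $p \ge r_{max}\,u$ (the sphere covers
  the sampled extent); sampling beyond the sphere raises an error instead
  of extrapolating.
* All template math is in micrometres; `adhesion_energy()` converts to SI
  at the boundary and returns J/m².
* Correlation ties take the lowest bank index — deterministic across runs
  and backends.
* The amplitude gate uses the *observed* image range, not the nominal bit
  depth, so under-exposed frames are judged on their own contrast, while
  image loading normalizes by bit depth so intensities remain comparable
  across a batch.
* Region growing on a constant profile (undefined amplitude) and
  regressions on a degenerate predictor raise errors rather than returning
  numbers.
* `0.5`-boundary rasterization in the line image rounds half-to-even in
  both the compiled and the reference path, keeping them bit-identical.

## Known limitations

* Center positions are integer pixels; no sub-pixel refinement is
  attempted (the size refinement absorbs most of the residual error).
* At noise well above the validation level ($\sigma \gtrsim 0.04$) the
  vote peak of strongly decayed adhering particles broadens and the
  pre-selection can place its nearest candidate 3–4 px off center.
* Absolute height is not resolved (single wavelength); only the $i = 0$
  relative height is reported, with the ambiguity period attached.
* The perfectly-spherical-cap assumption leaves a sharp contact-border
  transition; real probes show neck/meniscus artifacts there, which the
  matcher tolerates but does not model.
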