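---
title: "Measuring hematocrit from capillary-tube images: model, simulator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hematocrit from capillary-tube images: model, simulator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microhct)
```

## The measurement

After centrifugation, a microhaematocrit capillary tube separates into a
sealant plug, a packed red-cell column, a thin buffy coat, and plasma.
Hematocrit (Hct) is the packed-cell column as a fraction of the whole sample
column. An image-based reading places three horizontal markers on a
photograph of the vertical tube: *lower* at the plug/red-cell interface,
*buffy* at the red-cell/plasma interface (at the maximum excursion of any
meniscus), and *upper* at the top of the plasma. The measurement is then a
pure pixel ratio,

$$\mathrm{Hct} = 100 \cdot
  \frac{\text{lower} - \text{buffy}}{\text{lower} - \text{upper}}
  \;\text{percent},$$

which is invariant to zoom and translation of the image — the property that
lets a user magnify freely before placing markers. `compute_hct()` reports
the value rounded half-up to 0.1 percentage points and retains the raw value;
0.1 is the order of the smallest on-screen increment (below), and half-up is
what a person reading a scale reports for a value sitting exactly on an
increment.

The smallest increment the screen can register is one pixel out of the
sample-column span. For a viewport of $V$ logical pixels of which the column
occupies fraction $f$ after pinch-to-zoom framing, `hct_resolution()` returns
$100/(fV)$ percent per pixel: 0.23 on a 586-px viewport at 75% occupancy,
0.14 (printed 0.1) on a 932-px viewport. Note the 0.1 figure is the formula
value at 75% occupancy rounded to one decimal; it is also close to $100/932$,
so the two derivations are not distinguishable at the printed precision. A
mechanical microhaematocrit reader, by comparison, has 1% divisions and a
credible reading precision of about 0.5%.

## Capture geometry and parallax

The camera is modelled as a distortion-free pinhole above the bench plane.
Pose angles follow the on-screen convention for a tube photographed from
above: **pitch** rotates about the horizontal axis perpendicular to the tube
(positive tilting the camera top away from the tube, towards its plasma
end), **yaw** about the tube's long axis, **roll** about the optical axis.
The capture gate (`capture_gate()`) is strict: both $|\text{pitch}| < 5°$
and $|\text{yaw}| < 5°$, ties failing; roll and setback do not enter the
gate.

Off-nadir, perspective foreshortens the far end of the sample column and
biases the pixel ratio. With the sample centred in frame, camera height $h$,
pitch $\theta$, and the projective map along the tube, the apparent value is

$$\mathrm{Hct}_\text{app} = \mathrm{Hct}_\text{true} \cdot
  \frac{D + y_u \sin\theta}{D + y_b \sin\theta},$$

where $D$ is the distance from the camera to the tube along the optical
axis and $y_u, y_b$ are the plasma-top and buffy positions along the tube
relative to the optical-axis intersection. To first order the bias is
$\approx 100\,H(1-H)\,\sin\theta\,L/D$ percentage points for fill length
$L$: it grows linearly with the physical length of the sample column and
with $\sin$ of the pitch. `apparent_hct()` computes the exact value by
projecting the three physical interface points; it is invariant to focal
length (ratios of collinear projections) and recovers the true value exactly
at nadir. The sign-mirror property $\text{bias}(+\theta) =
-\text{bias}(-\theta)$ holds to first order only — the projective map is not
odd in $\theta$ — which is why the corresponding test allows a 0.05-point
second-order remainder.

Two geometric readings were open:

* **Pitched captures stay on target.** At a fixed 19.5 cm height, a 10–20°
  pitch with zero horizontal offset swings the view several hundred pixels
  off the sample; the capture of a framed sample implies the camera is also
  displaced. The default experiment conditions therefore pair pitch
  $\theta$ with a setback of $h\tan\theta$ — exactly the relation the
  standing-back condition (33° pitch, 10 cm setback) makes explicit. That
  triple is geometrically over-determined ($\arctan(10/19.5) \approx 27°$,
  not 33°); the simulator treats pitch, setback and height as independent
  inputs and reproduces the stated conditions verbatim rather than forcing
  consistency.
* **Angle origin.** Whether pitch is measured from the vertical or from the
  device's resting plane is a convention; the package measures from
  vertical (nadir = 0) and lets the caller supply any angles.

## The synthetic renderer

`render_tube()` draws the tube as a flat four-zone object in the bench
plane and inverse-maps every output pixel through the camera model, so zone
boundaries in the raster coincide with the projected physical interfaces to
sub-pixel accuracy with no resampling artifacts. Ground-truth marker rows
are recorded at sub-pixel precision by projecting the interface points
directly.

Default physical parameters (the study conditions; the tube supplier's
dimensions are not public, so these are declared, not inferred):

| parameter | default | rationale |
|---|---|---|
| tube length × bore | 75 × 1.1 mm | standard microhaematocrit tube |
| plug length | 10 mm | typical sealant plug |
| fill length | 25 mm | a typical finger-prick column; fixes the parallax-bias scale (≈0.5 / 1.0 / 1.5 pp at 10° / 20° / 33°+10 cm by the formula above) |
| buffy coat | 0.5 mm | sub-millimetre band |
| meniscus depth | 0.3 mm | concave, order of the bore radius |
| raster | 1136 × 192 px | small-phone screen height; default focal length puts the 75 mm tube at ~75% of the raster height |
| noise | i.i.d. Gaussian per channel, clipped | simplest model adequate for detection testing; lighting gradients are real-world features the simulator does not emulate |

The plasma-top meniscus is rendered as a parabola whose extremum sits on
the tube axis; the truth marker records the extremum row (the row a careful
operator targets). The buffy truth marker is the top of the packed red-cell
column, so packed cells over fill equals the nominal hematocrit exactly.
The framing precondition requires the measured column (plug top to plasma
top, plus a 2 mm margin) inside the field of view; the empty glass end of
the tube may crop, as it does in real phone frames.

What the synthetic fixtures do **not** emulate: uneven illumination,
haemolysis and agglutination artifacts, glass refraction and specular
highlights, camera distortion, focus blur. Tests passing on fixtures
demonstrate the measurement pipeline's correctness and its parallax
behaviour, not robustness to uncontrolled real-world photography.

## Automatic interface detection

`detect_markers()` replaces the human operator on fixtures so the pipeline
can be tested end to end. The image is box-smoothed (3×3) before palette
distances are computed; the largest non-background connected component
gives the tube, its principal axis the in-plane tilt. Each row is sampled
in a narrow band around the axis (half of the half-width, which reads the
meniscus at its extremum) and assigned the nearest palette colour within a
threshold of half the minimum pairwise palette separation; ambiguous rows
count against a confidence score. Markers sit at the midpoint between the
last row of one zone and the first row of the next — both "last of A" and
"first of B" are defensible, and the midpoint makes the quantisation error
symmetric. Nearest-centroid classification over a known palette was chosen
over edge detection because fixtures have exact palettes; real photographs
are supported only best-effort, with a user-supplied palette.

## The in-silico validity experiment

`run_validity_simulation()` renders a cohort (default 20 samples, true Hct
uniform on 38–48%) under the four capture conditions, measures each image
with the detector, and compares conditions with the same statistics used
for a live method-comparison: repeated-measures ANOVA with partial
$\eta^2$, Bonferroni paired *t* tests against nadir, and Bland–Altman
agreement against nadir. The mechanical-reader reference is simulated as
the true value plus zero-mean reading noise (SD 0.25, half a credible
division), quantised to the nearest 0.5.

Sample columns vary from draw to draw, so the simulation draws each tube's
fill length from a normal with SD 1.5 mm. Besides realism this matters
numerically: with identical tubes the lower/upper markers quantise to the
same pixel rows in every sample and the (deterministic) quantisation offset
of a noise-free render would not average out of a condition's mean
difference.

With the defaults, the 10° and 20° conditions stay inside the 1.2-point
good-agreement bound against nadir while the 33°/10 cm condition exceeds
it — the same good/poor split the angle experiment is designed to show. The
1.2% bound itself is an equivalence argument: 1.2% of a typical hematocrit
of 45 is ≈0.5 points, the smallest difference the mechanical reader can
credibly resolve.

Problem sizes throughout (20-tube cohorts, 10-seed noise sweeps, 200
reliability replicates) are chosen as the smallest that make the checked
contrasts unambiguous.

## Agreement and reliability statistics

All statistics operate on a long `trial_table()` (sample × rater × method ×
trial).

* **Bland–Altman** (`bland_altman()`): mean difference and
  $\text{mean} \pm 1.96\,\mathrm{SD}$ limits of agreement, sample (n−1) SD
  throughout. "Mean ± 1.96 of the difference" is read as mean ± 1.96 × SD
  of the differences, the standard construction. The good-agreement flag
  applies the 1.2-point rule to the absolute mean difference. With
  triplicate data the default is to compare per-sample trial means; raw
  trials can be passed directly.
* **ICC** (`icc()`): the form is a genuine choice; the default is the
  two-way absolute-agreement single-measure ICC(A,1) from variance
  components, because absolute agreement is the notion consistent with
  reading ICC alongside Bland–Altman (a systematic rater shift should count
  against reliability). Consistency ICC(C,1) and one-way ICC(1,1) are
  available behind `type=`. Confidence intervals use the standard F-based
  constructions. Zero total variance returns a flagged undefined ICC rather
  than a number.
* **Typical error**: SD of between-measurement differences divided by
  $\sqrt 2$ (the sports-science convention the term comes from), averaged
  over measurement pairs when there are more than two.
* **RM-ANOVA** (`rm_anova()`): subject-blocked one-way ANOVA;
  $\eta_p^2 = SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$, banded
  at 0.02 / 0.13 / 0.26. Sphericity is uncorrected by default (matching
  common reporting practice for such designs); Greenhouse–Geisser is
  available behind a flag. Sums of squares below $10^{-10}$ of the total
  are snapped to zero so that exactly constant contrasts report a zero
  effect instead of floating-point dust.
* **Paired t + Bonferroni** (`paired_t_bonferroni()`): two-sided paired
  *t* per pair, $p_\text{adj} = \min(1, m\,p)$, Cohen's *d* attached.
* **Cohen's d** (`cohens_d()`): mean difference over pooled SD, banded at
  0.2 / 0.5 / 0.8 on $|d|$.

### A worked run

```{r, eval = FALSE}
sim <- run_validity_simulation(n_samples = 20, seed = 1)
print(sim)
tidy(sim)
autoplot(sim)
```

## Known limitations

* Detection assumes one tube against a separable background with a known
  palette; it is not a general segmenter.
* The parallax model treats the tube as flat in the bench plane; bore-scale
  3-D effects (refraction through the glass wall, the cylindrical lens
  effect) are ignored.
* The rendered meniscus is geometric only; a real meniscus also changes
  local shading.
* The simulated reader error model (noise then 0.5-quantisation) is an
  assumption; no published error model exists for mechanical readers.
* Reported-value rounding is half-up at 0.1; callers needing bias-free
  aggregation should average `hct_raw`.
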