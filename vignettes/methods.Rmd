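---
title: "Models and methods behind pulseid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pulseid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pulseid implements a complete workflow for studying pulse-type weakly
electric fish (mormyrids such as *Gnathonemus petersii*) in a laboratory
tank: evaluating electrode layouts with a dipole field model, detecting and
normalizing electric organ discharges (EODs) on seven electrode channels,
attributing each EOD to an individual by regressing fish position from the
multichannel waveform, reconstructing closed 3D body surfaces from tracked
midline skeletons, computing active and passive electric images (EIs) with
a boundary element method (BEM), and summarising dyadic agonistic
encounters. This vignette explains the models, the tunable parameters, and
the numerical and design choices.

## The dipole fish mimic

A swimming fish is idealised as a current dipole: point poles of opposite
sign at the head and the tail, separated by the body length $L$. The
potential at a point is

$$V = kq\left(\frac{1}{R_1} - \frac{1}{R_2}\right),$$

with $R_1, R_2$ the distances to the head and tail pole. Only relative
channel differences matter for layout ranking, so the charge is set to the
reciprocal of the proportionality constant (`kq = 1`); with distances in cm
this bounds wall-electrode potentials comfortably inside ±1 V. Differential
channels are pairwise electrode differences; single-ended channels are
referenced to a ground electrode at the tank centre.

The tank is 66 × 72 cm; simulated fish keep both poles at least 10 cm from
every wall (the stricter whole-fish reading of the margin), with uniform
position and heading and lengths drawn from 20 evenly spaced values between
8 and 15 cm. Heading enters the regression targets as $(\sin\theta,
\cos\theta)$ to avoid angular wrap-around. The model is two-dimensional:
electrodes and fish share one horizontal plane, and wall boundary effects
are deliberately ignored.

### Electrode layouts

The six built-in layouts are the package's own reading of the published
arrangement drawings; only their qualitative descriptions are fixed
(layout 2 rotates the differential axis from pair to pair and has no
central reference; layout 3 is single-ended against a centre ground; 1 and
4 are the well-performing wall layouts; 6 is a perpendicular net plus
corner diagonals). Layout 1 — four inward-pointing short-baseline pairs
near the corners, two mid-wall pairs and one corner-to-corner diagonal —
was chosen because short-baseline pairs act as local field-gradient
sensors (good position resolution everywhere along the walls) while the
long diagonal retains far-field amplitude information that carries the
fish-length signal. Layout 2's long diametric baselines resolve the tank
centre but degrade badly toward the walls, which is why it ranks last.

### The localizer

The regressor is a random forest with 25 trees per target. No installed R
forest supports joint multi-output regression, so one forest per target is
fitted from a shared seed stream; the interface and results are those of a
single multi-output model. Hyperparameters (`mtry`, minimum node size,
depth cap, and the split rule — classical variance splitting or extremely
randomized splits) are chosen by a randomized search over a declared grid
with 25 candidates, scored by 3-fold cross-validation *on the training
split only*. The tuning objective is the cross-validated median spatial
error of the position targets, because localization is the quantity the
downstream workflow consumes and the statistic used to rank layouts. The
held-out score is the uniform average of the per-target
$R^2 = 1 - u/v$ values ($u$ the residual, $v$ the total sum of squares),
the multi-output convention of the reference scorer.

A single-hidden-layer perceptron baseline (widths 50/100/200, identity
output activation, iteration cap 10,000) is included for comparison only;
depth is deliberately not varied — capacity scales through the width of
the one hidden layer.

## EOD detection and the waveform vector

Detection applies a per-channel threshold to the *absolute* voltage
(polarity depends on the fish's orientation relative to a pair, so signed
thresholds would miss half the discharges). Each crossing is refined to the
local peak of the summed absolute channel signal, and peaks within a 400 µs
refractory window collapse onto the earliest — this both merges the several
crossings of one biphasic discharge and removes the later pulse of two
near-simultaneous fish, which the doublet screen recovers.

Alignment uses the mean of the absolute values across all channels; windows
span 272 µs before to 128 µs after the peak. At the 125 kHz sampling rate
these are exactly 34 and 16 samples, giving 51-sample windows and
357-element vectors for 7 channels. The concatenated window is divided by
its global absolute maximum, so every vector spans exactly ±1 — the
scale-invariance that makes assignment robust to fish size and distance.

The doublet screen compares each event's normalized mean-absolute trace to
the average trace over all detections, by default with an L1 residual (the
plain "absolute deviation"; L2 is available). Events above the
`1 - flag_fraction` residual quantile (default top 1%) are queued for
review. Two caveats are faithful to practice: events with low potentials on
all electrodes are noise-dominated and inflate the residual tail (the
dedicated overlap fixture therefore uses a high signal-to-noise scenario),
and an overlapping pulse is only conspicuous when it falls *inside* the
extraction window, so the planted fixtures offset the second discharge by
100 µs.

## Pose import and synchronisation

Tracking data are six-node midline skeletons (Schnauzenorgan, two head,
two mid, tail nodes) for up to two animals. The anchor is the second head
node, the midpoint between the pectoral fins. Because no R HDF5 reader is
available in the package's dependency set, the documented exchange format
is a long CSV; a bundled Python converter translates the tracker's HDF5
analysis export. Pixel-to-cm calibration comes from the known tank width.

Video frames are synchronised by a TTL pulse per exposure recorded next to
the electrode channels; rising edges give every frame's time on the
recording clock and a count mismatch is an error, never silently patched.
EOD rates can exceed 100 Hz against 10–30 Hz video, so poses at EOD times
are linearly interpolated between the flanking frames per node, falling
back to the nearest visible flank when a node is undetected on one side.
Identity swaps are assumed proofread upstream; a >15 cm/frame anchor jump
only warns.

## Identity assignment

A 100-tree-per-output forest maps the 357-element waveform vector to the
12 skeleton coordinates. Training uses single-fish segments only, where
identity is unambiguous. At assignment time the predicted skeleton is
compared to both tracked skeletons; the error aggregate is the sum over
the six node-to-node Euclidean distances (an RMS aggregate is available —
the two orderings differ only in edge cases for a fixed node count), with
invisible nodes excluded from both candidates symmetrically. The fish with
the smaller aggregate gets the EOD; exact ties break deterministically to
the lexicographically first id and raise the review flag.

Errors concentrate where the two fish are close and where the difference
between the two candidate errors is small. The review queue exposes the
`fraction` (5% or 10%) of assignments with the smallest error difference;
correcting only this queue captures a disproportionate share of all
errors. Confirmed doublets are credited to both fish's discharge trains
after automatic assignment.

## From skeleton to closed surface

A third-order polynomial is fitted to the visible skeleton nodes in a
fish-aligned frame (x-axis head→tail); 49 elliptical cross-sections of 17
nodes each are placed along the curve at uniform arc length (the spacing
rule is not prescribed anywhere; uniform arc length is the package's
choice), each ring re-oriented perpendicular to the local tangent.
Adjacent rings are stitched with triangle strips and the snout and tail
close with apex fans: 49 × 17 + 2 = 835 vertices and 1,666 triangles,
satisfying F = 2V − 4, E = 3F/2 = 2,499 and the Euler characteristic 2.
The construction generalises to any ring/node counts with the same
identities. Body semi-widths and semi-heights per ring come from a profile table;
the default is a smooth mormyrid-like taper (deepest behind the head,
narrow caudal peduncle) expressed as fractions of body length — it is a
plausible synthetic profile, not a measured one, and can be replaced. The
skeleton is 2D; the third dimension comes entirely from the profile, and
the mesh is vertically centred at half the water depth.

## The boundary element model

All media are ohmic ($J = \sigma E$), charge does not accumulate
(electrostatic approximation), and space is divided into homogeneous
volumes: fish bodies in an infinite water medium, each wrapped in a thin
resistive skin with the jump condition $\varphi_{in} - \varphi_{out} =
\rho_{skin} J_n$. The discharging fish carries an internal pole pair
(+I/−I, balanced to satisfy charge conservation) in the caudal peduncle,
where the mormyrid electric organ sits; the pole count and placement are
explicit assumptions, configurable, with M > 2 supported by the same
assembly.

Discretisation: collocation at triangle centroids with piecewise-constant
single-layer densities, one interior and one exterior density per panel
(2N unknowns). Centroid collocation keeps the single-layer jump factor at
exactly ½ and the flat-panel self-term of the normal-derivative kernel at
zero, avoiding solid-angle corrections at mesh vertices; nodal values are
obtained afterwards — current density by area-weighted interpolation from
incident panels ("linearly interpolated for the triangles"), potential by
direct evaluation of the layers at the nodes with an analytic vertex
integral. Numerical safeguards: analytic self-term integration, 16-point
subdivided quadrature for neighbouring panels, 64-point panel-averaged
evaluation of the pole fields (the poles sit just under the skin of the
thin tail), and enforcement of the discrete solid-angle column identity,
which makes the charge-conservation checks hold to better than 0.1% of the
pole current.

Validation: an insulating sphere in a uniform field reproduces the
classical 3/2 tangential-field enhancement within 2% at the default
49 × 17 resolution, refining from 25 to 49 rings changes it by under 1%,
and a zero-contrast body (conductivity equal to water, zero skin) perturbs
the field by under 5%. The zero-contrast configuration is the solver's
worst case — with no skin the jump equation degenerates toward a
first-kind integral equation — and its residual few-percent error is a
documented limitation; fish-like parameter regimes (resistive skin or
near-insulating bodies) are the accurate ones.

Units: the solver works in cm, S/cm and µA, so surface potentials emerge
in µV and current densities in µA/cm²; skin resistivity in Ω·cm² enters
without conversion.

### Material parameters and the head funnel

Water conductivity defaults to the measured 120 µS/cm. Skin resistivity
defaults to a uniform 3 kΩ·cm². Body conductivity defaults to 2 S/m, an
effective axial value chosen so the model reproduces the documented
physics of the mormyrid body: the tapering tail raises the internal
resistance locally while the bulky anterior body conducts well, so
discharge current is funneled forward and the basal image peaks on the
head region. With substantially lower body conductivity the slender body's
internal resistance dominates the skin and the image maximum moves to the
tail poles instead. All three parameters are prominent arguments of
`conductivity_scene()`, and results should be read relative to them.

### Images and first detection

The basal image is the lone discharging fish's own transcutaneous current
density; the active image is the nodewise difference between the
two-fish scene and the basal solve at the emitter's skin; the passive
image is the full-scene stimulus at the non-discharging fish's skin. The
scalar "EI amplitude" for the detection analysis is the maximum over
nodes of the absolute current density (RMS summaries are also computed
and plotted). One fish is predicted to have detected the other first at
the earliest instant where its amplitude exceeds the other's by a factor
of two while also exceeding the 0.1 µA model noise floor; the two series
are merged on the union of EOD times with the other fish's value carried
forward from its most recent discharge. The default pole current of 1 mA
puts near-contact images well above the floor and tank-scale separations
below it.

## Dyadic encounter statistics

Attacks and chases come from manual annotation files; the package never
infers them from video. Dominance is a strict attack-count majority (ties
and zero-attack encounters are undetermined, not errors). The size classes
split at a 20% relative length difference, with the boundary assigned to
"small" (the large class is strictly greater). All printed dominance and
initiation statistics use the one-sided exact binomial test; one-sided is
the reading consistent with every printed p-value (5/5 → 0.03125, 9/13 →
0.1334, 4/8 → 0.6367, reported to three figures as 0.031/0.133/0.636 —
full precision is reported here), and a two-sided variant is a flag away.

## The synthetic-data generator

The generator emulates the acquisition rig end to end: smooth heading
random walks at 5 cm/s reflected at the 10 cm wall margin (66 × 72 cm
tank), 6-node skeletons laid along the heading, gamma renewal discharge
trains (shape 3, mean inter-pulse interval 40 ms — pulse-fish rates span
a few to over 100 Hz), biphasic difference-of-Gaussians templates with a
mildly (+10%) wider second phase in one fish to mimic small individual
waveform differences, channel amplitudes from the dipole model at the
interpolated pose, Gaussian sensor noise calibrated so the median event
peak is 10 noise standard deviations (the default SNR condition), and TTL
pulses at the frame times. Ground-truth tables (times, identities, poses,
overlaps) always accompany the data, and everything is bit-reproducible
from the seed.

The default dyadic scenario lasts 20 s at 30 Hz video, yielding about
1,000 EODs from two 12 cm fish — the closed-loop condition under which
detection → training → assignment reproduces ground-truth identities at
≥ 90%. What the generator does not emulate: behavioural structure (no
attacks, chases or echo responses), water inhomogeneity, wall boundary
effects on the field, tracking errors or identity swaps, and EOD waveform
dependence on orientation beyond the dipole projection. Passing the
closed-loop tests therefore demonstrates the pipeline's mechanics and its
noise robustness, not performance on real recordings.

## Problem sizes used in the test-suite

The shipped tests run the full simulation study (2,500 placements) and the
full default closed loop (~1,000 dyadic EODs), but validate the BEM on
reduced meshes (9–25 rings, 8–17 nodes per ring) except for the sphere
oracle, which runs at the default 49 × 17 resolution; the dyad EI series
uses a sparse discharge sequence (about 20 scenes). These sizes were
chosen so the whole suite exercises every claim at full fidelity where the
claim depends on it, and at reduced scale where the property being tested
(conservation, decay, symmetry, linearity) is resolution-independent.
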