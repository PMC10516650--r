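---
title: "Methods: quantitative structural analysis of cryo-EM maps and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative structural analysis of cryo-EM maps and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoquant)
```

`cryoquant` turns four measurements that cryo-EM structural papers report
— calibrated pixel size, domain rotation angles, atom displacements, and
buried-hydrophobic-atom counts — into tested, scriptable computations.
This vignette records the models behind each one, the parameters that
matter, and the choices made where the field's conventions are silent.

## Density-map simulation

A map is simulated from a model by summing one isotropic 3-D Gaussian per
heavy atom:

$$\rho(\mathbf{r}) = \sum_i Z_i \exp\!\left(-\frac{\lVert\mathbf{r}-\mathbf{r}_i\rVert^2}{2\sigma^2}\right),
\qquad \sigma = 0.225\,d$$

where $d$ is the target resolution in Å and $Z_i$ the atomic number. The
width convention makes the kernel's Fourier transform fall to $1/e$ of its
maximum at spatial frequency $1/d$; it is the convention of the
molmap-style simulators that map-fitting tools use, so correlations
computed here are comparable with interactive practice. The default
resolution is 3.5 Å — the value typically used when correlating
intermediate-resolution ribosome maps against models. Amplitudes can be
switched to unit weighting (`amplitude_mode = "unit"`) for synthetic
work. Kernels are truncated at $4\sigma$ (a relative error on the order
of $10^{-4}$ of the peak, far below any quantity we report) and evaluated
separably along the three axes, so simulation is linear in the atom set
by construction. Hydrogens are excluded and alternate locations collapsed
to the highest-occupancy conformer before simulation, matching heavy-atom
deposited models.

This is a real-space approximation: no electron scattering factors, no
B-factor dependence, no solvent model. For map–model correlation sweeps
those refinements move the correlation values but hardly the location of
the optimum, which is what the calibration needs.

## Pixel-size calibration

Magnification errors make the physical pixel size differ from the nominal
value written in the map header. The calibration treats pixel size as
pure metadata:

1. For each candidate size $s$ in an inclusive sweep (e.g. 1.047–1.087 Å
   in 0.01 steps — five candidates), the experimental map's geometry is
   rescaled by $s/\text{nominal}$ **about the grid center**. Voxel values
   are never interpolated, so the experimental data stay bit-exact; the
   center is the fixed point because a reconstructed particle is centered
   in its box and this minimizes drift across the sweep.
2. The simulated model map is resampled onto that geometry by trilinear
   interpolation (points outside the source grid evaluate to 0).
3. The correlation is computed over the mask where the *simulated* map is
   positive, so empty corners and out-of-bounds zeros never enter.
4. The optimum is the argmax over candidates; with `refine = TRUE` a
   parabola through the top three points gives a sub-step optimum,
   clamped to the sweep range. At a sweep boundary, or if the three
   points fail to bend downward, the argmax is returned unchanged.

Two correlation modes are provided because interactive tools differ and
published methods sections rarely say which was used: `about_zero`
($\sum ab / \sqrt{\sum a^2 \sum b^2}$, the common default of map-fitting
tools, and this package's default) and `about_mean` (Pearson after
subtracting masked means). Both are reported by the CLI; the choice
shifts correlation values more than optima.

The model must already be docked in the map's frame — rigid-body fitting
is out of scope — and `model_map_overlap()` guards the sweep: below 50 %
of atoms inside the map footprint, calibration aborts with a docking
error rather than returning a silently meaningless curve. A `nominal`
override exists because deposited headers sometimes already carry a
corrected pixel size, while reproducing a published sweep requires the
original nominal value.

When a published sweep table is the only available input,
`calibration_curve()` applies the same argmax/parabolic selection to the
printed correlations. On the five-point large-subunit table this package
ships in its acceptance script the argmax is 1.067 Å (correlation
0.6136); on the corresponding 70S table the printed argmax is also the
third candidate, 1.067 Å, although the source reports 1.077 Å as optimal
— with a curve that flat (0.7371 vs 0.7347) the choice sits inside the
parabola's noise, and we report what the numbers give.

## Rigid-body domain motion

All motion quantities derive from the Kabsch SVD superposition, with the
reflection case corrected by a sign flip of the smallest singular
direction so the result is always a proper rotation. Degenerate
(collinear) point sets are rejected. Rotation matrices are converted to
axis–angle with an `atan2`-based angle (accurate near 0°) and an
eigenvector fallback near 180°.

`domain_rotation()` follows the two-step convention of structural papers:
superpose conformation B onto A using a *reference* selection (the frame,
e.g. rRNA body phosphates), then fit the *mobile* selection and report
its residual rotation. Alignment selections default to one atom per
residue — phosphorus for rRNA, C-alpha for protein — which makes pairing
robust to side-chain differences between deposited models. Atoms are
paired by (chain, residue number, insertion code, atom name); where
insertion codes disagree, a pair is accepted only if exactly one
candidate exists on each side.

Swivel/tilt is the quaternion twist–swing decomposition about a declared
axis: the twist about the axis is the swivel, the orthogonal swing is the
tilt, and `R = R_swing %*% R_twist` exactly (recomposition is asserted to
1e−6 in the tests). Published head-motion numbers never define their
axes, so the decomposition here is *declared, not inferred*: the natural
choice for a structure series is the rotation axis of the full
chimeric-to-POST head motion, computed once and then used for all
intermediates, which makes "back swivel" a signed twist along that axis
(`swivel_signed_deg`). Angle magnitudes are reported to 0.1°;
comparisons against integer-degree published values should use ±1°,
since boundary choices of the alignment selections move recovered angles
by that order.

Per-atom displacement (`displacement()`) and minimum inter-selection
distance (`min_distance()`) complete the set; both are plain Euclidean
quantities after superposition and are checked against brute-force scans.

## Solvent accessibility and the burial statistic

SASA is Shrake–Rupley with a deterministic golden-section-spiral point
set (default 960 points) on each expanded sphere $r_{vdw} + r_{probe}$: a
point is accessible iff it lies outside every neighbor's expanded sphere.
Determinism was chosen over Monte-Carlo placement so counts are
bit-reproducible; the price is a small orientation dependence, bounded in
the tests at 1 % of total SASA under rigid rotation. The neighbor search
is an exact radius cutoff on a cell grid, so results are identical to the
all-pairs scan (asserted bitwise in the tests). Radii are the Bondi set
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å) shipped as data and
overridable; the probe is 1.4 Å.

The buried-hydrophobic statistic counts carbon and sulfur atoms of
hydrophobic residues (ALA, VAL, LEU, ILE, PRO, PHE, MET, TRP) whose SASA
falls below a threshold, computed *in the context of the full assembly*:
rRNA and non-water heteroatoms occlude, but only protein atoms are
counted — the statistic is about the ribosomal proteins. Published
comparisons of this kind leave most parameters unstated, so the defaults
are explicit and conservative: absolute burial below 0.1 Å² (an atom
with essentially no accessible surface), with a relative mode
(< 5 % of the isolated-atom area) provided as an alternative. A
residue-level count is also reported (a residue is buried when every
counted atom of it is buried), since prose often says "residues" while
counts are of atoms.

`burial_excess()` is $100\,(a-b)/\text{baseline}$. Both baselines are
computed because the field is genuinely ambiguous here: for counts
10 265 vs 7 064 the excess is 45.3 % of the smaller count but 31.2 % of
the larger — two descriptions of the same difference, and which one a
given paper means can only be recovered by computing both.

## Synthetic data: what it emulates and what it does not

The generator exists so that every analysis can be validated by parameter
recovery without downloading deposited data.

* `make_helix_model()` builds ideal helices — alpha (1.5 Å rise,
  100°/residue, 2.3 Å radius, CA) and A-form RNA phosphate traces
  (2.81 Å, 32.7°, 8.8 Å, P) — with real residue and atom names so
  selection and burial logic run unmodified.
* `make_two_domain_pair()` emulates a body/head two-domain particle.
  Each domain is a four-helix bundle: a single helix has almost no lever
  arm about its own axis, whereas a real ribosomal domain is tens of Å
  wide, and the bundle gives rotation recovery a realistic footprint.
  The head motion is either a single axis–angle rotation or a composed
  swivel+tilt about declared axes, with optional per-coordinate Gaussian
  noise (σ in Å) for robustness tests.
* `make_mislabelled_map()` simulates a map at the *true* pixel size and
  relabels its geometry at the *labelled* one about the map center —
  exactly the situation the calibration sweep inverts. Optional voxel
  noise is expressed as a fraction of the peak density; 0.5 × peak is
  used as the stress condition in the acceptance suite.

One integer seed drives a single local RNG stream (global RNG state is
saved and restored), so identical specs give byte-identical fixtures.

What the toys do **not** emulate: real density falloff and B-factors,
solvent, CTF-shaped noise spectra (noise is white Gaussian), model errors
between two deposited structures, or non-rigid deformation. Passing the
recovery tests therefore demonstrates the correctness of the estimators,
not their error bars on experimental maps; on real data, alignment
boundary choices and map imperfections dominate the uncertainty.

## Problem sizes and numerical conventions

The test and acceptance runs use two-domain toys of 240 atoms per domain
with maps of roughly 40×40×200 voxels at ~1 Å/pixel, 20 calibration
trials per condition and 10–20 seeds per noise condition — sizes chosen
so the complete validation runs in about a minute on one CPU while
leaving every statistic's tolerance comfortably resolved. Other
conventions: residue ranges are inclusive on both ends in author
numbering (structural papers cite helix spans that way); only the first
model of multi-model files is read (deposited cryo-EM models are
single-model); selection constraints conjoin, with empty axes matching
everything; MRC axis order is normalized internally to (z, y, x)
regardless of the file's mapc/mapr/maps; map origins honor the ORIGIN
header when nonzero, else nstart × voxel; out-of-bounds resampling
yields 0 rather than an error, because sweep edges must not poison a
masked correlation.

## Limitations

* No rigid-body docking: models must arrive positioned in the map frame.
* No Fourier-space simulation, sharpening, or FSC computation.
* Magnification anisotropy (per-axis scaling) is out of scope; the sweep
  assumes one isotropic pixel size.
* Domain boundaries for real ribosomes (e.g. 16S head vs body residue
  spans) are inputs, not built-in knowledge; published angle values are
  reproducible only up to the boundary choice.
* SASA treats all alternate conformers as a single highest-occupancy
  conformer and ignores hydrogens.
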