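---
title: "Inferring oligomeric states and dimer-of-dimers geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring oligomeric states and dimer-of-dimers geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostate)
```

`oligostate` packages the analysis chain used to characterise
self-associating helical proteins such as SMN (Survival Motor Neuron),
whose C-terminal YG box forms a "YG zipper" dimer and, through a second
surface, higher-order oligomers.  This vignette documents the models, the
parameters that matter, the synthetic data used by the test-suite, and the
design decisions taken where the problem is genuinely open.

## Sequence motifs of the YG box

The YG box interleaves three step-4 motifs on one helix: the G-motif
(`GxxxGxxxG`, the glycine-zipper signature), the Y-motif (`YxxxYxxxY`) and
the s-motif of small residues.  `scan_motifs()` reports every *maximal* run
of three or more class residues spaced exactly four apart; runs in
different phases may overlap and are reported separately.  The s-motif
alphabet is \{G, A, S, T, C\}: the classical description emphasises
Ser/Ala/Thr, but glycine and cysteine belong to the same small-side-chain
class and excluding them would split runs that are chemically continuous.
The alphabet is a parameter for users who want the narrower definition.

With the ideal helical twist of 100 degrees per residue (3.6 residues per
turn) a step-4 motif advances only 40 degrees per member, so all members of
one three-residue hit lie within an 80-degree sector of the helix surface —
the geometric reason zipper motifs form interaction *faces*.
`helix_face_angle()` exposes this arithmetic; the twist and the 50-degree
same-face half-width are parameters.

Cross-species residue mapping (`position_map()`, `map_position()`) is
alignment-based.  The package ships
`inst/extdata/yg_alignment_synthetic.fasta`, a constructed (synthetic)
three-species YG-box alignment whose numbering and residue identities
encode the published human/fruit-fly/fission-yeast correspondences
(e.g. hs273 = dm204 = sp137, hs277 = dm208 = sp141) with constant offsets
dm = hs − 69 and sp = hs − 136; full-length ortholog sequences are user
input.  Positions aligned to a gap have *no equivalent* and map to `NA`,
never to a number.

## Coarse-grained helix bundles

`build_ideal_helix()` places one C-alpha per residue on an ideal helix
(rise 1.5 Å, twist 100°, C-alpha radius 2.3 Å) and a C-beta pseudo-atom
1.5 Å further out along the same radial direction.  There are no rotamers:
every statement about side chains is a statement about radial C-beta
geometry.

`assemble_dimer()` builds the zipper dimer: two identical helices, axes
7.5 Å apart, phased so the G-motif faces the partner, related by an exact
two-fold (about the bundle axis when parallel, about the perpendicular when
antiparallel).  Because the 100° twist puts residue azimuths on a 20° grid,
a face-on Gly–Gly contact at 7.5 Å separation would sit 2.90 Å between
C-alphas, marginally inside the 3.0 Å clash floor; the default
`interface_phase = 10` degrees is the unique grid offset that keeps the
contact just outside the floor (3.08 Å) while a G-motif residue still makes
the closest approach.  Assembly *fails loudly* on clashes rather than
auto-relaxing: a clashing model is a wrong model, not a warning.

The helix polarity inside the dimer is deliberately a parameter
(`polarity`, default `"parallel"`, the GxxxG convention): the available
data do not fix it, and the package takes no position.

## The tetramer models and crosslink scoring

Tetramers are modelled as dimers of dimers docked through a second
interface that uses one helix from each dimer (`assemble_tetramer()`).
Both modes are generated with an exact two-fold so that every residue has a
well-defined homotypic partner across the dimer–dimer interface:

* **parallel** — both dimers point the same way; the interface helices form
  a right-handed cross;
* **antiparallel** — head-to-tail stacked dimers with a shallow left-handed
  crossing and an axial stagger, patterned on stacked crystal-lattice
  dimers.

`predict_crosslinks()` converts the minimum homotypic C-beta–C-beta
distance at each position into a propensity with a decreasing logistic
(midpoint `d0 = 6` Å, width `w = 1` Å).  Rigid pre-formed disulfides need
roughly 3.5–4.6 Å between C-betas; helical interfaces breathe, so the
midpoint is set softer.  The score is monotone non-increasing in distance
by construction.

The **parallel interface geometry is constraint-built**, exactly as such
models are built in practice: the free parameters (crossing angle,
interface separation, crossing-point residue, interface phase) were chosen
once, from a grid of physically sensible values, so that the model (i) is
packed but clash-free and (ii) reproduces the experimentally observed
homotypic crosslinking pattern of the human YG box — T274C/Y277C efficient,
S266C/S270C inefficient, S262C/R281C intermediate.  The selected defaults
are a steep right-handed crossing (80°), 9.0 Å between the interface helix
axes, crossing point three residues C-terminal of the helix midpoint, and
interface phase 130°; this places the two-fold axis along the outward
T274/Y277 edge, so those homotypic pairs meet at the dyad while the
buried-face serines are displaced along the crossing.  A shallow (±25°)
crossing cannot reproduce the pattern with radial C-beta geometry, because
homotypic distance then depends almost only on helix-face azimuth and S270
lies azimuthally between T274 and Y277.  The antiparallel geometry was
*not* fitted to the crosslinking data; with its defaults the predicted
propensities anti-correlate with the measured ordering, which is the
package's quantitative restatement of why antiparallel stacking fits the
crosslinking data poorly.  All four parameters remain user-settable, and
none of this is a claim about atomic structure: the models are screening
tools for interface hypotheses.

## Light scattering (SEC-MALS)

`debye_slice_mass()` implements the Debye plot: at each chromatographic
slice, `K c / R(θ)` is regressed on `sin²(θ/2)`; the reciprocal intercept
is the slice's weight-average molar mass and the slope yields an Rg
estimate through the low-angle expansion.  The second virial coefficient is
neglected (dilute column eluant) and no Zimm double extrapolation is
performed.  Rg estimates are flagged unreliable below ~10 nm, where
multi-angle detectors carry no angular information.  Slices with
concentration below 3× the baseline noise (estimated from the annotated
buffer region) are marked invalid rather than raising errors.
`peak_average_mass()` is the concentration-weighted average over valid
slices, reported together with the min–max range across the peak, and
`assign_oligomer_range()` rounds that range geometrically onto the allowed
ladder \{1, 2, 4, 8\} to compose labels such as `"Di-Tet"`, appending `"+"`
when the maximum exceeds the octamer by more than 10%.

## Small-angle X-ray scattering

* `debye_profile()` — the Debye sum over point beads, with the `i = j` and
  `q → 0` limits evaluated analytically (`sinc → 1`), never by division.
  No atomic form factors or hydration layer: theoretical profiles are
  coarse-grained.
* `guinier_fit()` — iterative low-angle window selection until the fitted
  Rg and the `qRg ≤ 1.3` window agree; a non-negative slope is a fit error.
* `pr_invert()` — the indirect transform to P(r) on a uniform 101-point
  grid with endpoint-zero constraints and a second-difference smoothness
  penalty.  The regularization weight defaults to an L-curve corner
  search, which makes the classical "perceptual criteria" explicit and
  reproducible.
* `scan_dmax()` — re-inverts over a Dmax range and scores each candidate
  with reduced chi-square (weight 1), a P(r)-negativity penalty (weight 10)
  and a tail-oscillation penalty (weight 1).  The weights are configurable;
  the defaults encode the usual manual criteria (fit the data, keep P(r)
  non-negative, avoid a ringing tail).
* `parallel_axis_distance()` — solves
  `Rg² = f₁R₁g² + f₂R₂g² + f₁f₂L²` for the inter-body distance `L`; equal
  mass fractions (`f₁ = 0.5`) correspond to two identical dimers in a
  tetramer.  A negative radicand means the inputs are physically
  inconsistent and is an error, not `NaN`.
* `svd_efa()` — SVD plus forward/backward evolving factor analysis.  When
  per-point uncertainties are available the detection runs on the
  error-weighted (whitened) matrix, so the entry/exit criterion — the k-th
  singular value of the growing window exceeding 3× the random-matrix noise
  edge `σ(√frames + √n_q)` — has an exact noise scale; with signal-
  proportional noise, unwhitened detection systematically mislocates
  windows, which is why the field's EFA implementations weight by errors.
  The abstract basis is rotated into non-negative, windowed concentration
  profiles by alternating least squares under the first-in/first-out
  elution constraint.  Automated EFA truncates low-signal elution tails
  outside the detected windows; the reconstruction residual is reported so
  users can see exactly how much.

## The oligomer equilibrium ladder

Species are restricted to n ∈ \{1, 2, 4, 8\} protomer units — the
dimer-of-dimers ladder; one protomer is one SMN–Gemin2 heterodimer.
Stepwise mass action gives `[X₂] = [X₁]²/Kd₂`, `[X₄] = [X₂]²/Kd₄`,
`[X₈] = [X₄]²/Kd₈`, and the free-protomer concentration is found by
bisection on the strictly monotone conservation function (relative
tolerance 1e-12; conservation holds to better than 1e-10 in all tests).
Intermediate odd species are excluded by default but the ladder is
configurable.

Each step's free energy is `ΔG°(T) = ΔH°₀ + ΔCp(T − T₀) − T[ΔS°₀ +
ΔCp ln(T/T₀)]` with `Kd = exp(ΔG°/RT)`.  The defaults describe a
hydrophobically driven metazoan-like ladder: a tight dimer step (~1 nM), a
~1 µM tetramer step (the scale reported for the fission-yeast tetramer),
entropy-driven association at 25 °C and `ΔCp < 0`, so the higher-order
steps weaken on cooling across 0–40 °C.  At 10 µM total protomer this
yields a tetramer–octamer distribution at 25 °C and a shift toward dimers
and tetramers at 4 °C — the cold shift seen experimentally.  No published
thermodynamic parameters exist for the metazoan complexes, so these
defaults are illustrative; fitting step Kd values to titration data
(`fit_equilibrium()`, relative least squares over log₁₀ Kd) is the
supported quantitative path.

`predict_sbar()` is a trend tool only (`sₙ = s₁ n^(2/3)`, signal-weighted);
solving sedimentation boundary shapes is out of scope.
`predict_capture()` models tagged/untagged co-purification under
independent random assortment into n-mers: `P = 1 − (1 − p)^(n−1)`, which
makes a monomeric variant's failure to co-purify a structural zero.

## Synthetic data and what passing tests mean

The `gen_*` generators produce every input the analyses consume, under
mandatory seeds and bit-reproducibly:

* ortholog families that hold Y/G/s positions fixed while varying non-motif
  residues at a chosen divergence, with injected point mutations;
* SEC-MALS chromatograms with Gaussian elution peaks, light scattering
  `K·Σ cₛMₛ` (form factor ≈ 1 at light-scattering angles for these sizes)
  and fractional Gaussian noise on both channels (default 1%), plus an
  annotated buffer region;
* SEC-SAXS frame stacks as concentration-weighted Debye profiles with
  Poisson-like (variance-scaled) noise over a small residual buffer floor
  (default 1% of peak intensity);
* bead models of dimers and tetramers, optionally decorated with one
  20 Å "Gemin2-sized" sphere per protomer to mimic the full-complex
  envelope — a single sphere because no usable partner shape is available
  at this resolution.

Test problem sizes are deliberately desk-scale: 43-residue helices,
120-frame × 100-point SEC-SAXS stacks, 601-slice chromatograms,
16-point titrations, 40-mer motif-scan sequences (1,000 random cases
against the brute-force oracle).  Passing these tests shows the
*estimators* are correct and stable under the stated noise models; it does
not show robustness to the pathologies of real data — inter-detector
calibration drift, band broadening, radiation damage, capillary fouling,
concentration-dependent elution, or non-Gaussian outliers — none of which
the generators emulate.

## Known limitations

* Bead-level scattering only; comparisons with measured absolute
  intensities require external form-factor tools.
* The crosslink score has no rotamer chemistry: it ranks interface
  hypotheses, it does not predict absolute crosslinking yields.
* Automated EFA windowing truncates low-signal tails of overlapping peaks
  (reflected in the reported residual).
* Sedimentation is a scaling trend, not a hydrodynamic model.
* The fixture alignment is a numbering scaffold, not a biological
  alignment; real comparative work should supply real alignments.
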