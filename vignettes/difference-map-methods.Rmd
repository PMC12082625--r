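---
title: "Difference maps, extrapolated structure factors and flavin bending: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference maps, extrapolated structure factors and flavin bending: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmap)
```

redoxmap analyses isomorphous pairs of crystal datasets — a dark
(reference) state and a perturbed state such as a photoreduced or
oxidized redox state — and extracts the structural difference between
them: where density moved, what fraction of the crystal converted, and
how a flavin cofactor bent. This vignette explains the models behind
each stage, the parameters that matter, and the choices made where the
underlying protocols are conventionally under-specified.

## The two-state crystal model

A crystal in which a fraction $N$ of unit cells adopts a perturbed
structure while $1-N$ remain in the reference state diffracts with
structure factors

$$F_\mathrm{mix}(\mathbf{h}) = (1-N)\,F_\mathrm{ground}(\mathbf{h}) + N\,F_\mathrm{excited}(\mathbf{h}),$$

a *complex* sum: static disorder averages scattering densities, not
intensities. Observed amplitudes $|F_\mathrm{mix}|$ therefore carry the
perturbation only through its projection onto the reference phase, which
is the single most important fact behind the design decisions below —
it is why naive $F_o - F_o$ maps underestimate features by roughly a
factor of two, and why amplitude extrapolation needs a compensating
weight.

The synthetic generator (`make_ground_model()`,
`apply_perturbation()`, `simulate_observed()`) realises exactly this
model: a P1 cell of 22 Å (tiny, 40 atoms) or 30 Å (small, 150 atoms)
holding a planar idealized isoalloxazine with canonical atom names, a
cubane 4Fe-4S cluster with four S ligands (Fe–S bonds 2.3 Å, mild
anisotropic U on the cluster), and a random C/N/O/S scatter with no
contact below 1.5 Å. The isoalloxazine uses uniform 1.5 Å bonds — an
idealization that keeps every interatomic distance at or above the
generator's contact floor while preserving planarity, ring topology and
naming, which is all the downstream algebra uses. Gaussian noise is
added to amplitudes, $\sigma_h = f\,|F| + c$ with relative noise $f$
(default 0.03, a typical serial-crystallography merging precision) and
floor $c$ (default 0). Noise on amplitudes rather than intensities, and
truncation at zero without a French–Wilson correction, are deliberate
simplifications: the analysis pipeline consumes amplitudes, and at 3%
noise the truncation bias is negligible.

What the generator does **not** emulate: partiality and indexing
ambiguity of real serial data reduction, radiation damage, diffuse
scattering, bulk solvent, and crystal-to-crystal non-isomorphism.
Passing tests on these fixtures therefore demonstrate the correctness
of the *algebra* — scaling, weighting, Fourier synthesis, occupancy and
conformer estimation — under a faithful two-state disorder model, not
robustness to every pathology of experimental data.

## Structure factors and maps

Structure factors use 4-Gaussian Cromer–Mann form factors (built-in
table for H, C, N, O, Mg, P, S, Fe; ions treated as neutral atoms),
isotropic Debye–Waller factors $\exp(-B s^2/4)$ with $s = 1/d$, and
anisotropic factors $\exp(-2\pi^2 \mathbf{s}^\top U \mathbf{s})$ with
$U$ in the Cartesian crystal frame (the PDB ANISOU convention). The
default engine is direct summation — exact and fast at desk scale. An
independent FFT route samples each atom's Gaussian density on a fine
grid (spacing $d_\mathrm{min}/4$) with an extra smearing B of 20 Å²
that is deconvolved in reciprocal space; it agrees with direct
summation to much better than 0.1% and serves as the cross-check of
the engine.

Maps are synthesized by $\rho(\mathbf{x}) = V^{-1}\sum_\mathbf{h}
F(\mathbf{h}) e^{-2\pi i \mathbf{h}\cdot\mathbf{x}}$ with Friedel
completion, on grids of spacing $d_\mathrm{min}/3$ by default (a
synthesis request coarser than the Nyquist bound $d_\mathrm{min}/2$ is
an error). Map values are kept unscaled; sigma-scaling is applied on
demand for contouring. Difference maps are contoured and peak-listed at
$\pm 3.5\sigma$ by default; extrapolated (2Fo-type) maps at $1.0\sigma$.

## Scaling and q-weighted differences

`scale_to_reference()` fits $k$ and a relative isotropic $B$ so that
$k\,e^{-B s^2/4} F_o$ matches the reference in least squares, started
from the exact log-linear solution and polished by BFGS. Both observed
sets are scaled to the dark calculated amplitudes before differencing.

`qweight_differences()` forms $\Delta F = F_x - F_\mathrm{dark}$ with
$\sigma_{\Delta F} = (\sigma_x^2 + \sigma_\mathrm{dark}^2)^{1/2}$ and
down-weights each difference within equal-count resolution shells:

$$w_h = \Big(1 + \frac{\sigma_{\Delta F,h}^2}{\langle\sigma_{\Delta F}^2\rangle}
 + \alpha\,\frac{\Delta F_h^2}{\langle\Delta F^2\rangle}\Big)^{-1},
 \qquad \mathrm{dFo_{WN}}_{,h} = \frac{w_h \Delta F_h}{\langle w\rangle}.$$

The shell-wise $\langle w\rangle$ normalization preserves the scale of
each shell, so weighting redistributes emphasis without shrinking the
map globally. The $\alpha$ term (default 1 for display maps) suppresses
outliers — but note that on strong genuine signal it suppresses exactly
the reflections that carry it. For the *quantitative* stages (occupancy
scan, bending refinement) the pipeline therefore uses pure sigma
weighting ($\alpha = 0$, config key `scan_alpha`); for display maps the
outlier protection is worth the attenuation. Twenty equal-count shells
are the default; fewer are advisable below ~2000 reflections.

`fofo_map()` synthesizes the weighted differences with dark-model
phases, excluding reflections beyond a 10 Å low-resolution cutoff, and
lists peaks above the contour threshold with their nearest atoms. The
map is exactly antisymmetric under swapping the two states.

## Occupancy by negative-density inflection scan

`extrapolated_sf()` forms $|F_\mathrm{ext}| = |F_c^\mathrm{dark}| +
\mathrm{dFo_{WN}}/n$ at a trial occupancy $n$, keeping dark phases.
Once $n$ drops below the true occupancy $N$, extrapolation
over-subtracts density at vacated sites and spurious negative density
inflates — the onset carries $N$. `occupancy_scan()` integrates the
residual negative density inside a region of interest (2 Å spheres
around the cofactor of interest by default, 1.5 Å in the pipeline) over
a grid of trial occupancies (0.05–1.00, step 0.05) and estimates $N$
from the onset. Four numerical choices matter, all of which were
validated on synthetic data during development:

* **Fixed threshold.** Residual negative density is counted below
  $-3\sigma$ of the *dark calculated* map, not each trial map's own
  sigma. A trial map's sigma grows like $1/n$, so a self-referential
  threshold rises exactly where over-extrapolation must be detected
  and silences the signal.
* **Projection weight 2.** Because a dark-phased amplitude difference
  carries the true density change at half weight, the scan doubles the
  differences before dividing by $n$; the extrapolated map then holds
  the density change at weight $N/n$ and crosses zero at the vacated
  sites precisely when $n = N$. Without the factor the onset appears
  near $N/2$.
* **Signed synthesis.** Inside the scan, extrapolated values that fall
  below zero flip their phase by 180° rather than truncating
  (`method = "vector"` of `extrapolated_sf()`): truncation caps hole
  growth and systematically delays the onset. Written extrapolated
  datasets keep the conventional truncated amplitudes (with the
  truncated fraction recorded, and a warning above 5% — the classic
  symptom of over-extrapolation).
* **Vacancy-template fit.** A maximum-curvature knee detector is
  unreliable here: the scan curve diverges like $1/n$, so its largest
  second difference sits at the end of the grid regardless of $N$.
  Instead, the dark map itself predicts the curve: a region voxel
  holding dark density $A_v$ develops a hole of depth
  $s\,A_v\,(N/n - 1)$ and contributes once the hole passes the
  threshold. Least squares over $(N, s)$ — with $s \in [0.4, 1.3]$ a
  free shrinkage factor absorbing weighting attenuation — yields
  $\hat N$ on a 0.01 grid. The curve and its discrete curvature are
  retained in the result for inspection (`tidy()`, `autoplot()`).

On linear-regime fixtures (a few displaced atoms, a few percent of the
total scattering) this recovers $N \in [0.2, 0.7]$ with a median error
of ~0.03 at 3% amplitude noise, and $N = 1$ to within 0.05 noise-free.
Two limitations are inherent rather than numerical: when the perturbed
fraction of the total scattering is large (tens of percent, as in the
packaged demo where the whole 4Fe-4S cluster moves inside a 40-atom
cell), the complex-sum amplitudes leave the linear regime and any
amplitude-extrapolation estimate degrades (the demo documents a ±0.15
band); and a perturbation whose old and new sites overlap within an
atomic width partially refills its own holes, weakening the onset. A
featureless (all-zero) scan curve raises a structured
"no inflection detected" error carrying the curve.

## Flavin butterfly bending and dFoCC refinement

The isoalloxazine folds about its N5–N10 axis: the benzene wing
(C5a, C6–C9, C9a plus methyls) rotates by $\rho_C$ and the pyrimidine
wing (C4a, C10a, N1–C4 plus O2/O4) by $\rho_N$, in opposite senses so
that positive angles fold both wings toward the same face. N5 and N10
are fixed; each wing moves rigidly, so within-wing distances and all
central-ring bond lengths are preserved exactly. The shared atoms
C5a/C9a ride with the benzene wing and C4a/C10a with the pyrimidine
wing — the only reading under which both rigid wings and an intact
central ring can coexist.

Measuring the two angles back from coordinates is subtler than it
looks. For a flavin whose only axis substituent lies on the N5–N10
line, a $(\rho_C, \rho_N)$ bend and a $(\rho_C', \rho_N')$ bend with
the same sum differ only by a rigid rotation of the whole molecule —
the *split* between the two wings is not a function of the geometry at
all, and the least-squares plane of the central ring tilts by exactly
$(\rho_C - \rho_N)/2$, cancelling the split from any measurement made
against it. `butterfly_angles()` therefore measures each wing plane
against the reference plane spanned by the N5–N10 axis and the ribityl
arm (the first clearly off-axis substituent hanging off the axis
atoms, C2' in FAD and in the synthetic flavin), refined by a short
un-bend fixed-point iteration; bend-then-measure round trips are exact
to below $10^{-4}$ degrees and the measurement is invariant under
rigid motion. Published butterfly angles may use other conventions, so
absolute comparisons across software should be made with care; the
convention here is self-consistent across `bend_flavin()`,
`butterfly_angles()` and `dfocc_refine()`.

`dfocc_refine()` scores candidate bends by the real-space correlation
(dFoCC) between the observed difference map and a model-calculated
difference map within 2.5 Å of the flavin, over an exhaustive
$(\rho_C, \rho_N)$ grid (default ±30°, step 0.5°; ties resolve toward
the smaller total bend; deterministic by construction). Because the
observed $F_o - F_o$ map carries the density change in dark-phase
projected form, the candidate model maps are projected the same way —
amplitude differences $|F_c(\mathrm{bent})| - |F_c(\mathrm{dark})|$
with dark phases (`projection = "amplitude"`) — rather than as the
complex difference; correlating a projected observation against an
unprojected model leaves a systematic ~1–2° bias. With this matching,
noise-free refinement against simulated observations recovers injected
bends exactly to the grid step, and 3% noise costs under 2° at full
occupancy. `model_ded()` retains the complex difference as its default
output, which is the true density change and the right thing to
visualise.

## Geometry, B-factor and ADP analytics

These follow textbook definitions: minimum edge-to-edge distances over
non-hydrogen atoms (no periodic images by default — the intended use is
intramolecular cofactor spacing; a flag enables minimum-image search);
IUPAC backbone dihedrals with chain-break detection at C–N > 2.5 Å;
per-atom displacements computed in the common crystal frame by default
(the natural comparison for isomorphous pairs — superposition is
optional and explicit, since it removes exactly the rigid component a
difference map would show); per-residue main-chain B-factor profiles
and their Pearson correlation; per-atom eigen-decomposition of
anisotropic U with $U_\mathrm{eq}$, anisotropy $\lambda_{\min} /
\lambda_{\max}$ and positive-definiteness flags. The spectroscopic
helper converts a 470 nm difference absorbance into the oxidized
cluster fraction via
$(\Delta A_{470}/\Delta\varepsilon_{470}) / (A_{470}/\varepsilon_{470})$
with defaults $\Delta\varepsilon_{470} = 8400$ and $\varepsilon_{470} =
7500\ \mathrm{M^{-1} cm^{-1}}$.

## Problem sizes and determinism

All defaults were chosen so a complete demonstration — generation,
scaling, difference map, occupancy scan, bending refinement, geometry
report — runs in well under five minutes on one CPU: tiny fixtures for
bending (40 atoms, ~4000 reflections at 1.8–2.0 Å), small fixtures for
occupancy work (150 atoms, ~11000 reflections), bend scans of ±10–15°
in the tests. Every stochastic quantity is a pure function of its
declared seed; the pipeline manifest records parameters, seeds and
headline numbers, and identical configurations reproduce identical
manifests.

## File formats

Models read and write PDB (ATOM/HETATM/ANISOU/CRYST1) and a minimal
mmCIF subset (`atom_site`, `atom_site_anisotrop`, `cell`); reflections
use a plain-text tab-separated dialect (`# h k l F sigF` or
`# h k l F phi` header, preceded by a `# cell` line so files are
self-contained); maps use CCP4/MRC mode 2. Binary MTZ is not supported;
the TSV dialect is the exchange format, and `write_fixture()` /
`read_fixture()` bundle a complete two-state fixture with a JSON
manifest as its ground-truth record.
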