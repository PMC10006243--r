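---
title: "Voxel-S-value dosimetry and treatment planning for Y-90 radioembolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-S-value dosimetry and treatment planning for Y-90 radioembolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdose)
```

## The problem

Yttrium-90 microsphere radioembolization delivers a pure beta emitter to
liver tumors through the hepatic artery. Planning the injected activity
requires balancing tumor dose against two critical organs: the
non-tumoral ("normal") liver and, because a fraction of the
microspheres shunts through the hepatic circulation, the lungs. The
classical partition model works with three compartment mean doses; a 3D
dose map additionally supports dose-volume histograms (DVH) and
voxel-level dosimetrics.

The pre-treatment surrogate is a Tc-99m-MAA SPECT/CT: the MAA
distribution stands in for the microsphere distribution, the CT provides
density, and VOI masks define normal liver (NL = liver minus tumors),
tumors, and lungs. `voxdose` converts such data — or a synthetic phantom
with known ground truth — into absorbed dose maps by seven voxel-S-value
(VSV) methods, derives DVH dosimetrics, and computes the maximum
injected activity (MIA) by both the partition model and 3D dosimetry.

## Physical constants and units

All dose conversion rests on two constants for Y-90: the half-life
$T_{1/2} = 64.04$ h and the total energy released per administered GBq
over complete decay, $E = 49.67$ J/GBq. Activity maps $A$ (GBq) are
converted to time-integrated activity (TIA)
$\tilde A = A/\lambda = A \cdot T_{1/2}/\ln 2$ (92.390 GBq·h per GBq),
assuming permanent trapping with physical decay only. The energy
released per unit TIA is $\epsilon = E \ln 2 / T_{1/2} = 0.5376$
J/(GBq·h); kernels are expressed in Gy per GBq·h so that
$\epsilon$ makes the dimensional bookkeeping explicit while reproducing
the conventional 49.67 J/GBq. `y90_energy_per_gbq()` recomputes $E$ from
the mean beta energy per decay (0.9337 MeV) and the half-life as an
internal consistency check; it agrees with the dosimetric constant to
about 0.2%.

## Voxel-S-value kernels

A VSV kernel $K$ gives the dose to voxel $d$ per unit TIA in the central
voxel of an infinite uniform medium. Kernels for the liver medium
(1.06 g/cm³, 5×5×5 support) and lung medium (0.26 g/cm³, 21×21×21
support) are generated at the SPECT voxel size; both supports are chosen
so that more than 99% of the released energy is contained — the package
reports the exact captured fraction and never renormalizes a truncated
kernel.

### The dose-point kernel and its integration

The generator integrates an embedded radial dose-point kernel (DPK) for
the Y-90 beta spectrum, stored as a scaled energy-deposition
distribution $F(x)$ with $x = r/R_E$ and $R_E$ the end-point CSDA range
in water (11.0 mm). The tabulated shape — finite at the origin, a broad
maximum near $x \approx 0.35$, zero just beyond the range — is a
representative analytic stand-in for published Monte Carlo beta point
kernels; it is normalized internally so that its radial integral is
exactly 1, which makes all energy accounting self-consistent by
construction. Because every acceptance-grade quantity in the package
(capture fractions, energy conservation, density scaling, equilibrium
limits) depends on the normalization and the range rather than the fine
shape, results are robust to the exact tabulation; externally simulated
kernels (e.g. GATE Monte Carlo) can be imported through `load_kernel()`
for clinical bit-compatibility and are validated, not trusted blindly
(energy over-conservation is rejected, stochastic asymmetry is flagged).

Media other than water are handled by mass-range scaling,
$R_E(\rho) = R_E(\text{water})/\rho$, under which generated kernels obey
$K_\rho(r) = (\rho/\rho_w)^2 K_w(r\,\rho/\rho_w)$ — a property the test
suite verifies to machine precision by comparing a lung-medium kernel
against a water kernel generated at a proportionally scaled voxel size.

### Voxel-pair quadrature

The kernel value is the average of the DPK over all pairs of points in
the source and target voxels. The difference vector between two
uniformly distributed points in axis-aligned voxels has a separable
triangular density $T_d$, so

$$K(d) = \int_0^\infty j(r)\, r^2 \!\int_{S^2} T_d(r\omega)\, d\omega\, dr,$$

where $j(r) \propto F(r/R_E)/r^2$ is the DPK. The $r^2$ shell factor
cancels the DPK singularity analytically, leaving a bounded smooth
integrand — the self-dose voxel needs no special treatment, which is
where point-sampling schemes are least reliable. The radial integral
uses a midpoint grid (step `min(spacing)/32`) shared by all voxels, and
the angular integral a Gauss–Legendre × uniform product rule (16 × 32
directions). Because the triangular densities over all lattice offsets
form a partition of unity, the kernel voxel values sum to exactly the
released energy when integrated over the whole lattice; truncation to a
finite support strictly loses energy. The capture fraction is therefore
guaranteed to lie in $(0, 1]$ — a property a sampled quadrature cannot
guarantee near the singularity. Octant (and, for isotropic voxels,
permutation) symmetry is exact by replication.

```{r kernels}
liver_k <- generate_vsv_kernel(1.06, spacing = 4.8, half_size = 2)
lung_k <- generate_vsv_kernel(0.26, spacing = 4.8, half_size = 10)
c(liver = liver_k$capture_fraction, lung = lung_k$capture_fraction)
```

`half_size = 0` is the degenerate limit where all captured energy is
local and returns the LED kernel (below) with capture fraction 1 —
truncating an *extended* kernel to its center voxel instead yields the
honest self-dose share (about 25% for liver at 4.42 mm).

## The seven dose-conversion methods

With $\otimes$ stationary convolution (zero-padded: activity is zero
outside the body), $\rho_L = 1.06$, $\rho_{Lu} = 0.26$ the kernel
media, and $\rho(v)$ the CT-derived local density:

| Method | Formula |
|---|---|
| LED | $D(v) = \tilde A(v)\,\epsilon/M(v)$ |
| LiK | $D = \tilde A \otimes K_{Liver}$ |
| LiLuK | $D = \tilde A_{Liver} \otimes K_{Liver} + \tilde A_{Lungs} \otimes K_{Lung}$ |
| LiKD | $D(v) = [\tilde A \otimes K_{Liver}](v)\;\rho_L/\rho(v)$ |
| LiCK | $D = [\tilde A\,\rho_L/\rho] \otimes K_{Liver}$ |
| LiLuKD | $D(v) = [\tilde A_{Liver} \otimes K_{Liver}](v)\,\rho_L/\rho(v) + [\tilde A_{Lungs} \otimes K_{Lung}](v)\,\rho_{Lu}/\rho(v)$ |
| LiCKLuKD | $D = [\tilde A_{Liver}\,\rho_L/\rho] \otimes K_{Liver} + [\tilde A_{Lungs} \otimes K_{Lung}]\,\rho_{Lu}/\rho$ |

Two genuinely open design points deserve comment.

**Target- vs source-voxel density scaling.** LiKD applies the density
ratio at the dose-deposition (target) voxel — a voxelwise post-scaling
of one stationary convolution — while LiCK applies it at the emission
(source) voxel — a pre-scaling of the TIA map. The two operations are
often described as interchangeable because convolution is linear, yet
they are *not* the same operator on heterogeneous density maps, and
clinical comparisons consistently report different accuracies for the
two. This package keeps them distinct as defined above; in a uniform
medium at the kernel density they coincide exactly with LiK (verified
to 1e-12 in the tests).

**TIA outside liver and lungs.** In the two-kernel methods, TIA in
voxels belonging to neither compartment (possible after SPECT blur) is
routed to the liver-kernel component by default (`outside_policy =
"liver"`): soft tissue is far closer to liver than to lung in density.
A `"drop"` policy is available.

Densities are clamped below at 0.05 g/cm³ before any division so
near-air CT voxels cannot produce unbounded dose; a voxel with exactly
zero density but non-zero TIA is a hard error, not a silent fix.

### Energy behavior

In a uniform medium at liver density, an interior voxel of a large
uniform source reaches charged-particle equilibrium: the LiK dose
equals the LED dose times the kernel's capture fraction (a test asserts
0.1% agreement). For the density-corrected tissue-specific method
(LiLuKD) the target-side correction makes the deposited energy
$\sum_v D(v) M(v)$ equal *exactly* the captured released energy
whenever no voxel falls below the density floor — the correction
cancels against the voxel mass. The uncorrected methods do not share
this property: a lung kernel reaching across the lung boundary deposits
into soft-tissue masses four times its medium density, so LiLuK (and,
more mildly, LiCK through the convexity of $1/\rho$) can *over*-deposit
by a few percent on a realistic phantom. That excess is the physical
signature of why these methods misestimate lung dose, and the test
suite checks it as a bounded excess rather than pretending a
conservation law holds.

### Convolution backends

Both a direct spatial-sum backend and a zero-padded FFT backend are
provided; they agree to better than 1e-6 relative on random cases
(tested against an independent triple-loop oracle as well). FFT timing
makes all seven methods on a 64×64×72 grid a matter of seconds.

## DVH dosimetrics

Differential DVHs use half-open 1-Gy bins $[k, k+1)$ in percent of VOI
volume (summing to 100 by construction); the cumulative DVH at integer
thresholds is definitionally identical to the `v_at_dose()` metrics
(V\_NL,70Gy, V\_Tumors,200Gy, V\_Lungs,5Gy, V\_Lungs,13Gy). DVH
agreement between a method and a reference is summarized by the mean
absolute error over bins,

$$MAE = \frac{1}{D_{max}} \sum_{k=1}^{D_{max}} |V^{test}_k - V^{ref}_k|,$$

with $D_{max}$ the reference map's maximum VOI dose rounded up to whole
bins. When the test DVH extends beyond the reference range both are
zero-padded to the longer and the whole difference is summed (still
normalized by the reference $D_{max}$): tail dose invented by a method
counts as error. The $V$ units are percent of VOI volume per bin; an
alternative normalization (absolute volume) would rescale MAE values
but not method rankings. Method comparison across cases uses the
two-tailed paired Wilcoxon signed-rank test with Bonferroni correction
(`paired_wilcoxon_bonferroni()`) and Bland–Altman limits of agreement
in percent of reference (`bland_altman()`).

## Treatment planning

The compartment summaries use nominal densities (1.06 liver/tumor,
0.26 lung) times CT-segmented volumes for masses, the convention of the
partition model. With dose limits $D^{max}_{NL} = 70$ Gy and
$D^{max}_{Lungs} = 30$ Gy:

$$MIA_{PM} = \min\left[\frac{(M_{T}\,TNR + M_{NL})\,D^{max}_{NL}}
{49.67\,(1 - LSF/100)},\;
\frac{M_{Lu}\,D^{max}_{Lungs}}{49.67\,LSF/100}\right],\qquad
MIA_{3D} = \min\left[\frac{D^{max}_{NL}}{D^{mean}_{NL}/IA_{MAA}},\;
\frac{D^{max}_{Lungs}}{D^{mean}_{Lungs}/IA_{MAA}}\right].$$

Both terms are always computed and the binding constraint labelled —
the lung limit is rarely reached in practice, but the package reports
rather than drops constraints. The whole-liver activity in the LSF
definition includes tumors. An LSF above 20% triggers an advisory
warning only: high shunt does not reliably imply a lung dose above
30 Gy, so exclusion on LSF alone is left to the user. On a noiseless
uniform-density phantom the LED-based $MIA_{3D}$ and $MIA_{PM}$ reduce
to the same compartment algebra and agree to 1e-6 — a strong
cross-check of both routes.

```{r planning}
m <- c(tumors = 20.6 * 1.06e-3, nl = 1372.8 * 1.06e-3,
       lungs = 3591.2 * 0.26e-3)   # kg from mL at nominal densities
mia_partition(tnr = 1.3, lsf_pct = 1.5, masses_kg = m)[c("mia_gbq", "binding")]
```

## The digital phantom

`make_phantom()` builds a torso of soft tissue (1.00 g/cm³) in air,
containing an ellipsoidal liver (1.06 g/cm³, ~1106 mL) with spherical
tumors, and two ellipsoidal lungs (~2088 mL) whose density is Gaussian
per voxel (mean 0.26, SD 0.05, floored at 0.05 g/cm³ — clinical lung
density SDs run 0.14–0.23, so the default jitter is conservative).
Activity is assigned by compartment: lungs receive $IA \cdot LSF/100$
uniformly and the rest splits between tumors and NL at concentration
ratio TNR, so the configured LSF/TNR are recovered *exactly* by the
measurement operators on the noiseless phantom — parameter recovery is
a construction identity, which is what makes it a useful smoke test of
the whole measurement chain rather than of the generator.

Defaults: 64×64×72 grid at 4.42 mm (a typical SPECT voxel), LSF 5%,
TNR 4 (mid-range of clinical cohorts, which span roughly 1.5–21.2% and
1.2–38.9), IA\_MAA 0.111 GBq, one 25-mm tumor. Geometry, LSF/TNR,
tumors, densities, blur and noise are all configurable.

SPECT-like degradation applies a Gaussian blur (FWHM in mm) with
reflective boundary handling — chosen so total activity is conserved
exactly, which zero padding cannot do near the FOV edge — followed by
optional Poisson noise on a counts scale (default 5e6 total counts)
recalibrated back to the injected activity, reproducible under a seed.
Blur moves activity across the liver–lung boundary and perturbs the
recovered LSF by well under 2 percentage points at default geometry.

What the phantom does *not* emulate: projection-domain SPECT physics
(attenuation, scatter, collimator response, reconstruction artifacts),
respiratory motion, registration error, and realistic organ shapes.
Passing tests on the phantom therefore validate the dose-conversion,
DVH and planning arithmetic — not the quantitative accuracy of any
clinical SPECT reconstruction chain.

## Numerical choices, problem sizes, limitations

* Kernel radial step `min(spacing)/32`, angular rule 16×32: individual
  kernel voxels are converged to well under 1%, and energy accounting
  is exact by construction. Generation takes ~1 s per kernel.
* Convolutions default to the FFT backend; the direct backend is the
  reference implementation for verification.
* Tests and examples use grids up to 64×64×72 and kernel supports up to
  21³, the natural sizes of this application; the full suite runs in
  well under a minute.
* Dose at bin edges goes to the upper DVH bin; ties are deterministic.
* The embedded DPK covers the beta component only; bremsstrahlung
  transport beyond the local deposition it represents is out of scope,
  as are Monte Carlo radiation transport, SPECT reconstruction, image
  registration and DICOM I/O.
* Imported Monte Carlo kernels are used as-is after validation; whether
  an external kernel was symmetrized or renormalized is the supplier's
  choice and is surfaced as warnings, not corrected silently.
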