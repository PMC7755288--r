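---
title: "Methods: nematic cell polarity and co-orientational order"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nematic cell polarity and co-orientational order}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nematiq)
```

This vignette documents the models and numerical choices behind `nematiq`:
what is computed, under which assumptions, which defaults were chosen where
the design was genuinely open, and what the synthetic generators do and do
not emulate.

## Surface patterns and the multipole classification

A cell's membrane-domain distribution is represented as a *surface pattern*:
weighted samples `(d_k, w_k, v_k)` of a density on the unit sphere, where
`d_k` are unit directions, `w_k` solid-angle quadrature weights (steradian)
and `v_k` density values. Carrying explicit weights lets mesh-projected
cells (irregular samples) and regular grids share one code path.

`sph_decompose()` expands the density in complex orthonormal spherical
harmonics with Condon–Shortley phase,
$$f(\mathbf x) = \sum_{l} F_l(\mathbf x), \qquad
  F_l = \sum_{m=-l}^{l} f_{lm} Y_{lm}, \qquad
  f_{lm} = \sum_k w_k v_k \overline{Y_{lm}(\mathbf d_k)},$$
evaluated by a stable three-term recursion in the fully normalized
associated Legendre functions (degree blocks are streamed, so memory stays
linear in the band limit). For real densities $f_{l,-m} = (-1)^m \bar f_{lm}$,
which is validated in the tests. The *spherical power spectrum*
$\|F_l\|^2 = (4\pi)^{-1}\sum_m |f_{lm}|^2$ is rotation invariant and obeys a
Parseval identity $\|f\|^2 = \sum_l \|F_l\|^2$ for band-limited inputs.

The mode balance classifies polarity: a dominant $l=1$ mode (cap-like
patterns) means vectorial polarity; vanishing odd modes with a dominant
$l=2$ mode (rings, antipodal caps) means nematic polarity.

**Quadrature.** The default grid (`sphere_grid_gauss(L)`) crosses
Gauss–Legendre nodes in $\cos\theta$ with a uniform longitude grid
($L{+}1 \times 2L{+}1$ points), which integrates products of two degree-$L$
functions exactly; Parseval residuals for band-limited patterns are then at
rounding level ($<10^{-13}$ in practice). A Fibonacci equal-area grid
(`sphere_grid_fibonacci()`) is provided for workflows that prefer uniform
point budgets; its quadrature is approximate, so exactness-sensitive
operations default to the Gauss grid. The default band limit is $L = 16$:
the classification only uses $l \le 4$, and 16 leaves headroom for spectral
diagnostics.

**Band limits on sampled data.** A pattern with $n$ samples cannot resolve
more than $(L+1)^2 \le n$ coefficients; `sph_decompose()` warns (but does
not fail) beyond that.

## Radial projection of star-convex surfaces

`project_to_sphere()` maps a labelled triangle mesh (marker density per
face) to a surface pattern: each face contributes a sample at the unit
radial direction of its centroid, with weight equal to the **exact solid
angle** the face subtends at the projection center (Van Oosterom–Strackee
spherical-triangle formula) and value equal to the face density. Because
weights are solid angles, a uniform marker on *any* star-convex shape
projects to a uniform pattern — shape anisotropy is decoupled from pattern
anisotropy by construction (verified against a 2:1:1 ellipsoid, where
spurious anisotropic power stays below $10^{-3}$ relative).

Star-convexity is checked explicitly by casting 642 quasi-uniform probe rays
(an icosphere vertex set) from the center; any ray with more than one
interior triangle hit rejects the surface with the offending directions
reported. The projection center defaults to the area-weighted surface
centroid (`estimate_center()`); the choice of center is not canonical for
real cells, so it can always be supplied explicitly. Marker intensities can
be binarized (`binarize = t`) into an apical indicator; values are otherwise
treated as given densities. Minimal ASCII OBJ/PLY readers with a face-keyed
CSV sidecar cover mesh ingestion.

## Nematic tensor, axes, and equivalent cuboids

The nematic tensor of a pattern is
$$\mathbf A = \tfrac12 \sum_k w_k v_k\,(3\,\mathbf d_k\otimes\mathbf d_k - \mathbf 1),$$
symmetric and traceless, and depends only on the $l=2$ mode (adding $l=1$ or
$l=3$ content leaves it unchanged within $10^{-8}$; the Frobenius norm obeys
$\|\mathbf A\|_F^2 = \tfrac{24\pi^2}{5}\|F_2\|^2$, frozen as a regression
value). Eigenvalues are ordered $\alpha_1 \ge \alpha_3 \ge \alpha_2$: the
eigenvector `a1` of $\alpha_1$ is the *bipolar axis* (smallest moment of
inertia), `a2` of $\alpha_2$ the *ring axis* (largest moment of inertia;
normal of a ring-like band). On the unit sphere the traceless inertia tensor
is exactly $-\tfrac23\mathbf A$.

**Degeneracy and determinism.** Idealized rings and bipolar patterns are
exactly degenerate in one eigenvalue pair. Pairs within $10^{-8}\,\|A\|$ are
flagged; the returned frame is made deterministic by the symmetric
eigensolver's ordering plus sign canonicalization (first non-zero component
positive). Axis signs are cosmetic: every order parameter is sign-invariant
by construction (D2h symmetry).

**Equivalent cuboid.** For visualization, `equivalent_cuboid()` returns the
solid cuboid whose traceless inertia matches $-\tfrac23 \mathbf A$. The
scale convention matches the full second-moment tensor of the unit-sphere
distribution (trace equal to mass), giving squared half-lengths
$h_i^2 = 1 + 2\alpha_i/\text{mass}$, then rescales to unit volume (unit
longest edge when a side is zero). This makes the representable set
$\alpha_i/\text{mass} \ge -\tfrac12$, with idealized rings exactly on the
boundary (zero-thickness, "flat" cuboids); tensors outside the set raise an
error naming the bound. Longest edge ∥ `a1`, shortest ∥ `a2`; face colors
red/green/blue record `a1`/`a3`/`a2`.

## Classical OOP and co-orientational order parameters

Each biaxial object is a tripod of sign-free orthonormal axes
$(\mathbf n, \mathbf m, \mathbf l)$, summarized by the traceless tensors
$\mathbf Q = \tfrac12(3\mathbf n\otimes\mathbf n - \mathbf 1)$ and
$\mathbf B = \tfrac32(\mathbf l\otimes\mathbf l - \mathbf m\otimes\mathbf m)$.

**OOP.** `oop()` computes the classical biaxial order parameters
$(S, P, D, C)$ as averaged direction cosines against the eigenframe of the
ensemble-averaged $\langle\mathbf Q\rangle$. Inside (near-)degenerate
eigenvalue clusters of $\langle\mathbf Q\rangle$ the frame is refined by
diagonalizing the restriction of $\langle\mathbf B\rangle$ — without this,
$C$ would be undefined for perfectly uniaxial ensembles. The axis ordering
follows the Zannoni convention: an exhaustive search over the 6×6
permutations of principal and reference axes selects $|S|$ maximal, then
$P \ge 0$, then $C \ge 0$, remaining ties broken lexicographically — finite
and deterministic. A flag reports when $\langle\mathbf Q\rangle$ and
$\langle\mathbf B\rangle$ fail to co-diagonalize (relative commutator norm
above 0.05 with both norms above 0.05; the floor avoids flagging isotropic
noise).

**COOP.** `coop()` evaluates the same four direction-cosine averages with
*prescribed per-object reference frames* $(\mathbf w^{(i)}, \mathbf v^{(i)},
\mathbf u^{(i)})$, derived from reference nematic tensors by the fixed
eigenvalue ordering $\varepsilon_1 \ge \varepsilon_3 \ge \varepsilon_2$ with
$\mathbf w = \mathbf e_2$, $\mathbf v = \mathbf e_1$, $\mathbf u = \mathbf
e_3$. Because no data-dependent permutation is involved, COOP vary
continuously along smooth parameter paths; `continuity_diagnostic()`
tabulates both sets along a path and exhibits the contrast (COOP steps stay
below 0.05 on a 100-point path across a permutation switch, while OOP jump
by order one). Bounds: $\text{co-}S \in [-\tfrac12, 1]$,
$|\text{co-}P|, |\text{co-}D| \le \tfrac32$, $|\text{co-}C| \le 1$.

For uniaxial ensembles, $S$ and $P$ can equivalently be computed from the
second spherical mode of the axis distribution expanded in the reference
frame ($S = \sqrt{4\pi/5}\,f_{20}$, $P = \sqrt{24\pi/5}\,\mathrm{Re}
f_{22}$ with $z = \mathbf w$, $x = \mathbf u$, $y = \mathbf v$); this serves
as an independent oracle in the tests.

**Uncertainty.** Standard errors come from a nonparametric bootstrap (1000
resamples by default, locally seeded so the global RNG is untouched).

**Local reference field.** `local_reference_field()` builds per-cell
reference tensors as a punctured Gaussian average
$\mathbf E^{(i)} \propto \sum_{j\ne i} e^{-|\mathbf x_j-\mathbf x_i|^2/2\sigma^2}\mathbf A^{(j)}$
with $\sigma = 20\,\mu m$ by default and the kernel truncated at $4\sigma$
for speed. Puncturing excludes exactly the central cell ($j = i$), not a
radius. Cells without neighbours in the kernel support are flagged
`isolated`; reference tensors with eigenvalue gaps below $10^{-6}$ relative
are flagged `degenerate` and excluded downstream with a logged count
(synthetic idealizations hit exact degeneracy, so this must be explicit
rather than silent).

## Network anisotropy

`network_tensor()` summarizes the local orientation statistics of a segment
network (e.g. sinusoid centerlines) in a spherical region of interest:
$$\mathbf S = \sum_k w_k l_k (\mathbf d_k\otimes\mathbf d_k - \tfrac13\mathbf 1),$$
with binary weights selecting segments whose **midpoint** lies within the
radius (default $20\,\mu m$) and normalization $\sum_k w_k l_k = 1$.
Midpoint membership (rather than clipping partial overlaps) is the
documented choice; the tensor is then exactly invariant under subdivision of
segments into collinear halves whenever both halves stay in range, which
holds in the fine-segment limit of centerline data. The eigen-axes are `s1`
(largest eigenvalue, preferred segment orientation), `s2` (smallest, the
layer normal of a layered network) and `s3 = s1 × s2`. In-plane isotropy
(layered but without a preferred axis) makes `s1` degenerate; this is
flagged, never silently broken.

## The minimal co-alignment model

The interaction between a cell's ring axis and the local network tensor is
the leading-order symmetric coupling
$$H = -\lambda\,\alpha_2\,(\mathbf a_2\otimes\mathbf a_2):\mathbf S,$$
with $\lambda$ a dimensionless coupling in units of an effective temperature
and $\alpha_2 = -0.19$ the mean ring-axis eigenvalue of the polarity
tensors (the hepatocyte value; configurable). Orientations are drawn from
$p \propto e^{-H}$ by **exact rejection sampling** from a uniform spherical
proposal with the analytic envelope $\exp(\max_i \lambda\alpha_2
\varepsilon_i)$ — the density is bounded, so the sampler is
distribution-exact, and the empirical moments are validated against direct
quadrature of the density. Since the modelled objects are uniaxial, the
second tripod axis is completed uniformly at random in the orthogonal
plane; this convention is what makes the model's prediction for co-C
coincide with co-D across the sweep.

Two alternative couplings are available: the bipolar axis
($-\lambda\alpha_1 (\mathbf a_1\otimes\mathbf a_1):\mathbf S$) and the full
tensor ($-\lambda\,\mathbf A:\mathbf S$, sampled over uniform rotations with
the rearrangement-inequality envelope). The mean eigenvalue weights
$\alpha_1$ (default 0.38, a generic prolate value of twice $|\alpha_2|$) and
$\alpha_3 = -\alpha_1-\alpha_2$ are configuration fields, since only
$\alpha_2$ has an established empirical value.

Because $\alpha_2 < 0$, the energy is minimized with $\mathbf a_2$ along the
smallest-eigenvalue axis of $\mathbf S$ (the plane axis `s2`); flipping the
sign of $\alpha_2$ switches the attractor to the largest-eigenvalue axis.

**Sweeps and coupling recovery.** `coop_sweep()` computes COOP between
sampled tripods and the reference frame of a fixed tensor over a λ grid.
All grid points share one seed (*common random numbers*), so the sweep
curve is smooth and strictly monotone in practice and `fit_lambda()` —
isotonic regression on co-S(λ) followed by inverse interpolation — recovers
the coupling of an ensemble drawn with the same seed and size exactly at
grid points. For ensembles with independent sampling noise, the precision
of any λ estimate is limited by the information content of the data: with
$|\alpha_2| \approx 0.19$ and a normalized network tensor, the slope of
co-S(λ) near λ = 2 is only ≈ 0.015 per unit λ, so a few thousand cells
determine λ to roughly ±0.5 — a genuine property of the weak-coupling
regime, not of the estimator. `fit_lambda()` also reports the λ interval in
which all four simulated COOP fall within observed ± 3 combined standard
errors. The default sweep reference tensor has eigenvalues
$(\varepsilon_1, \varepsilon_3, \varepsilon_2) = (0.4, -0.1, -0.3)$, a
generic biaxial shape.

## Synthetic data: what it emulates and what it does not

The `synth_*` generators produce every input the pipeline consumes, each
deterministic under its seed and returning its ground truth:

* `synth_pattern()` — von Mises–Fisher caps (vectorial prototype), Watson
  girdles/bipolar densities (nematic prototypes), uniform, mixtures;
  `concentration = Inf` gives singular idealizations (point caps, delta
  rings on equally spaced nodes) whose tensors take closed-form values
  exactly. Default concentration 4 (clearly localized but well resolved at
  the default grid).
* `synth_tripods()` — the six prototype biaxial distributions (prolate,
  phase-biaxial, oblate, prolate with free second axis, molecular-biaxial,
  molecular-D) with a concentration parameter controlling order strength.
  Axis noise is von Mises–Fisher for the first axis and a bimodal
  von Mises density $\propto e^{b\cos 2\psi}$ for in-plane biases, which
  respects the nematic (antipodal) symmetry.
* `synth_layered_network()` — segments confined to parallel layers; with
  zero in-plane bias the in-plane angles are *equally spaced*, so the
  closed-form layered tensor $\mathrm{diag}(\tfrac16,\tfrac16,-\tfrac13)$
  is reproduced exactly rather than up to sampling noise.
* `synth_toy_lobule()` — an end-to-end fixture: ~1850 cells on a jittered
  lattice in a cylindrical shell, a layered segment network whose layer
  normal is tangent to circles around the central axis (a curved director
  field, as across a liver lobule), and polarity sampled from the
  co-alignment model at a known λ against the *measured* local network
  tensor of each cell, closing the generative loop the pipeline is asked to
  invert.

The generators emulate geometry, symmetry and order strength — not
realistic hepatocyte shapes, real vessel-network topology, segmentation
error, or imaging noise. Passing tests therefore demonstrate correctness of
the estimators and the internal consistency of the pipeline on ideal and
noisy-but-well-specified inputs; they do not certify performance on
real-tissue reconstructions, whose ingestion formats are supported but whose
data are not bundled.

## Numerical choices and limitations

* Problem sizes in tests and the acceptance script: ensembles of $10^4$
  tripods for isotropy/moment checks, $10^4$ model samples per sweep point,
  a ~1850-cell lobule; these give Monte-Carlo standard errors well below the
  asserted tolerances while keeping full runs to a few minutes.
* Tolerances: exact identities (Parseval, closed-form tensors, rotation
  invariance, subdivision invariance) are asserted at $10^{-8}$–$10^{-12}$;
  stochastic quantities at 3 Monte-Carlo standard errors.
* Degenerate inputs are first-class: zero tensors return deterministic
  frames with flags; empty neighborhoods and isolated cells are flagged or
  error with named stages; the pipeline excludes flagged rows and logs
  counts.
* Rotation machinery for spherical harmonics (Wigner D matrices) is not
  implemented; rotation invariance is validated numerically.
* The Mollweide map solves its auxiliary angle by Newton iteration
  (50-iteration cap, $10^{-14}$ step tolerance, exact poles) and is exactly
  equal-area; only coordinates are computed, plotting stays in `ggplot2`.
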