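---
title: "Angle-damped dihedral torsion potentials: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angle-damped dihedral torsion potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtorsion)
```

## The model problem

A directed dihedral $\phi_{ABCD} \in (-\pi, \pi]$ is the signed angle
between the ABC and BCD planes of four bonded atoms. It is undefined when
either contained bond angle $\theta_{ABC}$ or $\theta_{BCD}$ equals $0$ or
$\pi$. Two consequences shape everything in this package:

1. **Branch equivalency.** The coordinate pairs $(\theta, \phi)$ and
   $(2\pi - \theta, \phi \pm \pi)$ describe the same conformation, so any
   torsion potential that depends on bond angles must return identical
   energies on both branches. `branch_select()` folds raw coordinates onto
   the principal branch $\theta \in [0, \pi]$, and every angle-damped
   potential here satisfies the equivalency to $10^{-10}$ (property-tested
   on random draws).
2. **Damping at linearity.** Every $\phi$-dependent term must be
   extinguished as a contained angle approaches $\pi$, with a leading-order
   zero of degree $n$ for multiplicity-$n$ modes, or the forces are
   discontinuous exactly where linear excursions happen in dynamics.

## Elementary angle-damping functions

The bond angle enters through the *kangal* proxy
$x = \cos(\theta/2) \in [1, 0]$, which satisfies
$\sin\theta = 2x\sin(\theta/2)$ and flips sign under the branch map
$\theta \to 2\pi - \theta$, giving the parity bookkeeping that branch
equivalency requires. Multiplicity-specific polynomials

$$P_1 = \tfrac14 x + \tfrac34 x^3,\quad
  P_2 = \tfrac34 x^2 + \tfrac14 x^4,\quad
  P_3 = \tfrac32 x^3 - \tfrac34 x^5 + \tfrac14 x^7,\quad
  P_4 = \tfrac52 x^4 - \tfrac94 x^6 + \tfrac34 x^8$$

are fixed uniquely by: $P_n[1] = 1$, $P_n[\varepsilon] \propto
\varepsilon^n$, definite parity, and asymptotic matching of their series
about $x = 1$ through second order (so all multiplicities damp alike for
acute angles). The saturating map $Q[x] = \tanh(Kx)/\tanh(K)$ flattens the
factors toward 1 in the acute regime. $K$ is not a free parameter: matching
the first three non-zero Maclaurin terms of $\tanh$ to its saturated value
gives the quintic $x - x^3/3 + 2x^5/15 = 1$, whose unique real root
$x_\mathrm{root} = 1.244460035526845$ (the other four roots are complex; we
verify this via `polyroot`) sets $K = x_\mathrm{root}/P_1[\cos(\pi/4)]$ so
that saturation is reached at the perpendicular bond angle. The package
computes $K$ at load time by bracketed root finding plus Newton polishing
and aborts if $\tanh K$ deviates from its reference value
$0.992861208914406$ by more than $10^{-12}$.

The damping factors are then $f_0 = 1$ and
$f_n(\theta) = Q[P_n(x)]$ for $n = 1\ldots4$: monotone decreasing, equal to
1 at $\theta = 0$ and 0 at $\theta = \pi$. Ratios $f_n/f_{\lfloor n/2
\rfloor}$ appear inside the models; to avoid $0/0$ near linearity,
`damping_ratio()` switches to the exact leading-order expansions
($f_2/f_1 \to 3x$, $f_3/f_1 \to 6x^2$, $f_4/f_2 \to \tfrac{10}{3}x^2$) once
$x \le 10^{-4}$. The threshold is our choice (the continuity mismatch there
is below $10^{-6}$ relative, verified numerically); any value in
$[10^{-6}, 10^{-3}]$ would do.

## The torsion models

**ADDT.** Seven independent modes about the equilibrium dihedral
$\phi_{eq}$: cosine modes $m = 1..4$,

$$U_m = k_m\,\bigl(J_m - H_m\cos m(\phi - \phi_{eq})\bigr),$$

with $H_m$ the product of per-angle damping ratios
$(f_m/f_m^{eq})_{ABC}(f_m/f_m^{eq})_{BCD}$, and $J_m$ a per-angle
completing-the-squares bound
$A_m = \tfrac12[(f_j/f_j^{eq})^2 + ((f_j^{eq} f_m)/(f_m^{eq} f_j))^2]$,
$j = \lfloor m/2 \rfloor$, so that $J_m \ge H_m$ by the AM–GM inequality
with equality exactly at the equilibrium angles. $J_m - H_m$ is the
**torsion offset potential** (TOP): a $\phi$-independent, non-negative
angle-dependent energy that explains why an angle-scan energy curve can
have a non-zero slope at $\theta = \pi$ even though a pure bending
potential must not. The index choice $j = \lfloor m/2 \rfloor$ keeps the
TOP as small as feasible when the equilibrium angle is nearly linear
(choosing $j = 0$ or $m$ would make $1/f^{eq}$ factors blow up as
$\varepsilon^{-m}$).

Sine content enters through three orthogonal combinations — modes 5–7,
$\propto 3U_1^{\sin} - U_3^{\sin}$, $2U_2^{\sin} - U_4^{\sin}$,
$U_1^{\sin} + 3U_3^{\sin} - U_2^{\sin} - 2U_4^{\sin}$ with $U_n^{\sin} =
\sin n(\phi - \phi_{eq})$ — chosen so every mode has zero torsion force at
the equilibrium geometry without an external linear constraint. Each is
scaled by $1/\sqrt{10}$, $1/\sqrt 5$, $1/\sqrt{15}$ so its RMS amplitude
equals a single cosine's ($1/\sqrt 2$); the tests validate orthogonality
and normalization by quadrature rather than trusting the constants. Sine
modes are multiplied by the per-instance mirror descriptor $S$
(`s_instance()`, signum of $\sin\phi_{eq}$ by default, the smoothed
$\tanh(10^D \sin\phi_{eq})$ variant available), which is what lets two
mirror-image dihedral instances share one force-constant set: reflecting
the geometry maps $\phi \to -\phi$, $\phi_{eq} \to -\phi_{eq}$, $S \to -S$
and leaves every mode energy invariant.

**CADT** is ADDT with all damping frozen at 1 — appropriate when both
equilibrium angles are below 130°, where angles are stiff enough that
linear excursions are thermally inaccessible. It is exactly equivalent to a
Fourier series in $\phi - \phi_{eq}$ constrained to zero slope at
$\phi_{eq}$; `cadt_to_fourier()` performs the conversion and the
stationarity identity $\sum_n n\,b_n = 0$ falls out automatically.

**ADCO/CACO** impose even symmetry $U(\phi) = U(-\phi)$ for dihedrals whose
scans have no odd content. One force constant scales all modes; the
smart-selection coefficients $c_n$ fix the ratios (this reproduces the
training equilibrium dihedral more faithfully than independently fitted
per-mode constants). The ADCO mode is
$k\,c_n\,(H_n \cos n\phi - J_n \cos n\phi_{eq}^{train})$, which carries the
same TOP as the matched ADDT potential; the equivalence under the mapping
$k_n = -k\,c_n \cos n\phi_{eq}^{train}$ is property-tested.

**ADLD** covers equilibria with one or two linear contained angles, where
$\phi_{eq}$ does not exist and no equilibrium damping values may be divided
by. Even modes $n = 2j$ carry $(f_j^{ABC} f_j^{BCD})^2$ times
$(1 \mp \cos n\phi)$ and $S\sin n\phi$ terms; odd modes $n = 2j-1$ use the
completing-the-squares offset $\tfrac12[(f_{j-1}^{ABC} f_j^{BCD})^2 +
(f_j^{ABC} f_{j-1}^{BCD})^2]$, which bounds the combined damping $Q_n =
f_{j-1}^{ABC} f_j^{ABC} f_{j-1}^{BCD} f_j^{BCD}$, so the $k_{LD4}$ and
$k_{LD5}$ terms are non-negative everywhere (those constants, like
$k_{LD1}$ and $k_{LD2}$, are constrained $\ge 0$ in fitting). One subtlety:
for $j = 1$ the odd-mode offset does not vanish when only *one* angle is
linear — correctly so, since bending one angle of a linear molecule costs
energy at any value of the other; what does vanish at a linear angle is
every $\phi$-dependent factor, making the energy independent of the
then-undefined dihedral. The $n = 1$ terms arise only for double-linear
dihedrals anyway (`classify_linear_dihedral()` encodes the symmetry cases:
$\omega$-fold rotation axes keep only $n$ divisible by $\omega$; mirror
planes kill sine terms; accidental single-linear equilibria eliminate
$n = 1$). For acetylene, the single $k_{LD5}$ term penalizes cis-type
(bowl) bending and leaves the symmetric trans (wave) combination to the
bending potential — which is exactly the pattern in the benchmark
frequencies.

## Scan projection and smart selection

A torsion scan is a uniform grid of $T$ dihedral values over $(-\pi, \pi]$
with energies in kJ/mol. Its *norm* is the RMS deviation from the mean and
its *barrier* the max–min difference. The centered normalized curve is
projected onto orthonormalized projectors $\sqrt 2 P_m$ by discrete
quadrature; on a uniform grid the discrete orthogonality is exact provided
$T \ge 2 n_{max} + 2 = 10$ (the default $T = 18$ matches 20° scans), so
band-limited curves satisfy $\sum_m c_m^2 = 1$ exactly and generic curves
obey the Parseval bound $\sum c_m^2 \le 1$.

`sym_value` is the RMS of the antisymmetric part
$(E(\phi) - E(-\phi))/2$ divided by the norm: zero iff the scan is even.
Reflection about $\phi = 0$ is used because that is the mirror-image map; a
uniform grid over $(-\pi, \pi]$ is closed under negation, and periodic
linear interpolation covers reference energies off the grid. The
consistency identity $c^{DT}_n + c^{CO}_n \cos n\phi_{eq} = 0$ for even
curves is tested.

Smart selection is tiered on `sym_value`: $\le 0.01$ selects the
cosine-only basis with cutoff $|c_m| > 0.001$; $(0.01, 0.1]$ the DT basis
with cutoff $0.01$; above $0.1$ the DT basis with cutoff $0.1$ (a dropped
mode then costs at most $0.01$ of SumCSq). The comparison is strict, so a
coefficient exactly at the cutoff is kept. Model choice follows the
flowchart in `choose_model()`: ADLD within $\varepsilon = 0.03$ rad of a
linear equilibrium angle; otherwise angle-damped (ADDT/ADCO) when either
equilibrium angle is $\ge 130°$ (inclusive), constant-amplitude otherwise;
cosine-only iff `sym_value` $\le 0.01$.

Model curves use offset scenario 1 by default — zero at the training
equilibrium dihedral, which weights the low-energy geometries that dominate
thermal ensembles — while scenario 2 (average-matched) gives the exact
identity $R^2 = \mathrm{SumCSq}$ used as a cross-check.

## Constrained-angle prediction

`predict_constrained()` answers: given the optimized-geometry scan
projection, what does the torsion curve become when one bond angle is held
at a non-equilibrium value? Each multiplicity-$n$ cosine/sine amplitude is
rescaled by

$$r_n = \frac{f_n(\theta_{constr})}{f_n(\theta_{eq,1})}\cdot
        \frac{f_n(\theta_{other})}{f_n(\theta_{eq,2})},$$

the predicted norm is $\mathrm{norm}\cdot\sqrt{\sum_n r_n^2 (a_n^2 +
b_n^2)}$, coefficients are renormalized, and the minimum is located on a
0.01° grid of the rescaled curve. Working at the multiplicity level makes
the prediction identical between DT and CO bases for even scans. Since
$r_n$ grows faster for higher $n$ as an angle closes, the prediction
reproduces the characteristic growth of the $n = 2$ coefficient as a wide
angle is constrained shut — the geometric origin of "slip torsion", where a
constrained dihedral drives the wide angle toward linearity down the TOP
gradient. Constant-amplitude models predict unchanged amplitudes by
construction, and their returned minimum is the equilibrium-angle one.

## Flexibility models and normal modes

The engine sums harmonic stretches $\tfrac12 k (d - d_{eq})^2$, angle
bends, torsion terms (geometry measured through `branch_select`, with
numerically collinear geometries routed so that vanished damping factors
silence the undefined dihedral), and Coulomb + Lennard-Jones nonbonded
pairs with an exclusion list.

The bending potential deserves its own paragraph. The constraints it must
satisfy are: zero at $\theta_{eq}$; curvature exactly $k$ there (radians
treated as dimensionless, so $k$ is an energy); zero slope at
$\theta = \pi$ so the bending force is continuous across linear geometries
(any non-zero slope of an angle-scan curve at $\pi$ belongs to the TOP, not
the bend); and monotone increase away from the minimum. We implement these
as a tapered quadratic: with $w = \pi - \theta_{eq}$ and
$t = (\theta - \theta_{eq})/w$,
$U = \tfrac12 k w^2 (t^2 - \tfrac43 t^3 + \tfrac12 t^4)$, whose derivative
$k w\, t (1 - t)^2$ vanishes only at the minimum and at linearity; a
linear equilibrium angle (within 0.03 rad) uses the plain harmonic
$\tfrac12 k(\theta - \pi)^2$, which meets all the constraints already. The
benchmark vibrational frequencies pin the curvature behavior: they
reproduce to about 1 cm⁻¹ across all three fixture molecules, which is the
strongest check this surface admits.

Normal modes follow from the mass-weighted Hessian
$H_{ij}/\sqrt{m_i m_j}$, built by 4-point central finite differences of the
energy with step $10^{-3}$ Å (halving the step changes the fixture
frequencies by well under the test tolerance), symmetrized, and
diagonalized; eigenvalues convert to cm⁻¹ via CODATA constants, negative
eigenvalues are reported as negative wavenumbers and flagged. Modes with
$|\tilde\nu| < 15$ cm⁻¹ count as rigid-body — 6 for bent and 5 for linear
equilibrium structures on the fixtures — and frequencies within 0.5 cm⁻¹
are grouped as degenerate pairs (the linear fixtures show exact double
degeneracy of both bending pairs). Isotope substitution (HCCH → DCCD)
changes only the masses.

Internally everything is kJ/mol, Å, radians and amu; eV values are
converted at I/O boundaries with 1 eV = 96.485 kJ/mol. Degrees appear only
in files and user-facing arguments.

## Fitting

All five torsion models (and the stretch/bend terms) are linear in their
force constants at fixed mode shapes, so training reduces to bounded linear
least squares on relative energies $E_\mu - E_{opt}$, with the model's
reference energy pinned to the training set's optimum geometry (we pin
rather than re-locate the model optimum between iterations; for the
noiseless recovery tests and the benchmark fixtures the two coincide).
Bounds ($k \ge 0$ for stretches, bends, the single ADCO/CACO constant, the
four constrained ADLD constants, and a lone cosine torsion mode) are
enforced by variable splitting and a non-negative least-squares solve
(`pracma::lsqnonneg`); constants generated at zero are recovered exactly on
their bounds. LASSO-style shrinkage is deliberately not used: mode
selection is already handled by the smart-selection step, so the remaining
problem is a small, well-posed bounded regression. Rank deficiency is
detected by QR and reported rather than silently resolved. Goodness is
$R^2 = 1 - SSE/SST$ and $RMSE = \sqrt{SSE/N}$; norm-prediction accuracy
uses the mean (unsigned) log₁₀ error pair, with $MULE \ge |MLE|$.

## What the synthetic generators do and do not emulate

`synth_scan()` builds scans directly from mode coefficients plus optional
Gaussian noise: it emulates the *shape* content of quantum-chemistry
torsion scans (band-limited, known coefficients) and is therefore ideal for
round-trip and selection tests, but it contains no multi-coordinate
relaxation, no anharmonic coupling, and no correlated noise — so passing
projection tests says nothing about how well a four-mode truncation fits a
real molecule's scan. The fixture forcefields are rebuilt from *tabulated*
equilibrium internal coordinates and fitted constants; their frequencies
test the geometry builder, the model potentials, the Hessian and the unit
chain end-to-end, but the fixture constants themselves were fitted
elsewhere to coupled-cluster data, so agreement does not validate the
original fit, only this implementation of the models. Parameter-recovery
tests use noiseless synthetic energies on displaced-geometry sets; they
establish correctness of the linear algebra and constraints, not
robustness to real training-set noise (a reduced Monte-Carlo test covers
bias and spread at one noise level).

## Known limitations

- Dihedral/atom typing, pruning, and the classification of dihedrals as
  rotatable/hindered/nonrotatable are out of scope; the user supplies the
  term list and symmetry hints.
- `s_instance` option 3 (distinguishing mirror images when
  $\sin\phi_{eq} = 0$, required for ADLD sine terms) is accepted only as an
  externally supplied label; no pattern matcher is provided.
- Forces and Hessians are finite-difference only; analytic derivatives are
  not implemented.
- No periodic boundary conditions or Ewald electrostatics; nonbonded terms
  are intracluster with explicit exclusions and no cutoff.
- The constrained-angle minimum prediction reports the grid minimum of the
  amplitude-rescaled curve at fixed angles; it does not model relaxation of
  the unconstrained angle along the scan.
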