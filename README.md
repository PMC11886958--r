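# adtorsion

Angle-damped dihedral torsion model potentials for classical forcefields,
with torsion-scan mode projection, force-constant fitting, and harmonic
normal-mode analysis.

## The problem

A dihedral angle φ_ABCD becomes undefined when either of its contained bond
angles (θ_ABC, θ_BCD) reaches 180°. Conventional "dihedral-only" torsion
potentials U(φ) therefore have discontinuous forces — or outright wrong
dynamics — whenever a bond angle approaches linearity during molecular
dynamics or Monte Carlo sampling. This package implements a family of
*angle-damped* (Class B) torsion potentials U(θ_ABC, θ_BCD, φ) whose torsion
amplitudes are extinguished smoothly as a contained angle approaches
linearity, giving continuous derivatives of all orders, and which satisfy
the branch equivalency U(θ, φ) = U(2π − θ, φ ± π) required because those
coordinate pairs describe the same conformation.

The machinery, for forcefield developers and molecular-simulation method
builders:

- **Elementary angle-damping functions** `f_n(θ) = Q[P_n(cos(θ/2))]`, built
  from the *kangal* proxy variable x = cos(θ/2), asymptotically matched
  polynomials P₁–P₄ (one per torsion multiplicity), and the saturating map
  Q[x] = tanh(Kx)/tanh(K). The matching constant K is derived at load time
  from the unique real root x_root = 1.244460035526845 of
  x − x³/3 + 2x⁵/15 = 1 and satisfies tanh K = 0.992861208914406.
- **Five torsion model potentials**:
  - `ADDT` — seven angle-damped modes (4 cosine + 3 orthogonal sine
    combinations) about the equilibrium dihedral, including the
    non-negative **torsion offset potential** (TOP) that shifts the energy
    as bond angles deform and gives rise to the "slip torsion" phenomenon;
  - `CADT` — its constant-amplitude limit (all damping frozen at 1),
    equivalent to a constrained Fourier series;
  - `ADCO` / `CACO` — cosine-only variants for dihedrals whose torsion
    potential is an even function of φ;
  - `ADLD` — the linear-dihedral potential for equilibria containing one or
    two linear bond angles, built by completing the squares with no
    division by equilibrium damping values.
- **Torsion-scan projection** onto orthonormal mode bases, the `sym_value`
  odd-content descriptor, SumCSq and R² bookkeeping, tiered *smart mode
  selection*, a model-selection flowchart (`choose_model`), and prediction
  of how the torsion norm, mode coefficients and minimum location change
  when a bond angle is constrained away from equilibrium.
- **A flexibility-model engine** (harmonic stretches, an angle-bending
  potential with zero slope at θ = π, torsions, Coulomb + Lennard-Jones
  nonbonded terms) with finite-difference forces and mass-weighted Hessian
  normal-mode frequencies in cm⁻¹.
- **Bounded least-squares fitting** of force constants to training-set
  relative energies, with the non-negativity constraints the models
  require.
- **Fixtures** rebuilding benchmark forcefields for isocyanic acid (HNCO),
  hydrogen peroxide (HOOH) and acetylene (HCCH / DCCD) from tabulated
  internal coordinates and constants.

## Worked example

Project a torsion scan, pick modes, and predict the effect of closing a
bond angle:

```r
library(adtorsion)

# a single-cosine-mode dihedral: torsion norm 5.23 kJ/mol, phi_eq = 180 deg
scan <- synth_scan(c(1), basis = "DT", norm = 5.23, t_points = 18)
sel <- smart_select(scan)
sel$sym_value          # 0            (even curve)
sel$basis              # "CO"         (cosine-only basis selected)
sel$kept               # 1            (single mode kept)

# close the wide equilibrium angle (172.98777 deg) to 165 deg
proj <- project_scan(scan, "DT")
pred <- predict_constrained(proj, deg2rad(165), deg2rad(123.9),
                            deg2rad(c(172.98777, 123.57915)), model = "ADDT")
pred$norm              # 11.48503     kJ/mol: the torsion stiffens 2.2-fold
pred$ratios[1]         # 2.195991     mode-1 damping amplitude ratio

# vibrational frequencies of the isocyanic acid ADDT forcefield
fx <- make_fixture("HNCO", "ADDT")
normal_modes(fx$model, fx$structure)
#> vibrational frequencies (cm^-1): 3616 2278 1160 789 574 542
#> near-zero (rigid-body) modes: 6
```

The predicted norm 11.49 kJ/mol says that constraining the NCO angle 8°
below its near-linear equilibrium more than doubles the RMS torsion energy
— the angle-damping ratios, not new fitting, produce this. The six
frequencies are the HN stretch, the two NCO-frame stretches, two in-plane
bends and the torsion; the in-plane bends take their restoring force partly
from the torsion offset potential, which is why no NCO bend term appears in
the model.

A command-line launcher is installed at `exec/torsiontool`
(`project-scan`, `select-modes`, `predict-norm`, `fit`, `frequencies`), e.g.

```sh
Rscript $(Rscript -e 'cat(find.package("adtorsion"))')/exec/torsiontool \
    frequencies --fixture HNCO --out report.json
```

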