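# Flexibility-model assembly: energies, forces, Hessians and harmonic
# normal-mode analysis.
#
# All model parameters are stored in kJ/mol (lengths angstrom, angles
# radians); eV inputs are converted at construction.

.eps_linear_default <- 0.03

#' Harmonic bond-stretch energy
#' @param d bond length(s), angstrom
#' @param k force constant, energy/angstrom^2 (`k >= 0`)
#' @param d_eq equilibrium bond length, angstrom
#' @return `0.5 k (d - d_eq)^2`
#' @export
stretch_energy <- function(d, k, d_eq) {
  if (k < 0) stop("stretch_energy: k must be >= 0")
  0.5 * k * (d - d_eq)^2
}

#' Angle-bending energy with a flattened approach to linearity
#'
#' A bending potential obeying the constraints a torsion-offset-aware
#' forcefield places on the pure bend term: zero at `theta_eq`, curvature
#' exactly `k_angle` at `theta_eq` (radians treated as dimensionless), zero
#' slope at `theta = pi` so the bending force is continuous across linear
#' geometries, and monotone increase away from the minimum.  For a bent
#' equilibrium the quadratic is tapered by a quartic in
#' `t = (theta - theta_eq)/(pi - theta_eq)`:
#' `U = 0.5 k w^2 (t^2 - (4/3) t^3 + (1/2) t^4)`, whose derivative
#' `k w t (1 - t)^2` vanishes only at the minimum and at linearity.  When
#' the equilibrium itself is linear (within `eps_linear`) the potential is
#' the plain harmonic `0.5 k (theta - pi)^2`, which already has zero slope
#' at pi.
#'
#' @param theta bond angle(s), radians in `[0, pi]`
#' @param k_angle force constant (energy; `>= 0`)
#' @param theta_eq equilibrium angle, radians
#' @param eps_linear tolerance classifying `theta_eq` as linear
#' @return energy, vectorized over `theta`
#' @export
manz_bend_energy <- function(theta, k_angle, theta_eq,
                             eps_linear = .eps_linear_default) {
  if (k_angle < 0) stop("manz_bend_energy: k_angle must be >= 0")
  if (any(theta < -1e-9 | theta > pi + 1e-9)) {
    stop("manz_bend_energy: theta outside [0, pi]")
  }
  if (pi - theta_eq < eps_linear) {
    return(0.5 * k_angle * (theta - pi)^2)
  }
  w <- pi - theta_eq
  t <- (theta - theta_eq) / w
  0.5 * k_angle * w^2 * (t^2 - (4 / 3) * t^3 + 0.5 * t^4)
}

#' Nonbonded (Coulomb + Lennard-Jones) energy
#'
#' Sums over all unordered intracluster atom pairs not listed in the
#' exclusion set: `U = C q_A q_B / d + eps_AB ((d_AB/d)^12 - 2 (d_AB/d)^6)`
#' with the Lennard-Jones minimum at `d = d_AB` of depth `-eps_AB`.
#'
#' @param structure an [atomic_structure()]
#' @param charges per-atom charges, e
#' @param lj_epsilon symmetric matrix of well depths, kJ/mol (or `NULL`)
#' @param lj_d symmetric matrix of minimum-energy distances, angstrom
#' @param exclusions two-column matrix of excluded atom pairs (self, 1-2,
#'   1-3 and optionally 1-4 pairs); symmetric by construction
#' @return total nonbonded energy, kJ/mol
#' @export
nonbonded_energy <- function(structure, charges, lj_epsilon = NULL,
                             lj_d = NULL, exclusions = NULL) {
  X <- structure$coords
  n <- nrow(X)
  excl <- matrix(FALSE, n, n)
  diag(excl) <- TRUE
  if (!is.null(exclusions) && length(exclusions)) {
    exclusions <- as.matrix(exclusions)
    excl[exclusions] <- TRUE
    excl[exclusions[, 2:1, drop = FALSE]] <- TRUE
  }
  kc <- unit_constants$coulomb_ev_ang * unit_constants$ev_to_kjmol
  U <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (excl[a, b]) next
      d <- sqrt(sum((X[a, ] - X[b, ])^2))
      U <- U + kc * charges[a] * charges[b] / d
      if (!is.null(lj_epsilon)) {
        if (is.na(lj_epsilon[a, b]) || is.na(lj_d[a, b])) {
          stop("nonbonded_energy: missing LJ parameters for pair ", a, "-", b)
        }
        s <- (lj_d[a, b] / d)^6
        U <- U + lj_epsilon[a, b] * (s^2 - 2 * s)
      }
    }
  }
  U
}

# --- term constructors ------------------------------------------------------

.conv_k <- function(k, units) if (units == "eV") convert_energy(k, "eV", "kJmol") else k

#' Flexibility-model terms
#'
#' Constructors for the four term kinds of a [flexibility_model()].  Force
#' constants are given in `units` (converted to kJ/mol internally); torsion
#' parameters are `torsion_params` objects whose force constants must
#' already be in kJ/mol (use [convert_energy()]).
#'
#' @param atoms atom indices (2 for stretch, 3 for bend, 4 for torsion)
#' @param k force constant in `units`
#' @param d_eq equilibrium length, angstrom
#' @param units `"kJmol"` or `"eV"`
#' @return a `flex_term` list
#' @export
flex_stretch <- function(atoms, k, d_eq, units = "kJmol") {
  stopifnot(length(atoms) == 2L, k >= 0)
  list(kind = "stretch", atoms = as.integer(atoms),
       k = .conv_k(k, units), d_eq = d_eq)
}

#' @rdname flex_stretch
#' @param theta_eq equilibrium angle, radians
#' @export
flex_bend <- function(atoms, k, theta_eq, units = "kJmol") {
  stopifnot(length(atoms) == 3L, k >= 0)
  list(kind = "bend", atoms = as.integer(atoms),
       k = .conv_k(k, units), theta_eq = theta_eq)
}

#' @rdname flex_stretch
#' @param params a `torsion_params` object (constants in kJ/mol)
#' @export
flex_torsion <- function(atoms, params) {
  stopifnot(length(atoms) == 4L, inherits(params, "torsion_params"))
  list(kind = "torsion", atoms = as.integer(atoms), params = params)
}

#' @rdname flex_stretch
#' @param charges per-atom charges, e
#' @param lj_epsilon,lj_d symmetric LJ parameter matrices (kJ/mol, angstrom)
#' @param exclusions two-column matrix of excluded pairs
#' @export
flex_nonbonded <- function(charges, lj_epsilon = NULL, lj_d = NULL,
                           exclusions = NULL) {
  list(kind = "nonbonded", charges = charges, lj_epsilon = lj_epsilon,
       lj_d = lj_d, exclusions = exclusions)
}

#' Flexibility model
#'
#' A list of stretch/bend/torsion/nonbonded terms over one structure.
#'
#' @param terms list of `flex_term` objects
#' @return object of class `flexibility_model`
#' @export
flexibility_model <- function(terms) {
  structure(list(terms = terms), class = "flexibility_model")
}

# measure the angles and dihedral a torsion term needs, handling numerically
# collinear geometries (where the dihedral is undefined but every
# phi-dependent factor carries a vanishing damping amplitude)
.torsion_geometry <- function(structure, atoms) {
  th_abc <- bond_angle(structure, atoms[1:3])
  th_bcd <- bond_angle(structure, atoms[2:4])
  phi <- tryCatch(directed_dihedral(structure, atoms),
                  error = function(e) 0)
  list(th_abc = th_abc, th_bcd = th_bcd, phi = phi)
}

.term_energy <- function(term, structure) {
  switch(term$kind,
    stretch = stretch_energy(bond_length(structure, term$atoms), term$k,
                             term$d_eq),
    bend = manz_bend_energy(bond_angle(structure, term$atoms), term$k,
                            term$theta_eq),
    torsion = {
      g <- .torsion_geometry(structure, term$atoms)
      torsion_energy(term$params, g$th_abc, g$th_bcd, g$phi)
    },
    nonbonded = nonbonded_energy(structure, term$charges, term$lj_epsilon,
                                 term$lj_d, term$exclusions),
    stop("unknown term kind: ", term$kind))
}

#' Total flexibility-model energy
#' @param model a [flexibility_model()]
#' @param structure an [atomic_structure()]
#' @return energy in kJ/mol
#' @export
total_energy <- function(model, structure) {
  U <- 0
  for (term in model$terms) U <- U + .term_energy(term, structure)
  if (!is.finite(U)) stop("total_energy: non-finite energy (NaN geometry?)")
  U
}

.energy_of_coords <- function(model, structure) {
  force(model); force(structure)
  dims <- dim(structure$coords)
  function(v) {
    s <- structure
    s$coords <- matrix(v, dims[1], dims[2])
    total_energy(model, s)
  }
}

#' Atomic forces by central finite differences
#'
#' @param model a [flexibility_model()]
#' @param structure an [atomic_structure()]
#' @param step finite-difference step, angstrom
#' @return n x 3 matrix of forces (`-dU/dx`), kJ/mol/angstrom
#' @export
forces <- function(model, structure, step = 1e-5) {
  efun <- .energy_of_coords(model, structure)
  v <- as.vector(structure$coords)
  g <- vapply(seq_along(v), function(i) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + step
    vm[i] <- vm[i] - step
    (efun(vp) - efun(vm)) / (2 * step)
  }, numeric(1))
  -matrix(g, nrow(structure$coords), 3)
}

#' Cartesian Hessian by central finite differences of the energy
#'
#' @param model a [flexibility_model()]
#' @param structure an [atomic_structure()]
#' @param step finite-difference step, angstrom
#' @return symmetric 3n x 3n matrix, kJ/mol/angstrom^2 (coordinate order:
#'   all x, then all y, then all z, matching `as.vector(coords)`)
#' @export
hessian <- function(model, structure, step = 1e-3) {
  efun <- .energy_of_coords(model, structure)
  v <- as.vector(structure$coords)
  n <- length(v)
  H <- matrix(0, n, n)
  e0 <- efun(v)
  for (i in seq_len(n)) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + step; vm[i] <- vm[i] - step
    H[i, i] <- (efun(vp) - 2 * e0 + efun(vm)) / step^2
    if (i < n) {
      for (j in (i + 1):n) {
        vpp <- v; vpm <- v; vmp <- v; vmm <- v
        vpp[i] <- vpp[i] + step; vpp[j] <- vpp[j] + step
        vpm[i] <- vpm[i] + step; vpm[j] <- vpm[j] - step
        vmp[i] <- vmp[i] - step; vmp[j] <- vmp[j] + step
        vmm[i] <- vmm[i] - step; vmm[j] <- vmm[j] - step
        H[i, j] <- H[j, i] <-
          (efun(vpp) - efun(vpm) - efun(vmp) + efun(vmm)) / (4 * step^2)
      }
    }
  }
  (H + t(H)) / 2
}

#' Harmonic normal-mode analysis
#'
#' Builds the mass-weighted Hessian `H_ij / sqrt(m_i m_j)` by central finite
#' differences at the supplied geometry, diagonalizes it, and converts
#' eigenvalues to wavenumbers (negative eigenvalues are reported as negative
#' wavenumbers and flagged, not raised).  Near-zero modes (rigid-body
#' translation and rotation: 6 for nonlinear, 5 for linear equilibrium
#' structures) are separated by `zero_tol`.
#'
#' @param model a [flexibility_model()]
#' @param structure an [atomic_structure()] at (or near) the model
#'   equilibrium
#' @param masses optional mass override, amu (e.g. for isotope substitution)
#' @param step finite-difference step, angstrom
#' @param zero_tol rigid-body threshold on `abs(wavenumber)`, cm^-1
#' @param degeneracy_tol frequencies within this many cm^-1 are grouped as
#'   degenerate
#' @return object of class `normal_modes`: `frequencies` (cm^-1, vibrational
#'   modes sorted descending), `all_frequencies`, `vectors` (mass-weighted
#'   displacement directions, columns matching `all_frequencies`), `n_zero`,
#'   `n_imaginary`, `degenerate_groups`
#' @export
normal_modes <- function(model, structure, masses = NULL, step = 1e-3,
                         zero_tol = 15, degeneracy_tol = 0.5) {
  if (is.null(masses)) masses <- structure$masses
  H <- hessian(model, structure, step = step)
  mv <- rep(masses, times = 3)
  MW <- H / sqrt(outer(mv, mv))
  eig <- eigen((MW + t(MW)) / 2, symmetric = TRUE)
  wn <- mwh_eigenvalue_to_wavenumber(eig$values)
  o <- order(wn, decreasing = TRUE)
  wn <- wn[o]
  vec <- eig$vectors[, o, drop = FALSE]
  is_zero <- abs(wn) < zero_tol
  vib <- wn[!is_zero]
  groups <- list()
  if (length(vib)) {
    gi <- cumsum(c(TRUE, abs(diff(vib)) > degeneracy_tol))
    groups <- split(seq_along(vib), gi)
    groups <- groups[vapply(groups, length, 1L) > 1L]
  }
  structure(list(frequencies = vib, all_frequencies = wn, vectors = vec,
                 n_zero = sum(is_zero), n_imaginary = sum(wn < -zero_tol),
                 degenerate_groups = unname(groups)),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("vibrational frequencies (cm^-1):",
      paste(sprintf("%.0f", x$frequencies), collapse = " "), "\n")
  cat("near-zero (rigid-body) modes:", x$n_zero, "\n")
  if (x$n_imaginary > 0) cat("imaginary modes (negative):", x$n_imaginary, "\n")
  invisible(x)
}

#' Frequency report as a data frame
#' @param nm a `normal_modes` object
#' @return data frame with mode index and wavenumber
#' @export
frequency_table <- function(nm) {
  data.frame(mode = seq_along(nm$frequencies),
             wavenumber_cm1 = nm$frequencies)
}
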