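# The five Class B torsion model potentials.
#
# ADDT: angle-damped dihedral torsion (seven modes, torsion offset potential)
# CADT: constant-amplitude limit of ADDT (damping frozen at 1)
# ADCO: angle-damped cosine-only (even torsion potentials)
# CACO: constant-amplitude cosine-only
# ADLD: angle-damped linear dihedral (one or both equilibrium angles linear)
#
# All energies are in the unit of the supplied force constants; angles in
# radians.  Callers are expected to branch-select raw angles into [0, pi].

#' Mirror-image descriptor for sine torsion modes
#'
#' Sine (odd) torsion modes change sign under reflection; multiplying them
#' by a per-instance descriptor lets mirror-image dihedral instances share
#' one force-constant set.  Option 1 is the discrete signum of
#' `sin(phi_eq)`; option 2 the smoothed `tanh(10^D sin(phi_eq))`, where `D`
#' selects the decimal place at which smoothing acts.
#'
#' @param phi_eq equilibrium dihedral(s), radians in `(-pi, pi]`
#' @param option 1 (signum, default) or 2 (smoothed)
#' @param D smoothing exponent for option 2
#' @return value(s) in `[-1, 1]`
#' @export
s_instance <- function(phi_eq, option = 1L, D = 2) {
  s <- sin(phi_eq)
  if (option == 1L) {
    out <- sign(s)
    out[abs(s) < 1e-15] <- 0
    out
  } else if (option == 2L) {
    tanh(10^D * s)
  } else {
    stop("s_instance: option must be 1 or 2 (option 3 labels are supplied ",
         "externally)")
  }
}

# normalization constants making each sine-combination mode have RMS
# deviation 1/sqrt(2), i.e. the RMS amplitude of a single cosine
.mode_norm <- c(m5 = sqrt(10), m6 = sqrt(5), m7 = sqrt(15))

#' Dihedral-torsion (DT) mode basis functions
#'
#' The seven independent torsion modes of a rotatable dihedral, relative to
#' the reference `phi_eq`.  Modes 1-4 are the cosine family
#' `G_m = 1 - cos(m (phi - phi_eq))`; modes 5-7 are the orthogonal sine
#' combinations `(3 U1 - U3)/sqrt(10)`, `(2 U2 - U4)/sqrt(5)` and
#' `(U1 + 3 U3 - U2 - 2 U4)/sqrt(15)` with `U_n = sin(n (phi - phi_eq))`.
#' Every mode has zero slope at `phi = phi_eq`; every projector `P_m`
#' (`G_m` minus its mean) has zero mean and RMS amplitude `1/sqrt(2)`.
#'
#' @param m mode number, 1 to 7
#' @param phi dihedral value(s), radians
#' @param phi_eq reference dihedral, radians
#' @return list with components `G` (mode potential) and `P` (zero-mean
#'   projector)
#' @export
dt_mode_basis <- function(m, phi, phi_eq) {
  if (!(length(m) == 1L && m %in% 1:7)) stop("dt_mode_basis: m must be 1..7")
  d <- phi - phi_eq
  if (m <= 4L) {
    G <- 1 - cos(m * d)
    P <- G - 1
  } else {
    G <- switch(m - 4L,
                (3 * sin(d) - sin(3 * d)) / .mode_norm[["m5"]],
                (2 * sin(2 * d) - sin(4 * d)) / .mode_norm[["m6"]],
                (sin(d) + 3 * sin(3 * d) - sin(2 * d) - 2 * sin(4 * d)) /
                  .mode_norm[["m7"]])
    P <- G
  }
  list(G = G, P = P)
}

#' Cosine-only (CO) mode basis functions
#'
#' The four even-function torsion modes
#' `G_n = cos(n phi) - cos(n phi_eq_training)` with projectors
#' `P_n = cos(n phi)`.
#'
#' @param n mode number, 1 to 4
#' @param phi dihedral value(s), radians
#' @param phi_eq_training training-set equilibrium dihedral, radians
#' @return list with components `G` and `P`
#' @export
co_mode_basis <- function(n, phi, phi_eq_training) {
  if (!(length(n) == 1L && n %in% 1:4)) stop("co_mode_basis: n must be 1..4")
  list(G = cos(n * phi) - cos(n * phi_eq_training), P = cos(n * phi))
}

# combined damping amplitude ratio H_n for one mode: equals one at the
# equilibrium angles and vanishes as either angle approaches linearity
.H_n <- function(n, th_abc, th_bcd, eq_abc, eq_bcd) {
  (damping_f(n, th_abc) / damping_f(n, eq_abc)) *
    (damping_f(n, th_bcd) / damping_f(n, eq_bcd))
}

# per-angle completing-the-squares factor of J_n, j = floor(n/2):
#   A_n = 1/2 [ (f_j/f_j_eq)^2 + ( (f_j_eq f_n) / (f_n_eq f_j) )^2 ]
# By AM-GM, A_n >= f_n/f_n_eq with equality at the equilibrium angle.  The
# ratio f_n/f_j is routed through the guarded damping_ratio near linearity.
.A_n <- function(n, th, eq) {
  j <- n %/% 2L
  fj <- damping_f(j, th)
  fj_eq <- damping_f(j, eq)
  fn_eq <- damping_f(n, eq)
  ratio_nj <- if (j == 0L) damping_f(n, th) else damping_ratio(n, th)
  0.5 * ((fj / fj_eq)^2 + ((fj_eq / fn_eq) * ratio_nj)^2)
}

#' Torsion offset potential for one cosine mode
#'
#' `TOP_n = J_n - H_n`, where `H_n` is the combined damping amplitude ratio
#' and `J_n` the completing-the-squares bound built from the ratios
#' `f_j/f_j_eq` and `f_n/f_j` with `j = floor(n/2)`.  `TOP_n >= 0`
#' everywhere, with equality exactly at the equilibrium angles; its slope at
#' a linear bond angle is generally non-zero, which is what lets an
#' angle-scan energy curve have non-zero slope at `theta = pi` even though
#' any valid angle-bending potential must have zero slope there.
#'
#' @param n cosine-mode multiplicity, 1 to 4
#' @param th_abc,th_bcd contained bond angles, radians in `[0, pi]`
#' @param eq_abc,eq_bcd equilibrium bond angles (both `!= pi`)
#' @return list with components `J`, `H`, `TOP` (vectorized over the angles)
#' @export
top_n <- function(n, th_abc, th_bcd, eq_abc, eq_bcd) {
  if (min(eq_abc, eq_bcd) <= 0 || max(eq_abc, eq_bcd) >= pi - 1e-9) {
    stop("top_n: equilibrium angles must lie strictly inside (0, pi); ",
         "use the ADLD potential for linear equilibrium angles")
  }
  J <- .A_n(n, th_abc, eq_abc) * .A_n(n, th_bcd, eq_bcd)
  H <- .H_n(n, th_abc, th_bcd, eq_abc, eq_bcd)
  list(J = J, H = H, TOP = J - H)
}

# ---------------------------------------------------------------------------
# parameter containers

.norm_kmodes <- function(k_modes, n = 7L) {
  k <- numeric(n)
  if (!is.null(names(k_modes)) && any(names(k_modes) != "")) {
    idx <- as.integer(sub("^m", "", names(k_modes)))
    k[idx] <- as.numeric(k_modes)
  } else {
    k[seq_along(k_modes)] <- as.numeric(k_modes)
  }
  k
}

#' ADDT torsion parameters
#'
#' @param phi_eq equilibrium dihedral, radians in `(-pi, pi]`
#' @param theta_eq_abc,theta_eq_bcd equilibrium contained bond angles,
#'   radians, both strictly inside `(0, pi)`
#' @param k_modes numeric vector of force constants; either length 7
#'   (modes 1-7) or named like `c(m1 = ..., m5 = ...)`
#' @param s_inst mirror-image descriptor in `[-1, 1]`; default from
#'   [s_instance()] option 1
#' @return object of class `c("addt_params", "torsion_params")`
#' @export
addt_params <- function(phi_eq, theta_eq_abc, theta_eq_bcd, k_modes,
                        s_inst = s_instance(phi_eq)) {
  if (min(theta_eq_abc, theta_eq_bcd) <= 0 ||
      max(theta_eq_abc, theta_eq_bcd) >= pi - 1e-9) {
    stop("addt_params: equilibrium angles must be non-linear (use ADLD)")
  }
  k <- .norm_kmodes(k_modes)
  active <- which(k != 0)
  if (length(active) == 1L && active <= 4L && k[active] < 0) {
    warning("single active cosine mode with negative force constant: the ",
            "equilibrium geometry is not an energy minimum of this term")
  }
  structure(list(phi_eq = phi_eq, theta_eq_abc = theta_eq_abc,
                 theta_eq_bcd = theta_eq_bcd, k = k, active = active,
                 s_instance = s_inst),
            class = c("addt_params", "torsion_params"))
}

#' CADT torsion parameters
#' @inheritParams addt_params
#' @return object of class `c("cadt_params", "torsion_params")`
#' @export
cadt_params <- function(phi_eq, k_modes, s_inst = s_instance(phi_eq)) {
  k <- .norm_kmodes(k_modes)
  structure(list(phi_eq = phi_eq, k = k, active = which(k != 0),
                 s_instance = s_inst),
            class = c("cadt_params", "torsion_params"))
}

#' ADCO torsion parameters
#'
#' Cosine-only angle-damped potential: one adjustable force constant `k`
#' scales all modes; the smart-selection coefficients `c_co` fix the ratios
#' between modes.
#'
#' @param phi_eq_training training-set equilibrium dihedral, radians
#' @param k single force constant
#' @param c_co numeric vector of length 4: mode coefficients
#' @param theta_eq_abc,theta_eq_bcd equilibrium bond angles, radians
#' @return object of class `c("adco_params", "torsion_params")`
#' @export
adco_params <- function(phi_eq_training, k, c_co, theta_eq_abc, theta_eq_bcd) {
  if (min(theta_eq_abc, theta_eq_bcd) <= 0 ||
      max(theta_eq_abc, theta_eq_bcd) >= pi - 1e-9) {
    stop("adco_params: equilibrium angles must be non-linear (use ADLD)")
  }
  c_co <- .norm_kmodes(c_co, 4L)
  structure(list(phi_eq_training = phi_eq_training, k = k, c_co = c_co,
                 theta_eq_abc = theta_eq_abc, theta_eq_bcd = theta_eq_bcd),
            class = c("adco_params", "torsion_params"))
}

#' CACO torsion parameters
#' @inheritParams adco_params
#' @return object of class `c("caco_params", "torsion_params")`
#' @export
caco_params <- function(phi_eq_training, k, c_co) {
  c_co <- .norm_kmodes(c_co, 4L)
  structure(list(phi_eq_training = phi_eq_training, k = k, c_co = c_co),
            class = c("caco_params", "torsion_params"))
}

#' ADLD torsion parameters
#'
#' Linear-dihedral potential organised by half-multiplicity `j`: even modes
#' `n = 2 j` carry constants `k_ld1`, `k_ld2`, `k_ld3` and odd modes
#' `n = 2 j - 1` carry `k_ld4`, `k_ld5`, `k_ld6`.  `k_ld1`, `k_ld2`,
#' `k_ld4`, `k_ld5` must be non-negative.  `s_inst` must be supplied
#' externally for sine terms (mirror-image environment detection is outside
#' the scope of this package).
#'
#' @param even data frame with columns `j`, `k_ld1`, `k_ld2`, `k_ld3`
#'   (may be `NULL`)
#' @param odd data frame with columns `j`, `k_ld4`, `k_ld5`, `k_ld6`
#'   (may be `NULL`)
#' @param s_inst mirror-image descriptor in `[-1, 1]`
#' @return object of class `c("adld_params", "torsion_params")`
#' @export
adld_params <- function(even = NULL, odd = NULL, s_inst = 0) {
  chk <- function(df, cols) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    stopifnot(all(c("j", cols) %in% names(df)))
    if (any(df$j < 1 | df$j != round(df$j)) || 2 * max(df$j) > 8) {
      stop("adld_params: j must be whole numbers with multiplicity <= 8")
    }
    df
  }
  even <- chk(even, c("k_ld1", "k_ld2", "k_ld3"))
  odd <- chk(odd, c("k_ld4", "k_ld5", "k_ld6"))
  if (!is.null(even) && any(c(even$k_ld1, even$k_ld2) < 0)) {
    stop("adld_params: k_ld1 and k_ld2 must be >= 0")
  }
  if (!is.null(odd) && any(c(odd$k_ld4, odd$k_ld5) < 0)) {
    stop("adld_params: k_ld4 and k_ld5 must be >= 0")
  }
  structure(list(even = even, odd = odd, s_instance = s_inst),
            class = c("adld_params", "torsion_params"))
}

# ---------------------------------------------------------------------------
# energies

#' ADDT model potential energy
#'
#' Sum over active modes of the angle-damped dihedral torsion potential:
#' cosine modes `k_m (J_m - H_m cos(m (phi - phi_eq)))` (which include the
#' torsion offset potential `J_m - H_m`), and sine-combination modes 5-7
#' with each multiplicity damped by its own `H_n` and multiplied by the
#' mirror-image descriptor.  Zero at the equilibrium geometry; finite and
#' continuous as either contained angle approaches linearity.
#'
#' @param params an [addt_params()] object
#' @param th_abc,th_bcd contained bond angles, radians in `[0, pi]`
#' @param phi dihedral value(s), radians
#' @return energy (unit of the force constants), vectorized
#' @export
addt_energy <- function(params, th_abc, th_bcd, phi) {
  p <- params
  d <- phi - p$phi_eq
  H <- lapply(1:4, function(n) .H_n(n, th_abc, th_bcd,
                                    p$theta_eq_abc, p$theta_eq_bcd))
  U <- 0
  for (m in p$active) {
    if (m <= 4L) {
      tp <- top_n(m, th_abc, th_bcd, p$theta_eq_abc, p$theta_eq_bcd)
      U <- U + p$k[m] * (tp$J - tp$H * cos(m * d))
    } else {
      Us <- switch(m - 4L,
        (3 * H[[1]] * sin(d) - H[[3]] * sin(3 * d)) / .mode_norm[["m5"]],
        (2 * H[[2]] * sin(2 * d) - H[[4]] * sin(4 * d)) / .mode_norm[["m6"]],
        (H[[1]] * sin(d) + 3 * H[[3]] * sin(3 * d) - H[[2]] * sin(2 * d) -
           2 * H[[4]] * sin(4 * d)) / .mode_norm[["m7"]])
      U <- U + p$k[m] * p$s_instance * Us
    }
  }
  U
}

#' CADT model potential energy
#'
#' The constant-amplitude limit of [addt_energy()]: all damping factors
#' frozen at one.  Zero energy and zero slope at `phi_eq`.
#'
#' @param params a [cadt_params()] object
#' @param phi dihedral value(s), radians
#' @return energy, vectorized over `phi`
#' @export
cadt_energy <- function(params, phi) {
  p <- params
  U <- 0
  for (m in p$active) {
    g <- dt_mode_basis(m, phi, p$phi_eq)$G
    if (m > 4L) g <- g * p$s_instance
    U <- U + p$k[m] * g
  }
  U
}

#' Fourier-series form of a CADT potential
#'
#' Rewrites a CADT potential as
#' `U = alpha0 + sum_n a_n (1 - cos(n (phi - phi_eq))) + sum_n b_n sin(n (phi - phi_eq))`
#' with `alpha0 = 0`, `a_n` the cosine-mode force constants, and the sine
#' coefficients `b_n` assembled from modes 5-7.  The resulting series
#' automatically satisfies the zero-force stationarity constraint
#' `sum_n n b_n = 0` at `phi_eq`.
#'
#' @param params a [cadt_params()] object
#' @return list with `phi_eq`, `alpha0`, `a` (length 4), `b` (length 4)
#' @export
cadt_to_fourier <- function(params) {
  p <- params
  k <- p$k * as.numeric(seq_len(7) %in% p$active)
  S <- p$s_instance
  b <- c(S * (3 * k[5] / .mode_norm[["m5"]] + k[7] / .mode_norm[["m7"]]),
         S * (2 * k[6] / .mode_norm[["m6"]] - k[7] / .mode_norm[["m7"]]),
         S * (-k[5] / .mode_norm[["m5"]] + 3 * k[7] / .mode_norm[["m7"]]),
         S * (-k[6] / .mode_norm[["m6"]] - 2 * k[7] / .mode_norm[["m7"]]))
  list(phi_eq = p$phi_eq, alpha0 = 0, a = k[1:4], b = b)
}

#' Evaluate a Fourier-form torsion series
#' @param fourier a list as returned by [cadt_to_fourier()]
#' @param phi dihedral value(s), radians
#' @return energy, vectorized
#' @export
fourier_energy <- function(fourier, phi) {
  d <- phi - fourier$phi_eq
  U <- rep(fourier$alpha0, length(phi))
  for (n in 1:4) {
    U <- U + fourier$a[n] * (1 - cos(n * d)) + fourier$b[n] * sin(n * d)
  }
  U
}

#' ADCO model potential energy
#'
#' Cosine-only angle-damped potential
#' `U = k sum_n c_n (H_n cos(n phi) - J_n cos(n phi_eq_training))`:
#' an even function of `phi` at fixed bond angles, zero at the training
#' equilibrium geometry, and carrying the same torsion offset potential as
#' the matched ADDT potential.
#'
#' @param params an [adco_params()] object
#' @param th_abc,th_bcd contained bond angles, radians in `[0, pi]`
#' @param phi dihedral value(s), radians
#' @return energy, vectorized
#' @export
adco_energy <- function(params, th_abc, th_bcd, phi) {
  p <- params
  U <- 0
  for (n in which(p$c_co != 0)) {
    tp <- top_n(n, th_abc, th_bcd, p$theta_eq_abc, p$theta_eq_bcd)
    U <- U + p$k * p$c_co[n] *
      (tp$H * cos(n * phi) - tp$J * cos(n * p$phi_eq_training))
  }
  U
}

#' CACO model potential energy
#'
#' `U = k sum_n c_n (cos(n phi) - cos(n phi_eq_training))`: the
#' constant-amplitude cosine-only potential.
#'
#' @param params a [caco_params()] object
#' @param phi dihedral value(s), radians
#' @return energy, vectorized
#' @export
caco_energy <- function(params, phi) {
  p <- params
  U <- 0
  for (n in which(p$c_co != 0)) {
    U <- U + p$k * p$c_co[n] * co_mode_basis(n, phi, p$phi_eq_training)$G
  }
  U
}

#' ADLD model potential energy
#'
#' Torsion potential for dihedrals whose equilibrium contains one or two
#' linear bond angles.  No division by equilibrium damping values occurs.
#' Even modes `n = 2 j`:
#' `(f_j^ABC f_j^BCD)^2 (k_ld1 (1 - cos(n phi)) + k_ld2 (1 + cos(n phi)) + k_ld3 S sin(n phi))`.
#' Odd modes `n = 2 j - 1` use the completing-the-squares offset
#' `off = 1/2 ((f_(j-1)^ABC f_j^BCD)^2 + (f_j^ABC f_(j-1)^BCD)^2)` and the
#' combined damping `Q_n = f_(j-1)^ABC f_j^ABC f_(j-1)^BCD f_j^BCD`:
#' `k_ld4 (off - Q_n cos(n phi)) + k_ld5 (off + Q_n cos(n phi)) + k_ld6 S Q_n sin(n phi)`.
#' Since `off >= |Q_n|`, the `k_ld4` and `k_ld5` terms are non-negative
#' everywhere.
#'
#' @param params an [adld_params()] object
#' @param th_abc,th_bcd contained bond angles, radians in `[0, pi]`
#' @param phi dihedral value(s), radians; ignored wherever the damping has
#'   extinguished all `phi`-dependent factors
#' @return energy, vectorized
#' @export
adld_energy <- function(params, th_abc, th_bcd, phi) {
  p <- params
  U <- 0
  S <- p$s_instance
  if (!is.null(p$even)) {
    for (r in seq_len(nrow(p$even))) {
      j <- p$even$j[r]; n <- 2L * j
      amp <- (damping_f(j, th_abc) * damping_f(j, th_bcd))^2
      U <- U + amp * (p$even$k_ld1[r] * (1 - cos(n * phi)) +
                      p$even$k_ld2[r] * (1 + cos(n * phi)) +
                      p$even$k_ld3[r] * S * sin(n * phi))
    }
  }
  if (!is.null(p$odd)) {
    for (r in seq_len(nrow(p$odd))) {
      j <- p$odd$j[r]; n <- 2L * j - 1L
      fa1 <- damping_f(j - 1L, th_abc); fa2 <- damping_f(j, th_abc)
      fb1 <- damping_f(j - 1L, th_bcd); fb2 <- damping_f(j, th_bcd)
      off <- 0.5 * ((fa1 * fb2)^2 + (fa2 * fb1)^2)
      Q <- fa1 * fa2 * fb1 * fb2
      U <- U + p$odd$k_ld4[r] * (off - Q * cos(n * phi)) +
               p$odd$k_ld5[r] * (off + Q * cos(n * phi)) +
               p$odd$k_ld6[r] * S * Q * sin(n * phi)
    }
  }
  U
}

#' Evaluate any torsion model potential
#'
#' Generic dispatcher: angle-damped models receive the bond angles; CADT
#' and CACO ignore them.
#'
#' @param params a `torsion_params` object
#' @param th_abc,th_bcd contained bond angles, radians
#' @param phi dihedral value(s), radians
#' @return energy, vectorized
#' @export
torsion_energy <- function(params, th_abc, th_bcd, phi) {
  UseMethod("torsion_energy")
}

#' @export
torsion_energy.addt_params <- function(params, th_abc, th_bcd, phi) {
  addt_energy(params, th_abc, th_bcd, phi)
}
#' @export
torsion_energy.cadt_params <- function(params, th_abc, th_bcd, phi) {
  cadt_energy(params, phi)
}
#' @export
torsion_energy.adco_params <- function(params, th_abc, th_bcd, phi) {
  adco_energy(params, th_abc, th_bcd, phi)
}
#' @export
torsion_energy.caco_params <- function(params, th_abc, th_bcd, phi) {
  caco_energy(params, phi)
}
#' @export
torsion_energy.adld_params <- function(params, th_abc, th_bcd, phi) {
  adld_energy(params, th_abc, th_bcd, phi)
}

#' Classify a linear dihedral and list its admissible torsion modes
#'
#' A dihedral is "linear" when at least one equilibrium contained bond angle
#' is within `eps` of pi.  Classification follows the symmetry of the
#' equilibrium structure:
#' case 1 (symmetry-induced single-linear, 1a if the bent angle lies in a
#' mirror plane), case 2 (symmetry-induced double-linear, 2a if the linear
#' axis lies in two mirror planes, 2b if on a rotation axis), case 3
#' (accidental single-linear), case 4 (accidental double-linear).  An
#' `omega`-fold rotational symmetry keeps only multiplicities divisible by
#' `omega`; a mirror plane eliminates all sine terms; single-linear cases
#' always eliminate the `n = 1` terms.
#'
#' @param theta_eq_abc,theta_eq_bcd equilibrium bond angles, radians
#' @param omega order of the rotational symmetry about the linear axis
#'   (1 for none)
#' @param mirror whether the relevant mirror symmetry is present (bent angle
#'   contained in a mirror plane for single-linear; two mirror planes
#'   containing the axis for double-linear)
#' @param accidental whether the linearity is accidental rather than
#'   symmetry-induced
#' @param eps linearity tolerance in radians (0.03 by default)
#' @param n_max largest multiplicity considered
#' @return list with `case` label, `linear` flags, admissible cosine
#'   multiplicities `n_cos` and sine multiplicities `n_sin`
#' @export
classify_linear_dihedral <- function(theta_eq_abc, theta_eq_bcd, omega = 1L,
                                     mirror = FALSE, accidental = FALSE,
                                     eps = 0.03, n_max = 4L) {
  lin <- c(abc = pi - theta_eq_abc < eps, bcd = pi - theta_eq_bcd < eps)
  if (!any(lin)) {
    stop("classify_linear_dihedral: neither equilibrium angle is within eps",
         " of pi; this is not a linear dihedral")
  }
  n_all <- seq_len(n_max)
  single <- xor(lin[1], lin[2])
  if (single) {
    if (accidental) {
      case <- "3"
      n_cos <- setdiff(n_all, 1L)
      n_sin <- setdiff(n_all, 1L)
    } else {
      if (omega < 2L) stop("symmetry-induced single-linear dihedral requires",
                           " omega >= 2")
      case <- if (mirror) "1a" else "1b"
      n_cos <- n_all[n_all %% omega == 0]
      n_sin <- if (mirror) integer(0) else n_cos
    }
  } else {
    if (accidental) {
      case <- "4"
      n_cos <- n_all
      n_sin <- n_all
    } else if (mirror) {
      case <- "2a"
      n_cos <- n_all
      n_sin <- integer(0)
    } else {
      case <- "2b"
      n_cos <- if (omega > 1L) n_all[n_all %% omega == 0] else n_all
      n_sin <- n_cos
    }
  }
  list(case = case, linear = lin, n_cos = n_cos, n_sin = n_sin)
}
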