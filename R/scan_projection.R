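# Torsion-scan statistics, projection onto orthonormal mode bases, smart
# mode selection, model-potential selection and constrained-angle
# prediction.

#' Torsion scan container
#'
#' A uniform grid of dihedral values over `(-pi, pi]` with energies in
#' kJ/mol.
#'
#' @param phi dihedral grid, radians; must be uniformly spaced with `T >= 8`
#'   points covering one period
#' @param energy energies, kJ/mol, same length
#' @param phi_eq_training training equilibrium dihedral, radians
#' @param label optional label
#' @return object of class `torsion_scan`
#' @export
torsion_scan <- function(phi, energy, phi_eq_training = pi, label = "") {
  n <- length(phi)
  if (n < 8L) stop("torsion_scan: need at least 8 grid points")
  if (length(energy) != n) stop("torsion_scan: length mismatch")
  if (!all(is.finite(energy))) stop("torsion_scan: energies must be finite")
  o <- order(phi)
  phi <- phi[o]; energy <- energy[o]
  dphi <- diff(phi)
  if (max(abs(dphi - 2 * pi / n)) > 1e-8) {
    stop("torsion_scan: grid must be uniform over (-pi, pi]")
  }
  structure(list(phi = phi, energy = energy,
                 phi_eq_training = phi_eq_training, label = label),
            class = "torsion_scan")
}

#' Read a torsion scan from CSV
#'
#' Expected columns: `phi_deg`, `energy_kJmol` (header line required).
#' @param path CSV file path
#' @param phi_eq_training_deg training equilibrium dihedral in degrees
#' @param label optional label
#' @return a [torsion_scan()]
#' @export
read_scan_csv <- function(path, phi_eq_training_deg = 180, label = basename(path)) {
  df <- utils::read.csv(path)
  if (!all(c("phi_deg", "energy_kJmol") %in% names(df))) {
    stop("scan CSV must have columns phi_deg, energy_kJmol")
  }
  torsion_scan(deg2rad(df$phi_deg), df$energy_kJmol,
               phi_eq_training = deg2rad(phi_eq_training_deg), label = label)
}

#' Write a torsion scan to CSV
#' @param scan a [torsion_scan()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(data.frame(phi_deg = rad2deg(scan$phi),
                              energy_kJmol = scan$energy),
                   path, row.names = FALSE)
  invisible(path)
}

#' Torsion-scan summary statistics
#'
#' @param scan a [torsion_scan()]
#' @return list with `e_avg` (mean energy), `w` (self-overlap of the
#'   centered curve, i.e. the mean squared deviation), `norm` (RMS deviation
#'   from the mean, kJ/mol) and `barrier` (max - min, kJ/mol)
#' @export
scan_stats <- function(scan) {
  e_avg <- mean(scan$energy)
  dev <- scan$energy - e_avg
  w <- mean(dev^2)
  list(e_avg = e_avg, w = w, norm = sqrt(w),
       barrier = max(scan$energy) - min(scan$energy))
}

#' Odd-function symmetry descriptor of a torsion scan
#'
#' Quantifies the odd-function content of the scan about `phi = 0`:
#' the RMS of the antisymmetric part `(E(phi) - E(-phi))/2` divided by the
#' scan norm.  Zero iff `E(phi) = E(-phi)` within quadrature error.  When
#' the grid is not closed under negation, periodic linear interpolation is
#' used to evaluate `E(-phi)`.
#'
#' @param scan a [torsion_scan()]
#' @param ... unused (kept for interface stability)
#' @return dimensionless value `>= 0`
#' @export
sym_value <- function(scan, ...) {
  st <- scan_stats(scan)
  if (st$norm == 0) return(0)
  e_neg <- .interp_periodic(scan$phi, scan$energy, wrap_angle(-scan$phi))
  odd <- (scan$energy - e_neg) / 2
  sqrt(mean(odd^2)) / st$norm
}

# periodic linear interpolation on a uniform grid over (-pi, pi]
.interp_periodic <- function(phi, y, phi_out) {
  n <- length(phi)
  ext_phi <- c(phi[n] - 2 * pi, phi)
  ext_y <- c(y[n], y)
  stats::approx(ext_phi, ext_y, xout = wrap_angle(phi_out), rule = 2)$y
}

#' Project a torsion scan onto an orthonormal mode basis
#'
#' The centered, normalized scan `(E - E_avg)/norm` is projected onto the
#' orthonormalized projectors `sqrt(2) P_m` (DT basis: 7 modes about
#' `phi_eq`; CO basis: 4 cosine modes), using discrete quadrature on the
#' uniform grid.  For a band-limited curve the projection is exact and the
#' coefficients satisfy `sum(c^2) = 1`.
#'
#' @param scan a [torsion_scan()]
#' @param basis `"DT"` or `"CO"`
#' @param phi_eq reference dihedral (defaults to the scan's training value)
#' @return object of class `projection_result` with fields `basis`, `c`,
#'   `phi_eq`, `e_avg`, `w`, `norm`, `barrier`, `sym_value`, `sum_csq`
#' @export
project_scan <- function(scan, basis = c("DT", "CO"),
                         phi_eq = scan$phi_eq_training) {
  basis <- match.arg(basis)
  st <- scan_stats(scan)
  n_modes <- if (basis == "DT") 7L else 4L
  ehat <- if (st$norm > 0) (scan$energy - st$e_avg) / st$norm else
    rep(0, length(scan$phi))
  cc <- vapply(seq_len(n_modes), function(m) {
    P <- if (basis == "DT") dt_mode_basis(m, scan$phi, phi_eq)$P else
      co_mode_basis(m, scan$phi, phi_eq)$P
    sqrt(2) * mean(ehat * P)
  }, numeric(1))
  structure(list(basis = basis, c = cc, phi_eq = phi_eq,
                 phi_eq_training = scan$phi_eq_training,
                 e_avg = st$e_avg, w = st$w, norm = st$norm,
                 barrier = st$barrier, sym_value = sym_value(scan),
                 sum_csq = sum(cc^2), label = scan$label),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection (%s basis)  norm %.4g kJ/mol  barrier %.4g  sym %.4g\n",
              x$basis, x$norm, x$barrier, x$sym_value))
  cat("c:", sprintf("%.4f", x$c), "\n")
  cat("SumCSq:", sprintf("%.6f", x$sum_csq), "\n")
  invisible(x)
}

#' Kept-mode SumCSq and R-squared of a truncated model curve
#'
#' `SumCSq` is the sum of squared projection coefficients over the kept
#' modes: the fraction of the scan recovered by the model.  The model curve
#' is `norm * sqrt(2) * sum_kept c_m P_m` plus an offset chosen by scenario:
#' scenario 1 zeroes the model at the training equilibrium dihedral (the
#' default throughout); scenario 2 matches the model average to the
#' reference average, for which `R^2 = SumCSq` identically.
#'
#' @param scan the projected [torsion_scan()]
#' @param proj a `projection_result` from [project_scan()]
#' @param kept_modes integer vector of kept mode numbers
#' @param scenario 1 or 2
#' @return list with `sum_csq`, `r_squared`, `scenario`, `e_model_avg`,
#'   `model` (model curve on the scan grid) and `reference` (QM energies
#'   relative to the training equilibrium)
#' @export
sum_csq_and_r2 <- function(scan, proj, kept_modes = seq_along(proj$c),
                           scenario = 1L) {
  kept_modes <- intersect(kept_modes, seq_along(proj$c))
  sum_csq <- sum(proj$c[kept_modes]^2)
  shape <- rep(0, length(scan$phi))
  shape_eq <- 0
  for (m in kept_modes) {
    P <- if (proj$basis == "DT") dt_mode_basis(m, scan$phi, proj$phi_eq)$P else
      co_mode_basis(m, scan$phi, proj$phi_eq)$P
    P_eq <- if (proj$basis == "DT")
      dt_mode_basis(m, scan$phi_eq_training, proj$phi_eq)$P else
      co_mode_basis(m, scan$phi_eq_training, proj$phi_eq)$P
    shape <- shape + proj$c[m] * P
    shape_eq <- shape_eq + proj$c[m] * P_eq
  }
  shape <- proj$norm * sqrt(2) * shape
  shape_eq <- proj$norm * sqrt(2) * shape_eq
  e_at_eq <- .interp_periodic(scan$phi, scan$energy, scan$phi_eq_training)
  ref <- scan$energy - e_at_eq
  if (scenario == 1L) {
    e_model_avg <- -shape_eq
  } else if (scenario == 2L) {
    e_model_avg <- proj$e_avg - e_at_eq
  } else {
    stop("scenario must be 1 or 2")
  }
  model <- shape + e_model_avg
  sse <- sum((ref - model)^2)
  sst <- sum((ref - mean(ref))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  list(sum_csq = sum_csq, r_squared = r2, scenario = scenario,
       e_model_avg = e_model_avg, model = model, reference = ref)
}

#' Smart selection of torsion modes from a scan
#'
#' Projects the scan on both bases and applies the symmetry-tiered
#' thresholds: `sym_value <= 0.01` selects the cosine-only basis with
#' cutoff 0.001; `0.01 < sym_value <= 0.1` the DT basis with cutoff 0.01;
#' `sym_value > 0.1` the DT basis with cutoff 0.1.  A mode is kept iff
#' `abs(c_m)` strictly exceeds the cutoff.
#'
#' @param scan a [torsion_scan()]
#' @param phi_eq reference dihedral for the DT basis
#' @param thresholds length-3 numeric: cutoffs for the three symmetry tiers
#' @return list with `sym_value`, `basis`, `cutoff`, `kept`, the chosen
#'   `projection`, and the kept-mode `sum_csq`
#' @export
smart_select <- function(scan, phi_eq = scan$phi_eq_training,
                         thresholds = c(0.001, 0.01, 0.1)) {
  sv <- sym_value(scan)
  if (sv <= 0.01) {
    proj <- project_scan(scan, "CO", phi_eq)
    cutoff <- thresholds[1]
  } else {
    proj <- project_scan(scan, "DT", phi_eq)
    cutoff <- if (sv <= 0.1) thresholds[2] else thresholds[3]
  }
  kept <- which(abs(proj$c) > cutoff)
  list(sym_value = sv, basis = proj$basis, cutoff = cutoff, kept = kept,
       projection = proj, sum_csq = sum(proj$c[kept]^2))
}

#' Choose a torsion model potential for a dihedral type
#'
#' ADLD when either equilibrium contained bond angle is within `eps_linear`
#' of pi; otherwise an angle-damped variant (ADDT/ADCO) when either
#' equilibrium angle is >= 130 degrees, else a constant-amplitude variant
#' (CADT/CACO); the cosine-only member of the pair iff
#' `sym_value <= 0.01`.
#'
#' @param theta_eq_abc,theta_eq_bcd equilibrium bond angles, radians
#' @param sym_value symmetry descriptor of the dihedral's torsion scan
#' @param eps_linear linearity tolerance, radians
#' @return one of `"ADDT"`, `"ADCO"`, `"CADT"`, `"CACO"`, `"ADLD"`
#' @export
choose_model <- function(theta_eq_abc, theta_eq_bcd, sym_value = NA,
                         eps_linear = 0.03) {
  if (pi - theta_eq_abc < eps_linear || pi - theta_eq_bcd < eps_linear) {
    return("ADLD")
  }
  wide <- max(rad2deg(theta_eq_abc), rad2deg(theta_eq_bcd)) >= 130
  even <- !is.na(sym_value) && sym_value <= 0.01
  if (wide) {
    if (even) "ADCO" else "ADDT"
  } else {
    if (even) "CACO" else "CADT"
  }
}

# decompose a projection into plain cosine/sine multiplicity amplitudes of
# the normalized curve about the projection reference:
#   ehat = sqrt(2) * sum_n (a_n cos(n (phi - ref)) + b_n sin(n (phi - ref)))
# (CO basis: about phi = 0 with b = 0)
.multiplicity_amplitudes <- function(proj) {
  cc <- proj$c
  if (proj$basis == "CO") {
    list(a = cc, b = rep(0, 4), ref = 0)
  } else {
    a <- -cc[1:4]
    b <- c(3 * cc[5] / .mode_norm[["m5"]] + cc[7] / .mode_norm[["m7"]],
           2 * cc[6] / .mode_norm[["m6"]] - cc[7] / .mode_norm[["m7"]],
           -cc[5] / .mode_norm[["m5"]] + 3 * cc[7] / .mode_norm[["m7"]],
           -cc[6] / .mode_norm[["m6"]] - 2 * cc[7] / .mode_norm[["m7"]])
    list(a = a, b = b, ref = proj$phi_eq)
  }
}

#' Predict the torsion curve at constrained bond-angle values
#'
#' Rescales each multiplicity-`n` amplitude of the optimized-geometry scan
#' by its combined damping ratio
#' `r_n = (f_n(theta_constr)/f_n(theta_eq_1)) (f_n(theta_other)/f_n(theta_eq_2))`,
#' renormalizes the mode coefficients, and locates the predicted potential
#' minimum on a 0.01-degree grid.  For the constant-amplitude models (CADT,
#' CACO) the amplitudes are unchanged by construction and the returned
#' minimum is the equilibrium-angle one.
#'
#' @param proj a `projection_result` of the optimized-geometry scan
#' @param theta_constr constrained bond-angle value, radians
#' @param theta_other the other contained bond angle, radians
#' @param theta_eqs length-2 numeric: the two equilibrium bond angles
#'   (first the one being constrained), radians
#' @param model `"ADDT"`, `"ADCO"`, `"CADT"` or `"CACO"`
#' @return list with `norm` (predicted torsion norm, kJ/mol), `c`
#'   (renormalized predicted coefficients in the projection's basis),
#'   `ratios` (the per-multiplicity damping ratios) and `phi_min`
#'   (predicted minimum, radians, located on the 0.01-degree grid)
#' @export
predict_constrained <- function(proj, theta_constr, theta_other, theta_eqs,
                                model = c("ADDT", "ADCO", "CADT", "CACO")) {
  model <- match.arg(model)
  amp <- .multiplicity_amplitudes(proj)
  phig <- deg2rad(seq(-179.99, 180, by = 0.01))
  if (model %in% c("CADT", "CACO")) {
    shape <- rep(0, length(phig))
    for (n in 1:4) {
      shape <- shape + amp$a[n] * cos(n * (phig - amp$ref)) +
        amp$b[n] * sin(n * (phig - amp$ref))
    }
    return(list(norm = proj$norm, c = proj$c, ratios = rep(1, 4),
                phi_min = phig[which.min(shape)]))
  }
  r <- vapply(1:4, function(n) {
    (damping_f(n, theta_constr) / damping_f(n, theta_eqs[1])) *
      (damping_f(n, theta_other) / damping_f(n, theta_eqs[2]))
  }, numeric(1))
  a2 <- amp$a * r
  b2 <- amp$b * r
  scale <- sqrt(sum(a2^2 + b2^2))
  norm_pred <- proj$norm * scale
  shape <- rep(0, length(phig))
  for (n in 1:4) {
    shape <- shape + a2[n] * cos(n * (phig - amp$ref)) +
      b2[n] * sin(n * (phig - amp$ref))
  }
  phi_min <- phig[which.min(shape)]
  # re-project the rescaled curve onto the original basis and renormalize
  ehat <- sqrt(2) * shape / scale
  c_pred <- vapply(seq_along(proj$c), function(m) {
    P <- if (proj$basis == "DT") dt_mode_basis(m, phig, proj$phi_eq)$P else
      co_mode_basis(m, phig, proj$phi_eq)$P
    sqrt(2) * mean(ehat * P)
  }, numeric(1))
  list(norm = norm_pred, c = c_pred, ratios = r, phi_min = phi_min)
}
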