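# Benchmark fixtures: small-molecule geometries and forcefields rebuilt
# from tabulated internal coordinates and force constants, plus a synthetic
# torsion-scan generator.
#
# Sources of the tabulated values (coupled-cluster equilibrium geometries
# and fitted force constants):
#   isocyanic acid HNCO  - ADDT / ADCO torsion variants
#   hydrogen peroxide    - CADT / CACO torsion variants
#   acetylene / d2-acetylene - ADLD torsion variant

.fixture_tables <- list(
  HNCO = list(
    # atom order H, N, C, O; dihedral H-N-C-O
    geom = list(r_HN = 1.00578, r_NC = 1.21144, r_CO = 1.16029,
                a_HNC = 123.57915, a_NCO = 172.98777, phi = 180),
    ADDT = list(k_stretch = c(HN = 45.10, NC = 56.61, CO = 104.46),
                k_bend = c(HNC = 1.696), k_torsion = c(m1 = 0.05817)),
    ADCO = list(k_stretch = c(HN = 45.10, NC = 56.60, CO = 104.46),
                k_bend = c(HNC = 1.696), k = 0.05818,
                c_co = c(0.999999, 0.001117, 0, 0))
  ),
  HOOH = list(
    geom = list(r_HO = 0.9666, r_OO = 1.4378, a_HOO = 100.8215,
                phi = 111.0568),
    CACO = list(k_stretch = c(HO = 50.71, OO = 31.81),
                k_bend = c(HOO = 5.683), k = 0.1552,
                c_co = c(0.833919, 0.549530, 0.050017, 0.009368)),
    CADT = list(k_stretch = c(HO = 50.96, OO = 31.85),
                k_bend = c(HOO = 5.760),
                k_torsion = c(m1 = 0.04466, m2 = 0.06460, m3 = -0.00888,
                              m5 = -0.11657, m6 = 0.04935, m7 = -0.05040))
  ),
  HCCH = list(
    geom = list(r_HC = 1.06358, r_CC = 1.20183, a_HCC = 180),
    ADLD = list(k_stretch = c(HC = 41.91, CC = 111.34),
                k_bend = c(HCC = 1.045), k_ld5 = 3.400)
  )
)

#' Fixture specification tables
#'
#' Returns the tabulated internal coordinates (angstrom, degrees) and force
#' constants (eV, eV/angstrom^2) used by [make_fixture()].
#' @param molecule `"HNCO"`, `"HOOH"`, `"HCCH"` or `"DCCD"`
#' @return a nested list
#' @export
fixture_spec <- function(molecule = c("HNCO", "HOOH", "HCCH", "DCCD")) {
  molecule <- match.arg(molecule)
  .fixture_tables[[if (molecule == "DCCD") "HCCH" else molecule]]
}

.permute_structure <- function(s, perm) {
  atomic_structure(s$symbols[perm], s$coords[perm, , drop = FALSE],
                   s$masses[perm])
}

#' Build a benchmark structure and flexibility model
#'
#' Reconstructs the molecule's Cartesian geometry from its tabulated
#' internal coordinates and assembles the forcefield (harmonic stretches,
#' angle bends, and the requested torsion model) with the tabulated
#' constants.  `DCCD` is the acetylene structure and model with deuterium
#' masses substituted; nothing else changes.
#'
#' @param molecule `"HNCO"`, `"HOOH"`, `"HCCH"` or `"DCCD"`
#' @param torsion torsion-model variant; defaults to the molecule's
#'   tabulated variant (`"ADDT"` for HNCO, `"CADT"` for HOOH, `"ADLD"` for
#'   HCCH/DCCD)
#' @return list with `structure` (an [atomic_structure()]), `model`
#'   (a [flexibility_model()], kJ/mol internally) and `dihedral_atoms`
#' @export
make_fixture <- function(molecule = c("HNCO", "HOOH", "HCCH", "DCCD"),
                         torsion = NULL) {
  molecule <- match.arg(molecule)
  spec <- fixture_spec(molecule)
  g <- spec$geom
  if (molecule == "HNCO") {
    if (is.null(torsion)) torsion <- "ADDT"
    torsion <- match.arg(torsion, c("ADDT", "ADCO"))
    zmat <- data.frame(
      symbol = c("N", "C", "H", "O"),
      ref1 = c(NA, 1, 1, 2), bond = c(NA, g$r_NC, g$r_HN, g$r_CO),
      ref2 = c(NA, NA, 2, 1), angle = c(NA, NA, g$a_HNC, g$a_NCO),
      ref3 = c(NA, NA, NA, 3), dihedral = c(NA, NA, NA, g$phi))
    s <- .permute_structure(build_from_internal(zmat), c(3, 1, 2, 4))
    p <- spec[[torsion]]
    eqA <- deg2rad(g$a_HNC); eqB <- deg2rad(g$a_NCO)
    tors <- if (torsion == "ADDT") {
      addt_params(pi, eqA, eqB,
                  convert_energy(p$k_torsion, "eV", "kJmol"), s_inst = 0)
    } else {
      adco_params(pi, convert_energy(p$k, "eV", "kJmol"), p$c_co, eqA, eqB)
    }
    model <- flexibility_model(list(
      flex_stretch(c(1, 2), p$k_stretch[["HN"]], g$r_HN, units = "eV"),
      flex_stretch(c(2, 3), p$k_stretch[["NC"]], g$r_NC, units = "eV"),
      flex_stretch(c(3, 4), p$k_stretch[["CO"]], g$r_CO, units = "eV"),
      flex_bend(c(1, 2, 3), p$k_bend[["HNC"]], eqA, units = "eV"),
      flex_torsion(1:4, tors)))
    return(list(structure = s, model = model, dihedral_atoms = 1:4))
  }
  if (molecule == "HOOH") {
    if (is.null(torsion)) torsion <- "CADT"
    torsion <- match.arg(torsion, c("CADT", "CACO"))
    zmat <- data.frame(
      symbol = c("O", "O", "H", "H"),
      ref1 = c(NA, 1, 1, 2), bond = c(NA, g$r_OO, g$r_HO, g$r_HO),
      ref2 = c(NA, NA, 2, 1), angle = c(NA, NA, g$a_HOO, g$a_HOO),
      ref3 = c(NA, NA, NA, 3), dihedral = c(NA, NA, NA, g$phi))
    s <- .permute_structure(build_from_internal(zmat), c(3, 1, 2, 4))
    p <- spec[[torsion]]
    eq <- deg2rad(g$a_HOO); phieq <- deg2rad(g$phi)
    tors <- if (torsion == "CADT") {
      cadt_params(phieq, convert_energy(p$k_torsion, "eV", "kJmol"))
    } else {
      caco_params(phieq, convert_energy(p$k, "eV", "kJmol"), p$c_co)
    }
    model <- flexibility_model(list(
      flex_stretch(c(1, 2), p$k_stretch[["HO"]], g$r_HO, units = "eV"),
      flex_stretch(c(2, 3), p$k_stretch[["OO"]], g$r_OO, units = "eV"),
      flex_stretch(c(3, 4), p$k_stretch[["HO"]], g$r_HO, units = "eV"),
      flex_bend(c(1, 2, 3), p$k_bend[["HOO"]], eq, units = "eV"),
      flex_bend(c(2, 3, 4), p$k_bend[["HOO"]], eq, units = "eV"),
      flex_torsion(1:4, tors)))
    return(list(structure = s, model = model, dihedral_atoms = 1:4))
  }
  # HCCH / DCCD
  if (is.null(torsion)) torsion <- "ADLD"
  torsion <- match.arg(torsion, "ADLD")
  zmat <- data.frame(
    symbol = c("C", "C", if (molecule == "DCCD") c("D", "D") else c("H", "H")),
    ref1 = c(NA, 1, 1, 2), bond = c(NA, g$r_CC, g$r_HC, g$r_HC),
    ref2 = c(NA, NA, 2, 1), angle = c(NA, NA, g$a_HCC, g$a_HCC),
    ref3 = c(NA, NA, NA, 3), dihedral = c(NA, NA, NA, 0))
  s <- .permute_structure(build_from_internal(zmat), c(3, 1, 2, 4))
  p <- spec$ADLD
  tors <- adld_params(
    odd = data.frame(j = 1, k_ld4 = 0,
                     k_ld5 = convert_energy(p$k_ld5, "eV", "kJmol"),
                     k_ld6 = 0),
    s_inst = 0)
  model <- flexibility_model(list(
    flex_stretch(c(1, 2), p$k_stretch[["HC"]], g$r_HC, units = "eV"),
    flex_stretch(c(2, 3), p$k_stretch[["CC"]], g$r_CC, units = "eV"),
    flex_stretch(c(3, 4), p$k_stretch[["HC"]], g$r_HC, units = "eV"),
    flex_bend(c(1, 2, 3), p$k_bend[["HCC"]], pi, units = "eV"),
    flex_bend(c(2, 3, 4), p$k_bend[["HCC"]], pi, units = "eV"),
    flex_torsion(1:4, tors)))
  list(structure = s, model = model, dihedral_atoms = 1:4)
}

#' Generate a synthetic torsion scan from mode coefficients
#'
#' Builds `E(phi) = e_avg + norm * sqrt(2) * sum_m c_m P_m(phi)` on a
#' uniform grid of `t_points` dihedral values over `(-pi, pi]`, optionally
#' adding Gaussian noise.  A noiseless scan re-projects to its own
#' coefficients within quadrature tolerance.
#'
#' @param c_modes mode coefficients (length 7 for DT, 4 for CO);
#'   `sum(c^2) <= 1` expected for coefficients of a normalized curve
#' @param basis `"DT"` or `"CO"`
#' @param norm torsion norm, kJ/mol
#' @param e_avg average energy offset, kJ/mol
#' @param t_points number of grid points (must resolve the highest kept
#'   multiplicity: `t_points >= 2 * n_max + 2`)
#' @param phi_eq reference dihedral, radians
#' @param noise_sd Gaussian noise standard deviation, kJ/mol
#' @param seed optional RNG seed for reproducible noise
#' @return a [torsion_scan()]
#' @export
synth_scan <- function(c_modes, basis = c("DT", "CO"), norm = 1, e_avg = 0,
                       t_points = 18L, phi_eq = pi, noise_sd = 0,
                       seed = NULL) {
  basis <- match.arg(basis)
  n_modes <- if (basis == "DT") 7L else 4L
  c_modes <- .norm_kmodes(c_modes, n_modes)
  if (sum(c_modes^2) > 1 + 1e-3) {  # printed coefficients may round above 1
    stop("synth_scan: sum(c^2) exceeds one; not a normalized curve")
  }
  used <- which(c_modes != 0)
  n_max_used <- if (length(used)) {
    max(vapply(used, function(m) {
      if (basis == "CO") m else if (m <= 4L) m else c(3L, 4L, 4L)[m - 4L]
    }, integer(1)))
  } else 1L
  if (t_points < 2L * n_max_used + 2L) {
    stop("synth_scan: grid too coarse for multiplicity ", n_max_used)
  }
  phi <- -pi + 2 * pi * seq_len(t_points) / t_points
  E <- rep(e_avg, t_points)
  for (m in used) {
    P <- if (basis == "DT") dt_mode_basis(m, phi, phi_eq)$P else
      co_mode_basis(m, phi, phi_eq)$P
    E <- E + norm * sqrt(2) * c_modes[m] * P
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    E <- E + stats::rnorm(t_points, sd = noise_sd)
  }
  torsion_scan(phi, E, phi_eq_training = phi_eq)
}
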