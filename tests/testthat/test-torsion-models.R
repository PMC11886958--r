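test_that("s_instance options behave as specified", {
  expect_equal(s_instance(pi), 0)
  expect_equal(s_instance(0), 0)
  expect_equal(s_instance(deg2rad(-64.7)), -1)
  expect_equal(s_instance(deg2rad(30)), 1)
  expect_equal(s_instance(pi, option = 2, D = 2), 0, tolerance = 1e-12)
  expect_equal(s_instance(deg2rad(30), option = 2, D = 2), 1, tolerance = 1e-6)
  expect_error(s_instance(0.1, option = 3), "option")
})

test_that("the seven DT modes are orthogonal with cosine-scale RMS amplitude", {
  phi <- phi_grid(720)
  phi_eq <- deg2rad(111)
  P <- sapply(1:7, function(m) dt_mode_basis(m, phi, phi_eq)$P)
  G <- sapply(1:7, function(m) dt_mode_basis(m, phi, phi_eq)$G)
  overlap <- crossprod(P) / length(phi)
  expect_equal(overlap, diag(rep(0.5, 7)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colMeans(P), rep(0, 7), tolerance = 1e-12)
  # zero slope at phi_eq for every mode
  h <- 1e-6
  for (m in 1:7) {
    g <- dt_mode_basis(m, phi_eq + c(-h, h), phi_eq)$G
    expect_equal((g[2] - g[1]) / (2 * h), 0, tolerance = 1e-9)
  }
  # ethane-like projector: P3 at phi_eq = pi equals -cos(3 (phi - pi))
  expect_equal(dt_mode_basis(3, phi, pi)$P, -cos(3 * (phi - pi)))
  expect_equal(G[, 1:4] - P[, 1:4], matrix(1, length(phi), 4))
})

test_that("TOP is non-negative, zero only at equilibrium, with unit J and H there", {
  eqA <- deg2rad(123.57915); eqB <- deg2rad(172.98777)
  thA <- seq(deg2rad(60), pi, length.out = 60)
  thB <- seq(deg2rad(60), pi, length.out = 60)
  for (n in 1:4) {
    tp0 <- top_n(n, eqA, eqB, eqA, eqB)
    expect_equal(tp0$J, 1, tolerance = 1e-12)
    expect_equal(tp0$H, 1, tolerance = 1e-12)
    expect_equal(tp0$TOP, 0, tolerance = 1e-12)
    grid <- expand.grid(a = thA, b = thB)
    tp <- top_n(n, grid$a, grid$b, eqA, eqB)
    expect_true(all(tp$TOP >= -1e-13))
    expect_true(all(tp$J >= 0))
    off_eq <- abs(grid$a - eqA) > 1e-2 | abs(grid$b - eqB) > 1e-2
    expect_true(all(tp$TOP[off_eq] > 0))
  }
  # non-zero slope of the mode-1 TOP at a linear bond angle, in contrast to
  # the zero slope required of any pure bending potential there
  h <- 1e-5
  tp <- top_n(1, eqA, c(pi - h, pi), eqA, eqB)
  slope <- (tp$TOP[2] - tp$TOP[1]) / h
  expect_gt(abs(slope), 0.1)
  expect_error(top_n(1, eqA, eqB, eqA, pi), "ADLD")
})

test_that("ADDT branch equivalency holds to 1e-10 on random draws", {
  set.seed(42)
  for (i in 1:60) {
    p <- random_addt_params()
    thA <- stats::runif(1, 0.3, pi)
    thB <- stats::runif(1, 0.3, pi)
    ph <- stats::runif(1, -pi, pi)
    u0 <- addt_energy(p, thA, thB, ph)
    bB <- branch_select(2 * pi - thB, ph + pi)
    expect_equal(addt_energy(p, thA, bB$theta, bB$phi), u0, tolerance = 1e-10)
    bA <- branch_select(2 * pi - thA, ph - pi)
    expect_equal(addt_energy(p, bA$theta, thB, bA$phi), u0, tolerance = 1e-10)
  }
})

test_that("ADLD branch equivalency and linear-angle limit", {
  set.seed(43)
  for (i in 1:40) {
    p <- random_adld_params(s_inst = sample(c(-1, 1), 1))
    thA <- stats::runif(1, 0.3, pi)
    thB <- stats::runif(1, 0.3, pi)
    ph <- stats::runif(1, -pi, pi)
    u0 <- adld_energy(p, thA, thB, ph)
    bB <- branch_select(2 * pi - thB, ph + pi)
    expect_equal(adld_energy(p, thA, bB$theta, bB$phi), u0, tolerance = 1e-10)
  }
  # at a linear angle the dihedral is undefined, so every phi-dependent
  # factor must vanish: the energy is independent of phi there, and it is
  # identically zero when both angles are linear
  p <- random_adld_params()
  ph <- seq(-pi, pi, length.out = 17)
  u_lin <- adld_energy(p, pi, deg2rad(150), ph)
  expect_equal(u_lin, rep(u_lin[1], length(ph)), tolerance = 1e-12)
  expect_equal(adld_energy(p, pi, pi, deg2rad(40)), 0, tolerance = 1e-12)
  expect_error(adld_params(odd = data.frame(j = 1, k_ld4 = -1, k_ld5 = 0,
                                            k_ld6 = 0)), ">= 0")
})

test_that("ADLD odd mode matches its hand-expanded completing-the-squares form", {
  # single k_ld5 term, j = 1 (the acetylene case): offset is
  # (f1_abc^2 + f1_bcd^2)/2 and the cosine carries f1_abc * f1_bcd
  kld5 <- convert_energy(3.400, "eV", "kJmol")
  p <- adld_params(odd = data.frame(j = 1, k_ld4 = 0, k_ld5 = kld5, k_ld6 = 0))
  th <- deg2rad(170)
  u <- damping_f(1, th)
  expect_equal(adld_energy(p, th, th, 0), kld5 * (u^2 + u * u),
               tolerance = 1e-12)
  expect_equal(adld_energy(p, th, th, pi), kld5 * (u^2 - u * u),
               tolerance = 1e-12)
  # non-negative everywhere on a grid
  grid <- expand.grid(a = seq(2, pi, length.out = 25),
                      b = seq(2, pi, length.out = 25),
                      ph = seq(-pi, pi, length.out = 13))
  expect_true(all(adld_energy(p, grid$a, grid$b, grid$ph) >= -1e-12))
})

test_that("CADT equals ADDT with damping frozen and matches its Fourier form", {
  set.seed(44)
  phi <- phi_grid(721)
  for (i in 1:20) {
    pA <- random_addt_params()
    pC <- cadt_params(pA$phi_eq, pA$k, s_inst = pA$s_instance)
    # at the equilibrium angles every damping ratio is one
    expect_equal(addt_energy(pA, pA$theta_eq_abc, pA$theta_eq_bcd, phi),
                 cadt_energy(pC, phi), tolerance = 1e-11)
    four <- cadt_to_fourier(pC)
    expect_equal(fourier_energy(four, phi), cadt_energy(pC, phi),
                 tolerance = 1e-10)
    # stationarity at phi_eq carried by the series
    expect_equal(sum(seq_len(4) * four$b), 0, tolerance = 1e-12)
    expect_equal(cadt_energy(pC, pA$phi_eq), 0, tolerance = 1e-12)
  }
  pC <- cadt_params(1, c(m5 = 0, m6 = 0, m7 = 0, m1 = 2))
  expect_equal(cadt_to_fourier(pC)$b, rep(0, 4))
})

test_that("cosine-only potentials are even, zero at training phi_eq", {
  phieq <- deg2rad(111.0568)
  pc <- caco_params(phieq, convert_energy(0.1552, "eV", "kJmol"),
                    c(0.833919, 0.549530, 0.050017, 0.009368))
  phi <- phi_grid(360)
  expect_equal(caco_energy(pc, phi), caco_energy(pc, -phi), tolerance = 1e-12)
  expect_equal(caco_energy(pc, phieq), 0, tolerance = 1e-12)
  pa <- adco_params(phieq, 5, c(0.8, 0.5, 0.04, 0.01),
                    deg2rad(100.8), deg2rad(100.8))
  thA <- deg2rad(95); thB <- deg2rad(104)
  expect_equal(adco_energy(pa, thA, thB, phi), adco_energy(pa, thA, thB, -phi),
               tolerance = 1e-12)
  expect_equal(adco_energy(pa, deg2rad(100.8), deg2rad(100.8), phieq), 0,
               tolerance = 1e-12)
})

test_that("ADCO and ADDT agree through the force-constant mapping for even scans", {
  # with phi_eq = pi and k_n = -k_adco c_n cos(n phi_eq), the cosine-mode
  # energies (including the offset terms) coincide
  eqA <- deg2rad(123.57915); eqB <- deg2rad(172.98777)
  k_adco <- 6
  c_co <- c(0.9, 0.1, 0.02, 0.004)
  k_addt <- -k_adco * c_co * cos((1:4) * pi)
  pa <- adco_params(pi, k_adco, c_co, eqA, eqB)
  pd <- addt_params(pi, eqA, eqB, c(k_addt, 0, 0, 0), s_inst = 0)
  set.seed(45)
  for (i in 1:40) {
    thA <- stats::runif(1, 1.5, pi)
    thB <- stats::runif(1, 1.5, pi)
    ph <- stats::runif(1, -pi, pi)
    expect_equal(adco_energy(pa, thA, thB, ph), addt_energy(pd, thA, thB, ph),
                 tolerance = 1e-10)
  }
})

test_that("mirror invariance: reflected instance with flipped S gives equal energy", {
  set.seed(46)
  for (i in 1:100) {
    p <- random_addt_params()
    pm <- addt_params(mirror_phi_eq(p$phi_eq), p$theta_eq_abc, p$theta_eq_bcd,
                      p$k, s_inst = -p$s_instance)
    thA <- stats::runif(1, 0.5, pi - 0.01)
    thB <- stats::runif(1, 0.5, pi - 0.01)
    ph <- stats::runif(1, -pi, pi)
    expect_equal(addt_energy(p, thA, thB, ph),
                 addt_energy(pm, thA, thB, mirror_phi_eq(ph)),
                 tolerance = 1e-10)
  }
  for (i in 1:100) {
    p <- random_adld_params(s_inst = 1)
    pm <- p; pm$s_instance <- -1
    thA <- stats::runif(1, 0.5, pi)
    thB <- stats::runif(1, 0.5, pi)
    ph <- stats::runif(1, -pi, pi)
    expect_equal(adld_energy(p, thA, thB, ph),
                 adld_energy(pm, thA, thB, mirror_phi_eq(ph)),
                 tolerance = 1e-10)
  }
})

test_that("angle-damped energies stay finite and continuous approaching linearity", {
  p <- addt_params(pi, deg2rad(123.6), deg2rad(173), c(m1 = 5.6), s_inst = 0)
  th <- seq(deg2rad(175), pi, by = 1e-4)
  u <- addt_energy(p, deg2rad(123.6), th, deg2rad(40))
  expect_true(all(is.finite(u)))
  expect_lt(max(abs(diff(u))), 1e-2)
  pl <- random_adld_params()
  ul <- adld_energy(pl, deg2rad(160), th, deg2rad(40))
  expect_true(all(is.finite(ul)))
  expect_lt(max(abs(diff(ul))), 1e-2)
})

test_that("linear-dihedral case classification follows the symmetry rules", {
  # acetylene: double-linear with two mirror planes
  cl <- classify_linear_dihedral(pi, pi, mirror = TRUE)
  expect_equal(cl$case, "2a")
  expect_equal(cl$n_sin, integer(0))
  expect_true(1 %in% cl$n_cos)
  # acetonitrile: 3-fold symmetry-induced single-linear in a mirror plane
  cl <- classify_linear_dihedral(deg2rad(109.9), pi, omega = 3, mirror = TRUE)
  expect_equal(cl$case, "1a")
  expect_equal(cl$n_cos, 3L)
  expect_equal(cl$n_sin, integer(0))
  # accidental single-linear: n = 1 eliminated
  cl <- classify_linear_dihedral(deg2rad(120), deg2rad(179.5),
                                 accidental = TRUE)
  expect_equal(cl$case, "3")
  expect_false(1 %in% cl$n_cos)
  cl <- classify_linear_dihedral(pi, pi, omega = 2)
  expect_equal(cl$case, "2b")
  expect_equal(cl$n_cos, c(2L, 4L))
  expect_error(classify_linear_dihedral(deg2rad(120), deg2rad(130)),
               "not a linear dihedral")
})

test_that("torsion parameter YAML blocks round-trip", {
  p <- addt_params(deg2rad(-64.7), deg2rad(111.1), deg2rad(109),
                   c(m1 = 3.2, m5 = -1.1))
  path <- tempfile(fileext = ".yml")
  write_params_yaml(p, path, units = "eV")
  p2 <- read_params_yaml(path)
  phi <- phi_grid(36)
  expect_equal(addt_energy(p2, deg2rad(100), deg2rad(105), phi),
               addt_energy(p, deg2rad(100), deg2rad(105), phi),
               tolerance = 1e-9)
  pl <- adld_params(odd = data.frame(j = 1, k_ld4 = 0, k_ld5 = 328, k_ld6 = 0),
                    even = data.frame(j = 1, k_ld1 = 1, k_ld2 = 2, k_ld3 = 0))
  write_params_yaml(pl, path)
  pl2 <- read_params_yaml(path)
  expect_equal(adld_energy(pl2, deg2rad(160), deg2rad(170), 0.3),
               adld_energy(pl, deg2rad(160), deg2rad(170), 0.3),
               tolerance = 1e-9)
})
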