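test_that("scan statistics: constant, single-cosine and synthetic curves", {
  phi <- phi_grid(18)
  flat <- torsion_scan(phi, rep(2.5, 18))
  st <- scan_stats(flat)
  expect_equal(st$norm, 0)
  expect_equal(st$barrier, 0)
  # pure A * (-cos(3 phi)) has RMS A / sqrt(2)
  A <- 4.7
  sc <- torsion_scan(phi, A * (-cos(3 * phi)) + 1)
  st <- scan_stats(sc)
  expect_equal(st$norm, A / sqrt(2), tolerance = 1e-12)
  expect_equal(st$e_avg, 1, tolerance = 1e-12)
  expect_equal(st$w, st$norm^2)
  # an ethane-like single-mode curve with norm 4.47 has barrier
  # norm * sqrt(2) * (max - min of the projector) = norm * 2 sqrt(2)
  eth <- synth_scan(c(0, 0, 1), basis = "DT", norm = 4.47, t_points = 72)
  expect_equal(scan_stats(eth)$barrier, 4.47 * 2 * sqrt(2), tolerance = 1e-10)
  expect_equal(scan_stats(eth)$barrier, 12.65, tolerance = 0.01)
})

test_that("projection recovers coefficients of band-limited curves exactly", {
  # basis self-projection
  s <- synth_scan(c(0, 0, 0, 0, 1, 0, 0), basis = "DT", norm = 3, t_points = 18)
  pr <- project_scan(s, "DT")
  expect_equal(pr$c, c(0, 0, 0, 0, 1, 0, 0), tolerance = 1e-10)
  expect_equal(pr$norm, 3, tolerance = 1e-10)
  # a mixed-coefficient curve round-trips on the default 18-point grid
  cc <- c(0.3014, 0.4028, -0.0322, 0, -0.7479, 0.3257, -0.2835)
  cc <- cc / sqrt(sum(cc^2))
  s <- synth_scan(cc, basis = "DT", norm = 10.68, e_avg = 5,
                  phi_eq = deg2rad(111.1), t_points = 18)
  pr <- project_scan(s, "DT", phi_eq = deg2rad(111.1))
  expect_equal(pr$c, cc, tolerance = 1e-8)
  expect_equal(pr$sum_csq, 1, tolerance = 1e-10)
  # CO basis round trip
  cco <- c(0.8390, 0.5430, 0.0361, 0.0001)
  sco <- synth_scan(cco, basis = "CO", norm = 10.68, t_points = 36)
  prc <- project_scan(sco, "CO")
  # printed coefficients round to slightly above unit sum of squares; the
  # projection recovers them up to that overall normalization
  expect_equal(prc$c, cco / sqrt(sum(cco^2)), tolerance = 1e-10)
})

test_that("Parseval bound: sum of squared coefficients never exceeds one", {
  set.seed(91)
  for (i in 1:50) {
    e <- stats::rnorm(24)
    sc <- torsion_scan(phi_grid(24), e)
    for (basis in c("DT", "CO")) {
      pr <- project_scan(sc, basis, phi_eq = stats::runif(1, -pi, pi))
      expect_lte(pr$sum_csq, 1 + 1e-10)
    }
  }
})

test_that("sym_value detects odd-function content", {
  phi <- phi_grid(36)
  even_curve <- torsion_scan(phi, 3 * cos(phi) + cos(2 * phi))
  expect_equal(sym_value(even_curve), 0, tolerance = 1e-12)
  odd_curve <- torsion_scan(phi, 2 * sin(phi))
  expect_equal(sym_value(odd_curve), 1, tolerance = 1e-10)
  # mixed: sym^2 equals the odd energy fraction
  mixed <- torsion_scan(phi, cos(phi) + sin(2 * phi))
  expect_equal(sym_value(mixed)^2, 0.5, tolerance = 1e-10)
})

test_that("scenario 2 gives R^2 = SumCSq identically; scenario 1 bounded by it", {
  set.seed(92)
  for (i in 1:25) {
    e <- stats::rnorm(24, sd = 3)
    sc <- torsion_scan(phi_grid(24), e, phi_eq_training = pi)
    pr <- project_scan(sc, "DT")
    kept <- sample(1:7, 4)
    g2 <- sum_csq_and_r2(sc, pr, kept, scenario = 2)
    expect_equal(g2$r_squared, g2$sum_csq, tolerance = 1e-12)
    g1 <- sum_csq_and_r2(sc, pr, kept, scenario = 1)
    expect_lte(g1$r_squared, g2$sum_csq + 1e-12)
    expect_equal(g1$sum_csq, sum(pr$c[kept]^2))
  }
  # complete expansion of a band-limited curve: both scenarios reach R^2 = 1
  s <- synth_scan(c(0.6, 0.3, 0.1, 0, 0.5, 0.2, 0.1) /
                    sqrt(sum(c(0.6, 0.3, 0.1, 0, 0.5, 0.2, 0.1)^2)),
                  basis = "DT", norm = 5, t_points = 18)
  pr <- project_scan(s, "DT")
  expect_equal(sum_csq_and_r2(s, pr, 1:7, 1)$r_squared, 1, tolerance = 1e-9)
})

test_that("DT and CO coefficients of an even curve satisfy the delta identity", {
  # Delta_n = c_DT_n + c_CO_n cos(n phi_eq) = 0 when sym_value = 0
  cco <- c(0.8, 0.5, 0.1, 0.02)
  cco <- cco / sqrt(sum(cco^2))
  s <- synth_scan(cco, basis = "CO", norm = 8, t_points = 36, phi_eq = pi)
  expect_equal(sym_value(s), 0, tolerance = 1e-12)
  dt <- project_scan(s, "DT", phi_eq = pi)
  co <- project_scan(s, "CO")
  delta <- dt$c[1:4] + co$c * cos((1:4) * pi)
  expect_equal(delta, rep(0, 4), tolerance = 1e-10)
})

test_that("smart selection applies the symmetry-tiered cutoffs", {
  # ethane-like even curve -> CO basis, single mode 3
  eth <- synth_scan(c(0, 0, 1), basis = "CO", norm = 4.47, t_points = 18)
  sel <- smart_select(eth)
  expect_equal(sel$basis, "CO")
  expect_equal(sel$cutoff, 0.001)
  expect_equal(sel$kept, 3L)
  # mildly asymmetric curve (small sine content about phi = 0) -> DT basis
  # with the 0.01 cutoff
  cc <- c(0.93, 0.25, 0.015, 0.005, 0.06, 0, 0)
  cc <- cc / sqrt(sum(cc^2))
  s <- synth_scan(cc, basis = "DT", norm = 5, t_points = 36, phi_eq = pi)
  sel <- smart_select(s, phi_eq = pi)
  expect_equal(sel$basis, "DT")
  expect_gt(sel$sym_value, 0.01)
  expect_lte(sel$sym_value, 0.1)
  expect_equal(sel$cutoff, 0.01)
  expect_setequal(sel$kept, c(1L, 2L, 3L, 5L))
  # strongly asymmetric curve -> DT basis with 0.1 cutoff
  cc <- c(0.55, 0.3, 0.09, 0, 0.7, 0.2, 0.05)
  cc <- cc / sqrt(sum(cc^2))
  s <- synth_scan(cc, basis = "DT", norm = 6, t_points = 36, phi_eq = pi)
  sel <- smart_select(s, phi_eq = pi)
  expect_gt(sel$sym_value, 0.1)
  expect_equal(sel$cutoff, 0.1)
  expect_setequal(sel$kept, c(1L, 2L, 5L, 6L))
  # threshold monotonicity: raising a cutoff never adds modes
  pr <- sel$projection
  for (cut in c(0.001, 0.01, 0.1, 0.5)) {
    kept_lo <- which(abs(pr$c) > cut)
    kept_hi <- which(abs(pr$c) > cut * 2)
    expect_true(all(kept_hi %in% kept_lo))
  }
})

test_that("model-potential selection follows the angle and symmetry rules", {
  expect_equal(choose_model(deg2rad(123.6), deg2rad(173.0), 0), "ADCO")
  expect_equal(choose_model(deg2rad(100.8), deg2rad(100.8), 0), "CACO")
  expect_equal(choose_model(pi, pi, NA), "ADLD")
  expect_equal(choose_model(deg2rad(109.9), pi, 0), "ADLD")
  expect_equal(choose_model(deg2rad(123.6), deg2rad(173.0), 0.5), "ADDT")
  expect_equal(choose_model(deg2rad(111), deg2rad(109), 0.85), "CADT")
  # 130 degrees is inclusive for the angle-damped branch
  expect_equal(choose_model(deg2rad(130), deg2rad(100), 0.5), "ADDT")
  expect_equal(choose_model(deg2rad(129.9), deg2rad(100), 0.5), "CADT")
})

test_that("constrained-angle prediction: identity at equilibrium, rescale off it", {
  # identity when constrained at the equilibrium angles
  cc <- c(1, 0, 0, 0, 0, 0, 0)
  s <- synth_scan(cc, basis = "DT", norm = 5.23, t_points = 18)
  pr <- project_scan(s, "DT")
  eqs <- deg2rad(c(172.98777, 123.57915))
  pred <- predict_constrained(pr, eqs[1], eqs[2], eqs, model = "ADDT")
  expect_equal(pred$norm, 5.23, tolerance = 1e-9)
  expect_equal(pred$ratios, rep(1, 4), tolerance = 1e-12)
  # CADT prediction returns the unchanged optimized norm
  predc <- predict_constrained(pr, deg2rad(165), deg2rad(123.9), eqs,
                               model = "CADT")
  expect_equal(predc$norm, 5.23)
  # constrained narrower than equilibrium: every damping ratio exceeds one
  pred <- predict_constrained(pr, deg2rad(165), deg2rad(123.9), eqs,
                              model = "ADDT")
  expect_true(all(pred$ratios > 1))
  # c2 grows monotonically as the wide angle closes (the slip-torsion trend)
  cc2 <- c(0.9914, 0.1307, 0, 0, 0, 0, 0)
  cc2 <- cc2 / sqrt(sum(cc2^2))
  s2 <- synth_scan(cc2, basis = "DT", norm = 0.675, t_points = 18)
  pr2 <- project_scan(s2, "DT")
  eqs2 <- deg2rad(c(173.8, 95.4))
  c2 <- sapply(c(165, 155, 140, 125), function(a) {
    predict_constrained(pr2, deg2rad(a), deg2rad(95.7), eqs2, "ADDT")$c[2]
  })
  expect_true(all(diff(c2) > 0))
  # predicted coefficients stay normalized
  expect_equal(sum(predict_constrained(pr2, deg2rad(140), deg2rad(95.7),
                                       eqs2, "ADDT")$c^2), 1,
               tolerance = 1e-6)
})

test_that("scan CSV round-trips through files", {
  s <- synth_scan(c(0.6, 0.8, 0, 0), basis = "CO", norm = 7, e_avg = 3,
                  t_points = 18)
  path <- tempfile(fileext = ".csv")
  write_scan_csv(s, path)
  s2 <- read_scan_csv(path, phi_eq_training_deg = 180)
  expect_equal(s2$phi, s$phi, tolerance = 1e-9)
  expect_equal(s2$energy, s$energy, tolerance = 1e-9)
})

test_that("synthetic scans are deterministic under a seed", {
  a <- synth_scan(c(0, 0, 1), "DT", norm = 4, noise_sd = 0.3, seed = 7)
  b <- synth_scan(c(0, 0, 1), "DT", norm = 4, noise_sd = 0.3, seed = 7)
  expect_identical(a$energy, b$energy)
  expect_error(synth_scan(c(0, 0, 0, 2), "CO"), "exceeds")
  expect_error(synth_scan(c(0, 0, 0, 1), "CO", t_points = 8), "too coarse")
})
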