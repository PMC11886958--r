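# Shared generators for property-style tests.

# independent directed-dihedral oracle: atan2 form,
# y = (n1 x n2) . unit(b2), x = n1 . n2
oracle_dihedral <- function(A, B, C, D) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  atan2(sum(cross(n1, n2) * b2 / sqrt(sum(b2 * b2))), sum(n1 * n2))
}

random_four_atoms <- function() {
  repeat {
    X <- matrix(stats::runif(12, -2, 2), 4, 3)
    s <- atomic_structure(c("C", "C", "C", "C"), X)
    ok <- tryCatch({
      directed_dihedral(s, 1:4)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(s)
  }
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_addt_params <- function(phi_eq = NULL) {
  if (is.null(phi_eq)) phi_eq <- stats::runif(1, -pi, pi)
  addt_params(phi_eq,
              theta_eq_abc = stats::runif(1, deg2rad(95), deg2rad(170)),
              theta_eq_bcd = stats::runif(1, deg2rad(95), deg2rad(170)),
              k_modes = stats::rnorm(7),
              s_inst = s_instance(phi_eq))
}

random_adld_params <- function(s_inst = 1) {
  adld_params(
    even = data.frame(j = 1:2, k_ld1 = stats::runif(2), k_ld2 = stats::runif(2),
                      k_ld3 = stats::rnorm(2)),
    odd = data.frame(j = 1:2, k_ld4 = stats::runif(2), k_ld5 = stats::runif(2),
                     k_ld6 = stats::rnorm(2)),
    s_inst = s_inst)
}

# uniform dihedral grid over (-pi, pi]
phi_grid <- function(t_points) -pi + 2 * pi * seq_len(t_points) / t_points

# training geometries for a four-atom chain: vary both angles and the
# dihedral around a reference internal-coordinate set
chain_geometries <- function(r = c(1.0, 1.4, 1.0), th1_deg, th2_deg, phi_deg) {
  out <- list()
  for (a1 in th1_deg) for (a2 in th2_deg) for (ph in phi_deg) {
    zm <- data.frame(symbol = c("C", "C", "H", "H"),
                     ref1 = c(NA, 1, 1, 2), bond = c(NA, r[2], r[1], r[3]),
                     ref2 = c(NA, NA, 2, 1), angle = c(NA, NA, a1, a2),
                     ref3 = c(NA, NA, NA, 3), dihedral = c(NA, NA, NA, ph))
    s <- build_from_internal(zm)
    out[[length(out) + 1L]] <-
      atomic_structure(s$symbols[c(3, 1, 2, 4)], s$coords[c(3, 1, 2, 4), ])
  }
  out
}
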