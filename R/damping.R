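# Elementary angle-damping functions.
#
# A torsion amplitude must be extinguished as a contained bond angle
# approaches linearity, because the dihedral becomes undefined there.  The
# machinery below maps a bond angle theta in [0, pi] onto the "kangal" proxy
# variable x = cos(theta/2) in [1, 0], pushes it through asymptotically
# matched polynomials P_n (one per torsion multiplicity n = 1..4) and a
# saturating map Q, producing damping factors f_n(theta) in [0, 1] that are
# ~1 for acute angles, decay through the wide-angle regime, and vanish with
# leading order x^n at linearity.

.damping <- new.env(parent = emptyenv())

# coefficients of the odd cubic P1 and even quartic P2 (gamma = 1/4,
# varpi = 3/4) and of the higher matched polynomials P3, P4
.damping$gamma <- 1 / 4
.damping$varpi <- 3 / 4
.damping$coef3 <- c(3 / 2, -3 / 4, 1 / 4)   # x^3, x^5, x^7
.damping$coef4 <- c(5 / 2, -9 / 4, 3 / 4)   # x^4, x^6, x^8

# printed reference values used as a self-check at load time
.damping$x_root_ref <- 1.244460035526845
.damping$tanh_K_ref <- 0.992861208914406

# leading-order constants of the near-linear ratio expansions
.damping$mu <- c(`2_1` = 3, `3_1` = 6, `4_2` = 10 / 3)

# switch to the series expansion of damping ratios when kangal <= this
.damping$near_linear_threshold <- 1e-4

compute_damping_constants <- function() {
  # unique real root of the quintic from matching the first three non-zero
  # Maclaurin terms of tanh[x] to its saturated value 1:
  #   x - x^3/3 + 2 x^5/15 = 1
  quintic <- function(x) x - x^3 / 3 + 2 * x^5 / 15 - 1
  x_root <- stats::uniroot(quintic, c(0.5, 2), tol = .Machine$double.eps)$root
  # polish by Newton steps
  for (i in 1:5) {
    x_root <- x_root - quintic(x_root) / (1 - x_root^2 + 2 * x_root^4 / 3)
  }
  # uniqueness: companion-matrix roots of the quintic, all others complex
  cr <- polyroot(c(-1, 1, 0, -1 / 3, 0, 2 / 15))
  n_real <- sum(abs(Im(cr)) < 1e-9)
  if (n_real != 1L) stop("quintic root structure unexpected")
  # K scales the argument of tanh so that saturation (the matched three-term
  # expansion reaching 1) occurs at the perpendicular bond angle, where
  # P1[kangal(pi/2)] = P1[cos(pi/4)]
  K <- x_root / poly_P(1, cos(pi / 4))
  list(x_root = x_root, K = K, tanh_K = tanh(K))
}

#' Angle-damping constants
#'
#' Returns the constants defining the elementary angle-damping functions:
#' the polynomial coefficients, the quintic root `x_root`, the saturation
#' constant `K` and `tanh_K`, the near-linear series constants `mu`, and the
#' kangal threshold below which damping ratios switch to their leading-order
#' expansions.
#' @return a named list
#' @export
damping_constants <- function() {
  list(gamma = .damping$gamma, varpi = .damping$varpi,
       coef3 = .damping$coef3, coef4 = .damping$coef4,
       x_root = .damping$x_root, K = .damping$K, tanh_K = .damping$tanh_K,
       mu = .damping$mu,
       near_linear_threshold = .damping$near_linear_threshold)
}

#' Kangal proxy variable
#'
#' Maps a bond angle onto `cos(theta/2)`, which decreases monotonically from
#' 1 at `theta = 0` to 0 at `theta = pi` and satisfies
#' `sin(theta) = 2 * kangal(theta) * sin(theta/2)`.
#'
#' @param theta bond angle(s) in radians, in `[0, pi]`
#' @return dimensionless value(s) in `[0, 1]`
#' @export
kangal <- function(theta) {
  if (any(theta < -1e-12 | theta > pi + 1e-12)) {
    stop("kangal: theta outside [0, pi]; apply branch_select() first")
  }
  cos(pmin(pmax(theta, 0), pi) / 2)
}

#' Asymptotically matched damping polynomials
#'
#' `P_1` to `P_4` are monotonically increasing on `[0, 1]` with `P_n[1] = 1`,
#' `P_n[0] = 0` and leading order `x^n` near zero; `P_1`, `P_3` are odd and
#' `P_2`, `P_4` even.  Their series about `x = 1` agree through second order,
#' which keeps the damping factors of all multiplicities matched for acute
#' bond angles.
#'
#' @param n multiplicity, 1 to 4
#' @param x kangal value(s) in `[0, 1]`
#' @return polynomial value(s)
#' @export
poly_P <- function(n, x) {
  if (!(length(n) == 1L && n %in% 1:4)) stop("poly_P: n must be 1, 2, 3 or 4")
  g <- .damping$gamma; w <- .damping$varpi
  a3 <- .damping$coef3; a4 <- .damping$coef4
  switch(n,
         g * x + (1 - g) * x^3,
         w * x^2 + (1 - w) * x^4,
         a3[1] * x^3 + a3[2] * x^5 + a3[3] * x^7,
         a4[1] * x^4 + a4[2] * x^6 + a4[3] * x^8)
}

#' Saturating map Q
#'
#' The odd, monotonically increasing map `Q[x] = tanh(K x) / tanh(K)` with
#' `Q[0] = 0`, `Q[1] = 1` and first-order leading Maclaurin term, used to
#' flatten the damping factors toward 1 in the acute-angle regime.
#'
#' @param x dimensionless value(s) in `[0, 1]` (any real accepted; Q is odd)
#' @return value(s) in `[-1, 1]` for inputs in `[-1, 1]`
#' @export
Q_map <- function(x) tanh(.damping$K * x) / .damping$tanh_K

#' Elementary angle-damping factor
#'
#' `f_0 = 1`; for `n >= 1`, `f_n(theta) = Q[P_n(kangal(theta))]`, a
#' monotonically decreasing function of the bond angle with `f_n(0) = 1` and
#' `f_n(pi) = 0` (leading order `kangal^n`).
#'
#' @param n multiplicity, 0 to 4
#' @param theta bond angle(s) in radians, `[0, pi]`
#' @return damping value(s) in `[0, 1]`
#' @export
damping_f <- function(n, theta) {
  if (!(length(n) == 1L && n %in% 0:4)) stop("damping_f: n must be 0..4")
  if (n == 0L) return(rep(1, length(theta)))
  Q_map(poly_P(n, kangal(theta)))
}

#' Damping-factor ratio with near-linear series guard
#'
#' Returns `f_n / f_floor(n/2)` for `n` = 2, 3, 4.  Away from linearity the
#' ratio is evaluated directly; once `kangal(theta)` falls below the
#' near-linear threshold the leading-order expansions
#' `f_2/f_1 ~ 3 x`, `f_3/f_1 ~ 6 x^2`, `f_4/f_2 ~ (10/3) x^2`
#' (with `x = kangal`) replace the quotient to avoid 0/0.
#'
#' @param n multiplicity, 2 to 4
#' @param theta bond angle(s) in radians, `[0, pi]`
#' @return ratio value(s)
#' @export
damping_ratio <- function(n, theta) {
  if (!(length(n) == 1L && n %in% 2:4)) stop("damping_ratio: n must be 2..4")
  j <- n %/% 2L
  x <- kangal(theta)
  out <- numeric(length(x))
  near <- x <= .damping$near_linear_threshold
  if (any(!near)) {
    out[!near] <- damping_f(n, theta[!near]) / damping_f(j, theta[!near])
  }
  if (any(near)) {
    mu <- .damping$mu[[paste0(n, "_", j)]]
    out[near] <- mu * x[near]^(n - j)
  }
  out
}

.onLoad <- function(libname, pkgname) {
  cst <- compute_damping_constants()
  if (abs(tanh(cst$K) - .damping$tanh_K_ref) > 1e-12) {
    stop("angle-damping constant self-check failed: tanh(K) = ",
         format(tanh(cst$K), digits = 16))
  }
  .damping$x_root <- cst$x_root
  .damping$K <- cst$K
  .damping$tanh_K <- cst$tanh_K
  invisible()
}
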