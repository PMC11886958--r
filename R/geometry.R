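# Internal-coordinate measurement and structure construction.

#' Atomic structure container
#'
#' A minimal molecular/cluster container: element symbols, per-atom masses
#' (amu) and Cartesian coordinates (angstrom, one row per atom).
#'
#' @param symbols character vector of element symbols (use `"D"` for
#'   deuterium)
#' @param coords numeric matrix, n x 3, Cartesian coordinates in angstrom
#' @param masses optional numeric vector of masses in amu; looked up from the
#'   built-in table when omitted
#' @return an object of class `atomic_structure`
#' @export
atomic_structure <- function(symbols, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(symbols)) {
    stop("coords must be an n x 3 matrix matching length(symbols)")
  }
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(masses)) masses <- lookup_masses(symbols)
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(symbols = as.character(symbols), masses = as.numeric(masses),
                 coords = unname(coords)),
            class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat("atomic_structure:", length(x$symbols), "atoms (",
      paste(x$symbols, collapse = " "), ")\n")
  invisible(x)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.check_distinct <- function(structure, idx) {
  X <- structure$coords
  for (a in seq_along(idx)[-1]) {
    for (b in seq_len(a - 1)) {
      if (sum((X[idx[a], ] - X[idx[b], ])^2) < 1e-16) {
        stop("degenerate geometry: atoms ", idx[b], " and ", idx[a],
             " coincide")
      }
    }
  }
}

#' Bond length
#' @param structure an [atomic_structure()]
#' @param indices two atom indices
#' @return distance in angstrom
#' @export
bond_length <- function(structure, indices) {
  stopifnot(length(indices) == 2L)
  .check_distinct(structure, indices)
  X <- structure$coords
  sqrt(sum((X[indices[1], ] - X[indices[2], ])^2))
}

#' Bond angle
#'
#' Angle at the middle atom of three bonded atoms, via the arccosine of the
#' normalized dot product with its argument clamped to `[-1, 1]`.
#'
#' @param structure an [atomic_structure()]
#' @param indices three atom indices (A, B, C); the angle is at B
#' @return angle in radians, `[0, pi]`
#' @export
bond_angle <- function(structure, indices) {
  stopifnot(length(indices) == 3L)
  .check_distinct(structure, indices)
  X <- structure$coords
  u <- X[indices[1], ] - X[indices[2], ]
  v <- X[indices[3], ] - X[indices[2], ]
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u * u) * sum(v * v)))))
}

#' Directed dihedral angle
#'
#' Signed dihedral of four bonded atoms A-B-C-D in `(-pi, pi]`.  The
#' magnitude is the clamped arccosine of the angle between the ABC and BCD
#' plane normals; the sign is fixed by the triple product of the first plane
#' normal with the C->D bond (positive when D lies on the side toward which
#' the normal points).
#'
#' @param structure an [atomic_structure()]
#' @param indices four atom indices A, B, C, D
#' @param tol collinearity tolerance on `sin(theta)` of the contained bond
#'   angles; below it the dihedral is undefined and an error is raised
#' @return dihedral in radians, `(-pi, pi]`
#' @export
directed_dihedral <- function(structure, indices, tol = 1e-9) {
  stopifnot(length(indices) == 4L)
  .check_distinct(structure, indices)
  X <- structure$coords
  b1 <- X[indices[2], ] - X[indices[1], ]
  b2 <- X[indices[3], ] - X[indices[2], ]
  b3 <- X[indices[4], ] - X[indices[3], ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  s1 <- sqrt(sum(n1^2) / (sum(b1^2) * sum(b2^2)))  # sin(theta_ABC)
  s2 <- sqrt(sum(n2^2) / (sum(b2^2) * sum(b3^2)))  # sin(theta_BCD)
  if (s1 < tol || s2 < tol) {
    stop("directed_dihedral: contained bond angle within tolerance of 0 or pi;",
         " dihedral undefined")
  }
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(min(1, max(-1, cosphi)))
  if (sum(n1 * b3) < 0) phi <- -phi
  if (phi <= -pi) phi <- pi
  phi
}

#' Reflect a structure through a Cartesian coordinate plane
#'
#' Reflection (default about the X = 0 plane) leaves all bond lengths and
#' bond angles invariant and maps every directed dihedral `phi` to `-phi`
#' (0 and pi map onto themselves).
#'
#' @param structure an [atomic_structure()]
#' @param plane one of `"x"`, `"y"`, `"z"`: the coordinate negated
#' @return the reflected [atomic_structure()]
#' @export
reflect <- function(structure, plane = c("x", "y", "z")) {
  plane <- match.arg(plane)
  j <- match(plane, c("x", "y", "z"))
  out <- structure
  out$coords[, j] <- -out$coords[, j]
  out
}

#' Mirror-image mapping of an equilibrium dihedral
#'
#' Taking the mirror image of a structure (e.g. exchanging S and R
#' enantiomers) maps a dihedral reference value to
#' `pi - mod(phi + pi, 2 pi)`, i.e. `phi -> -phi` with the boundary value
#' pi kept at pi so the result stays in `(-pi, pi]`.
#'
#' @param phi dihedral(s) in radians, `(-pi, pi]`
#' @return mapped dihedral(s) in `(-pi, pi]`
#' @export
mirror_phi_eq <- function(phi) {
  pi - (phi + pi) %% (2 * pi)
}

#' Branch selection for an angle-dihedral coordinate pair
#'
#' The coordinate pairs `(theta, phi)` and `(2 pi - theta, phi +/- pi)`
#' describe the same conformation.  This maps an angle that has swept past
#' pi (or below 0) back into `[0, pi]`, adjusting the dihedral accordingly,
#' so every angle-damped potential can be evaluated on its principal branch.
#'
#' @param theta bond angle(s) in radians, any real value
#' @param phi dihedral(s) in radians
#' @return list with components `theta` in `[0, pi]` and `phi` in `(-pi, pi]`
#' @export
branch_select <- function(theta, phi) {
  th <- theta %% (2 * pi)
  flip <- th > pi
  th[flip] <- 2 * pi - th[flip]
  ph <- phi
  ph[flip] <- ph[flip] + pi
  list(theta = th, phi = wrap_angle(ph))
}

#' Build Cartesian coordinates from a Z-matrix specification
#'
#' Each row after the first places one atom by a bond length to `ref1`, a
#' bond angle to `ref1`-`ref2` and a directed dihedral to
#' `ref1`-`ref2`-`ref3`, using the same sign convention as
#' [directed_dihedral()], so measuring the built structure reproduces the
#' specified internal coordinates.  Rows whose reference angle is at 0 or pi
#' fall back to placement along the reference axis (the dihedral is
#' irrelevant there).
#'
#' @param zmat data frame with columns `symbol`, `ref1`, `bond`, `ref2`,
#'   `angle`, `ref3`, `dihedral`; angles in degrees, bonds in angstrom.
#'   Unused references are `NA`.
#' @param masses optional masses passed to [atomic_structure()]
#' @return an [atomic_structure()]
#' @export
build_from_internal <- function(zmat, masses = NULL) {
  n <- nrow(zmat)
  X <- matrix(0, n, 3)
  unit <- function(v) v / sqrt(sum(v * v))
  for (i in seq_len(n)) {
    if (i == 1L) next
    r1 <- zmat$ref1[i]; b <- zmat$bond[i]
    if (i == 2L) { X[2, ] <- X[r1, ] + c(0, 0, b); next }
    th <- deg2rad(zmat$angle[i])
    r2 <- zmat$ref2[i]
    uz <- unit(X[r2, ] - X[r1, ])
    if (i == 3L || is.na(zmat$ref3[i])) {
      # place in the xz-plane of the local frame
      w <- c(1, 0, 0)
      if (abs(sum(w * uz)) > 1 - 1e-8) w <- c(0, 1, 0)
      w <- unit(w - sum(w * uz) * uz)
      X[i, ] <- X[r1, ] + b * (cos(th) * uz + sin(th) * w)
      next
    }
    ph <- deg2rad(zmat$dihedral[i])
    r3 <- zmat$ref3[i]
    vref <- X[r3, ] - X[r2, ]
    vperp <- vref - sum(vref * uz) * uz
    if (sqrt(sum(vperp^2)) < 1e-10) {
      # reference chain collinear: dihedral reference is arbitrary
      w <- c(1, 0, 0)
      if (abs(sum(w * uz)) > 1 - 1e-8) w <- c(0, 1, 0)
      vperp <- w - sum(w * uz) * uz
    }
    w <- unit(vperp)
    uy <- .cross3(w, uz)  # right-handed frame matching directed_dihedral's sign
    X[i, ] <- X[r1, ] + b * (cos(th) * uz + sin(th) * (cos(ph) * w + sin(ph) * uy))
  }
  atomic_structure(zmat$symbol, X, masses = masses)
}

#' Read an XYZ file
#' @param path file path (standard XYZ: count, comment, `El x y z` lines)
#' @return an [atomic_structure()]
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2L) stop("malformed XYZ file: ", path)
  rows <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  symbols <- vapply(rows, `[[`, "", 1L)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  atomic_structure(symbols, coords)
}

#' Write an XYZ file
#' @param structure an [atomic_structure()]
#' @param path output file path
#' @param comment comment line
#' @return `path`, invisibly
#' @export
write_xyz <- function(structure, path, comment = "") {
  n <- length(structure$symbols)
  body <- sprintf("%-2s %18.10f %18.10f %18.10f", structure$symbols,
                  structure$coords[, 1], structure$coords[, 2],
                  structure$coords[, 3])
  writeLines(c(as.character(n), comment, body), path)
  invisible(path)
}
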