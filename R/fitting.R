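# Force-constant optimization against training-set relative energies.
#
# Every model term implemented here is linear in its force constants at
# fixed mode shapes, so fitting reduces to bounded linear least squares on
# relative energies.  Bounds are handled by variable splitting and a
# non-negative least-squares solve (pracma::lsqnonneg); constrained
# constants sit exactly on their bounds when active.

#' Training set container
#'
#' @param geometries list of [atomic_structure()] objects
#' @param ref_rel_energy reference relative energies, kJ/mol
#'   (`E_el - E_el_opt` per geometry)
#' @param opt_index index of the reference optimum geometry
#' @param weights per-observation weights (default 1)
#' @return object of class `training_set`
#' @export
training_set <- function(geometries, ref_rel_energy, opt_index = 1L,
                         weights = NULL) {
  stopifnot(length(geometries) == length(ref_rel_energy))
  if (!all(is.finite(ref_rel_energy))) stop("training energies must be finite")
  if (abs(ref_rel_energy[opt_index]) > 1e-9) {
    stop("ref_rel_energy[opt_index] must be zero")
  }
  if (is.null(weights)) weights <- rep(1, length(geometries))
  structure(list(geometries = geometries, ref_rel_energy = ref_rel_energy,
                 opt_index = opt_index, weights = weights),
            class = "training_set")
}

# enumerate the free force constants of a model:
# data.frame(term, slot, lower)
.free_params <- function(model) {
  rows <- list()
  for (ti in seq_along(model$terms)) {
    term <- model$terms[[ti]]
    if (term$kind == "stretch" || term$kind == "bend") {
      rows[[length(rows) + 1L]] <- data.frame(term = ti, slot = "k", lower = 0)
    } else if (term$kind == "torsion") {
      p <- term$params
      if (inherits(p, c("addt_params", "cadt_params"))) {
        act <- p$active
        for (m in act) {
          # a lone cosine mode must keep the equilibrium geometry a minimum
          lo <- if (length(act) == 1L && m <= 4L) 0 else -Inf
          rows[[length(rows) + 1L]] <-
            data.frame(term = ti, slot = paste0("m", m), lower = lo)
        }
      } else if (inherits(p, c("adco_params", "caco_params"))) {
        rows[[length(rows) + 1L]] <- data.frame(term = ti, slot = "k",
                                                lower = 0)
      } else if (inherits(p, "adld_params")) {
        if (!is.null(p$even)) {
          for (r in seq_len(nrow(p$even))) {
            for (s in c("k_ld1", "k_ld2", "k_ld3")) {
              rows[[length(rows) + 1L]] <- data.frame(
                term = ti, slot = paste0("even", r, ".", s),
                lower = if (s == "k_ld3") -Inf else 0)
            }
          }
        }
        if (!is.null(p$odd)) {
          for (r in seq_len(nrow(p$odd))) {
            for (s in c("k_ld4", "k_ld5", "k_ld6")) {
              rows[[length(rows) + 1L]] <- data.frame(
                term = ti, slot = paste0("odd", r, ".", s),
                lower = if (s == "k_ld6") -Inf else 0)
            }
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

.set_param <- function(model, term, slot, value) {
  t <- model$terms[[term]]
  if (t$kind %in% c("stretch", "bend")) {
    t$k <- value
  } else {
    p <- t$params
    if (grepl("^m[0-9]$", slot)) {
      p$k[as.integer(sub("m", "", slot))] <- value
    } else if (slot == "k") {
      p$k <- value
    } else {
      parity <- sub("^(even|odd)([0-9]+)\\..*$", "\\1", slot)
      r <- as.integer(sub("^(even|odd)([0-9]+)\\..*$", "\\2", slot))
      s <- sub("^(even|odd)[0-9]+\\.", "", slot)
      p[[parity]][[s]][r] <- value
    }
    t$params <- p
  }
  model$terms[[term]] <- t
  model
}

.get_param <- function(model, term, slot) {
  t <- model$terms[[term]]
  if (t$kind %in% c("stretch", "bend")) return(t$k)
  p <- t$params
  if (grepl("^m[0-9]$", slot)) return(p$k[as.integer(sub("m", "", slot))])
  if (slot == "k") return(p$k)
  parity <- sub("^(even|odd)([0-9]+)\\..*$", "\\1", slot)
  r <- as.integer(sub("^(even|odd)([0-9]+)\\..*$", "\\2", slot))
  s <- sub("^(even|odd)[0-9]+\\.", "", slot)
  p[[parity]][[s]][r]
}

# zero out every free constant (constraint-satisfying baseline); nonbonded
# and any non-enumerated constants stay fixed
.zero_model <- function(model, params) {
  for (i in seq_len(nrow(params))) {
    model <- .set_param(model, params$term[i], params$slot[i], 0)
  }
  model
}

#' Fit force constants by bounded linear least squares
#'
#' Minimizes `sum_mu w_mu ((U_mu - U_opt) - (E_mu - E_opt))^2` over all free
#' force constants of the model: stretch and bend constants, ADDT/CADT
#' per-mode constants, the single ADCO/CACO constant, and the ADLD block
#' constants.  Non-negativity is imposed on stretch, bend, ADCO/CACO,
#' ADLD `k_ld1`/`k_ld2`/`k_ld4`/`k_ld5`, and on a lone cosine torsion mode.
#' The model optimum is pinned to the training set's reference optimum
#' geometry.  Minimizing this loss is equivalent to maximizing the training
#' R-squared.
#'
#' @param model a [flexibility_model()] template (constants of fitted terms
#'   are overwritten; nonbonded terms are treated as fixed)
#' @param training a [training_set()]
#' @param lower optional named lower-bound overrides
#'   (names `"<term>:<slot>"`)
#' @return list of class `fit_result`: fitted `model`, `constants`
#'   (data frame of term/slot/value/lower/at_bound), `r_squared`, `rmse`,
#'   `sse`, `sst`, `predicted`, `residuals`, `rank_deficient`
#' @export
fit_force_constants <- function(model, training, lower = NULL) {
  params <- .free_params(model)
  if (is.null(params) || nrow(params) == 0L) stop("model has no free constants")
  if (!is.null(lower)) {
    key <- paste0(params$term, ":", params$slot)
    hit <- match(names(lower), key)
    if (anyNA(hit)) stop("unknown bound name(s): ",
                         paste(names(lower)[is.na(hit)], collapse = ", "))
    params$lower[hit] <- as.numeric(lower)
  }
  geoms <- training$geometries
  nobs <- length(geoms)
  base <- .zero_model(model, params)
  e_fixed <- vapply(geoms, function(g) total_energy(base, g), numeric(1))
  X <- matrix(0, nobs, nrow(params))
  for (p in seq_len(nrow(params))) {
    unit <- .set_param(base, params$term[p], params$slot[p], 1)
    X[, p] <- vapply(geoms, function(g) total_energy(unit, g), numeric(1)) -
      e_fixed
  }
  iopt <- training$opt_index
  Xr <- sweep(X, 2, X[iopt, ])
  y <- training$ref_rel_energy - (e_fixed - e_fixed[iopt])
  sw <- sqrt(training$weights)
  Xw <- Xr * sw
  yw <- y * sw
  rank_def <- qr(Xw)$rank < ncol(Xw)
  if (rank_def) {
    warning("design matrix is rank deficient; solution is not unique ",
            "(multicollinear flexibility terms)")
  }
  # bounded LS via variable splitting + NNLS:
  # x = lower + u (u >= 0) for bounded vars; x = u - v for free vars
  bounded <- is.finite(params$lower)
  Acols <- list(); map <- list()
  offset <- rep(0, nobs)
  for (p in seq_len(nrow(params))) {
    if (bounded[p]) {
      if (params$lower[p] != 0) offset <- offset + Xw[, p] * params$lower[p]
      Acols[[length(Acols) + 1L]] <- Xw[, p]
      map[[length(map) + 1L]] <- c(p, +1)
    } else {
      Acols[[length(Acols) + 1L]] <- Xw[, p]
      map[[length(map) + 1L]] <- c(p, +1)
      Acols[[length(Acols) + 1L]] <- -Xw[, p]
      map[[length(map) + 1L]] <- c(p, -1)
    }
  }
  A <- do.call(cbind, Acols)
  sol <- pracma::lsqnonneg(A, yw - offset)
  x <- params$lower
  x[!bounded] <- 0
  for (ci in seq_along(map)) {
    p <- map[[ci]][1]
    x[p] <- x[p] + map[[ci]][2] * sol$x[ci]
  }
  fitted_model <- model
  for (p in seq_len(nrow(params))) {
    fitted_model <- .set_param(fitted_model, params$term[p], params$slot[p],
                               x[p])
  }
  pred <- as.vector(Xr %*% x) + (e_fixed - e_fixed[iopt])
  g <- goodness(pred, training$ref_rel_energy, weights = training$weights)
  constants <- cbind(params, value = x,
                     at_bound = bounded & abs(x - params$lower) < 1e-12)
  structure(list(model = fitted_model, constants = constants,
                 r_squared = g$r_squared, rmse = g$rmse, sse = g$sse,
                 sst = g$sst, predicted = pred,
                 residuals = training$ref_rel_energy - pred,
                 rank_deficient = rank_def),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit: R^2 = %.6f, RMSE = %.4g kJ/mol\n", x$r_squared, x$rmse))
  print(x$constants[, c("term", "slot", "value", "at_bound")],
        row.names = FALSE)
  invisible(x)
}

#' Goodness-of-fit statistics
#'
#' `R^2 = 1 - SSE/SST` with `SSE = sum w (ref - pred)^2` and
#' `SST = sum w (ref - mean(ref))^2`; `RMSE = sqrt(SSE / N_obs)`.
#'
#' @param pred predicted values
#' @param ref reference values
#' @param weights optional observation weights
#' @return list with `r_squared` (NA with a warning when the reference is
#'   flat), `rmse`, `sse`, `sst`
#' @export
goodness <- function(pred, ref, weights = NULL) {
  stopifnot(length(pred) == length(ref))
  if (is.null(weights)) weights <- rep(1, length(ref))
  sse <- sum(weights * (ref - pred)^2)
  sst <- sum(weights * (ref - stats::weighted.mean(ref, weights))^2)
  r2 <- if (sst > 0) 1 - sse / sst else {
    warning("flat reference data: R-squared undefined")
    NA_real_
  }
  list(r_squared = r2, rmse = sqrt(sse / length(ref)), sse = sse, sst = sst)
}

#' Mean (unsigned) log10 errors of predicted torsion norms
#'
#' `MLE` is the mean of `log10(predicted/reference)`; `MULE` the mean of its
#' absolute value.  `MULE >= abs(MLE)` always.
#'
#' @param predicted_norms,reference_norms positive norms
#' @return list with `mle` and `mule`
#' @export
mle_mule <- function(predicted_norms, reference_norms) {
  stopifnot(length(predicted_norms) == length(reference_norms))
  if (any(predicted_norms <= 0) || any(reference_norms <= 0)) {
    stop("mle_mule: norms must be positive")
  }
  lr <- log10(predicted_norms / reference_norms)
  list(mle = mean(lr), mule = mean(abs(lr)))
}
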