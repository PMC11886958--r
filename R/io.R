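# Serialization: torsion parameter blocks and flexibility models as YAML,
# reports as JSON.  Angles are stored in degrees and energies in the file's
# declared unit; everything is converted to internal conventions (radians,
# kJ/mol) on read.

#' Write a torsion parameter block to YAML
#'
#' @param params a `torsion_params` object (constants in kJ/mol)
#' @param path output path
#' @param units unit to write the constants in
#' @return `path`, invisibly
#' @export
write_params_yaml <- function(params, path, units = c("kJmol", "eV")) {
  units <- match.arg(units)
  cv <- function(x) convert_energy(x, "kJmol", units)
  out <- list(units = units)
  if (inherits(params, "addt_params")) {
    out$model <- "ADDT"
    out$phi_eq_deg <- rad2deg(params$phi_eq)
    out$theta_eq_abc_deg <- rad2deg(params$theta_eq_abc)
    out$theta_eq_bcd_deg <- rad2deg(params$theta_eq_bcd)
    out$k_modes <- as.list(stats::setNames(cv(params$k[params$active]),
                                           paste0("m", params$active)))
    out$s_instance <- params$s_instance
  } else if (inherits(params, "cadt_params")) {
    out$model <- "CADT"
    out$phi_eq_deg <- rad2deg(params$phi_eq)
    out$k_modes <- as.list(stats::setNames(cv(params$k[params$active]),
                                           paste0("m", params$active)))
    out$s_instance <- params$s_instance
  } else if (inherits(params, "adco_params")) {
    out$model <- "ADCO"
    out$phi_eq_training_deg <- rad2deg(params$phi_eq_training)
    out$theta_eq_abc_deg <- rad2deg(params$theta_eq_abc)
    out$theta_eq_bcd_deg <- rad2deg(params$theta_eq_bcd)
    out$k <- cv(params$k)
    out$c_co <- params$c_co
  } else if (inherits(params, "caco_params")) {
    out$model <- "CACO"
    out$phi_eq_training_deg <- rad2deg(params$phi_eq_training)
    out$k <- cv(params$k)
    out$c_co <- params$c_co
  } else if (inherits(params, "adld_params")) {
    out$model <- "ADLD"
    if (!is.null(params$even)) {
      ev <- params$even
      ev[c("k_ld1", "k_ld2", "k_ld3")] <- lapply(ev[c("k_ld1", "k_ld2", "k_ld3")], cv)
      out$even <- lapply(seq_len(nrow(ev)), function(i) as.list(ev[i, ]))
    }
    if (!is.null(params$odd)) {
      od <- params$odd
      od[c("k_ld4", "k_ld5", "k_ld6")] <- lapply(od[c("k_ld4", "k_ld5", "k_ld6")], cv)
      out$odd <- lapply(seq_len(nrow(od)), function(i) as.list(od[i, ]))
    }
    out$s_instance <- params$s_instance
  } else stop("unknown torsion_params variant")
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

.params_from_list <- function(x) {
  units <- if (is.null(x$units)) "kJmol" else x$units
  cv <- function(v) convert_energy(unlist(v), units, "kJmol")
  switch(toupper(x$model),
    ADDT = addt_params(deg2rad(x$phi_eq_deg), deg2rad(x$theta_eq_abc_deg),
                       deg2rad(x$theta_eq_bcd_deg), cv(x$k_modes),
                       s_inst = if (is.null(x$s_instance))
                         s_instance(deg2rad(x$phi_eq_deg)) else x$s_instance),
    CADT = cadt_params(deg2rad(x$phi_eq_deg), cv(x$k_modes),
                       s_inst = if (is.null(x$s_instance))
                         s_instance(deg2rad(x$phi_eq_deg)) else x$s_instance),
    ADCO = adco_params(deg2rad(x$phi_eq_training_deg), cv(x$k),
                       unlist(x$c_co), deg2rad(x$theta_eq_abc_deg),
                       deg2rad(x$theta_eq_bcd_deg)),
    CACO = caco_params(deg2rad(x$phi_eq_training_deg), cv(x$k),
                       unlist(x$c_co)),
    ADLD = {
      mk <- function(rows, cols) {
        if (is.null(rows)) return(NULL)
        df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
        df[cols] <- lapply(df[cols], function(v) convert_energy(v, units, "kJmol"))
        df
      }
      adld_params(even = mk(x$even, c("k_ld1", "k_ld2", "k_ld3")),
                  odd = mk(x$odd, c("k_ld4", "k_ld5", "k_ld6")),
                  s_inst = if (is.null(x$s_instance)) 0 else x$s_instance)
    },
    stop("unknown torsion model: ", x$model))
}

#' Read a torsion parameter block from YAML
#' @param path YAML file path
#' @return a `torsion_params` object (constants in kJ/mol)
#' @export
read_params_yaml <- function(path) {
  .params_from_list(yaml::read_yaml(path))
}

#' Write a flexibility model to YAML
#' @param model a [flexibility_model()]
#' @param path output path
#' @param units unit for the written constants
#' @return `path`, invisibly
#' @export
write_model_yaml <- function(model, path, units = c("kJmol", "eV")) {
  units <- match.arg(units)
  cv <- function(x) convert_energy(x, "kJmol", units)
  terms <- lapply(model$terms, function(t) {
    switch(t$kind,
      stretch = list(kind = "stretch", atoms = t$atoms, k = cv(t$k),
                     d_eq = t$d_eq),
      bend = list(kind = "bend", atoms = t$atoms, k = cv(t$k),
                  theta_eq_deg = rad2deg(t$theta_eq)),
      torsion = {
        tmp <- tempfile()
        write_params_yaml(t$params, tmp, units = units)
        pl <- yaml::read_yaml(tmp)
        unlink(tmp)
        pl$units <- NULL
        c(list(kind = "torsion", atoms = t$atoms), pl)
      },
      nonbonded = list(kind = "nonbonded", charges = t$charges,
                       lj_epsilon = if (is.null(t$lj_epsilon)) NULL else
                         apply(cv(t$lj_epsilon), 1, as.list),
                       lj_d = if (is.null(t$lj_d)) NULL else
                         apply(t$lj_d, 1, as.list),
                       exclusions = if (is.null(t$exclusions)) NULL else
                         apply(as.matrix(t$exclusions), 1, as.list)))
  })
  yaml::write_yaml(list(units = units, terms = terms), path, precision = 15)
  invisible(path)
}

#' Read a flexibility model from YAML
#' @param path YAML file path
#' @return a [flexibility_model()] (constants in kJ/mol)
#' @export
read_model_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  units <- if (is.null(x$units)) "kJmol" else x$units
  terms <- lapply(x$terms, function(t) {
    atoms <- unlist(t$atoms)
    switch(t$kind,
      stretch = flex_stretch(atoms, convert_energy(t$k, units, "kJmol"),
                             t$d_eq),
      bend = flex_bend(atoms, convert_energy(t$k, units, "kJmol"),
                       deg2rad(t$theta_eq_deg)),
      torsion = {
        t$units <- units
        flex_torsion(atoms, .params_from_list(t))
      },
      nonbonded = flex_nonbonded(
        unlist(t$charges),
        if (is.null(t$lj_epsilon)) NULL else
          convert_energy(do.call(rbind, lapply(t$lj_epsilon, unlist)),
                         units, "kJmol"),
        if (is.null(t$lj_d)) NULL else
          do.call(rbind, lapply(t$lj_d, unlist)),
        if (is.null(t$exclusions)) NULL else
          do.call(rbind, lapply(t$exclusions, unlist))),
      stop("unknown term kind in model YAML: ", t$kind))
  })
  flexibility_model(terms)
}

#' Write a report object as JSON
#' @param x a list (report content)
#' @param path output path, or `""` for stdout
#' @return `path`, invisibly
#' @export
write_report_json <- function(x, path = "") {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  if (identical(path, "")) cat(json, "\n") else writeLines(json, path)
  invisible(path)
}
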