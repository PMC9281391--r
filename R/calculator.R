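#' Calculator interface
#'
#' A calculator is anything that deterministically maps a structure to an
#' energy/forces/virial result: analytic toy potentials, fitted GAP models,
#' or the full delta-learning composite. External electronic-structure codes
#' can be plugged in by wrapping their invocation in `fn`.
#'
#' @param name tag identifying the calculator (used in model archives).
#' @param fn function(structure) returning an [efs_result()].
#' @param params optional parameter list stored alongside (serialised into
#'   archives for reconstruction).
#' @return object of class `dgap_calculator`.
#' @export
calculator <- function(name, fn, params = NULL) {
  stopifnot(is.function(fn))
  structure(list(name = name, fn = fn, params = params),
            class = "dgap_calculator")
}

#' Evaluate a calculator on a structure
#'
#' @param calc a [calculator()].
#' @param structure a [periodic_structure()].
#' @param forces whether force/virial output is required.
#' @return an [efs_result()].
#' @export
calc_evaluate <- function(calc, structure, forces = TRUE) {
  res <- calc$fn(structure, forces)
  if (!inherits(res, "efs_result")) stop("calculator returned a non-EFS result")
  res
}

#' Wrap a GAP model as a calculator
#' @param model a [fit_gap()] model.
#' @return a [calculator()].
#' @export
gap_calculator <- function(model) {
  calculator("gap", function(structure, forces = TRUE) {
    predict(model, structure, forces = forces)
  })
}

# named calculator factories, used when loading model archives
.calc_registry <- new.env(parent = emptyenv())

#' Register a calculator factory by name
#'
#' Model archives store only the baseline's name and parameters; on load the
#' factory registered under that name rebuilds it.
#'
#' @param name calculator name.
#' @param factory function(params) returning a [calculator()].
#' @export
register_calculator <- function(name, factory) {
  assign(name, factory, envir = .calc_registry)
  invisible(name)
}

resolve_calculator <- function(name, params) {
  if (!exists(name, envir = .calc_registry)) {
    stop("no calculator factory registered under '", name, "'")
  }
  get(name, envir = .calc_registry)(params)
}
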