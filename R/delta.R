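#' Delta-GAP composite model
#'
#' The delta-learning energy expression: a long-ranged physical baseline
#' plus short-ranged machine-learned corrections,
#' `E = E_baseline + sum_types sum_molecules dE_intra(monomer) + dE_inter(crystal)`,
#' with one intramolecular GAP per component type and a single
#' intermolecular GAP shared by all components. Corrections apply to
#' energies, forces and virials, so the composite supports full
#' variable-cell relaxation and constant-pressure dynamics.
#'
#' @param baseline a [calculator()].
#' @param intra_models named list of [fit_gap()] models, one per component
#'   type the model supports.
#' @param inter_model a single [fit_gap()] model for the intermolecular
#'   residual.
#' @param library the [component_library()] used for molecule typing.
#' @return object of class `delta_model`.
#' @export
delta_model <- function(baseline, intra_models, inter_model, library) {
  stopifnot(inherits(baseline, "dgap_calculator"),
            inherits(inter_model, "gap_model"),
            inherits(library, "component_library"))
  missing <- setdiff(names(intra_models), names(library$entries))
  if (length(missing)) {
    stop("intra models without library entries: ",
         paste(missing, collapse = ", "))
  }
  structure(list(baseline = baseline, intra_models = intra_models,
                 inter_model = inter_model, library = library),
            class = "delta_model")
}

#' Evaluate the delta-GAP composite on a structure
#'
#' Molecules are identified and typed, each monomer is unwrapped and passed
#' through its component's intramolecular correction (forces mapped back
#' onto the parent atoms, virial accumulated from the unwrapped geometry —
#' gauge-consistent because intramolecular forces sum to zero per
#' molecule), the intermolecular correction is evaluated on the full
#' periodic structure, and everything is added to the baseline.
#'
#' @param model a [delta_model()].
#' @param structure a [periodic_structure()]; every molecule must match a
#'   component with an intramolecular model.
#' @param forces compute forces/virial (default) or energies only.
#' @param tolerance bond-perception tolerance for molecule identification.
#' @return an [efs_result()] whose `decomposition` attribute holds the
#'   baseline energy, the per-type intramolecular sums and the
#'   intermolecular correction (summing exactly to the total).
#' @export
delta_gap_evaluate <- function(model, structure, forces = TRUE,
                               tolerance = 1.2) {
  base <- calc_evaluate(model$baseline, structure, forces = forces)
  units <- identify_molecules(structure, tolerance)
  units <- assign_component_types(units, structure, model$library, tolerance)
  types <- vapply(units, `[[`, "", "component_type")
  bad <- setdiff(unique(types), names(model$intra_models))
  if (length(bad)) {
    stop("no intramolecular model for component(s): ",
         paste(bad, collapse = ", "))
  }
  n <- n_atoms(structure)
  intra_by_type <- setNames(rep(0, length(model$intra_models)),
                            names(model$intra_models))
  Fi <- if (forces) matrix(0, n, 3L) else NULL
  Vi <- if (forces) matrix(0, 3L, 3L) else NULL
  for (k in seq_along(units)) {
    mono <- extract_monomer(structure, units[[k]])
    res <- predict(model$intra_models[[types[k]]], mono, forces = forces)
    intra_by_type[types[k]] <- intra_by_type[types[k]] + res$energy
    if (forces) {
      Fi[units[[k]]$atom_indices, ] <- Fi[units[[k]]$atom_indices, ] +
        res$forces
      Vi <- Vi + res$virial
    }
  }
  inter <- predict(model$inter_model, structure, forces = forces)
  energy <- base$energy + sum(intra_by_type) + inter$energy
  F <- if (forces) base$forces + Fi + inter$forces else NULL
  V <- if (forces && !is.null(base$virial)) base$virial + Vi + inter$virial
       else NULL
  out <- efs_result(energy, F, V)
  attr(out, "decomposition") <- list(baseline = base$energy,
                                     intra = intra_by_type,
                                     inter = inter$energy)
  out
}

#' Wrap a delta model as a calculator
#' @param model a [delta_model()].
#' @param tolerance bond-perception tolerance.
#' @return a [calculator()].
#' @export
delta_calculator <- function(model, tolerance = 1.2) {
  calculator("delta_gap", function(structure, forces = TRUE) {
    delta_gap_evaluate(model, structure, forces = forces,
                       tolerance = tolerance)
  })
}

#' Intramolecular training labels from gas-phase monomers
#'
#' Single-point target minus baseline differences on isolated molecules:
#' `energy = E_target - E_baseline`, `forces = F_target - F_baseline`.
#' Calculator failures skip the monomer with a warning (the exclusion is
#' recorded in the `excluded` attribute).
#'
#' @param monomers list of non-periodic [periodic_structure()] objects.
#' @param target,baseline [calculator()] objects.
#' @param weight_class tag passed to [training_observation()].
#' @return list of [training_observation()].
#' @export
label_intra <- function(monomers, target, baseline,
                        weight_class = "default") {
  out <- list(); excluded <- integer(0)
  for (i in seq_along(monomers)) {
    mono <- monomers[[i]]
    if (any(mono$pbc)) stop("monomers must be non-periodic")
    obs <- tryCatch({
      rt <- calc_evaluate(target, mono)
      rb <- calc_evaluate(baseline, mono)
      training_observation(mono, energy = rt$energy - rb$energy,
                           forces = rt$forces - rb$forces,
                           weight_class = weight_class)
    }, error = function(e) {
      warning("monomer ", i, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(obs)) excluded <- c(excluded, i) else {
      out[[length(out) + 1L]] <- obs
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Intermolecular training labels: the residual after intra corrections
#'
#' The intermolecular label is defined as the total delta residual after
#' subtracting the fitted intramolecular predictions, which makes the
#' composite energy expression exact by construction at training time:
#' `energy = [E_target - E_baseline](crystal) - sum_molecules dE_intra`,
#' and analogously for forces (and virials when both calculators provide
#' them).
#'
#' @param crystals list of periodic [periodic_structure()] objects.
#' @param target,baseline [calculator()] objects.
#' @param intra_models named list of fitted intramolecular [fit_gap()]
#'   models (one per component type present).
#' @param library a [component_library()].
#' @param with_virial include virial labels when available.
#' @param weight_class tag passed to [training_observation()].
#' @param tolerance bond-perception tolerance.
#' @return list of [training_observation()] (attribute `excluded` lists
#'   skipped crystals).
#' @export
label_inter <- function(crystals, target, baseline, intra_models, library,
                        with_virial = FALSE, weight_class = "default",
                        tolerance = 1.2) {
  out <- list(); excluded <- integer(0)
  for (i in seq_along(crystals)) {
    st <- crystals[[i]]
    obs <- tryCatch({
      rt <- calc_evaluate(target, st)
      rb <- calc_evaluate(baseline, st)
      units <- identify_molecules(st, tolerance)
      units <- assign_component_types(units, st, library, tolerance)
      de <- rt$energy - rb$energy
      df <- rt$forces - rb$forces
      dv <- if (with_virial && !is.null(rt$virial) && !is.null(rb$virial)) {
        rt$virial - rb$virial
      } else NULL
      for (u in units) {
        ty <- u$component_type
        if (!ty %in% names(intra_models)) {
          stop("no intra model for component '", ty, "'")
        }
        res <- predict(intra_models[[ty]], extract_monomer(st, u))
        de <- de - res$energy
        df[u$atom_indices, ] <- df[u$atom_indices, ] - res$forces
        if (!is.null(dv)) dv <- dv - res$virial
      }
      training_observation(st, energy = de, forces = df, virial = dv,
                           weight_class = weight_class)
    }, error = function(e) {
      warning("crystal ", i, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(obs)) excluded <- c(excluded, i) else {
      out[[length(out) + 1L]] <- obs
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Save / load a delta-model archive
#'
#' Bundles the intra/inter GAP models, the component library and the
#' baseline calculator's name and parameters into one JSON archive. On
#' load the baseline is rebuilt from the factory registered under its name
#' (see [register_calculator()]).
#'
#' @param model a [delta_model()].
#' @param path file path (JSON).
#' @export
save_delta_model <- function(model, path) {
  ser_gap <- function(g) {
    list(spec = unclass(g$spec), sparse_points = g$sparse_points,
         sparse_species = g$sparse_species, weights = g$weights,
         per_species_offset = as.list(g$per_species_offset),
         regularization = g$regularization, jitter = g$jitter)
  }
  lib <- lapply(model$library$entries, function(e) {
    list(species = e$species, bonds = e$bonds, geometry = e$geometry)
  })
  base_params <- lapply(model$baseline$params, function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  obj <- list(format = "dgap-delta-1",
              baseline = list(name = model$baseline$name,
                              params = base_params),
              intra = lapply(model$intra_models, ser_gap),
              inter = ser_gap(model$inter_model),
              library = lib)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_delta_model
#' @export
load_delta_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dgap-delta-1")) stop("unknown archive format")
  de_gap <- function(g) {
    spec <- do.call(soap_spec, g$spec[c("cutoff", "species", "n_max", "l_max",
                                        "sigma_atom", "zeta", "switch_width",
                                        "exclude_intramolecular")])
    structure(list(spec = spec, sparse_points = as.matrix(g$sparse_points),
                   sparse_species = g$sparse_species, weights = g$weights,
                   per_species_offset = unlist(g$per_species_offset),
                   regularization = g$regularization, jitter = g$jitter),
              class = "gap_model")
  }
  entries <- lapply(obj$library, function(e) {
    component_entry(e$species, as.matrix(e$bonds), as.matrix(e$geometry))
  })
  baseline <- resolve_calculator(obj$baseline$name, obj$baseline$params)
  delta_model(baseline, lapply(obj$intra, de_gap), de_gap(obj$inter),
              component_library(entries))
}
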