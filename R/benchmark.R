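# End-to-end delta-learning study on the toy universe: pool generation and
# baseline pre-relaxation, FPS selection of training and test sets,
# intra/inter label generation and GAP fitting, and the evaluation
# protocol (lattice-energy and force-component error statistics).

#' Co-former identifiers of the toy study
#' @return character vector of the four active/co-former pairs' co-formers.
#' @export
toy_study_pairs <- function() c("n2", "co", "co2", "o3")

#' Stoichiometries spanned for one active/co-former pair
#'
#' Both single-component crystals plus 1:1, 2:1 and 1:2 co-crystal
#' compositions, mirroring a screening pool that spans all stoichiometries.
#'
#' @param coformer co-former component id.
#' @return list of named count vectors.
#' @export
toy_pair_stoichiometries <- function(coformer) {
  out <- list(c(api = 1), setNames(1L, coformer),
              setNames(c(1L, 1L), c("api", coformer)),
              setNames(c(2L, 1L), c("api", coformer)),
              setNames(c(1L, 2L), c("api", coformer)))
  out
}

# relax that returns the last structure instead of failing
relax_or_last <- function(structure, calc, fmax, relax_cell, max_steps) {
  tryCatch(relax(structure, calc, fmax = fmax, relax_cell = relax_cell,
                 max_steps = max_steps),
           dgap_relax_error = function(e) e$structure)
}

# perturbed gas-phase configuration that keeps the component's bond graph:
# a distance-perceived topology change (broken or spurious bond) would put
# the configuration in a different molecule's basin and make its
# delta label meaningless as intramolecular training data
perturbed_monomer <- function(entry, amplitude, seed, max_tries = 25L) {
  ref <- periodic_structure(entry$species, entry$geometry, pbc = FALSE)
  want <- entry$bonds[order(entry$bonds[, 1], entry$bonds[, 2]), ,
                      drop = FALSE]
  for (t in seq_len(max_tries)) {
    cand <- perturb_structure(ref, amplitude, 0, seed + 1000003L * (t - 1L))
    got <- perceive_bonds(cand$species, cand$positions)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    if (identical(unname(got), unname(want))) return(cand)
  }
  stop("could not draw a topology-preserving perturbation (amplitude ",
       amplitude, ")")
}

#' Build one pair's trial-crystal pool
#'
#' Generates random trial crystals for every stoichiometry of the pair and
#' locally relaxes their atomic positions with the baseline calculator
#' (quasi-Newton, fixed cell), mirroring a screening pool of
#' baseline-relaxed candidates. Structures whose molecules no longer
#' round-trip to the requested composition are dropped.
#'
#' @param coformer co-former id.
#' @param library the toy [component_library()].
#' @param baseline baseline [calculator()].
#' @param n_per_composition structures per stoichiometry.
#' @param seed integer seed.
#' @param prerelax_steps optimizer-step cap of the pre-relaxation.
#' @param prerelax_fmax loose force target of the pre-relaxation (eV/A).
#' @return list with `structures` and parallel `composition` list.
#' @export
make_toy_pool <- function(coformer, library, baseline, n_per_composition,
                          seed, prerelax_steps = 300L, prerelax_fmax = 0.05) {
  raw <- generate_trial_crystals(library, toy_pair_stoichiometries(coformer),
                                 n_per_composition, seed)
  structures <- list(); comps <- list()
  for (st in raw) {
    rel <- tryCatch(
      relax_or_last(st, baseline, prerelax_fmax, FALSE, prerelax_steps),
      error = function(e) NULL)
    if (is.null(rel)) next
    ok <- tryCatch({
      tab <- composition_of(rel, library)
      comp <- attr(st, "composition")
      identical(sort(names(tab[tab > 0])), sort(names(comp))) &&
        all(tab[names(comp)] == comp)
    }, error = function(e) FALSE)
    if (ok) {
      attr(rel, "composition") <- attr(st, "composition")
      structures[[length(structures) + 1L]] <- rel
      comps[[length(comps) + 1L]] <- attr(st, "composition")
    }
  }
  list(structures = structures, composition = comps)
}

#' Default SOAP specs of the toy study
#'
#' Short-cutoff descriptors for the intramolecular corrections, longer
#' cutoff for the intermolecular one (the two corrections live on
#' different length scales); sized for the toy universe's three species
#' and 2-3 atom molecules.
#'
#' @return list with elements `intra` and `inter`.
#' @export
toy_soap_specs <- function() {
  list(intra = soap_spec(3.0, species = c("C", "N", "O"), n_max = 6L,
                         l_max = 3L, sigma_atom = 0.5, zeta = 4),
       inter = soap_spec(5.0, species = c("C", "N", "O"), n_max = 10L,
                         l_max = 2L, sigma_atom = 0.30, zeta = 4,
                         exclude_intramolecular = TRUE))
}

#' Regularisation used for the (noise-free) toy labels
#' @return regularization list for [fit_gap()].
#' @export
toy_regularization <- function() {
  list(default = c(energy = 2e-4, force = 0.004, virial = 0.05),
       perturbed = c(energy = 2e-3, force = 0.04, virial = 0.2))
}

#' Run the full toy delta-learning benchmark
#'
#' The package's central validation: on four active/co-former pairs, build
#' baseline-pre-relaxed pools, select training and test crystals by
#' farthest point sampling (test selection includes the training set to
#' maximise distance), augment with relaxed-and-perturbed single-component
#' crystals, fit per-component intramolecular corrections on gas-phase
#' monomers and a single intermolecular correction on the residuals, and
#' score baseline vs delta-GAP lattice energies and force components
#' against the target calculator on the held-out test sets.
#'
#' @param seed master seed; every random stage derives from it.
#' @param n_pool_per_comp pool structures per stoichiometry (5 per pair).
#' @param n_train,n_test FPS-selected training/test crystals per pair.
#' @param n_sparse_inter,n_sparse_intra sparse points of the inter/intra
#'   models.
#' @param n_gas_configs perturbed gas-phase configurations per component.
#' @param n_mono_per_component monomers drawn from training crystals.
#' @param prerelax_steps pool pre-relaxation step cap.
#' @param augment include relaxed-and-perturbed single-component crystals
#'   (the known-crystal analogue) in the intermolecular training set.
#' @param verbose print stage timings.
#' @return list: `model` (the [delta_model()]), `gas_refs`, per-pair test
#'   `results`, and `summary` (lattice-energy and force-component
#'   [error_summary()] objects for baseline and delta-GAP, plus
#'   improvement ratios).
#' @export
toy_delta_benchmark <- function(seed = 1L, n_pool_per_comp = 120L,
                                n_train = 150L, n_test = 100L,
                                n_sparse_inter = 450L, n_sparse_intra = 80L,
                                n_gas_configs = 120L,
                                n_mono_per_component = 150L,
                                prerelax_steps = 300L, augment = TRUE,
                                verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  elapsed <- function() sprintf("[%5.1f s]", as.numeric(Sys.time() - t0,
                                                        units = "secs"))
  library <- make_toy_components()
  baseline <- toy_baseline()
  target <- toy_target()
  specs <- toy_soap_specs()
  reg <- toy_regularization()
  pairs <- toy_study_pairs()

  pools <- list(); train_sets <- list(); test_sets <- list()
  aug_sets <- list(); aug_relaxed <- list(); aug_perturbed <- list()
  for (pi in seq_along(pairs)) {
    cf <- pairs[pi]
    pool <- make_toy_pool(cf, library, baseline, n_pool_per_comp,
                          seed + 101L * pi, prerelax_steps = prerelax_steps)
    say("%s pair %s: pool %d", elapsed(), cf, length(pool$structures))
    eb <- vapply(pool$structures,
                 function(s) calc_evaluate(baseline, s, forces = FALSE)$energy,
                 0)
    desc <- lapply(pool$structures, compute_soap, spec = specs$inter)
    sel_tr <- fps_select(desc, min(n_train, length(desc)),
                         seed_index = which.min(eb), zeta = specs$inter$zeta)
    rest <- setdiff(seq_along(desc), sel_tr$chosen)
    sel_te <- fps_select(desc[rest], min(n_test, length(rest)),
                         preselected = desc[sel_tr$chosen],
                         zeta = specs$inter$zeta)
    train_sets[[cf]] <- pool$structures[sel_tr$chosen]
    test_sets[[cf]] <- pool$structures[rest[sel_te$chosen]]
    # dense known-crystal augmentation: the most stable single-component
    # and co-crystal pool entries, compacted and fully relaxed (cell
    # included) with the baseline, plus random perturbations — covering
    # the compressed regime the loosely packed pool never visits
    aug <- list()
    if (augment) {
      bases <- integer(0)
      for (comp in c("api", cf)) {
        singles <- which(vapply(pool$composition, function(cc) {
          length(cc) == 1L && names(cc) == comp
        }, TRUE))
        if (length(singles)) bases <- c(bases, singles[which.min(eb[singles])])
      }
      multis <- which(vapply(pool$composition, function(cc) {
        length(cc) == 2L && sum(cc) >= 3L
      }, TRUE))
      if (length(multis)) {
        bases <- c(bases, multis[order(eb[multis])][1:min(2L, length(multis))])
      }
      for (bi in seq_along(bases)) {
        add <- tryCatch({
          st0 <- compress_structure(pool$structures[[bases[bi]]],
                                    vol_per_molecule = 140)
          relaxed <- relax_or_last(st0, baseline, 0.05, TRUE, 300L)
          composition_of(relaxed, library) # validates molecule integrity
          c(list(relaxed),
            lapply(1:2, function(k) {
              perturb_structure(relaxed, 0.05, 0.015,
                                seed + 977L * pi + 31L * bi + k)
            }))
        }, error = function(e) list())
        aug <- c(aug, add)
      }
    }
    aug_sets[[cf]] <- aug
    aug_relaxed[[cf]] <- aug[seq_along(aug) %% 3 == 1]   # the minima
    aug_perturbed[[cf]] <- aug[seq_along(aug) %% 3 != 1] # their perturbations
    say("%s pair %s: train %d test %d aug %d", elapsed(), cf,
        length(train_sets[[cf]]), length(test_sets[[cf]]), length(aug))
  }

  # ---- intramolecular corrections, one per component
  components <- c("api", pairs)
  intra_models <- list()
  for (ci in seq_along(components)) {
    comp <- components[ci]
    entry <- library$entries[[comp]]
    ref <- periodic_structure(entry$species, entry$geometry, pbc = FALSE)
    monos <- list(ref)
    amps <- c(0.03, 0.07, 0.12)
    per_amp <- ceiling(n_gas_configs / length(amps))
    for (ai in seq_along(amps)) {
      monos <- c(monos, lapply(seq_len(per_amp), function(k) {
        perturbed_monomer(entry, amps[ai], seed + 7919L * ci + 97L * ai + k)
      }))
    }
    # monomers extracted from the training crystals
    crys_monos <- list()
    for (cf in pairs) {
      for (st in train_sets[[cf]]) {
        units <- identify_molecules(st)
        units <- assign_component_types(units, st, library)
        for (u in units) {
          if (u$component_type == comp) {
            crys_monos[[length(crys_monos) + 1L]] <- extract_monomer(st, u)
          }
        }
      }
    }
    if (length(crys_monos) > n_mono_per_component) {
      keep <- withr::with_seed(seed + ci,
                               sample.int(length(crys_monos),
                                          n_mono_per_component))
      crys_monos <- crys_monos[keep]
    }
    obs <- label_intra(c(monos, crys_monos), target, baseline)
    intra_models[[comp]] <- fit_gap(obs, specs$intra,
                                    m_sparse = min(n_sparse_intra,
                                                   3L * length(obs)),
                                    regularization = reg, seed = seed + ci)
    say("%s intra '%s': %d monomers", elapsed(), comp, length(obs))
  }

  # ---- single intermolecular correction across all pairs; the dense
  # known-crystal augmentation carries the looser "perturbed" noise class
  iobs <- c(
    label_inter(do.call(c, unname(train_sets)), target, baseline,
                intra_models, library),
    label_inter(do.call(c, unname(aug_relaxed)), target, baseline,
                intra_models, library),
    label_inter(do.call(c, unname(aug_perturbed)), target, baseline,
                intra_models, library, weight_class = "perturbed"))
  say("%s inter labels: %d crystals", elapsed(), length(iobs))
  inter_model <- fit_gap(iobs, specs$inter, m_sparse = n_sparse_inter,
                         regularization = reg, seed = seed + 17L)
  say("%s inter model fitted (%d sparse points)", elapsed(), n_sparse_inter)
  model <- delta_model(baseline, intra_models, inter_model, library)
  delta_calc <- delta_calculator(model)

  # ---- optimised gas-phase references per method, for lattice energies
  gas_refs <- list()
  for (m in c("baseline", "target", "delta")) {
    calc <- switch(m, baseline = baseline, target = target,
                   delta = delta_calc)
    gas_refs[[m]] <- vapply(components, function(comp) {
      entry <- library$entries[[comp]]
      ref <- periodic_structure(entry$species, entry$geometry, pbc = FALSE)
      relax_or_last(ref, calc, 0.005, FALSE, 200L)$labels$energy
    }, 0)
  }
  say("%s gas references done", elapsed())

  # ---- held-out evaluation
  results <- list()
  lat_b <- lat_d <- lat_t <- numeric(0)
  f_b <- f_d <- f_t <- list()
  for (cf in pairs) {
    for (st in test_sets[[cf]]) {
      counts <- attr(st, "composition")
      rb <- calc_evaluate(baseline, st)
      rt <- calc_evaluate(target, st)
      rd <- delta_gap_evaluate(model, st)
      lat_b <- c(lat_b, lattice_energy(rb$energy, gas_refs$baseline, counts))
      lat_t <- c(lat_t, lattice_energy(rt$energy, gas_refs$target, counts))
      lat_d <- c(lat_d, lattice_energy(rd$energy, gas_refs$delta, counts))
      f_b[[length(f_b) + 1L]] <- rb$forces
      f_t[[length(f_t) + 1L]] <- rt$forces
      f_d[[length(f_d) + 1L]] <- rd$forces
    }
    results[[cf]] <- list(n_test = length(test_sets[[cf]]))
  }
  say("%s test evaluation done (%d crystals)", elapsed(), length(lat_t))

  fb <- unlist(f_b); ft <- unlist(f_t); fd <- unlist(f_d)
  summary <- list(
    lattice_baseline = error_summary(lat_b, lat_t),
    lattice_delta = error_summary(lat_d, lat_t),
    force_baseline = error_summary(fb, ft),
    force_delta = error_summary(fd, ft))
  summary$lattice_improvement <-
    summary$lattice_baseline$mae / summary$lattice_delta$mae
  summary$force_improvement <-
    summary$force_baseline$mae / summary$force_delta$mae

  list(model = model, gas_refs = gas_refs, train_sets = train_sets,
       test_sets = test_sets, results = results, summary = summary,
       specs = specs, seed = seed)
}

#' Relaxation comparison study on held-out toy co-crystals
#'
#' Emulates the experimental-structure comparison of co-crystal screening
#' studies: each held-out co-crystal is compacted and fully relaxed with
#' the target calculator to produce a well-defined reference minimum (the
#' stand-in for an experimentally known structure), and that reference is
#' then fully relaxed (positions and cell) with the baseline and with the
#' delta-GAP model. The over-binding baseline contracts away from the
#' reference; the delta model should stay near it.
#'
#' @param bm a [toy_delta_benchmark()] result.
#' @param n_structures number of multi-molecule test crystals to use.
#' @param fmax convergence threshold (eV/A).
#' @param max_steps optimizer step budget per relaxation.
#' @return data.frame with columns `rho_base`, `rho_target`, `rho_delta`
#'   (g/cm^3, one row per structure).
#' @export
toy_relaxation_study <- function(bm, n_structures = 12L, fmax = 0.03,
                                 max_steps = 500L) {
  baseline <- toy_baseline()
  target <- toy_target()
  dcalc <- delta_calculator(bm$model)
  per_pair <- list()
  for (cf in toy_study_pairs()) {
    cand <- Filter(function(s) {
      cc <- attr(s, "composition")
      !is.null(cc) && length(cc) == 2L && sum(cc) >= 3L
    }, bm$test_sets[[cf]])
    per_pair[[cf]] <- head(cand, n_structures)
  }
  # interleave the pairs so the first successes span all co-formers
  starts <- list()
  for (k in seq_len(n_structures)) {
    for (cf in toy_study_pairs()) {
      if (k <= length(per_pair[[cf]])) {
        starts <- c(starts, per_pair[[cf]][k])
      }
    }
  }
  rows <- list()
  for (si in seq_along(starts)) {
    if (length(rows) >= n_structures) break
    ref <- tryCatch({
      st <- compress_structure(starts[[si]],
                               vol_per_molecule = 130 + 10 * (si %% 5))
      relax_or_last(st, target, fmax, TRUE, max_steps)
    }, error = function(e) NULL)
    if (is.null(ref)) next
    rb <- tryCatch(relax_or_last(ref, baseline, fmax, TRUE, max_steps),
                   error = function(e) NULL)
    rd <- tryCatch(relax_or_last(ref, dcalc, fmax, TRUE, max_steps),
                   error = function(e) NULL)
    if (is.null(rb) || is.null(rd)) next
    rows[[length(rows) + 1L]] <- data.frame(
      rho_base = structure_density(rb),
      rho_target = structure_density(ref),
      rho_delta = structure_density(rd))
  }
  do.call(rbind, rows)
}
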