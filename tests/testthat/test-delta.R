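specs_cno <- list(
  intra = soap_spec(3.0, species = c("C", "N", "O"), n_max = 4L, l_max = 2L,
                    zeta = 4),
  inter = soap_spec(5.0, species = c("C", "N", "O"), n_max = 4L, l_max = 2L,
                    zeta = 4, exclude_intramolecular = TRUE))

zero_gap <- function(spec, n_sparse = 3) {
  # a model with all-zero weights and offsets: the null correction
  sp <- compute_soap(random_cluster(n_sparse, seed = 1,
                                    species = c("C", "N", "O")), spec)
  structure(list(spec = spec, sparse_points = sp$vectors,
                 sparse_species = sp$center_species,
                 weights = rep(0, nrow(sp$vectors)),
                 per_species_offset = c(C = 0, N = 0, O = 0),
                 regularization = NULL, jitter = 0),
            class = "gap_model")
}

mini_delta <- function(seed = 1) {
  # a small but real delta model fitted on one api/co2 pair
  lib <- make_toy_components()
  base <- toy_baseline(); targ <- toy_target()
  reg <- list(default = c(energy = 5e-4, force = 0.01, virial = 0.05))
  intra <- list()
  for (comp in c("api", "co2")) {
    e <- lib$entries[[comp]]
    ref <- periodic_structure(e$species, e$geometry, pbc = FALSE)
    monos <- c(list(ref), lapply(1:45, function(i) {
      dgap:::perturbed_monomer(e, c(0.03, 0.07, 0.12)[1 + (i %% 3)],
                               seed * 1000 + i)
    }))
    intra[[comp]] <- fit_gap(label_intra(monos, targ, base), specs_cno$intra,
                             m_sparse = 30, regularization = reg,
                             seed = seed)
  }
  train <- toy_crystal_set(8, seed = seed + 5)
  iobs <- label_inter(train, targ, base, intra, lib)
  inter <- fit_gap(iobs, specs_cno$inter, m_sparse = 60,
                   regularization = reg, seed = seed)
  delta_model(base, intra, inter, lib)
}

test_that("all-zero corrections reproduce the baseline exactly", {
  lib <- make_toy_components()
  base <- toy_baseline()
  dm <- delta_model(base,
                    list(api = zero_gap(specs_cno$intra),
                         co2 = zero_gap(specs_cno$intra)),
                    zero_gap(specs_cno$inter), lib)
  st <- toy_crystal_set(1, seed = 101, prerelax = FALSE)[[3]]
  r0 <- calc_evaluate(base, st)
  r1 <- delta_gap_evaluate(dm, st)
  expect_equal(r1$energy, r0$energy, tolerance = 1e-12)
  expect_equal(r1$forces, r0$forces, tolerance = 1e-12)
  expect_equal(r1$virial, r0$virial, tolerance = 1e-12)
})

test_that("the reported decomposition sums exactly to the total", {
  dm <- mini_delta(seed = 2)
  for (st in toy_crystal_set(2, seed = 113)[1:6]) {
    r <- delta_gap_evaluate(dm, st)
    dec <- attr(r, "decomposition")
    expect_lt(abs(r$energy - (dec$baseline + sum(dec$intra) + dec$inter)),
              1e-10)
  }
})

test_that("single molecule in a huge cell: intra correction equals the
           gas-phase prediction", {
  dm <- mini_delta(seed = 3)
  lib <- dm$library
  e <- lib$entries$api
  st <- periodic_structure(e$species, e$geometry + 15, diag(3) * 40, TRUE)
  r <- delta_gap_evaluate(dm, st)
  dec <- attr(r, "decomposition")
  mono <- periodic_structure(e$species, e$geometry, pbc = FALSE)
  gas <- predict(dm$intra_models$api, mono, forces = FALSE)$energy
  expect_equal(unname(sum(dec$intra)), gas, tolerance = 1e-8)
  expect_equal(r$energy - dec$baseline - dec$inter, unname(sum(dec$intra)),
               tolerance = 1e-10)
})

test_that("intra labels follow target minus baseline with sane identities", {
  lib <- make_toy_components()
  base <- toy_baseline(); targ <- toy_target()
  e <- lib$entries$co2
  monos <- lapply(1:4, function(i) {
    perturb_structure(periodic_structure(e$species, e$geometry, pbc = FALSE),
                      0.05, 0, seed = i)
  })
  # target == baseline -> all labels zero
  obs0 <- label_intra(monos, base, base)
  expect_true(all(abs(vapply(obs0, `[[`, 0, "energy")) < 1e-14))
  expect_true(all(abs(unlist(lapply(obs0, `[[`, "forces"))) < 1e-14))
  # target = baseline + c per atom -> energy labels c*n, zero forces
  cpa <- 0.25
  shifted <- calculator("shifted", function(st, forces = TRUE) {
    r <- calc_evaluate(base, st, forces)
    r$energy <- r$energy + cpa * length(st$species)
    r
  })
  obs1 <- label_intra(monos, shifted, base)
  expect_true(all(abs(vapply(obs1, `[[`, 0, "energy") -
                      cpa * 3) < 1e-12))
  expect_true(all(abs(unlist(lapply(obs1, `[[`, "forces"))) < 1e-14))
  # labels invariant under rigid rotation of the monomer
  R <- random_rotation_matrix(3)
  rot <- lapply(monos, function(m) {
    m$positions <- m$positions %*% R
    m
  })
  obs_r <- label_intra(rot, targ, base)
  obs <- label_intra(monos, targ, base)
  expect_equal(vapply(obs_r, `[[`, 0, "energy"),
               vapply(obs, `[[`, 0, "energy"), tolerance = 1e-10)
})

test_that("inter labels are the exact bookkeeping residual", {
  lib <- make_toy_components()
  base <- toy_baseline(); targ <- toy_target()
  dm <- mini_delta(seed = 4)
  crystals <- toy_crystal_set(2, seed = 131)[2:5]
  obs <- label_inter(crystals, targ, base, dm$intra_models, lib)
  for (k in seq_along(obs)) {
    st <- obs[[k]]$structure
    eb <- calc_evaluate(base, st)$energy
    et <- calc_evaluate(targ, st)$energy
    units <- assign_component_types(identify_molecules(st), st, lib)
    intra_sum <- sum(vapply(units, function(u) {
      predict(dm$intra_models[[u$component_type]],
              extract_monomer(st, u), forces = FALSE)$energy
    }, 0))
    expect_lt(abs(obs[[k]]$energy + intra_sum + eb - et), 1e-10)
  }
  # target == baseline -> labels equal minus the intra predictions
  obs0 <- label_inter(crystals[1], base, base, dm$intra_models, lib)
  st <- crystals[[1]]
  units <- assign_component_types(identify_molecules(st), st, lib)
  intra_sum <- sum(vapply(units, function(u) {
    predict(dm$intra_models[[u$component_type]],
            extract_monomer(st, u), forces = FALSE)$energy
  }, 0))
  expect_equal(obs0[[1]]$energy, -intra_sum, tolerance = 1e-10)
})

test_that("delta forces match finite differences of the delta energy", {
  dm <- mini_delta(seed = 5)
  st <- toy_crystal_set(1, seed = 149)[[3]]
  res <- delta_gap_evaluate(dm, st)
  efun <- function(s) delta_gap_evaluate(dm, s, forces = FALSE)$energy
  expect_lt(max(abs(res$forces - fd_forces(efun, st))), 1e-5)
})

test_that("delta archives round-trip through JSON", {
  dm <- mini_delta(seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_delta_model(dm, path)
  back <- load_delta_model(path)
  st <- toy_crystal_set(1, seed = 151)[[4]]
  r1 <- delta_gap_evaluate(dm, st)
  r2 <- delta_gap_evaluate(back, st)
  expect_equal(r2$energy, r1$energy, tolerance = 1e-10)
  expect_equal(r2$forces, r1$forces, tolerance = 1e-9)
})
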