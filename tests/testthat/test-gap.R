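gap_spec <- soap_spec(3.0, species = c("N", "O"), n_max = 5L, l_max = 3L,
                      sigma_atom = 0.5, zeta = 4)
tight <- list(default = c(energy = 1e-6, force = 1e-4, virial = 1e-3))

# label source for regression fixtures: a toy pair potential whose LJ well
# (sigma ~2.1 A) sits inside the descriptor cutoff, so compact clusters
# carry O(1) eV energies and O(1) eV/A forces
cluster_calc <- toy_calculator(
  toy_potential_params(pair_epsilon = c(N = 0.22, O = 0.25, C = 0.23),
                       pair_sigma = c(N = 2.1, O = 2.0, C = 2.2),
                       cutoff = 2.95, switch_on = 2.4),
  name = "toy_cluster")

obs_set <- function(n, seed, with_forces = TRUE) {
  lapply(seq_len(n), function(k) {
    st <- compact_cluster(seed = seed * 100 + k)
    res <- calc_evaluate(cluster_calc, st)
    training_observation(st, energy = res$energy,
                         forces = if (with_forces) res$forces else NULL)
  })
}

test_that("sparse-point FPS picks duplicates last and can take everything", {
  sts <- lapply(1:3, function(k) compact_cluster(seed = 40 + k))
  sp_all <- select_sparse_points(sts, 12, gap_spec, seed = 1)
  expect_equal(nrow(sp_all$vectors), 12L)
  # duplicate environments (copy of a structure) are never chosen before
  # all distinct environments
  sts2 <- c(sts, sts[1])
  sel <- select_sparse_points(sts2, 16, gap_spec, seed = 1)
  expect_false(any(duplicated(sel$vectors[1:12, ])))
  expect_error(select_sparse_points(sts, 100, gap_spec), "exceeds")
})

test_that("fit_gap interpolates training energies in the full-GP limit", {
  # sparse points = every training environment, tiny noise targets:
  # training energies must be reproduced to solver precision
  sts <- lapply(1:6, function(k) compact_cluster(seed = 70 + k))
  obs <- lapply(sts, function(st) {
    r <- calc_evaluate(cluster_calc, st)
    training_observation(st, energy = r$energy)
  })
  sp <- select_sparse_points(sts, 24, gap_spec, seed = 2)
  fit <- fit_gap(obs, gap_spec, sparse_points = sp,
                 regularization = list(default = c(energy = 1e-7,
                                                   force = 1e-4,
                                                   virial = 1e-3)))
  for (o in obs) {
    expect_lt(abs(predict(fit, o$structure, forces = FALSE)$energy -
                  o$energy), 1e-6)
  }
})

test_that("a constant per-atom energy shift is absorbed by the offsets", {
  obs <- obs_set(8, seed = 3, with_forces = FALSE)
  fit0 <- fit_gap(obs, gap_spec, m_sparse = 12, seed = 5)
  cshift <- 3.7
  obs2 <- lapply(obs, function(o) {
    o$energy <- o$energy + cshift * length(o$structure$species)
    o
  })
  fit1 <- fit_gap(obs2, gap_spec, m_sparse = 12, seed = 5)
  probe <- compact_cluster(seed = 999)
  e0 <- predict(fit0, probe, forces = FALSE)$energy
  e1 <- predict(fit1, probe, forces = FALSE)$energy
  expect_equal(e1 - e0, cshift * length(probe$species), tolerance = 1e-6)
})

test_that("force labels reduce held-out force error on noisy data", {
  # few training structures: energies alone underdetermine the model,
  # force labels supply 12 extra constraints per structure
  one_species <- function(n, seed) {
    lapply(seq_len(n), function(k) {
      st <- compact_cluster(seed = seed * 100 + k, species = "O")
      res <- calc_evaluate(cluster_calc, st)
      training_observation(st, energy = res$energy, forces = res$forces)
    })
  }
  withr::with_seed(11, {
    train <- one_species(5, seed = 20)
    train_e <- lapply(train, function(o) {
      training_observation(o$structure,
                           energy = o$energy + rnorm(1, sd = 0.01))
    })
    train_ef <- lapply(train, function(o) {
      training_observation(o$structure,
                           energy = o$energy + rnorm(1, sd = 0.01),
                           forces = o$forces +
                             matrix(rnorm(12, sd = 0.01), ncol = 3))
    })
  })
  reg <- list(default = c(energy = 0.01, force = 0.03, virial = 0.1))
  sp <- select_sparse_points(lapply(train, `[[`, "structure"), 20, gap_spec,
                             seed = 4)
  fe <- fit_gap(train_e, gap_spec, sparse_points = sp, regularization = reg)
  fef <- fit_gap(train_ef, gap_spec, sparse_points = sp, regularization = reg)
  test <- one_species(8, seed = 50)
  rmse <- function(fit) {
    sqrt(mean(unlist(lapply(test, function(o) {
      (predict(fit, o$structure)$forces - o$forces)^2
    }))))
  }
  expect_lt(rmse(fef), rmse(fe))
})

test_that("predicted forces and virial match finite differences", {
  obs <- obs_set(6, seed = 6)
  fit <- fit_gap(obs, gap_spec, m_sparse = 18, seed = 7)
  st <- compact_cluster(seed = 321)
  res <- predict(fit, st)
  efun <- function(s) predict(fit, s, forces = FALSE)$energy
  expect_lt(max(abs(res$forces - fd_forces(efun, st))), 1e-5)
  expect_equal(sum(attr(res, "local_energies")), res$energy,
               tolerance = 1e-10)

  # periodic structure for the strain derivative
  stp <- toy_crystal_set(1, seed = 61, prerelax = FALSE)[[3]]
  spec_cno <- soap_spec(3.0, species = c("C", "N", "O"), n_max = 4L,
                        l_max = 2L, zeta = 4)
  obs_p <- lapply(toy_crystal_set(1, seed = 62, prerelax = FALSE)[2:4],
                  function(s) {
                    r <- calc_evaluate(toy_target(), s)
                    training_observation(s, energy = r$energy,
                                         forces = r$forces)
                  })
  fit_p <- fit_gap(obs_p, spec_cno, m_sparse = 15, seed = 8)
  res_p <- predict(fit_p, stp)
  efun_p <- function(s) predict(fit_p, s, forces = FALSE)$energy
  expect_lt(max(abs(res_p$virial - fd_virial(efun_p, stp))), 1e-5)
})

test_that("predictions are extensive and rotation-covariant", {
  spec_cno <- soap_spec(3.0, species = c("C", "N", "O"), n_max = 4L,
                        l_max = 2L, zeta = 4)
  obs_p <- lapply(toy_crystal_set(1, seed = 65, prerelax = FALSE)[2:4],
                  function(s) {
                    r <- calc_evaluate(toy_target(), s)
                    training_observation(s, energy = r$energy,
                                         forces = r$forces)
                  })
  fit <- fit_gap(obs_p, spec_cno, m_sparse = 12, seed = 9)
  st <- toy_crystal_set(1, seed = 66, prerelax = FALSE)[[3]]
  e1 <- predict(fit, st, forces = FALSE)$energy
  # 1x1x2 supercell doubles the energy
  st2 <- periodic_structure(rep(st$species, 2),
                            rbind(st$positions,
                                  sweep(st$positions, 2, st$cell[3, ], `+`)),
                            cell = diag(c(1, 1, 2)) %*% st$cell, pbc = TRUE)
  expect_equal(predict(fit, st2, forces = FALSE)$energy, 2 * e1,
               tolerance = 1e-8)
  # rotation: energy invariant, forces co-rotate
  R <- random_rotation_matrix(13)
  str <- st
  str$positions <- st$positions %*% R
  str$cell <- st$cell %*% R
  res <- predict(fit, st); resr <- predict(fit, str)
  expect_equal(resr$energy, res$energy, tolerance = 1e-8)
  expect_lt(max(abs(resr$forces - res$forces %*% R)), 1e-8)
})

test_that("model archives round-trip predictions exactly", {
  obs <- obs_set(5, seed = 77)
  fit <- fit_gap(obs, gap_spec, m_sparse = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_gap_model(fit, path)
  back <- load_gap_model(path)
  st <- compact_cluster(seed = 500)
  expect_equal(predict(back, st)$energy, predict(fit, st)$energy,
               tolerance = 1e-9)
  expect_equal(predict(back, st)$forces, predict(fit, st)$forces,
               tolerance = 1e-8)
})

test_that("fit_gap rejects label-free observations and uncovered species", {
  expect_error(training_observation(random_cluster(3, seed = 1)),
               "at least one label")
  obs <- obs_set(3, seed = 88)
  spec_small <- soap_spec(3.0, species = "O", n_max = 4L, l_max = 2L)
  expect_error(fit_gap(obs, spec_small, m_sparse = 5),
               "species")
})
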