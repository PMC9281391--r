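test_that("relax returns an already-converged structure unchanged", {
  base <- toy_baseline()
  p <- toy_baseline_params()
  st <- periodic_structure(c("N", "N"),
                           rbind(c(0, 0, 0), c(p$bond_r0[["N-N"]], 0, 0)),
                           pbc = FALSE)
  out <- relax(st, base, fmax = 0.01)
  expect_identical(out$positions, st$positions)
})

test_that("a stretched diatomic relaxes to the analytic equilibrium", {
  base <- toy_baseline()
  p <- toy_baseline_params()
  st <- periodic_structure(c("C", "O"),
                           rbind(c(0, 0, 0), c(p$bond_r0[["C-O"]] + 0.25, 0, 0)),
                           pbc = FALSE)
  out <- relax(st, base, fmax = 1e-5)
  expect_equal(as.numeric(dist(out$positions)), p$bond_r0[["C-O"]],
               tolerance = 1e-4)
  # idempotence
  out2 <- relax(out, base, fmax = 1e-5)
  expect_identical(out2$positions, out$positions)
})

test_that("variable-cell relaxation reduces energy and reaches the force
           and stress targets", {
  targ <- toy_target()
  st <- toy_crystal_set(1, seed = 301)[[4]]
  e0 <- calc_evaluate(targ, st, forces = FALSE)$energy
  out <- relax(st, targ, fmax = 0.02, relax_cell = TRUE, max_steps = 2000)
  res <- out$labels
  expect_lt(res$energy, e0)
  expect_lte(max(abs(res$forces)), 0.02)
  expect_lte(max(abs(res$virial)) / cell_volume(out)^(1 / 3), 0.02)
})

test_that("relax raises a structured error on non-convergence", {
  targ <- toy_target()
  st <- toy_crystal_set(1, seed = 307, prerelax = FALSE)[[3]]
  err <- tryCatch(relax(st, targ, fmax = 1e-9, max_steps = 3L),
                  dgap_relax_error = function(e) e)
  expect_s3_class(err, "dgap_relax_error")
  expect_s3_class(err$structure, "periodic_structure")
  expect_true(is.finite(err$residual))
})

test_that("NVT Langevin dynamics equilibrates to the set temperature", {
  targ <- toy_target()
  st <- relax(toy_crystal_set(1, seed = 311)[[4]], targ, fmax = 0.05,
              relax_cell = TRUE, max_steps = 1500)
  traj <- run_npt(st, targ, temperature = 120, n_steps = 6000,
                  timestep = 1, seed = 5, barostat = FALSE,
                  sample_interval = 10)
  tmean <- mean(tail(traj$thermo$temperature, 400))
  expect_equal(tmean, 120, tolerance = 0.10)
})

test_that("the zero-temperature limit stays at the minimum", {
  targ <- toy_target()
  st <- relax(toy_crystal_set(1, seed = 313)[[3]], targ, fmax = 1e-5,
              relax_cell = FALSE, max_steps = 3000)
  traj <- run_npt(st, targ, temperature = 0, n_steps = 300, timestep = 0.5,
                  seed = 2, barostat = FALSE, sample_interval = 50)
  final <- traj$frames[[length(traj$frames)]]
  expect_lt(max(abs(final$positions - st$positions)), 1e-6)
})

test_that("higher pressure gives higher (or equal) mean density", {
  targ <- toy_target()
  st <- relax(toy_crystal_set(1, seed = 317)[[4]], targ, fmax = 0.05,
              relax_cell = TRUE, max_steps = 1500)
  d1 <- mean_density(run_npt(st, targ, temperature = 150, pressure = 1,
                             n_steps = 3000, seed = 11))
  d2 <- mean_density(run_npt(st, targ, temperature = 150, pressure = 3e4,
                             n_steps = 3000, seed = 11))
  expect_lte(d1[["mean"]], d2[["mean"]] + 0.005)
})

test_that("mean_density block averaging follows its closed forms", {
  mk_traj <- function(rho) {
    structure(list(frames = list(),
                   thermo = data.frame(step = seq_along(rho), density = rho)),
              class = "trajectory")
  }
  cons <- mean_density(mk_traj(rep(1.25, 50)), discard_fraction = 0)
  expect_equal(unname(cons), c(1.25, 0))
  two <- mean_density(mk_traj(c(rep(1, 50), rep(2, 50))),
                      discard_fraction = 0.5)
  expect_equal(two[["mean"]], 2)
  expect_error(mean_density(mk_traj(rep(1, 4)), blocks = 5), "blocks")
  # block standard error is near sd/sqrt(n) for iid noise
  x <- withr::with_seed(4, rnorm(2000, 1.0, 0.05))
  se <- mean_density(mk_traj(x), discard_fraction = 0, blocks = 5)[["se"]]
  expect_lt(se, 3 * 0.05 / sqrt(2000))
  expect_gt(se, 0.05 / sqrt(2000) / 3)
})
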