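test_that("the component library holds distinct components with exact
           reference geometries", {
  lib <- make_toy_components()
  expect_gte(length(lib$entries), 3L)
  # pairwise non-isomorphic is enforced by the constructor; re-check two
  ids <- names(lib$entries)
  expect_false(dgap:::graphs_isomorphic(
    lib$entries$api$species, lib$entries$api$bonds,
    lib$entries$o3$species, lib$entries$o3$bonds))
  # stated bond lengths
  blen <- function(e, b) sqrt(sum((e$geometry[b[1], ] - e$geometry[b[2], ])^2))
  expect_equal(blen(lib$entries$api, c(1, 2)), 1.20, tolerance = 1e-12)
  expect_equal(blen(lib$entries$n2, c(1, 2)), 1.10, tolerance = 1e-12)
  expect_equal(blen(lib$entries$co2, c(1, 3)), 1.16, tolerance = 1e-12)
  expect_equal(blen(lib$entries$o3, c(1, 2)), 1.28, tolerance = 1e-12)
})

test_that("generated crystals recover their requested composition", {
  lib <- make_toy_components()
  sts <- generate_trial_crystals(lib, toy_pair_stoichiometries("o3"),
                                 2, seed = 77)
  expect_length(sts, 10L)
  for (st in sts) {
    comp <- attr(st, "composition")
    tab <- dgap:::composition_of(st, lib)
    expect_equal(sort(names(tab[tab > 0])), sort(names(comp)))
    expect_true(all(tab[names(comp)] == comp))
  }
  # determinism
  sts2 <- generate_trial_crystals(lib, toy_pair_stoichiometries("o3"),
                                  2, seed = 77)
  expect_equal(sts[[5]]$positions, sts2[[5]]$positions)
  expect_equal(sts[[5]]$cell, sts2[[5]]$cell)
})

test_that("toy calculator: isolated pieces behave analytically", {
  base <- toy_baseline()
  p <- toy_baseline_params()
  # diatomic at its equilibrium length: only the dissociation offset
  st <- periodic_structure(c("N", "N"),
                           rbind(c(0, 0, 0), c(p$bond_r0[["N-N"]], 0, 0)),
                           pbc = FALSE)
  r <- calc_evaluate(base, st)
  expect_equal(r$energy, -p$bond_d, tolerance = 1e-12)
  expect_lt(max(abs(r$forces)), 1e-12)
  # two molecules beyond the cutoff: intermolecular part exactly zero
  far <- periodic_structure(rep("N", 4),
                            rbind(c(0, 0, 0), c(1.13, 0, 0),
                                  c(20, 0, 0), c(21.13, 0, 0)),
                            pbc = FALSE)
  lone <- periodic_structure(rep("N", 2), rbind(c(0, 0, 0), c(1.13, 0, 0)),
                             pbc = FALSE)
  expect_equal(calc_evaluate(base, far)$energy,
               2 * calc_evaluate(base, lone)$energy, tolerance = 1e-12)
})

test_that("toy forces and virial are exact derivatives", {
  targ <- toy_target()
  st <- toy_crystal_set(1, seed = 203, prerelax = FALSE)[[4]]
  res <- calc_evaluate(targ, st)
  efun <- function(s) calc_evaluate(targ, s)$energy
  expect_lt(max(abs(res$forces - fd_forces(efun, st, h = 1e-5))), 1e-6)
  expect_lt(max(abs(res$virial - fd_virial(efun, st, h = 1e-6))), 1e-6)
})

test_that("the baseline over-binds relative to the target", {
  base <- toy_baseline(); targ <- toy_target()
  sts <- toy_crystal_set(2, seed = 207)
  de <- vapply(sts, function(s) {
    calc_evaluate(base, s, forces = FALSE)$energy -
      calc_evaluate(targ, s, forces = FALSE)$energy
  }, 0)
  # on contact-bearing structures the baseline lies below the target
  multi <- vapply(sts, function(s) length(identify_molecules(s)) > 1, TRUE)
  expect_lt(mean(de[multi]), 0)
})

test_that("perturbation is seed-deterministic with the stated RMS", {
  st <- toy_crystal_set(1, seed = 211, prerelax = FALSE)[[3]]
  p1 <- perturb_structure(st, 0.05, 0.01, seed = 9)
  p2 <- perturb_structure(st, 0.05, 0.01, seed = 9)
  expect_identical(p1$positions, p2$positions)
  expect_gt(det(p1$cell), 0)
  p0 <- perturb_structure(st, 0, 0, seed = 9)
  expect_equal(p0$positions, st$positions)
  expect_equal(p0$cell, st$cell)
  # Monte-Carlo: per-atom RMS displacement ~ amplitude * sqrt(3)
  amp <- 0.08
  mono <- periodic_structure(c("N", "O", "O"),
                             make_toy_components()$entries$api$geometry,
                             pbc = FALSE)
  disp2 <- vapply(1:2000, function(s) {
    mean((perturb_structure(mono, amp, 0, seed = s)$positions -
          mono$positions)^2)
  }, 0)
  expect_equal(sqrt(mean(disp2) * 3), amp * sqrt(3), tolerance = 0.05)
})
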