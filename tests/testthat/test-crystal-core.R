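test_that("structure constructor enforces its invariants", {
  expect_error(periodic_structure(character(0), matrix(0, 0, 3)),
               "at least one atom")
  expect_error(periodic_structure("O", matrix(0, 1, 2)), "n x 3")
  bad_cell <- diag(3) * c(-1, 1, 1)
  expect_error(periodic_structure("O", matrix(1, 1, 3), bad_cell, TRUE),
               "determinant")
  expect_error(periodic_structure("Xx", matrix(0, 1, 3)), "unknown element")
})

test_that("wrapping positions changes no minimum-image distance", {
  st <- water_box()
  st$positions <- st$positions + 5.3 # push atoms outside the cell
  d0 <- dgap:::min_image_distances(st)
  d1 <- dgap:::min_image_distances(wrap_structure(st))
  expect_lt(max(abs(d0 - d1)), 1e-10)
})

test_that("identify_molecules separates bonded from non-bonded atoms", {
  st <- water_box()
  units <- identify_molecules(st, tolerance = 1.2)
  expect_length(units, 2L)
  expect_equal(sort(vapply(units, function(u) length(u$atom_indices), 0L)),
               c(3L, 3L))
  all_idx <- sort(unlist(lapply(units, `[[`, "atom_indices")))
  expect_equal(all_idx, 1:6) # partition property

  single <- periodic_structure("O", matrix(5, 1, 3), diag(3) * 10, TRUE)
  u1 <- identify_molecules(single)
  expect_length(u1, 1L)
  expect_equal(u1[[1]]$image_shifts, matrix(0L, 1, 3))
})

test_that("boundary-crossing diatomic is unwrapped to its true bond length", {
  cell <- diag(3) * 6
  st <- periodic_structure(c("N", "N"),
                           rbind(c(5.9, 1, 1), c(0.15, 1, 1)), cell, TRUE)
  units <- identify_molecules(st)
  expect_length(units, 1L)
  mono <- extract_monomer(st, units[[1]])
  # brute-force 3x3x3 supercell oracle for the bond length
  sup <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% cell
  d_oracle <- min(sqrt(rowSums(sweep(sup, 2,
                                     st$positions[2, ] - st$positions[1, ],
                                     `+`)^2)))
  expect_equal(as.numeric(dist(mono$positions)), d_oracle, tolerance = 1e-12)
})

test_that("molecule identification is invariant to translation and atom order", {
  sts <- toy_crystal_set(1, seed = 91, prerelax = FALSE)
  st <- sts[[3]]
  ref <- lapply(identify_molecules(st), `[[`, "atom_indices")

  st_t <- st
  st_t$positions <- st$positions + 3.7
  got <- lapply(identify_molecules(st_t), `[[`, "atom_indices")
  expect_equal(lapply(ref, sort), lapply(got, sort))

  perm <- withr::with_seed(5, sample(seq_along(st$species)))
  st_p <- st
  st_p$species <- st$species[perm]
  st_p$positions <- st$positions[perm, ]
  got_p <- lapply(identify_molecules(st_p), function(u) sort(perm[u$atom_indices]))
  # same membership sets after mapping back through the permutation
  key <- function(l) sort(vapply(l, paste, "", collapse = ","))
  expect_equal(key(lapply(ref, sort)), key(got_p))
})

test_that("periodic polymers are rejected rather than mis-partitioned", {
  # a chain of O atoms 1.4 A apart spanning the cell
  st <- periodic_structure(rep("O", 3),
                           rbind(c(0, 2, 2), c(1.4, 2, 2), c(2.8, 2, 2)),
                           diag(c(4.2, 20, 20)), TRUE)
  expect_error(identify_molecules(st), "polymer|unsafe")
})

test_that("component typing matches element-labelled graphs, not formulas", {
  lib <- make_toy_components()
  sts <- toy_crystal_set(1, seed = 17, prerelax = FALSE)
  st <- sts[[3]] # api + co2
  units <- identify_molecules(st)
  units <- assign_component_types(units, st, lib)
  expect_setequal(vapply(units, `[[`, "", "component_type"), c("api", "co2"))

  # empty library: everything unknown
  units0 <- assign_component_types(identify_molecules(st), st,
                                   component_library(list(
                                     x = component_entry("He", matrix(0L, 0, 2),
                                                         matrix(0, 1, 3)))))
  expect_true(all(vapply(units0, `[[`, "", "component_type") == "unknown"))

  # same formula, different bond graph: linear OCO vs a triangle-free
  # "CO + O" style chain O-O-C must type differently
  iso1 <- component_entry(c("C", "O", "O"), rbind(c(1L, 2L), c(1L, 3L)),
                          rbind(c(0, 0, 0), c(1.16, 0, 0), c(-1.16, 0, 0)))
  iso2 <- component_entry(c("O", "O", "C"), rbind(c(1L, 2L), c(2L, 3L)),
                          rbind(c(0, 0, 0), c(1.3, 0, 0), c(1.3, 1.2, 0)))
  expect_false(dgap:::graphs_isomorphic(iso1$species, iso1$bonds,
                                        iso2$species, iso2$bonds))
  lib2 <- component_library(list(a = iso1, b = iso2))
  expect_length(lib2$entries, 2L)
})

test_that("extracted monomer geometry is invariant to the stored wrapping", {
  sts <- toy_crystal_set(1, seed = 23, prerelax = FALSE)
  st <- sts[[4]]
  units <- identify_molecules(st)
  ref <- lapply(units, function(u) {
    as.numeric(dist(extract_monomer(st, u)$positions))
  })
  for (rep in 1:3) {
    st2 <- st
    st2$positions <- st$positions +
      withr::with_seed(rep, matrix(sample(-2:2, 3 * length(st$species),
                                          TRUE), ncol = 3)) %*% st$cell
    units2 <- identify_molecules(st2)
    got <- lapply(units2, function(u) {
      as.numeric(dist(extract_monomer(st2, u)$positions))
    })
    key <- function(l) sort(vapply(l, function(x) paste(round(x, 8),
                                                        collapse = ","), ""))
    expect_equal(key(ref), key(got))
  }
})

test_that("k-point grids satisfy the smallest-integer length rule", {
  expect_equal(kpoint_grid(diag(c(10, 10, 10)), 30), c(3L, 3L, 3L))
  expect_equal(kpoint_grid(diag(c(7, 31, 15)), 30), c(5L, 1L, 2L))
  expect_equal(kpoint_grid(diag(c(30, 30, 30)), 30), c(1L, 1L, 1L))
  expect_error(kpoint_grid(diag(3) * 10, -1), "positive")
})
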