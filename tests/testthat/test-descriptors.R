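spec53 <- soap_spec(3.0, species = c("N", "O"), n_max = 5L, l_max = 3L,
                    sigma_atom = 0.5, zeta = 4)

test_that("descriptors are normalised and invariant to rotation, translation
           and same-species permutation", {
  st <- random_cluster(6, seed = 2)
  d0 <- compute_soap(st, spec53)$vectors
  expect_lt(max(abs(rowSums(d0^2) - 1)), 1e-10)

  R <- random_rotation_matrix(7)
  st_r <- st; st_r$positions <- st$positions %*% R
  expect_lt(max(abs(d0 - compute_soap(st_r, spec53)$vectors)), 1e-8)

  st_t <- st; st_t$positions <- st$positions + c(2.5, -1, 4)[col(st$positions)]
  expect_lt(max(abs(d0 - compute_soap(st_t, spec53)$vectors)), 1e-8)

  perm <- withr::with_seed(3, sample(6))
  st_p <- st
  st_p$species <- st$species[perm]; st_p$positions <- st$positions[perm, ]
  dp <- compute_soap(st_p, spec53)$vectors
  expect_lt(max(abs(d0[perm, ] - dp)), 1e-8)
})

test_that("isolated atoms carry the pure self-contribution descriptor", {
  st <- periodic_structure(c("O", "O", "N"),
                           rbind(c(0, 0, 0), c(9, 0, 0), c(0, 9, 0)),
                           diag(3) * 30, TRUE)
  d <- compute_soap(st, spec53)$vectors
  expect_lt(max(abs(d[1, ] - d[2, ])), 1e-12) # same species, same descriptor
  expect_gt(max(abs(d[1, ] - d[3, ])), 1e-3)  # species channel differs
  sg <- soap_gradients(st, spec53)
  expect_length(sg$entry_center, 0L)          # no neighbours, no gradients
})

test_that("periodic descriptor equals the bare cluster when images are
           beyond the cutoff", {
  st <- random_cluster(5, seed = 4)
  stp <- periodic_structure(st$species, st$positions + 10, diag(3) * 20, TRUE)
  expect_lt(max(abs(compute_soap(st, spec53)$vectors -
                    compute_soap(stp, spec53)$vectors)), 1e-10)
})

test_that("environment kernel follows (a.b)^zeta", {
  a <- c(1, 0, 0); b <- c(0, 1, 0)
  expect_equal(environment_kernel(a, a, 4), 1.0)
  expect_equal(environment_kernel(a, b, 4), 0.0)
  v <- c(0.9, sqrt(1 - 0.81))
  expect_equal(environment_kernel(c(1, 0), v, 4), 0.9^4, tolerance = 1e-12)
  expect_error(environment_kernel(a, c(1, 0), 4), "lengths differ")
})

test_that("structure dissimilarity is a symmetric Hausdorff metric with
           exact-match zero", {
  A <- compute_soap(random_cluster(5, seed = 11), spec53)
  B <- compute_soap(random_cluster(6, seed = 12), spec53)
  expect_lt(structure_dissimilarity(A, A, 4), 1e-7)
  dab <- structure_dissimilarity(A, B, 4)
  expect_equal(dab, structure_dissimilarity(B, A, 4), tolerance = 1e-12)
  # brute-force oracle over all environment pairs
  k <- pmax(A$vectors %*% t(B$vectors), 0)^4
  d <- sqrt(pmax(2 - 2 * k, 0))
  expect_equal(dab, max(max(apply(d, 1, min)), max(apply(d, 2, min))),
               tolerance = 1e-12)
  # single-pair case: k = 0.5 -> sqrt(2 - 1) = 1
  e1 <- matrix(c(1, 0), 1)
  dot <- 0.5^(1 / 4) # so that k = dot^4 = 0.5
  e2 <- matrix(c(dot, sqrt(1 - dot^2)), 1)
  expect_equal(structure_dissimilarity(e1, e2, 4), 1.0, tolerance = 1e-10)
  expect_error(structure_dissimilarity(matrix(0, 0, 2), e1, 4), "empty")
})

test_that("analytic descriptor gradients match the finite-difference oracle", {
  st <- random_cluster(5, seed = 8)
  dense <- dgap:::soap_gradients_dense(soap_gradients(st, spec53))
  fd <- soap_gradients_fd(st, spec53, step = 1e-4)
  expect_lt(max(abs(dense - fd)), 1e-5)
  # rigid-translation sum rule: gradients over all moved atoms cancel
  expect_lt(max(abs(apply(dense, c(1, 2, 4), sum))), 1e-10)
})

test_that("descriptors cross the cutoff smoothly", {
  spec <- spec53
  mk <- function(r) {
    periodic_structure(c("O", "N"), rbind(c(0, 0, 0), c(r, 0, 0)),
                       pbc = FALSE)
  }
  inside <- compute_soap(mk(spec$cutoff - 5e-4), spec)$vectors[1, ]
  outside <- compute_soap(mk(spec$cutoff + 5e-4), spec)$vectors[1, ]
  isolated <- compute_soap(mk(25), spec)$vectors[1, ]
  expect_lt(max(abs(inside - outside)), 1e-6)
  expect_lt(max(abs(outside - isolated)), 1e-12)
})

test_that("kernel Gram matrices are positive semidefinite", {
  for (seed in 1:3) {
    envs <- do.call(rbind, lapply(1:4, function(k) {
      compute_soap(random_cluster(4, seed = 10 * seed + k), spec53)$vectors
    }))
    G <- pmax(envs %*% t(envs), 0)^4
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("intermolecular-only descriptors ignore own-molecule neighbours
           but keep periodic self-copies", {
  spec_x <- soap_spec(5.0, species = c("C", "N", "O"), n_max = 4L, l_max = 2L,
                      zeta = 4, exclude_intramolecular = TRUE)
  lib <- make_toy_components()
  e <- lib$entries$api
  # isolated molecule: every environment reduces to the self-contribution
  mono <- periodic_structure(e$species, e$geometry, pbc = FALSE)
  d <- compute_soap(mono, spec_x)$vectors
  lone_n <- compute_soap(periodic_structure("N", matrix(0, 1, 3), pbc = FALSE),
                         spec_x)$vectors
  expect_lt(max(abs(d[1, ] - lone_n[1, ])), 1e-12)
  # the same molecule in a tight periodic cell sees its own images
  tight <- periodic_structure(e$species, e$geometry + 2, diag(3) * 4.2, TRUE)
  dt <- compute_soap(tight, spec_x)$vectors
  expect_gt(max(abs(dt[1, ] - lone_n[1, ])), 1e-4)
})
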