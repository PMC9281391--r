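# shared fixture builders and numerical oracles

water_box <- function() {
  # two water molecules > 3 A apart in an 8 A cubic cell
  w <- function(origin) {
    rbind(origin,
          origin + c(0.7572, 0.5865, 0),
          origin + c(-0.7572, 0.5865, 0))
  }
  periodic_structure(rep(c("O", "H", "H"), 2),
                     rbind(w(c(1.5, 1.5, 1.5)), w(c(5.5, 5.5, 5.5))),
                     cell = diag(3) * 8, pbc = TRUE)
}

random_cluster <- function(n = 5, seed = 1, species = c("N", "O")) {
  withr::with_seed(seed, {
    repeat {
      pos <- matrix(rnorm(3 * n, sd = 1.6), n, 3)
      # spacing above every bond-perception cutoff: atoms stay unbonded
      if (n < 2 || min(dist(pos)) > 1.9) break
    }
    periodic_structure(sample(species, n, replace = TRUE), pos, pbc = FALSE)
  })
}

# compact cluster: every pair within the descriptor cutoff but none
# bonded (distances ~1.9-3.2 A); a jittered tetrahedron
compact_cluster <- function(seed = 1, species = c("N", "O")) {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    2.35 / (2 * sqrt(2))
  withr::with_seed(seed, {
    pos <- tet + matrix(rnorm(12, sd = 0.13), 4, 3)
    periodic_structure(sample(species, 4, replace = TRUE), pos, pbc = FALSE)
  })
}

random_rotation_matrix <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# five-point finite-difference derivative (O(h^4) truncation): sparse-GP
# surfaces can have large third derivatives, so plain central differences
# at the reference step would be truncation-limited
fd5 <- function(f, h) {
  (8 * (f(h) - f(-h)) - (f(2 * h) - f(-2 * h))) / (12 * h)
}

# finite-difference forces of any calculator-like function
fd_forces <- function(energy_fn, st, h = 1e-4) {
  n <- nrow(st$positions)
  F <- matrix(0, n, 3)
  for (a in seq_len(n)) for (d in 1:3) {
    F[a, d] <- -fd5(function(hh) {
      sp <- st; sp$positions[a, d] <- sp$positions[a, d] + hh
      energy_fn(sp)
    }, h)
  }
  F
}

# finite-strain virial of any calculator-like function
fd_virial <- function(energy_fn, st, h = 1e-5) {
  W <- matrix(0, 3, 3)
  for (a in 1:3) for (b in a:3) {
    W[a, b] <- W[b, a] <- -fd5(function(hh) {
      E <- matrix(0, 3, 3)
      E[a, b] <- E[a, b] + hh / 2; E[b, a] <- E[b, a] + hh / 2
      sp <- st; sp$cell <- st$cell %*% (diag(3) + E)
      sp$positions <- st$positions %*% (diag(3) + E)
      energy_fn(sp)
    }, h)
  }
  W
}

toy_crystal_set <- function(n_per_composition, seed,
                            coformer = "co2", prerelax = TRUE) {
  lib <- make_toy_components()
  base <- toy_baseline()
  sts <- generate_trial_crystals(
    lib, toy_pair_stoichiometries(coformer), n_per_composition, seed)
  if (prerelax) {
    sts <- lapply(sts, function(s) {
      out <- tryCatch(dgap:::relax_or_last(s, base, 0.2, FALSE, 40L),
                      error = function(e) NULL)
      if (is.null(out)) return(NULL)
      ok <- tryCatch({
        tab <- dgap:::composition_of(out, lib)
        comp <- attr(s, "composition")
        identical(sort(names(tab[tab > 0])), sort(names(comp))) &&
          all(tab[names(comp)] == comp)
      }, error = function(e) FALSE)
      if (ok) out else NULL
    })
    keep <- !vapply(sts, is.null, TRUE)
    # keep list positions stable for the survivors
    sts <- sts[keep]
  }
  sts
}
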