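# Toy universe: small molecular components, an analytic baseline/target
# calculator pair whose difference is a smooth, SOAP-learnable function of
# local geometry, and random trial-crystal generation. This is the
# desk-scale stand-in for the DFTB+D4 -> hybrid-DFT setting: the baseline
# deliberately over-binds intermolecular contacts so that baseline-relaxed
# crystals are too dense, and delta-learning has a real, physical error to
# correct.

#' Toy component library
#'
#' One "active" component (a bent N-centred triatomic) and four co-formers
#' (a homonuclear diatomic, a heteronuclear diatomic, a linear triatomic
#' and a bent all-oxygen triatomic), all mutually non-isomorphic as
#' element-labelled graphs, each with a reference gas-phase geometry.
#'
#' @return a [component_library()].
#' @export
make_toy_components <- function() {
  bent <- function(r, theta_deg) {
    h <- theta_deg / 2 * pi / 180
    rbind(c(0, 0, 0),
          c(r * sin(h), r * cos(h), 0),
          c(-r * sin(h), r * cos(h), 0))
  }
  component_library(list(
    api = component_entry(c("N", "O", "O"), rbind(c(1L, 2L), c(1L, 3L)),
                          bent(1.20, 116)),
    n2 = component_entry(c("N", "N"), rbind(c(1L, 2L)),
                         rbind(c(0, 0, 0), c(1.10, 0, 0))),
    co = component_entry(c("C", "O"), rbind(c(1L, 2L)),
                         rbind(c(0, 0, 0), c(1.16, 0, 0))),
    co2 = component_entry(c("C", "O", "O"), rbind(c(1L, 2L), c(1L, 3L)),
                          rbind(c(0, 0, 0), c(1.16, 0, 0), c(-1.16, 0, 0))),
    o3 = component_entry(c("O", "O", "O"), rbind(c(1L, 2L), c(1L, 3L)),
                         bent(1.28, 117))
  ))
}

#' Toy potential parameters
#'
#' Intramolecular harmonic bonds (per species pair) and harmonic-cosine
#' angles (per centred species triple, smooth through linear geometries),
#' plus intermolecular Lennard-Jones with Lorentz-Berthelot mixing, an
#' optional extra attractive r^-6 dispersion tail, and an optional
#' short-ranged wrapped Coulomb term. All interactions are smoothly
#' switched off between `switch_on` and `cutoff`.
#'
#' @param bond_k named vector, eV/A^2, keys like `"N-O"` (sorted species).
#' @param bond_r0 named vector of equilibrium lengths (Angstrom).
#' @param bond_d bond dissociation energy (eV), subtracted per perceived
#'   bond. Shared by baseline and target, it cancels in every delta label;
#'   it exists so that intact molecules are globally more stable than
#'   dissociated van-der-Waals clusters of their atoms.
#' @param angle_k named vector, eV, keys like `"O-N-O"` (centre in the
#'   middle, ends sorted).
#' @param angle_cos0 named vector of equilibrium cosines.
#' @param pair_epsilon per-species LJ well depth (eV).
#' @param pair_sigma per-species LJ length scale (Angstrom), > 0.
#' @param tail_strength prefactor of the extra `-eps (sigma/r)^6` tail.
#' @param charge optional per-species point charges (e).
#' @param cutoff,switch_on intermolecular cutoff and switch onset (Angstrom).
#' @return parameter list of class `toy_potential_params`.
#' @export
toy_potential_params <- function(
    bond_k = c("N-O" = 32, "N-N" = 38, "C-O" = 34, "O-O" = 28),
    bond_r0 = c("N-O" = 1.20, "N-N" = 1.10, "C-O" = 1.16, "O-O" = 1.28),
    bond_d = 4.0,
    angle_k = c("O-N-O" = 4.0, "O-C-O" = 4.0, "O-O-O" = 4.0),
    angle_cos0 = c("O-N-O" = cos(116 * pi / 180), "O-C-O" = -1,
                   "O-O-O" = cos(117 * pi / 180)),
    pair_epsilon = c(N = 0.10, O = 0.12, C = 0.11),
    pair_sigma = c(N = 3.3, O = 3.2, C = 3.4),
    tail_strength = 0.8,
    charge = NULL,
    cutoff = 5.0, switch_on = 4.0) {
  stopifnot(all(pair_sigma > 0), all(bond_k >= 0), switch_on < cutoff)
  structure(list(bond_k = bond_k, bond_r0 = bond_r0, bond_d = bond_d,
                 angle_k = angle_k,
                 angle_cos0 = angle_cos0, pair_epsilon = pair_epsilon,
                 pair_sigma = pair_sigma, tail_strength = tail_strength,
                 charge = charge, cutoff = cutoff, switch_on = switch_on),
            class = "toy_potential_params")
}

#' Baseline / target parameter sets of the toy universe
#'
#' The baseline over-binds intermolecular contacts (deeper wells, smaller
#' sigma, stronger dispersion tail) and carries slightly wrong bond
#' stiffnesses, lengths and angles; the target is the reference the
#' delta model must recover.
#'
#' @return [toy_potential_params()].
#' @export
toy_target_params <- function() toy_potential_params()

#' @rdname toy_target_params
#' @export
toy_baseline_params <- function() {
  p <- toy_potential_params()
  p$bond_k <- p$bond_k * 0.85
  p$bond_r0 <- p$bond_r0 + 0.03
  p$angle_k <- p$angle_k * 0.9
  p$angle_cos0 <- c("O-N-O" = cos(118 * pi / 180), "O-C-O" = -1,
                    "O-O-O" = cos(119 * pi / 180))
  p$pair_epsilon <- p$pair_epsilon * 1.4
  p$pair_sigma <- p$pair_sigma * 0.96
  p$tail_strength <- 1.3
  p
}

# quintic switch shared with the descriptors: 1 below r_on, 0 above r_cut
toy_switch <- function(r, r_on, r_cut) {
  t <- pmin(pmax((r - r_on) / (r_cut - r_on), 0), 1)
  s <- t^3 * (10 + t * (-15 + 6 * t))
  ds <- ifelse(r > r_on & r < r_cut,
               -(t^2 * (30 + t * (-60 + 30 * t))) / (r_cut - r_on), 0)
  list(f = 1 - s, df = ds)
}

#' Analytic toy calculator
#'
#' Energy = intramolecular harmonic bond and angle terms (on unwrapped
#' molecules) + intermolecular pairwise terms (Lennard-Jones, optional
#' smoothly truncated attractive tail, optional short-ranged Coulomb),
#' summed over all periodic images within the cutoff. Forces and the
#' virial are analytic.
#'
#' @param params a [toy_potential_params()].
#' @param dispersion_tail include the extra attractive tail term.
#' @param name calculator tag.
#' @return a [calculator()].
#' @export
toy_calculator <- function(params, dispersion_tail = TRUE,
                           name = "toy") {
  force(params); force(dispersion_tail)
  tab <- toy_param_tables(params)
  calculator(name, function(structure, forces = TRUE) {
    toy_eval(structure, params, dispersion_tail, tab)
  }, params = c(unclass(params), list(dispersion_tail = dispersion_tail)))
}

# dense per-species lookup tables for the compiled evaluator
toy_param_tables <- function(params) {
  sp <- names(params$pair_epsilon)
  S <- length(sp)
  bk <- matrix(-1, S, S, dimnames = list(sp, sp))
  br <- matrix(0, S, S)
  for (key in names(params$bond_k)) {
    ab <- strsplit(key, "-", fixed = TRUE)[[1]]
    i <- match(ab[1], sp); j <- match(ab[2], sp)
    bk[i, j] <- bk[j, i] <- params$bond_k[[key]]
    br[i, j] <- br[j, i] <- params$bond_r0[[key]]
  }
  ak <- array(0, c(S, S, S))
  ac <- array(0, c(S, S, S))
  for (key in names(params$angle_k)) {
    abc <- strsplit(key, "-", fixed = TRUE)[[1]]
    e1 <- match(abc[1], sp); ce <- match(abc[2], sp); e2 <- match(abc[3], sp)
    ak[e1, ce, e2] <- ak[e2, ce, e1] <- params$angle_k[[key]]
    ac[e1, ce, e2] <- ac[e2, ce, e1] <- params$angle_cos0[[key]]
  }
  list(species = sp,
       bond_k = bk, bond_r0 = br,
       angle_k = ak, angle_cos0 = ac,
       eps = sqrt(outer(params$pair_epsilon, params$pair_epsilon)),
       sig = outer(params$pair_sigma, params$pair_sigma, `+`) / 2,
       charge = if (is.null(params$charge)) rep(0, S) else
         params$charge[sp],
       rcov = covalent_radius(sp))
}

#' @rdname toy_calculator
#' @export
toy_baseline <- function() {
  toy_calculator(toy_baseline_params(), TRUE, "toy_baseline")
}

#' @rdname toy_calculator
#' @export
toy_target <- function() {
  toy_calculator(toy_target_params(), TRUE, "toy_target")
}

pair_key <- function(s1, s2) {
  paste(pmin(s1, s2), pmax(s1, s2), sep = "-")
}

toy_eval <- function(structure, params, dispersion_tail,
                     tab = toy_param_tables(params)) {
  if (any(structure$pbc)) structure <- wrap_structure(structure)
  sidx <- match(structure$species, tab$species)
  if (anyNA(sidx)) {
    stop("species without toy parameters: ",
         paste(unique(structure$species[is.na(sidx)]), collapse = ", "))
  }
  res <- cpp_toy_eval(as.integer(sidx - 1L), structure$positions,
                      structure$cell, structure$pbc, tab$bond_k,
                      tab$bond_r0, params$bond_d, tab$angle_k,
                      tab$angle_cos0, tab$eps, tab$sig,
                      params$tail_strength, isTRUE(dispersion_tail),
                      tab$charge, !is.null(params$charge), params$cutoff,
                      params$switch_on, tab$rcov, 1.2, tab$species,
                      3L)
  efs_result(res$energy, res$forces, res$virial)
}

# reference implementation in plain R, retained as the compiled
# evaluator's cross-check oracle
toy_eval_ref <- function(structure, params, dispersion_tail) {
  n <- n_atoms(structure)
  sp <- structure$species
  pos <- structure$positions
  E <- 0
  F <- matrix(0, n, 3L)
  W <- matrix(0, 3L, 3L)

  units <- identify_molecules(structure)
  mol_id <- integer(n)
  unwrap <- matrix(0L, n, 3L)
  for (k in seq_along(units)) {
    mol_id[units[[k]]$atom_indices] <- k
    unwrap[units[[k]]$atom_indices, ] <- units[[k]]$image_shifts
  }

  # ---- intramolecular bonds and angles on unwrapped monomers
  for (u in units) {
    idx <- u$atom_indices
    P <- pos[idx, , drop = FALSE] + u$image_shifts %*% structure$cell
    bonds <- perceive_bonds(sp[idx], P)
    nb <- vector("list", length(idx))
    if (nrow(bonds)) for (bi in seq_len(nrow(bonds))) {
      a <- bonds[bi, 1L]; b <- bonds[bi, 2L]
      key <- pair_key(sp[idx[a]], sp[idx[b]])
      k0 <- params$bond_k[key]; r0 <- params$bond_r0[key]
      if (is.na(k0)) stop("no bond parameters for ", key)
      uvec <- P[b, ] - P[a, ]
      r <- sqrt(sum(uvec^2))
      E <- E - params$bond_d + 0.5 * k0 * (r - r0)^2
      g <- k0 * (r - r0) * uvec / r      # dE/du
      F[idx[b], ] <- F[idx[b], ] - g
      F[idx[a], ] <- F[idx[a], ] + g
      W <- W - outer(g, uvec)
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
    for (b in seq_along(idx)) {
      nbs <- nb[[b]]
      if (length(nbs) < 2L) next
      for (ai in 1:(length(nbs) - 1L)) for (ci in (ai + 1L):length(nbs)) {
        a <- nbs[ai]; c3 <- nbs[ci]
        ends <- sort(c(sp[idx[a]], sp[idx[c3]]))
        key <- paste(ends[1], sp[idx[b]], ends[2], sep = "-")
        ka <- params$angle_k[key]
        if (is.na(ka)) next
        c0 <- params$angle_cos0[key]
        u1 <- P[a, ] - P[b, ]; u2 <- P[c3, ] - P[b, ]
        r1 <- sqrt(sum(u1^2)); r2 <- sqrt(sum(u2^2))
        cth <- sum(u1 * u2) / (r1 * r2)
        E <- E + 0.5 * ka * (cth - c0)^2
        pref <- ka * (cth - c0)
        g1 <- pref * (u2 / (r1 * r2) - cth * u1 / r1^2)
        g2 <- pref * (u1 / (r1 * r2) - cth * u2 / r2^2)
        F[idx[a], ] <- F[idx[a], ] - g1
        F[idx[c3], ] <- F[idx[c3], ] - g2
        F[idx[b], ] <- F[idx[b], ] + g1 + g2
        W <- W - outer(g1, u1) - outer(g2, u2)
      }
    }
  }

  # ---- intermolecular pairs over all periodic images within the cutoff
  rc <- params$cutoff
  shifts <- matrix(0L, 1L, 3L)
  if (any(structure$pbc)) {
    hh <- cell_heights(structure$cell)
    nrep <- ifelse(structure$pbc, pmax(ceiling(rc / hh), 0L), 0L)
    grid <- as.matrix(expand.grid(-nrep[1]:nrep[1], -nrep[2]:nrep[2],
                                  -nrep[3]:nrep[3]))
    keep <- grid[, 1] > 0 | (grid[, 1] == 0 & grid[, 2] > 0) |
      (grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] > 0)
    pos_shifts <- grid[keep, , drop = FALSE]
  } else {
    pos_shifts <- matrix(0L, 0L, 3L)
  }

  # a same-molecule pair's *intramolecular* image lives at the shift
  # difference of the atoms' unwrap images; that one image is excluded,
  # every other image is a genuine self-image interaction
  intra_image <- function(iv, jv, sh) {
    mol_id[iv] == mol_id[jv] &
      sh[, 1] == unwrap[jv, 1] - unwrap[iv, 1] &
      sh[, 2] == unwrap[jv, 2] - unwrap[iv, 2] &
      sh[, 3] == unwrap[jv, 3] - unwrap[iv, 3]
  }
  ii <- integer(0); jj <- integer(0); Umat <- matrix(0, 0, 3L)
  if (n > 1L) {
    up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- !intra_image(up[, 1], up[, 2],
                        matrix(0L, nrow(up), 3L))
    if (any(sel)) {
      ii <- up[sel, 1]; jj <- up[sel, 2]
      Umat <- pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE]
    }
  }
  ns <- nrow(pos_shifts)
  if (ns) {
    i0 <- rep(seq_len(n), times = n)          # all ordered pairs
    j0 <- rep(seq_len(n), each = n)
    base_u <- pos[j0, , drop = FALSE] - pos[i0, , drop = FALSE]
    offs <- pos_shifts %*% structure$cell      # ns x 3
    for (si in seq_len(ns)) {
      sh <- matrix(rep(as.integer(pos_shifts[si, ]), each = n * n), ncol = 3L)
      keep <- !intra_image(i0, j0, sh)
      ii <- c(ii, i0[keep])
      jj <- c(jj, j0[keep])
      Umat <- rbind(Umat,
                    base_u[keep, , drop = FALSE] +
                      offs[rep(si, sum(keep)), , drop = FALSE])
    }
  }
  if (length(ii)) {
    r <- sqrt(rowSums(Umat^2))
    keep <- r < rc & r > 1e-8
    if (any(keep)) {
      ii <- ii[keep]; jj <- jj[keep]
      Umat <- Umat[keep, , drop = FALSE]; r <- r[keep]
      eps <- sqrt(params$pair_epsilon[sp[ii]] * params$pair_epsilon[sp[jj]])
      sig <- (params$pair_sigma[sp[ii]] + params$pair_sigma[sp[jj]]) / 2
      sr6 <- (sig / r)^6
      sr12 <- sr6^2
      phi <- 4 * eps * (sr12 - sr6)
      dphi <- 4 * eps * (-12 * sr12 + 6 * sr6) / r
      if (dispersion_tail) {
        phi <- phi - params$tail_strength * eps * sr6
        dphi <- dphi + params$tail_strength * eps * 6 * sr6 / r
      }
      if (!is.null(params$charge)) {
        qq <- COULOMB_EVA * params$charge[sp[ii]] * params$charge[sp[jj]]
        phi <- phi + qq / r
        dphi <- dphi - qq / r^2
      }
      sw <- toy_switch(r, params$switch_on, rc)
      dtot <- dphi * sw$f + phi * sw$df
      E <- E + sum(phi * sw$f)
      g <- Umat * (dtot / r)
      # accumulate forces (rowsum keyed by atom index)
      for (d in 1:3) {
        aj <- rowsum(g[, d], jj)
        F[as.integer(rownames(aj)), d] <-
          F[as.integer(rownames(aj)), d] - aj[, 1]
        ai <- rowsum(g[, d], ii)
        F[as.integer(rownames(ai)), d] <-
          F[as.integer(rownames(ai)), d] + ai[, 1]
      }
      W <- W - t(g) %*% Umat
    }
  }
  efs_result(E, F, (W + t(W)) / 2)
}

# random rotation matrix (Haar-ish via QR of a Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L, 3L)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate random trial crystals from toy components
#'
#' Random cells (lengths and angles within configured ranges, scaled so
#' every cell height is at least `min_height`) filled with rigid copies of
#' the library's reference geometries at random positions and orientations.
#' Placements with any intermolecular atom pair closer than `min_dist` are
#' rejected and retried. Deterministic for a given seed.
#'
#' @param library a [component_library()].
#' @param stoichiometries list of named integer vectors (component counts
#'   per cell), e.g. `list(c(api = 1, co2 = 1))`.
#' @param n_per_composition structures per stoichiometry.
#' @param seed integer seed.
#' @param cell_volume_per_molecule sampled volume range per molecule (A^3).
#' @param min_height minimum cell height (Angstrom).
#' @param angle_range cell angle range (degrees).
#' @param min_dist intermolecular rejection distance (Angstrom). The
#'   default 2.4 A is ~0.73 of the toy LJ diameters and stays above the
#'   covalent bond-perception cutoff of every heavy-atom pair, so freshly
#'   generated contacts are never mistaken for bonds.
#' @param max_restarts placement restarts per structure before giving up.
#' @return list of [periodic_structure()] objects, each with a
#'   `composition` attribute.
#' @export
generate_trial_crystals <- function(library, stoichiometries,
                                    n_per_composition, seed,
                                    cell_volume_per_molecule = c(380, 550),
                                    min_height = 8.5,
                                    angle_range = c(80, 100),
                                    min_dist = 2.4,
                                    max_restarts = 60L) {
  stopifnot(length(stoichiometries) > 0)
  out <- list()
  withr::with_seed(seed, {
    for (comp in stoichiometries) {
      comp <- comp[comp > 0]
      mols <- rep(names(comp), comp)
      n_mol <- length(mols)
      for (kk in seq_len(n_per_composition)) {
        placed <- NULL
        for (restart in seq_len(max_restarts)) {
          vol <- stats::runif(1, cell_volume_per_molecule[1],
                              cell_volume_per_molecule[2]) * n_mol
          ratios <- stats::runif(3, 0.85, 1.2)
          angs <- stats::runif(3, angle_range[1], angle_range[2])
          cell <- cell_from_parameters(ratios[1], ratios[2], ratios[3],
                                       angs[1], angs[2], angs[3])
          cell <- cell * (vol / abs(det(cell)))^(1 / 3)
          hh <- cell_heights(cell)
          if (min(hh) < min_height) cell <- cell * (min_height / min(hh))
          inv <- solve(cell)
          species <- character(0)
          P <- matrix(0, 0, 3L)
          ok <- TRUE
          for (m in mols) {
            geom <- library$entries[[m]]$geometry
            geom <- sweep(geom, 2L, colMeans(geom))
            success <- FALSE
            for (att in 1:80) {
              rot <- random_rotation()
              cand <- geom %*% t(rot)
              cand <- sweep(cand, 2L, as.numeric(stats::runif(3) %*% cell),
                            `+`)
              if (nrow(P)) {
                df <- P[rep(seq_len(nrow(P)), each = nrow(cand)), ,
                        drop = FALSE] -
                  cand[rep(seq_len(nrow(cand)), nrow(P)), , drop = FALSE]
                fr <- df %*% inv
                fr <- fr - round(fr)
                dmin <- min(sqrt(rowSums((fr %*% cell)^2)))
                if (dmin < min_dist) next
              }
              P <- rbind(P, cand)
              species <- c(species, library$entries[[m]]$species)
              success <- TRUE
              break
            }
            if (!success) { ok <- FALSE; break }
          }
          if (ok) {
            placed <- periodic_structure(
              species, P, cell = cell, pbc = TRUE,
              provenance = sprintf("toy:%s:%d",
                                   paste(names(comp), comp, sep = "",
                                         collapse = "+"), kk))
            attr(placed, "composition") <- comp
            break
          }
        }
        if (is.null(placed)) {
          stop("placement budget exhausted; increase cell_volume_per_molecule")
        }
        out[[length(out) + 1L]] <- placed
      }
    }
  })
  out
}

#' Randomly perturb a structure
#'
#' Gaussian positional noise plus a random symmetric cell strain (positions
#' transform affinely with the cell). Deterministic per seed. Perturbations
#' creating atom overlaps closer than 0.5 A are resampled up to a budget.
#'
#' @param structure a [periodic_structure()].
#' @param position_amplitude per-coordinate Gaussian sigma (Angstrom).
#' @param cell_amplitude per-component strain sigma (dimensionless).
#' @param seed integer seed.
#' @return the perturbed [periodic_structure()].
#' @export
perturb_structure <- function(structure, position_amplitude, cell_amplitude,
                              seed) {
  stopifnot(position_amplitude >= 0, cell_amplitude >= 0)
  comp <- attr(structure, "composition")
  out <- withr::with_seed(seed, {
    res <- NULL
    for (att in 1:20) {
      e <- stats::rnorm(6) * cell_amplitude
      Emat <- matrix(c(e[1], e[4] / 2, e[5] / 2,
                       e[4] / 2, e[2], e[6] / 2,
                       e[5] / 2, e[6] / 2, e[3]), 3L, 3L)
      Fmat <- diag(3L) + Emat
      st <- structure
      st$cell <- structure$cell %*% Fmat
      st$positions <- structure$positions %*% Fmat +
        matrix(stats::rnorm(3L * n_atoms(structure),
                            sd = position_amplitude),
               ncol = 3L)
      if (det(st$cell) <= 0) next
      if (n_atoms(st) > 1L) {
        if (min(min_image_distances(st)[upper.tri(diag(n_atoms(st)))]) < 0.5)
          next
      }
      res <- st
      break
    }
    res
  })
  if (is.null(out)) stop("perturbation kept creating overlaps < 0.5 A")
  attr(out, "composition") <- comp
  out
}

#' Compress a molecular structure to a target volume per molecule
#'
#' Scales the cell isotropically while keeping each molecule rigid
#' (centres of mass move affinely, internal geometry is preserved). Used
#' to produce compact, interaction-dominated starting points for
#' variable-cell relaxation from loosely packed trial structures. If the
#' requested volume would create intermolecular contacts below
#' `min_contact`, the target volume is backed off until it does not.
#'
#' @param structure a fully periodic [periodic_structure()].
#' @param vol_per_molecule target cell volume per molecule (A^3).
#' @param min_contact smallest allowed intermolecular distance (Angstrom).
#' @param max_backoff maximum number of 10% volume increases.
#' @return the compressed [periodic_structure()].
#' @export
compress_structure <- function(structure, vol_per_molecule,
                               min_contact = 2.2, max_backoff = 25L) {
  units <- identify_molecules(structure)
  n_mol <- length(units)
  v <- vol_per_molecule
  for (try in seq_len(max_backoff)) {
    s <- (v * n_mol / cell_volume(structure))^(1 / 3)
    if (s >= 1) return(structure)
    st <- structure
    st$cell <- structure$cell * s
    for (u in units) {
      pos <- structure$positions[u$atom_indices, , drop = FALSE] +
        u$image_shifts %*% structure$cell
      com <- colMeans(pos)
      st$positions[u$atom_indices, ] <-
        sweep(pos, 2L, com) + rep(com * s, each = nrow(pos)) -
        u$image_shifts %*% st$cell
    }
    ok <- tryCatch({
      units2 <- identify_molecules(st)
      length(units2) == n_mol
    }, error = function(e) FALSE)
    if (ok) {
      d <- min_image_distances(st)
      mol <- integer(n_atoms(st))
      for (k in seq_along(units)) mol[units[[k]]$atom_indices] <- k
      inter <- d[outer(mol, mol, `!=`)]
      if (!length(inter) || min(inter) >= min_contact) {
        attr(st, "composition") <- attr(structure, "composition")
        return(st)
      }
    }
    v <- v * 1.1
  }
  structure
}
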