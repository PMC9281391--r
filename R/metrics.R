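#' Lattice energy per molecule
#'
#' `(E_crystal - sum_t n_t E_gas,t) / sum_t n_t`: the crystal energy minus
#' the energies of its optimised gas-phase constituents, normalised by the
#' number of molecules in the cell. Single-component crystals are the
#' special case of one non-zero count.
#'
#' @param e_crystal crystal total energy (eV).
#' @param gas_refs named vector/list: optimised gas-phase energy per
#'   component (eV).
#' @param counts named vector: molecules of each component in the cell.
#' @return lattice energy in eV per molecule.
#' @export
lattice_energy <- function(e_crystal, gas_refs, counts) {
  counts <- counts[counts > 0]
  if (!length(counts) || any(counts < 0)) {
    stop("counts must be non-negative with positive total")
  }
  missing <- setdiff(names(counts), names(gas_refs))
  if (length(missing)) {
    stop("missing gas reference for: ", paste(missing, collapse = ", "))
  }
  gas <- unlist(gas_refs)[names(counts)]
  (e_crystal - sum(counts * gas)) / sum(counts)
}

#' Percentage density deviation between two structures
#'
#' `100 (rho - rho_ref) / rho_ref`; positive when the structure is denser
#' than the reference (e.g. an over-binding baseline), negative when its
#' volume is larger.
#'
#' @param structure,reference fully periodic structures with the same
#'   chemical formula per cell.
#' @param absolute return the absolute value.
#' @return percent deviation.
#' @export
density_deviation <- function(structure, reference, absolute = FALSE) {
  if (!identical(sort(structure$species), sort(reference$species))) {
    stop("structures have different chemical formulas")
  }
  dev <- 100 * (structure_density(structure) / structure_density(reference) - 1)
  if (absolute) abs(dev) else dev
}

#' Error summary: MAE and standard deviation of signed errors
#'
#' Population convention (divisor n) for the standard deviation, as used
#' for lattice-energy and force-component error statistics.
#'
#' @param predicted,reference numeric vectors of equal length.
#' @return object of class `error_summary`: `mae`, `std`, `n` and the
#'   signed `errors` they are recomputable from.
#' @export
error_summary <- function(predicted, reference) {
  if (length(predicted) != length(reference) || !length(predicted)) {
    stop("predicted and reference must have equal positive length")
  }
  err <- as.numeric(predicted) - as.numeric(reference)
  structure(list(mae = mean(abs(err)),
                 std = sqrt(mean((err - mean(err))^2)),
                 n = length(err), errors = err),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary: n = %d, MAE = %.6g, STD = %.6g>\n",
              x$n, x$mae, x$std))
  invisible(x)
}

#' Maximum remaining force
#'
#' Largest per-atom Euclidean force norm of a calculator result.
#'
#' @param efs an [efs_result()] with forces.
#' @return eV/A scalar.
#' @export
max_remaining_force <- function(efs) {
  if (is.null(efs$forces)) stop("result carries no forces")
  max(sqrt(rowSums(efs$forces^2)))
}

# Kabsch: optimal proper rotation+translation of P onto Q (n x 3 each)
kabsch_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- P0 %*% t(R)
  sqrt(mean(rowSums((Pr - Q0)^2)))
}

# molecule records of a structure: typed units with unwrapped coordinates
molecule_records <- function(structure, library, tolerance = 1.2) {
  units <- identify_molecules(structure, tolerance)
  units <- assign_component_types(units, structure, library, tolerance)
  lapply(units, function(u) {
    pos <- structure$positions[u$atom_indices, , drop = FALSE] +
      u$image_shifts %*% structure$cell
    list(indices = u$atom_indices, type = u$component_type,
         species = structure$species[u$atom_indices], pos = pos,
         com = colSums(pos * atomic_mass(structure$species[u$atom_indices])) /
           sum(atomic_mass(structure$species[u$atom_indices])))
  })
}

# 15-molecule cluster around a central molecule (periodic images allowed):
# list of molecule instances (record + lattice shift), central first
build_cluster <- function(records, cell, central, n_mol = 15L, reach = 2L) {
  shifts <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
  inst <- list()
  c0 <- records[[central]]$com
  for (k in seq_along(records)) {
    for (s in seq_len(nrow(shifts))) {
      off <- as.numeric(shifts[s, ] %*% cell)
      inst[[length(inst) + 1L]] <- list(
        rec = k, off = off,
        dist = sqrt(sum((records[[k]]$com + off - c0)^2)))
    }
  }
  d <- vapply(inst, `[[`, 0, "dist")
  # round before ordering so rigid motions cannot permute tied images
  ord <- order(round(d, 6), vapply(inst, `[[`, 0L, "rec"),
               vapply(inst, function(x) x$off[1], 0),
               vapply(inst, function(x) x$off[2], 0),
               vapply(inst, function(x) x$off[3], 0))
  if (length(ord) < n_mol) stop("fewer than ", n_mol, " molecules obtainable")
  inst[ord[seq_len(n_mol)]]
}

cluster_coords <- function(records, inst, heavy_only = TRUE) {
  do.call(rbind, lapply(inst, function(x) {
    r <- records[[x$rec]]
    keep <- if (heavy_only) r$species != "H" else rep(TRUE, length(r$species))
    sweep(r$pos[keep, , drop = FALSE], 2L, x$off, `+`)
  }))
}

cluster_coms <- function(records, inst) {
  t(vapply(inst, function(x) records[[x$rec]]$com + x$off, numeric(3)))
}

#' RMSD over 15-molecule clusters (RMSD15)
#'
#' The standard crystal-packing similarity measure: from the reference a
#' cluster of a central molecule plus its 14 nearest neighbours (by
#' centre-of-mass distance, periodic images allowed) is extracted, the
#' corresponding cluster is built from the compared structure, molecules
#' are matched greedily by centre-of-mass distance after a superposition
#' seeded on the central molecules (refined once), and the non-hydrogen
#' atoms of the matched clusters are superimposed by the optimal proper
#' rotation/translation. The reported value is the minimum over candidate
#' central molecules of the reference. No inversion/mirroring is allowed.
#'
#' @param structure the structure to score.
#' @param reference the reference structure (same component multiset).
#' @param library a [component_library()] for molecule typing.
#' @param n_mol cluster size (default 15).
#' @param align superimpose before scoring (disable to measure raw
#'   deviations in the given frames).
#' @param tolerance bond-perception tolerance.
#' @return RMSD in Angstrom.
#' @export
rmsd15 <- function(structure, reference, library, n_mol = 15L, align = TRUE,
                   tolerance = 1.2) {
  rec_s <- molecule_records(structure, library, tolerance)
  rec_r <- molecule_records(reference, library, tolerance)
  tys <- sort(vapply(rec_s, `[[`, "", "type"))
  tyr <- sort(vapply(rec_r, `[[`, "", "type"))
  if (!identical(tys, tyr)) stop("component multisets differ")

  # molecule correspondence between cells: by atom-index sets when the two
  # structures share an atom ordering, else greedily by type
  match_mol <- function(kr) {
    for (ks in seq_along(rec_s)) {
      if (identical(sort(rec_s[[ks]]$indices), sort(rec_r[[kr]]$indices)) &&
          rec_s[[ks]]$type == rec_r[[kr]]$type) {
        return(ks)
      }
    }
    which(vapply(rec_s, `[[`, "", "type") == rec_r[[kr]]$type)[1]
  }

  best <- Inf
  for (central_r in seq_along(rec_r)) {
    central_s <- match_mol(central_r)
    cl_r <- build_cluster(rec_r, reference$cell, central_r, n_mol)
    cl_s <- build_cluster(rec_s, structure$cell, central_s, n_mol)
    if (!align) {
      P <- cluster_coords(rec_s, cl_s)
      Q <- cluster_coords(rec_r, cl_r)
      if (nrow(P) != nrow(Q)) next
      best <- min(best, sqrt(mean(rowSums((P - Q)^2))))
      next
    }
    # initial superposition seeded on the central molecules
    c_s <- rec_s[[cl_s[[1]]$rec]]
    c_r <- rec_r[[cl_r[[1]]$rec]]
    keep_s <- c_s$species != "H"; keep_r <- c_r$species != "H"
    P0 <- sweep(c_s$pos[keep_s, , drop = FALSE], 2L, cl_s[[1]]$off, `+`)
    Q0 <- sweep(c_r$pos[keep_r, , drop = FALSE], 2L, cl_r[[1]]$off, `+`)
    trans <- function(coords, P, Q) {
      # rigid transform mapping P-frame onto Q-frame, applied to coords
      cp <- colMeans(P); cq <- colMeans(Q)
      H <- t(sweep(P, 2L, cp)) %*% sweep(Q, 2L, cq)
      sv <- svd(H)
      d <- sign(det(sv$v %*% t(sv$u)))
      R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
      sweep(sweep(coords, 2L, cp) %*% R, 2L, cq, `+`)
    }
    assignment <- NULL
    coms_r <- cluster_coms(rec_r, cl_r)
    for (pass in 1:2) {
      coms_s <- cluster_coms(rec_s, cl_s)
      if (nrow(P0) >= 3L && nrow(P0) == nrow(Q0)) {
        coms_s <- trans(coms_s, P0, Q0)
      } else {
        coms_s <- sweep(coms_s, 2L, coms_s[1, ] - coms_r[1, ])
      }
      # greedy type-respecting assignment by COM distance
      ty_s <- vapply(cl_s, function(x) rec_s[[x$rec]]$type, "")
      ty_r <- vapply(cl_r, function(x) rec_r[[x$rec]]$type, "")
      used <- rep(FALSE, n_mol)
      assignment <- integer(n_mol)
      dd <- as.matrix(stats::dist(rbind(coms_r, coms_s)))[seq_len(n_mol),
                                                          n_mol + seq_len(n_mol)]
      for (kr in order(apply(dd, 1L, min))) {
        cand <- which(!used & ty_s == ty_r[kr])
        if (!length(cand)) stop("cluster composition mismatch")
        pick <- cand[which.min(dd[kr, cand])]
        assignment[kr] <- pick
        used[pick] <- TRUE
      }
      if (pass == 1L) {
        # refine: re-seed the superposition on all matched molecules' COMs
        P0 <- cluster_coms(rec_s, cl_s)[assignment, , drop = FALSE]
        Q0 <- coms_r
      }
    }
    P <- cluster_coords(rec_s, cl_s[assignment])
    Q <- cluster_coords(rec_r, cl_r)
    if (nrow(P) != nrow(Q)) next
    best <- min(best, kabsch_rmsd(P, Q))
  }
  if (!is.finite(best)) stop("no comparable clusters found")
  best
}
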