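#' Component library of molecular building blocks
#'
#' Maps component identifiers to element-labelled molecular graphs plus a
#' reference gas-phase geometry. Component typing of molecules found in a
#' crystal is by element-labelled graph isomorphism against these entries.
#'
#' @param entries named list; each element is created by [component_entry()].
#' @return an object of class `component_library`.
#' @export
component_library <- function(entries) {
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("entries must be a named list")
  }
  ids <- names(entries)
  if (length(ids) > 1L) {
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      if (graphs_isomorphic(entries[[i]]$species, entries[[i]]$bonds,
                            entries[[j]]$species, entries[[j]]$bonds)) {
        stop("library entries '", ids[i], "' and '", ids[j],
             "' have isomorphic element-labelled graphs")
      }
    }
  }
  structure(list(entries = entries), class = "component_library")
}

#' Library entry: an element-labelled molecular graph with a reference geometry
#'
#' @param species element symbols per atom.
#' @param bonds integer m x 2 matrix of bonded atom index pairs (1-based).
#' @param geometry n x 3 matrix, reference gas-phase Cartesian coordinates.
#' @return a list usable in [component_library()].
#' @export
component_entry <- function(species, bonds, geometry) {
  geometry <- as.matrix(geometry)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  stopifnot(nrow(geometry) == length(species))
  list(species = as.character(species), bonds = bonds, geometry = geometry)
}

# Element-labelled graph isomorphism via igraph VF2 with vertex colours.
graphs_isomorphic <- function(sp1, bonds1, sp2, bonds2) {
  if (length(sp1) != length(sp2)) return(FALSE)
  if (!identical(sort(sp1), sort(sp2))) return(FALSE)
  lev <- sort(unique(c(sp1, sp2)))
  g1 <- igraph::make_empty_graph(n = length(sp1), directed = FALSE)
  if (nrow(bonds1)) g1 <- igraph::add_edges(g1, t(bonds1))
  g2 <- igraph::make_empty_graph(n = length(sp2), directed = FALSE)
  if (nrow(bonds2)) g2 <- igraph::add_edges(g2, t(bonds2))
  igraph::isomorphic(g1, g2, method = "vf2",
                     vertex.color1 = match(sp1, lev),
                     vertex.color2 = match(sp2, lev))
}

# Bond perception for a non-periodic geometry: i,j bonded iff
# d(i,j) <= tolerance * (rcov_i + rcov_j).
perceive_bonds <- function(species, positions, tolerance = 1.2) {
  n <- length(species)
  rc <- covalent_radius(species)
  out <- matrix(integer(0), ncol = 2L)
  if (n < 2L) return(out)
  d <- as.matrix(stats::dist(positions))
  cut <- tolerance * outer(rc, rc, `+`)
  idx <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  matrix(as.integer(idx[, c(1L, 2L), drop = FALSE]), ncol = 2L)
}

#' Identify intact molecules in a periodic structure
#'
#' Builds the periodic bond graph (atoms bonded iff any minimum-image
#' distance is below `tolerance` times the sum of covalent radii) and
#' returns its connected components as molecular units, each with integer
#' lattice translations (`image_shifts`) that make the molecule whole.
#'
#' Valid when molecular diameters are below half the shortest cell height;
#' a molecule bonding to its own periodic image (a periodic polymer) or
#' exceeding that bound raises an error rather than mis-partitioning.
#'
#' @param structure a [periodic_structure()].
#' @param tolerance dimensionless multiplier on summed covalent radii
#'   (default 1.2, a standard heuristic for organic molecules).
#' @return list of molecular units: `atom_indices`, `image_shifts`
#'   (n x 3 integer), `component_type` (initially `"unknown"`).
#' @export
identify_molecules <- function(structure, tolerance = 1.2) {
  if (tolerance <= 0) stop("tolerance must be positive")
  n <- n_atoms(structure)
  rc <- covalent_radius(structure$species)
  # self-image bonds: periodic polymer through the cell
  if (any(structure$pbc)) {
    lens <- cell_heights(structure$cell)[structure$pbc]
    if (any(lens <= 2 * tolerance * max(rc) * 2)) {
      # cell so small an atom could bond its own image; check explicitly
      for (i in seq_len(n)) {
        rng <- lapply(1:3, function(k) if (structure$pbc[k]) -1:1 else 0L)
        sh <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
        sh <- sh[rowSums(abs(sh)) > 0, , drop = FALSE]
        dd <- sqrt(rowSums((sh %*% structure$cell)^2))
        if (any(dd <= tolerance * 2 * rc[i])) {
          stop("atom ", i, " bonds its own periodic image (periodic polymer)")
        }
      }
    }
  }
  # adjacency with image shifts (vectorised over pairs and image shifts);
  # the +-1 search is centred on the rounded fractional difference so that
  # positions arbitrarily far outside the cell are handled exactly
  adj <- vector("list", n)
  if (n > 1L) {
    rng <- lapply(1:3, function(k) if (structure$pbc[k]) -1:1 else 0L)
    shifts <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    offs <- shifts %*% structure$cell
    up <- which(upper.tri(diag(n)), arr.ind = TRUE)
    pv <- structure$positions[up[, 2], , drop = FALSE] -
      structure$positions[up[, 1], , drop = FALSE]
    fd <- pv %*% solve(structure$cell)
    base <- -round(fd)
    base[, !structure$pbc] <- 0
    pv <- pv + base %*% structure$cell
    d2 <- matrix(0, nrow(up), nrow(shifts))
    for (s in seq_len(nrow(shifts))) {
      d2[, s] <- (pv[, 1] + offs[s, 1])^2 + (pv[, 2] + offs[s, 2])^2 +
        (pv[, 3] + offs[s, 3])^2
    }
    best <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_len(nrow(up)), best)])
    cut <- tolerance * (rc[up[, 1]] + rc[up[, 2]])
    for (p in which(dmin <= cut)) {
      i <- up[p, 1]; j <- up[p, 2]
      sh <- as.integer(shifts[best[p], ] + base[p, ])
      adj[[i]] <- c(adj[[i]], list(list(j = j, shift = sh)))
      adj[[j]] <- c(adj[[j]], list(list(j = i, shift = -sh)))
    }
  }
  comp <- rep(NA_integer_, n)
  shifts <- matrix(NA_integer_, n, 3L)
  n_comp <- 0L
  for (root in seq_len(n)) {
    if (!is.na(comp[root])) next
    n_comp <- n_comp + 1L
    comp[root] <- n_comp
    shifts[root, ] <- 0L
    queue <- root
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (e in adj[[i]]) {
        s <- shifts[i, ] + e$shift
        if (is.na(comp[e$j])) {
          comp[e$j] <- n_comp
          shifts[e$j, ] <- s
          queue <- c(queue, e$j)
        } else if (any(shifts[e$j, ] != s)) {
          stop("molecular component ", n_comp,
               " wraps onto itself through the cell (periodic polymer)")
        }
      }
    }
  }
  units <- lapply(seq_len(n_comp), function(k) {
    idx <- which(comp == k)
    sh <- shifts[idx, , drop = FALSE]
    # re-anchor shifts so the first atom has zero shift
    sh <- sweep(sh, 2L, sh[1L, ], `-`)
    list(atom_indices = idx, image_shifts = sh, component_type = "unknown")
  })
  # diameter check: minimum-image bonding is only safe for compact molecules
  if (any(structure$pbc)) {
    hmin <- min(cell_heights(structure$cell)[structure$pbc])
    for (k in seq_along(units)) {
      u <- units[[k]]
      if (length(u$atom_indices) < 2L) next
      pos <- structure$positions[u$atom_indices, , drop = FALSE] +
        u$image_shifts %*% structure$cell
      diam <- max(stats::dist(pos))
      if (diam >= hmin / 2) {
        stop("molecule ", k, " has diameter ", signif(diam, 4),
             " A >= half the smallest cell height (", signif(hmin / 2, 4),
             " A); minimum-image molecule identification is unsafe")
      }
    }
  }
  units
}

#' Assign component types to molecular units
#'
#' Each unit's bond graph (perceived on the unwrapped monomer geometry) is
#' matched against the library by element-labelled graph isomorphism;
#' unmatched units are labelled `"unknown"`.
#'
#' @param units output of [identify_molecules()].
#' @param structure the parent [periodic_structure()].
#' @param library a [component_library()].
#' @param tolerance bond-perception tolerance, as in [identify_molecules()].
#' @return `units` with `component_type` filled in.
#' @export
assign_component_types <- function(units, structure, library,
                                   tolerance = 1.2) {
  for (k in seq_along(units)) {
    mono <- extract_monomer(structure, units[[k]])
    bonds <- perceive_bonds(mono$species, mono$positions, tolerance)
    units[[k]]$component_type <- "unknown"
    for (id in names(library$entries)) {
      e <- library$entries[[id]]
      if (graphs_isomorphic(mono$species, bonds, e$species, e$bonds)) {
        units[[k]]$component_type <- id
        break
      }
    }
  }
  units
}

#' Extract a gas-phase monomer from a crystal
#'
#' Returns the unit's atoms at unwrapped Cartesian coordinates (image shifts
#' applied) as a non-periodic structure, in `atom_indices` order.
#'
#' @param structure parent [periodic_structure()].
#' @param unit one element of the [identify_molecules()] output.
#' @return a non-periodic [periodic_structure()].
#' @export
extract_monomer <- function(structure, unit) {
  idx <- unit$atom_indices
  if (any(idx < 1L) || any(idx > n_atoms(structure))) {
    stop("unit atom indices outside parent structure")
  }
  pos <- structure$positions[idx, , drop = FALSE] +
    unit$image_shifts %*% structure$cell
  periodic_structure(structure$species[idx], pos, cell = NULL, pbc = FALSE,
                     provenance = paste0("monomer<", structure$provenance, ">"))
}

# Multiset of component types in a structure (named integer vector).
composition_of <- function(structure, library, tolerance = 1.2) {
  units <- identify_molecules(structure, tolerance)
  units <- assign_component_types(units, structure, library, tolerance)
  types <- vapply(units, `[[`, "", "component_type")
  table(types)
}
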