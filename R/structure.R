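#' Periodic crystal structure
#'
#' The central container of the package: a set of atoms with Cartesian
#' positions, a 3x3 cell matrix (rows are lattice vectors, Angstrom) and
#' periodic-boundary flags. Optional energy/force/virial labels attach the
#' output of a calculator to the structure.
#'
#' @param species character vector of element symbols, one per atom.
#' @param positions numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell 3x3 matrix of lattice vectors (rows), Angstrom. May be `NULL`
#'   for non-periodic structures (a large bounding box is stored).
#' @param pbc logical(3) (or a single logical) periodicity flags.
#' @param labels optional [efs_result()] holding energy (eV), forces (eV/A)
#'   and virial (eV) labels for this structure.
#' @param provenance free-text tag recording where the structure came from.
#' @return an object of class `periodic_structure`.
#' @export
periodic_structure <- function(species, positions, cell = NULL,
                               pbc = !is.null(cell), labels = NULL,
                               provenance = "") {
  species <- as.character(species)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (length(species) == 0L) stop("structure must contain at least one atom")
  if (nrow(positions) != length(species) || ncol(positions) != 3L) {
    stop("positions must be an n x 3 matrix matching species length")
  }
  if (length(pbc) == 1L) pbc <- rep(as.logical(pbc), 3L)
  pbc <- as.logical(pbc)
  if (length(pbc) != 3L || anyNA(pbc)) stop("pbc must be three booleans")
  if (is.null(cell)) {
    if (any(pbc)) stop("periodic structure requires a cell")
    span <- max(apply(positions, 2L, function(x) diff(range(x))), 1) + 100
    cell <- diag(3L) * span
  }
  cell <- as.matrix(cell)
  storage.mode(cell) <- "double"
  if (!all(dim(cell) == c(3L, 3L))) stop("cell must be a 3x3 matrix")
  if (all(pbc) && det(cell) <= 0) {
    stop("cell must have strictly positive determinant when fully periodic")
  }
  covalent_radius(unique(species))  # validate symbols early
  x <- structure(
    list(species = species, positions = positions, cell = cell, pbc = pbc,
         labels = labels, provenance = provenance),
    class = "periodic_structure"
  )
  x
}

#' Energy/forces/virial result
#'
#' @param energy total potential energy (eV).
#' @param forces n x 3 matrix of forces (eV/A), or `NULL`.
#' @param virial symmetric 3x3 virial (eV, `-dE/d(strain)`), or `NULL`.
#' @return an object of class `efs_result`.
#' @export
efs_result <- function(energy, forces = NULL, virial = NULL) {
  energy <- as.numeric(energy)
  if (length(energy) != 1L || !is.finite(energy)) {
    stop("energy must be a single finite number")
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    storage.mode(forces) <- "double"
    if (ncol(forces) != 3L) stop("forces must be an n x 3 matrix")
  }
  if (!is.null(virial)) {
    virial <- as.matrix(virial)
    storage.mode(virial) <- "double"
    if (!all(dim(virial) == c(3L, 3L))) stop("virial must be 3x3")
    if (max(abs(virial - t(virial))) > 1e-10) {
      stop("virial must be symmetric within 1e-10 eV")
    }
    virial <- (virial + t(virial)) / 2
  }
  structure(list(energy = energy, forces = forces, virial = virial),
            class = "efs_result")
}

#' @export
print.periodic_structure <- function(x, ...) {
  cat(sprintf("<periodic_structure: %d atoms (%s), pbc = %s>\n",
              length(x$species),
              paste(names(sort(-table(x$species))), collapse = ","),
              paste(ifelse(x$pbc, "T", "F"), collapse = "")))
  invisible(x)
}

n_atoms <- function(structure) length(structure$species)

#' Cell volume in Angstrom^3
#' @param structure a [periodic_structure()].
#' @return scalar volume.
#' @export
cell_volume <- function(structure) abs(det(structure$cell))

#' Mass density of a periodic structure
#' @param structure a fully periodic [periodic_structure()].
#' @return density in g/cm^3.
#' @export
structure_density <- function(structure) {
  if (!all(structure$pbc)) stop("density requires a fully periodic structure")
  sum(atomic_mass(structure$species)) * AMU_A3_TO_GCM3 / cell_volume(structure)
}

# Perpendicular heights of the cell (distance between opposite faces).
cell_heights <- function(cell) {
  v <- abs(det(cell))
  a <- cell[1L, ]; b <- cell[2L, ]; c3 <- cell[3L, ]
  cr <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                         u[3] * w[1] - u[1] * w[3],
                         u[1] * w[2] - u[2] * w[1])
  c(v / sqrt(sum(cr(b, c3)^2)),
    v / sqrt(sum(cr(c3, a)^2)),
    v / sqrt(sum(cr(a, b)^2)))
}

fractional_coords <- function(structure) {
  structure$positions %*% solve(structure$cell)
}

#' Wrap atoms into the unit cell
#' @param structure a [periodic_structure()].
#' @return the structure with all fractional coordinates in `[0, 1)` along
#'   periodic directions.
#' @export
wrap_structure <- function(structure) {
  frac <- fractional_coords(structure)
  for (k in 1:3) if (structure$pbc[k]) frac[, k] <- frac[, k] - floor(frac[, k])
  structure$positions <- frac %*% structure$cell
  structure
}

# Minimum-image displacement vectors from atom i to atom j (single pair),
# searching neighbouring image shifts. Returns list(vec, shift).
min_image_vector <- function(structure, i, j) {
  d0 <- structure$positions[j, ] - structure$positions[i, ]
  if (!any(structure$pbc)) return(list(vec = d0, shift = c(0L, 0L, 0L)))
  base <- -round(d0 %*% solve(structure$cell))[1, ]
  base[!structure$pbc] <- 0
  d0 <- d0 + as.numeric(base %*% structure$cell)
  rng <- lapply(1:3, function(k) if (structure$pbc[k]) -1:1 else 0L)
  shifts <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  cand <- sweep(shifts %*% structure$cell, 2L, d0, `+`)
  best <- which.min(rowSums(cand^2))
  list(vec = cand[best, ], shift = as.integer(shifts[best, ] + base))
}

# All-pairs minimum-image distance matrix (small structures only).
min_image_distances <- function(structure) {
  n <- n_atoms(structure)
  d <- matrix(0, n, n)
  if (n == 1L) return(d)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sqrt(sum(min_image_vector(structure, i, j)$vec^2))
  }
  d
}

#' Smallest k-point grid satisfying a length criterion
#'
#' Per reciprocal direction the number of k points `n` is the smallest
#' integer with `n * a >= x`, where `a` is the corresponding cell vector
#' length; `n` is at least 1.
#'
#' @param cell 3x3 matrix of lattice vectors (rows), Angstrom.
#' @param x length threshold in Angstrom (conventionally 30).
#' @return integer vector of three grid divisions.
#' @export
kpoint_grid <- function(cell, x) {
  cell <- as.matrix(cell)
  lens <- sqrt(rowSums(cell^2))
  if (any(lens <= 0) || length(x) != 1L || x <= 0) {
    stop("cell lengths and x must be positive")
  }
  pmax(as.integer(ceiling(x / lens)), 1L)
}
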