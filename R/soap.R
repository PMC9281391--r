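#' SOAP descriptor specification
#'
#' Hyperparameters of the smooth-overlap-of-atomic-positions power-spectrum
#' descriptor. Neighbour densities are Gaussian-smeared, expanded in
#' `n_max` radial Gaussians times spherical harmonics up to `l_max`,
#' contracted to the rotation-invariant power spectrum over species pairs
#' and L2-normalised. A quintic polynomial switch over the outer
#' `switch_width` Angstrom makes every descriptor component go smoothly to
#' its isolated-atom value as neighbours cross the cutoff.
#'
#' @param cutoff radial cutoff (Angstrom).
#' @param species ordered character vector of element symbols the descriptor
#'   knows about.
#' @param n_max number of radial basis functions (>= 1).
#' @param l_max spherical-harmonic limit (0..4).
#' @param sigma_atom Gaussian smearing width of the neighbour density
#'   (Angstrom).
#' @param zeta kernel exponent used with these descriptors (>= 1).
#' @param switch_width width of the smooth cutoff region (Angstrom).
#' @param exclude_intramolecular build each atom's neighbour density from
#'   *other* molecules only (same-molecule-instance neighbours are dropped;
#'   periodic copies of the own molecule still count). This is the natural
#'   descriptor for intermolecular corrections, whose signal would
#'   otherwise be swamped by the always-present covalent neighbours.
#' @return an object of class `soap_spec`.
#' @export
soap_spec <- function(cutoff, species, n_max = 8L, l_max = 4L,
                      sigma_atom = 0.5, zeta = 4, switch_width = 0.5,
                      exclude_intramolecular = FALSE) {
  stopifnot(cutoff > 0, n_max >= 1, l_max >= 0, sigma_atom > 0, zeta >= 1,
            switch_width > 0, switch_width < cutoff)
  if (l_max > 4L) stop("l_max up to 4 is supported")
  structure(list(cutoff = cutoff, species = as.character(species),
                 n_max = as.integer(n_max), l_max = as.integer(l_max),
                 sigma_atom = sigma_atom, zeta = zeta,
                 switch_width = switch_width,
                 exclude_intramolecular = isTRUE(exclude_intramolecular)),
            class = "soap_spec")
}

.soap_cache <- new.env(parent = emptyenv())

soap_radial_table <- function(spec) {
  key <- paste(spec$n_max, spec$l_max, spec$cutoff, spec$sigma_atom,
               sep = "|")
  tab <- .soap_cache[[key]]
  if (is.null(tab)) {
    tab <- cpp_radial_table(spec$n_max, spec$l_max, spec$cutoff,
                            spec$sigma_atom, 600L, 321L)
    .soap_cache[[key]] <- tab
  }
  tab
}

soap_species_index <- function(structure, spec) {
  idx <- match(structure$species, spec$species)
  if (anyNA(idx)) {
    stop("species not covered by SOAP spec: ",
         paste(unique(structure$species[is.na(idx)]), collapse = ", "))
  }
  as.integer(idx - 1L)
}

soap_call <- function(structure, spec, want_grad) {
  if (any(structure$pbc)) structure <- wrap_structure(structure)
  sidx <- soap_species_index(structure, spec)
  n <- n_atoms(structure)
  mol_id <- integer(n)
  shifts <- matrix(0L, n, 3L)
  if (isTRUE(spec$exclude_intramolecular)) {
    units <- identify_molecules(structure)
    for (k in seq_along(units)) {
      mol_id[units[[k]]$atom_indices] <- k
      shifts[units[[k]]$atom_indices, ] <- units[[k]]$image_shifts
    }
  } else {
    mol_id <- seq_len(n) * 0L + seq_len(n) # unique ids: no exclusion
  }
  res <- cpp_soap(sidx, structure$positions, structure$cell, structure$pbc,
                  length(spec$species), spec$n_max, spec$l_max, spec$cutoff,
                  spec$sigma_atom, spec$switch_width,
                  soap_radial_table(spec), want_grad,
                  mol_id, shifts, isTRUE(spec$exclude_intramolecular))
  res$center_species <- structure$species
  res$species_index <- sidx
  res
}

#' Compute SOAP descriptors for every atom of a structure
#'
#' @param structure a [periodic_structure()]; all periodic images within the
#'   cutoff contribute to each atom's neighbour density.
#' @param spec a [soap_spec()] covering all species present.
#' @return object of class `soap_descriptors`: a list with `vectors`
#'   (n_atoms x D matrix of unit-norm descriptors) and `center_species`.
#' @export
compute_soap <- function(structure, spec) {
  res <- soap_call(structure, spec, FALSE)
  structure(list(vectors = res$desc, center_species = res$center_species),
            class = "soap_descriptors")
}

#' SOAP descriptors with analytic Cartesian gradients
#'
#' Returns, in addition to the descriptors, the sparse list of
#' (center, neighbour-image) gradient entries needed for force-capable
#' regression: for entry `e`, `grads[, , e]` is the D x 3 derivative of the
#' center's descriptor with respect to the image vector
#' `u = x_neighbor + L - x_center`.
#'
#' @inheritParams compute_soap
#' @return list with `vectors`, `center_species`, `entry_center`,
#'   `entry_neighbor`, `entry_vec` (K x 3) and `grads` (D x 3 x K array).
#' @export
soap_gradients <- function(structure, spec) {
  res <- soap_call(structure, spec, TRUE)
  list(vectors = res$desc, center_species = res$center_species,
       entry_center = res$entry_center, entry_neighbor = res$entry_neighbor,
       entry_vec = res$entry_vec, grads = res$grads)
}

#' Finite-difference descriptor gradients (reference implementation)
#'
#' Central finite differences of [compute_soap()] with respect to every
#' atom's Cartesian position. Slow; retained as the independent oracle the
#' analytic gradients are validated against.
#'
#' @inheritParams compute_soap
#' @param step displacement step (Angstrom).
#' @return array D x 3 x n_atoms x n_atoms: `[, dim, moved, center]`.
#' @export
soap_gradients_fd <- function(structure, spec, step = 1e-4) {
  n <- n_atoms(structure)
  d0 <- compute_soap(structure, spec)$vectors
  out <- array(0, dim = c(ncol(d0), 3L, n, n))
  for (a in seq_len(n)) for (dim in 1:3) {
    sp <- sm <- structure
    sp$positions[a, dim] <- sp$positions[a, dim] + step
    sm$positions[a, dim] <- sm$positions[a, dim] - step
    dp <- compute_soap(sp, spec)$vectors
    dm <- compute_soap(sm, spec)$vectors
    for (i in seq_len(n)) out[, dim, a, i] <- (dp[i, ] - dm[i, ]) / (2 * step)
  }
  out
}

# collapse per-entry gradients into dD_i/dx_a (D x 3 x moved x center)
soap_gradients_dense <- function(sg) {
  n <- length(sg$center_species)
  D <- ncol(sg$vectors)
  out <- array(0, dim = c(D, 3L, n, n))
  for (e in seq_along(sg$entry_center)) {
    i <- sg$entry_center[e]; j <- sg$entry_neighbor[e]
    g <- sg$grads[, , e, drop = FALSE]
    dim(g) <- dim(g)[1:2]
    out[, , j, i] <- out[, , j, i] + g
    out[, , i, i] <- out[, , i, i] - g
  }
  out
}

#' SOAP environment kernel
#'
#' Similarity of two normalised environment descriptors,
#' `k = (a . b)^zeta`; `k(a, a) = 1`.
#'
#' @param a,b numeric descriptor vectors of equal length (unit norm).
#' @param zeta positive kernel exponent.
#' @return similarity in `[0, 1]`.
#' @export
environment_kernel <- function(a, b, zeta = 4) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("descriptor lengths differ")
  max(sum(a * b), 0)^zeta
}

#' Structure dissimilarity from environment kernels
#'
#' With the kernel-induced environment distance
#' `d(i, j) = sqrt(2 - 2 k(i, j))`, returns the symmetric Hausdorff value
#' `max(max_i min_j d, max_j min_i d)`: the largest distance from any
#' environment of one structure to its best match in the other. Zero iff
#' the two environment sets match exactly.
#'
#' @param A,B [soap_descriptors()][compute_soap] objects (or plain
#'   matrices of row descriptors).
#' @param zeta kernel exponent.
#' @return non-negative scalar.
#' @export
structure_dissimilarity <- function(A, B, zeta = 4) {
  va <- if (is.matrix(A)) A else A$vectors
  vb <- if (is.matrix(B)) B else B$vectors
  if (is.null(va) || is.null(vb) || nrow(va) == 0L || nrow(vb) == 0L) {
    stop("empty environment set")
  }
  k <- pmax(va %*% t(vb), 0)^zeta
  d <- sqrt(pmax(2 - 2 * k, 0))
  max(max(apply(d, 1L, min)), max(apply(d, 2L, min)))
}
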