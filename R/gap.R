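#' Training observation for GAP regression
#'
#' @param structure a [periodic_structure()].
#' @param energy total-energy label (eV), or `NULL`.
#' @param forces n x 3 force labels (eV/A), or `NULL`.
#' @param virial 3x3 virial label (eV), or `NULL`.
#' @param weight_class tag selecting per-class regularisation strengths.
#' @return object of class `training_observation`.
#' @export
training_observation <- function(structure, energy = NULL, forces = NULL,
                                 virial = NULL, weight_class = "default") {
  if (is.null(energy) && is.null(forces) && is.null(virial)) {
    stop("at least one label (energy, forces, virial) is required")
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    stopifnot(nrow(forces) == n_atoms(structure), ncol(forces) == 3L)
  }
  structure(list(structure = structure, energy = energy, forces = forces,
                 virial = virial, weight_class = weight_class),
            class = "training_observation")
}

#' Select sparse points by environment-level farthest point sampling
#'
#' Pools every atomic environment of the observations, then greedily picks
#' `m` environments maximising the minimum kernel-induced distance
#' `sqrt(2 - 2 k)` to the already-selected set. The starting environment is
#' drawn with the given seed; everything after is deterministic.
#'
#' @param observations list of [training_observation()] (or of
#'   [periodic_structure()]).
#' @param m number of sparse environments.
#' @param spec a [soap_spec()].
#' @param seed integer seed for the starting environment.
#' @return list with `vectors` (m x D matrix) and `species` (length m).
#' @export
select_sparse_points <- function(observations, m, spec, seed = 1L) {
  structures <- lapply(observations, function(o) {
    if (inherits(o, "training_observation")) o$structure else o
  })
  descs <- lapply(structures, compute_soap, spec = spec)
  E <- do.call(rbind, lapply(descs, `[[`, "vectors"))
  sp <- unlist(lapply(descs, `[[`, "center_species"))
  n <- nrow(E)
  if (m > n) stop("m exceeds the pooled environment count (", n, ")")
  start <- withr::with_seed(seed, sample.int(n, 1L))
  chosen <- integer(m)
  chosen[1L] <- start
  # species-blocked kernel: distance sqrt(2) across species
  env_dist <- function(i) {
    k <- pmax(as.numeric(E %*% E[i, ]), 0)^spec$zeta
    k[sp != sp[i]] <- 0
    sqrt(pmax(2 - 2 * k, 0))
  }
  mindist <- env_dist(start)
  mindist[start] <- -Inf
  if (m > 1L) for (t in 2:m) {
    nxt <- which.max(mindist)
    chosen[t] <- nxt
    mindist <- pmin(mindist, env_dist(nxt))
    mindist[nxt] <- -Inf
  }
  list(vectors = E[chosen, , drop = FALSE], species = sp[chosen])
}

default_gap_regularization <- function() {
  list(default = c(energy = 0.001, force = 0.05, virial = 0.05))
}

#' Fit a sparse Gaussian approximation potential
#'
#' Sparse-GP regression of summed local SOAP energies, fitted jointly to
#' total energies, forces and (optionally) virials. The total energy model
#' is `E = sum_atoms [offset(species) + sum_s w_s k(d_atom, u_s)]` with the
#' polynomial SOAP kernel `k = (d . u)^zeta` (zero across center species).
#' Weights solve the regularised sparse-GP system via a QR factorisation of
#' the stacked design matrix `[Sigma^-1/2 Phi; chol(K_mm)]` — energy rows
#' are kernel sums, force rows come from descriptor gradients by the chain
#' rule, virial rows from strain derivatives.
#'
#' @param observations list of [training_observation()].
#' @param spec a [soap_spec()] covering all species present.
#' @param sparse_points optional result of [select_sparse_points()]; when
#'   `NULL`, `m_sparse` environments are selected automatically.
#' @param m_sparse number of sparse points if `sparse_points` is `NULL`.
#' @param regularization named list: per weight class a vector with entries
#'   `energy` (eV/atom), `force` (eV/A), `virial` (eV). Classes missing from
#'   the list fall back to `default`.
#' @param jitter diagonal jitter added to the sparse Gram matrix.
#' @param seed seed for sparse-point selection.
#' @return object of class `gap_model`.
#' @export
fit_gap <- function(observations, spec, sparse_points = NULL,
                    m_sparse = 100L,
                    regularization = default_gap_regularization(),
                    jitter = 1e-8, seed = 1L) {
  if (!length(observations)) stop("no training observations")
  if (is.null(sparse_points)) {
    sparse_points <- select_sparse_points(observations, m_sparse, spec, seed)
  }
  U <- sparse_points$vectors
  u_species <- sparse_points$species
  m <- nrow(U)
  sidx_sparse <- as.integer(match(u_species, spec$species) - 1L)
  if (anyNA(sidx_sparse)) stop("sparse-point species not in spec")

  reg_for <- function(class) {
    r <- regularization[[class]]
    if (is.null(r)) r <- regularization[["default"]]
    if (is.null(r)) stop("no regularization for weight class '", class, "'")
    r
  }

  # per-species energy offsets from energy-labelled observations
  sp_all <- spec$species
  has_e <- vapply(observations, function(o) !is.null(o$energy), TRUE)
  offsets <- setNames(rep(0, length(sp_all)), sp_all)
  if (any(has_e)) {
    Cnt <- t(vapply(observations[has_e], function(o) {
      vapply(sp_all, function(s) sum(o$structure$species == s), 0)
    }, numeric(length(sp_all))))
    if (length(sp_all) == 1L) Cnt <- matrix(Cnt, ncol = 1L)
    yv <- vapply(observations[has_e], `[[`, 0, "energy")
    fit <- stats::lm.fit(Cnt, yv)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    offsets[] <- beta
  }

  rows <- list(); ys <- list(); ws <- list()
  for (o in observations) {
    st <- o$structure
    reg <- reg_for(o$weight_class)
    need_grad <- !is.null(o$forces) || !is.null(o$virial)
    sg <- soap_call(st, spec, need_grad)
    gr <- cpp_gap_rows(sg$desc, sg$species_index, sg$entry_center,
                       sg$entry_neighbor, sg$entry_vec,
                       if (need_grad) sg$grads else array(0, c(1, 3, 0)),
                       U, sidx_sparse, spec$zeta, need_grad)
    if (!is.null(o$energy)) {
      w <- 1 / (reg[["energy"]] * n_atoms(st))
      rows[[length(rows) + 1L]] <- matrix(gr$e_row, nrow = 1L)
      ys[[length(ys) + 1L]] <- o$energy -
        sum(offsets[st$species])
      ws[[length(ws) + 1L]] <- w
    }
    if (!is.null(o$forces)) {
      rows[[length(rows) + 1L]] <- gr$f_rows
      ys[[length(ys) + 1L]] <- as.numeric(t(o$forces))
      ws[[length(ws) + 1L]] <- rep(1 / reg[["force"]], 3L * n_atoms(st))
    }
    if (!is.null(o$virial)) {
      rows[[length(rows) + 1L]] <- gr$v_rows
      ys[[length(ys) + 1L]] <- as.numeric(t(o$virial))
      ws[[length(ws) + 1L]] <- rep(1 / reg[["virial"]], 9L)
    }
  }
  Phi <- do.call(rbind, rows)
  y <- unlist(ys)
  w <- unlist(ws)

  Kmm <- pmax(U %*% t(U), 0)^spec$zeta
  Kmm[outer(u_species, u_species, `!=`)] <- 0
  # prune near-duplicate sparse points (pivoted Cholesky): directions the
  # data cannot constrain otherwise blow the weights up and wreck
  # off-manifold predictions
  pc <- suppressWarnings(chol(Kmm + jitter * diag(m), pivot = TRUE))
  dsq <- diag(pc)^2
  keep_rank <- sum(dsq > 1e-7 * dsq[1])
  if (keep_rank < m) {
    piv <- attr(pc, "pivot")[seq_len(keep_rank)]
    U <- U[piv, , drop = FALSE]
    u_species <- u_species[piv]
    m <- keep_rank
    Phi <- Phi[, piv, drop = FALSE]
    Kmm <- Kmm[piv, piv, drop = FALSE]
  }
  L <- NULL
  jit <- jitter
  for (tries in 1:6) {
    L <- tryCatch(chol(Kmm + jit * diag(m)), error = function(e) NULL)
    if (!is.null(L)) break
    jit <- jit * 100
  }
  if (is.null(L)) {
    stop("sparse Gram matrix is singular even after jitter ",
         signif(jit, 3), "; condition estimate ",
         signif(kappa(Kmm), 3))
  }
  A <- rbind(Phi * w, L)
  b <- c(y * w, rep(0, m))
  weights <- qr.coef(qr(A, LAPACK = TRUE), b)
  if (!all(is.finite(weights))) {
    stop("regression system numerically singular; condition estimate ",
         signif(kappa(Kmm), 3))
  }

  structure(list(spec = spec, sparse_points = U, sparse_species = u_species,
                 weights = as.numeric(weights), per_species_offset = offsets,
                 regularization = regularization, jitter = jit),
            class = "gap_model")
}

#' Predict energy, forces and virial with a GAP model
#'
#' @param object a [fit_gap()] model.
#' @param structure a [periodic_structure()].
#' @param forces compute forces and virial (via analytic descriptor
#'   gradients); disable for a faster energy-only evaluation.
#' @param ... unused.
#' @return an [efs_result()]; attribute `local_energies` carries the
#'   per-atom decomposition (summing exactly to the total energy).
#' @export
predict.gap_model <- function(object, structure, forces = TRUE, ...) {
  spec <- object$spec
  sidx_sparse <- as.integer(match(object$sparse_species, spec$species) - 1L)
  sg <- soap_call(structure, spec, forces)
  gr <- cpp_gap_rows(sg$desc, sg$species_index, sg$entry_center,
                     sg$entry_neighbor, sg$entry_vec,
                     if (forces) sg$grads else array(0, c(1, 3, 0)),
                     object$sparse_points, sidx_sparse, spec$zeta, forces)
  local <- as.numeric(gr$local %*% object$weights) +
    object$per_species_offset[structure$species]
  energy <- sum(local)
  F <- NULL; V <- NULL
  if (forces) {
    F <- matrix(as.numeric(gr$f_rows %*% object$weights), ncol = 3L,
                byrow = TRUE)
    V <- matrix(as.numeric(gr$v_rows %*% object$weights), 3L, 3L,
                byrow = TRUE)
    V <- (V + t(V)) / 2
  }
  out <- efs_result(energy, F, V)
  attr(out, "local_energies") <- unname(local)
  out
}

#' Save / load a GAP model archive
#'
#' A single self-describing JSON archive holding the descriptor spec,
#' sparse descriptors, weights, offsets, regularisation and a format
#' version.
#'
#' @param model a `gap_model`.
#' @param path file path (JSON).
#' @export
save_gap_model <- function(model, path) {
  obj <- list(format = "dgap-gap-1",
              spec = unclass(model$spec),
              sparse_points = model$sparse_points,
              sparse_species = model$sparse_species,
              weights = model$weights,
              per_species_offset = as.list(model$per_species_offset),
              regularization = model$regularization,
              jitter = model$jitter)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gap_model
#' @export
load_gap_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dgap-gap-1")) stop("unknown model format")
  spec <- do.call(soap_spec, obj$spec[c("cutoff", "species", "n_max", "l_max",
                                        "sigma_atom", "zeta", "switch_width",
                                        "exclude_intramolecular")])
  structure(list(spec = spec,
                 sparse_points = as.matrix(obj$sparse_points),
                 sparse_species = obj$sparse_species,
                 weights = obj$weights,
                 per_species_offset = unlist(obj$per_species_offset),
                 regularization = obj$regularization,
                 jitter = obj$jitter),
            class = "gap_model")
}
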