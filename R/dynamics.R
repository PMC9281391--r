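#' Variable-cell local relaxation
#'
#' Quasi-Newton (L-BFGS-B) minimisation of the calculator energy over a
#' combined coordinate of fractional positions and (optionally) six
#' symmetric strain components applied to the cell. Converged when every
#' Cartesian force component is below `fmax` and, for variable cells, every
#' virial component divided by V^(1/3) is below it too.
#'
#' @param structure a [periodic_structure()].
#' @param calc a [calculator()] (must supply a virial when `relax_cell`).
#' @param fmax force convergence threshold (eV/A).
#' @param relax_cell optimise the cell as well as the positions.
#' @param max_steps maximum optimizer iterations across restarts.
#' @param verbose print energy per restart.
#' @return the relaxed structure, labels set to its final [efs_result()].
#'   On non-convergence an error of class `dgap_relax_error` is raised
#'   carrying the last structure and residual force.
#' @export
relax <- function(structure, calc, fmax = 0.01, relax_cell = FALSE,
                  max_steps = 500L, verbose = FALSE) {
  stopifnot(fmax > 0)
  if (relax_cell && !all(structure$pbc)) {
    stop("relax_cell requires a fully periodic structure")
  }
  n <- n_atoms(structure)
  cell0 <- structure$cell
  cf <- abs(det(cell0))^(1 / 3) # strain variables scaled to length units

  build <- function(theta) {
    st <- structure
    if (relax_cell) {
      e <- theta[3 * n + 1:6] / cf
      Emat <- matrix(c(e[1], e[4], e[5],
                       e[4], e[2], e[6],
                       e[5], e[6], e[3]), 3L, 3L)
      st$cell <- cell0 %*% (diag(3L) + Emat)
    }
    frac <- matrix(theta[1:(3 * n)], n, 3L, byrow = TRUE)
    st$positions <- frac %*% st$cell
    st
  }
  resid <- function(res, st) {
    r <- max(abs(res$forces))
    if (relax_cell) {
      r <- max(r, max(abs(res$virial)) / abs(det(st$cell))^(1 / 3))
    }
    r
  }
  # L-BFGS-B requests fn and gr at the same point; evaluate once
  memo <- new.env(parent = emptyenv())
  eval_at <- function(theta) {
    if (!is.null(memo$theta) && identical(memo$theta, theta)) {
      return(memo$res)
    }
    res <- calc_evaluate(calc, build(theta))
    memo$theta <- theta
    memo$res <- res
    res
  }
  fn <- function(theta) eval_at(theta)$energy
  gr <- function(theta) {
    st <- build(theta)
    res <- eval_at(theta)
    gfrac <- -res$forces %*% t(st$cell) # dE/dfrac
    g <- as.numeric(t(gfrac))
    if (relax_cell) {
      if (is.null(res$virial)) stop("calculator provides no virial")
      dEde <- -res$virial # dE/dstrain (symmetric)
      g <- c(g, c(dEde[1, 1], dEde[2, 2], dEde[3, 3],
                  2 * dEde[1, 2], 2 * dEde[1, 3], 2 * dEde[2, 3]) / cf)
    }
    g
  }

  frac0 <- structure$positions %*% solve(cell0)
  theta <- as.numeric(t(frac0))
  if (relax_cell) theta <- c(theta, rep(0, 6))

  res0 <- calc_evaluate(calc, structure)
  if (resid(res0, structure) <= fmax) {
    structure$labels <- res0
    return(structure)
  }

  steps_left <- max_steps
  st <- structure
  # per-round trust box: caps coordinate moves (~0.8 A Cartesian, ~5%
  # strain) so a line search can never tunnel through a repulsive wall
  # into a spuriously bonded/unbonded topology
  lens <- sqrt(rowSums(cell0^2))
  cap <- rep(0.8 / lens, times = n) # fractional cap per coordinate
  if (relax_cell) cap <- c(cap, rep(0.05 * cf, 6))
  memo$theta <- theta
  memo$res <- res0
  cap_scale <- 1
  for (round in 1:40) {
    # a failed evaluation (e.g. a trial step fragmenting a molecule) aborts
    # the line search; restart quasi-Newton from the last good point with a
    # contracted trust box so the offending step cannot recur
    opt <- tryCatch(
      stats::optim(theta, fn, gr, method = "L-BFGS-B",
                   lower = theta - cap * cap_scale,
                   upper = theta + cap * cap_scale,
                   control = list(maxit = min(steps_left, 100L),
                                  factr = 10)),
      error = function(e) NULL)
    if (is.null(opt)) {
      if (!is.null(memo$theta)) theta <- memo$theta
      cap_scale <- max(cap_scale / 4, 1 / 256)
      st <- build(theta)
      res <- calc_evaluate(calc, st)
      steps_left <- steps_left - 5L
      if (resid(res, st) <= fmax) {
        st$labels <- res
        st$provenance <- paste0("relaxed<", structure$provenance, ">")
        attr(st, "composition") <- attr(structure, "composition")
        return(st)
      }
      if (steps_left <= 0) break
      next
    }
    cap_scale <- min(1, cap_scale * 2)
    theta <- opt$par
    st <- build(theta)
    res <- calc_evaluate(calc, st)
    if (verbose) {
      message(sprintf("relax round %d: E = %.6f eV, resid = %.4f",
                      round, res$energy, resid(res, st)))
    }
    if (resid(res, st) <= fmax) {
      st$labels <- res
      st$provenance <- paste0("relaxed<", structure$provenance, ">")
      attr(st, "composition") <- attr(structure, "composition")
      return(st)
    }
    steps_left <- steps_left - opt$counts[["gradient"]]
    if (steps_left <= 0) break
  }
  res <- calc_evaluate(calc, st)
  st$labels <- res
  cond <- structure(
    class = c("dgap_relax_error", "error", "condition"),
    list(message = sprintf(
      "relaxation did not converge: residual %.4f eV/A > fmax %.4f",
      resid(res, st), fmax),
      call = sys.call(-1), structure = st, residual = resid(res, st)))
  stop(cond)
}

#' Constant-pressure (NPT) molecular dynamics
#'
#' Langevin (BAOAB) thermostatted dynamics with an isotropic stochastic
#' Monte-Carlo barostat: every `barostat_interval` steps a random volume
#' change is proposed and accepted with the Metropolis NPT criterion,
#' scaling positions and cell affinely. With `barostat = FALSE` this is
#' plain NVT. Fully reproducible for a given seed.
#'
#' @param structure a fully periodic [periodic_structure()].
#' @param calc a [calculator()].
#' @param temperature target temperature (K).
#' @param pressure external pressure (bar).
#' @param n_steps number of MD steps.
#' @param timestep integration step (fs).
#' @param seed integer seed.
#' @param friction Langevin friction (1/fs).
#' @param barostat enable the volume moves.
#' @param barostat_interval steps between volume-move attempts.
#' @param sample_interval steps between recorded thermo samples.
#' @param max_force abort threshold for force blow-up (eV/A).
#' @return object of class `trajectory`: `frames` (list of structures) and
#'   `thermo` (data.frame: step, temperature, pressure, density, energy,
#'   volume).
#' @export
run_npt <- function(structure, calc, temperature, pressure = 1,
                    n_steps = 2000L, timestep = 1, seed = 1L,
                    friction = 0.02, barostat = TRUE,
                    barostat_interval = 10L, sample_interval = 10L,
                    max_force = 50) {
  stopifnot(temperature >= 0, timestep > 0, all(structure$pbc))
  masses <- atomic_mass(structure$species)
  n <- n_atoms(structure)
  p_ev <- pressure / EVA3_TO_BAR # eV/A^3
  kT <- KB_EV * max(temperature, 1e-12)

  withr::with_seed(seed, {
    st <- structure
    v <- matrix(rnorm(3 * n), n, 3L) *
      sqrt(KB_EV * temperature * ACC_UNIT / masses)
    if (temperature == 0) v[] <- 0
    res <- calc_evaluate(calc, st)
    c1 <- exp(-friction * timestep)
    c2m <- sqrt((1 - c1^2) * KB_EV * temperature * ACC_UNIT / masses)
    frames <- list(); thermo <- list()
    dv_scale <- 0.02 * cell_volume(st)

    for (step in seq_len(n_steps)) {
      if (max(abs(res$forces)) > max_force) {
        cond <- structure(
          class = c("dgap_md_error", "error", "condition"),
          list(message = sprintf("force blow-up at step %d (max |F| = %.1f)",
                                 step, max(abs(res$forces))),
               call = NULL, structure = st))
        stop(cond)
      }
      acc <- res$forces * (ACC_UNIT / masses)
      v <- v + 0.5 * timestep * acc
      st$positions <- st$positions + 0.5 * timestep * v
      v <- c1 * v + c2m * matrix(rnorm(3 * n), n, 3L)
      st$positions <- st$positions + 0.5 * timestep * v
      res <- calc_evaluate(calc, st)
      v <- v + 0.5 * timestep * res$forces * (ACC_UNIT / masses)

      if (barostat && step %% barostat_interval == 0L) {
        V <- cell_volume(st)
        dV <- rnorm(1, 0, dv_scale)
        s <- ((V + dV) / V)^(1 / 3)
        if (V + dV > 0) {
          st2 <- st
          st2$cell <- st$cell * s
          st2$positions <- st$positions * s
          res2 <- calc_evaluate(calc, st2)
          darg <- (res2$energy - res$energy) + p_ev * dV -
            n * kT * log((V + dV) / V)
          if (temperature > 0 && runif(1) < exp(-darg / kT)) {
            st <- st2; res <- res2
          } else if (temperature == 0 && darg < 0) {
            st <- st2; res <- res2
          }
        }
      }

      if (step %% sample_interval == 0L) {
        ke <- 0.5 * sum(masses * rowSums(v^2)) / ACC_UNIT
        Tk <- 2 * ke / (3 * n * KB_EV)
        V <- cell_volume(st)
        Pk <- if (!is.null(res$virial)) {
          (sum(diag(res$virial)) / 3 + n * KB_EV * Tk) / V * EVA3_TO_BAR
        } else NA_real_
        fr <- st
        fr$labels <- res
        frames[[length(frames) + 1L]] <- fr
        thermo[[length(thermo) + 1L]] <-
          data.frame(step = step, temperature = Tk, pressure = Pk,
                     density = structure_density(st), energy = res$energy,
                     volume = V)
      }
    }
    structure(list(frames = frames, thermo = do.call(rbind, thermo)),
              class = "trajectory")
  })
}

#' Mean density of a trajectory with block-averaged standard error
#'
#' @param traj a [run_npt()] trajectory.
#' @param discard_fraction initial fraction of frames discarded as
#'   equilibration (default 0.2).
#' @param blocks number of blocks for the standard error (default 5).
#' @return named numeric: `mean` and `se` (g/cm^3).
#' @export
mean_density <- function(traj, discard_fraction = 0.2, blocks = 5L) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  rho <- traj$thermo$density
  rho <- rho[(floor(length(rho) * discard_fraction) + 1L):length(rho)]
  if (length(rho) < blocks) stop("fewer retained frames than blocks")
  grp <- cut(seq_along(rho), blocks, labels = FALSE)
  bm <- tapply(rho, grp, mean)
  c(mean = mean(rho), se = stats::sd(bm) / sqrt(blocks))
}
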