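#' Farthest point sampling of structures
#'
#' Greedy max-min selection under the SOAP structure dissimilarity
#' ([structure_dissimilarity()]): starting from a seed structure (or from a
#' preselected set, e.g. an existing training set when choosing maximally
#' distant test structures), each step adds the pool structure with the
#' largest minimum distance to everything already selected. Ties are broken
#' by lowest pool index, making the procedure fully deterministic.
#'
#' @param pool list of descriptor sets ([compute_soap()] outputs or plain
#'   descriptor matrices), one per candidate structure.
#' @param n_select number of structures to select (<= pool size).
#' @param seed_index pool index of the starting structure; ignored when
#'   `preselected` is given.
#' @param preselected optional list of descriptor sets already in the
#'   selected set (not part of the pool, never returned).
#' @param zeta kernel exponent of the environment kernel.
#' @return object of class `selection_result`: `chosen` (ordered pool
#'   indices) and `distances` (for each chosen structure, its min distance
#'   to the previously selected set; `NA` for a seed start).
#' @export
fps_select <- function(pool, n_select, seed_index = 1L, preselected = NULL,
                       zeta = 4) {
  n <- length(pool)
  if (n_select < 1L || n_select > n) {
    stop("n_select must be between 1 and the pool size")
  }
  mats <- lapply(pool, function(p) if (is.matrix(p)) p else p$vectors)
  # stacked environments with group offsets for fast incremental distances
  counts <- vapply(mats, nrow, 0L)
  offs <- c(0L, cumsum(counts))
  E <- do.call(rbind, mats)

  dist_to <- function(M) {
    # distances from structure M to every pool structure
    k <- pmax(E %*% t(M), 0)^zeta
    d <- sqrt(pmax(2 - 2 * k, 0))
    vapply(seq_len(n), function(j) {
      blk <- d[(offs[j] + 1L):offs[j + 1L], , drop = FALSE]
      max(max(apply(blk, 1L, min)), max(apply(blk, 2L, min)))
    }, numeric(1))
  }

  chosen <- integer(0)
  dists <- numeric(0)
  if (!is.null(preselected)) {
    mindist <- rep(Inf, n)
    for (p in preselected) {
      mp <- if (is.matrix(p)) p else p$vectors
      mindist <- pmin(mindist, dist_to(mp))
    }
  } else {
    if (seed_index < 1L || seed_index > n) stop("invalid seed_index")
    chosen <- as.integer(seed_index)
    dists <- NA_real_
    mindist <- dist_to(mats[[seed_index]])
    mindist[seed_index] <- -Inf
  }
  while (length(chosen) < n_select) {
    nxt <- which.max(mindist) # first maximum = lowest index on ties
    chosen <- c(chosen, nxt)
    dists <- c(dists, mindist[nxt])
    if (length(chosen) == n_select) break
    mindist <- pmin(mindist, dist_to(mats[[nxt]]))
    mindist[nxt] <- -Inf
  }
  structure(list(chosen = chosen, distances = dists),
            class = "selection_result")
}
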