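# brute-force greedy FPS oracle, recomputing every distance from scratch
fps_oracle <- function(pool, n_select, seed_index = 1, preselected = NULL,
                       zeta = 4) {
  dmat <- function(a, b) structure_dissimilarity(a, b, zeta)
  chosen <- integer(0); dists <- numeric(0)
  sel_sets <- preselected
  if (is.null(preselected)) {
    chosen <- seed_index; dists <- NA_real_
    sel_sets <- pool[seed_index]
  }
  while (length(chosen) < n_select) {
    cand <- setdiff(seq_along(pool), chosen)
    mind <- vapply(cand, function(j) {
      min(vapply(sel_sets, function(s) dmat(s, pool[[j]]), 0))
    }, 0)
    pick <- cand[which.max(mind)]
    chosen <- c(chosen, pick)
    dists <- c(dists, max(mind))
    sel_sets <- c(sel_sets, pool[pick])
  }
  list(chosen = chosen, distances = dists)
}
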