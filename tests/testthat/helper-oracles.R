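# Independent oracles and fixture builders shared across test files.

# Exhaustive best split over all (variable, midpoint-threshold) pairs for
# the rows `rows`, least-squares gain, complete cases of each candidate
# variable only.  Mirrors the documented tie rules: first strictly better
# gain wins, variables scanned in column order, thresholds ascending.
oracle_best_split <- function(X, y, rows, min_node) {
  best <- list(gain = 0, var = NA_integer_, split = NA_real_)
  for (j in seq_len(ncol(X))) {
    obs <- rows[!is.na(X[rows, j])]
    if (length(obs) < 2 * min_node) next
    xs <- sort(unique(X[obs, j]))
    if (length(xs) < 2) next
    thr <- (xs[-length(xs)] + xs[-1]) / 2
    tot <- sum(y[obs])
    for (t in thr) {
      L <- obs[X[obs, j] < t]
      R <- obs[X[obs, j] >= t]
      if (length(L) < min_node || length(R) < min_node) next
      gain <- sum(y[L])^2 / length(L) + sum(y[R])^2 / length(R) -
        tot^2 / length(obs)
      if (gain > best$gain + 1e-12)
        best <- list(gain = gain, var = j, split = t, L = L, R = R)
    }
  }
  best
}

# Best-first greedy tree via the exhaustive split oracle (complete data):
# repeatedly split the leaf with the largest gain, up to `depth` splits.
# Returns per-row fitted values (leaf means).
oracle_tree_fit <- function(X, y, depth, min_node) {
  fitted <- rep(mean(y), nrow(X))
  leaves <- list(seq_len(nrow(X)))
  for (k in seq_len(depth)) {
    cands <- lapply(leaves, function(rw)
      oracle_best_split(X, y, rw, min_node))
    gains <- vapply(cands, `[[`, numeric(1), "gain")
    if (max(gains) <= 1e-12) break
    b <- which.max(gains)
    cb <- cands[[b]]
    fitted[cb$L] <- mean(y[cb$L])
    fitted[cb$R] <- mean(y[cb$R])
    leaves <- c(leaves[-b], list(cb$L), list(cb$R))
  }
  fitted
}

# small mixed-type fixture (no missing values unless na_frac > 0)
make_fixture <- function(n, p = 4, seed = 1, na_frac = 0) {
  set.seed(seed)
  X <- cbind(matrix(rnorm(n * ceiling(p / 2)), n),
             matrix(rbinom(n * floor(p / 2), 1, 0.4), n))[, 1:p, drop = FALSE]
  colnames(X) <- paste0("v", seq_len(p))
  if (na_frac > 0) X[matrix(runif(n * p) < na_frac, n, p)] <- NA
  list(X = X, y = rnorm(n))
}

# a ps_incomplete with a hand-chosen mask
with_mask <- function(sample, mask) {
  inc <- impose_mcar(sample, 0, seed = 1)
  inc$mask <- mask
  colnames(inc$mask) <- paste0("x", 1:4)
  inc
}
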