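# Independent brute-force oracles used to check the selection algorithms.
# These deliberately reimplement each rule from scratch (plain loops, no
# shared code with the package internals).

random_cloud <- function(n, d) matrix(runif(n * d), n, d)

# next Kennard-Stone pick: the unselected point whose minimum distance to
# the selected set is largest (ties: lowest index)
oracle_ks_step <- function(DM, selected) {
  n <- nrow(DM)
  best <- NA_integer_
  best_val <- -Inf
  for (i in setdiff(seq_len(n), selected)) {
    mind <- min(DM[i, selected])
    if (mind > best_val) {
      best_val <- mind
      best <- i
    }
  }
  best
}

# exhaustive D-optimal subset of a given size (with intercept column)
oracle_dopt_best <- function(points, n_select, intercept = TRUE) {
  Fm <- if (intercept) cbind(1, points) else points
  combos <- combn(nrow(Fm), n_select)
  dets <- apply(combos, 2L, function(s) det(crossprod(Fm[s, , drop = FALSE])))
  list(indices = sort(combos[, which.max(dets)]), det = max(dets))
}

# full MDC sequence recomputed from scratch at every step
oracle_mdc_sequence <- function(DM, n_select) {
  n <- nrow(DM)
  # rank of i in j's neighbour list, ties by lower index
  r <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    others <- setdiff(seq_len(n), j)
    ord <- others[order(DM[others, j], others)]
    for (m in seq_along(ord)) r[ord[m], j] <- m
  }
  w <- rep(1, n)
  taken <- integer(0)
  for (s in seq_len(n_select)) {
    score <- rep(-Inf, n)
    for (i in setdiff(seq_len(n), taken)) {
      acc <- 0
      for (j in seq_len(n)) if (j != i) acc <- acc + w[j] / r[i, j]
      score[i] <- acc
    }
    c_i <- which.max(score)
    taken <- c(taken, c_i)
    for (j in seq_len(n)) if (j != c_i) w[j] <- w[j] * (1 - 1 / r[c_i, j])
    w[c_i] <- 0
  }
  taken
}

# total priority score after adding batch B, computed with plain loops
oracle_batch_total <- function(DM, selected, B, ex) {
  n <- nrow(DM)
  tot <- 0
  sel <- c(selected, B)
  for (x in seq_len(n)) {
    ps <- 1
    for (i in sel) ps <- ps * (1 - (1 - DM[x, i])^ex)
    tot <- tot + ps
  }
  tot
}

oracle_best_batch <- function(DM, selected, batch, ex) {
  cands <- setdiff(seq_len(nrow(DM)), selected)
  combos <- combn(cands, batch)
  tots <- apply(combos, 2L, function(B) oracle_batch_total(DM, selected, B, ex))
  sort(combos[, which.min(tots)])
}

# small synthetic problem reused across adaptive tests
small_synthetic <- function(n = 60, n_sparse = 20, seed = 1) {
  generate_synthetic(synthetic_spec(n, n_sparse = n_sparse, seed = seed))
}
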