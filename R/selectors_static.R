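#' Selection result
#'
#' Common return type of all selection algorithms: an ordered list of selected
#' compound indices plus method-specific diagnostics.
#'
#' @param indices integer vector of selected compound indices (selection
#'   order).
#' @param method method tag.
#' @param n total number of compounds in the space.
#' @param meta list of diagnostics (determinant trajectory, bin count,
#'   score trajectory, ...).
#' @return Object of class `selection_result`.
#' @export
selection_result <- function(indices, method, n, meta = list()) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection contains duplicate indices")
  if (length(indices) && (min(indices) < 1L || max(indices) > n))
    stop("selection index out of range")
  structure(list(indices = indices, method = method,
                 size = length(indices), n = n, meta = meta),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d of %d compounds\n  %s\n",
              x$method, x$size, x$n,
              paste(x$indices, collapse = " ")))
  invisible(x)
}

#' Kennard-Stone maximin selection
#'
#' Starts from the most central compound (minimum distance sum; see
#' [central_index()]) or a caller-supplied start, then repeatedly adds the
#' compound with the largest Euclidean distance to its closest neighbour
#' among those already selected. Ties are broken by the lowest index, making
#' the sequence fully deterministic; consequently the first `k` picks of a
#' longer run equal the full output of a shorter run (prefix property).
#'
#' @param space a [chem_space()].
#' @param n_select number of compounds to select.
#' @param start `"central"` or an explicit start index.
#' @return A [selection_result()].
#' @export
kennard_stone <- function(space, n_select, start = "central") {
  DM <- space$DM
  n <- nrow(DM)
  if (n_select < 1L || n_select > n) stop("n_select must lie in 1..n")
  first <- if (identical(start, "central")) central_index(DM) else as.integer(start)
  sel <- integer(n_select)
  sel[1L] <- first
  if (n_select > 1L) {
    # min distance of every compound to the selected set, updated per pick
    mind <- DM[, first]
    for (s in 2:n_select) {
      mind[sel[seq_len(s - 1L)]] <- -Inf
      sel[s] <- which.max(mind)
      mind <- pmin(mind, DM[, sel[s]])
    }
  }
  selection_result(sel, "kennard-stone", n)
}

#' D-Optimal selection with Fedorov exchanges
#'
#' Maximizes the determinant of the information matrix `t(F) %*% F`, where
#' `F` holds the selected rows of the model matrix (component scores plus, by
#' default, an intercept column). Each restart begins from a random subset
#' containing the `fixed` points and repeatedly performs the single best
#' Fedorov exchange — swapping one free selected point against one unselected
#' point — as long as the determinant increases. The best restart wins.
#'
#' The exchange gain is evaluated with the standard rank-two update on the
#' dispersion matrix; the accepted swap's determinant is recomputed exactly,
#' so the recorded trajectory is exact and non-decreasing.
#'
#' @param space a [chem_space()].
#' @param n_select total number of points in the design (including `fixed`).
#'   Should be at least d+1 (d = space dimension plus intercept) for a
#'   non-singular information matrix.
#' @param fixed indices that must be part of the design (used by the adaptive
#'   PLS-Optimal extension); kept in place, never exchanged.
#' @param restarts number of random restarts.
#' @param intercept append an intercept column to the model matrix?
#' @return A [selection_result()] whose `meta` holds `det` (final
#'   determinant), `trajectory` (determinants of the winning restart,
#'   non-decreasing) and `restarts`.
#' @export
d_optimal_fedorov <- function(space, n_select, fixed = integer(0),
                              restarts = 10L, intercept = TRUE) {
  Fm <- space$points
  if (intercept) Fm <- cbind(1, Fm)
  n <- nrow(Fm); p <- ncol(Fm)
  fixed <- as.integer(fixed)
  if (n_select > n) stop("n_select exceeds the number of compounds")
  if (length(fixed) > n_select) stop("more fixed points than n_select")
  free_pool <- setdiff(seq_len(n), fixed)
  n_free <- n_select - length(fixed)

  best <- NULL
  for (r in seq_len(restarts)) {
    sel <- c(fixed, if (n_free > 0L) sample(free_pool, n_free))
    M <- crossprod(Fm[sel, , drop = FALSE])
    det_cur <- det(M)
    traj <- det_cur
    if (!is.finite(det_cur) || det_cur <= 0) { # singular start: try next restart
      if (is.null(best)) best <- list(sel = sel, det = det_cur, traj = traj,
                                      singular = TRUE)
      next
    }
    repeat {
      if (n_free == 0L) break
      D <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(D)) break
      sel_free <- setdiff(sel, fixed)
      out <- setdiff(seq_len(n), sel)
      if (!length(out)) break
      A <- Fm %*% D                       # n x p
      dvec <- rowSums(A * Fm)             # x' D x for every point
      Cmat <- A[sel_free, , drop = FALSE] %*% t(Fm[out, , drop = FALSE])
      # det ratio for removing i, adding j: 1 + d_j - d_i - (d_i*d_j - d_ij^2)
      delta <- outer(1 - dvec[sel_free], dvec[out], "*") + Cmat^2 -
        dvec[sel_free]
      wm <- arrayInd(which.max(delta), dim(delta))
      if (delta[wm] <= 1e-12) break
      cand <- sel
      cand[cand == sel_free[wm[1L]]] <- out[wm[2L]]
      M_new <- crossprod(Fm[cand, , drop = FALSE])
      det_new <- det(M_new)
      if (!(det_new > det_cur)) break     # numeric guard: accept only true gains
      sel <- cand; M <- M_new; det_cur <- det_new
      traj <- c(traj, det_cur)
    }
    if (is.null(best) || isTRUE(best$singular) || det_cur > best$det)
      best <- list(sel = sel, det = det_cur, traj = traj, singular = FALSE)
  }
  if (is.null(best) || isTRUE(best$singular))
    stop("information matrix singular at every restart: ",
         "degenerate space or n_select too small")
  selection_result(best$sel, "d-optimal", n,
                   meta = list(det = best$det, trajectory = best$traj,
                               restarts = restarts))
}

#' Space-filling design on a three-dimensional space
#'
#' Partitions each of the three axes into `b` equal bins, giving `b^3` cells.
#' The bin count is not fixed in advance: `b` is increased from 1 until the
#' number of non-empty cells reaches `n_select`. Each kept cell contributes
#' the compound closest (Euclidean) to the cell center; when more cells are
#' occupied than compounds requested, the `n_select` most populated cells are
#' kept (ties by lowest cell linear index). The final bin on each axis is
#' right-closed, so every point falls in exactly one cell.
#'
#' @param space a [chem_space()] with exactly 3 dimensions (typically the
#'   first three principal components).
#' @param n_select number of compounds to select.
#' @param b_max safety cap on the bin scan.
#' @return A [selection_result()] with `meta$b` (chosen bin count) and
#'   `meta$n_occupied`.
#' @export
space_filling <- function(space, n_select, b_max = 200L) {
  P <- space$points
  if (ncol(P) != 3L)
    stop("space_filling operates on exactly 3 components; got ", ncol(P))
  n <- nrow(P)
  if (n_select > nrow(unique(P)))
    stop("n_select exceeds the number of distinct points")
  lo <- apply(P, 2L, min); hi <- apply(P, 2L, max)
  for (b in seq_len(b_max)) {
    w <- (hi - lo) / b
    bin <- matrix(1L, n, 3L)
    for (ax in 1:3) {
      if (w[ax] > 0)
        bin[, ax] <- pmin(b, floor((P[, ax] - lo[ax]) / w[ax]) + 1L)
    }
    cell <- (bin[, 1L] - 1L) + b * (bin[, 2L] - 1L) + b^2 * (bin[, 3L] - 1L) + 1L
    counts <- table(cell)
    if (length(counts) >= n_select) {
      occ <- as.integer(names(counts))
      keep <- occ[order(-as.integer(counts), occ)][seq_len(n_select)]
      sel <- integer(n_select)
      for (i in seq_along(keep)) {
        cid <- keep[i]
        members <- which(cell == cid)
        # cell center in original coordinates
        idx3 <- c((cid - 1L) %% b,
                  ((cid - 1L) %/% b) %% b,
                  (cid - 1L) %/% b^2) + 1L
        ctr <- lo + (idx3 - 0.5) * w
        ctr[w == 0] <- lo[w == 0]
        d2 <- colSums((t(P[members, , drop = FALSE]) - ctr)^2)
        sel[i] <- members[which.min(d2)]
      }
      return(selection_result(sel, "space-filling", n,
                              meta = list(b = b, n_occupied = length(counts))))
    }
  }
  stop("could not occupy enough cells within b_max bins")
}

# Rank matrix for MDC: r[i, j] = rank of compound i in compound j's
# nearest-neighbour ordering (1 = nearest; self excluded; distance ties by
# lower index). r[j, j] = Inf so that self terms vanish in reciprocal sums.
mdc_rank_matrix <- function(DM) {
  n <- nrow(DM)
  r <- matrix(Inf, n, n)
  for (j in seq_len(n)) {
    others <- setdiff(seq_len(n), j)
    o <- others[order(DM[others, j], others)]
    r[o, j] <- seq_len(n - 1L)
  }
  r
}

#' Most descriptive compound (MDC) selection
#'
#' Sequential similarity-based selection: every compound carries a
#' representativeness score, the top scorer is picked, and the information it
#' explains is removed before the next pick. Scores follow the
#' reciprocal-rank scheme of Hudson et al.: with `r[i, j]` the rank of
#' compound `i` in compound `j`'s nearest-neighbour list and weights `w[j]`
#' (all 1 initially), `score[i] = sum_j w[j] / r[i, j]`. After picking
#' compound `c`, `w[j] <- w[j] * (1 - 1 / r[c, j])` for every other compound
#' and `w[c] <- 0`. A fixed number of compounds is selected rather than using
#' a score-based stop criterion.
#'
#' @param space a [chem_space()].
#' @param n_select number of compounds to select.
#' @return A [selection_result()] with `meta$score_trajectory`, the winning
#'   score at each pick.
#' @export
mdc <- function(space, n_select) {
  DM <- space$DM
  n <- nrow(DM)
  if (n_select > n) stop("n_select exceeds the number of compounds")
  r <- mdc_rank_matrix(DM)
  rr <- 1 / r                      # reciprocal ranks; diagonal 0
  w <- rep(1, n)
  sel <- integer(n_select)
  traj <- numeric(n_select)
  avail <- rep(TRUE, n)
  for (s in seq_len(n_select)) {
    score <- as.vector(rr %*% w)
    score[!avail] <- -Inf
    c_i <- which.max(score)
    sel[s] <- c_i
    traj[s] <- score[c_i]
    w <- w * (1 - rr[c_i, ])
    w[c_i] <- 0
    avail[c_i] <- FALSE
  }
  selection_result(sel, "mdc", n, meta = list(score_trajectory = traj))
}

#' Random selection
#'
#' Uniform sample without replacement; the reference baseline. Uses the
#' global RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param n total number of compounds.
#' @param n_select number to select.
#' @return A [selection_result()].
#' @export
random_select <- function(n, n_select) {
  if (n_select > n) stop("n_select exceeds n")
  selection_result(sample.int(n, n_select), "random", n)
}
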