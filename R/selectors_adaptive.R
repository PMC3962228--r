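#' Score descriptors against the endpoint measured so far
#'
#' First phase of a DescRep cycle. Every descriptor receives a score
#' `S[i] = |Pearson cor(descriptor i over the measured compounds, y)|`;
#' descriptors that are constant over the measured compounds score 0. The
#' absolute pairwise descriptor-descriptor correlation matrix `M` is computed
#' over the *whole* design set (it is property-independent and far more
#' stable at small n than a measured-only estimate); entries involving a
#' constant descriptor are 0 off the diagonal and 1 on it.
#'
#' @param X_measured descriptor matrix restricted to the measured compounds
#'   (>= 3 rows).
#' @param y_measured endpoint values for those compounds.
#' @param X_design descriptor matrix of the full design set.
#' @return Object of class `descriptor_scores`: list with `S` (non-negative
#'   vector) and `M` (symmetric, in \[0,1\], unit diagonal).
#' @export
score_descriptors <- function(X_measured, y_measured, X_design) {
  X_measured <- as.matrix(X_measured)
  if (nrow(X_measured) < 3L)
    stop("need at least 3 measured compounds to correlate descriptors")
  if (nrow(X_measured) != length(y_measured))
    stop("X_measured rows and y_measured length differ")
  S <- suppressWarnings(abs(as.vector(stats::cor(X_measured, y_measured))))
  S[!is.finite(S)] <- 0
  names(S) <- colnames(X_measured)
  M <- suppressWarnings(abs(stats::cor(as.matrix(X_design))))
  M[!is.finite(M)] <- 0
  diag(M) <- 1
  structure(list(S = S, M = M), class = "descriptor_scores")
}

#' Select descriptors with cubic redundancy down-weighting
#'
#' Iteratively picks the descriptor with the highest score; after picking
#' descriptor `x`, every remaining score is updated to
#' `S[i] <- S[i] * (1 - M[i, x])^3`, so descriptors highly correlated to an
#' already chosen one are suppressed (annihilated entirely at |cor| = 1).
#' Ties go to the lowest index. If every remaining score reaches 0 before
#' `k` picks, the remaining slots are filled by lowest index and a warning is
#' raised (the measured signal is exhausted).
#'
#' @param scores a [score_descriptors()] result.
#' @param k number of descriptors to select.
#' @return Integer vector of descriptor indices in pick order, with
#'   attribute `trace`: a list holding the current score vector before each
#'   pick (selected entries `-Inf`), exposing the down-weighting arithmetic.
#' @examples
#' sc <- structure(list(S = c(.9, .6), M = diag(2)),
#'                 class = "descriptor_scores")
#' select_descriptors(sc, 2)
#' @export
select_descriptors <- function(scores, k) {
  S <- scores$S; M <- scores$M
  d <- length(S)
  if (k > d) stop("k exceeds the number of descriptors")
  sel <- integer(0)
  S_cur <- S
  trace <- vector("list", 0L)
  for (s in seq_len(k)) {
    S_cur[sel] <- -Inf
    trace[[s]] <- S_cur
    if (all(S_cur[setdiff(seq_len(d), sel)] <= 0)) {
      warning("descriptor scores exhausted after ", length(sel),
              " picks; filling remaining slots by index")
      sel <- c(sel, setdiff(seq_len(d), sel)[seq_len(k - length(sel))])
      break
    }
    x <- which.max(S_cur)
    sel <- c(sel, x)
    S_cur <- S_cur * (1 - M[, x])^3
  }
  structure(sel, trace = trace)
}

#' Initial seed by k-means partitioning
#'
#' Partitions the chemical space (principal-component scores) into `k`
#' clusters with k-means, restarted `restarts` times from randomly drawn data
#' points as initial centers. The winning partition is the one with the
#' lowest total within-cluster sum of pairwise distances; the seed contains
#' each cluster's medoid — the compound with the lowest sum of pairwise
#' distances to all other compounds in the same cluster.
#'
#' @param space a [chem_space()].
#' @param k seed size (number of clusters).
#' @param restarts number of k-means restarts (default 15).
#' @return Integer vector of `k` compound indices (ascending).
#' @export
initial_seed <- function(space, k, restarts = 15L) {
  DM <- space$DM
  n <- nrow(DM)
  if (k > n) stop("seed size exceeds the number of compounds")
  if (k == 1L) return(central_index(DM))
  best_cost <- Inf
  best_cl <- NULL
  for (r in seq_len(restarts)) {
    cl <- NULL
    for (try in seq_len(10L)) {
      ctr <- space$points[sample.int(n, k), , drop = FALSE]
      cl <- tryCatch(
        stats::kmeans(space$points, centers = ctr)$cluster,
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(cl) && length(unique(cl)) == k) break
      cl <- NULL
    }
    if (is.null(cl)) next
    cost <- sum(vapply(seq_len(k), function(g) {
      m <- which(cl == g)
      sum(DM[m, m]) / 2
    }, numeric(1)))
    if (cost < best_cost) { best_cost <- cost; best_cl <- cl }
  }
  if (is.null(best_cl))
    stop("k-means produced an empty cluster at every restart")
  seed <- vapply(seq_len(k), function(g) {
    m <- which(best_cl == g)
    m[which.min(rowSums(DM[m, m, drop = FALSE]))]
  }, integer(1))
  sort(seed)
}

#' Adaptive coverage exponent
#'
#' The correction-factor kernel `CF = 1 - (1 - DM)^exp` needs an exponent
#' matched to the local density of the space. Taking the most central
#' compound as reference, `exp` is chosen so that exactly its `n_cover`
#' nearest neighbours satisfy `(1 - DM)^exp >= lamda`: with `d_k` the
#' distance to the `n_cover`-th nearest neighbour,
#' `exp = log(lamda) / log(1 - d_k)`. `d_k` is clamped into
#' `[1e-9, 1 - 1e-9]` before taking logarithms, so near-duplicate
#' neighbourhoods yield a very large (sharp) exponent and saturated
#' neighbourhoods a very small one. `n_cover` is taken as the number of
#' compounds already selected plus the batch to be selected in this cycle.
#'
#' @param DM normalized distance matrix.
#' @param central index of the reference (most central) compound.
#' @param n_cover number of neighbours to cover (1 <= n_cover < n).
#' @param lamda coverage threshold in (0,1); default 0.75.
#' @return Positive scalar exponent.
#' @examples
#' DM <- distance_matrix(cbind(c(0, .5, 1)))
#' compute_exponent(DM, central = 2, n_cover = 1)
#' @export
compute_exponent <- function(DM, central, n_cover, lamda = 0.75) {
  n <- nrow(DM)
  if (n < 2L) stop("need at least two compounds")
  if (n_cover < 1L || n_cover >= n) stop("n_cover must lie in 1..(n-1)")
  if (lamda <= 0 || lamda >= 1) stop("lamda must lie in (0,1)")
  d_k <- sort(DM[central, -central])[n_cover]
  eps <- 1e-9
  d_k <- min(max(d_k, eps), 1 - eps)
  log(lamda) / log(1 - d_k)
}

#' Priority scores of unselected compounds
#'
#' `PS[x]` measures how poorly compound `x` is represented by the selected
#' set: the product over selected compounds `i` of the correction factor
#' `CF[x, i] = 1 - (1 - DM[x, i])^exp`. A compound coinciding with a
#' selected one gets PS 0 (fully covered); a compound at maximal distance
#' from every selected one keeps PS 1 (uncovered). Enlarging the selected
#' set can only decrease each PS because every CF lies in \[0,1\].
#'
#' @param DM normalized distance matrix.
#' @param selected non-empty vector of selected indices.
#' @param exp coverage exponent, see [compute_exponent()].
#' @return Numeric vector of length `nrow(DM)` in \[0,1\].
#' @export
priority_scores <- function(DM, selected, exp) {
  if (!length(selected)) stop("selected set must be non-empty")
  CF <- 1 - (1 - DM[, selected, drop = FALSE])^exp
  apply(CF, 1L, prod)
}

#' Select the batch minimizing total priority score
#'
#' Finds the batch `B` of unselected compounds for which the sum of priority
#' scores over all compounds, computed with `selected` united with `B`, is
#' minimal. All combinations are enumerated when
#' `choose(n_candidates, batch) <= max_exhaustive`; beyond that a greedy
#' completion is used (each new compound minimizes the resulting total PS),
#' which is the documented approximation for large batches.
#'
#' @param DM normalized distance matrix.
#' @param selected indices already selected (non-empty).
#' @param batch number of compounds to add.
#' @param exp coverage exponent for this cycle.
#' @param max_exhaustive combination-count cap for exhaustive search.
#' @return Integer vector of `batch` new indices (ascending for the
#'   exhaustive route, pick order for the greedy route), with attribute
#'   `mode` (`"exhaustive"` or `"greedy"`).
#' @export
select_batch <- function(DM, selected, batch, exp, max_exhaustive = 20000) {
  n <- nrow(DM)
  cands <- setdiff(seq_len(n), selected)
  if (batch < 1L) stop("batch must be >= 1")
  if (batch > length(cands)) stop("batch exceeds the unselected count")
  PS0 <- priority_scores(DM, selected, exp)
  CF <- 1 - (1 - DM)^exp
  if (choose(length(cands), batch) <= max_exhaustive) {
    combos <- utils::combn(cands, batch)
    totals <- apply(combos, 2L, function(B) {
      ps <- PS0
      for (b in B) ps <- ps * CF[, b]
      sum(ps)
    })
    B <- combos[, which.min(totals)]
    return(structure(as.integer(B), mode = "exhaustive"))
  }
  # greedy completion
  B <- integer(0)
  ps <- PS0
  pool <- cands
  for (s in seq_len(batch)) {
    totals <- colSums(ps * CF[, pool, drop = FALSE])
    pick <- pool[which.min(totals)]
    B <- c(B, pick)
    ps <- ps * CF[, pick]
    pool <- setdiff(pool, pick)
  }
  structure(B, mode = "greedy")
}

#' Run the DescRep adaptive design
#'
#' Alternates descriptor refinement and representativeness-based compound
#' selection along an increasing sample-size schedule. Cycle 0 draws the
#' initial seed with [initial_seed()] on a principal-component space and
#' queries the endpoint oracle. Every later cycle (one per schedule entry):
#'
#' 1. scores all descriptors against the endpoint values measured so far
#'    ([score_descriptors()]) and picks `k_descriptors` of them with cubic
#'    redundancy down-weighting ([select_descriptors()]);
#' 2. rebuilds the chemical space from those descriptor columns;
#' 3. recomputes the adaptive exponent ([compute_exponent()]) with
#'    `n_cover` = compounds selected so far + batch size;
#' 4. adds the batch minimizing the total priority score
#'    ([select_batch()]) and reveals its endpoint values.
#'
#' Selections are nested: the selection at any schedule size is a prefix of
#' the selection at every later size.
#'
#' @param table a [descriptor_table()]; normalized internally if not already.
#' @param oracle function `(indices) -> numeric` returning measured endpoint
#'   values; called once per cycle with newly selected row indices.
#' @param schedule strictly increasing cumulative sample sizes; the first
#'   entry is the seed size.
#' @param k_descriptors number of descriptors spanning the refined space
#'   (default 5, matching the five-component search space of the static
#'   designs).
#' @param n_pcs principal components used for the seed space.
#' @param lamda coverage threshold.
#' @param restarts k-means restarts for the seed.
#' @param max_exhaustive see [select_batch()].
#' @return Object of class `adaptive_run`: list with `method`, `schedule`,
#'   `selected` (full ordered index vector), `y` (revealed endpoint values,
#'   aligned with `selected`) and `cycles` (per-cycle records: target size,
#'   descriptor set, exponent, batch).
#' @export
descrep_run <- function(table, oracle, schedule, k_descriptors = 5L,
                        n_pcs = 5L, lamda = 0.75, restarts = 15L,
                        max_exhaustive = 20000) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!table$normalized) table <- normalize_minmax(table)
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  X <- table$X
  n <- nrow(X)
  if (max(schedule) > n) stop("schedule exceeds the number of compounds")
  space0 <- pca_project(table, min(n_pcs, min(dim(X))))
  selected <- initial_seed(space0, schedule[1L], restarts = restarts)
  y <- oracle(selected)
  cycles <- list(list(size = schedule[1L], descriptors = NULL,
                      exponent = NA_real_, batch = selected))
  for (s in schedule[-1L]) {
    batch <- s - length(selected)
    sc <- score_descriptors(X[selected, , drop = FALSE], y, X)
    desc <- select_descriptors(sc, min(k_descriptors, ncol(X)))
    sp <- chem_space(X[, desc, drop = FALSE], source = "selected_descriptors")
    ctr <- central_index(sp$DM)
    n_cover <- min(length(selected) + batch, n - 1L)
    ex <- compute_exponent(sp$DM, ctr, n_cover, lamda)
    B <- select_batch(sp$DM, selected, batch, ex, max_exhaustive)
    y <- c(y, oracle(B))
    selected <- c(selected, B)
    cycles[[length(cycles) + 1L]] <-
      list(size = s, descriptors = desc, exponent = ex, batch = as.integer(B))
  }
  structure(list(method = "descrep", schedule = schedule,
                 selected = as.integer(selected), y = y, cycles = cycles),
            class = "adaptive_run")
}

#' @export
print.adaptive_run <- function(x, ...) {
  cat(sprintf("adaptive_run [%s]: schedule %s; %d compounds selected\n",
              x$method, paste(x$schedule, collapse = ","),
              length(x$selected)))
  invisible(x)
}

#' Extend a selection by the PLS-Optimal criterion
#'
#' One PLS-Optimal cycle: fit a PLS regression on the measured compounds
#' (all normalized descriptors), project every design-set compound onto the
#' first `n_latent` latent variables — which are ranked by covariance with
#' the endpoint rather than by descriptor variance — and run the D-Optimal
#' Fedorov exchange on that latent space with the current selection as fixed
#' points.
#'
#' @param table a normalized [descriptor_table()].
#' @param y_measured endpoint values for `selected` (same order).
#' @param selected indices measured so far.
#' @param batch number of compounds to add; `batch = 0` returns `selected`.
#' @param n_latent latent variables spanning the search space (default 5);
#'   reduced with a warning when the measured set cannot support it.
#' @param restarts Fedorov restarts.
#' @return Integer vector: `selected` followed by the new indices.
#' @export
pls_optimal_extend <- function(table, y_measured, selected, batch,
                               n_latent = 5L, restarts = 10L) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!table$normalized) stop("table must be normalized")
  selected <- as.integer(selected)
  if (batch == 0L) return(selected)
  X <- table$X
  nl <- min(n_latent, length(selected) - 1L, ncol(X))
  if (nl < n_latent)
    warning("n_latent reduced to ", nl, " (measured set too small)")
  if (nl < 1L) stop("need at least 2 measured compounds for PLS-Optimal")
  fit <- suppressWarnings(
    mixOmics::pls(X[selected, , drop = FALSE], y_measured, ncomp = nl,
                  mode = "regression", scale = FALSE))
  lv <- suppressWarnings(stats::predict(fit, X)$variates)
  sp <- chem_space(as.matrix(lv), source = "pls_latent_variables")
  res <- d_optimal_fedorov(sp, n_select = length(selected) + batch,
                           fixed = selected, restarts = restarts)
  c(selected, setdiff(res$indices, selected))
}

#' Run the PLS-Optimal adaptive design
#'
#' Same schedule discipline as [descrep_run()]: the seed is drawn with
#' [initial_seed()] on the principal-component space, and every later cycle
#' extends the selection with [pls_optimal_extend()] on latent variables
#' refit to the endpoint values measured so far.
#'
#' @inheritParams descrep_run
#' @param n_latent latent variables for the refined space.
#' @param restarts_fedorov Fedorov exchange restarts per cycle.
#' @return An `adaptive_run` (see [descrep_run()]).
#' @export
pls_optimal_run <- function(table, oracle, schedule, n_latent = 5L,
                            n_pcs = 5L, restarts = 15L,
                            restarts_fedorov = 10L) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!table$normalized) table <- normalize_minmax(table)
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  X <- table$X
  n <- nrow(X)
  if (max(schedule) > n) stop("schedule exceeds the number of compounds")
  space0 <- pca_project(table, min(n_pcs, min(dim(X))))
  selected <- initial_seed(space0, schedule[1L], restarts = restarts)
  y <- oracle(selected)
  cycles <- list(list(size = schedule[1L], batch = selected))
  for (s in schedule[-1L]) {
    batch <- s - length(selected)
    ext <- pls_optimal_extend(table, y, selected, batch,
                              n_latent = n_latent,
                              restarts = restarts_fedorov)
    B <- setdiff(ext, selected)
    y <- c(y, oracle(B))
    selected <- c(selected, B)
    cycles[[length(cycles) + 1L]] <- list(size = s, batch = as.integer(B))
  }
  structure(list(method = "pls-optimal", schedule = schedule,
                 selected = as.integer(selected), y = y, cycles = cycles),
            class = "adaptive_run")
}
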