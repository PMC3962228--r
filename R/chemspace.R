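#' Pairwise distance matrix normalized to \[0,1\]
#'
#' Euclidean distances between all pairs of points, divided by the maximum
#' pairwise distance, so that the largest entry is exactly 1 (unless all
#' points coincide, in which case an all-zero matrix is returned with a
#' warning).
#'
#' @param points numeric matrix, one row per compound.
#' @return Symmetric matrix with zero diagonal, entries in \[0,1\].
#' @export
distance_matrix <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least two points")
  DM <- as.matrix(stats::dist(points))
  m <- max(DM)
  if (m == 0) {
    warning("all points identical: degenerate (all-zero) distance matrix")
    return(DM)
  }
  unname(DM / m)
}

#' Chemical search space
#'
#' Bundles a point configuration (principal-component scores or selected
#' descriptor columns) with its normalized pairwise distance matrix. All
#' selection algorithms in the package operate on this object.
#'
#' @param points numeric matrix (n compounds x d dimensions).
#' @param source tag recording how the space was built
#'   (`"principal_components"` or `"selected_descriptors"`).
#' @return Object of class `chem_space`: list with `points`, `DM`, `source`.
#' @export
chem_space <- function(points, source = "selected_descriptors") {
  points <- as.matrix(points)
  DM <- if (nrow(points) == 1L) matrix(0, 1L, 1L)
        else distance_matrix(points)
  structure(list(points = points, DM = DM, source = source),
            class = "chem_space")
}

#' @export
print.chem_space <- function(x, ...) {
  cat(sprintf("chem_space: %d compounds in %d dimensions (%s)\n",
              nrow(x$points), ncol(x$points), x$source))
  invisible(x)
}

#' Principal-component projection of a descriptor table
#'
#' Projects a normalized descriptor table onto its leading principal
#' components and returns the resulting [chem_space()]. By default the data
#' are *not* centered before the orthogonal transformation: on min-max
#' normalized group-count descriptors the uncentered cross-product
#' decomposition keeps the sparse-descriptor origin meaningful. Centered PCA
#' is available through `centered = TRUE`.
#'
#' @param table a normalized [descriptor_table()].
#' @param k number of components to retain; must not exceed `min(n, d)`.
#' @param centered center columns before the decomposition?
#' @return A [chem_space()] with additional elements `loadings` (d x k),
#'   `sdev` (singular values / sqrt(n)), `explained` (variance shares of the
#'   returned components), `center` and `rank`. If `k` exceeds the numerical
#'   rank only the available components are returned, with a warning.
#' @export
pca_project <- function(table, k, centered = FALSE) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!table$normalized)
    stop("pca_project expects a normalized table; call normalize_minmax() first")
  X <- table$X
  n <- nrow(X); d <- ncol(X)
  if (k < 1L || k > min(n, d))
    stop("k must lie in 1..min(n compounds, n descriptors)")
  ctr <- if (centered) colMeans(X) else rep(0, d)
  Xc <- sweep(X, 2L, ctr, "-")
  s <- svd(Xc)
  tol <- max(n, d) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > tol)
  k_eff <- k
  if (k > rank) {
    warning(sprintf("requested %d components but numerical rank is %d; returning %d",
                    k, rank, rank))
    k_eff <- max(rank, 1L)
  }
  scores <- s$u[, seq_len(k_eff), drop = FALSE] %*%
    diag(s$d[seq_len(k_eff)], k_eff)
  rownames(scores) <- table$ids
  colnames(scores) <- paste0("PC", seq_len(k_eff))
  sp <- chem_space(scores, source = "principal_components")
  sp$loadings <- s$v[, seq_len(k_eff), drop = FALSE]
  sp$sdev <- s$d[seq_len(k_eff)] / sqrt(n)
  sp$explained <- s$d[seq_len(k_eff)]^2 / sum(s$d^2)
  sp$center <- ctr
  sp$rank <- rank
  sp
}

#' Most central compound of a space
#'
#' The compound with the minimum sum of distances to all other compounds.
#' Ties are broken by the lowest index, so the result is deterministic.
#'
#' @param DM normalized distance matrix, or a [chem_space()].
#' @return Integer index of the central compound.
#' @export
central_index <- function(DM) {
  if (inherits(DM, "chem_space")) DM <- DM$DM
  which.min(rowSums(DM))
}

# Uncentered 2-component PCA used by the disruptor detector.
pca2 <- function(X) {
  s <- svd(X, nu = 2L, nv = 2L)
  list(scores = s$u %*% diag(s$d[1:2], 2L), loadings = s$v)
}

#' Detect a structural disruptor
#'
#' A structural disruptor is a compound that (a) shifts the loadings of the
#' first or second principal component when it is added to the dataset and
#' (b) lies at least five standard deviations from 97% of all other
#' compounds along one of those components. This function appends a candidate
#' descriptor row to a normalized table, recomputes the (uncentered) PCA, and
#' measures both effects.
#'
#' The distance criterion is operationalized on each of PC1 and PC2 as the
#' candidate score's absolute deviation from the mean of the central 97% of
#' the other compounds' scores, in units of that trimmed subset's standard
#' deviation (`sd_distance`). The loading criterion is reported as
#' `loading_shift` = 1 - |cos angle| between the component loadings with and
#' without the candidate; no threshold is applied to it because the loading
#' change is inherently qualitative — the boolean verdict rests on the
#' 5-trimmed-SD rule alone.
#'
#' @param table a normalized [descriptor_table()] with at least 34 compounds
#'   (below that a central-97% trim is meaningless).
#' @param candidate_row numeric descriptor vector expressed in the table's
#'   normalized column ranges (values may exceed \[0,1\] for out-of-range
#'   compounds).
#' @param centered center the PCA? Default matches [pca_project()].
#' @return Object of class `disruptor_report`: list with `is_disruptor`,
#'   `component` (1 or 2, the more extreme one), `sd_distance` (on that
#'   component) and `loading_shift` (length-2 vector for PC1 and PC2), plus
#'   `sd_distance_by_component`.
#' @export
detect_disruptor <- function(table, candidate_row, centered = FALSE) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!table$normalized) stop("table must be normalized")
  X <- table$X
  n <- nrow(X)
  if (n < 34L)
    stop("disruptor detection needs >= 34 compounds for a central-97% trim")
  candidate_row <- as.numeric(candidate_row)
  if (length(candidate_row) != ncol(X))
    stop("candidate row length does not match the descriptor count")
  ctr <- if (centered) colMeans(X) else rep(0, ncol(X))
  before <- pca2(sweep(X, 2L, ctr, "-"))
  Xa <- rbind(X, candidate_row)
  ctra <- if (centered) colMeans(Xa) else rep(0, ncol(Xa))
  after <- pca2(sweep(Xa, 2L, ctra, "-"))

  sd_dist <- numeric(2L)
  shift <- numeric(2L)
  n_drop <- round(0.015 * n)  # 1.5% per tail -> central 97%
  for (comp in 1:2) {
    sc <- after$scores[seq_len(n), comp]
    cand <- after$scores[n + 1L, comp]
    kept <- sort(sc)[(n_drop + 1L):(n - n_drop)]
    sd_dist[comp] <- abs(cand - mean(kept)) / stats::sd(kept)
    shift[comp] <- 1 - abs(sum(before$loadings[, comp] * after$loadings[, comp]))
  }
  component <- which.max(sd_dist)
  structure(
    list(is_disruptor = max(sd_dist) >= 5,
         component = component,
         sd_distance = sd_dist[component],
         sd_distance_by_component = sd_dist,
         loading_shift = shift),
    class = "disruptor_report")
}

#' @export
print.disruptor_report <- function(x, ...) {
  cat(sprintf(
    "disruptor_report: %s (PC%d at %.2f trimmed SDs; loading shift %.3f / %.3f)\n",
    if (x$is_disruptor) "DISRUPTOR" else "in distribution",
    x$component, x$sd_distance, x$loading_shift[1], x$loading_shift[2]))
  invisible(x)
}
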