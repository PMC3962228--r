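#' Specification for a synthetic descriptor table
#'
#' Describes the generator that emulates the statistical structure of a
#' small-molecule QSAR descriptor set: a few dense continuous descriptors
#' (solubility/lipophilicity-like, correlated Gaussians) plus a large block
#' of sparse non-negative group-count descriptors (E-State-like, zero for
#' most compounds), and an endpoint that is a weighted sum of a small driver
#' subset of descriptors plus Gaussian noise.
#'
#' @param n_compounds number of compounds.
#' @param n_dense dense continuous descriptors (default 2).
#' @param n_sparse sparse group-count descriptors (default 200).
#' @param sparsity probability that a sparse descriptor is zero for a
#'   compound (default 0.9).
#' @param drivers descriptor column indices carrying signal; default: the
#'   dense descriptors plus the first three sparse ones.
#' @param weights effect weights aligned with `drivers`; default
#'   `c(1, -0.7, 0.5, 0.5, 0.5)` truncated/recycled to the driver count.
#' @param noise_sd Gaussian noise SD on the endpoint (default 0.5, roughly a
#'   third of the signal SD under the defaults — measurement noise typical
#'   of a curated physicochemical endpoint).
#' @param nonlinearity add a mild quadratic term in the first driver?
#' @param dense_cor pairwise correlation among dense descriptors (default
#'   -0.6, mimicking the solubility/lipophilicity anticorrelation).
#' @param seed optional RNG seed applied by [generate_synthetic()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds, n_dense = 2L, n_sparse = 200L,
                           sparsity = 0.9, drivers = NULL, weights = NULL,
                           noise_sd = 0.5, nonlinearity = FALSE,
                           dense_cor = -0.6, seed = NULL) {
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0,1)")
  d <- n_dense + n_sparse
  if (is.null(drivers))
    drivers <- c(seq_len(n_dense),
                 if (n_sparse > 0L) n_dense + seq_len(min(3L, n_sparse)))
  if (any(drivers < 1L) || any(drivers > d))
    stop("driver indices outside the descriptor range")
  if (is.null(weights))
    weights <- rep_len(c(1, -0.7, 0.5, 0.5, 0.5), length(drivers))
  if (length(weights) != length(drivers))
    stop("weights must align with drivers")
  if (n_dense > 1L && dense_cor <= -1 / (n_dense - 1))
    stop("dense_cor makes the dense covariance non-positive-definite")
  structure(list(n_compounds = n_compounds, n_dense = n_dense,
                 n_sparse = n_sparse, sparsity = sparsity,
                 drivers = as.integer(drivers), weights = weights,
                 noise_sd = noise_sd, nonlinearity = isTRUE(nonlinearity),
                 dense_cor = dense_cor, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor table and endpoint
#'
#' Dense descriptors are drawn from a correlated multivariate Gaussian;
#' sparse descriptors are (Bernoulli mask) x |Gaussian|, i.e. zero with
#' probability `sparsity` and a positive group-sum-like value otherwise.
#' The endpoint is `y = sum_j w_j x_j (+ optional 0.15 * x_driver1^2) +
#' N(0, noise_sd)` over the driver columns. The returned truth record makes
#' driver-recovery checks possible downstream.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (raw [descriptor_table()]), `y` (endpoint
#'   vector) and `truth` (list: `drivers`, `weights`, `noise_sd`,
#'   `nonlinearity`, `spec`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_compounds
  p_dense <- spec$n_dense; p_sparse <- spec$n_sparse
  X <- matrix(0, n, p_dense + p_sparse)
  if (p_dense > 0L) {
    Sigma <- matrix(spec$dense_cor, p_dense, p_dense)
    diag(Sigma) <- 1
    X[, seq_len(p_dense)] <-
      matrix(stats::rnorm(n * p_dense), n, p_dense) %*% chol(Sigma)
  }
  if (p_sparse > 0L) {
    mask <- matrix(stats::runif(n * p_sparse) >= spec$sparsity, n, p_sparse)
    X[, p_dense + seq_len(p_sparse)] <-
      mask * abs(matrix(stats::rnorm(n * p_sparse), n, p_sparse))
  }
  colnames(X) <- c(if (p_dense > 0L) sprintf("dense_%02d", seq_len(p_dense)),
                   if (p_sparse > 0L) sprintf("group_%03d", seq_len(p_sparse)))
  truth <- list(drivers = spec$drivers, weights = spec$weights,
                noise_sd = spec$noise_sd, nonlinearity = spec$nonlinearity,
                spec = spec)
  y <- endpoint_from_truth(truth, X) + stats::rnorm(n, 0, spec$noise_sd)
  list(table = descriptor_table(X, ids = sprintf("C%04d", seq_len(n))),
       y = y, truth = truth)
}

#' Noise-free endpoint value under a synthetic truth record
#'
#' @param truth the `truth` element of [generate_synthetic()].
#' @param X descriptor row (named vector) or matrix in raw units.
#' @return Numeric vector of noise-free endpoint values.
#' @export
endpoint_from_truth <- function(truth, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  y <- as.numeric(X[, truth$drivers, drop = FALSE] %*% truth$weights)
  if (isTRUE(truth$nonlinearity))
    y <- y + 0.15 * X[, truth$drivers[1L]]^2
  y
}

#' Construct a structural disruptor for a descriptor table
#'
#' Builds a descriptor row that behaves like a genuine structural outlier: a
#' compound carrying substantial values on chemical groups that are
#' near-constant in the rest of the dataset, placed far enough out that it
#' shifts the first/second principal-component loadings and sits at least
#' `magnitude_sd` trimmed standard deviations from the central 97% of
#' compounds.
#'
#' The criterion is evaluated the way an extended dataset is actually
#' analysed: the candidate row is appended to the raw table, the whole
#' extended table is re-normalized to \[0,1\], and [detect_disruptor()] is
#' applied in those coordinates. (Calibrating in the base table's ranges
#' would overstate the outlier: re-normalization compresses the very columns
#' the disruptor dominates.) The displacement is doubled until detection
#' fires, then bisected so the final row sits just past the requested
#' magnitude rather than arbitrarily far out.
#'
#' @param table a [descriptor_table()] with raw descriptor values.
#' @param magnitude_sd required trimmed-SD distance (>= 5, the disruptor
#'   definition threshold).
#' @param n_direction number of near-constant descriptors spanning the
#'   outlying direction; defaults to 10% of the descriptors (at least 5) —
#'   a large molecule elevating a sizeable share of the group-count block,
#'   which is what lets a single compound rotate the leading components of
#'   a re-normalized dataset. If the criterion is unreachable at the
#'   requested width (re-normalization bounds how far one compound can sit
#'   out along few columns), the direction is widened automatically.
#' @param max_iter cap on the doubling search.
#' @return Object of class `disruptor`: list with `x_raw` (row in the
#'   table's raw units), `x_norm` (row in the *extended* table's normalized
#'   units), `report` (the final [detect_disruptor()] report) and `scale`
#'   (displacement used, in units of column range).
#' @export
make_disruptor <- function(table, magnitude_sd = 5, n_direction = NULL,
                           max_iter = 20L) {
  stopifnot(inherits(table, "descriptor_table"))
  if (magnitude_sd < 5)
    stop("magnitude_sd below 5 would not meet the disruptor definition")
  X <- table$X
  n <- nrow(X)
  if (is.null(n_direction))
    n_direction <- max(5L, ceiling(0.1 * ncol(X)))
  vars <- apply(normalize_minmax(table)$X, 2L, stats::var)
  cand_cols <- which(vars > 0)
  if (length(cand_cols) < 1L) stop("all descriptors constant")
  cand_cols <- cand_cols[order(vars[cand_cols])]
  rng_raw <- apply(X, 2L, max) - apply(X, 2L, min)
  base <- colMeans(X)
  make_dir <- function(width) {
    dir_cols <- cand_cols[seq_len(min(width, length(cand_cols)))]
    dirv <- numeric(ncol(X))
    # displacement in raw units, proportional to each column's range
    dirv[dir_cols] <- rng_raw[dir_cols] / sqrt(length(dir_cols))
    dirv
  }
  report_at <- function(t, dirv) {
    ext <- normalize_minmax(descriptor_table(
      rbind(X, base + t * dirv),
      ids = c(table$ids, ".disruptor."),
      descriptor_names = table$descriptor_names))
    body <- descriptor_table(ext$X[seq_len(n), , drop = FALSE],
                             ids = table$ids,
                             descriptor_names = table$descriptor_names,
                             normalized = TRUE)
    list(report = detect_disruptor(body, ext$X[n + 1L, ]),
         x_norm = ext$X[n + 1L, ])
  }
  width <- n_direction
  t_hi <- NA_real_
  for (w_try in seq_len(12L)) {
    dirv <- make_dir(width)
    t_try <- 1
    for (i in seq_len(max_iter)) {
      if (report_at(t_try, dirv)$report$sd_distance >= magnitude_sd) {
        t_hi <- t_try
        break
      }
      t_try <- t_try * 2
    }
    if (!is.na(t_hi)) break
    if (width >= length(cand_cols)) break
    width <- min(length(cand_cols), ceiling(width * 1.5))
  }
  if (is.na(t_hi))
    stop("could not reach the disruptor criterion at any direction width")
  t_lo <- t_hi / 2
  for (i in seq_len(20L)) {
    mid <- (t_lo + t_hi) / 2
    if (report_at(mid, dirv)$report$sd_distance >= magnitude_sd) t_hi <- mid
    else t_lo <- mid
  }
  final <- report_at(t_hi, dirv)
  x_raw <- base + t_hi * dirv
  names(x_raw) <- table$descriptor_names
  structure(list(x_raw = x_raw, x_norm = final$x_norm,
                 report = final$report, scale = t_hi,
                 n_direction = width),
            class = "disruptor")
}
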