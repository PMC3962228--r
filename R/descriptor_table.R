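#' Compound-by-descriptor table
#'
#' Container used throughout the package: a numeric matrix of molecular
#' descriptors (rows = compounds, columns = named descriptors) together with
#' unique compound identifiers and a flag recording whether the columns have
#' been min-max normalized to \[0,1\].
#'
#' @param X numeric matrix or data frame, one row per compound. Must be free
#'   of missing values.
#' @param ids character vector of unique compound identifiers; defaults to
#'   rownames of `X` or `"C1" ... "Cn"`.
#' @param descriptor_names column names; defaults to colnames of `X` or
#'   `"d1" ... "dp"`.
#' @param normalized logical; set by [normalize_minmax()], rarely by hand.
#'
#' @return An object of class `descriptor_table`: a list with elements `ids`,
#'   `X` (matrix with `ids` as rownames and descriptor names as colnames),
#'   `descriptor_names`, `normalized` and (after normalization) `norm_params`.
#' @seealso [normalize_minmax()], [read_descriptor_table()]
#' @export
descriptor_table <- function(X, ids = NULL, descriptor_names = NULL,
                             normalized = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L || ncol(X) < 1L)
    stop("descriptor table needs at least one compound and one descriptor")
  if (anyNA(X))
    stop("descriptor table contains missing values; clean the input first")
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("C", seq_len(nrow(X)))
  ids <- as.character(ids)
  if (length(ids) != nrow(X)) stop("length(ids) must equal nrow(X)")
  if (anyDuplicated(ids)) stop("duplicate compound identifiers")
  if (is.null(descriptor_names)) descriptor_names <- colnames(X)
  if (is.null(descriptor_names))
    descriptor_names <- paste0("d", seq_len(ncol(X)))
  descriptor_names <- as.character(descriptor_names)
  if (length(descriptor_names) != ncol(X))
    stop("length(descriptor_names) must equal ncol(X)")
  dimnames(X) <- list(ids, descriptor_names)
  structure(
    list(ids = ids, X = X, descriptor_names = descriptor_names,
         normalized = isTRUE(normalized), norm_params = NULL),
    class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d compounds x %d descriptors (%s)\n",
              nrow(x$X), ncol(x$X),
              if (x$normalized) "normalized to [0,1]" else "raw"))
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$X)

#' Read a descriptor table from CSV/TSV
#'
#' Expects a header row, a first column of compound identifiers named `id`
#' (any name is accepted; the first column is always taken as the identifier)
#' and numeric descriptor columns thereafter.
#'
#' @param path file path.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` read as tab, otherwise comma).
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("need an id column plus at least one descriptor")
  ids <- as.character(df[[1L]])
  X <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric descriptor values in ", path)
  descriptor_table(X, ids = ids)
}

#' Write a descriptor table to CSV
#'
#' @param table a [descriptor_table()].
#' @param path output file path.
#' @export
write_descriptor_table <- function(table, path) {
  stopifnot(inherits(table, "descriptor_table"))
  df <- data.frame(id = table$ids, table$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalization of descriptor columns
#'
#' Maps every descriptor column to \[0,1\] via `(x - min) / (max - min)`.
#' Normalization rather than autoscaling is appropriate for group-count
#' descriptors (E-State-like), which are zero for most compounds and far from
#' Gaussian. Constant columns are mapped to all zeros and kept, so column
#' indexing stays stable across data partitions. The operation is idempotent.
#'
#' When `params` is supplied (the `norm_params` fitted on a design partition)
#' those column ranges are applied instead of refitting, and values falling
#' outside the fitted range are clipped to \[0,1\] when `clip = TRUE`. This is
#' the leakage-free protocol used by the evaluation harness: ranges are fitted
#' on the design set only and applied to validation compounds.
#'
#' @param table a [descriptor_table()].
#' @param params optional list with numeric vectors `min` and `max` (one entry
#'   per descriptor) from a previous fit.
#' @param clip logical; clip transformed values into \[0,1\] (only meaningful
#'   with `params`).
#' @return A normalized [descriptor_table()] whose `norm_params` element holds
#'   the per-column `min` and `max` used.
#' @examples
#' tab <- descriptor_table(cbind(a = c(2, 4, 6), b = c(5, 5, 5)))
#' normalize_minmax(tab)$X
#' @export
normalize_minmax <- function(table, params = NULL, clip = FALSE) {
  stopifnot(inherits(table, "descriptor_table"))
  X <- table$X
  if (is.null(params)) {
    if (table$normalized) return(table)  # idempotent
    params <- list(min = apply(X, 2L, min), max = apply(X, 2L, max))
  } else {
    if (length(params$min) != ncol(X) || length(params$max) != ncol(X))
      stop("normalization parameters do not match the descriptor count")
  }
  rng <- params$max - params$min
  Z <- sweep(X, 2L, params$min, "-")
  nz <- rng > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2L, rng[nz], "/")
  Z[, !nz] <- 0
  if (clip) Z <- pmin(pmax(Z, 0), 1)
  out <- descriptor_table(Z, ids = table$ids,
                          descriptor_names = table$descriptor_names,
                          normalized = TRUE)
  out$norm_params <- params
  out
}

#' Normalization parameters of a fitted table
#'
#' @param table a normalized [descriptor_table()].
#' @return List with per-column `min` and `max`.
#' @export
norm_params <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(table$norm_params))
    stop("table has no fitted normalization parameters")
  table$norm_params
}
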