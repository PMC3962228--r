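#' Repeated design/validation splits
#'
#' Draws `trials` independent random partitions of `n` compounds into a
#' design set (default 84%) used for compound selection and model training,
#' and a validation set (the remaining 16%) used only for scoring. With 250
#' splits of this size every compound sits in 84% of the design sets on
#' average (210 of 250) and in 40 of the validation sets, and two random
#' design sets share about two thirds of the dataset.
#'
#' @param n number of compounds.
#' @param trials number of splits (default 250).
#' @param fraction design-set fraction (default 0.84); the design size is
#'   `floor(fraction * n + 0.5)` (round half up).
#' @return Object of class `split_set`: list with `trials` (each a list of
#'   `design` and `validation` index vectors), `n`, `fraction`, `n_design`.
#' @export
make_splits <- function(n, trials = 250L, fraction = 0.84) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0,1)")
  n_design <- floor(fraction * n + 0.5)
  if (n_design < 1L) stop("design set would be empty")
  tr <- lapply(seq_len(trials), function(t) {
    des <- sort(sample.int(n, n_design))
    list(design = des, validation = setdiff(seq_len(n), des))
  })
  structure(list(trials = tr, n = n, fraction = fraction,
                 n_design = n_design),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("split_set: %d trials, %d/%d design/validation compounds\n",
              length(x$trials), x$n_design, x$n - x$n_design))
  invisible(x)
}

#' Paired sign (binomial) test on trial-wise RMSE
#'
#' Exact two-sided binomial test of whether method A beats method B more
#' often than chance across paired trials: wins are trials with
#' `rmse_a < rmse_b`, ties (and pairs with a missing value) are dropped, and
#' the remaining wins are referred to Binomial(m, 1/2).
#'
#' @param rmse_a,rmse_b paired per-trial RMSE vectors.
#' @return List with `p_value`, `wins`, `n_effective` and `all_ties` (TRUE
#'   when no pair was informative, in which case `p_value` is 1).
#' @export
sign_binomial_test <- function(rmse_a, rmse_b) {
  if (length(rmse_a) != length(rmse_b))
    stop("rmse vectors must be paired (equal length)")
  ok <- is.finite(rmse_a) & is.finite(rmse_b)
  a <- rmse_a[ok]; b <- rmse_b[ok]
  informative <- a != b
  m <- sum(informative)
  if (m == 0L)
    return(list(p_value = 1, wins = 0L, n_effective = 0L, all_ties = TRUE))
  wins <- sum(a < b)
  p <- stats::binom.test(wins, m, p = 0.5,
                         alternative = "two.sided")$p.value
  list(p_value = min(p, 1), wins = wins, n_effective = m, all_ties = FALSE)
}

# one selector dispatch used by run_benchmark; static methods select from
# scratch at every size, adaptive runs are nested along the schedule.
static_selector <- function(method, spaces, n_select, n_design) {
  switch(method,
    "random" = random_select(n_design, n_select)$indices,
    "kennard-stone" = kennard_stone(spaces$pc, n_select)$indices,
    "d-optimal" = d_optimal_fedorov(spaces$pc, n_select,
                                    restarts = spaces$fedorov_restarts)$indices,
    "space-filling" = space_filling(spaces$pc3, n_select)$indices,
    "mdc" = mdc(spaces$pc, n_select)$indices,
    stop("unknown static method: ", method))
}

#' Run the full selection benchmark
#'
#' The robustness protocol: for every split, every selection method is run
#' on the design partition at every requested sample size, a PLS model with
#' cross-validated component choice is fitted on the selected compounds
#' (all normalized descriptors), and the model is scored on the validation
#' partition. Static methods (`random`, `kennard-stone`, `d-optimal`,
#' `space-filling`, `mdc`) restart from scratch at each size; adaptive
#' methods (`descrep`, `pls-optimal`) run once per trial along the full size
#' schedule, so their selections are nested.
#'
#' Normalization is leakage-free: column ranges are fitted on the design
#' partition and applied (with clipping) to the validation compounds. When a
#' structural disruptor is supplied, its raw descriptor row is appended to
#' every design partition before normalization and selection — it can be
#' selected and then contributes its endpoint value to model training — but
#' never enters the validation partition.
#'
#' Per-trial seeds are derived from the global RNG stream at entry, so a
#' single `set.seed()` call makes the whole grid reproducible. Failures of a
#' single (trial, method) combination are recorded as missing and counted,
#' not fatal.
#'
#' @param table a [descriptor_table()] with raw (unnormalized) descriptors.
#' @param y endpoint vector for all compounds (the benchmark oracle).
#' @param splits a [make_splits()] result.
#' @param methods character vector of method tags (see above).
#' @param sizes increasing sample sizes; also the adaptive schedule.
#' @param disruptor optional list with `x_raw` (raw descriptor row) and `y`
#'   (its endpoint value), e.g. from [make_disruptor()] plus
#'   [endpoint_from_truth()].
#' @param n_pcs principal components for the static/seed search space.
#' @param k_descriptors DescRep descriptor-space size.
#' @param lamda DescRep coverage threshold.
#' @param kmeans_restarts,fedorov_restarts,max_exhaustive tuning knobs passed
#'   through to the selectors.
#' @param progress print a dot per trial?
#' @return A `benchmark_grid`: data frame with columns `trial`, `method`,
#'   `size`, `rmse`, `r`, `selected` (id string, `";"`-separated), plus
#'   attributes `with_disruptor` and `n_failed`.
#' @export
run_benchmark <- function(table, y, splits, methods, sizes,
                          disruptor = NULL, n_pcs = 5L, k_descriptors = 5L,
                          lamda = 0.75, kmeans_restarts = 15L,
                          fedorov_restarts = 10L, max_exhaustive = 20000,
                          progress = FALSE) {
  stopifnot(inherits(table, "descriptor_table"), inherits(splits, "split_set"))
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  if (length(y) != nrow(table$X)) stop("endpoint length mismatch")
  known <- c("random", "kennard-stone", "d-optimal", "space-filling", "mdc",
             "descrep", "pls-optimal")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  n_trials <- length(splits$trials)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  adaptive <- intersect(methods, c("descrep", "pls-optimal"))
  static <- setdiff(methods, adaptive)
  rows <- vector("list", n_trials * length(methods) * length(sizes))
  ri <- 0L
  n_failed <- 0L
  for (t in seq_len(n_trials)) {
    set.seed(trial_seeds[t])
    des <- splits$trials[[t]]$design
    val <- splits$trials[[t]]$validation
    X_raw <- table$X[des, , drop = FALSE]
    ids_d <- table$ids[des]
    y_d <- y[des]
    if (!is.null(disruptor)) {
      X_raw <- rbind(X_raw, disruptor$x_raw)
      ids_d <- c(ids_d, "synthetic_disruptor")
      y_d <- c(y_d, disruptor$y)
    }
    tab_d <- normalize_minmax(
      descriptor_table(X_raw, ids = ids_d,
                       descriptor_names = table$descriptor_names))
    Xn <- tab_d$X
    params <- norm_params(tab_d)
    X_val <- normalize_minmax(
      descriptor_table(table$X[val, , drop = FALSE], ids = table$ids[val],
                       descriptor_names = table$descriptor_names),
      params = params, clip = TRUE)$X
    y_val <- y[val]
    n_d <- nrow(Xn)
    spaces <- list(fedorov_restarts = fedorov_restarts)
    if (length(setdiff(static, "random")) || length(adaptive))
      spaces$pc <- pca_project(tab_d, min(n_pcs, min(dim(Xn))))
    if ("space-filling" %in% static)
      spaces$pc3 <- pca_project(tab_d, 3L)

    selections <- list()
    for (m in adaptive) {
      run <- tryCatch(suppressWarnings(
        if (m == "descrep")
          descrep_run(tab_d, oracle = function(i) y_d[i], schedule = sizes,
                      k_descriptors = k_descriptors, n_pcs = n_pcs,
                      lamda = lamda, restarts = kmeans_restarts,
                      max_exhaustive = max_exhaustive)
        else
          pls_optimal_run(tab_d, oracle = function(i) y_d[i],
                          schedule = sizes, n_pcs = n_pcs,
                          restarts = kmeans_restarts,
                          restarts_fedorov = fedorov_restarts)),
        error = function(e) NULL)
      selections[[m]] <- run
    }
    for (m in methods) {
      for (s in sizes) {
        ri <- ri + 1L
        idx <- tryCatch({
          if (m %in% adaptive) {
            if (is.null(selections[[m]])) stop("adaptive run failed")
            selections[[m]]$selected[seq_len(s)]
          } else {
            suppressWarnings(static_selector(m, spaces, s, n_d))
          }
        }, error = function(e) NULL)
        res <- if (is.null(idx)) NULL else tryCatch(suppressWarnings({
          model <- fit_pls_cv(Xn[idx, , drop = FALSE], y_d[idx])
          evaluate_model(model, X_val, y_val)
        }), error = function(e) NULL)
        if (is.null(res)) {
          n_failed <- n_failed + 1L
          rows[[ri]] <- data.frame(trial = t, method = m, size = s,
                                   rmse = NA_real_, r = NA_real_,
                                   selected = NA_character_)
        } else {
          rows[[ri]] <- data.frame(
            trial = t, method = m, size = s,
            rmse = res$rmse, r = res$r,
            selected = paste(ids_d[idx], collapse = ";"))
        }
      }
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  grid <- do.call(rbind, rows)
  attr(grid, "with_disruptor") <- !is.null(disruptor)
  attr(grid, "n_failed") <- n_failed
  class(grid) <- c("benchmark_grid", "data.frame")
  grid
}

#' Summarize a benchmark grid
#'
#' Per (method, size): mean and standard deviation of RMSE across trials,
#' mean correlation, number of informative trials, and selection variability
#' — the number of *distinct* compounds selected over all trials (a fixed
#' deterministic selection gives `variability == size`; random selection
#' approaches the design-set size).
#'
#' @param grid a `benchmark_grid`.
#' @return Data frame with one row per (method, size).
#' @export
summarize_benchmark <- function(grid) {
  key <- interaction(grid$method, grid$size, drop = TRUE)
  out <- do.call(rbind, lapply(split(grid, key), function(g) {
    ids <- unlist(strsplit(g$selected[!is.na(g$selected)], ";", fixed = TRUE))
    data.frame(method = g$method[1L], size = g$size[1L],
               mean_rmse = mean(g$rmse, na.rm = TRUE),
               sd_rmse = stats::sd(g$rmse, na.rm = TRUE),
               mean_r = mean(g$r, na.rm = TRUE),
               n_trials = sum(!is.na(g$rmse)),
               n_missing = sum(is.na(g$rmse)),
               variability = length(unique(ids)))
  }))
  out <- out[order(out$method, out$size), ]
  rownames(out) <- NULL
  out
}

#' RMSE difference between clean and disruptor-extended runs
#'
#' Pairs two grids run on the same splits — one without and one with the
#' structural disruptor appended to the design partitions — and reports, per
#' (method, size), `delta = mean_rmse(without) - mean_rmse(with)`. Positive
#' values mean the method produced *better* models when the disruptor was
#' present; the magnitude |delta| measures sensitivity to a single
#' structurally diverse compound.
#'
#' @param grid_without,grid_with paired `benchmark_grid`s (same methods,
#'   sizes and trial count).
#' @return Data frame with `method`, `size`, `delta`.
#' @export
delta_rmse <- function(grid_without, grid_with) {
  a <- summarize_benchmark(grid_without)
  b <- summarize_benchmark(grid_with)
  m <- merge(a[, c("method", "size", "mean_rmse")],
             b[, c("method", "size", "mean_rmse")],
             by = c("method", "size"), suffixes = c("_without", "_with"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b))
    stop("grids do not cover the same (method, size) combinations")
  m$delta <- m$mean_rmse_without - m$mean_rmse_with
  m[order(m$method, m$size), c("method", "size", "delta")]
}

#' Extract a paired per-trial RMSE vector
#'
#' Convenience accessor for [sign_binomial_test()]: the RMSE of one method
#' at one size, ordered by trial.
#'
#' @param grid a `benchmark_grid`.
#' @param method method tag.
#' @param size sample size.
#' @return Numeric vector (one entry per trial, `NA` for failed trials).
#' @export
grid_rmse <- function(grid, method, size) {
  g <- grid[grid$method == method & grid$size == size, ]
  g$rmse[order(g$trial)]
}
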