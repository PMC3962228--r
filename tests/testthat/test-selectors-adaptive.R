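test_that("descriptor scores are absolute endpoint correlations", {
  set.seed(101)
  X <- cbind(lin = 0:4, noise = rnorm(5), const = rep(2, 5))
  y <- c(0, 2, 4, 6, 8)
  sc <- score_descriptors(X, y, X)
  expect_equal(sc$S[["lin"]], 1)             # identical to y up to scale
  expect_equal(sc$S[["const"]], 0)           # degenerate convention
  expect_equal(unname(which.max(sc$S)), 1L)  # linear column ranks first
  expect_equal(sc$S[["noise"]], abs(cor(X[, 2], y)))
  expect_true(all(diag(sc$M) == 1))
  expect_true(all(sc$M >= 0 & sc$M <= 1))
  expect_error(score_descriptors(X[1:2, ], y[1:2], X), "3")
})

test_that("cubic down-weighting suppresses correlated descriptors exactly", {
  # two perfectly correlated top descriptors: the runner-up is annihilated
  M <- diag(3); M[1, 2] <- M[2, 1] <- 1
  sc <- structure(list(S = c(0.9, 0.85, 0.3), M = M),
                  class = "descriptor_scores")
  picks <- select_descriptors(sc, 2)
  expect_equal(as.integer(picks), c(1L, 3L))
  trace <- attr(picks, "trace")
  expect_equal(trace[[2]][2], 0)             # 0.85 * (1 - 1)^3
  expect_equal(trace[[2]][3], 0.3)           # M = 0 leaves score untouched

  # printed-formula spot check: 0.6 * (1 - 0.5)^3 = 0.075
  M2 <- diag(2); M2[1, 2] <- M2[2, 1] <- 0.5
  sc2 <- structure(list(S = c(0.9, 0.6), M = M2),
                   class = "descriptor_scores")
  p2 <- select_descriptors(sc2, 2)
  expect_equal(attr(p2, "trace")[[2]][2], 0.6 * (1 - 0.5)^3)
  expect_equal(attr(p2, "trace")[[2]][2], 0.075)
})

test_that("exhausted descriptor scores fill remaining slots with a warning", {
  M <- diag(3); M[1, 2] <- M[2, 1] <- 1; M[1, 3] <- M[3, 1] <- 1
  sc <- structure(list(S = c(0.9, 0.5, 0.4), M = M),
                  class = "descriptor_scores")
  expect_warning(picks <- select_descriptors(sc, 3), "exhausted")
  expect_equal(as.integer(picks), c(1L, 2L, 3L))
})

test_that("k-means seed returns one medoid per well-separated cluster", {
  set.seed(111)
  pts <- rbind(matrix(rnorm(4, sd = .01), 2, 2),
               matrix(rnorm(4, mean = 10, sd = .01), 2, 2))
  sp <- chem_space(pts)
  seed <- initial_seed(sp, 2)
  expect_length(seed, 2L)
  expect_true(any(seed %in% 1:2) && any(seed %in% 3:4))

  expect_equal(initial_seed(sp, 1), central_index(sp))
})

test_that("k-means seed matches exhaustive partition scoring on three triads", {
  set.seed(112)
  centers <- rbind(c(0, 0), c(10, 0), c(5, 9))
  pts <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(6, sd = 0.1), 3, 2), 2, centers[g, ], "+")))
  sp <- chem_space(pts)
  seed <- initial_seed(sp, 3)

  # brute force: all 3^9 labelings, keep 3-cluster ones, minimize within-
  # cluster pairwise distance sums, then take medoids
  DM <- sp$DM
  best_cost <- Inf; best_lab <- NULL
  for (code in 0:(3^9 - 1)) {
    lab <- (code %/% 3^(0:8)) %% 3 + 1
    if (length(unique(lab)) < 3) next
    cost <- sum(vapply(1:3, function(g) {
      m <- which(lab == g); sum(DM[m, m]) / 2
    }, numeric(1)))
    if (cost < best_cost) { best_cost <- cost; best_lab <- lab }
  }
  medoids <- sort(vapply(1:3, function(g) {
    m <- which(best_lab == g)
    m[which.min(rowSums(DM[m, m, drop = FALSE]))]
  }, integer(1)))
  expect_equal(seed, medoids)
})

test_that("the adaptive exponent solves the coverage equation", {
  # d_k = 0.5, lamda = 0.75: exp = ln .75 / ln .5
  DM <- matrix(c(0, .5, 1, .5, 0, .5, 1, .5, 0), 3)
  ex <- compute_exponent(DM, central = 2, n_cover = 1, lamda = 0.75)
  expect_equal(ex, log(0.75) / log(0.5))
  expect_equal(ex, 0.415, tolerance = 1e-3)
  expect_equal((1 - 0.5)^ex, 0.75)

  # fixed point: 1 - d_k = lamda gives exp = 1
  DM2 <- matrix(c(0, .25, .25, 0), 2)
  expect_equal(compute_exponent(DM2, 1, 1, lamda = 0.75), 1)

  # near-duplicate neighbourhood: exponent blows up (sharp kernel)
  DM3 <- matrix(c(0, 1e-12, 1, 1e-12, 0, 1, 1, 1, 0), 3)
  expect_gt(compute_exponent(DM3, 1, 1, lamda = 0.75), 1e7)
})

test_that("priority scores follow the correction-factor product", {
  DM <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(priority_scores(DM, selected = 1, exp = 2)[2],
               1 - (1 - 0.5)^2)               # CF = 0.75
  expect_equal(priority_scores(DM, selected = 1, exp = 2)[1], 0)  # covered

  DM_far <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(priority_scores(DM_far, 1, exp = 3)[2], 1)  # uncovered
})

test_that("priority scores are monotone under selection growth", {
  set.seed(121)
  for (rep in 1:20) {
    DM <- distance_matrix(random_cloud(15, 3))
    ex <- runif(1, 0.3, 3)
    s1 <- sample(15, 3)
    s2 <- c(s1, sample(setdiff(1:15, s1), 2))
    expect_true(all(priority_scores(DM, s2, ex) <=
                    priority_scores(DM, s1, ex) + 1e-12))
  }
})

test_that("batch selection minimizes total priority score", {
  # uncovered remote cluster wins a batch of one
  pts <- rbind(matrix(rnorm(8, sd = .1), 4, 2),
               matrix(rnorm(8, mean = 8, sd = .1), 4, 2))
  DM <- distance_matrix(pts)
  b <- select_batch(DM, selected = 1:2, batch = 1, exp = 1)
  expect_true(b %in% 5:8)

  set.seed(131)
  for (rep in 1:50) {
    DM <- distance_matrix(random_cloud(10, 2))
    ex <- runif(1, 0.3, 2)
    sel <- sample(10, 2)
    b <- select_batch(DM, sel, 2, ex)
    expect_equal(sort(as.integer(b)), oracle_best_batch(DM, sel, 2, ex))
    # adding a batch can only decrease the total priority score
    expect_lte(sum(priority_scores(DM, c(sel, b), ex)),
               sum(priority_scores(DM, sel, ex)) + 1e-12)
  }
})

test_that("greedy batch mode engages beyond the exhaustive cap", {
  set.seed(132)
  DM <- distance_matrix(random_cloud(30, 3))
  b <- select_batch(DM, 1:3, 5, exp = 1, max_exhaustive = 10)
  expect_equal(attr(b, "mode"), "greedy")
  expect_length(b, 5L)
  bx <- select_batch(DM, 1:3, 2, exp = 1)
  expect_equal(attr(bx, "mode"), "exhaustive")
})

test_that("DescRep runs are deterministic, nested, and seed-equivalent", {
  g <- small_synthetic(seed = 7)
  tab <- normalize_minmax(g$table)
  oracle <- function(i) g$y[i]
  sched <- c(5, 8, 12)

  set.seed(201)
  r1 <- suppressWarnings(descrep_run(tab, oracle, sched))
  set.seed(201)
  r2 <- suppressWarnings(descrep_run(tab, oracle, sched))
  expect_identical(r1$selected, r2$selected)

  # nestedness: cycle batches tile the selected vector along the schedule
  expect_equal(length(r1$selected), 12L)
  expect_false(anyDuplicated(r1$selected) > 0)
  sizes <- vapply(r1$cycles, `[[`, numeric(1), "size")
  expect_equal(sizes, sched)
  acc <- integer(0)
  for (cy in r1$cycles) {
    acc <- c(acc, cy$batch)
    expect_equal(acc, r1$selected[seq_along(acc)])
  }

  # schedule of just the seed size equals the k-means seed itself
  set.seed(202)
  r0 <- descrep_run(tab, oracle, 5)
  set.seed(202)
  sp <- pca_project(tab, 5)
  expect_equal(r0$selected, initial_seed(sp, 5))
})

test_that("DescRep cycles are equivariant under compound reordering", {
  g <- small_synthetic(n = 40, seed = 9)
  tab <- normalize_minmax(g$table)
  X <- tab$X
  sel <- c(3L, 11L, 25L, 32L, 40L)
  sc <- score_descriptors(X[sel, ], g$y[sel], X)
  desc <- as.integer(select_descriptors(sc, 5))
  DM <- distance_matrix(X[, desc])
  ex <- compute_exponent(DM, central_index(DM), n_cover = 7)
  batch <- as.integer(select_batch(DM, sel, 2, ex))

  set.seed(301)
  perm <- sample(40)
  Xp <- X[perm, ]
  selp <- match(sel, perm)
  scp <- score_descriptors(Xp[selp, ], g$y[sel], Xp)
  expect_equal(as.integer(select_descriptors(scp, 5)), desc)
  DMp <- distance_matrix(Xp[, desc])
  exp_p <- compute_exponent(DMp, central_index(DMp), n_cover = 7)
  expect_equal(exp_p, ex)
  batch_p <- as.integer(select_batch(DMp, selp, 2, exp_p))
  expect_equal(sort(perm[batch_p]), sort(batch))  # same compound identities
})

test_that("PLS-Optimal extension honours fixed points and the determinant", {
  g <- small_synthetic(n = 50, seed = 13)
  tab <- normalize_minmax(g$table)
  sel <- c(2L, 9L, 17L, 30L, 44L, 48L)
  y_m <- g$y[sel]

  expect_equal(pls_optimal_extend(tab, y_m, sel, batch = 0), sel)

  set.seed(401)
  ext <- suppressWarnings(pls_optimal_extend(tab, y_m, sel, batch = 4,
                                             n_latent = 3))
  expect_equal(ext[1:6], sel)
  expect_length(ext, 10L)

  # the extension's information determinant beats 50 random extensions in
  # the same latent space
  fit <- suppressWarnings(mixOmics::pls(tab$X[sel, ], y_m, ncomp = 3,
                                        mode = "regression", scale = FALSE))
  lv <- suppressWarnings(predict(fit, tab$X)$variates)
  Fm <- cbind(1, as.matrix(lv))
  det_of <- function(idx) det(crossprod(Fm[idx, ]))
  set.seed(402)
  rand <- replicate(50, det_of(c(sel, sample(setdiff(1:50, sel), 4))))
  expect_gte(det_of(ext), max(rand))
})

test_that("a single-descriptor endpoint concentrates the first latent variable", {
  set.seed(411)
  X <- matrix(runif(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("d", 1:6)))
  y <- 3 * X[, 4]
  fit <- suppressWarnings(mixOmics::pls(X, y, ncomp = 1,
                                        mode = "regression", scale = FALSE))
  w <- abs(fit$loadings$X[, 1])
  expect_equal(which.max(w), 4L, ignore_attr = TRUE)
})
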