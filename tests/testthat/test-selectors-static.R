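test_that("Kennard-Stone starts central and follows the maximin rule", {
  sp <- chem_space(cbind(c(0, 0.5, 1)))
  ks <- kennard_stone(sp, 2)
  expect_equal(ks$indices[1], 2L)          # central point
  expect_true(ks$indices[2] %in% c(1L, 3L))

  set.seed(41)
  for (rep in 1:50) {
    sp <- chem_space(random_cloud(12, 3))
    ks <- kennard_stone(sp, 4)
    for (s in 2:4)
      expect_equal(ks$indices[s],
                   oracle_ks_step(sp$DM, ks$indices[seq_len(s - 1)]))
  }
})

test_that("Kennard-Stone has the prefix property and exhausts at n_select = n", {
  set.seed(42)
  sp <- chem_space(random_cloud(15, 2))
  long <- kennard_stone(sp, 10)$indices
  for (k in c(3, 6, 9))
    expect_equal(kennard_stone(sp, k)$indices, long[seq_len(k)])
  expect_setequal(kennard_stone(sp, 15)$indices, 1:15)
  expect_error(kennard_stone(sp, 16))
})

test_that("D-optimal selection maximizes the information determinant", {
  # d = 1 with intercept: the extreme pair {0, 1} wins over any pair with 0.2
  sp <- chem_space(cbind(c(0, 0.2, 1)))
  set.seed(50)
  res <- d_optimal_fedorov(sp, 2)
  expect_setequal(res$indices, c(1L, 3L))
  expect_equal(res$meta$det, oracle_dopt_best(sp$points, 2)$det)

  # exhaustive-oracle equivalence on 50 tiny instances
  set.seed(51)
  for (rep in 1:50) {
    pts <- cbind(runif(5))
    sp <- chem_space(pts)
    res <- d_optimal_fedorov(sp, 2, restarts = 10)
    expect_equal(res$meta$det, oracle_dopt_best(pts, 2)$det,
                 tolerance = 1e-9)
  }
})

test_that("Fedorov trajectories never decrease and fixed points are kept", {
  set.seed(52)
  for (rep in 1:10) {
    sp <- chem_space(random_cloud(30, 4))
    res <- d_optimal_fedorov(sp, 8, fixed = c(1L, 2L), restarts = 3)
    expect_true(all(diff(res$meta$trajectory) >= 0))
    expect_true(all(c(1L, 2L) %in% res$indices))
  }
  # fully fixed selection is returned unchanged, with its determinant
  sp <- chem_space(random_cloud(10, 2))
  res <- d_optimal_fedorov(sp, 3, fixed = c(2L, 5L, 9L))
  expect_equal(sort(res$indices), c(2L, 5L, 9L))
  Fm <- cbind(1, sp$points[c(2, 5, 9), ])
  expect_equal(res$meta$det, det(crossprod(Fm)))
})

test_that("converged D-optimal beats random same-size subsets", {
  set.seed(53)
  sp <- chem_space(random_cloud(40, 3))
  res <- d_optimal_fedorov(sp, 8, restarts = 5)
  Fm <- cbind(1, sp$points)
  rand_dets <- replicate(50, det(crossprod(Fm[sample(40, 8), ])))
  expect_gte(res$meta$det, max(rand_dets))
})

test_that("space filling covers a unit cube corner per octant", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  sf <- space_filling(chem_space(cube), 8)
  expect_equal(sf$meta$b, 2L)
  expect_setequal(sf$indices, 1:8)
  one <- space_filling(chem_space(cbind(0, 0, 0)), 1)
  expect_equal(one$indices, 1L)
  expect_equal(one$meta$b, 1L)
})

test_that("space-filling representatives are closest to their cell centers", {
  set.seed(61)
  P <- random_cloud(100, 3)
  sf <- space_filling(chem_space(P), 10)
  b <- sf$meta$b
  lo <- apply(P, 2, min); hi <- apply(P, 2, max); w <- (hi - lo) / b
  bin_of <- function(x) pmin(b, floor((x - lo) / w) + 1L)
  for (i in sf$indices) {
    cell <- bin_of(P[i, ])
    members <- which(apply(P, 1, function(p) all(bin_of(p) == cell)))
    ctr <- lo + (cell - 0.5) * w
    d2 <- apply(P[members, , drop = FALSE], 1,
                function(p) sum((p - ctr)^2))
    expect_equal(sum((P[i, ] - ctr)^2), min(d2), tolerance = 1e-12)
  }
})

test_that("MDC prefers dense regions and matches from-scratch recomputation", {
  # exactly tied distances: rank ties resolve by lowest index, so the first
  # pick is compound 1 (a float equilateral is never exactly tied)
  tie_space <- structure(list(points = diag(3),
                              DM = matrix(1, 3, 3) - diag(3),
                              source = "selected_descriptors"),
                         class = "chem_space")
  expect_equal(mdc(tie_space, 1)$indices, 1L)

  # dense cluster plus remote singleton: never the singleton first
  pts <- rbind(matrix(rnorm(12, sd = .05), 6, 2), c(50, 50))
  expect_true(mdc(chem_space(pts), 1)$indices %in% 1:6)

  set.seed(71)
  for (rep in 1:50) {
    sp <- chem_space(random_cloud(8, 2))
    expect_equal(mdc(sp, 3)$indices, oracle_mdc_sequence(sp$DM, 3))
  }
})

test_that("random selection is uniform, seeded, and exhaustive at n", {
  set.seed(81)
  a <- random_select(20, 6)$indices
  set.seed(81)
  b <- random_select(20, 6)$indices
  expect_identical(a, b)
  expect_setequal(random_select(5, 5)$indices, 1:5)

  set.seed(82)
  draws <- replicate(1e4, paste(sort(random_select(4, 2)$indices),
                                collapse = "-"))
  counts <- table(draws)
  expect_equal(length(counts), 6L)
  expected <- 1e4 / 6
  sigma <- sqrt(1e4 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("all selectors return unique in-range indices of requested size", {
  set.seed(91)
  sp <- chem_space(random_cloud(25, 3))
  for (res in list(kennard_stone(sp, 7), d_optimal_fedorov(sp, 7),
                   space_filling(sp, 7), mdc(sp, 7), random_select(25, 7))) {
    expect_equal(res$size, 7L)
    expect_false(anyDuplicated(res$indices) > 0)
    expect_true(all(res$indices >= 1 & res$indices <= 25))
  }
})
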