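test_that("grid nodes, spacing and linear indexing are consistent", {
  g <- grid_spec(c(0, 1), 3, c(10, 12), 5)
  G <- grid_points(g)
  expect_equal(nrow(G), 15)
  expect_equal(grid_spacing(g), c(0.5, 0.5))
  # linear index m = p + (q-1)P
  expect_equal(G[1, ], c(0, 10))
  expect_equal(G[3 + 2 * 3, ], c(1, 11))   # p=3, q=3
  expect_equal(G[15, ], c(1, 12))
  expect_error(grid_spec(c(1, 0), 5), "min < max")
  expect_error(grid_spec(c(0, 1), 1), ">= 2")
})

test_that("exact user surface peaks at the node nearest the user", {
  g <- grid_2d_small()
  co <- grid_coords(g)
  d_on <- c(co$x[10], co$y[17])
  s <- user_surface_exact(d_on, g, h = 0.8)
  expect_equal(max(s$values), 1)
  expect_equal(which.max(s$values), 10 + (17 - 1) * 25)
  # 1D localization: d = 0, 1000 nodes on [-15, 15], h = 2
  g1 <- grid_1d_attack()
  s1 <- user_surface_exact(0, g1, h = 2)
  xhat <- grid_coords(g1)$x[which.max(s1$values)]
  expect_lt(abs(xhat), grid_spacing(g1))
})

test_that("exact surface mass approximates the unnormalized Gaussian integral", {
  # Riemann sum x cell area -> 2*pi*h^2 when the kernel fits in the extent
  g <- grid_spec(c(-8, 8), 161, c(-8, 8), 161)
  h <- 0.7
  s <- user_surface_exact(c(0.3, -0.4), g, h)
  mass <- sum(s$values) * prod(grid_spacing(g))
  expect_lt(abs(mass - 2 * pi * h^2) / (2 * pi * h^2), 0.01)
})

test_that("rff user surface sums B cosines and is B at the user's node", {
  g <- grid_2d_small()
  co <- grid_coords(g)
  d <- c(co$x[5], co$y[5])
  for (B in c(1L, 4L)) {
    b <- sample_frequencies(B, 0.6, 2, seed = 21)
    s <- user_surface_rff(d, b, 0.6, g)
    expect_true(all(s$values >= -B - 1e-12 & s$values <= B + 1e-12))
    expect_equal(s$values[5, 5], B)
    expect_equal(s$meta$n_ops, 25 * 25 * B)
  }
})

test_that("rff surface converges entrywise to the exact surface as B grows", {
  g <- grid_2d_small()
  d <- c(0.3, -0.7)
  ex <- user_surface_exact(d, g, 0.8)
  devs <- vapply(c(200L, 5000L), function(B) {
    b <- sample_frequencies(B, 0.8, 2, seed = 4)
    max(abs(user_surface_rff(d, b, 0.8, g)$values / B - ex$values))
  }, numeric(1))
  expect_lt(devs[2], devs[1])
  expect_lt(devs[2], 0.05)
})

test_that("translation moves an rff response rigidly", {
  # same basis, user at d and d + t, grids offset by t: identical surfaces
  b <- sample_frequencies(3, 0.5, 2, seed = 6)
  g <- grid_2d_small()
  t <- c(1.25, -0.5)
  gt <- grid_spec(g$x_range + t[1], g$p, g$y_range + t[2], g$q)
  d <- c(0.2, 0.4)
  s0 <- user_surface_rff(d, b, 0.5, g)
  s1 <- user_surface_rff(d + t, b, 0.5, gt)
  expect_equal(s1$values, s0$values, tolerance = 1e-12)
})

test_that("aggregation is the entrywise mean (exact) or sum/(NB) (rff) and is linear", {
  g <- grid_spec(c(0, 1), 4, c(0, 1), 4)
  set.seed(31)
  surfs <- lapply(1:6, function(i) surface(matrix(rnorm(16), 4), g))
  agg <- aggregate_surfaces(surfs, "exact")
  expect_equal(agg$values, Reduce(`+`, lapply(surfs, `[[`, "values")) / 6)
  # N identical surfaces -> unchanged
  same <- aggregate_surfaces(surfs[c(1, 1, 1)], "exact")
  expect_equal(same$values, surfs[[1]]$values)
  # linearity oracle: aggregate(A u B) = weighted mean of sub-aggregates
  aggA <- aggregate_surfaces(surfs[1:2], "exact")
  aggB <- aggregate_surfaces(surfs[3:6], "exact")
  expect_equal(agg$values, (2 * aggA$values + 4 * aggB$values) / 6)
  # rff normalization: N=1, B=1 surface of ones stays ones
  ones <- surface(matrix(1, 4, 4), g)
  expect_equal(aggregate_surfaces(list(ones), "rff", B = 1)$values,
               ones$values)
  expect_error(aggregate_surfaces(list(), "exact"), "no surfaces")
  g2 <- grid_spec(c(0, 2), 4, c(0, 1), 4)
  expect_error(
    aggregate_surfaces(list(surfs[[1]], surface(matrix(1, 4, 4), g2)),
                       "exact"), "different grids")
})

test_that("pooled fast paths equal per-user aggregation", {
  g <- grid_2d_small()
  X <- sample_mixture(builtin_mixture("grid9"), 8, seed = 9)
  h <- 0.6
  per_user <- aggregate_surfaces(
    lapply(seq_len(nrow(X)), function(i) user_surface_exact(X[i, ], g, h)),
    "exact")
  expect_equal(federated_kde(X, g, h, chunk = 3)$values, per_user$values)
  B <- 3L
  W <- rffkde:::user_frequencies(nrow(X), B, h, 2, seed = 42)
  rff_users <- lapply(seq_len(nrow(X)), function(i)
    user_surface_rff(X[i, ], rffkde:::basis_for_user(W, i, B, h, 42), h, g))
  agg <- aggregate_surfaces(rff_users, "rff", B = B)
  fast <- federated_rff_kde(X, g, h, B = B, seed = 42, chunk = 5)
  expect_equal(fast$values, agg$values)
})

test_that("repeated queries to an unmoved user are bit-identical", {
  g <- grid_2d_small()
  b <- sample_frequencies(2, 0.5, 2, seed = 15)
  d <- c(-0.3, 0.9)
  expect_identical(user_surface_rff(d, b, 2.5, g)$values,
                   user_surface_rff(d, b, 2.5, g)$values)
  expect_identical(federated_rff_kde(matrix(d, 1), g, 0.5, 1, seed = 3)$values,
                   federated_rff_kde(matrix(d, 1), g, 0.5, 1, seed = 3)$values)
})

test_that("maximum bandwidth scales with area side and inverse band count", {
  expect_equal(max_bandwidth(0.5, 2, 20), 2 * max_bandwidth(0.5, 2, 10))
  expect_equal(max_bandwidth(0.5, 4, 10), max_bandwidth(0.5, 2, 10) / 2)
  expect_equal(max_bandwidth(0.25, 2, 10), sqrt(0.25) * 10 / (4 * pi))
  expect_gt(max_bandwidth(0.9, 2, 10), max_bandwidth(0.1, 2, 10))
  expect_error(max_bandwidth(0.5, 1, 10), "j")
  expect_error(max_bandwidth(-1, 2, 10), "gamma")
})

test_that("band-count coverage at h_max satisfies the chi-squared guarantee", {
  gamma <- 0.5; j <- 2L; l <- 10
  h <- max_bandwidth(gamma, j, l)
  set.seed(17)
  cnt <- replicate(4000, count_bands(rnorm(2, sd = 1 / h),
                                     runif(2, 0, l), l))
  expect_gte(mean(cnt >= j), 1 - pchisq(gamma, df = 2))
})

test_that("query validation enforces h_max, the (4n+1) set and B_max", {
  pol <- bandwidth_policy(h0 = 0.1, gamma = 1, j = 2, l = 40, B_max = 8)
  expect_true(validate_query(pol, 0.5, 1)$accepted)      # h = 5 h0
  expect_true(validate_query(pol, 0.1, 8)$accepted)      # n = 0 allowed
  expect_true(validate_query(pol, 0.9, 2)$accepted)      # n = 2
  d <- validate_query(pol, 0.25, 1)                      # 2.5 h0: not 4n+1
  expect_false(d$accepted)
  expect_equal(d$reason, "bandwidth_not_in_policy_set")
  d <- validate_query(pol, 4.1, 1)                       # in set, too large
  expect_false(d$accepted)
  expect_equal(d$reason, "bandwidth_exceeds_maximum")
  d <- validate_query(pol, 0.5, 9)
  expect_false(d$accepted)
  expect_equal(d$reason, "feature_count_exceeds_maximum")
  # decimal round-trip tolerance
  h_rt <- as.numeric(format(13 * 0.1, digits = 15))
  expect_true(validate_query(bandwidth_policy(0.1, 1, 2, 200, 8),
                             h_rt, 1)$accepted)
})

test_that("user response cost is linear in grid size and feature count", {
  g <- grid_spec(c(0, 1), 30, c(0, 1), 40)
  expect_equal(response_cost(g, 1), 1200)
  expect_equal(response_cost(g, 8), 8 * response_cost(g, 1))
  g2 <- grid_spec(c(0, 1), 60, c(0, 1), 40)
  expect_equal(response_cost(g2, 3), 2 * response_cost(g, 3))
  # the per-user surface reports the same count
  b <- sample_frequencies(5, 1, 2, seed = 1)
  s <- user_surface_rff(c(0.5, 0.5), b, 1, g)
  expect_equal(s$meta$n_ops, response_cost(g, 5))
})

test_that("users and features trade off interchangeably at fixed N*B", {
  mx <- builtin_mixture("grid9")
  g <- study_grid_a()
  truth <- mixture_density(mx, g)
  err <- function(n, b, s) {
    X <- sample_mixture(mx, n, seed = s)
    est <- federated_rff_kde(X, g, 0.55, B = b, seed = s)
    sqrt(mean((est$values / (2 * pi * 0.55^2) - truth$values)^2))
  }
  e_nb <- median(vapply(1:3, function(s) err(5000, 2, s), 1))
  e_n <- median(vapply(1:3, function(s) err(10000, 1, s), 1))
  expect_lt(e_nb, 2 * e_n)
  expect_lt(e_n, 2 * e_nb)
})
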