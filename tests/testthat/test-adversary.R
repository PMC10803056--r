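test_that("local maxima detection matches brute force and handles plateaus", {
  # unimodal exact surface: exactly one maximum, at the node nearest d
  g <- grid_2d_small()
  d <- c(0.31, -0.87)
  s <- user_surface_exact(d, g, 0.7)
  m <- find_local_maxima(s)
  expect_equal(nrow(m), 1)
  G <- grid_points(g)
  expect_equal(m$index, which.min(rowSums(sweep(G, 2, d)^2)))
  # constant surface: one representative (plateau rule), lowest index
  cst <- surface(matrix(2, g$p, g$q), g)
  mc <- find_local_maxima(cst)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$index, 1)
  # 1D cos(2*pi*x) on [0, 3], 301 nodes: maxima at x = 0, 1, 2, 3
  g1 <- grid_spec(c(0, 3), 301)
  v <- cos(2 * pi * grid_coords(g1)$x)
  s1 <- surface(v, g1)
  m1 <- find_local_maxima(s1)
  expect_equal(m1$x, c(0, 1, 2, 3))
  expect_equal(m1$index, brute_maxima_1d(v))
  # random surfaces agree with the 1D brute-force oracle
  set.seed(23)
  for (rep in 1:10) {
    v <- rnorm(40)
    expect_equal(find_local_maxima(surface(v, grid_spec(c(0, 1), 40)))$index,
                 brute_maxima_1d(v))
  }
})

test_that("per-user privacy score filters, weights and averages distances", {
  # single maximum exactly at d_true -> Z = 0
  g <- grid_spec(c(0, 1), 11, c(0, 1), 11)
  d <- c(0.5, 0.5)
  r <- privacy_score_user(user_surface_exact(d, g, 0.3), d)
  expect_equal(r$Z, 0)
  expect_false(r$fallback)
  # two equal maxima at distances 1 and 3 -> Z = 2
  g1 <- grid_spec(c(-4, 4), 81)
  x <- grid_coords(g1)$x
  v <- exp(-(x + 1)^2) + exp(-(x - 3)^2)
  r2 <- privacy_score_user(surface(v, g1), 0)
  expect_equal(sum(r2$maxima$kept), 2)
  expect_equal(r2$Z, 2, tolerance = 1e-6)
  # the epsilon filter drops weak maxima from the weighting
  v3 <- exp(-(x + 1)^2) + 0.5 * exp(-(x - 3)^2)
  r3 <- privacy_score_user(surface(v3, g1), 0, epsilon_filter = 1.1)
  expect_equal(sum(r3$maxima$kept), 1)
  expect_equal(r3$Z, 1, tolerance = 1e-6)
  # kept weights sum to one
  expect_equal(sum(r2$maxima$weight[r2$maxima$kept]), 1)
  # literal variant divides by the kept count
  r2l <- privacy_score_user(surface(v, g1), 0, literal = TRUE)
  expect_equal(r2l$Z, r2$Z / 2, tolerance = 1e-6)
  # all-nonpositive surface falls back to the unweighted mean, flagged
  vneg <- -1 - (x - 1)^2 / 10
  rf <- privacy_score_user(surface(vneg, g1), 0)
  expect_true(rf$fallback)
  expect_equal(rf$Z, 1, tolerance = 1e-6)
  expect_error(privacy_score_user(surface(v, g1), 0, epsilon_filter = 0.5),
               ">= 1")
})

test_that("exact-KDE attack localizes an on-grid user to within one spacing", {
  g <- study_grid_a()
  co <- grid_coords(g)
  d <- c(co$x[12], co$y[30])
  r <- privacy_score_user(user_surface_exact(d, g, 0.55), d)
  expect_lte(r$Z, grid_spacing(g)[1])
})

test_that("system score is the mean and is permutation invariant", {
  expect_equal(privacy_score_system(c(0, 2)), 1)
  expect_equal(privacy_score_system(rep(3.5, 7)), 3.5)
  set.seed(4)
  z <- runif(20)
  expect_equal(privacy_score_system(z), privacy_score_system(sample(z)))
  expect_error(privacy_score_system(numeric(0)), "no scores")
  expect_error(privacy_score_system(list()), "no reports")
})

test_that("zero-feature score is the mean node distance", {
  g1 <- grid_spec(c(-1, 1), 2)
  expect_equal(zero_feature_score(g1, 0), 1)
  # direct-sum oracle at grid center, 2D
  g <- grid_spec(c(-2, 2), 9, c(-2, 2), 9)
  G <- grid_points(g)
  d <- c(0, 0)
  expect_equal(zero_feature_score(g, d),
               sum(sqrt(rowSums(sweep(G, 2, d)^2))) / nrow(G))
  # moving to a corner strictly increases the score
  expect_gt(zero_feature_score(g, c(2, 2)), zero_feature_score(g, c(0, 0)))
})

test_that("equivalence-class members are indistinguishable at every query point", {
  bbox <- grid_spec(c(-5, 5), 12, c(-5, 5), 12)
  set.seed(29)
  for (rep in 1:25) {
    om <- rnorm(2, sd = 2)
    x <- runif(2, -4, 4)
    ec <- equivalence_class_points(om, x, bbox)
    expect_true(any(ec$alpha == 0))      # x's own line is in D(x)
    G <- grid_points(bbox)
    base <- cos(as.numeric(G %*% om) - sum(om * x))
    for (i in seq_len(nrow(ec$points))) {
      resp <- cos(as.numeric(G %*% om) - sum(om * ec$points[i, ]))
      expect_lt(max(abs(resp - base)), 1e-9)
    }
    # consecutive lines separated by 2*pi/||omega|| along omega-hat
    expect_equal(ec$spacing, 2 * pi / sqrt(sum(om^2)))
  }
  # 1D: omega = 2*pi, x = 0.3 -> integer lattice offsets
  ec1 <- equivalence_class_points(2 * pi, 0.3, grid_spec(c(-3, 3), 10))
  expect_equal(sort(ec1$points[, 1]), seq(-2.7, 2.3, by = 1))
  expect_error(equivalence_class_points(c(0, 0), c(0, 0), bbox), "nonzero")
})

test_that("the grid argmax always lies on the delocalized maxima structure", {
  # the response maximum can only sit on (near) the
  # equivalence-class geometry; the node nearest the user attains the global
  # peak value up to discretization
  g <- grid_2d_small()
  diag_cell <- sqrt(sum(grid_spacing(g)^2))
  set.seed(37)
  for (B in 1:3) {
    for (rep in 1:5) {
      d <- runif(2, -2, 2)
      b <- sample_frequencies(B, 0.5, 2, seed = 100 * B + rep)
      s <- user_surface_rff(d, b, 0.5, g)
      imax <- which.max(s$values)
      gmax <- grid_points(g)[imax, ]
      # value near d is within discretization slack of the peak value B
      inear <- which.min(rowSums(sweep(grid_points(g), 2, d)^2))
      wnorm <- max(sqrt(rowSums(b$omegas^2)))
      slack <- B * wnorm^2 * diag_cell^2 / 2    # cos curvature bound
      expect_gte(s$values[inear], B - slack)
      expect_gte(s$values[imax], s$values[inear])
      if (B == 1) {
        # argmax within a cell of one of the D(d) band lines
        om <- b$omegas[1, ]
        frac <- (sum(om * (gmax - d)) / (2 * pi)) %% 1
        dist_to_line <- min(frac, 1 - frac) * 2 * pi / sqrt(sum(om^2))
        expect_lte(dist_to_line, diag_cell)
      }
    }
  }
})

test_that("policy-compliant rescaling keeps multiple invariant bands; arbitrary rescaling does not", {
  g1 <- grid_spec(c(-40, 40), 8000)
  set.seed(41)
  h0 <- 0.5
  w0 <- rnorm(1, sd = 1 / h0)
  d <- 0.3
  # compliant pair (h0, 5h0): every rescaled maximum sits on a base band,
  # one overlap every 5 bands, at least floor(m/5) invariant bands
  bo <- band_overlap(w0, h0, 5 * h0, d = d, grid = g1, tol_frac = 0.05)
  m <- length(bo$base_maxima)
  expect_equal(bo$matched_fraction, 1)
  expect_equal(bo$period, 5)
  expect_gte(length(bo$rescaled_maxima), floor(m / 5))
  # incommensurate bandwidth: only the user's own band survives comparison
  bo_bad <- band_overlap(w0, h0, exp(1) * h0, d = d, grid = g1,
                         tol_frac = 0.05)
  n_matched <- round(bo_bad$matched_fraction * length(bo_bad$rescaled_maxima))
  expect_equal(n_matched, 1)
})

test_that("released information orders the privacy scores", {
  # more features -> tighter localization; exact KDE is the no-privacy floor
  # and the constant response the ceiling
  g <- study_grid_a()
  X <- sample_mixture(builtin_mixture("grid9"), 150, seed = 3)
  h <- 0.55
  z_ex <- median(privacy_scores(X, g, "exact", h = h)$Z)
  z_b8 <- median(privacy_scores(X, g, "rff", h = h, B = 8, seed = 3)$Z)
  z_b1 <- median(privacy_scores(X, g, "rff", h = h, B = 1, seed = 3)$Z)
  z_00 <- median(privacy_scores(X, g, "zero")$Z)
  expect_lt(z_ex, z_b8)
  expect_lt(z_b8, z_b1)
  expect_lte(z_b1, z_00)
})

test_that("the privacy score is invariant under joint translation of user and grid", {
  g <- grid_2d_small()
  t <- c(2.5, -1.5)
  gt <- grid_spec(g$x_range + t[1], g$p, g$y_range + t[2], g$q)
  b <- sample_frequencies(2, 0.5, 2, seed = 19)
  d <- c(0.4, 0.2)
  r0 <- privacy_score_user(user_surface_rff(d, b, 0.5, g), d)
  r1 <- privacy_score_user(user_surface_rff(d + t, b, 0.5, gt), d + t)
  expect_equal(r1$Z, r0$Z)
})
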