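shift_mat <- function(V, di, dj) {
  p <- nrow(V); q <- ncol(V)
  out <- matrix(NA_real_, p, q)
  ri <- seq_len(p) + di
  cj <- seq_len(q) + dj
  ok_i <- ri >= 1 & ri <= p
  ok_j <- cj >= 1 & cj <= q
  out[ok_i, ok_j] <- V[ri[ok_i], cj[ok_j], drop = FALSE]
  out
}

neighbor_offsets <- rbind(
  c(-1, -1), c(-1, 0), c(-1, 1),
  c(0, -1),           c(0, 1),
  c(1, -1), c(1, 0), c(1, 1))

# Local maxima of a value matrix: a cell qualifies iff its value >= every
# existing neighbor (8-neighborhood; 2-neighborhood falls out for P x 1);
# connected equal-valued plateaus contribute one representative, the lowest
# column-major linear index. Returns idx (linear) and value, idx ascending.
local_maxima_matrix <- function(V) {
  p <- nrow(V); q <- ncol(V)
  cand <- matrix(TRUE, p, q)
  for (r in seq_len(nrow(neighbor_offsets))) {
    nb <- shift_mat(V, neighbor_offsets[r, 1], neighbor_offsets[r, 2])
    cand <- cand & (is.na(nb) | V >= nb)
  }
  idx <- which(cand)
  if (!length(idx)) return(list(idx = integer(0), value = numeric(0)))
  # plateau grouping: BFS over adjacent equal-valued candidates; iterating in
  # ascending linear order makes the first cell of each component its
  # representative (lowest index), so the attack output is deterministic
  visited <- logical(p * q)
  is_cand <- as.vector(cand)
  reps <- integer(0)
  for (start in idx) {
    if (visited[start]) next
    reps <- c(reps, start)
    queue <- start
    visited[start] <- TRUE
    v0 <- V[start]
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      i <- ((cur - 1) %% p) + 1
      j <- ((cur - 1) %/% p) + 1
      for (r in seq_len(nrow(neighbor_offsets))) {
        ii <- i + neighbor_offsets[r, 1]
        jj <- j + neighbor_offsets[r, 2]
        if (ii < 1 || ii > p || jj < 1 || jj > q) next
        lin <- ii + (jj - 1) * p
        if (!visited[lin] && is_cand[lin] && V[lin] == v0) {
          visited[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
  }
  reps <- sort(reps)
  list(idx = reps, value = V[reps])
}

#' Locate local maxima of a response surface
#'
#' The first step of the localization attack: the server can only predict
#' that a user sits at (or near) a maximum of the response surface it
#' received. A grid cell is a local maximum iff its value is >= all its
#' existing neighbors (8-neighborhood in 2D, 2-neighborhood in 1D; boundary
#' cells compare only the neighbors they have). A connected plateau of equal
#' values contributes a single representative, the cell with the lowest
#' column-major linear index, so the output is deterministic.
#'
#' @param surf an \code{rff_surface}.
#' @return A data frame with columns \code{index} (linear grid index),
#'   \code{x}, \code{y} (\code{NA} for 1D) and \code{value}, ordered by
#'   ascending index.
#' @export
find_local_maxima <- function(surf) {
  stopifnot(inherits(surf, "rff_surface"))
  lm <- local_maxima_matrix(surf$values)
  G <- grid_points(surf$grid)
  data.frame(index = lm$idx,
             x = G[lm$idx, 1],
             y = if (ncol(G) == 2) G[lm$idx, 2] else NA_real_,
             value = lm$value)
}

score_from_maxima <- function(idx, value, G, d_true, epsilon, literal) {
  dif <- sweep(G[idx, , drop = FALSE], 2, d_true)
  dists <- sqrt(rowSums(dif^2))
  emax <- max(value)
  if (emax <= 0) {
    kept <- rep(TRUE, length(idx))
    w <- rep(1 / length(idx), length(idx))
    Z <- mean(dists)
    fallback <- TRUE
  } else {
    kept <- value >= emax / epsilon
    w <- numeric(length(idx))
    w[kept] <- value[kept] / sum(value[kept])
    Z <- sum(w[kept] * dists[kept])
    fallback <- FALSE
  }
  if (literal) Z <- Z / sum(kept)
  list(Z = Z, kept = kept, weights = w, dists = dists, fallback = fallback)
}

#' Localization attack and privacy score for one user
#'
#' Scores how well the maxima-based attacker localizes a user from a single
#' response surface. Local maxima with evaluation below
#' \code{max / epsilon_filter} are discarded (the attacker ignores weak
#' candidates); the remaining maxima are weighted by their normalized
#' evaluations and the score is the weighted mean distance to the true
#' location:
#' \deqn{Z_i = \sum_j e'_{ji} \, \|g_{ji} - d_i\|_2 .}
#' \code{Z_i} is the attacker's expected localization error in map units:
#' near zero means the user is localized (exact federated KDE), large means
#' the candidate maxima are spread across the area. If no maximum is
#' positive the attacker has no evidence ordering and the score falls back
#' to the unweighted mean distance over all maxima (flagged).
#'
#' @param surf the user's response \code{rff_surface}.
#' @param d_true the user's true location.
#' @param epsilon_filter filter parameter >= 1; default 1.1.
#' @param literal if \code{TRUE}, additionally divide by the kept-maxima
#'   count (the double-normalized variant).
#' @return An object of class \code{attack_report}: the maxima table with
#'   \code{kept}, \code{weight}, \code{dist} columns, the score \code{Z},
#'   \code{epsilon_filter} and a \code{fallback} flag.
#' @export
privacy_score_user <- function(surf, d_true, epsilon_filter = 1.1,
                               literal = FALSE) {
  stopifnot(inherits(surf, "rff_surface"))
  if (epsilon_filter < 1) stop("epsilon_filter must be >= 1")
  d_true <- as.numeric(d_true)
  if (length(d_true) != grid_dim(surf$grid))
    stop("d_true dimension does not match the surface grid")
  lm <- local_maxima_matrix(surf$values)
  G <- grid_points(surf$grid)
  sc <- score_from_maxima(lm$idx, lm$value, G, d_true, epsilon_filter,
                          literal)
  maxima <- data.frame(index = lm$idx,
                       x = G[lm$idx, 1],
                       y = if (ncol(G) == 2) G[lm$idx, 2] else NA_real_,
                       value = lm$value,
                       kept = sc$kept,
                       weight = sc$weights,
                       dist = sc$dists)
  structure(list(maxima = maxima, Z = sc$Z,
                 epsilon_filter = epsilon_filter,
                 fallback = sc$fallback, d_true = d_true),
            class = "attack_report")
}

#' @export
print.attack_report <- function(x, ...) {
  cat(sprintf("attack report: %d local maxima, %d kept, Z = %.4g%s\n",
              nrow(x$maxima), sum(x$maxima$kept), x$Z,
              if (x$fallback) " (fallback: no positive maximum)" else ""))
  invisible(x)
}

#' System-level privacy score
#'
#' The arithmetic mean of per-user scores \eqn{Z = (1/N)\sum_i Z_i}.
#'
#' @param reports a nonempty list of \code{attack_report}s, or a numeric
#'   vector of per-user scores.
#' @return The mean score.
#' @export
privacy_score_system <- function(reports) {
  if (is.numeric(reports)) {
    if (!length(reports)) stop("no scores to average")
    return(mean(reports))
  }
  if (!length(reports)) stop("no reports to average")
  mean(vapply(reports, function(r) r$Z, numeric(1)))
}

#' Privacy score of the zero-feature baseline
#'
#' A user answering every query with a constant reveals nothing; the best
#' the attacker can do is a uniform guess over grid nodes, so the score is
#' the mean distance from the user's location to every node. No mechanism
#' can score higher (while responses stay inside the area).
#'
#' @param grid a \code{grid_spec}.
#' @param d the user's location.
#' @return Mean distance from \code{d} to all grid nodes.
#' @export
zero_feature_score <- function(grid, d) {
  stopifnot(inherits(grid, "grid_spec"))
  d <- as.numeric(d)
  if (length(d) != grid_dim(grid))
    stop("point dimension does not match the grid")
  G <- grid_points(grid)
  mean(sqrt(rowSums(sweep(G, 2, d)^2)))
}

#' Indistinguishable locations under a single frozen frequency
#'
#' The equivalence class of a location \code{x} for one basis function with
#' frequency \eqn{\omega}:
#' \deqn{D(x) = \{\, x + \alpha \tfrac{2\pi}{\|\omega\|^2}\omega + u :
#'   \alpha \in Z,\ \omega^\top u = 0 \,\}}
#' — a family of parallel lines orthogonal to \eqn{\omega} with spacing
#' \eqn{2\pi/\|\omega\|} (in 1D, a lattice with spacing \eqn{2\pi/|\omega|}).
#' Every member produces exactly the same single-feature projection as
#' \code{x} at every query point, so no number of queries can distinguish
#' them. This function materializes members clipped to a bounding grid.
#'
#' @param omega nonzero frequency vector (length 1 or 2).
#' @param x anchor location.
#' @param bbox a \code{grid_spec} bounding box to clip to.
#' @param n_per_line number of sample points along each line (2D only).
#' @return A list of class \code{equivalence_class}: \code{points} (matrix of
#'   members inside the box), \code{alpha} (line index per point),
#'   \code{spacing} (distance between consecutive lines), \code{omega},
#'   \code{x}.
#' @export
equivalence_class_points <- function(omega, x, bbox, n_per_line = 11L) {
  omega <- as.numeric(omega); x <- as.numeric(x)
  stopifnot(inherits(bbox, "grid_spec"))
  if (all(omega == 0)) stop("omega must be nonzero")
  if (length(omega) != length(x) || length(omega) != grid_dim(bbox))
    stop("dimensions of omega, x and bbox must agree")
  wn <- sqrt(sum(omega^2))
  spacing <- 2 * pi / wn
  if (length(omega) == 1L) {
    step <- 2 * pi / omega          # signed; members x + alpha * step
    a_bounds <- (bbox$x_range - x) / step
    alphas <- seq(ceiling(min(a_bounds)), floor(max(a_bounds)))
    pts <- matrix(x + alphas * step, ncol = 1)
    keep <- pts[, 1] >= bbox$x_range[1] & pts[, 1] <= bbox$x_range[2]
    return(structure(list(points = pts[keep, , drop = FALSE],
                          alpha = alphas[keep], spacing = spacing,
                          omega = omega, x = x),
                     class = "equivalence_class"))
  }
  v <- 2 * pi * omega / wn^2        # step between lines, along omega-hat
  u_hat <- c(-omega[2], omega[1]) / wn
  corners <- rbind(c(bbox$x_range[1], bbox$y_range[1]),
                   c(bbox$x_range[2], bbox$y_range[1]),
                   c(bbox$x_range[1], bbox$y_range[2]),
                   c(bbox$x_range[2], bbox$y_range[2]))
  proj <- as.numeric(sweep(corners, 2, x) %*% (omega / wn)) / spacing
  alphas <- seq(floor(min(proj)), ceiling(max(proj)))
  tproj <- as.numeric(sweep(corners, 2, x) %*% u_hat)
  tgrid <- seq(min(tproj), max(tproj), length.out = n_per_line)
  pts <- do.call(rbind, lapply(alphas, function(a)
    cbind(x[1] + a * v[1] + tgrid * u_hat[1],
          x[2] + a * v[2] + tgrid * u_hat[2])))
  alpha_all <- rep(alphas, each = n_per_line)
  keep <- pts[, 1] >= bbox$x_range[1] & pts[, 1] <= bbox$x_range[2] &
    pts[, 2] >= bbox$y_range[1] & pts[, 2] <= bbox$y_range[2]
  structure(list(points = pts[keep, , drop = FALSE],
                 alpha = alpha_all[keep], spacing = spacing,
                 omega = omega, x = x),
            class = "equivalence_class")
}

#' Band overlap between policy-rescaled responses
#'
#' Demonstrates the (4n+1) rescaling rule on a 1D single-feature response: a
#' user with frequency drawn at base bandwidth \code{h0} answers a query at
#' \code{h = (4n+1) h0} with the same frozen frequency rescaled, so the
#' maxima of the rescaled surface all coincide with every (4n+1)-th band of
#' the base surface — multiple invariant bands survive, and cross-bandwidth
#' comparison cannot single out the user's band. For a non-policy bandwidth
#' the rescaled maxima generically fall between base bands.
#'
#' @param omega0 the user's (1D) frequency, drawn at base bandwidth
#'   \code{h0}.
#' @param h0 base bandwidth.
#' @param h queried bandwidth (policy-compliant values are
#'   \code{(4n+1)*h0}).
#' @param d the user's location.
#' @param grid a 1D \code{grid_spec}, dense enough to resolve the base
#'   bands.
#' @param tol_frac match tolerance as a fraction of the base band spacing.
#' @return A list: \code{period} (spacing, in base-band counts, between
#'   consecutive rescaled maxima that coincide with base bands; \code{NA} if
#'   irregular), \code{matched_fraction} (fraction of rescaled maxima lying
#'   on a base band), \code{base_maxima}, \code{rescaled_maxima} (positions).
#' @export
band_overlap <- function(omega0, h0, h, d = 0, grid, tol_frac = 0.25) {
  stopifnot(inherits(grid, "grid_spec"), grid_dim(grid) == 1L)
  omega0 <- as.numeric(omega0)
  stopifnot(length(omega0) == 1, omega0 != 0, h0 > 0, h > 0)
  xs <- grid_coords(grid)$x
  w1 <- omega0 * h0 / h
  s0 <- cos(omega0 * (xs - d))
  s1 <- cos(w1 * (xs - d))
  interior <- function(vals) {
    lm <- local_maxima_matrix(matrix(vals, ncol = 1))
    idx <- lm$idx[lm$idx > 1 & lm$idx < length(vals)]
    xs[idx]
  }
  p0 <- interior(s0)
  p1 <- interior(s1)
  if (!length(p0) || !length(p1))
    return(list(period = NA_real_, matched_fraction = 0,
                base_maxima = p0, rescaled_maxima = p1))
  tol <- tol_frac * 2 * pi / abs(omega0)
  nearest <- vapply(p1, function(p) which.min(abs(p0 - p)), integer(1))
  matched <- abs(p0[nearest] - p1) < tol
  ords <- sort(nearest[matched])
  per <- unique(diff(ords))
  list(period = if (length(per) == 1) as.numeric(per) else NA_real_,
       matched_fraction = mean(matched),
       base_maxima = p0, rescaled_maxima = p1)
}

#' Per-user privacy scores for a whole dataset
#'
#' Runs the localization attack against every user's response surface and
#' returns the per-user scores. Surfaces are rebuilt exactly as the protocol
#' would emit them: \code{"exact"} uses kernel evaluations, \code{"rff"} uses
#' each user's frozen basis (derived from \code{seed} with the same per-user
#' substreams as \code{\link{federated_rff_kde}}, so attack and estimation
#' analyze the very same responses), \code{"zero"} scores the constant
#' response via \code{\link{zero_feature_score}}.
#'
#' @param points N x dim matrix of true user locations.
#' @param grid a \code{grid_spec}.
#' @param method \code{"exact"}, \code{"rff"} or \code{"zero"}.
#' @param h bandwidth (exact/rff).
#' @param B features per user (rff).
#' @param h0 base bandwidth for the rff frequency draw (default \code{h}).
#' @param seed master seed for per-user bases (rff).
#' @param epsilon_filter attack filter parameter.
#' @param surf_points optional N x dim matrix of the locations the surfaces
#'   are built from, when they differ from the true locations (the GeoInd
#'   baseline perturbs before responding); scores always measure distance to
#'   \code{points}.
#' @return A data frame with columns \code{user}, \code{K} (local maxima
#'   count; \code{NA} for zero), \code{Z}, \code{fallback}.
#' @export
privacy_scores <- function(points, grid, method = c("exact", "rff", "zero"),
                           h = NULL, B = 1L, h0 = h, seed = 1L,
                           epsilon_filter = 1.1, surf_points = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "grid_spec"))
  X <- as_points_matrix(points, grid_dim(grid))
  n <- nrow(X)
  G <- grid_points(grid)
  if (method == "zero") {
    g2 <- rowSums(G^2)
    Z <- vapply(seq_len(n), function(i)
      mean(sqrt(pmax(0, g2 - 2 * (G %*% X[i, ]) + sum(X[i, ]^2)))),
      numeric(1))
    return(data.frame(user = seq_len(n), K = NA_integer_, Z = Z,
                      fallback = FALSE))
  }
  if (is.null(h)) stop("h is required for exact/rff scoring")
  S <- if (is.null(surf_points)) X else as_points_matrix(surf_points,
                                                         grid_dim(grid))
  if (nrow(S) != n) stop("surf_points must match points row-for-row")
  p <- grid$p
  q <- if (grid_dim(grid) == 1L) 1L else grid$q
  tG <- t(G)
  if (method == "rff") {
    B <- as.integer(B)
    W <- user_frequencies(n, B, h0, ncol(X), seed) * (h0 / h)
  }
  K <- integer(n); Z <- numeric(n); fb <- logical(n)
  for (i in seq_len(n)) {
    vals <- if (method == "exact") {
      kernel_to_nodes(S[i, ], G, h)
    } else {
      Wi <- W[((i - 1L) * B + 1L):(i * B), , drop = FALSE]
      colSums(cos(Wi %*% tG - as.numeric(Wi %*% S[i, ])))
    }
    lm <- local_maxima_matrix(matrix(vals, p, q))
    sc <- score_from_maxima(lm$idx, lm$value, G, X[i, ], epsilon_filter,
                            FALSE)
    K[i] <- length(lm$idx); Z[i] <- sc$Z; fb[i] <- sc$fallback
  }
  data.frame(user = seq_len(n), K = K, Z = Z, fallback = fb)
}
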