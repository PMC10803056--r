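#' Construct a Gaussian mixture specification
#'
#' @param weights nonnegative weights summing to 1.
#' @param means list of component mean vectors (all the same length, 1 or 2).
#' @param covariances list of SPD covariance matrices (scalars/1x1 in 1D).
#' @return An object of class \code{mixture_spec}.
#' @export
mixture_spec <- function(weights, means, covariances) {
  weights <- as.numeric(weights)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  k <- length(weights)
  if (length(means) != k || length(covariances) != k)
    stop("weights, means and covariances must have equal length")
  means <- lapply(means, as.numeric)
  dim <- length(means[[1]])
  if (!dim %in% c(1L, 2L)) stop("only 1D and 2D mixtures are supported")
  if (any(vapply(means, length, 1L) != dim))
    stop("all component means must share one dimension")
  covariances <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    if (nrow(S) != dim || ncol(S) != dim)
      stop("covariance dimensions must match the means")
    if (max(abs(S - t(S))) > 1e-10) stop("covariances must be symmetric")
    if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("covariances must be positive definite")
    S
  })
  structure(list(weights = weights, means = means,
                 covariances = covariances, dim = as.integer(dim)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d components in %dD\n",
              length(x$weights), x$dim))
  invisible(x)
}

#' Built-in synthetic study mixtures
#'
#' Three reference populations used throughout the synthetic experiments:
#' \describe{
#'   \item{\code{grid9}}{9 equal-weight isotropic Gaussians on the 3 x 3
#'     lattice \eqn{\{-1,0,1\}^2}, each with covariance
#'     \code{diag(0.25, 0.25)} — a smooth, near-uniform surface.}
#'   \item{\code{octagon8}}{8 equal-weight anisotropic Gaussians with means
#'     \eqn{\mu_i = (3\cos(\pi i/4), 3\sin(\pi i/4))}, \eqn{i = 1..8}, each
#'     covariance the rotated ellipse
#'     \eqn{R(\pi i/4)\,\mathrm{diag}(1, 0.16^2)\,R(\pi i/4)^\top}
#'     (tangentially elongated) — a heterogeneous ring.}
#'   \item{\code{tri1d}}{the 1D illustration: components
#'     \eqn{N(-10, 2^2)}, \eqn{N(0, 2^2)}, \eqn{N(5, 2^2)} with weights
#'     1:3:1, i.e. \code{(0.2, 0.6, 0.2)}.}
#' }
#'
#' @param name one of \code{"grid9"}, \code{"octagon8"}, \code{"tri1d"}.
#' @return A \code{mixture_spec}.
#' @export
builtin_mixture <- function(name) {
  switch(name,
    grid9 = {
      mu <- expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1))
      mixture_spec(rep(1 / 9, 9),
                   lapply(seq_len(9), function(i) as.numeric(mu[i, ])),
                   replicate(9, diag(c(0.25, 0.25)), simplify = FALSE))
    },
    octagon8 = {
      means <- lapply(1:8, function(i)
        c(3 * cos(pi * i / 4), 3 * sin(pi * i / 4)))
      covs <- lapply(1:8, function(i) {
        th <- pi * i / 4
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        R %*% diag(c(1, 0.16^2)) %*% t(R)
      })
      mixture_spec(rep(1 / 8, 8), means, covs)
    },
    tri1d = mixture_spec(c(0.2, 0.6, 0.2),
                         list(-10, 0, 5),
                         list(matrix(4), matrix(4), matrix(4))),
    stop(sprintf("unknown mixture '%s'", name))
  )
}

#' Sample locations from a Gaussian mixture
#'
#' Component membership is multinomial in the weights; draws within a
#' component use the Cholesky factor of its covariance. 1D and 2D share one
#' code path.
#'
#' @param spec a \code{mixture_spec}.
#' @param n number of points (>= 1).
#' @param seed optional seed (caller's RNG state preserved if given).
#' @return An \code{n x dim} matrix of locations; the generating component
#'   index of each row is attached as attribute \code{"component"}.
#' @export
sample_mixture <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be an integer >= 1")
  if (!is.null(seed)) {
    reset <- restore_rng(); on.exit(reset())
    set.seed(seed)
  }
  k <- length(spec$weights)
  comp <- sample.int(k, n, replace = TRUE, prob = spec$weights)
  X <- matrix(0, n, spec$dim)
  for (j in seq_len(k)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    Z <- matrix(stats::rnorm(length(idx) * spec$dim), ncol = spec$dim)
    L <- chol(spec$covariances[[j]])
    X[idx, ] <- sweep(Z %*% L, 2, spec$means[[j]], `+`)
  }
  attr(X, "component") <- comp
  X
}

#' Exact mixture density on a grid
#'
#' The properly normalized ground-truth pdf evaluated at every grid node —
#' the reference surface for utility scoring on synthetic data.
#'
#' @param spec a \code{mixture_spec}.
#' @param grid a \code{grid_spec} of matching dimension.
#' @return An \code{rff_surface} of density values (method tag
#'   \code{"truth"}).
#' @export
mixture_density <- function(spec, grid) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(grid, "grid_spec"))
  if (spec$dim != grid_dim(grid))
    stop("mixture and grid dimensions differ")
  G <- grid_points(grid)
  vals <- numeric(nrow(G))
  for (j in seq_along(spec$weights)) {
    S <- spec$covariances[[j]]
    mu <- spec$means[[j]]
    dif <- sweep(G, 2, mu)
    if (spec$dim == 1L) {
      q <- dif[, 1]^2 / S[1, 1]
      nc <- sqrt(2 * pi * S[1, 1])
    } else {
      Sinv <- solve(S)
      q <- rowSums((dif %*% Sinv) * dif)
      nc <- 2 * pi * sqrt(det(S))
    }
    vals <- vals + spec$weights[j] * exp(-q / 2) / nc
  }
  surface(vals, grid, meta = list(method = "truth"))
}
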