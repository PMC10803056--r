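#' Gaussian kernel between two points
#'
#' The shift-invariant Gaussian kernel
#' \deqn{k_h(x, y) = \exp(-\|x - y\|^2 / (2 h^2)),}
#' the unique form consistent with frequency sampling from
#' \eqn{N(0, h^{-2} I)} via Bochner's theorem. By default the kernel is
#' unnormalized (peaks at 1), matching the per-user response surfaces of the
#' federated protocol; rank-based utility and the privacy score are invariant
#' to the constant. Set \code{normalize = TRUE} to divide by
#' \eqn{(2\pi h^2)^{d/2}} for comparison against true densities.
#'
#' @param x,y numeric vectors of equal length (1 or 2), the two locations.
#' @param h positive bandwidth in map units.
#' @param normalize logical; divide by the Gaussian normalizing constant.
#' @return Kernel value in \code{(0, 1]} (unnormalized).
#' @examples
#' gaussian_kernel(c(0, 0), c(0, 0), h = 1)        # 1
#' gaussian_kernel(0, 2, h = 2)                    # exp(-1/2)
#' @export
gaussian_kernel <- function(x, y, h, normalize = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have the same dimension")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("point coordinates must be finite")
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop("h must be a positive number")
  v <- exp(-sum((x - y)^2) / (2 * h^2))
  if (normalize) v <- v / (2 * pi * h^2)^(length(x) / 2)
  v
}

# Kernel evaluations of one point d against all rows of a node matrix G.
kernel_to_nodes <- function(d, G, h) {
  d2 <- rowSums(sweep(G, 2, d)^2)
  exp(-d2 / (2 * h^2))
}

restore_rng <- function() {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Draw an n x dim frequency matrix ~ N(0, h0^-2 I) under a private stream.
draw_frequencies <- function(n, h0, dim, seed) {
  reset <- restore_rng(); on.exit(reset())
  set.seed(seed)
  matrix(stats::rnorm(n * dim, sd = 1 / h0), nrow = n, ncol = dim)
}

#' Sample a user's frozen random Fourier frequencies
#'
#' Draws \code{B} frequency vectors i.i.d. from \eqn{N(0, h_0^{-2} I)}, the
#' Fourier density of the Gaussian kernel with base bandwidth \code{h0}. The
#' returned basis is the user's private state: it is sampled exactly once and
#' never redrawn, so repeated or rescaled queries can reveal nothing beyond
#' the projections it generates. Queries at other bandwidths reuse these
#' frequencies through \code{\link{rescale_frequencies}}.
#'
#' @param B integer >= 1, number of basis functions.
#' @param h0 positive base bandwidth.
#' @param dim 1 or 2.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return An object of class \code{rff_basis} with fields \code{omegas}
#'   (\code{B x dim} matrix), \code{h0}, \code{B}, \code{dim}, \code{seed}.
#' @export
sample_frequencies <- function(B, h0, dim, seed) {
  B <- as.integer(B)
  if (is.na(B) || B < 1) stop("B must be an integer >= 1")
  if (!is.numeric(h0) || length(h0) != 1 || !is.finite(h0) || h0 <= 0)
    stop("h0 must be a positive number")
  if (!dim %in% c(1, 2)) stop("dim must be 1 or 2")
  omegas <- draw_frequencies(B, h0, dim, seed)
  structure(list(omegas = omegas, h0 = h0, B = B, dim = as.integer(dim),
                 seed = as.integer(seed)),
            class = "rff_basis")
}

#' @export
print.rff_basis <- function(x, ...) {
  cat(sprintf("rff_basis: B = %d frozen %dD frequencies, h0 = %g, seed = %d\n",
              x$B, x$dim, x$h0, x$seed))
  invisible(x)
}

#' Rescale frozen frequencies to a queried bandwidth
#'
#' A query at bandwidth \code{h} is answered with the stored frequencies
#' multiplied by \code{h0 / h}: directions are preserved (so the bands of the
#' response surface cannot shift laterally between queries) and the rescaled
#' rows are distributed exactly \eqn{N(0, h^{-2} I)}.
#'
#' @param basis an \code{rff_basis}.
#' @param h positive query bandwidth.
#' @return The effective \code{B x dim} frequency matrix.
#' @export
rescale_frequencies <- function(basis, h) {
  stopifnot(inherits(basis, "rff_basis"))
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop("h must be a positive number")
  basis$omegas * (basis$h0 / h)
}

#' Random-feature projection between two points
#'
#' The Monte-Carlo kernel approximation
#' \deqn{\frac{1}{B}\sum_b \cos(\omega_b^\top (g - d))}
#' with the basis frequencies rescaled to bandwidth \code{h}. Each summand is
#' \eqn{\cos(\omega^\top g)\cos(\omega^\top d) +
#' \sin(\omega^\top g)\sin(\omega^\top d)}, i.e. the inner product of the two
#' points' feature vectors; the value is an unbiased estimate of
#' \code{gaussian_kernel(g, d, h)}, lies in \code{[-1, 1]}, equals 1 at
#' \code{g = d}, and depends on the points only through \code{g - d}.
#'
#' @param basis an \code{rff_basis}.
#' @param h positive query bandwidth.
#' @param d,g numeric vectors of the basis dimension (data point and query
#'   point).
#' @return Mean projection over the B basis functions.
#' @export
rff_projection <- function(basis, h, d, g) {
  stopifnot(inherits(basis, "rff_basis"))
  d <- as.numeric(d); g <- as.numeric(g)
  if (length(d) != basis$dim || length(g) != basis$dim)
    stop("point dimension does not match the basis")
  W <- rescale_frequencies(basis, h)
  mean(cos(as.numeric(W %*% (g - d))))
}
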