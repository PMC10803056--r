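#' Define an evaluation grid
#'
#' A grid specification describes the regular lattice of query coordinates
#' the server sends to users. Coordinates are evenly spaced and inclusive of
#' both endpoints on each axis; index \code{p} runs over x and \code{q} over
#' y, so a surface aligned to the grid is a \code{P x Q} matrix whose linear
#' (column-major) index \code{m = p + (q-1)*P} corresponds to the point
#' \code{(x[p], y[q])}.
#'
#' @param x_range numeric length-2, \code{c(min, max)} of the x axis.
#' @param p integer >= 2, number of grid points along x.
#' @param y_range numeric length-2 or \code{NULL} for a 1D grid.
#' @param q integer >= 2, number of grid points along y (ignored for 1D).
#' @return An object of class \code{grid_spec}.
#' @examples
#' g2 <- grid_spec(c(-3, 3), 50, c(-3, 3), 50)
#' g1 <- grid_spec(c(-15, 15), 1000)
#' @export
grid_spec <- function(x_range, p, y_range = NULL, q = NULL) {
  stopifnot(is.numeric(x_range), length(x_range) == 2, all(is.finite(x_range)))
  if (x_range[1] >= x_range[2]) stop("x_range must satisfy min < max")
  p <- as.integer(p)
  if (is.na(p) || p < 2) stop("p must be an integer >= 2")
  if (!is.null(y_range)) {
    stopifnot(is.numeric(y_range), length(y_range) == 2,
              all(is.finite(y_range)))
    if (y_range[1] >= y_range[2]) stop("y_range must satisfy min < max")
    q <- as.integer(q)
    if (is.na(q) || q < 2) stop("q must be an integer >= 2")
  } else {
    q <- NULL
  }
  structure(list(x_range = as.numeric(x_range), p = p,
                 y_range = if (is.null(y_range)) NULL else as.numeric(y_range),
                 q = q),
            class = "grid_spec")
}

#' Dimensionality of a grid
#' @param grid a \code{grid_spec}.
#' @return 1 or 2.
#' @export
grid_dim <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(grid$y_range)) 1L else 2L
}

#' Axis coordinates of a grid
#' @param grid a \code{grid_spec}.
#' @return A list with components \code{x} (length P) and, for 2D grids,
#'   \code{y} (length Q).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  out <- list(x = seq(grid$x_range[1], grid$x_range[2], length.out = grid$p))
  if (grid_dim(grid) == 2L)
    out$y <- seq(grid$y_range[1], grid$y_range[2], length.out = grid$q)
  out
}

#' All grid nodes as a point matrix
#'
#' Row \code{m} holds the coordinates of the node with column-major linear
#' index \code{m} in an aligned surface matrix.
#'
#' @param grid a \code{grid_spec}.
#' @return A numeric matrix with \code{P*Q} rows (P rows for 1D) and
#'   \code{grid_dim(grid)} columns.
#' @export
grid_points <- function(grid) {
  co <- grid_coords(grid)
  if (grid_dim(grid) == 1L) return(matrix(co$x, ncol = 1))
  cbind(rep(co$x, times = length(co$y)),
        rep(co$y, each = length(co$x)))
}

#' Grid spacing per axis
#' @param grid a \code{grid_spec}.
#' @return Numeric vector of per-axis spacings (length 1 or 2).
#' @export
grid_spacing <- function(grid) {
  dx <- diff(grid$x_range) / (grid$p - 1)
  if (grid_dim(grid) == 1L) dx
  else c(dx, diff(grid$y_range) / (grid$q - 1))
}

#' @export
print.grid_spec <- function(x, ...) {
  if (grid_dim(x) == 1L) {
    cat(sprintf("1D grid: %d points on [%g, %g]\n",
                x$p, x$x_range[1], x$x_range[2]))
  } else {
    cat(sprintf("2D grid: %d x %d points on [%g, %g] x [%g, %g]\n",
                x$p, x$q, x$x_range[1], x$x_range[2],
                x$y_range[1], x$y_range[2]))
  }
  invisible(x)
}

#' Construct a density surface aligned to a grid
#'
#' A surface is a \code{P x Q} real matrix (a \code{P x 1} matrix for a 1D
#' grid) carrying the grid it is aligned to and provenance metadata (method
#' tag, bandwidth, feature count, user count).
#'
#' @param values numeric matrix or vector of evaluations; recycled into a
#'   \code{P x Q} matrix in column-major (linear grid index) order.
#' @param grid the \code{grid_spec} the values are aligned to.
#' @param meta named list of metadata (e.g. \code{method}, \code{h},
#'   \code{B}, \code{N}, \code{seed}).
#' @return An object of class \code{rff_surface}.
#' @export
surface <- function(values, grid, meta = list()) {
  stopifnot(inherits(grid, "grid_spec"))
  nq <- if (grid_dim(grid) == 1L) 1L else grid$q
  if (is.matrix(values)) {
    if (nrow(values) != grid$p || ncol(values) != nq)
      stop("values shape does not match the grid")
  } else {
    if (length(values) != grid$p * nq)
      stop("values length does not match the grid")
    values <- matrix(values, nrow = grid$p, ncol = nq)
  }
  if (!all(is.finite(values))) stop("surface values must be finite")
  structure(list(values = values, grid = grid, meta = meta),
            class = "rff_surface")
}

#' @export
print.rff_surface <- function(x, ...) {
  m <- x$meta
  tag <- if (!is.null(m$method)) m$method else "surface"
  cat(sprintf("%s surface on ", tag))
  print(x$grid)
  cat(sprintf("  range [%.4g, %.4g]", min(x$values), max(x$values)))
  if (!is.null(m$h)) cat(sprintf("  h = %g", m$h))
  if (!is.null(m$B)) cat(sprintf("  B = %d", m$B))
  if (!is.null(m$N)) cat(sprintf("  N = %d", m$N))
  cat("\n")
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x_range, b$x_range)) && a$p == b$p &&
    grid_dim(a) == grid_dim(b) &&
    (grid_dim(a) == 1L ||
       (isTRUE(all.equal(a$y_range, b$y_range)) && a$q == b$q))
}

as_points_matrix <- function(x, dim = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = length(x))
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("point coordinates must be finite")
  if (!is.null(dim) && ncol(x) != dim)
    stop(sprintf("points have dimension %d, expected %d", ncol(x), dim))
  if (!ncol(x) %in% c(1L, 2L)) stop("only 1D and 2D points are supported")
  unname(x)
}
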