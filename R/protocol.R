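#' Per-user exact kernel response surface
#'
#' What a user returns under exact federated KDE: the Gaussian kernel
#' evaluated between their location and every node of the server's grid.
#' The surface peaks at the node nearest the user, which is exactly why this
#' protocol has no privacy: the server reads the location off the argmax.
#'
#' @param d numeric vector, the user's location.
#' @param grid a \code{grid_spec}.
#' @param h positive bandwidth.
#' @return An \code{rff_surface} with values in \code{(0, 1]}.
#' @export
user_surface_exact <- function(d, grid, h) {
  stopifnot(inherits(grid, "grid_spec"))
  d <- as.numeric(d)
  if (length(d) != grid_dim(grid))
    stop("point dimension does not match the grid")
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("h must be positive")
  G <- grid_points(grid)
  surface(kernel_to_nodes(d, G, h), grid,
          meta = list(method = "exact", h = h, N = 1L))
}

#' Per-user random-feature response surface
#'
#' What a user returns under federated RFF KDE: at each grid node the SUM
#' over their B frozen basis functions,
#' \eqn{\sum_b \cos(\tilde\omega_b^\top (g - d))} with
#' \eqn{\tilde\omega = (h_0/h)\,\omega}. Entries lie in \code{[-B, B]}; the
#' server divides the aggregate by \code{N B}. The basis is never redrawn,
#' so repeated queries are bit-identical and queries at other policy
#' bandwidths only rescale the pattern.
#'
#' @param d numeric vector, the user's location.
#' @param basis the user's \code{rff_basis}.
#' @param h positive query bandwidth (assumed policy-validated).
#' @param grid a \code{grid_spec}.
#' @return An \code{rff_surface}; meta records \code{n_ops = P*Q*B}, the
#'   user-side basis-function evaluation count.
#' @export
user_surface_rff <- function(d, basis, h, grid) {
  stopifnot(inherits(grid, "grid_spec"), inherits(basis, "rff_basis"))
  d <- as.numeric(d)
  if (length(d) != grid_dim(grid) || basis$dim != grid_dim(grid))
    stop("dimensions of point, basis and grid must agree")
  W <- rescale_frequencies(basis, h)
  G <- grid_points(grid)
  vals <- colSums(cos(W %*% t(G) - as.numeric(W %*% d)))
  surface(vals, grid,
          meta = list(method = "rff", h = h, B = basis$B, N = 1L,
                      n_ops = nrow(G) * basis$B))
}

#' Server-side aggregation of user responses
#'
#' In exact mode the server averages the N kernel surfaces, recovering the
#' pooled KDE on the grid. In RFF mode the per-user surfaces are raw sums
#' over basis functions, so the server divides the total by \code{N * B}.
#' Aggregation is linear and needs nothing but the surfaces themselves.
#'
#' @param surfaces nonempty list of \code{rff_surface} on a shared grid.
#' @param mode \code{"exact"} or \code{"rff"}.
#' @param B feature count per user (required in rff mode; all users must
#'   share it).
#' @return The aggregated \code{rff_surface}.
#' @export
aggregate_surfaces <- function(surfaces, mode = c("exact", "rff"), B = NULL) {
  mode <- match.arg(mode)
  if (!length(surfaces)) stop("no surfaces to aggregate")
  if (!all(vapply(surfaces, inherits, TRUE, "rff_surface")))
    stop("all inputs must be rff_surface objects")
  g0 <- surfaces[[1]]$grid
  for (s in surfaces)
    if (!same_grid(g0, s$grid)) stop("surfaces are on different grids")
  n <- length(surfaces)
  tot <- Reduce(`+`, lapply(surfaces, `[[`, "values"))
  if (mode == "exact") {
    vals <- tot / n
  } else {
    if (is.null(B)) stop("B is required in rff mode")
    vals <- tot / (n * B)
  }
  meta <- surfaces[[1]]$meta
  meta$N <- n
  meta$method <- if (mode == "exact") "exact" else "rff"
  surface(vals, g0, meta)
}

# Shared chunked evaluator: accumulate FUN over column blocks of size `chunk`.
chunk_indices <- function(n, chunk) {
  if (n <= chunk) return(list(seq_len(n)))
  split(seq_len(n), ceiling(seq_len(n) / chunk))
}

#' Pooled exact federated KDE surface
#'
#' Direct computation of the exact-mode aggregate
#' \eqn{(1/N)\sum_i k_h(g, d_i)} over all grid nodes, equal (to floating
#' tolerance) to aggregating the N per-user surfaces but evaluated in
#' vectorized blocks so large N is cheap.
#'
#' @param points N x dim matrix (or data frame) of user locations.
#' @param grid a \code{grid_spec}.
#' @param h positive bandwidth.
#' @param chunk block size for vectorized evaluation.
#' @return The pooled \code{rff_surface}.
#' @export
federated_kde <- function(points, grid, h, chunk = 2000L) {
  stopifnot(inherits(grid, "grid_spec"))
  X <- as_points_matrix(points, grid_dim(grid))
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("h must be positive")
  G <- grid_points(grid)
  g2 <- rowSums(G^2)
  acc <- numeric(nrow(G))
  for (idx in chunk_indices(nrow(X), chunk)) {
    Xc <- X[idx, , drop = FALSE]
    d2 <- outer(g2, rowSums(Xc^2), `+`) - 2 * (G %*% t(Xc))
    d2[d2 < 0] <- 0
    acc <- acc + rowSums(exp(-d2 / (2 * h^2)))
  }
  surface(acc / nrow(X), grid,
          meta = list(method = "exact", h = h, N = nrow(X)))
}

# All users' frequencies in one reproducible block: user i owns rows
# ((i-1)B+1):(iB), so each basis is recoverable from (seed, i, B) alone,
# independently of evaluation order.
user_frequencies <- function(n_users, B, h0, dim, seed) {
  draw_frequencies(n_users * B, h0, dim, seed)
}

basis_for_user <- function(W, i, B, h0, seed) {
  rows <- ((i - 1L) * B + 1L):(i * B)
  structure(list(omegas = W[rows, , drop = FALSE], h0 = h0, B = B,
                 dim = ncol(W), seed = as.integer(seed)),
            class = "rff_basis")
}

#' Aggregated federated RFF KDE surface
#'
#' The full protocol in one call: every user draws B frozen frequencies at
#' base bandwidth \code{h0} (from a per-user substream of \code{seed}),
#' rescales them to the queried \code{h}, evaluates the cosine projections on
#' the grid, and the server averages the \code{N*B} summands. Identical (to
#' floating tolerance) to aggregating \code{\link{user_surface_rff}} over
#' users, but evaluated in blocks.
#'
#' @param points N x dim matrix of user locations.
#' @param grid a \code{grid_spec}.
#' @param h queried bandwidth.
#' @param B features per user.
#' @param h0 base bandwidth at which frequencies are drawn (default \code{h}).
#' @param seed master seed for the per-user frequency substreams.
#' @param chunk block size over the N*B summands.
#' @return The aggregated \code{rff_surface} (estimates the unnormalized
#'   pooled kernel mean, values approaching \code{\link{federated_kde}}'s as
#'   \code{N*B} grows).
#' @export
federated_rff_kde <- function(points, grid, h, B, h0 = h, seed = 1L,
                              chunk = 5000L) {
  stopifnot(inherits(grid, "grid_spec"))
  X <- as_points_matrix(points, grid_dim(grid))
  B <- as.integer(B)
  if (is.na(B) || B < 1) stop("B must be an integer >= 1")
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("h must be positive")
  n <- nrow(X)
  W <- user_frequencies(n, B, h0, ncol(X), seed) * (h0 / h)
  # summand r belongs to user ceiling(r / B): phase offset uses that user's d
  off <- as.numeric(rowSums(W * X[rep(seq_len(n), each = B), , drop = FALSE]))
  G <- grid_points(grid)
  tG <- t(G)
  acc <- numeric(nrow(G))
  for (idx in chunk_indices(nrow(W), chunk)) {
    # rows = summands, so the per-summand phase offset recycles column-major
    phase <- W[idx, , drop = FALSE] %*% tG - off[idx]
    acc <- acc + colSums(cos(phase))
  }
  surface(acc / (n * B), grid,
          meta = list(method = "rff", h = h, B = B, N = n, h0 = h0,
                      seed = as.integer(seed)))
}

#' Maximum policy bandwidth for a target band count
#'
#' The largest bandwidth a user should accept so that, with probability at
#' least \eqn{1 - C(\gamma)} over the frequency draw (C the chi-squared CDF
#' with 2 df), at least \code{j} bands of a single-feature response cross the
#' largest inscribed square of the query area:
#' \deqn{h_{max} = \sqrt{\gamma}\, l / (2 \pi j).}
#' The \eqn{\sqrt\gamma} arises because \eqn{\|\omega\|^2 \sim h^{-2}\chi^2_2}
#' and the band count across a side-\code{l} square is about
#' \eqn{l\|\omega\|/(2\pi)}; the bound is validated empirically by
#' \code{\link{count_bands}} Monte Carlo.
#'
#' @param gamma positive risk parameter (smaller = stricter guarantee).
#' @param j integer >= 2, minimum band count to guarantee.
#' @param l side length of the largest square inscribed in the query area.
#' @return The maximum acceptable bandwidth.
#' @export
max_bandwidth <- function(gamma, j, l) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be positive")
  if (!is.numeric(l) || length(l) != 1 || l <= 0) stop("l must be positive")
  j <- as.integer(j)
  if (is.na(j) || j < 2)
    stop("j must be an integer >= 2 (fewer bands cannot protect edge users)")
  sqrt(gamma) * l / (2 * pi * j)
}

#' Count response-surface bands crossing a square
#'
#' For a single frequency \code{omega}, the maxima of
#' \eqn{\cos(\omega^\top(x - d))} are the lines
#' \eqn{\omega^\top x = \omega^\top d + 2\pi k}; this counts how many such
#' lines intersect the axis-aligned square \code{[0, l]^2}. Used as the
#' Monte-Carlo oracle behind \code{\link{max_bandwidth}}.
#'
#' @param omega numeric length-2 frequency vector.
#' @param d numeric length-2 user location.
#' @param l square side length.
#' @return Integer band count.
#' @export
count_bands <- function(omega, d, l) {
  omega <- as.numeric(omega)
  stopifnot(length(omega) == 2, length(d) == 2, l > 0)
  corners <- rbind(c(0, 0), c(l, 0), c(0, l), c(l, l))
  s <- as.numeric(corners %*% omega)
  t0 <- sum(omega * d)
  lo <- ceiling((min(s) - t0) / (2 * pi))
  hi <- floor((max(s) - t0) / (2 * pi))
  max(0L, hi - lo + 1L)
}

#' Construct a user-side bandwidth/feature policy
#'
#' The policy a user enforces unilaterally against an adaptive server:
#' queried bandwidths must not exceed \code{max_bandwidth(gamma, j, l)} and
#' must belong to the rescaling set \eqn{\{(4n+1) h_0 : n \ge 0\}}, which
#' guarantees that responses at different bandwidths share multiple invariant
#' bands (so cross-bandwidth comparison cannot single out the user's band);
#' the feature count must not exceed \code{B_max}. Refusal depends only on
#' the policy parameters, never on the user's location.
#'
#' @param h0 base bandwidth at which the user's frequencies were drawn.
#' @param gamma risk parameter of the band-count guarantee.
#' @param j minimum band count (integer >= 2).
#' @param l inscribed-square side of the query area.
#' @param B_max maximum feature count per user.
#' @return An object of class \code{bandwidth_policy} (with computed
#'   \code{h_max}).
#' @export
bandwidth_policy <- function(h0, gamma, j, l, B_max) {
  if (!is.numeric(h0) || length(h0) != 1 || h0 <= 0)
    stop("h0 must be positive")
  B_max <- as.integer(B_max)
  if (is.na(B_max) || B_max < 1) stop("B_max must be an integer >= 1")
  structure(list(h0 = h0, gamma = gamma, j = as.integer(j), l = l,
                 B_max = B_max, h_max = max_bandwidth(gamma, j, l)),
            class = "bandwidth_policy")
}

#' @export
print.bandwidth_policy <- function(x, ...) {
  cat(sprintf(
    "bandwidth policy: h0 = %g, allowed h in {(4n+1)h0} up to h_max = %.6g\n",
    x$h0, x$h_max))
  cat(sprintf("  gamma = %g, j = %d, l = %g, B_max = %d\n",
              x$gamma, x$j, x$l, x$B_max))
  invisible(x)
}

#' Validate a server query against a policy
#'
#' Accepts iff \code{h <= h_max}, \code{h} lies in the rescaling set
#' \code{(4n+1)*h0} for a nonnegative integer n (relative tolerance 1e-9, to
#' absorb decimal round-trips through config files), and \code{B <= B_max}.
#' Refusal is a value (with a reason code), not an error, and carries no
#' information about the user's location. \code{n = 0} (the base bandwidth
#' itself) is allowed.
#'
#' @param policy a \code{bandwidth_policy}.
#' @param h queried bandwidth.
#' @param B queried feature count.
#' @return A list with \code{accepted} (logical) and \code{reason} (string,
#'   \code{"ok"} when accepted).
#' @export
validate_query <- function(policy, h, B) {
  stopifnot(inherits(policy, "bandwidth_policy"))
  decision <- function(ok, reason)
    structure(list(accepted = ok, reason = reason, h = h, B = B),
              class = "query_decision")
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    return(decision(FALSE, "bandwidth_not_positive"))
  if (h > policy$h_max * (1 + 1e-9))
    return(decision(FALSE, "bandwidth_exceeds_maximum"))
  n <- (h / policy$h0 - 1) / 4
  n_int <- round(n)
  in_set <- n_int >= 0 &&
    abs(h - (4 * n_int + 1) * policy$h0) <= 1e-9 * max(h, policy$h0)
  if (!in_set)
    return(decision(FALSE, "bandwidth_not_in_policy_set"))
  if (as.integer(B) > policy$B_max)
    return(decision(FALSE, "feature_count_exceeds_maximum"))
  decision(TRUE, "ok")
}

#' @export
print.query_decision <- function(x, ...) {
  if (x$accepted) cat(sprintf("query accepted (h = %g, B = %d)\n", x$h, x$B))
  else cat(sprintf("query refused (h = %g, B = %d): %s\n", x$h, x$B, x$reason))
  invisible(x)
}

#' User-side response cost of a query
#'
#' Basis-function evaluation count for one response: \code{P * Q * B} (the
#' protocol's per-user complexity is linear in grid size and feature count;
#' exact KDE corresponds to \code{B = 1} kernel evaluations per node).
#'
#' @param grid a \code{grid_spec}.
#' @param B features per user.
#' @return Integer operation count.
#' @export
response_cost <- function(grid, B) {
  stopifnot(inherits(grid, "grid_spec"))
  nq <- if (grid_dim(grid) == 1L) 1L else grid$q
  as.numeric(grid$p) * nq * as.integer(B)
}
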