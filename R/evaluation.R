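#' Rank-correlation utility between two surfaces
#'
#' Spearman correlation between two surfaces flattened over grid nodes
#' (average ranks for ties). Rank correlation is the utility metric of
#' choice here because it is invariant to the monotone rescalings that
#' separate unnormalized kernel means from true densities.
#'
#' @param a,b \code{rff_surface} objects on the same grid.
#' @return Correlation in \code{[-1, 1]}.
#' @export
spearman_surface <- function(a, b) {
  stopifnot(inherits(a, "rff_surface"), inherits(b, "rff_surface"))
  if (!same_grid(a$grid, b$grid)) stop("surfaces are on different grids")
  va <- as.vector(a$values); vb <- as.vector(b$values)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop(structure(class = c("rffkde_constant_surface", "error", "condition"),
                   list(message = "rank correlation undefined for a constant surface",
                        call = sys.call(-1))))
  stats::cor(va, vb, method = "spearman")
}

kth_nn_dist <- function(P, Q, k, exclude_self) {
  # for each row of P, distance to its k-th nearest neighbor among rows of Q
  q2 <- rowSums(Q^2)
  vapply(seq_len(nrow(P)), function(i) {
    d2 <- pmax(0, q2 - 2 * as.numeric(Q %*% P[i, ]) + sum(P[i, ]^2))
    d <- sqrt(d2)
    kk <- if (exclude_self) k + 1L else k
    sort(d, partial = kk)[kk]
  }, numeric(1))
}

#' Data-driven bandwidth selection
#'
#' The k-nearest-neighbor heuristic: draw a fraction of the data without
#' replacement, compute each selected point's distance to its k-th nearest
#' neighbor (self excluded) within the subsample, and return the mean.
#' Defaults follow the synthetic-study settings (\code{k = 200},
#' \code{fraction = 0.1}); \code{k = 500} suits dense check-in data. Set
#' \code{pool = "full"} to search neighbors in the complete dataset instead
#' of the subsample.
#'
#' @param points N x dim matrix of locations.
#' @param k neighbor order.
#' @param fraction subsample fraction in (0, 1].
#' @param seed optional seed for the subsample draw.
#' @param pool \code{"subsample"} (default) or \code{"full"}.
#' @return The selected bandwidth (map units).
#' @export
select_bandwidth <- function(points, k = 200L, fraction = 0.1, seed = NULL,
                             pool = c("subsample", "full")) {
  pool <- match.arg(pool)
  X <- as_points_matrix(points)
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be an integer >= 1")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- ceiling(fraction * nrow(X))
  if (m <= k) stop("subsample size must exceed k")
  if (!is.null(seed)) {
    reset <- restore_rng(); on.exit(reset())
    set.seed(seed)
  }
  idx <- sample.int(nrow(X), m)
  S <- X[idx, , drop = FALSE]
  Q <- if (pool == "subsample") S else X
  mean(kth_nn_dist(S, Q, k, exclude_self = TRUE))
}

default_grid <- function(mixture_name) {
  switch(mixture_name,
         grid9 = grid_spec(c(-3, 3), 50, c(-3, 3), 50),
         octagon8 = grid_spec(c(-5, 5), 100, c(-5, 5), 100),
         tri1d = grid_spec(c(-15, 15), 1000),
         stop(sprintf("no default grid for mixture '%s'", mixture_name)))
}

sweep_cell <- function(method, param, X, grid, h, seed, ref, truth,
                       epsilon_filter) {
  if (method == "zero") {
    priv <- mean(privacy_scores(X, grid, "zero")$Z)
    return(list(utility = NA_real_, privacy = priv))
  }
  if (method == "exact") {
    surf <- federated_kde(X, grid, h)
    priv <- mean(privacy_scores(X, grid, "exact", h = h,
                                epsilon_filter = epsilon_filter)$Z)
  } else if (method == "rff") {
    surf <- federated_rff_kde(X, grid, h, B = param, h0 = h, seed = seed)
    priv <- mean(privacy_scores(X, grid, "rff", h = h, B = param, h0 = h,
                                seed = seed,
                                epsilon_filter = epsilon_filter)$Z)
  } else if (method == "geoind") {
    pert <- geoind_perturb(X, param, seed = seed)
    surf <- federated_kde(pert, grid, h)
    priv <- mean(privacy_scores(X, grid, "exact", h = h,
                                epsilon_filter = epsilon_filter,
                                surf_points = pert)$Z)
  } else stop(sprintf("unknown method '%s'", method))
  list(utility = spearman_surface(surf, ref), privacy = priv)
}

#' Privacy-utility trade-off sweep
#'
#' The evaluation harness: for every combination of method, method
#' parameter, sample size and seed it generates a dataset from the mixture,
#' builds the estimated surface, scores utility (Spearman against the
#' reference) and system privacy (mean localization-attack score over all
#' users), and emits one record. Methods covered: exact federated KDE
#' (best-case utility / zero privacy), federated RFF KDE over \code{b_list},
#' the GeoInd planar-Laplace baseline over \code{epsilon_list}, and the
#' zero-feature baseline (best-case privacy; its constant surface has no
#' defined utility and is recorded as \code{NA}).
#'
#' @param mixture a mixture name (\code{"grid9"}, \code{"octagon8"},
#'   \code{"tri1d"}) or a \code{mixture_spec}.
#' @param n_list integer vector of sample sizes.
#' @param seeds integer vector of replicate seeds.
#' @param grid a \code{grid_spec}; defaults to the study grid when a
#'   built-in mixture name is given.
#' @param h numeric bandwidth, or \code{"auto"} for the k-NN heuristic.
#' @param b_list feature counts for the RFF method (empty to skip).
#' @param epsilon_list GeoInd privacy parameters (empty to skip).
#' @param include_exact,include_zero include the two baselines.
#' @param reference \code{"truth"} (mixture density; synthetic mode) or
#'   \code{"kde"} (pooled exact-KDE surface; the real-data convention).
#' @param k neighbor order for automatic bandwidth selection.
#' @param epsilon_filter attack filter parameter.
#' @return A data frame of records: \code{method}, \code{param} (B or
#'   epsilon, \code{NA} for baselines), \code{n}, \code{seed}, \code{h},
#'   \code{utility}, \code{privacy}.
#' @export
tradeoff_sweep <- function(mixture, n_list, seeds, grid = NULL, h = "auto",
                           b_list = integer(), epsilon_list = numeric(),
                           include_exact = TRUE, include_zero = TRUE,
                           reference = c("truth", "kde"), k = 200L,
                           epsilon_filter = 1.1) {
  reference <- match.arg(reference)
  if (is.character(mixture)) {
    if (is.null(grid)) grid <- default_grid(mixture)
    mixture <- builtin_mixture(mixture)
  }
  stopifnot(inherits(mixture, "mixture_spec"))
  if (is.null(grid)) stop("grid is required for a custom mixture_spec")
  if (length(epsilon_list) && grid_dim(grid) != 2L)
    stop("the GeoInd baseline is 2D only")
  truth <- if (reference == "truth") mixture_density(mixture, grid) else NULL
  cells <- list()
  if (include_exact) cells <- c(cells, list(list("exact", NA_real_)))
  for (b in b_list) cells <- c(cells, list(list("rff", as.numeric(b))))
  for (e in epsilon_list) cells <- c(cells, list(list("geoind", e)))
  if (include_zero) cells <- c(cells, list(list("zero", NA_real_)))
  if (!length(cells)) stop("no methods requested")
  rows <- list()
  for (n in n_list) {
    for (seed in seeds) {
      X <- sample_mixture(mixture, n, seed = seed)
      h_use <- if (identical(h, "auto"))
        select_bandwidth(X, k = k, fraction = 0.1, seed = seed)
      else as.numeric(h)
      ref <- if (reference == "truth") truth
             else federated_kde(X, grid, h_use)
      for (cell in cells) {
        res <- sweep_cell(cell[[1]], cell[[2]], X, grid, h_use, seed, ref,
                          truth, epsilon_filter)
        rows[[length(rows) + 1L]] <-
          data.frame(method = cell[[1]], param = cell[[2]], n = n,
                     seed = seed, h = h_use, utility = res$utility,
                     privacy = res$privacy)
      }
    }
  }
  do.call(rbind, rows)
}

#' Utility gain per unit privacy cost of extra features
#'
#' For RFF records, compares each feature count \code{B > 1} against the
#' single-feature baseline: gain is the median-utility increase
#' \eqn{u(B) - u(1)}, cost is the privacy give-up \eqn{Z(1) - Z(B)} (scores
#' fall as features are added, so this is nonnegative), and the ratio is
#' gain per unit cost. A zero cost with positive gain yields \code{Inf}
#' rather than an error. Medians are taken over seeds within each
#' \code{(n, B)} group.
#'
#' @param records a record data frame from \code{\link{tradeoff_sweep}}
#'   (only \code{method == "rff"} rows are used) containing \code{B = 1}.
#' @return Data frame with \code{n}, \code{B}, \code{gain}, \code{cost},
#'   \code{ratio} for each \code{B > 1}.
#' @export
gain_per_cost <- function(records) {
  r <- records[records$method == "rff", , drop = FALSE]
  if (!nrow(r)) stop("no rff records")
  agg <- stats::aggregate(cbind(utility, privacy) ~ n + param, data = r,
                          FUN = stats::median)
  out <- list()
  for (n in unique(agg$n)) {
    a <- agg[agg$n == n, , drop = FALSE]
    base <- a[a$param == 1, , drop = FALSE]
    if (!nrow(base)) stop("records must include the B = 1 baseline")
    for (i in which(a$param > 1)) {
      gain <- a$utility[i] - base$utility[1]
      cost <- base$privacy[1] - a$privacy[i]
      ratio <- if (cost == 0) {
        if (gain > 0) Inf else if (gain < 0) -Inf else NaN
      } else gain / cost
      out[[length(out) + 1L]] <-
        data.frame(n = n, B = a$param[i], gain = gain, cost = cost,
                   ratio = ratio)
    }
  }
  do.call(rbind, out)
}
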