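# Shared in-code fixtures for the suite.

grid_2d_small <- function() grid_spec(c(-3, 3), 25, c(-3, 3), 25)
grid_1d_attack <- function() grid_spec(c(-15, 15), 1000)
study_grid_a <- function() grid_spec(c(-3, 3), 50, c(-3, 3), 50)

# RMSE between two aligned surfaces
surf_rmse <- function(a, b) sqrt(mean((a$values - b$values)^2))

# brute-force local maxima of a 1D series: value >= existing neighbors,
# plateau representative = first index of a run of equal qualifying cells
brute_maxima_1d <- function(v) {
  n <- length(v)
  ok <- vapply(seq_len(n), function(i) {
    (i == 1 || v[i] >= v[i - 1]) && (i == n || v[i] >= v[i + 1])
  }, logical(1))
  idx <- which(ok)
  keep <- idx[c(TRUE, diff(idx) > 1 | v[idx[-1]] != v[idx[-length(idx)]])]
  keep
}
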