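provenance <- function(extra = list()) {
  c(list(package = "rffkde",
         version = as.character(utils::packageVersion("rffkde"))),
    extra)
}

#' Read a location dataset from CSV
#'
#' Expects a header line \code{x} (1D), \code{x,y} (2D) or \code{lat,lon}
#' (check-in convention; mapped to planar coordinates with \code{x = lon},
#' \code{y = lat} — coordinates are treated as planar, not geodesic).
#' Malformed rows are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return An N x dim numeric matrix of locations.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  header <- tolower(gsub("[\" ]", "", lines[1]))
  swap <- FALSE
  dim <- switch(header,
                "x" = 1L, "x,y" = 2L,
                "lat,lon" = { swap <- TRUE; 2L },
                stop(sprintf(
                  "%s: line 1: header must be 'x', 'x,y' or 'lat,lon', got '%s'",
                  path, lines[1])))
  body <- lines[-1]
  if (!length(body)) stop(sprintf("%s: no data rows", path))
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != dim)
  if (length(bad))
    stop(sprintf("%s: line %s: expected %d field(s)", path,
                 paste(bad + 1L, collapse = ", "), dim))
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = dim, byrow = TRUE))
  bad <- which(apply(!is.finite(vals), 1, any))
  if (length(bad))
    stop(sprintf("%s: line %s: non-numeric value", path,
                 paste(bad + 1L, collapse = ", ")))
  if (swap) vals <- vals[, c(2, 1), drop = FALSE]   # (lat,lon) -> (x=lon, y=lat)
  vals
}

#' Write a location dataset to CSV
#'
#' @param points N x dim matrix of locations.
#' @param path output CSV path (header \code{x} or \code{x,y}).
#' @return The path, invisibly.
#' @export
write_dataset <- function(points, path) {
  X <- as_points_matrix(points)
  header <- if (ncol(X) == 1L) "x" else "x,y"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(X, 1, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = ",")), con)
  invisible(path)
}

#' Write a surface as CSV plus JSON sidecar
#'
#' The value matrix goes to \code{<prefix>.csv} (P rows, Q columns, no
#' headers); the grid specification, metadata and provenance go to
#' \code{<prefix>.json}.
#'
#' @param surf an \code{rff_surface}.
#' @param prefix output path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_surface <- function(surf, prefix) {
  stopifnot(inherits(surf, "rff_surface"))
  utils::write.table(surf$values, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  g <- surf$grid
  side <- provenance(list(
    grid = list(x_range = g$x_range, p = g$p,
                y_range = g$y_range, q = g$q),
    meta = surf$meta))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Read a surface written by \code{write_surface}
#' @param prefix path prefix used when writing.
#' @return The reconstructed \code{rff_surface}.
#' @export
read_surface <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  g <- side$grid
  grid <- grid_spec(g$x_range, g$p,
                    if (is.null(g$y_range)) NULL else g$y_range, g$q)
  vals <- as.matrix(utils::read.table(paste0(prefix, ".csv"), sep = ","))
  dimnames(vals) <- NULL
  meta <- side$meta
  surface(vals, grid, meta = if (is.null(meta)) list() else as.list(meta))
}

#' Write a bandwidth policy to JSON
#' @param policy a \code{bandwidth_policy}.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "bandwidth_policy"))
  jsonlite::write_json(
    provenance(list(h0 = policy$h0, gamma = policy$gamma, j = policy$j,
                    l = policy$l, B_max = policy$B_max)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bandwidth policy from JSON
#' @param path JSON path written by \code{write_policy}.
#' @return A \code{bandwidth_policy}.
#' @export
read_policy <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  bandwidth_policy(p$h0, p$gamma, p$j, p$l, p$B_max)
}

#' Write a per-user attack score table to CSV
#'
#' @param scores the data frame returned by \code{\link{privacy_scores}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one user's attack report to JSON
#'
#' @param report an \code{attack_report}.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_attack_report <- function(report, path) {
  stopifnot(inherits(report, "attack_report"))
  jsonlite::write_json(
    provenance(list(Z = report$Z, epsilon_filter = report$epsilon_filter,
                    fallback = report$fallback, maxima = report$maxima)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
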