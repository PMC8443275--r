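#' Delaunay triangulation of a nuclei point pattern
#'
#' Triangulates cell-nuclei centroids so that per-cell local density can be
#' read off the areas of the triangles incident to each nucleus. Exact
#' duplicate points are removed with a warning (they make the
#' triangulation ill-defined); triangles whose area falls below
#' `degenerate_tol` are dropped and their number reported.
#'
#' @param pattern A [point_pattern()], or a two-column matrix/data frame of
#'   x/y coordinates in um.
#' @param degenerate_tol Absolute area tolerance (um^2) below which a
#'   triangle is treated as degenerate and removed.
#' @return An object of class `delaunay_tri`: `points` (n x 2 matrix),
#'   `triangles` (m x 3 matrix of 1-based vertex indices), `areas` (um^2),
#'   `hull` (logical, convex-hull membership per point), `n_degenerate`,
#'   and `dedup_map` mapping original rows to retained points.
#' @examples
#' tri <- triangulate(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
#' tri$areas
#' @export
triangulate <- function(pattern, degenerate_tol = 1e-12) {
  xy <- as_coord_matrix(pattern)
  if (anyNA(xy)) stopf("coordinates must not contain NA")
  key <- paste(xy[, 1], xy[, 2], sep = "\r")
  keep <- !duplicated(key)
  dedup_map <- match(key, key[keep])
  if (any(!keep))
    warnf("removed %d exact duplicate point(s) before triangulation",
          sum(!keep))
  pts <- xy[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) stopf("triangulation undefined: fewer than 3 distinct points")
  tri <- delaunay_bw(pts)
  if (nrow(tri) == 0)
    stopf("triangulation undefined: points are collinear")
  areas <- triangle_areas(pts, tri)
  degen <- areas < degenerate_tol
  if (any(degen)) {
    message(sprintf("removed %d degenerate triangle(s) below area %g um^2",
                    sum(degen), degenerate_tol))
    tri <- tri[!degen, , drop = FALSE]
    areas <- areas[!degen]
  }
  hull <- rep(FALSE, n)
  hull[chull(pts)] <- TRUE
  structure(
    list(points = pts, triangles = tri, areas = areas, hull = hull,
         n_degenerate = sum(degen), dedup_map = dedup_map),
    class = "delaunay_tri")
}

#' @export
print.delaunay_tri <- function(x, ...) {
  cat(sprintf("delaunay_tri: %d points, %d triangles (%d on hull)\n",
              nrow(x$points), nrow(x$triangles), sum(x$hull)))
  invisible(x)
}

#' @noRd
as_coord_matrix <- function(pattern) {
  if (inherits(pattern, "point_pattern"))
    return(cbind(pattern$points$x_um, pattern$points$y_um))
  m <- as.matrix(pattern)
  if (ncol(m) < 2) stopf("need a two-column coordinate matrix")
  storage.mode(m) <- "double"
  m[, 1:2, drop = FALSE]
}

#' @noRd
triangle_areas <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
}

#' Per-cell local density from a Delaunay triangulation
#'
#' For each nucleus, the triangles sharing that vertex define a local
#' neighbourhood; their areas `A(i)`, `i = 1..n`, yield the local density.
#' Two published readings of the statistic are supported:
#'
#' * `inverse_of_sum` (default): `rho = 1 / sum(A(i))` — the reciprocal of
#'   the total incident area, i.e. the prose definition "the inverse of
#'   this sum".
#' * `sum_of_inverses`: `rho = sum(1 / A(i))` — the literal typeset
#'   formula.
#'
#' For a vertex incident to a single triangle the two coincide. Convex-hull
#' cells are computed but flagged, because their incident fan is truncated
#' by the field edge and their density is biased; group comparisons exclude
#' them by default.
#'
#' @param tri A `delaunay_tri` from [triangulate()].
#' @param variant Which formula reading to use; recorded in the output.
#' @return A data frame with one row per distinct point: `point_id`,
#'   `x_um`, `y_um`, `rho` (um^-2, `NA` when the point has no incident
#'   triangle), `n_incident`, `hull_flag`, `variant`.
#' @examples
#' tri <- triangulate(cbind(c(0, 1, 0), c(0, 0, 1)))
#' local_density(tri)$rho # each vertex: 1 / 0.5 = 2
#' @export
local_density <- function(tri,
                          variant = c("inverse_of_sum", "sum_of_inverses")) {
  stopifnot(inherits(tri, "delaunay_tri"))
  variant <- match.arg(variant)
  n <- nrow(tri$points)
  m <- nrow(tri$triangles)
  vert <- as.vector(tri$triangles)          # 3m vertex incidences
  tri_of <- rep(seq_len(m), times = 3)
  n_inc <- tabulate(vert, nbins = n)
  u <- unique(vert)
  if (variant == "inverse_of_sum") {
    sumA <- numeric(n)
    sumA[u] <- as.vector(rowsum(tri$areas[tri_of], vert, reorder = FALSE))
    rho <- ifelse(n_inc > 0, 1 / sumA, NA_real_)
  } else {
    sumInv <- numeric(n)
    sumInv[u] <- as.vector(rowsum(1 / tri$areas[tri_of], vert,
                                  reorder = FALSE))
    rho <- ifelse(n_inc > 0, sumInv, NA_real_)
  }
  data.frame(point_id = seq_len(n),
             x_um = tri$points[, 1], y_um = tri$points[, 2],
             rho = rho, n_incident = n_inc, hull_flag = tri$hull,
             variant = variant, stringsAsFactors = FALSE)
}

#' Local density of every cell in a point pattern, by subline
#'
#' Convenience wrapper: triangulates the pattern and joins the per-cell
#' density back onto the subline and caspase labels.
#'
#' @param pattern A [point_pattern()].
#' @inheritParams local_density
#' @return The [local_density()] data frame with `subline` and
#'   `caspase_pos` columns added (duplicated points inherit the density of
#'   their retained copy).
#' @export
pattern_density <- function(pattern,
                            variant = c("inverse_of_sum",
                                        "sum_of_inverses")) {
  stopifnot(inherits(pattern, "point_pattern"))
  variant <- match.arg(variant)
  tri <- triangulate(pattern)
  dens <- local_density(tri, variant)
  out <- dens[tri$dedup_map, , drop = FALSE]
  out$point_id <- seq_len(nrow(out))
  out$subline <- pattern$points$subline
  out$caspase_pos <- pattern$points$caspase_pos
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of density distributions
#'
#' Compares two groups of per-cell local densities (e.g. wild-type cells
#' in separate culture vs in co-culture) with the two-sample KS statistic
#' `D = sup |F1 - F2|` and its asymptotic p-value. `NA` densities
#' (undefined cells) are dropped.
#'
#' @param x,y Numeric vectors of per-cell densities.
#' @return A list with `D`, `p`, `n1`, `n2`.
#' @examples
#' compare_density(rnorm(50), rnorm(50, 2))
#' @export
compare_density <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stopf("each group needs at least 2 defined densities")
  D <- ks_statistic(x, y)
  n1 <- length(x); n2 <- length(y)
  en <- n1 * n2 / (n1 + n2)
  p <- ks_p_asymptotic(sqrt(en) * D)
  list(D = D, p = p, n1 = n1, n2 = n2)
}

# Exact two-sample KS statistic: maximum ECDF gap over the pooled sample,
# evaluated by a sorted merge walk (ties handled by grouping equal values).
#' @noRd
ks_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  g <- c(rep(1L, n1), rep(2L, n2))
  o <- order(v)
  v <- v[o]; g <- g[o]
  # cumulative gap F1 - F2 after each pooled order statistic
  cum <- cumsum(ifelse(g == 1L, 1 / n1, -1 / n2))
  # at tied values only the state after the whole tie group counts
  last_of_run <- c(v[-1] != v[-length(v)], TRUE)
  max(abs(cum[last_of_run]))
}

# Asymptotic Kolmogorov tail Q(lambda) = 2 * sum_{j>=1} (-1)^{j-1} e^{-2 j^2 lambda^2}
#' @noRd
ks_p_asymptotic <- function(lambda, terms = 100L) {
  if (lambda < 1e-8) return(1)
  j <- seq_len(terms)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Write a per-cell density table to CSV
#'
#' @param density Data frame from [pattern_density()] or [local_density()].
#' @param path Output CSV path.
#' @export
write_density <- function(density, path) {
  write.csv(density, path, row.names = FALSE)
  invisible(path)
}
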