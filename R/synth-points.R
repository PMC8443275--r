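#' Imaging field specification
#'
#' Describes the physical field of view that synthetic patterns and images
#' are generated on.
#'
#' @param width,height Field extent in micrometres.
#' @param pixel_size Pixel edge length in micrometres per pixel (used only
#'   when rendering raster images).
#' @param seed Integer seed; identical seeds give bit-identical output from
#'   every generator that consumes it.
#' @return An object of class `field_spec`.
#' @examples
#' field_spec(1000, 1000, pixel_size = 0.5, seed = 1)
#' @export
field_spec <- function(width, height, pixel_size = 0.5, seed = 1L) {
  check_positive(width, "width")
  check_positive(height, "height")
  check_positive(pixel_size, "pixel_size")
  structure(
    list(width = width, height = height, pixel_size = pixel_size,
         seed = as.integer(seed)),
    class = "field_spec")
}

#' Parameters for synthetic nuclei point patterns
#'
#' Controls the spatial layout of two co-cultured sublines ("winner" and
#' "loser") and the apoptosis-marker (cleaved caspase-3) positivity model.
#'
#' @param n_winner,n_loser Number of cells of each subline.
#' @param mode `"uniform"` (both sublines homogeneous over the field),
#'   `"corralled"` (losers confined to high-density discs, winners uniform)
#'   or `"confrontation"` (sublines in opposing half-planes separated by a
#'   gap, as when a removable culture insert has just been lifted).
#' @param cluster_radius,cluster_count Corralled mode: losers are placed
#'   uniformly inside `cluster_count` discs of radius `cluster_radius` um
#'   whose centres are themselves uniform over the field (a Matern-cluster
#'   style construction).
#' @param gap_width Confrontation mode: width of the cell-free gap between
#'   the two populations, in um. The default 500 um matches the defined gap
#'   left by a standard two-well silicone insert.
#' @param apoptosis_base_rate Baseline probability that any cell is
#'   caspase-positive.
#' @param apoptosis_amplitude Confrontation mode: added positivity for
#'   loser cells at the border; decays into loser territory.
#' @param apoptosis_decay_length Confrontation mode: e-folding length (um)
#'   of the added loser positivity with distance from the border.
#' @return An object of class `pattern_params`.
#' @export
pattern_params <- function(n_winner, n_loser,
                           mode = c("uniform", "corralled", "confrontation"),
                           cluster_radius = 50, cluster_count = 4L,
                           gap_width = 500,
                           apoptosis_base_rate = 0.05,
                           apoptosis_amplitude = 0.4,
                           apoptosis_decay_length = 100) {
  mode <- match.arg(mode)
  if (n_winner < 0 || n_loser < 0)
    stopf("cell counts must be non-negative")
  check_positive(cluster_radius, "cluster_radius")
  if (cluster_count < 1) stopf("`cluster_count` must be >= 1")
  check_positive(gap_width, "gap_width")
  check_prob(apoptosis_base_rate, "apoptosis_base_rate")
  check_prob(apoptosis_amplitude, "apoptosis_amplitude")
  check_positive(apoptosis_decay_length, "apoptosis_decay_length")
  structure(
    list(n_winner = as.integer(n_winner), n_loser = as.integer(n_loser),
         mode = mode, cluster_radius = cluster_radius,
         cluster_count = as.integer(cluster_count), gap_width = gap_width,
         apoptosis_base_rate = apoptosis_base_rate,
         apoptosis_amplitude = apoptosis_amplitude,
         apoptosis_decay_length = apoptosis_decay_length),
    class = "pattern_params")
}

#' Construct a nuclei point pattern
#'
#' A `point_pattern` is the centroid-table substrate of the density and
#' border analyses: per-cell x/y in micrometres, subline label and
#' caspase-positivity flag, plus the field bounds.
#'
#' @param x,y Coordinates in um.
#' @param subline Character/factor label per point (`"winner"`/`"loser"`).
#' @param caspase_pos Logical per point.
#' @param bounds Numeric `c(width, height)` in um.
#' @param border_x True interface x-position (um) when known, else `NA`.
#' @param mode Generation mode, for provenance.
#' @return An object of class `point_pattern` with a `points` data frame.
#' @export
point_pattern <- function(x, y, subline, caspase_pos = rep(FALSE, length(x)),
                          bounds, border_x = NA_real_, mode = "unknown") {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) stopf("coordinates must not contain NA")
  if (length(x) > 0 &&
      (any(x < 0 | x > bounds[1]) || any(y < 0 | y > bounds[2])))
    stopf("points fall outside the stated bounds")
  structure(
    list(points = data.frame(x_um = x, y_um = y,
                             subline = as.character(subline),
                             caspase_pos = as.logical(caspase_pos),
                             stringsAsFactors = FALSE),
         bounds = as.numeric(bounds), border_x = border_x, mode = mode),
    class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d cells (%s) on %g x %g um field\n",
              nrow(x$points),
              paste(sprintf("%s=%d", names(table(x$points$subline)),
                            as.integer(table(x$points$subline))),
                    collapse = ", "),
              x$bounds[1], x$bounds[2]))
  if (!is.na(x$border_x))
    cat(sprintf("  interface at x = %g um (mode %s)\n", x$border_x, x$mode))
  invisible(x)
}

#' Generate a synthetic nuclei point pattern
#'
#' Draws winner and loser nuclei positions under one of three spatial
#' regimes and assigns caspase-positivity flags. In `uniform` and
#' `corralled` modes every cell is positive with `apoptosis_base_rate`;
#' in `confrontation` mode loser cells follow
#' `p(d) = base + amplitude * exp(-d / decay_length)` where `d >= 0` is the
#' perpendicular distance from the border into loser territory, emulating
#' the elevated apoptosis observed near a confrontation front.
#'
#' @param field A [field_spec()]; its `seed` drives all randomness.
#' @param params A [pattern_params()].
#' @param border_x Confrontation mode only: interface x-position in um
#'   (default: field midline). Winners occupy `x < border_x - gap/2`,
#'   losers `x > border_x + gap/2`.
#' @return A [point_pattern()]. Zero total cells gives an empty pattern.
#' @examples
#' fld <- field_spec(1000, 1000, seed = 7)
#' pp <- make_point_pattern(fld, pattern_params(200, 200, "corralled"))
#' pp
#' @export
make_point_pattern <- function(field, params, border_x = NULL) {
  stopifnot(inherits(field, "field_spec"), inherits(params, "pattern_params"))
  w <- field$width; h <- field$height
  with_seed(field$seed, {
    bx <- NA_real_
    if (params$mode == "uniform") {
      xw <- runif(params$n_winner, 0, w); yw <- runif(params$n_winner, 0, h)
      xl <- runif(params$n_loser, 0, w);  yl <- runif(params$n_loser, 0, h)
    } else if (params$mode == "corralled") {
      xw <- runif(params$n_winner, 0, w); yw <- runif(params$n_winner, 0, h)
      cl <- sample_cluster_points(params$n_loser, params$cluster_count,
                                  params$cluster_radius, w, h)
      xl <- cl$x; yl <- cl$y
    } else { # confrontation
      bx <- border_x %||% (w / 2)
      half <- params$gap_width / 2
      if (bx - half <= 0 || bx + half >= w)
        stopf("gap of %g um around border_x = %g does not fit in the field",
              params$gap_width, bx)
      xw <- runif(params$n_winner, 0, bx - half)
      yw <- runif(params$n_winner, 0, h)
      xl <- runif(params$n_loser, bx + half, w)
      yl <- runif(params$n_loser, 0, h)
    }
    cw <- runif(params$n_winner) < params$apoptosis_base_rate
    if (params$mode == "confrontation") {
      d <- xl - bx # distance into loser territory, always > gap/2 here
      p <- pmin(params$apoptosis_base_rate +
                  params$apoptosis_amplitude *
                  exp(-d / params$apoptosis_decay_length), 1)
      cl_pos <- runif(params$n_loser) < p
    } else {
      cl_pos <- runif(params$n_loser) < params$apoptosis_base_rate
    }
    point_pattern(
      x = c(xw, xl), y = c(yw, yl),
      subline = rep(c("winner", "loser"), c(params$n_winner, params$n_loser)),
      caspase_pos = c(cw, cl_pos),
      bounds = c(w, h), border_x = bx, mode = params$mode)
  })
}

# Matern-cluster style draw: parent centres uniform over the field,
# offspring uniform in the disc, resampled until inside the field.
#' @noRd
sample_cluster_points <- function(n, k, radius, w, h) {
  px <- runif(k, 0, w); py <- runif(k, 0, h)
  parent <- sample.int(k, n, replace = TRUE)
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    m <- length(todo)
    r <- radius * sqrt(runif(m))
    th <- runif(m, 0, 2 * pi)
    cx <- px[parent[todo]] + r * cos(th)
    cy <- py[parent[todo]] + r * sin(th)
    ok <- cx >= 0 & cx <= w & cy >= 0 & cy <= h
    x[todo[ok]] <- cx[ok]; y[todo[ok]] <- cy[ok]
    todo <- todo[!ok]
  }
  list(x = x, y = y)
}
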