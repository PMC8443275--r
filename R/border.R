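#' Signed distance of each cell to the confrontation border
#'
#' In a confrontation assay two populations meet at a near-straight
#' interface; every cell is assigned a positional identity as its
#' perpendicular signed distance to that line. The sign convention is
#' positive into the territory of the focal (loser) population.
#'
#' When `border = "estimate"` the interface is placed at the midpoint
#' between the opposing fronts: the focal population's 5th-percentile
#' advance and the other population's 95th-percentile advance along x
#' (robust to straggler cells that have crossed the line).
#'
#' @param pattern A [point_pattern()] with two subline labels.
#' @param border Either a numeric x-position in um, or `"estimate"`.
#' @param focal Subline whose territory carries positive sign
#'   (default `"loser"`).
#' @return Numeric vector of signed distances (um), one per cell, with the
#'   border position used attached as attribute `border_x`.
#' @export
assign_border_distance <- function(pattern, border = "estimate",
                                   focal = "loser") {
  stopifnot(inherits(pattern, "point_pattern"))
  pts <- pattern$points
  if (!focal %in% pts$subline)
    stopf("focal subline '%s' absent from the pattern", focal)
  if (identical(border, "estimate")) {
    bx <- estimate_border(pattern, focal)
  } else {
    bx <- as.numeric(border)
    if (is.na(bx) || bx < 0 || bx > pattern$bounds[1])
      stopf("supplied border position must lie within the field bounds")
  }
  focal_right <- mean(pts$x_um[pts$subline == focal]) >= bx
  d <- if (focal_right) pts$x_um - bx else bx - pts$x_um
  attr(d, "border_x") <- bx
  d
}

# Midpoint between the opposing 5th/95th-percentile fronts along x.
#' @noRd
estimate_border <- function(pattern, focal = "loser") {
  pts <- pattern$points
  subs <- unique(pts$subline)
  if (length(subs) < 2)
    stopf("border estimation needs two populations")
  xf <- pts$x_um[pts$subline == focal]
  xo <- pts$x_um[pts$subline != focal]
  if (mean(xf) >= mean(xo)) {
    # focal on the right: its front is its low quantile
    (quantile(xf, 0.05, names = FALSE) +
       quantile(xo, 0.95, names = FALSE)) / 2
  } else {
    (quantile(xf, 0.95, names = FALSE) +
       quantile(xo, 0.05, names = FALSE)) / 2
  }
}

#' Binned caspase-positive fraction versus distance to the border
#'
#' Bins the signed border distances into contiguous intervals of
#' `bin_width` um and reports, per bin, the total cell count, the
#' caspase-positive count and the positive fraction (the per-area
#' percentage construction of a confrontation-assay profile).
#'
#' @param pattern A [point_pattern()].
#' @param distances Signed distances from [assign_border_distance()].
#' @param bin_width Bin width in um (default 50).
#' @return Data frame `bin_lo_um`, `bin_hi_um`, `n_total`, `n_pos`,
#'   `fraction` (`NA` for empty bins); bins are contiguous and cover the
#'   full distance range.
#' @export
profile_caspase <- function(pattern, distances, bin_width = 50) {
  stopifnot(inherits(pattern, "point_pattern"))
  check_positive(bin_width, "bin_width")
  if (length(distances) != nrow(pattern$points))
    stopf("`distances` must have one value per cell")
  lo <- floor(min(distances) / bin_width) * bin_width
  hi <- ceiling(max(distances) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- findInterval(distances, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  n_total <- tabulate(idx, nbins = nb)
  n_pos <- tabulate(idx[pattern$points$caspase_pos], nbins = nb)
  data.frame(bin_lo_um = edges[-length(edges)], bin_hi_um = edges[-1],
             n_total = n_total, n_pos = n_pos,
             fraction = ifelse(n_total > 0, n_pos / n_total, NA_real_))
}

#' Maximum-likelihood refit of the border apoptosis decay
#'
#' Fits `p(d) = base + amplitude * exp(-d / decay_length)` to the
#' per-cell caspase outcomes of focal-side cells (`d >= 0`) by binomial
#' maximum likelihood, recovering the decay length of the elevated
#' apoptosis zone next to the border.
#'
#' @param distances Signed border distances (um).
#' @param positive Logical caspase flags, same length.
#' @param init Optional named list with starting values `base`,
#'   `amplitude`, `decay_length`.
#' @return List with `base`, `amplitude`, `decay_length`, `logLik`,
#'   `converged`, `n`.
#' @export
fit_caspase_decay <- function(distances, positive, init = NULL) {
  keep <- distances >= 0 & !is.na(distances)
  d <- distances[keep]; yobs <- as.numeric(positive[keep])
  if (length(d) < 50)
    stopf("too few focal-side cells (%d) to fit the decay model", length(d))
  if (is.null(init)) {
    far <- d > quantile(d, 0.7)
    b0 <- max(mean(yobs[far]), 1e-3)
    near <- d < quantile(d, 0.1)
    a0 <- max(mean(yobs[near]) - b0, 0.02)
    init <- list(base = min(b0, 0.9), amplitude = min(a0, 0.9),
                 decay_length = diff(range(d)) / 5)
  }
  nll <- function(th) {
    b <- plogis(th[1]); a <- plogis(th[2]); L <- exp(th[3])
    p <- pmin(pmax(b + a * exp(-d / L), 1e-12), 1 - 1e-12)
    -sum(yobs * log(p) + (1 - yobs) * log(1 - p))
  }
  th0 <- c(qlogis(init$base), qlogis(init$amplitude),
           log(init$decay_length))
  fit <- optim(th0, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(base = plogis(fit$par[1]), amplitude = plogis(fit$par[2]),
       decay_length = exp(fit$par[3]), logLik = -fit$value,
       converged = fit$convergence == 0, n = length(d))
}

#' Interface displacement over a confrontation time course
#'
#' Estimates the inter-population interface position at each timepoint and
#' reports its displacement relative to the first timepoint. Positive
#' displacement means the winner population has advanced into loser
#' territory (the "pushed back" phenotype).
#'
#' @param patterns List of [point_pattern()] objects, one per timepoint.
#' @param times Numeric timepoints (e.g. hours post-contact).
#' @param focal Subline whose territory defines the positive direction.
#' @return Data frame `time`, `border_x_um`, `displacement_um`, `flagged`
#'   (TRUE when a timepoint lacked one population and could not be
#'   estimated).
#' @export
front_displacement <- function(patterns, times, focal = "loser") {
  if (length(patterns) < 2)
    stopf("front displacement needs at least 2 timepoints")
  if (length(times) != length(patterns))
    stopf("`times` must match `patterns` in length")
  est <- vapply(patterns, function(p) {
    subs <- unique(p$points$subline)
    if (length(subs) < 2) return(NA_real_)
    estimate_border(p, focal)
  }, numeric(1))
  flagged <- is.na(est)
  # direction of loser territory, from the first estimable timepoint
  ref <- which(!flagged)[1]
  if (is.na(ref)) stopf("no timepoint has both populations present")
  p0 <- patterns[[ref]]$points
  focal_right <- mean(p0$x_um[p0$subline == focal]) >= est[ref]
  sgn <- if (focal_right) 1 else -1
  data.frame(time = times, border_x_um = est,
             displacement_um = sgn * (est - est[ref]),
             flagged = flagged)
}

#' Write a border profile to CSV
#' @param profile Data frame from [profile_caspase()].
#' @param path Output CSV path.
#' @export
write_border_profile <- function(profile, path) {
  write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
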