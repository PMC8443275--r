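# nN per (Pa * sqrt(um) * um^1.5): sqrt(1e-6) * (1e-6)^1.5 * 1e9 = 1e-3
.hertz_unit <- 1e-3

#' Hertz spherical-indenter force
#'
#' Classical Hertz contact force for a sphere of radius `R` indenting an
#' incompressible elastic half-space by `delta`:
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)`, with `E` in Pa,
#' `R` and `delta` in um and the result in nN.
#'
#' @param delta Indentation depth(s) in um; must be non-negative.
#' @param E Apparent Young's modulus in Pa.
#' @param R Probe sphere radius in um (default 2.5, a 5-um bead).
#' @param nu Poisson ratio (default 0.5, incompressible).
#' @return Force in nN, vectorised over `delta`.
#' @examples
#' hertz_force(1, E = 1000) # ~2.81 nN
#' @export
hertz_force <- function(delta, E, R = 2.5, nu = 0.5) {
  if (any(delta < 0)) stopf("indentation `delta` must be non-negative")
  check_positive(E, "E")
  check_positive(R, "R")
  if (nu < 0 || nu > 0.5) stopf("`nu` must lie in [0, 0.5]")
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5 * .hertz_unit
}

#' Ground truth for a synthetic AFM force curve
#'
#' @param E_true True apparent Young's modulus, Pa.
#' @param R Probe sphere radius, um.
#' @param nu Poisson ratio.
#' @param contact_offset Probe travel (um) at which contact occurs; force
#'   is zero before it.
#' @param noise_sd SD of additive Gaussian force noise, nN.
#' @param max_indentation Maximum post-contact indentation depth, um.
#' @return An object of class `hertz_truth`.
#' @export
hertz_truth <- function(E_true = 1000, R = 2.5, nu = 0.5,
                        contact_offset = 0.2, noise_sd = 0,
                        max_indentation = 1) {
  check_positive(E_true, "E_true")
  check_positive(R, "R")
  if (nu < 0 || nu > 0.5) stopf("`nu` must lie in [0, 0.5]")
  if (contact_offset < 0) stopf("`contact_offset` must be >= 0")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  check_positive(max_indentation, "max_indentation")
  structure(list(E_true = E_true, R = R, nu = nu,
                 contact_offset = contact_offset, noise_sd = noise_sd,
                 max_indentation = max_indentation),
            class = "hertz_truth")
}

#' Simulate an AFM force-indentation curve
#'
#' Samples probe travel monotonically from 0 to
#' `contact_offset + max_indentation`; force is zero before contact and
#' Hertzian beyond it, with additive Gaussian noise.
#'
#' @param truth A [hertz_truth()].
#' @param n_samples Number of samples (>= 10).
#' @param seed RNG seed for the noise.
#' @return An object of class `force_curve`: `data` (data frame
#'   `indentation_um`, `force_nN`), `probe_radius`, `poisson`,
#'   `approach_speed` (um/s metadata, default 2).
#' @export
make_force_curve <- function(truth, n_samples = 200, seed = 1L) {
  stopifnot(inherits(truth, "hertz_truth"))
  if (n_samples < 10) stopf("`n_samples` must be >= 10")
  z <- seq(0, truth$contact_offset + truth$max_indentation,
           length.out = n_samples)
  f <- hertz_force(pmax(z - truth$contact_offset, 0),
                   E = truth$E_true, R = truth$R, nu = truth$nu)
  if (truth$noise_sd > 0)
    f <- f + with_seed(seed, rnorm(n_samples, 0, truth$noise_sd))
  structure(
    list(data = data.frame(indentation_um = z, force_nN = f),
         probe_radius = truth$R, poisson = truth$nu, approach_speed = 2),
    class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "force_curve: %d samples to %.3g um, R = %g um, nu = %g\n",
    nrow(x$data), max(x$data$indentation_um), x$probe_radius, x$poisson))
  invisible(x)
}

#' Fit the Hertz model to a force-indentation curve
#'
#' Jointly estimates the contact point and the apparent Young's modulus by
#' nonlinear least squares on
#' `F(z) = (4/3) E / (1 - nu^2) sqrt(R) * max(z - z0, 0)^(3/2)`.
#' The contact point is initialised at the first sample whose force
#' exceeds three baseline standard deviations (baseline taken from the
#' first fifth of the curve) and then refined as a free parameter. Only
#' the shallow part of the curve is fit: post-contact indentations up to
#' `fit_fraction` of the maximum, where the small-indentation Hertz
#' approximation holds.
#'
#' @param curve A `force_curve` (or data frame with `indentation_um`,
#'   `force_nN` columns plus `R`/`nu` arguments).
#' @param fit_fraction Fraction (0, 1] of the post-contact indentation
#'   range used in the fit; default 0.5.
#' @param R,nu Probe radius (um) and Poisson ratio; defaults taken from
#'   the curve object.
#' @return An object of class `hertz_fit`: `E_Pa`, `contact_point_um`,
#'   `rss` (nN^2), `n_points_used`, `converged`, `fit_fraction`, and
#'   `diagnostic` when not converged.
#' @export
fit_hertz <- function(curve, fit_fraction = 0.5, R = NULL, nu = NULL) {
  if (inherits(curve, "force_curve")) {
    R <- R %||% curve$probe_radius
    nu <- nu %||% curve$poisson
    dat <- curve$data
  } else {
    dat <- as.data.frame(curve)
    R <- R %||% 2.5
    nu <- nu %||% 0.5
  }
  if (fit_fraction <= 0 || fit_fraction > 1)
    stopf("`fit_fraction` must be in (0, 1]")
  z <- dat$indentation_um
  f <- dat$force_nN
  if (is.unsorted(z)) stopf("samples must be ordered in increasing travel")
  failed <- function(msg) structure(
    list(E_Pa = NA_real_, contact_point_um = NA_real_, rss = NA_real_,
         n_points_used = 0L, converged = FALSE, fit_fraction = fit_fraction,
         diagnostic = msg),
    class = "hertz_fit")
  if (max(f) <= 0 || diff(range(f)) == 0)
    return(failed("flat or non-positive force signal"))
  # baseline noise from the first fifth of the curve
  nb <- max(5L, floor(length(z) / 5))
  base_sd <- sd(f[seq_len(nb)])
  thresh <- max(3 * base_sd, 1e-9 * max(abs(f)))
  ic <- which(f > thresh)[1]
  if (is.na(ic)) return(failed("no sample exceeds the contact threshold"))
  z0_init <- z[ic]
  post <- z > z0_init
  if (sum(post) < 10)
    return(failed("fewer than 10 post-contact samples"))
  # fit window: shallow part of the post-contact range (fixed during fit)
  depth_max <- max(z) - z0_init
  win <- z <= z0_init + fit_fraction * depth_max
  # include the pre-contact tail so z0 is constrained from both sides
  zw <- z[win]; fw <- f[win]
  k_unit <- (4 / 3) / (1 - nu^2) * sqrt(R) * .hertz_unit
  # initial E from linearised F^(2/3) ~ z on post-contact window samples
  sel <- zw > z0_init & fw > 0
  if (sum(sel) >= 3) {
    lf <- lm(I(fw[sel]^(2 / 3)) ~ zw[sel])
    slope <- coef(lf)[2]
    E_init <- if (is.finite(slope) && slope > 0)
      slope^1.5 / k_unit else max(fw) / (k_unit * depth_max^1.5)
  } else {
    E_init <- max(fw) / (k_unit * depth_max^1.5)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fw ~ k_unit * E * pmax(zw - z0, 0)^1.5,
      start = list(E = max(E_init, 1e-3), z0 = z0_init),
      lower = c(E = 1e-6, z0 = min(z)),
      upper = c(E = Inf, z0 = max(z)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("nonlinear least squares failed"))
  est <- coef(fit)
  structure(
    list(E_Pa = unname(est["E"]), contact_point_um = unname(est["z0"]),
         rss = sum(residuals(fit)^2), n_points_used = length(zw),
         converged = TRUE, fit_fraction = fit_fraction, diagnostic = NULL),
    class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "hertz_fit: E = %.1f Pa, contact at %.4g um (%d points, rss %.3g)\n",
      x$E_Pa, x$contact_point_um, x$n_points_used, x$rss))
  else
    cat(sprintf("hertz_fit: not converged (%s)\n", x$diagnostic))
  invisible(x)
}

#' Hierarchical per-cell and per-experiment stiffness summaries
#'
#' AFM sessions take several force curves per cell and several cells per
#' experiment. The cell value is the mean modulus of its converged fits;
#' the experiment value is the mean of its cell values — raw fits are
#' never pooled across cells, so unevenly sampled cells are not
#' over-weighted.
#'
#' @param fits Data frame with columns `E_Pa`, `converged`, `cell_id` and
#'   `experiment_id`.
#' @return List with `cells` (`experiment_id`, `cell_id`, `E_Pa`,
#'   `n_fits`) and `experiments` (`experiment_id`, `E_Pa`, `n_cells`).
#' @export
summarize_cells <- function(fits) {
  need <- c("E_Pa", "converged", "cell_id", "experiment_id")
  if (!all(need %in% names(fits)))
    stopf("`fits` must have columns %s", paste(need, collapse = ", "))
  ok <- fits$converged & !is.na(fits$E_Pa)
  dropped <- setdiff(unique(fits$cell_id), unique(fits$cell_id[ok]))
  if (length(dropped) > 0)
    warnf("dropping %d cell(s) with no converged fit", length(dropped))
  good <- fits[ok, ]
  if (nrow(good) == 0) stopf("no converged fits to summarise")
  cells <- aggregate(E_Pa ~ experiment_id + cell_id, data = good, mean)
  nfits <- aggregate(cbind(n_fits = E_Pa) ~ experiment_id + cell_id,
                     data = good, length)
  cells <- merge(cells, nfits, by = c("experiment_id", "cell_id"))
  experiments <- aggregate(E_Pa ~ experiment_id, data = cells, mean)
  ncells <- aggregate(cbind(n_cells = cell_id) ~ experiment_id,
                      data = cells, length)
  experiments <- merge(experiments, ncells, by = "experiment_id")
  list(cells = cells[order(cells$experiment_id, cells$cell_id), ],
       experiments = experiments)
}
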