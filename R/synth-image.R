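#' Ground truth for a synthetic two-channel immunofluorescence image
#'
#' Describes nuclei as uniform discs and a marker channel whose per-cell
#' nuclear mean is `nc_partition` times its cytoplasmic mean, the quantity
#' the downstream N/C ratio measurement should recover.
#'
#' @param nuclei_centers Two-column matrix of (x, y) centres in um.
#' @param nuclear_radius Nucleus disc radius in um.
#' @param nc_partition True nuclear-to-cytoplasmic mean intensity ratio of
#'   the marker channel.
#' @param cyto_radius Outer radius (um) of the cytoplasmic annulus around
#'   each nucleus; default twice the nuclear radius.
#' @param cyto_intensity Base cytoplasmic marker intensity per cell.
#' @param background Additive constant background of the marker channel.
#' @param noise_sd SD of additive Gaussian noise, in marker-intensity
#'   units; the nuclei channel receives the same noise relative to its
#'   own unit amplitude.
#' @return An object of class `image_truth`.
#' @export
image_truth <- function(nuclei_centers, nuclear_radius = 8,
                        nc_partition = 2, cyto_radius = 2 * nuclear_radius,
                        cyto_intensity = 100, background = 0,
                        noise_sd = 0) {
  nuclei_centers <- as.matrix(nuclei_centers)
  check_positive(nuclear_radius, "nuclear_radius")
  check_positive(nc_partition, "nc_partition")
  if (cyto_radius <= nuclear_radius)
    stopf("`cyto_radius` must exceed `nuclear_radius`")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  structure(
    list(nuclei_centers = nuclei_centers, nuclear_radius = nuclear_radius,
         nc_partition = nc_partition, cyto_radius = cyto_radius,
         cyto_intensity = cyto_intensity, background = background,
         noise_sd = noise_sd),
    class = "image_truth")
}

#' Render a synthetic two-channel cell image
#'
#' Produces a nuclei channel (discs of `nuclear_radius` per centre) and a
#' marker channel built additively per cell: `nc_partition * cyto_intensity`
#' over the nuclear disc plus `cyto_intensity` over the surrounding
#' annulus, on a constant background, with optional Gaussian noise.
#' Pixels are sampled at their centres; a pixel belongs to a disc when its
#' centre does. Cells whose nuclear discs overlap are flagged in the truth
#' table (their measured ratios mix two cells).
#'
#' @param truth An [image_truth()].
#' @param field A [field_spec()]; `pixel_size` must resolve the nuclei.
#' @return An object of class `cell_image`: `nuclei` and `markers` (named
#'   list of matrices, here one channel `"marker"`), `pixel_size`, and a
#'   `truth` data frame (`cell_id`, centre, true nuclear/cytoplasmic
#'   values, `nc_partition`, `overlap`).
#' @export
render_image <- function(truth, field) {
  stopifnot(inherits(truth, "image_truth"), inherits(field, "field_spec"))
  ps <- field$pixel_size
  if (ps >= truth$nuclear_radius)
    stopf("pixel_size (%g um) cannot resolve nuclei of radius %g um",
          ps, truth$nuclear_radius)
  ctr <- truth$nuclei_centers
  if (nrow(ctr) > 0 &&
      (any(ctr[, 1] < 0 | ctr[, 1] > field$width) ||
       any(ctr[, 2] < 0 | ctr[, 2] > field$height)))
    stopf("nuclei centres must lie within the field")
  nx <- max(1L, round(field$width / ps))
  ny <- max(1L, round(field$height / ps))
  # pixel centres in um; matrices are indexed [row = y, col = x]
  px <- (seq_len(nx) - 0.5) * ps
  py <- (seq_len(ny) - 0.5) * ps
  nuc <- matrix(0, ny, nx)
  mark <- matrix(truth$background, ny, nx)
  k <- nrow(ctr)
  v_nuc <- truth$nc_partition * truth$cyto_intensity
  v_cyt <- truth$cyto_intensity
  for (i in seq_len(k)) {
    dx2 <- (px - ctr[i, 1])^2
    dy2 <- (py - ctr[i, 2])^2
    d2 <- outer(dy2, dx2, "+")
    in_nuc <- d2 <= truth$nuclear_radius^2
    in_ann <- !in_nuc & d2 <= truth$cyto_radius^2
    nuc[in_nuc] <- 1
    mark[in_nuc] <- mark[in_nuc] + v_nuc
    mark[in_ann] <- mark[in_ann] + v_cyt
  }
  overlap <- rep(FALSE, k)
  if (k > 1) {
    dd <- as.matrix(dist(ctr))
    diag(dd) <- Inf
    overlap <- apply(dd < 2 * truth$nuclear_radius, 1, any)
  }
  if (truth$noise_sd > 0) {
    # noise_sd is in marker units; the unit-amplitude nuclei channel gets
    # the same noise relative to its own signal
    rel_sd <- truth$noise_sd / max(v_nuc + truth$background, 1e-12)
    with_seed(field$seed, {
      nuc <- nuc + matrix(rnorm(ny * nx, 0, rel_sd), ny, nx)
      mark <- mark + matrix(rnorm(ny * nx, 0, truth$noise_sd), ny, nx)
    })
    nuc <- pmax(nuc, 0)
    mark <- pmax(mark, 0)
  }
  truth_df <- data.frame(
    cell_id = seq_len(k),
    x_um = ctr[, 1], y_um = ctr[, 2],
    v_nuclear = rep(v_nuc, length.out = k),
    v_cytoplasm = rep(v_cyt, length.out = k),
    nc_partition = rep(truth$nc_partition, length.out = k),
    overlap = overlap)
  structure(
    list(nuclei = nuc, markers = list(marker = mark), pixel_size = ps,
         truth = truth_df),
    class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("cell_image: %d x %d px (%g um/px), channels: nuclei + %s\n",
              nrow(x$nuclei), ncol(x$nuclei), x$pixel_size,
              paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

#' Place non-overlapping nuclei centres on a field
#'
#' Rejection-samples centres so that nuclear discs do not overlap and stay
#' clear of the field edge; a convenience for building clean synthetic
#' images.
#'
#' @param field A [field_spec()] (its seed drives the sampling).
#' @param n Number of nuclei.
#' @param min_dist Minimum centre-to-centre distance in um.
#' @param margin Margin from the field edge in um.
#' @return An n x 2 matrix of centres.
#' @export
place_nuclei <- function(field, n, min_dist, margin = min_dist) {
  stopifnot(inherits(field, "field_spec"))
  with_seed(field$seed, {
    out <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(out) < n && tries < 200L * n) {
      cand <- c(runif(1, margin, field$width - margin),
                runif(1, margin, field$height - margin))
      ok <- nrow(out) == 0 ||
        all((out[, 1] - cand[1])^2 + (out[, 2] - cand[2])^2 >= min_dist^2)
      if (ok) out <- rbind(out, cand)
      tries <- tries + 1L
    }
    if (nrow(out) < n)
      stopf("could not place %d nuclei at min_dist %g in the field",
            n, min_dist)
    dimnames(out) <- NULL
    out
  })
}
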