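#' Segment nuclei from the nuclei (Hoechst) channel
#'
#' Global Otsu threshold, connected-component labelling and a minimum-area
#' filter; optionally a distance-transform watershed to split touching
#' nuclei. Deterministic for a fixed input image.
#'
#' @param image A [cell_image()][render_image] or a numeric matrix
#'   (the nuclei channel).
#' @param min_area Minimum object area in pixels.
#' @param watershed Split touching nuclei with a distance-transform
#'   watershed.
#' @param pixel_size um per pixel (taken from the image when available).
#' @return An object of class `nuclei_mask`: `labels` (integer matrix,
#'   0 = background), `centroids` data frame (`cell_id`, `row`, `col`,
#'   `x_um`, `y_um`, `area_px`), `pixel_size`.
#' @export
segment_nuclei <- function(image, min_area = 20, watershed = FALSE,
                           pixel_size = NULL) {
  if (inherits(image, "cell_image")) {
    pixel_size <- pixel_size %||% image$pixel_size
    img <- image$nuclei
  } else {
    img <- as.matrix(image)
    pixel_size <- pixel_size %||% 1
  }
  rng <- range(img)
  if (diff(rng) <= 0) {
    warnf("nuclei channel is constant; returning an empty mask")
    return(empty_nuclei_mask(img, pixel_size))
  }
  norm <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bin <- (norm > thr) * 1
  if (watershed) {
    dm <- EBImage::distmap(bin)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    lab <- EBImage::bwlabel(bin)
  }
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  # size filter, then relabel contiguously
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) {
    warnf("no nuclei above min_area = %d px; returning an empty mask",
          min_area)
    return(empty_nuclei_mask(img, pixel_size))
  }
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  centroids <- mask_centroids(lab, pixel_size)
  structure(list(labels = lab, centroids = centroids,
                 pixel_size = pixel_size),
            class = "nuclei_mask")
}

#' @noRd
empty_nuclei_mask <- function(img, pixel_size) {
  structure(
    list(labels = matrix(0L, nrow(img), ncol(img)),
         centroids = data.frame(cell_id = integer(), row = numeric(),
                                col = numeric(), x_um = numeric(),
                                y_um = numeric(), area_px = integer()),
         pixel_size = pixel_size),
    class = "nuclei_mask")
}

#' @noRd
mask_centroids <- function(lab, pixel_size) {
  ids <- sort(unique(lab[lab > 0]))
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]; l <- lab[lab > 0]
  rbar <- tapply(rows, l, mean); cbar <- tapply(cols, l, mean)
  area <- tabulate(l)[ids]
  data.frame(cell_id = ids,
             row = as.numeric(rbar), col = as.numeric(cbar),
             # pixel centres: 0-based index + 0.5, y-down frame
             x_um = (as.numeric(cbar) - 0.5) * pixel_size,
             y_um = (as.numeric(rbar) - 0.5) * pixel_size,
             area_px = area)
}

#' @export
print.nuclei_mask <- function(x, ...) {
  cat(sprintf("nuclei_mask: %d nuclei on %d x %d px\n",
              nrow(x$centroids), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Build inner-nucleus and cytoplasm-ring masks by dilation/erosion
#'
#' For each segmented nucleus the inner mask is its erosion by a Euclidean
#' disc of `radius_px` pixels and the cytoplasm mask is its dilation by
#' the same disc minus the union of all nuclei — so cytoplasm is never
#' contaminated by any nucleus. Ring pixels claimed by more than one
#' cell's dilation are assigned to the nearest nucleus (ties to the lowest
#' label) and the cells involved are flagged `contested_ring`; cells whose
#' dilation touches the image edge are flagged `edge_cell`; cells whose
#' nucleus erodes away entirely are flagged `empty_inner`.
#'
#' Morphology is computed with exact Euclidean distance transforms:
#' erosion keeps pixels farther than `radius_px` from the background and
#' dilation keeps pixels within `radius_px` of the nucleus, which is the
#' disc structuring element in distance form.
#'
#' @param mask A `nuclei_mask` from [segment_nuclei()].
#' @param radius_px Disc radius in pixels (default 15, the standard
#'   dilate/erode width for this assay).
#' @return An object of class `cell_masks`: `inner` and `ring` labelled
#'   integer matrices (0 = unassigned) and a `flags` data frame
#'   (`cell_id`, `empty_inner`, `edge_cell`, `contested_ring`).
#' @export
build_masks <- function(mask, radius_px = 15L) {
  stopifnot(inherits(mask, "nuclei_mask"))
  if (radius_px < 1) stopf("`radius_px` must be >= 1")
  lab <- mask$labels
  ids <- mask$centroids$cell_id
  ny <- nrow(lab); nx <- ncol(lab)
  inner <- matrix(0L, ny, nx)
  ring <- matrix(0L, ny, nx)
  any_nuc <- lab > 0
  k <- length(ids)
  flags <- data.frame(cell_id = ids,
                      empty_inner = logical(k), edge_cell = logical(k),
                      contested_ring = logical(k))
  if (k == 0)
    return(structure(list(inner = inner, ring = ring, flags = flags,
                          radius_px = radius_px), class = "cell_masks"))
  # distance from every pixel to cell i's nucleus (0 inside it)
  dist_to <- vector("list", k)
  dil_count <- matrix(0L, ny, nx)
  for (i in seq_len(k)) {
    nuc_i <- (lab == ids[i]) * 1
    # distmap: per nonzero pixel, Euclidean distance to the nearest zero
    dist_to[[i]] <- as.matrix(EBImage::distmap(1 - nuc_i))
    ero <- as.matrix(EBImage::distmap(nuc_i)) > radius_px
    inner[ero] <- ids[i]
    dil_i <- dist_to[[i]] <= radius_px
    dil_count <- dil_count + dil_i
    flags$empty_inner[i] <- !any(ero)
    flags$edge_cell[i] <- any(dil_i[1, ]) || any(dil_i[ny, ]) ||
      any(dil_i[, 1]) || any(dil_i[, nx])
  }
  # nearest-nucleus owner over the whole frame (ties -> lowest label)
  dstack <- array(unlist(dist_to), dim = c(ny * nx, k))
  owner <- max.col(-dstack, ties.method = "first")
  mind <- dstack[cbind(seq_len(ny * nx), owner)]
  ring_px <- !any_nuc & matrix(mind, ny, nx) <= radius_px
  ring[ring_px] <- ids[owner[as.vector(ring_px)]]
  contested <- dil_count > 1 & !any_nuc
  if (any(contested)) {
    for (i in seq_len(k))
      flags$contested_ring[i] <- any(contested & dist_to[[i]] <= radius_px)
  }
  structure(list(inner = inner, ring = ring, flags = flags,
                 radius_px = as.integer(radius_px)),
            class = "cell_masks")
}

#' Per-cell nuclear and cytoplasmic marker intensity
#'
#' Means the named marker channel over each cell's inner-nucleus mask and
#' cytoplasm ring, and forms the nuclear-to-cytoplasmic ratio
#' `nc_ratio = nuclear_mean / cytoplasm_mean`. Ratios are reported only
#' for clean cells: `empty_inner` cells have no nuclear mean, and cells
#' with an empty ring or zero cytoplasmic mean are flagged
#' `zero_cytoplasm` with an undefined ratio. Means remain reported
#' wherever their mask is non-empty.
#'
#' @param image A `cell_image` (or named list of matrices).
#' @param masks A `cell_masks` from [build_masks()].
#' @param channel Marker channel name (e.g. `"marker"`, `"YAP"`).
#' @param centroids Optional centroid table to carry through (defaults to
#'   none).
#' @param background Constant offset subtracted from the channel before
#'   averaging; 0 (no background subtraction) by default.
#' @return Data frame with `cell_id`, `nuclear_mean`, `cytoplasm_mean`,
#'   `nc_ratio`, and logical flags `empty_inner`, `zero_cytoplasm`,
#'   `edge_cell`, `contested_ring`.
#' @export
measure <- function(image, masks, channel = "marker", centroids = NULL,
                    background = 0) {
  stopifnot(inherits(masks, "cell_masks"))
  chans <- if (inherits(image, "cell_image")) image$markers else image
  if (!channel %in% names(chans))
    stopf("unknown channel '%s'; available: %s", channel,
          paste(names(chans), collapse = ", "))
  img <- chans[[channel]] - background
  if (!all(dim(img) == dim(masks$inner)))
    stopf("channel and mask dimensions differ")
  ids <- masks$flags$cell_id
  nuc_mean <- mask_mean(img, masks$inner, ids)
  cyt_mean <- mask_mean(img, masks$ring, ids)
  out <- masks$flags
  out$channel <- channel
  out$nuclear_mean <- nuc_mean
  out$cytoplasm_mean <- cyt_mean
  out$zero_cytoplasm <- is.na(cyt_mean) | cyt_mean == 0
  out$nc_ratio <- ifelse(!out$empty_inner & !out$zero_cytoplasm,
                         nuc_mean / cyt_mean, NA_real_)
  if (!is.null(centroids))
    out <- merge(centroids, out, by = "cell_id", sort = TRUE)
  out[order(out$cell_id), ]
}

#' @noRd
mask_mean <- function(img, lab, ids) {
  sel <- lab > 0
  if (!any(sel)) return(rep(NA_real_, length(ids)))
  s <- tapply(img[sel], lab[sel], mean)
  out <- rep(NA_real_, length(ids))
  m <- match(ids, as.integer(names(s)))
  out[!is.na(m)] <- as.numeric(s[m[!is.na(m)]])
  out
}

#' End-to-end N/C quantification of a synthetic or real image
#'
#' Convenience pipeline: segment nuclei, build dilate/erode masks and
#' measure one channel.
#'
#' @inheritParams segment_nuclei
#' @inheritParams build_masks
#' @inheritParams measure
#' @return The [measure()] data frame with centroid columns.
#' @export
quantify_nc <- function(image, channel = "marker", radius_px = 15L,
                        min_area = 20, watershed = FALSE) {
  mask <- segment_nuclei(image, min_area = min_area, watershed = watershed)
  masks <- build_masks(mask, radius_px = radius_px)
  measure(image, masks, channel = channel, centroids = mask$centroids)
}
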