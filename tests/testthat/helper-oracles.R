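# Independent brute-force oracles, deliberately naive: they share no code
# with the package internals they check.

# Circumcircle of triangle rows a, b, c: centre and squared radius.
circumcircle <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]
  bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(cx = ux, cy = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
}

# TRUE when every triangle's circumcircle is empty of other points,
# up to a relative tolerance on the squared radius.
oracle_empty_circumcircle <- function(pts, triangles, tol = 1e-9) {
  for (t in seq_len(nrow(triangles))) {
    idx <- triangles[t, ]
    cc <- circumcircle(pts[idx, , drop = FALSE])
    others <- setdiff(seq_len(nrow(pts)), idx)
    d2 <- (pts[others, 1] - cc$cx)^2 + (pts[others, 2] - cc$cy)^2
    if (any(d2 < cc$r2 * (1 - tol))) return(FALSE)
  }
  TRUE
}

# Per-point density recomputed by scanning the triangle list row by row,
# independent of any adjacency bookkeeping.
oracle_density <- function(pts, triangles, variant) {
  n <- nrow(pts)
  rho <- rep(NA_real_, n)
  tri_area <- function(i) {
    p <- pts[triangles[i, ], ]
    abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
          (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])) / 2
  }
  areas <- vapply(seq_len(nrow(triangles)), tri_area, numeric(1))
  for (j in seq_len(n)) {
    inc <- which(apply(triangles == j, 1, any))
    if (length(inc) == 0) next
    rho[j] <- if (variant == "inverse_of_sum") 1 / sum(areas[inc])
              else sum(1 / areas[inc])
  }
  rho
}

# Exhaustive two-sample KS: maximum ECDF difference over all candidate
# evaluation points.
oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(v)
    abs(mean(x <= v) - mean(y <= v)), numeric(1)))
}

# Per-pixel disc membership by the same pixel-centre rule the renderer
# documents, recomputed from scratch.
oracle_disc_pixels <- function(center, radius, nx, ny, ps) {
  px <- (seq_len(nx) - 0.5) * ps
  py <- (seq_len(ny) - 0.5) * ps
  outer((py - center[2])^2, (px - center[1])^2, "+") <= radius^2
}

random_pattern <- function(n, seed, w = 100) {
  set.seed(seed)
  cbind(runif(n, 0, w), runif(n, 0, w))
}

# Labelled-mask centroid table rebuilt by direct pixel averaging (the
# nuclei_mask constructor path is bypassed on purpose).
mask_centroid_df <- function(lab, pixel_size) {
  ids <- sort(unique(lab[lab > 0]))
  do.call(rbind, lapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    data.frame(cell_id = k, row = mean(w[, 1]), col = mean(w[, 2]),
               x_um = (mean(w[, 2]) - 0.5) * pixel_size,
               y_um = (mean(w[, 1]) - 0.5) * pixel_size,
               area_px = nrow(w))
  }))
}
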