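# Shared clean synthetic image: 12 well-separated nuclei, no noise.
clean_image <- function(nc_partition = 2, noise_sd = 0, seed = 3,
                        background = 0) {
  fld <- field_spec(200, 200, pixel_size = 0.5, seed = seed)
  ctr <- place_nuclei(fld, 12, min_dist = 40, margin = 20)
  render_image(image_truth(ctr, nuclear_radius = 8,
                           nc_partition = nc_partition,
                           background = background, noise_sd = noise_sd),
               fld)
}

test_that("rendering validates its geometry and records overlap", {
  fld <- field_spec(100, 100, pixel_size = 0.5, seed = 1)
  expect_error(
    render_image(image_truth(cbind(50, 50), nuclear_radius = 0.4), fld),
    "resolve")
  img <- render_image(
    image_truth(cbind(c(30, 36, 70), c(30, 30, 70)), nuclear_radius = 8),
    fld)
  expect_equal(img$truth$overlap, c(TRUE, TRUE, FALSE))
})

test_that("total marker intensity matches the analytic per-cell sum", {
  fld <- field_spec(150, 150, pixel_size = 0.5, seed = 2)
  ctr <- place_nuclei(fld, 6, min_dist = 40, margin = 20)
  truth <- image_truth(ctr, nuclear_radius = 8, nc_partition = 3,
                       cyto_intensity = 50, background = 7)
  img <- render_image(truth, fld)
  nx <- ncol(img$markers$marker); ny <- nrow(img$markers$marker)
  expected <- 7 * nx * ny
  for (i in seq_len(nrow(ctr))) {
    nucpx <- oracle_disc_pixels(ctr[i, ], 8, nx, ny, 0.5)
    cytpx <- oracle_disc_pixels(ctr[i, ], 16, nx, ny, 0.5) & !nucpx
    expected <- expected + 150 * sum(nucpx) + 50 * sum(cytpx)
  }
  expect_equal(sum(img$markers$marker), expected)
})

test_that("segmentation recovers disc nuclei and their centroids", {
  img <- clean_image()
  mask <- segment_nuclei(img)
  expect_equal(nrow(mask$centroids), 12L)
  truth <- img$truth[order(img$truth$x_um, img$truth$y_um), ]
  est <- mask$centroids[order(mask$centroids$x_um, mask$centroids$y_um), ]
  expect_lt(max(abs(est$x_um - truth$x_um)), 0.5) # within one pixel
  expect_lt(max(abs(est$y_um - truth$y_um)), 0.5)
  blank <- matrix(0, 64, 64)
  expect_warning(empty <- segment_nuclei(blank), "constant")
  expect_equal(nrow(empty$centroids), 0L)
})

test_that("touching nuclei split under watershed, logged otherwise", {
  fld <- field_spec(100, 100, pixel_size = 0.5, seed = 4)
  # 30% overlap: centre distance 1.4 r
  ctr <- cbind(c(40, 40 + 1.4 * 8), c(50, 50))
  img <- render_image(image_truth(ctr, nuclear_radius = 8), fld)
  plain <- segment_nuclei(img)
  expect_true(nrow(plain$centroids) %in% c(1L, 2L))
  split <- segment_nuclei(img, watershed = TRUE)
  expect_equal(nrow(split$centroids), 2L)
})

test_that("disc morphology: erode/dilate by 15 px gives the documented annuli", {
  lab <- matrix(0L, 100, 100)
  ctr <- c(50.5, 50.5)
  d <- sqrt(outer((seq_len(100) - 0.5 - ctr[2])^2,
                  (seq_len(100) - 0.5 - ctr[1])^2, "+"))
  lab[d <= 20] <- 1L
  mask <- structure(list(labels = lab,
                         centroids = mask_centroid_df(lab, 1)),
                    class = "nuclei_mask")
  ms <- build_masks(mask, radius_px = 15)
  inner <- ms$inner == 1
  ring <- ms$ring == 1
  # inner approximates the radius-5 disc, ring the 20..35 annulus
  expect_true(all(d[inner] <= 5 + 1.5))
  expect_gte(sum(inner), sum(d <= 5 - 1.5))
  expect_true(all(d[ring] >= 20 - 1.5 & d[ring] <= 35 + 1.5))
  expect_false(ms$flags$empty_inner)
  expect_false(ms$flags$edge_cell)
  # a 10 px nucleus erodes away under a 15 px disc
  lab2 <- matrix(0L, 100, 100)
  lab2[d <= 10] <- 1L
  mask2 <- structure(list(labels = lab2,
                          centroids = mask_centroid_df(lab2, 1)),
                     class = "nuclei_mask")
  ms2 <- build_masks(mask2, radius_px = 15)
  expect_true(ms2$flags$empty_inner)
  expect_equal(sum(ms2$inner), 0)
})

test_that("contested ring pixels go to the nearest nucleus, exactly", {
  lab <- matrix(0L, 80, 120)
  c1 <- c(40.5, 40.5); c2 <- c(65.5, 40.5) # 25 px apart
  d1 <- sqrt(outer((seq_len(80) - 0.5 - c1[2])^2,
                   (seq_len(120) - 0.5 - c1[1])^2, "+"))
  d2 <- sqrt(outer((seq_len(80) - 0.5 - c2[2])^2,
                   (seq_len(120) - 0.5 - c2[1])^2, "+"))
  lab[d1 <= 8] <- 1L
  lab[d2 <= 8] <- 2L
  mask <- structure(list(labels = lab,
                         centroids = mask_centroid_df(lab, 1)),
                    class = "nuclei_mask")
  ms <- build_masks(mask, radius_px = 15)
  expect_true(all(ms$flags$contested_ring))
  # brute-force per-pixel assignment oracle on the whole frame
  ring_px <- which(ms$ring > 0, arr.ind = TRUE)
  for (j in seq_len(nrow(ring_px))) {
    r <- ring_px[j, 1]; cc <- ring_px[j, 2]
    dd1 <- d1[r, cc]; dd2 <- d2[r, cc]
    expect_equal(ms$ring[r, cc], if (dd1 <= dd2) 1L else 2L)
  }
  # masks are disjoint: inner vs ring, and rings of distinct cells
  expect_equal(sum(ms$inner > 0 & ms$ring > 0), 0)
  expect_equal(sum(ms$ring > 0 & lab > 0), 0)
})

test_that("uniform image yields N/C ratio 1 and flags guard division", {
  img <- clean_image(nc_partition = 1)
  res <- quantify_nc(img)
  ok <- !res$empty_inner & !res$zero_cytoplasm
  expect_true(all(abs(res$nc_ratio[ok] - 1) < 1e-9))
  # zero cytoplasm: blank out the marker channel
  img$markers$marker[] <- 0
  mask <- segment_nuclei(img)
  ms <- build_masks(mask, 15)
  res0 <- measure(img, ms, "marker")
  expect_true(all(res0$zero_cytoplasm))
  expect_true(all(is.na(res0$nc_ratio)))
  expect_error(measure(img, ms, "no_such_channel"), "unknown channel")
})

test_that("N/C ratios recover the true partition across a 0.5-4x range", {
  for (part in c(0.5, 1, 2, 4)) {
    img <- clean_image(nc_partition = part)
    res <- quantify_nc(img)
    ok <- !res$empty_inner & !res$zero_cytoplasm & !res$edge_cell
    expect_gt(sum(ok), 6)
    expect_lt(abs(median(res$nc_ratio[ok]) - part) / part, 0.02)
  }
  # at 5% noise the median ratio stays within 10%
  img <- clean_image(nc_partition = 2, noise_sd = 5)
  res <- quantify_nc(img)
  ok <- !res$empty_inner & !res$zero_cytoplasm & !res$edge_cell
  expect_lt(abs(median(res$nc_ratio[ok]) - 2) / 2, 0.1)
})

test_that("means respond affinely to intensity shifts and scalings", {
  img <- clean_image(nc_partition = 2)
  mask <- segment_nuclei(img)
  ms <- build_masks(mask, 15)
  base <- measure(img, ms, "marker")
  shifted <- img; shifted$markers$marker <- img$markers$marker + 13
  scaled <- img; scaled$markers$marker <- img$markers$marker * 2.5
  rs <- measure(shifted, ms, "marker")
  rc <- measure(scaled, ms, "marker")
  expect_equal(rs$nuclear_mean, base$nuclear_mean + 13)
  expect_equal(rs$cytoplasm_mean, base$cytoplasm_mean + 13)
  expect_equal(rc$nuclear_mean, base$nuclear_mean * 2.5)
  expect_equal(rc$nc_ratio, base$nc_ratio) # ratio invariant under scaling
  # the background flag removes a known constant offset
  rb <- measure(shifted, ms, "marker", background = 13)
  expect_equal(rb$nc_ratio, base$nc_ratio)
})

test_that("cell image TIFF + sidecar round-trips with value equality", {
  img <- clean_image(nc_partition = 3)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_cell_image(img, path)
  back <- read_cell_image(path)
  expect_lt(max(abs(back$nuclei - img$nuclei)), 1e-4)
  expect_lt(max(abs(back$markers$marker - img$markers$marker)), 1e-4)
  expect_equal(back$pixel_size, img$pixel_size)
  expect_equal(back$truth$nc_partition, img$truth$nc_partition)
})
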