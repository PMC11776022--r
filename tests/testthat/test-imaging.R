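test_that("tissue detection applies the 210 luminance threshold exactly", {
  white <- slide_image(array(255, dim = c(8, 8, 3)), 2)
  expect_false(any(detect_tissue(white)))
  just_below <- slide_image(array(209, dim = c(8, 8, 3)), 2)
  expect_true(all(detect_tissue(just_below)))
  at_threshold <- slide_image(array(210, dim = c(8, 8, 3)), 2)
  expect_false(any(detect_tissue(at_threshold)))
  expect_error(detect_tissue(slide_image(array(100.5, dim = c(4, 4, 3)), 2)),
               "8-bit")
})

test_that("tissue mask covers the rendered villous and fibrin pixels", {
  sl <- generate_slide(small_slide_params(seed = 3L))
  tissue <- detect_tissue(sl$image)
  gt <- sl$truth$label_mask$labels
  solid <- gt == label_codes()[["villi"]] | gt == label_codes()[["fibrin"]]
  expect_gte(mean(tissue[solid]), 0.99)
})

test_that("classification equals the analytic mask on pure-colour rectangles", {
  fx <- make_rect_image()
  got <- classify_villous_tissue(fx$image)
  expect_identical(got$labels, fx$labels)
})

test_that("classifier recovers generated labels and drops intervillous artifacts", {
  sl <- generate_slide(small_slide_params(seed = 5L))
  labels <- classify_villous_tissue(sl$image)
  gt <- sl$truth$label_mask$labels
  acc <- mean(labels$labels == gt)
  expect_gte(acc, 0.90)
  # generator places artifacts only in the intervillous space, so after
  # reassignment no artifact-class pixels remain
  expect_identical(sum(labels$labels == label_codes()[["artifact"]]), 0L)
  # label partition invariant
  expect_identical(length(labels$labels), nrow(gt) * ncol(gt))

  blank <- slide_image(array(255, dim = c(16, 16, 3)), 2)
  expect_true(all(classify_villous_tissue(blank)$labels ==
                    label_codes()[["background"]]))
})

test_that("stain deconvolution inverts the forward render", {
  # white pixel: zero absorbance
  white <- array(255, dim = c(1, 1, 3))
  expect_equal(extract_stain_channel(white)[1, 1], 0, tolerance = 1e-8)

  # pure AEC at known concentration, continuous render
  conc <- 0.73
  px <- render_stain_rgb(0, conc)
  arr <- array(px, dim = c(1, 1, 3))
  expect_equal(extract_stain_channel(arr)[1, 1], conc, tolerance = 1e-6)

  # pure hematoxylin leaks almost nothing into the AEC channel
  hx <- array(render_stain_rgb(0.6, 0), dim = c(1, 1, 3))
  stains <- deconvolve_stains(hx)
  expect_lte(abs(stains$aec[1, 1]), 0.05 * stains$hematoxylin[1, 1])
})

test_that("vessel segmentation splits, fills and filters instances", {
  lab <- label_mask(matrix(1L, 100, 100), 1)

  # two discs overlapping ~10% of radius: watershed must split them
  m <- matrix(0, 100, 100)
  m[villistry:::disc_indices(100, 100, 50, 40, 10)] <- 0.8
  m[villistry:::disc_indices(100, 100, 50, 58, 10)] <- 0.8
  v <- segment_vessels(m, lab, vessel_params(min_area_um2 = 5))
  expect_identical(nrow(v$records), 2L)
  expect_true(all(v$records$inside_villi))

  # annulus: the lumen is filled, the instance area is the outer disc
  m2 <- matrix(0, 60, 60)
  outer_idx <- villistry:::disc_indices(60, 60, 30, 30, 15)
  m2[outer_idx] <- 0.8
  m2[villistry:::disc_indices(60, 60, 30, 30, 8)] <- 0
  lab2 <- label_mask(matrix(1L, 60, 60), 1)
  v2 <- segment_vessels(m2, lab2, vessel_params(min_area_um2 = 5))
  expect_identical(nrow(v2$records), 1L)
  expect_equal(v2$records$area_um2, length(outer_idx))

  # a disc below the minimum area is dropped
  m3 <- matrix(0, 60, 60)
  m3[villistry:::disc_indices(60, 60, 30, 30, 1.5)] <- 0.8
  v3 <- segment_vessels(m3, lab2, vessel_params(min_area_um2 = 20))
  expect_identical(nrow(v3$records), 0L)

  # no villous pixels anywhere
  bg <- label_mask(matrix(0L, 20, 20), 1)
  expect_error(segment_vessels(matrix(0, 20, 20), bg), "no villous tissue")
})

test_that("detected vessel count is monotone in generated vessel density", {
  counts <- vapply(c(400, 1324, 2400), function(density) {
    sl <- generate_slide(slide_params(width_px = 256L, height_px = 256L,
                                      pixel_size_um = 2,
                                      vessel_density_per_mm2 = density,
                                      seed = 9L))
    seg <- segment_slide(sl$image)
    sum(seg$vessels$records$inside_villi)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("exclusion polygons clip, exclude and propagate to denominators", {
  sl <- generate_slide(small_slide_params(seed = 2L))
  labels <- classify_villous_tissue(sl$image)

  expect_identical(apply_exclusions(labels, list())$labels, labels$labels)

  nr <- nrow(labels$labels); nc <- ncol(labels$labels)
  whole <- rbind(c(0, 0), c(0, nc + 5), c(nr + 5, nc + 5), c(nr + 5, 0))
  expect_warning(all_exc <- apply_exclusions(labels, list(whole)), "clipping")
  expect_true(all(all_exc$labels == label_codes()[["excluded"]]))
  expect_error(compute_metrics(all_exc), "no villous tissue")

  # excluding the left half roughly halves the villous pixel count
  half <- rbind(c(0.5, 0.5), c(0.5, nc / 2), c(nr + 0.5, nc / 2), c(nr + 0.5, 0.5))
  half_exc <- suppressWarnings(apply_exclusions(labels, list(half)))
  n_before <- sum(labels$labels == 1L)
  n_after <- sum(half_exc$labels == 1L)
  n_left <- sum(labels$labels[, 1:(nc / 2)] == 1L)
  expect_equal(n_after, n_before - n_left, tolerance = 0.02 * n_before)
})

test_that("slide QC flags artifact load and weak staining", {
  clean <- generate_slide(small_slide_params(seed = 4L, artifact_fraction = 0))
  seg <- segment_slide(clean$image)
  qc <- qc_slide(seg$labels, seg$stain_field)
  expect_true(qc$pass)

  arty <- generate_slide(small_slide_params(seed = 4L, artifact_fraction = 0.3))
  seg_a <- segment_slide(arty$image)
  qc_a <- qc_slide(seg_a$labels, seg_a$stain_field)
  expect_false(qc_a$pass)
  expect_match(qc_a$reason, "artifact fraction")

  weak <- generate_slide(small_slide_params(seed = 4L, artifact_fraction = 0,
                                            stain_intensity_scale = 0.1))
  seg_w <- segment_slide(weak$image)
  qc_w <- qc_slide(seg_w$labels, seg_w$stain_field)
  expect_false(qc_w$pass)
  expect_match(qc_w$reason, "weak staining")
})
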