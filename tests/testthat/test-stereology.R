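test_that("metrics match hand arithmetic on the toy mask", {
  m <- compute_metrics(toy_mask_10x10(), toy_vessels())
  expect_equal(m$density_villi_pct, 50)
  expect_equal(m$vessel_area_pct, 16)        # 8 vessel px / 50 villi px
  expect_equal(m$vessel_count_per_mm2, 2 / 5e-5)  # 2 instances / 50 um^2

  # fibrin-free denominator variant
  m_leg <- compute_metrics(toy_mask_10x10(), toy_vessels(),
                           legend_denominator = TRUE)
  expect_equal(m_leg$density_villi_pct, 100 * 50 / 90)
})

test_that("vessel-free metrics are zero and density is unchanged", {
  m <- compute_metrics(toy_mask_10x10(), NULL)
  expect_equal(m$vessel_area_pct, 0)
  expect_equal(m$vessel_count_per_mm2, 0)
  expect_equal(m$density_villi_pct, 50)
})

test_that("computed density tracks the generator villous fraction", {
  sl <- generate_slide(small_slide_params(seed = 6L, villous_fraction = 0.5))
  seg <- segment_slide(sl$image)
  m <- compute_metrics(seg$labels, seg$vessels)
  expect_lt(abs(m$density_villi_pct - 50), 5)
})

test_that("metrics are scale invariant under 2x nearest-neighbour resampling", {
  lab <- toy_mask_10x10()
  ves <- toy_vessels()
  m1 <- compute_metrics(lab, ves)

  up <- function(m) m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  lab2 <- label_mask(up(lab$labels), lab$pixel_size_um / 2)
  rec2 <- ves$records
  rec2$area_um2 <- rec2$area_um2            # areas in um^2 are physical
  rec2$centroid_row <- rec2$centroid_row * 2 - 0.5
  rec2$centroid_col <- rec2$centroid_col * 2 - 0.5
  ves2 <- vessel_instances(up(ves$instance_labels), rec2, ves$pixel_size_um / 2)
  m2 <- compute_metrics(lab2, ves2)

  expect_equal(m2$density_villi_pct, m1$density_villi_pct, tolerance = 0.01)
  expect_equal(m2$vessel_area_pct, m1$vessel_area_pct, tolerance = 0.01)
  expect_equal(m2$vessel_count_per_mm2, m1$vessel_count_per_mm2, tolerance = 0.01)
})

test_that("counts decompose over an exact partition and regions stay within the whole", {
  sl <- generate_slide(small_slide_params(seed = 8L))
  seg <- segment_slide(sl$image)
  whole <- compute_metrics(seg$labels, seg$vessels)

  nr <- nrow(seg$labels$labels); nc <- ncol(seg$labels$labels)
  left_poly <- rbind(c(0.5, 0.5), c(0.5, nc / 2 + 0.5),
                     c(nr + 0.5, nc / 2 + 0.5), c(nr + 0.5, 0.5))
  right_poly <- rbind(c(0.5, nc / 2 + 0.5), c(0.5, nc + 0.5),
                      c(nr + 0.5, nc + 0.5), c(nr + 0.5, nc / 2 + 0.5))
  keep_right <- compute_metrics(suppressWarnings(
    apply_exclusions(seg$labels, list(left_poly))), seg$vessels)
  keep_left <- compute_metrics(suppressWarnings(
    apply_exclusions(seg$labels, list(right_poly))), seg$vessels)
  n_whole <- whole$vessel_count_per_mm2 * whole$villous_area_mm2
  n_parts <- keep_left$vessel_count_per_mm2 * keep_left$villous_area_mm2 +
    keep_right$vessel_count_per_mm2 * keep_right$villous_area_mm2
  expect_equal(n_parts, n_whole, tolerance = 1e-9)

  # region terms never exceed whole-section terms
  regions <- place_regions(seg$labels, k = 2, diameter_um = 400, seed = 1)
  for (r in regions) {
    mr <- compute_metrics(seg$labels, seg$vessels, region = r)
    expect_lte(mr$villous_area_mm2, whole$villous_area_mm2)
    expect_lte(mr$vessel_count_per_mm2 * mr$villous_area_mm2, n_whole)
  }
})

test_that("region placement is greedy-optimal, floored and deterministic", {
  # uniform all-villi mask: any three non-overlapping circles, fraction 1
  lab <- label_mask(matrix(1L, 200, 200), 10)
  regs <- place_regions(lab, k = 3, diameter_um = 500, seed = 2)
  expect_length(regs, 3)
  for (r in regs) {
    m <- compute_metrics(lab, region = r)
    expect_equal(m$density_villi_pct, 100)
  }
  for (i in 1:2) for (j in (i + 1):3) {
    d <- sqrt(sum((regs[[i]]$center - regs[[j]]$center)^2))
    expect_gte(d, 500 / 10)   # no overlap: centre distance >= diameter in px
  }

  # all-background mask: no candidate meets the villous floor
  bg <- label_mask(matrix(0L, 200, 200), 10)
  expect_error(place_regions(bg, k = 1, diameter_um = 500, seed = 1),
               "insufficient villous tissue")

  # greedy k = 1 on a dense candidate grid equals the exhaustive argmax
  sl <- generate_slide(slide_params(width_px = 64L, height_px = 64L,
                                    pixel_size_um = 4, seed = 12L,
                                    vessel_density_per_mm2 = 0))
  lab2 <- sl$truth$label_mask
  got <- place_regions(lab2, k = 1, diameter_um = 120, seed = 3, stride_px = 1,
                       floor = 0)[[1]]
  villi_in_circle <- function(cy, cx) {
    sum(lab2$labels[villistry:::disc_indices(64, 64, cy, cx, 15)] == 1L)
  }
  best <- -1
  for (cy in 16:49) for (cx in 16:49) {
    best <- max(best, villi_in_circle(cy, cx))
  }
  expect_equal(villi_in_circle(got$center[1], got$center[2]), best)

  # determinism
  got2 <- place_regions(lab2, k = 1, diameter_um = 120, seed = 3, stride_px = 1,
                        floor = 0)[[1]]
  expect_identical(got$center, got2$center)
})
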