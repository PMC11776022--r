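# Programmatic fixtures shared across test files.

# A small slide at 4 um/px for fast end-to-end checks.
small_slide_params <- function(seed = 1L, ...) {
  args <- list(width_px = 256L, height_px = 256L, pixel_size_um = 4,
               seed = seed)
  do.call(slide_params, utils::modifyList(args, list(...)))
}

# Axis-aligned rectangles of pure class colours: the classifier must
# reproduce the analytic mask exactly on these.
make_rect_image <- function(nr = 60, nc = 80, pixel_size_um = 2) {
  cols <- list(background = c(250, 250, 250),
               villi = round(render_stain_rgb(0.6, 0)[1, ]),
               fibrin = round(render_stain_rgb(0.05, 0.15)[1, ]),
               vessel = round(render_stain_rgb(0.2, 0.9)[1, ]))
  rgb <- array(0, dim = c(nr, nc, 3))
  lab <- matrix(label_codes()[["background"]], nr, nc)
  put <- function(rows, colsel, colour, code) {
    for (ch in 1:3) rgb[rows, colsel, ch] <<- colour[ch]
    lab[rows, colsel] <<- code
  }
  put(1:nr, 1:nc, cols$background, label_codes()[["background"]])
  put(10:40, 5:35, cols$villi, label_codes()[["villi"]])
  put(45:55, 50:70, cols$fibrin, label_codes()[["fibrin"]])
  put(20:28, 10:18, cols$vessel, label_codes()[["villi"]])  # vessels are villi
  list(image = slide_image(rgb, pixel_size_um, id = "rects"),
       labels = lab)
}

# One fully sedentary valid day: wear block of `wear` minutes of constant
# low counts, zeros elsewhere.
sedentary_day <- function(wear = 600, count = 50) {
  counts <- integer(1440)
  counts[201:(200 + wear)] <- count
  data.frame(subject_id = "S001", period = "<20w", day = 1L,
             minute_of_day = 0:1439, counts = counts,
             stringsAsFactors = FALSE)
}

# A label mask with known composition on a grid, pixel 1 um.
toy_mask_10x10 <- function() {
  lab <- matrix(label_codes()[["background"]], 10, 10)  # 40 intervillous
  lab[1:5, ] <- label_codes()[["villi"]]                # 50 villi
  lab[6, ] <- label_codes()[["fibrin"]]                 # 10 fibrin
  label_mask(lab, 1)
}

# Two vessel instances (4 px each) on the villous rows of the toy mask.
toy_vessels <- function() {
  inst <- matrix(0L, 10, 10)
  inst[2:3, 2:3] <- 1L
  inst[2:3, 6:7] <- 2L
  rec <- data.frame(id = 1:2, area_um2 = c(4, 4),
                    centroid_row = c(2.5, 2.5), centroid_col = c(2.5, 6.5),
                    inside_villi = c(TRUE, TRUE))
  vessel_instances(inst, rec, 1)
}
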