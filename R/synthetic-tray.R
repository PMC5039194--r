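#' Rendering style for synthetic tray images
#'
#' Controls the appearance of [render_tray_image()]: image resolution,
#' soil background colour and texture, the leaf colour set (by default
#' the nine-green reference palette of [default_green_palette()]), and
#' the leaf-fan geometry.  Rosettes are drawn as fans of rotated
#' ellipses: controllable area and elongation without claiming
#' botanical realism.
#'
#' @param width,height Image size in pixels (default 640 x 480; the
#'   platform-native 2560 x 1920 renders the same scene at 4x scale).
#' @param soil_rgb Background soil colour (RGB, 0-255).
#' @param soil_texture_sd SD of per-pixel luminance jitter added to all
#'   three soil channels (keeps the excess-green index of soil exactly
#'   at its noise-free value).
#' @param leaf_palette k x 3 matrix of leaf RGB colours (0-255).
#' @param hue_weights Sampling weights over palette rows for leaf
#'   colours; recycled/normalised.
#' @param n_leaves_range Integer range of leaves per rosette.
#' @param leaf_aspect Length/width ratio of a single leaf ellipse.
#' @param pixel_noise_sd SD of independent per-channel Gaussian noise
#'   added to the final image (0 = exact palette colours).
#' @return A list of class `tray_style`.
#' @export
tray_style <- function(width = 640, height = 480,
                       soil_rgb = c(110, 85, 60), soil_texture_sd = 6,
                       leaf_palette = default_green_palette(),
                       hue_weights = NULL,
                       n_leaves_range = c(6, 10), leaf_aspect = 2.5,
                       pixel_noise_sd = 0) {
  leaf_palette <- as.matrix(leaf_palette)
  stopifnot(ncol(leaf_palette) == 3, nrow(leaf_palette) >= 1)
  if (is.null(hue_weights)) hue_weights <- rep(1, nrow(leaf_palette))
  hue_weights <- rep_len(hue_weights, nrow(leaf_palette))
  hue_weights <- hue_weights / sum(hue_weights)
  structure(list(width = width, height = height, soil_rgb = soil_rgb,
                 soil_texture_sd = soil_texture_sd,
                 leaf_palette = leaf_palette, hue_weights = hue_weights,
                 n_leaves_range = n_leaves_range, leaf_aspect = leaf_aspect,
                 pixel_noise_sd = pixel_noise_sd),
            class = "tray_style")
}

#' Reference nine-green leaf palette
#'
#' Nine green hues ordered dark to light, spanning the colour range of
#' healthy to stressed rosette tissue.  All entries satisfy the default
#' vegetation criterion of [segment_rosette()] (excess green > 25,
#' G > 50).
#'
#' @return A 9 x 3 numeric matrix (rows = hues, columns = R, G, B in
#'   0-255).
#' @export
default_green_palette <- function() {
  m <- matrix(c(
     30,  60,  25,
     40,  80,  30,
     50,  95,  40,
     55, 110,  45,
     60, 125,  50,
     70, 140,  60,
     85, 155,  70,
    100, 170,  85,
    120, 185, 100), ncol = 3, byrow = TRUE)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Render a synthetic tray image with exact ground truth
#'
#' Draws one tray of potted rosettes on a textured soil background.
#' Each rosette is a fan of rotated-ellipse leaves centred in its pot
#' cell; leaf sizes are iteratively rescaled until the rendered pixel
#' area is within 3% of the requested target (well inside the 10%
#' contract).  Each leaf is painted in one palette colour, so the
#' per-pot hue composition is known exactly.
#'
#' @param design A [generate_design()] tibble.
#' @param tray_index Which tray to render.
#' @param day Measurement day (recorded in the ground truth).
#' @param style A [tray_style()].
#' @param area_targets Named numeric vector of target rosette areas in
#'   pixels, named by `plant_id`; plants without a target get 0 (empty
#'   pot).  A target too large for the pot cell is an error.
#' @param seed Integer seed.
#' @return A list of class `tray_render`: `image` (height x width x 3
#'   array, 0-255), `layout`, and `truth`, a tibble with one row per
#'   occupied pot: `plant_id`, `tray_row`, `tray_col`, `area_target`,
#'   `area_px` (exact rendered mask area), `mask` (list column of
#'   logical matrices, pot-cell sized), `hue_map` (list column, integer
#'   palette index per pixel, 0 = background) and `hue_frac` (list
#'   column, exact rendered palette fractions).
#' @export
render_tray_image <- function(design, tray_index, day, style = tray_style(),
                              area_targets, seed = 1) {
  stopifnot(inherits(style, "tray_style"))
  layout <- attr(design, "layout")
  if (is.null(layout)) layout <- c(rows = 4, cols = 5)
  H <- style$height; W <- style$width
  ch <- H %/% layout[["rows"]]; cw <- W %/% layout[["cols"]]
  pots <- design[design$tray == tray_index, , drop = FALSE]
  if (nrow(pots) == 0) abort("tray ", tray_index, " has no plants")

  withr_seed(seed + 7919L * tray_index + day, {
    # soil background with luminance-only texture
    lum <- matrix(rnorm(H * W, 0, style$soil_texture_sd), H, W)
    img <- array(0, c(H, W, 3))
    for (c3 in 1:3) img[, , c3] <- pmin(255, pmax(0, style$soil_rgb[c3] + lum))

    truth <- purrr::pmap(pots, function(plant_id, tray_row, tray_col, ...) {
      target <- if (plant_id %in% names(area_targets)) {
        area_targets[[plant_id]]
      } else 0
      res <- draw_rosette(ch, cw, target, style)
      r0 <- (tray_row - 1) * ch; c0 <- (tray_col - 1) * cw
      hm <- res$hue_map
      on <- hm > 0
      if (any(on)) {
        idx <- which(on, arr.ind = TRUE)
        for (c3 in 1:3) {
          flat <- cbind(idx[, 1] + r0, idx[, 2] + c0, c3)
          img[flat] <<- style$leaf_palette[hm[on], c3]
        }
      }
      k <- nrow(style$leaf_palette)
      frac <- if (any(on)) {
        tabulate(hm[on], nbins = k) / sum(on)
      } else rep(NA_real_, k)
      tibble(plant_id = plant_id, tray_row = tray_row, tray_col = tray_col,
             day = day, area_target = target, area_px = sum(on),
             mask = list(on), hue_map = list(hm), hue_frac = list(frac))
    }) |> dplyr::bind_rows()

    if (style$pixel_noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, style$pixel_noise_sd), dim(img))
      img <- pmin(255, pmax(0, img))
    }
  })
  structure(list(image = img, layout = layout, day = day, truth = truth),
            class = "tray_render")
}

# draw one leaf-fan rosette in a ch x cw cell; returns hue_map (integer)
draw_rosette <- function(ch, cw, area_target, style) {
  hm <- matrix(0L, ch, cw)
  if (area_target <= 0) return(list(hue_map = hm))
  max_len <- (min(ch, cw) / 2 - 2) # leaf length limit from cell geometry
  n_leaves <- sample(style$n_leaves_range[1]:style$n_leaves_range[2], 1)
  angles <- seq(0, 2 * pi, length.out = n_leaves + 1)[-1] +
    runif(n_leaves, -0.25, 0.25)
  rel_len <- runif(n_leaves, 0.75, 1)
  hues <- sample.int(nrow(style$leaf_palette), n_leaves, replace = TRUE,
                     prob = style$hue_weights)
  # initial guess: leaves tile ~80% non-overlapping
  L <- sqrt(area_target * style$leaf_aspect * 4 /
              (pi * sum(rel_len^2) * 0.8))
  yy <- matrix(seq_len(ch) - (ch + 1) / 2, ch, cw)
  xx <- matrix(seq_len(cw) - (cw + 1) / 2, ch, cw, byrow = TRUE)
  for (iter in 1:6) {
    if (L * max(rel_len) > max_len) {
      abort("area target ", area_target,
            " px exceeds the pot cell (", ch, " x ", cw, ")")
    }
    hm[] <- 0L
    for (i in seq_len(n_leaves)) {
      a <- L * rel_len[i] / 2                    # semi-major
      b <- a / style$leaf_aspect                 # semi-minor
      d <- a                                     # centre offset from hub
      th <- angles[i]
      u <- xx * cos(th) + yy * sin(th) - d
      v <- -xx * sin(th) + yy * cos(th)
      hm[(u / a)^2 + (v / b)^2 <= 1] <- hues[i]
    }
    got <- sum(hm > 0)
    if (got > 0 && abs(got - area_target) / area_target <= 0.03) break
    ratio <- if (got == 0) 2 else sqrt(area_target / got)
    L <- L * min(max(ratio, 0.5), 2)
  }
  list(hue_map = hm)
}
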