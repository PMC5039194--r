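#' Tray layout
#'
#' Grid geometry used to cut a tray image into pot cells.  Cells are
#' half-open row-major intervals, origin at the top-left pixel; an
#' optional outer margin (pixels) is removed before tiling.
#'
#' @param rows,cols Number of pot rows/columns (default 4 x 5).
#' @param margin Outer margin stripped from all four sides, in pixels.
#' @return A list of class `tray_layout`.
#' @export
tray_layout <- function(rows = 4, cols = 5, margin = 0) {
  if (rows < 1 || cols < 1) abort("`rows` and `cols` must be >= 1")
  if (margin < 0) abort("`margin` must be >= 0")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 margin = as.integer(margin)), class = "tray_layout")
}

#' Cut a tray image into per-pot crops
#'
#' Splits the usable region of a tray image into `rows x cols` equal
#' cells in row-major order.  The cells partition the region exactly:
#' every usable pixel lands in exactly one crop.
#'
#' @param image Height x width x 3 numeric array (RGB, 0-255), or a
#'   height x width matrix.
#' @param layout A [tray_layout()].
#' @return A list of `rows * cols` crops (same type as the input), in
#'   row-major order, with attributes `tray_row`/`tray_col` on each.
#' @examples
#' img <- array(0, c(480, 640, 3))
#' crops <- crop_tray(img, tray_layout(4, 5))
#' dim(crops[[1]])   # 120 128 3
#' @export
crop_tray <- function(image, layout = tray_layout()) {
  stopifnot(inherits(layout, "tray_layout"))
  d <- dim(image)
  if (length(d) < 2) abort("`image` must be a matrix or H x W x 3 array")
  m <- layout$margin
  H <- d[1] - 2 * m; W <- d[2] - 2 * m
  if (H <= 0 || W <= 0) abort("margin leaves no usable image region")
  if (H %% layout$rows != 0 || W %% layout$cols != 0) {
    abort(sprintf(
      "image region %d x %d does not divide into a %d x %d grid (cells would be %.2f x %.2f px)",
      H, W, layout$rows, layout$cols, H / layout$rows, W / layout$cols))
  }
  ch <- H %/% layout$rows; cw <- W %/% layout$cols
  out <- vector("list", layout$rows * layout$cols)
  k <- 1L
  for (r in seq_len(layout$rows)) {
    for (cc in seq_len(layout$cols)) {
      ri <- m + (r - 1) * ch + seq_len(ch)
      ci <- m + (cc - 1) * cw + seq_len(cw)
      crop <- if (length(d) == 3) image[ri, ci, , drop = FALSE]
              else image[ri, ci, drop = FALSE]
      attr(crop, "tray_row") <- r
      attr(crop, "tray_col") <- cc
      out[[k]] <- crop
      k <- k + 1L
    }
  }
  out
}

#' Segment vegetation pixels in a pot crop
#'
#' Background subtraction by a colour-index threshold: a pixel is
#' classified as plant when its excess-green index 2G - R - B exceeds
#' `exg_threshold` and its green channel exceeds `min_green`.  Soil,
#' pot rims and shadows are predominantly grey-brown (2G - R - B near
#' or below 0), so the rule separates green vegetation robustly and is
#' fully reproducible, unlike proprietary platform segmenters.
#'
#' @param pot_image Height x width x 3 RGB array (0-255).
#' @param exg_threshold Excess-green threshold (0-255 scale).
#' @param min_green Minimum green-channel value.
#' @return A logical matrix (`TRUE` = plant) of class `rosette_mask`.
#' @export
segment_rosette <- function(pot_image, exg_threshold = 25, min_green = 50) {
  d <- dim(pot_image)
  if (length(d) != 3 || d[3] != 3) abort("`pot_image` must be an H x W x 3 RGB array")
  exg <- 2 * pot_image[, , 2] - pot_image[, , 1] - pot_image[, , 3]
  mask <- exg > exg_threshold & pot_image[, , 2] > min_green
  class(mask) <- c("rosette_mask", class(mask))
  mask
}

#' Clean a binary rosette mask
#'
#' Standard binary clean-up: removes speckles smaller than
#' `min_object_px`, then selects the largest connected plant object
#' and fills its enclosed holes.  Connectivity is judged on a
#' morphologically *closed* copy of the mask (disc brush of
#' `closing_radius`), so separate leaves of one rosette count as one
#' object, but the counted pixels are the originally segmented ones —
#' the closing dilation itself is never added to the area, which keeps
#' pixel counts faithful for small rosettes.  Component-size ties are
#' broken by lowest centroid row, then column.  Idempotent, and the
#' empty mask maps to itself.
#'
#' @param mask Logical matrix.
#' @param min_object_px Minimum component size kept, in pixels.
#' @param closing_radius Radius (px) of the connectivity closing brush;
#'   0 disables closing (plain connected components).
#' @return Cleaned logical matrix of class `rosette_mask`.
#' @export
clean_mask <- function(mask, min_object_px = 20, closing_radius = 2) {
  m <- (unclass(mask) > 0) * 1
  empty <- matrix(FALSE, nrow(mask), ncol(mask))
  class(empty) <- c("rosette_mask", class(empty))
  if (!any(m > 0)) return(empty)

  # drop speckles first so closing cannot weld them to the rosette
  lb <- EBImage::bwlabel(m)
  sizes <- tabulate(lb[lb > 0])
  keep <- which(sizes >= min_object_px)
  if (length(keep) == 0) return(empty)
  m <- matrix(as.numeric(lb %in% keep), nrow(mask), ncol(mask))

  # connectivity view: closed + hole-filled copy
  conn <- m
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    conn <- as.matrix(EBImage::closing(conn, brush))
  }
  conn <- as.matrix(EBImage::fillHull(conn))

  lb <- EBImage::bwlabel(conn)
  n_obj <- max(lb)
  if (n_obj > 1) {
    sizes <- tabulate(lb[lb > 0], nbins = n_obj)
    best <- which(sizes == max(sizes))
    if (length(best) > 1) { # tie-break: lowest centroid row, then column
      cent <- t(vapply(best, function(i) {
        idx <- which(lb == i, arr.ind = TRUE)
        c(mean(idx[, 1]), mean(idx[, 2]))
      }, numeric(2)))
      best <- best[order(cent[, 1], cent[, 2])][1]
    }
  } else best <- 1
  # original pixels of the winning object, plus its enclosed holes
  m <- m * (lb == best)
  m <- as.matrix(EBImage::fillHull(m))
  out <- m > 0
  class(out) <- c("rosette_mask", class(out))
  out
}

#' Rosette area in pixels
#'
#' @param mask Logical matrix (cleaned rosette mask).
#' @return Non-negative integer pixel count.
#' @export
rosette_area <- function(mask) {
  sum(unclass(mask) > 0)
}

#' Segment every pot of a rendered or loaded tray
#'
#' Convenience wrapper chaining [crop_tray()], [segment_rosette()] and
#' [clean_mask()] over a whole tray image.
#'
#' @param image Tray RGB array (0-255).
#' @param layout A [tray_layout()].
#' @param exg_threshold,min_green Passed to [segment_rosette()].
#' @param min_object_px,closing_radius Passed to [clean_mask()].
#' @return A tibble with one row per pot: `tray_row`, `tray_col`,
#'   `area_px`, the cleaned `mask`, the colour-true surface mask
#'   `veg_mask` (cleaned mask intersected with the raw colour-index
#'   mask, i.e. excluding pixels only added by closing/hole filling —
#'   the right pixel set for colour work) and the `crop` itself
#'   (list columns).
#' @export
segment_tray <- function(image, layout = tray_layout(),
                         exg_threshold = 25, min_green = 50,
                         min_object_px = 20, closing_radius = 2) {
  crops <- crop_tray(image, layout)
  purrr::map(crops, function(cr) {
    raw <- segment_rosette(cr, exg_threshold, min_green)
    mk <- clean_mask(raw, min_object_px, closing_radius)
    # colour-true plant surface: cleaned extent minus closing fill-in
    veg <- mk & raw
    tibble(tray_row = attr(cr, "tray_row"), tray_col = attr(cr, "tray_col"),
           area_px = rosette_area(mk), mask = list(mk),
           veg_mask = list(veg), crop = list(cr))
  }) |> dplyr::bind_rows()
}
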