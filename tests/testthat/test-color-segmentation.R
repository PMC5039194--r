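make_img <- function(colours, n_each, w = 10) {
  # stack horizontal bands of the given colours
  h <- length(colours) * n_each %/% w
  img <- array(0, c(length(colours) * ceiling(n_each / w), w, 3))
  mask <- matrix(FALSE, dim(img)[1], w)
  r0 <- 0
  for (i in seq_along(colours)) {
    rows <- r0 + seq_len(ceiling(n_each / w))
    for (c3 in 1:3) img[rows, , c3] <- colours[[i]][c3]
    mask[rows, ] <- TRUE
    r0 <- r0 + length(rows)
  }
  list(img = img, mask = mask)
}

test_that("calibration pixel pooling counts, caps and strata behave", {
  g <- default_green_palette()
  a <- make_img(list(g[1, ]), n_each = 100)
  b <- make_img(list(g[2, ]), n_each = 200)
  px <- collect_calibration_pixels(list(a$img, b$img), list(a$mask, b$mask))
  expect_equal(nrow(px), sum(a$mask) + sum(b$mask))

  capped <- collect_calibration_pixels(list(a$img, b$img),
                                       list(a$mask, b$mask),
                                       cap_per_image = 50, seed = 3)
  expect_equal(nrow(capped), 100)
  again <- collect_calibration_pixels(list(a$img, b$img),
                                      list(a$mask, b$mask),
                                      cap_per_image = 50, seed = 3)
  expect_identical(capped, again)

  # background-only image contributes nothing
  emp <- matrix(FALSE, dim(a$img)[1], dim(a$img)[2])
  px2 <- collect_calibration_pixels(list(a$img, a$img),
                                    list(a$mask, emp))
  expect_equal(nrow(px2), sum(a$mask))
  expect_error(collect_calibration_pixels(list(a$img), list(emp)), "empty")
})

test_that("k-means palette recovers an exact 9-colour dataset with WCSS 0", {
  g <- default_green_palette()
  px <- tibble::tibble(R = rep(g[, 1], each = 12),
                       G = rep(g[, 2], each = 12),
                       B = rep(g[, 3], each = 12))
  pal <- build_hue_palette(px, k = 9, seed = 1)
  expect_equal(pal$wcss, 0, tolerance = 1e-8)
  expect_equal(max(palette_match_dist(pal$centroids, g)), 0, tolerance = 1e-8)
  # deterministic under seed
  pal2 <- build_hue_palette(px, k = 9, seed = 1)
  expect_identical(pal$centroids, pal2$centroids)
})

test_that("k = 1 centroid is the arithmetic mean; too few colours error", {
  px <- tibble::tibble(R = c(0, 10, 20), G = c(0, 10, 20), B = c(30, 60, 90))
  pal <- build_hue_palette(px, k = 1, seed = 1)
  expect_equal(unname(pal$centroids[1, ]), c(10, 10, 60))
  expect_error(build_hue_palette(px, k = 9), "3")
})

test_that("colour assignment is nearest-centroid with lowest-index ties", {
  g <- default_green_palette()
  px <- tibble::tibble(R = rep(g[, 1], 10), G = rep(g[, 2], 10),
                       B = rep(g[, 3], 10))
  pal <- build_hue_palette(px, k = 9, seed = 1)
  # pixel exactly at centroid 3
  img <- array(rep(pal$centroids[3, ], each = 1), c(1, 1, 3))
  lab <- segment_colors(img, matrix(TRUE, 1, 1), pal)
  expect_equal(lab[1, 1], 3L)
  # equidistant pixel between centroids 1 and 2 -> lowest index
  mid <- (pal$centroids[1, ] + pal$centroids[2, ]) / 2
  img2 <- array(rep(mid, each = 1), c(1, 1, 3))
  expect_equal(segment_colors(img2, matrix(TRUE, 1, 1), pal)[1, 1], 1L)
})

test_that("hue abundance is a probability vector with exact fractions", {
  lab <- matrix(0L, 5, 4)
  lab[1, 1:4] <- 4L; lab[2, 1:4] <- 4L; lab[3, 1:2] <- 4L # 10 px of hue 4
  ab <- hue_abundance(lab, rosette_area = 10, k = 9)
  expect_equal(ab$fraction[4], 1)
  expect_equal(sum(ab$fraction), 1)

  lab2 <- matrix(c(rep(1L, 60), rep(2L, 40)), 10, 10)
  ab2 <- hue_abundance(lab2, k = 9)
  expect_equal(ab2$fraction[1:2], c(0.6, 0.4))

  empty <- hue_abundance(matrix(0L, 3, 3), k = 9)
  expect_true(all(empty$empty) && all(is.na(empty$fraction)))
  expect_error(hue_abundance(lab2, rosette_area = 99), "does not match")
})

test_that("salt/control hue ratio handles equality, change and zero control", {
  ab <- tidyr::expand_grid(accession = "a", day = 1, hue = 1:2,
                           treatment = c("control", "salt"),
                           replicate = 1:2)
  ab$fraction <- with(ab, ifelse(hue == 1,
                                 ifelse(treatment == "salt", 0.3, 0.15),
                                 0.5))
  r <- hue_salt_ratio(ab)
  expect_equal(r$ratio[r$hue == 1], 2)
  expect_equal(r$ratio[r$hue == 2], 1)

  ab0 <- ab
  ab0$fraction[ab0$treatment == "control" & ab0$hue == 1] <- 0
  r0 <- hue_salt_ratio(ab0)
  expect_true(is.na(r0$ratio[r0$hue == 1]) && r0$control_zero[r0$hue == 1])

  expect_error(hue_salt_ratio(ab[ab$treatment == "salt", ]), "treatment")
})

test_that("palette and abundance are recovered from a painted tray", {
  design <- small_design()
  targets <- stats::setNames(rep(2200, nrow(design)), design$plant_id)
  rt <- render_tray_image(design, 1, 0, tray_style(), targets, seed = 21)
  pots <- segment_tray(rt$image)
  px <- collect_calibration_pixels(pots$crop, pots$veg_mask,
                                   cap_per_image = 3000, seed = 1)
  pal <- build_hue_palette(px, k = 9, seed = 1)
  expect_lt(max(palette_match_dist(pal$centroids, default_green_palette())), 5)

  m <- dplyr::inner_join(pots, rt$truth, by = c("tray_row", "tray_col"),
                         suffix = c("_seg", "_true"))
  m <- m[m$area_px_true > 0, ]
  for (i in seq_len(nrow(m))) {
    lab <- segment_colors(m$crop[[i]], m$veg_mask[[i]], pal)
    ab <- hue_abundance(lab, k = 9)
    expect_equal(sum(ab$fraction), 1, tolerance = 1e-12)
    expect_lt(max(abs(ab$fraction - m$hue_frac[[i]])), 0.02)
  }
})
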