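#' Pool calibration pixels for palette building
#'
#' Collects the RGB values of all mask-true (rosette) pixels from a set
#' of images, typically sampled from the start, middle and end of the
#' phenotyping period and from both treatments, so the colour scale is
#' unbiased with respect to time and stress level.  An optional
#' per-image cap subsamples pixels deterministically under the seed.
#'
#' @param images List of H x W x 3 RGB arrays (0-255).
#' @param masks List of logical matrices aligned with `images`.
#' @param strata Optional character vector labelling each image (e.g.
#'   `"start/control"`); recycled.
#' @param cap_per_image Maximum pixels kept per image (`Inf` = all).
#' @param seed Integer seed for subsampling.
#' @return A tibble with columns `R`, `G`, `B`, `stratum`, `image`.
#' @export
collect_calibration_pixels <- function(images, masks, strata = NULL,
                                       cap_per_image = Inf, seed = 1) {
  stopifnot(length(images) == length(masks))
  if (length(images) == 0) abort("no calibration images supplied")
  if (is.null(strata)) strata <- "all"
  strata <- rep_len(strata, length(images))
  rows <- purrr::imap(images, function(img, i) {
    m <- unclass(masks[[i]]) > 0
    if (any(dim(m) != dim(img)[1:2])) {
      abort("mask ", i, " is not aligned with its image")
    }
    on <- which(m)
    if (length(on) == 0) return(NULL)
    if (is.finite(cap_per_image) && length(on) > cap_per_image) {
      withr_seed(seed + i, on <- sort(sample(on, cap_per_image)))
    }
    tibble(R = img[, , 1][on], G = img[, , 2][on], B = img[, , 3][on],
           stratum = strata[i], image = i)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("all calibration masks are empty")
  out
}

#' Build a hue palette by k-means in RGB space
#'
#' Clusters pooled rosette pixels into `k` base hues by k-means on
#' Euclidean distance in RGB space.  Initial centres are drawn with
#' k-means++ sampling over the distinct colours (so heavily duplicated
#' pixel values cannot collapse the seeding); `nstart` seeded restarts
#' are run and the solution with the best within-cluster sum of
#' squares is kept.  Centroids are ordered dark to light by luminance
#' (0.299 R + 0.587 G + 0.114 B), which fixes the meaning of
#' "hue 1 .. hue k" for a given experiment.
#'
#' @param pixels A data frame with columns `R`, `G`, `B` (0-255), as
#'   from [collect_calibration_pixels()].
#' @param k Number of hues (default 9).
#' @param seed Integer seed; fixed seed gives a bit-identical palette.
#' @param nstart Number of k-means restarts.
#' @return A list of class `hue_palette`: `centroids` (k x 3 matrix,
#'   rows ordered by luminance), `k`, `wcss` (total within-cluster sum
#'   of squares), `seed`, `n_pixels`.
#' @export
build_hue_palette <- function(pixels, k = 9, seed = 1, nstart = 10) {
  x <- as.matrix(pixels[, c("R", "G", "B")])
  ux <- unique(x)
  if (nrow(ux) < k) {
    abort("need at least k = ", k, " distinct colours; dataset has only ",
          nrow(ux))
  }
  withr_seed(seed, {
    best <- NULL
    for (rep in seq_len(nstart)) {
      init <- kmeanspp_init(ux, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    km <- best
  })
  ctr <- km$centers
  lum <- ctr %*% c(0.299, 0.587, 0.114)
  ord <- order(lum)
  ctr <- ctr[ord, , drop = FALSE]
  rownames(ctr) <- paste0("hue_", seq_len(k))
  colnames(ctr) <- c("R", "G", "B")
  structure(list(centroids = ctr, k = k, wcss = km$tot.withinss,
                 seed = seed, n_pixels = nrow(x)),
            class = "hue_palette")
}

# k-means++ seeding over distinct points: first centre uniform, each
# further centre with probability proportional to squared distance to
# the nearest centre chosen so far
kmeanspp_init <- function(ux, k) {
  n <- nrow(ux)
  centres <- matrix(NA_real_, k, ncol(ux))
  centres[1, ] <- ux[sample.int(n, 1), ]
  d2 <- rowSums((ux - matrix(centres[1, ], n, ncol(ux), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    pick <- if (all(d2 == 0)) sample.int(n, 1)
            else sample.int(n, 1, prob = d2)
    centres[j, ] <- ux[pick, ]
    d2 <- pmin(d2, rowSums((ux - matrix(centres[j, ], n, ncol(ux),
                                        byrow = TRUE))^2))
  }
  centres
}

#' @export
print.hue_palette <- function(x, ...) {
  cat("<hue_palette> k =", x$k, "from", x$n_pixels,
      "pixels; WCSS =", format(x$wcss), "\n")
  print(round(x$centroids, 1))
  invisible(x)
}

#' Assign every rosette pixel to its nearest palette hue
#'
#' @param pot_image H x W x 3 RGB array (0-255).
#' @param mask Logical matrix aligned with `pot_image`.
#' @param palette A [build_hue_palette()] object.
#' @return Integer matrix of palette indices (1..k) for mask-true
#'   pixels, 0 elsewhere.  Distance ties go to the lowest index.
#' @export
segment_colors <- function(pot_image, mask, palette) {
  stopifnot(inherits(palette, "hue_palette"))
  m <- unclass(mask) > 0
  if (any(dim(m) != dim(pot_image)[1:2])) abort("mask/image misaligned")
  labels <- matrix(0L, nrow(m), ncol(m))
  on <- which(m)
  if (length(on) == 0) return(labels)
  px <- cbind(pot_image[, , 1][on], pot_image[, , 2][on], pot_image[, , 3][on])
  ctr <- palette$centroids
  # squared distances, n x k; max.col("first") gives the lowest-index tie
  d2 <- outer(rowSums(px^2), rep(1, nrow(ctr))) -
    2 * px %*% t(ctr) + outer(rep(1, nrow(px)), rowSums(ctr^2))
  labels[on] <- max.col(-d2, ties.method = "first")
  labels
}

#' Area-normalised hue abundance of one plant
#'
#' Divides the pixel count of each palette hue by the rosette area, so
#' the composition is comparable across plants of different sizes.
#'
#' @param labels Integer matrix from [segment_colors()] (or a vector of
#'   labels), 0 = background.
#' @param rosette_area The plant's rosette area in pixels; must equal
#'   the number of labelled pixels.
#' @param k Number of hues (defaults to `max(labels)`).
#' @return A tibble with columns `hue` (1..k) and `fraction`, summing
#'   to 1 for non-empty plants; all-`NA` fractions (flagged missing)
#'   for an empty plant.
#' @export
hue_abundance <- function(labels, rosette_area = NULL, k = NULL) {
  lab <- as.integer(labels[labels > 0])
  if (is.null(k)) k <- max(lab, 1L)
  if (is.null(rosette_area)) rosette_area <- length(lab)
  if (length(lab) == 0 || rosette_area == 0) {
    return(tibble(hue = seq_len(k), fraction = NA_real_, empty = TRUE))
  }
  if (length(lab) != rosette_area) {
    abort("rosette_area (", rosette_area, ") does not match the number of ",
          "labelled pixels (", length(lab), ")")
  }
  fraction <- tabulate(lab, nbins = k) / rosette_area
  # fold the floating-point residual (<= 1 ulp) into the largest
  # fraction so the vector sums to 1 exactly
  imax <- which.max(fraction)
  fraction[imax] <- fraction[imax] + (1 - sum(fraction))
  tibble(hue = seq_len(k), fraction = fraction, empty = FALSE)
}

#' Salt-to-control hue abundance ratio
#'
#' For every accession x day x hue, the mean abundance under salt
#' divided by the mean abundance under control.  A zero control mean
#' yields a flagged missing ratio rather than infinity.
#'
#' @param abundance A long data frame with columns `accession`, `day`,
#'   `treatment` (`"control"`/`"salt"`), `hue`, `fraction`.
#' @return A tibble `accession`, `day`, `hue`, `ratio`,
#'   `control_zero` (flag).
#' @export
hue_salt_ratio <- function(abundance) {
  need <- c("accession", "day", "treatment", "hue", "fraction")
  if (!all(need %in% names(abundance))) {
    abort("`abundance` needs columns ", paste(need, collapse = ", "))
  }
  wide <- abundance |>
    dplyr::group_by(.data$accession, .data$day, .data$hue, .data$treatment) |>
    dplyr::summarise(m = mean(.data$fraction, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "m")
  if (!all(c("control", "salt") %in% names(wide)) ||
      anyNA(wide$control) || anyNA(wide$salt)) {
    abort("both treatment arms must be present for every accession/day/hue")
  }
  wide |>
    dplyr::mutate(
      control_zero = .data$control == 0,
      ratio = dplyr::if_else(.data$control_zero, NA_real_,
                             .data$salt / .data$control)) |>
    dplyr::select("accession", "day", "hue", "ratio", "control_zero")
}
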