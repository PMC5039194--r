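test_that("OLS slope matches closed form on small examples", {
  f <- fit_growth_rate(0:4, c(50, 70, 90, 110, 130), c(0, 4))
  expect_equal(f$gr, 20, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  expect_equal(fit_growth_rate(0:4, rep(42, 5), c(0, 4))$gr, 0,
               tolerance = 1e-12)

  # hand OLS: x = 0,1,2; y = 10,14,16 -> slope 3
  expect_equal(fit_growth_rate(0:2, c(10, 14, 16), c(0, 2))$gr, 3,
               tolerance = 1e-12)

  expect_true(is.na(fit_growth_rate(c(0, 7), c(1, 2), c(3, 4))$gr))
  expect_error(fit_growth_rate(c(2, 2), c(1, 5), c(0, 4)), "same day")
})

test_that("SIIT is the ratio to the accession control mean", {
  growth <- tibble::tibble(
    plant_id = sprintf("p%d", 1:6),
    accession = "a",
    treatment = rep(c("control", "salt"), each = 3),
    gr_early = c(18, 20, 22, 10, 20, 30),
    gr_late = c(18, 20, 22, -2, 10, 20))
  s <- siit(growth)
  expect_equal(s$siit1, c(10, 20, 30) / 20)
  # negative late slope clipped to zero with a flag
  expect_equal(s$siit2, c(0, 10, 20) / 20)
  expect_true(s$gr_clipped[1] && !s$gr_clipped[2])
  expect_error(siit(growth[growth$treatment == "salt", ]), "no control")
})

test_that("growth rates are affine invariant as contracted", {
  g <- simulate_growth_series(12, 25, area0 = 80, noise_sd = 4, seed = 3)
  f0 <- fit_growth_rate(g$day, g$area_px, c(0, 4))$gr
  expect_equal(fit_growth_rate(g$day, g$area_px + 500, c(0, 4))$gr, f0,
               tolerance = 1e-9)
  expect_equal(fit_growth_rate(g$day, g$area_px * 3, c(0, 4))$gr, 3 * f0,
               tolerance = 1e-9)
})

test_that("a 0.6 GR-ratio cohort yields mean SIIT near 0.6", {
  n <- 16
  gr_c <- 20; ratio <- 0.6
  mk <- function(ids, gr, trt, seed0) {
    purrr::map_dfr(seq_along(ids), function(i) {
      g <- simulate_growth_series(gr, gr, area0 = 50,
                                  noise_sd = 0.05 * 50, seed = seed0 + i)
      tibble::tibble(plant_id = ids[i], accession = "a", treatment = trt,
                     day = g$day, area_px = g$area_px)
    })
  }
  areas <- dplyr::bind_rows(
    mk(sprintf("c%02d", 1:n), gr_c, "control", 200),
    mk(sprintf("s%02d", 1:n), gr_c * ratio, "salt", 300))
  growth <- fit_growth_rates(areas)
  s <- siit(growth)
  expect_gt(mean(s$siit1), 0.55)
  expect_lt(mean(s$siit1), 0.65)
})

test_that("control-vs-control SIIT has mean near 1", {
  n <- 16
  mk <- function(ids, trt, seed0) {
    purrr::map_dfr(seq_along(ids), function(i) {
      g <- simulate_growth_series(20, 20, area0 = 50, noise_sd = 2.5,
                                  seed = seed0 + i)
      tibble::tibble(plant_id = ids[i], accession = "a", treatment = trt,
                     day = g$day, area_px = g$area_px)
    })
  }
  areas <- dplyr::bind_rows(mk(sprintf("c%02d", 1:n), "control", 400),
                            mk(sprintf("s%02d", 1:n), "pseudo_salt", 500))
  s <- siit(fit_growth_rates(areas))
  expect_gt(mean(c(s$siit1, s$siit2)), 0.95)
  expect_lt(mean(c(s$siit1, s$siit2)), 1.05)
})

test_that("zero-noise SIIT equals the generating ratio exactly", {
  mk <- function(id, gr, trt) {
    g <- simulate_growth_series(gr, gr / 2, area0 = 50, noise_sd = 0)
    tibble::tibble(plant_id = id, accession = "a", treatment = trt,
                   day = g$day, area_px = g$area_px)
  }
  areas <- dplyr::bind_rows(mk("c1", 20, "control"), mk("s1", 12, "salt"))
  s <- siit(fit_growth_rates(areas))
  expect_equal(s$siit1, 0.6, tolerance = 1e-9)
  expect_equal(s$siit2, 0.6, tolerance = 1e-9)
})
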