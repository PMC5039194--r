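quench <- chlf_protocol("quenching")

test_that("level extraction reproduces a noise-free simulated trace", {
  truth <- chlf_truth(fo = 0.2, fm = 1.0)
  tr <- simulate_chlf_trace(truth, quench, noise_sd = 0)
  lv <- extract_levels(tr, quench)
  expect_equal(lv$Fo, 0.2, tolerance = 1e-12)
  expect_equal(lv$Fm, 1.0, tolerance = 1e-12)
  expect_equal(lv$Fp, truth$fp, tolerance = 1e-12)
  st_true <- attr(tr, "truth_states")
  expect_equal(lv$states$Fm_prime, st_true$fm_prime, tolerance = 1e-12)
  expect_equal(lv$states$Ft, st_true$ft, tolerance = 1e-12)
})

test_that("Fo under noise is estimated within the noise scale", {
  errs <- vapply(1:20, function(i) {
    tr <- simulate_chlf_trace(chlf_truth(), quench, noise_sd = 0.005,
                              seed = 50 + i)
    abs(extract_levels(tr, quench)$Fo - 0.2)
  }, numeric(1))
  expect_lt(mean(errs), 0.005)
})

test_that("missing annotations are reported by event name", {
  tr <- simulate_chlf_trace(chlf_truth(), quench, noise_sd = 0)
  broken <- tr
  broken$event[broken$event == "FmPulse"] <- ""
  expect_error(extract_levels(broken, quench), "Fm window not found")
  broken2 <- tr
  broken2$event[broken2$event == "L2"] <- ""
  expect_error(extract_levels(broken2, quench), "L2")
  degen <- tr
  degen$signal[degen$event == "FmPulse"] <- 0.1
  expect_error(extract_levels(degen, quench), "degenerate")
})

test_that("image-stack integration is background-invariant", {
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  frames <- lapply(c(1, 2, 3), function(v) {
    f <- matrix(0, 8, 8); f[mask] <- v; f
  })
  tr <- integrate_image_stack(frames, mask)
  expect_equal(tr$signal, c(1, 2, 3))
  # constant offset on all pixels cancels
  shifted <- lapply(frames, function(f) f + 7.5)
  expect_equal(integrate_image_stack(shifted, mask)$signal, tr$signal)
  # half-covered two-valued frame -> plant-half mean
  f2 <- matrix(c(rep(4, 32), rep(0, 32)), 8, 8)
  m2 <- matrix(c(rep(TRUE, 32), rep(FALSE, 32)), 8, 8)
  expect_equal(integrate_image_stack(list(f2), m2)$signal, 4)
  expect_error(integrate_image_stack(frames, matrix(FALSE, 8, 8)), "empty")
})

test_that("Oxborough-Baker Fo' matches hand evaluation and monotonicity", {
  expect_equal(fo_prime(0.2, 1.0, 1.0), 0.2, tolerance = 1e-12)
  expect_equal(fo_prime(0.2, 1.0, 0.8), 0.2 / (0.8 + 0.25), tolerance = 1e-12)
  fmp <- seq(0.5, 1.0, by = 0.05)
  fop <- fo_prime(0.2, 1.0, fmp)
  expect_true(all(diff(fop) > 0))          # Fo' grows with Fm'
  expect_true(all(fop[fmp < 1] < 0.2))     # quenching lowers Fo'
  expect_error(fo_prime(0.5, 0.4, 1), "Fm > Fo")
})

test_that("derived parameters match hand-evaluated formulas", {
  lv <- structure(list(
    Fo = 0.2, Fm = 1.0, Fv = 0.8, Fp = 0.8,
    states = tibble::tibble(state = "L1", phase = "light", t_phase = 8,
                            irradiance = 210, Ft = 0.4, Fm_prime = 0.8,
                            Fo_prime = fo_prime(0.2, 1.0, 0.8)),
    kind = "quenching"), class = "fluor_levels")
  p <- derive_parameters(lv)
  val <- function(tr) p$value[p$trait == tr & p$state == "L1"]
  fop <- 0.2 / (0.8 + 0.25)
  expect_equal(val("PhiP"), 0.5, tolerance = 1e-12)
  expect_equal(val("PhiNO"), 0.4, tolerance = 1e-12)
  expect_equal(val("PhiNPQ"), 0.1, tolerance = 1e-12)
  expect_equal(val("NPQ"), 0.25, tolerance = 1e-12)
  expect_equal(val("qP"), (0.8 - 0.4) / (0.8 - fop), tolerance = 1e-12)
  expect_equal(val("qL"), val("qP") * fop / 0.4, tolerance = 1e-12)
  expect_equal(val("qN"), (1 - 0.8) / (1 - fop), tolerance = 1e-12)
  expect_equal(p$value[p$trait == "FvFm"], 0.8, tolerance = 1e-12)
})

test_that("dark-equivalent state gives NPQ 0, qN 0, qP 1", {
  lv <- structure(list(
    Fo = 0.2, Fm = 1.0, Fv = 0.8, Fp = 0.8,
    states = tibble::tibble(state = "D3", phase = "dark", t_phase = 90,
                            irradiance = 0, Ft = 0.2, Fm_prime = 1.0,
                            Fo_prime = fo_prime(0.2, 1.0, 1.0)),
    kind = "quenching"), class = "fluor_levels")
  p <- derive_parameters(lv)
  val <- function(tr) p$value[p$trait == tr & p$state == "D3"]
  expect_equal(val("NPQ"), 0, tolerance = 1e-12)
  expect_equal(val("qN"), 0, tolerance = 1e-12)
  expect_equal(val("qP"), 1, tolerance = 1e-12)
})

test_that("energy partition closes on random valid level sets", {
  set.seed(99)
  n <- 1e4
  Fo <- runif(n, 0.05, 0.4)
  Fm <- Fo + runif(n, 0.2, 1)
  Fmp <- Fo + (Fm - Fo) * runif(n, 0.3, 1)
  Fop <- fo_prime_v <- Fo / ((Fm - Fo) / Fm + Fo / Fmp)
  Ft <- Fop + (Fmp - Fop) * runif(n)
  PhiP <- (Fmp - Ft) / Fmp
  PhiNO <- Ft / Fm
  PhiNPQ <- Ft / Fmp - Ft / Fm
  expect_lt(max(abs(PhiP + PhiNO + PhiNPQ - 1)), 1e-9)
})

test_that("raising NPQ capacity raises extracted NPQ, lowers Fm' at Lss", {
  res <- t(vapply(c(0.2, 0.5, 1.0, 1.5), function(nm) {
    tr <- simulate_chlf_trace(chlf_truth(npq_max = nm), quench, noise_sd = 0)
    lv <- extract_levels(tr, quench)
    p <- derive_parameters(lv)
    c(p$value[p$state == "Lss" & p$trait == "NPQ"],
      p$value[p$state == "Lss" & p$trait == "PhiNPQ"],
      lv$states$Fm_prime[lv$states$state == "Lss"])
  }, numeric(3)))
  expect_true(all(diff(res[, 1]) > 0))
  expect_true(all(diff(res[, 2]) > 0))
  expect_true(all(diff(res[, 3]) < 0))
})

test_that("overall-mean normalisation yields unit column means", {
  tab <- tibble::tibble(trait = rep(c("a", "b"), each = 2),
                        value = c(1, 3, 5, 5))
  out <- relative_trait_table(tab)
  expect_equal(out$value[out$trait == "a"], c(0.5, 1.5))
  expect_equal(out$value[out$trait == "b"], c(1, 1))
  set.seed(1)
  tab2 <- tibble::tibble(trait = "x", state = "L1", value = rnorm(50, 10))
  expect_equal(mean(relative_trait_table(tab2)$value), 1, tolerance = 1e-12)
  expect_error(relative_trait_table(tibble::tibble(trait = "z",
                                                   value = c(-1, 1))),
               "zero grand mean")
})
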