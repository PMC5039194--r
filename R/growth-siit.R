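#' Fit a linear growth rate over one day interval
#'
#' Ordinary least-squares slope of projected rosette area against day,
#' restricted to observations inside the closed interval.
#'
#' @param day,area_px Numeric vectors of observation days and areas.
#' @param interval Closed day range `c(start, end)`.
#' @return A one-row tibble: `gr` (slope, px/day), `n` (points used),
#'   `r_squared`.  Fewer than 2 points inside the interval gives an
#'   `NA` slope (flagged, not an error); 2+ points all on the same day
#'   is an error.
#' @examples
#' fit_growth_rate(0:4, 50 + 20 * (0:4), c(0, 4)) # gr = 20, R2 = 1
#' @export
fit_growth_rate <- function(day, area_px, interval) {
  stopifnot(length(day) == length(area_px), length(interval) == 2)
  keep <- day >= interval[1] & day <= interval[2] & is.finite(area_px)
  d <- day[keep]; a <- area_px[keep]
  if (length(d) < 2) {
    return(tibble(gr = NA_real_, n = length(d), r_squared = NA_real_))
  }
  if (length(unique(d)) < 2) {
    abort("all observations in [", interval[1], ", ", interval[2],
          "] fall on the same day; slope undefined")
  }
  fit <- lm(a ~ d)
  ss_tot <- sum((a - mean(a))^2)
  r2 <- if (ss_tot < 1e-12) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  tibble(gr = unname(coef(fit)[2]), n = length(d), r_squared = r2)
}

#' Per-plant growth rates over the two standard intervals
#'
#' @param areas Long data frame with columns `plant_id`, `day`,
#'   `area_px` (plus any metadata columns, carried through).
#' @param intervals List of two day ranges; defaults to the
#'   protocol-development intervals `[0, 4]` and `[7, 11]`.  Use
#'   `list(c(0, 3), c(4, 7))` for a 7-day natural-variation screen.
#' @return A tibble with one row per plant: metadata, `gr_early`,
#'   `gr_late`, fit sizes and R-squared values.
#' @export
fit_growth_rates <- function(areas, intervals = list(c(0, 4), c(7, 11))) {
  check_intervals(intervals)
  need <- c("plant_id", "day", "area_px")
  if (!all(need %in% names(areas))) {
    abort("`areas` needs columns ", paste(need, collapse = ", "))
  }
  meta_cols <- setdiff(names(areas), c("day", "area_px", "area_true"))
  areas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::summarise(
      fit1 = list(fit_growth_rate(.data$day, .data$area_px, intervals[[1]])),
      fit2 = list(fit_growth_rate(.data$day, .data$area_px, intervals[[2]])),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("fit1") |>
    dplyr::rename(gr_early = "gr", n_early = "n", r2_early = "r_squared") |>
    tidyr::unnest_wider("fit2") |>
    dplyr::rename(gr_late = "gr", n_late = "n", r2_late = "r_squared")
}

#' Shoot ion-independent tolerance (SIIT) index
#'
#' For every salt-treated plant, SIIT = GR(salt plant) / mean GR of the
#' control plants of the same accession, computed separately for the
#' early and late intervals (SIIT1, SIIT2).  Negative fitted slopes are
#' clipped to zero (flagged) so tolerance is never negative; a
#' non-positive control mean yields a flagged missing SIIT.
#'
#' @param growth A [fit_growth_rates()] table with columns `plant_id`,
#'   `accession`, `treatment`, `gr_early`, `gr_late`.
#' @param control Value of `treatment` identifying control plants.
#' @return The salt-plant rows with `siit1`, `siit2`, clip flags
#'   `gr_clipped`, and the control means used
#'   (`gr_control_early`, `gr_control_late`).
#' @export
siit <- function(growth, control = "control") {
  need <- c("plant_id", "accession", "treatment", "gr_early", "gr_late")
  if (!all(need %in% names(growth))) {
    abort("`growth` needs columns ", paste(need, collapse = ", "))
  }
  clip0 <- function(x) pmax(x, 0)
  ctrl <- growth |>
    dplyr::filter(.data$treatment == control) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(gr_control_early = mean(clip0(.data$gr_early), na.rm = TRUE),
                     gr_control_late = mean(clip0(.data$gr_late), na.rm = TRUE),
                     n_control = dplyr::n(), .groups = "drop")
  if (nrow(ctrl) == 0) abort("no control plants found (treatment == \"",
                             control, "\")")
  salt <- dplyr::filter(growth, .data$treatment != control)
  missing_ctrl <- setdiff(unique(salt$accession), ctrl$accession)
  if (length(missing_ctrl) > 0) {
    abort("no control plants for accession(s): ",
          paste(missing_ctrl, collapse = ", "))
  }
  salt |>
    dplyr::left_join(ctrl, by = "accession") |>
    dplyr::mutate(
      gr_clipped = (.data$gr_early < 0 | .data$gr_late < 0) %in% TRUE,
      siit1 = dplyr::if_else(.data$gr_control_early > 0,
                             clip0(.data$gr_early) / .data$gr_control_early,
                             NA_real_),
      siit2 = dplyr::if_else(.data$gr_control_late > 0,
                             clip0(.data$gr_late) / .data$gr_control_late,
                             NA_real_))
}
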