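#' Define a PAM chlorophyll-fluorescence measuring protocol
#'
#' Two pulse schedules are supported, both preceded by dark adaptation,
#' a 5 s measuring-flash window for Fo and an 800 ms saturation pulse
#' (1200 umol m-2 s-1) for Fm, followed by 17 s of dark relaxation:
#'
#' * `"quenching"`: 70 s of actinic light at 210 umol m-2 s-1 with
#'   saturation pulses at 8, 18, 28, 48, 68 s (states L1, L2, L3, L4,
#'   Lss), then 100 s darkness with relaxation pulses at 30, 60, 90 s
#'   (states D1, D2, D3).
#' * `"light_curve"`: four 60 s actinic steps at 95, 210, 320, 440
#'   umol m-2 s-1 (states L1-L4) with one saturation pulse at the end of
#'   each step.
#'
#' @param kind `"quenching"` or `"light_curve"`.
#' @param dark_adaptation_s Dark adaptation before the trace starts
#'   (seconds; informational, the trace clock starts at the Fo window).
#' @return A list of class `chlf_protocol` with the event timetable:
#'   `fo_window`, `fm_pulse` (absolute times, s), `actinic_start`,
#'   `actinic_end`, and a tibble `pulses` with columns `state`,
#'   `t_pulse` (absolute pulse start), `t_phase` (time since actinic
#'   start for L states / since darkness for D states), `phase`
#'   (`"light"`/`"dark"`) and `irradiance` (umol m-2 s-1).
#' @examples
#' chlf_protocol("quenching")$pulses
#' @export
chlf_protocol <- function(kind = c("quenching", "light_curve"),
                          dark_adaptation_s = 900) {
  kind <- match.arg(kind)
  fo_window <- c(0, 5)
  sat_pulse_s <- 0.8
  fm_pulse <- c(5, 5 + sat_pulse_s)
  relax_s <- 17
  actinic_start <- fm_pulse[2] + relax_s

  if (kind == "quenching") {
    t_light <- c(8, 18, 28, 48, 68)
    light <- tibble(
      state = c("L1", "L2", "L3", "L4", "Lss"),
      t_phase = t_light,
      t_pulse = actinic_start + t_light,
      phase = "light",
      irradiance = 210
    )
    actinic_end <- actinic_start + 70
    t_dark <- c(30, 60, 90)
    dark <- tibble(
      state = c("D1", "D2", "D3"),
      t_phase = t_dark,
      t_pulse = actinic_end + t_dark,
      phase = "dark",
      irradiance = 0
    )
    pulses <- dplyr::bind_rows(light, dark)
    t_end <- actinic_end + 100
  } else {
    t_light <- c(60, 120, 180, 240)
    light <- tibble(
      state = c("L1", "L2", "L3", "L4"),
      t_phase = t_light,
      t_pulse = actinic_start + t_light,
      phase = "light",
      irradiance = c(95, 210, 320, 440)
    )
    pulses <- light
    actinic_end <- actinic_start + 240
    t_end <- actinic_end + 5
  }
  stopifnot(all(diff(pulses$t_pulse) > 0))
  structure(
    list(kind = kind,
         dark_adaptation_s = dark_adaptation_s,
         fo_window = fo_window,
         fm_pulse = fm_pulse,
         sat_pulse_s = sat_pulse_s,
         sat_irradiance = 1200,
         actinic_start = actinic_start,
         actinic_end = actinic_end,
         t_end = t_end,
         pulses = pulses),
    class = "chlf_protocol"
  )
}

#' @export
print.chlf_protocol <- function(x, ...) {
  cat("<chlf_protocol> kind:", x$kind, "\n")
  cat("  Fo window", x$fo_window[1], "-", x$fo_window[2], "s; Fm pulse at",
      x$fm_pulse[1], "s; actinic", x$actinic_start, "-", x$actinic_end, "s\n")
  print(x$pulses, n = Inf)
  invisible(x)
}
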