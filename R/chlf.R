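#' Extract fluorescence levels from an annotated trace
#'
#' Reads the measured levels off a PAM trace following a
#' [chlf_protocol()] timetable:
#'
#' * `Fo` — mean signal over the `FoWin` measuring-flash window.
#' * `Fm` — maximum inside the `FmPulse` saturation-pulse window.
#' * `Fp` — maximum during the actinic rise, between actinic onset and
#'   0.5 s before the first light saturation pulse.
#' * per state `s`: `Fm'(s)` — maximum inside the state's pulse
#'   window; `Ft(s)` — mean of the 200 ms window ending at the pulse
#'   start.
#'
#' `Fo'` per state is computed with [fo_prime()].
#'
#' @param trace A data frame with columns `time_s`, `signal`, `event`
#'   (annotations `FoWin`, `FmPulse` and state names).
#' @param protocol The [chlf_protocol()] the trace was measured under.
#' @param ft_window_s Averaging window for Ft, ending at the pulse
#'   start (seconds).
#' @return A list of class `fluor_levels`: scalars `Fo`, `Fm`, `Fv`,
#'   `Fp` and a tibble `states` with columns `state`, `phase`,
#'   `t_phase`, `irradiance`, `Ft`, `Fm_prime`, `Fo_prime`.
#' @export
extract_levels <- function(trace, protocol, ft_window_s = 0.2) {
  need <- c("time_s", "signal", "event")
  if (!all(need %in% names(trace))) {
    abort("`trace` needs columns ", paste(need, collapse = ", "))
  }
  ev <- trace$event
  if (!any(ev == "FoWin")) abort("Fo window not found in trace annotations")
  if (!any(ev == "FmPulse")) abort("Fm window not found in trace annotations")
  Fo <- mean(trace$signal[ev == "FoWin"])
  Fm <- max(trace$signal[ev == "FmPulse"])
  if (Fm <= Fo) abort("degenerate trace: Fm <= Fo")

  states <- protocol$pulses
  first_pulse <- min(states$t_pulse)
  rise <- trace$time_s > protocol$actinic_start &
    trace$time_s < first_pulse - 0.5 & ev == ""
  if (!any(rise)) abort("actinic rise window not found in trace")
  Fp <- max(trace$signal[rise])

  per_state <- purrr::pmap(states, function(state, t_pulse, ...) {
    in_pulse <- ev == state
    if (!any(in_pulse)) abort(state, " window not found in trace annotations")
    fmp <- max(trace$signal[in_pulse])
    ft_w <- trace$time_s >= t_pulse - ft_window_s & trace$time_s < t_pulse
    if (!any(ft_w)) abort("Ft window before ", state, " not found")
    ft <- mean(trace$signal[ft_w])
    tibble(state = state, Ft = ft, Fm_prime = fmp)
  }) |> dplyr::bind_rows()

  st <- dplyr::left_join(states, per_state, by = "state")
  st$Fo_prime <- fo_prime(Fo, Fm, st$Fm_prime)
  structure(list(Fo = Fo, Fm = Fm, Fv = Fm - Fo, Fp = Fp,
                 states = dplyr::select(st, "state", "phase", "t_phase",
                                        "irradiance", "Ft", "Fm_prime",
                                        "Fo_prime"),
                 kind = protocol$kind),
            class = "fluor_levels")
}

#' @export
print.fluor_levels <- function(x, ...) {
  cat(sprintf("<fluor_levels> %s  Fo=%.4g Fm=%.4g Fv=%.4g Fp=%.4g\n",
              x$kind, x$Fo, x$Fm, x$Fv, x$Fp))
  print(x$states, n = Inf)
  invisible(x)
}

#' Integrate a fluorescence image stack into a rosette-mean trace
#'
#' Per frame, the signal is the mean over mask-true pixels after
#' subtracting the frame's background level (the mean over mask-false
#' pixels), so a constant offset added to all pixels cancels exactly.
#'
#' @param frames List of numeric matrices (one per frame) or an
#'   H x W x n array.
#' @param mask Logical matrix aligned with the frames.
#' @param time_s Optional frame times; defaults to frame index - 1.
#' @param events Optional per-frame event annotations.
#' @return A tibble `time_s`, `signal`, `event`.
#' @export
integrate_image_stack <- function(frames, mask, time_s = NULL, events = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- purrr::map(seq_len(dim(frames)[3]), \(i) frames[, , i])
  }
  m <- unclass(mask) > 0
  if (!any(m)) abort("empty mask: nothing to integrate")
  if (any(dim(m) != dim(frames[[1]]))) abort("mask/frame misaligned")
  bg_present <- any(!m)
  signal <- purrr::map_dbl(frames, function(fr) {
    bg <- if (bg_present) mean(fr[!m]) else 0
    mean(fr[m]) - bg
  })
  n <- length(signal)
  tibble(time_s = if (is.null(time_s)) seq_len(n) - 1 else time_s,
         signal = signal,
         event = if (is.null(events)) rep("", n) else events)
}

#' Minimum fluorescence in the light-adapted state (Oxborough-Baker)
#'
#' Fo' = Fo / (Fv/Fm + Fo/Fm'), the standard estimate of the
#' light-adapted minimum fluorescence when it is not measured directly
#' with far-red illumination.
#'
#' @param Fo,Fm Dark-adapted minimum and maximum fluorescence,
#'   `Fm > Fo > 0`.
#' @param Fm_prime Light-adapted maximum fluorescence (> 0); vectorised.
#' @return Fo' in (0, Fm'); equals `Fo` when `Fm_prime == Fm`.
#' @examples
#' fo_prime(0.2, 1.0, 0.8) # 0.1904762
#' @export
fo_prime <- function(Fo, Fm, Fm_prime) {
  if (!(Fm > Fo && Fo > 0)) abort("need Fm > Fo > 0")
  if (any(Fm_prime <= 0)) abort("`Fm_prime` must be > 0")
  Fo / ((Fm - Fo) / Fm + Fo / Fm_prime)
}

#' Derive photosynthetic parameters from fluorescence levels
#'
#' Energy-partition (lake-model) parameter set per light/dark state:
#'
#' * `FvFm = (Fm - Fo) / Fm` (dark-adapted, one per trace)
#' * `FvpFmp = (Fm' - Fo') / Fm'`
#' * `PhiP = (Fm' - Ft) / Fm'` (operating quantum yield)
#' * `qP = (Fm' - Ft) / (Fm' - Fo')`
#' * `qL = qP * Fo' / Ft`
#' * `qN = (Fm - Fm') / (Fm - Fo')`
#' * `NPQ = Fm / Fm' - 1`
#' * `PhiNO = Ft / Fm`, `PhiNPQ = Ft / Fm' - Ft / Fm`; the partition
#'   `PhiP + PhiNPQ + PhiNO = 1` holds algebraically.
#' * `Rfd = (Fp - Ft_ss) / Ft_ss` against the steady state (`Lss` for
#'   the quenching protocol, `L4` for the light curve).
#'
#' Degenerate states (`Fm' = Fo'` or `Ft = 0`) yield flagged `NA`
#' values instead of errors so one plant cannot abort a tray.
#'
#' @param levels A [extract_levels()] result.
#' @return A tibble of class `chlf_parameters` in long format:
#'   `state`, `trait`, `value`.  Whole-trace traits carry state
#'   `"dark"` (`FvFm`) and the steady state's name (`Rfd`).
#' @export
derive_parameters <- function(levels) {
  stopifnot(inherits(levels, "fluor_levels"))
  st <- levels$states
  Fo <- levels$Fo; Fm <- levels$Fm
  safe <- function(num, den) {
    out <- num / den
    out[rep_len(abs(den) < 1e-12, length(out))] <- NA_real_
    out
  }

  per_state <- st |>
    dplyr::mutate(
      FvpFmp = safe(.data$Fm_prime - .data$Fo_prime, .data$Fm_prime),
      PhiP = safe(.data$Fm_prime - .data$Ft, .data$Fm_prime),
      qP = safe(.data$Fm_prime - .data$Ft, .data$Fm_prime - .data$Fo_prime),
      qL = .data$qP * safe(.data$Fo_prime, .data$Ft),
      qN = safe(Fm - .data$Fm_prime, Fm - .data$Fo_prime),
      NPQ = safe(Fm, .data$Fm_prime) - 1,
      PhiNO = safe(.data$Ft, Fm),
      PhiNPQ = safe(.data$Ft, .data$Fm_prime) - safe(.data$Ft, Fm)
    ) |>
    dplyr::select("state", "FvpFmp", "PhiP", "qP", "qL", "qN", "NPQ",
                  "PhiNO", "PhiNPQ") |>
    tidyr::pivot_longer(-"state", names_to = "trait", values_to = "value")

  ss_state <- if (levels$kind == "quenching") "Lss" else "L4"
  ft_ss <- st$Ft[st$state == ss_state]
  rfd <- if (length(ft_ss) == 1 && is.finite(ft_ss) && ft_ss > 1e-12) {
    (levels$Fp - ft_ss) / ft_ss
  } else NA_real_

  out <- dplyr::bind_rows(
    tibble(state = "dark", trait = "FvFm", value = (Fm - Fo) / Fm),
    per_state,
    tibble(state = ss_state, trait = "Rfd", value = rfd)
  )
  class(out) <- c("chlf_parameters", class(out))
  out
}

#' Normalise a trait table by overall trait means
#'
#' Divides every value by the grand mean of its trait (and state, when
#' a `state` column is present), so fluctuations due to development and
#' treatment are expressed relative to the experiment-wide average; the
#' mean of every normalised trait column is 1.
#'
#' @param table Long data frame with columns `trait`, `value` and
#'   optionally `state`.
#' @return The input with `value` replaced by the normalised value and
#'   the grand mean appended as `trait_mean`.
#' @export
relative_trait_table <- function(table) {
  if (!all(c("trait", "value") %in% names(table))) {
    abort("`table` needs columns `trait` and `value`")
  }
  keys <- intersect(c("trait", "state"), names(table))
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(trait_mean = mean(.data$value, na.rm = TRUE)) |>
    dplyr::ungroup()
  if (any(abs(out$trait_mean) < 1e-12, na.rm = TRUE)) {
    abort("a trait has zero grand mean; cannot normalise")
  }
  dplyr::mutate(out, value = .data$value / .data$trait_mean)
}
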