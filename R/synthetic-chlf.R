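#' True photosynthetic parameters for a simulated plant
#'
#' Ground-truth parameter set driving [simulate_chlf_trace()].  The
#' non-photochemical quenching build-up follows a single-exponential
#' NPQ(t) = `npq_max` * (1 - exp(-t / `tau_npq`)) during actinic light
#' and relaxes as NPQ(t_dark) = NPQ(end) * exp(-t_dark / `tau_relax`)
#' in darkness.  The photochemical quenching coefficient declines from
#' 1 to `qp_ss` with time constant `tau_qp` in light and recovers
#' toward 1 with `tau_relax` in darkness.  Fluorescence levels follow
#' from Fm'(t) = Fm / (1 + NPQ(t)), the Oxborough-Baker estimate
#' Fo'(t) = Fo / (Fv/Fm + Fo/Fm'(t)), and
#' Ft(t) = Fm'(t) - qP(t) * (Fm'(t) - Fo'(t)).
#'
#' @param fo,fm Minimum and maximum dark-adapted fluorescence (a.u.),
#'   `fm > fo > 0`.
#' @param fp Peak fluorescence during the initial actinic rise
#'   (Kautsky peak); defaults to `fo + 0.75 * (fm - fo)`.
#' @param npq_max Asymptotic NPQ under actinic light; must be >= 0.
#' @param tau_npq,tau_relax,tau_qp Time constants (s); must be > 0.
#' @param qp_ss Steady-state photochemical quenching in light, in (0, 1].
#' @return A list of class `chlf_truth`.
#' @export
chlf_truth <- function(fo = 0.2, fm = 1.0, fp = NULL,
                       npq_max = 0.8, tau_npq = 20, tau_relax = 40,
                       qp_ss = 0.6, tau_qp = 15) {
  if (!(fm > fo && fo > 0)) abort("need fm > fo > 0")
  if (npq_max < 0) abort("`npq_max` must be >= 0")
  if (tau_npq <= 0 || tau_relax <= 0 || tau_qp <= 0) {
    abort("time constants must be > 0")
  }
  if (qp_ss <= 0 || qp_ss > 1) abort("`qp_ss` must be in (0, 1]")
  if (is.null(fp)) fp <- fo + 0.75 * (fm - fo)
  if (fp <= fo || fp > fm) abort("`fp` must lie in (fo, fm]")
  structure(list(fo = fo, fm = fm, fp = fp, npq_max = npq_max,
                 tau_npq = tau_npq, tau_relax = tau_relax,
                 qp_ss = qp_ss, tau_qp = tau_qp),
            class = "chlf_truth")
}

# NPQ / qP trajectories and per-state levels implied by a chlf_truth
chlf_truth_states <- function(truth, protocol) {
  p <- protocol$pulses
  t_actinic_end <- protocol$actinic_end - protocol$actinic_start
  npq_end <- truth$npq_max * (1 - exp(-t_actinic_end / truth$tau_npq))
  qp_end <- truth$qp_ss + (1 - truth$qp_ss) * exp(-t_actinic_end / truth$tau_qp)
  npq <- ifelse(p$phase == "light",
                truth$npq_max * (1 - exp(-p$t_phase / truth$tau_npq)),
                npq_end * exp(-p$t_phase / truth$tau_relax))
  qp <- ifelse(p$phase == "light",
               truth$qp_ss + (1 - truth$qp_ss) * exp(-p$t_phase / truth$tau_qp),
               1 - (1 - qp_end) * exp(-p$t_phase / truth$tau_relax))
  fm_prime <- truth$fm / (1 + npq)
  fvfm <- (truth$fm - truth$fo) / truth$fm
  fo_prime <- truth$fo / (fvfm + truth$fo / fm_prime)
  ft <- fm_prime - qp * (fm_prime - fo_prime)
  dplyr::mutate(p, npq = npq, qp = qp, fm_prime = fm_prime,
                fo_prime = fo_prime, ft = ft)
}

#' Simulate a chlorophyll-fluorescence trace
#'
#' Emits a sampled fluorescence signal following a [chlf_protocol()]
#' timetable and the dynamics of a [chlf_truth()] parameter set: an Fo
#' plateau in the measuring-flash window, Fm during the dark saturation
#' pulse, a Kautsky rise peaking at Fp after actinic onset, and, around
#' every saturation pulse, a steady Ft plateau just before the pulse and
#' an Fm' plateau inside it.  Additive Gaussian noise is applied to
#' every sample; the signal is clipped at zero.
#'
#' @param truth A [chlf_truth()] object.
#' @param protocol A [chlf_protocol()] object.
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u.).
#' @param seed Integer seed.
#' @param hz Sampling rate, samples per second (default 50, the frame
#'   rate of the fluorescence cameras used on tray-based platforms).
#' @return A tibble of class `chlf_trace` with columns `time_s`,
#'   `signal` and `event` (`""` outside annotated windows; `"FoWin"`,
#'   `"FmPulse"` and the state names `"L1"`..`"D3"` inside them).  The
#'   per-state ground truth is attached as attribute `truth_states`.
#' @examples
#' tr <- simulate_chlf_trace(chlf_truth(), chlf_protocol("quenching"),
#'                           noise_sd = 0, seed = 1)
#' head(tr)
#' @export
simulate_chlf_trace <- function(truth, protocol, noise_sd = 0, seed = 1,
                                hz = 50) {
  stopifnot(inherits(truth, "chlf_truth"), inherits(protocol, "chlf_protocol"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  st <- chlf_truth_states(truth, protocol)
  dt <- 1 / hz
  time_s <- seq(0, protocol$t_end, by = dt)
  n <- length(time_s)
  signal <- numeric(n)
  event <- character(n)

  in_win <- function(a, b) time_s >= a & time_s < b

  # Fo measuring-flash window
  w <- in_win(protocol$fo_window[1], protocol$fo_window[2])
  signal[w] <- truth$fo; event[w] <- "FoWin"
  # Fm saturation pulse
  w <- in_win(protocol$fm_pulse[1], protocol$fm_pulse[2])
  signal[w] <- truth$fm; event[w] <- "FmPulse"
  # dark relaxation between Fm pulse and actinic onset: decay back to Fo
  w <- in_win(protocol$fm_pulse[2], protocol$actinic_start)
  signal[w] <- truth$fo +
    (truth$fm - truth$fo) * exp(-(time_s[w] - protocol$fm_pulse[2]) / 2)

  # actinic rise: Fo -> Fp peak -> decline toward Ft of the first state
  first_pulse <- min(st$t_pulse)
  t_peak <- protocol$actinic_start + 0.3 * (first_pulse - protocol$actinic_start)
  ft1 <- st$ft[which.min(st$t_pulse)]
  w <- in_win(protocol$actinic_start, t_peak)
  signal[w] <- truth$fo + (truth$fp - truth$fo) *
    (time_s[w] - protocol$actinic_start) / (t_peak - protocol$actinic_start)
  w <- time_s >= t_peak & time_s < first_pulse
  signal[w] <- ft1 + (truth$fp - ft1) *
    exp(-(time_s[w] - t_peak) / ((first_pulse - t_peak) / 4))
  # force the peak sample to hit Fp exactly (max-based extraction)
  i_peak <- which.min(abs(time_s - t_peak))
  signal[i_peak] <- truth$fp

  # per-state plateaus: Ft in the 0.5 s before the pulse, Fm' inside it
  for (i in seq_len(nrow(st))) {
    t0 <- st$t_pulse[i]
    w <- in_win(t0 - 0.5, t0)
    signal[w] <- st$ft[i]
    w <- in_win(t0, t0 + protocol$sat_pulse_s)
    signal[w] <- st$fm_prime[i]; event[w] <- st$state[i]
    # post-pulse: relax back toward Ft level
    w <- in_win(t0 + protocol$sat_pulse_s, t0 + protocol$sat_pulse_s + 2)
    signal[w] <- st$ft[i] + (st$fm_prime[i] - st$ft[i]) *
      exp(-(time_s[w] - t0 - protocol$sat_pulse_s) / 0.3)
  }
  # smooth fill of remaining gaps between plateaus
  unset <- signal == 0 & event == "" & time_s >= first_pulse
  if (any(unset)) {
    known <- which(!unset)
    signal[unset] <- stats::approx(time_s[known], signal[known],
                                   xout = time_s[unset], rule = 2)$y
  }

  withr_seed(seed, {
    noise <- rnorm(n, 0, noise_sd)
  })
  out <- tibble(time_s = time_s, signal = pmax(signal + noise, 0),
                event = event)
  attr(out, "truth_states") <- st
  attr(out, "truth") <- truth
  attr(out, "protocol_kind") <- protocol$kind
  class(out) <- c("chlf_trace", class(out))
  out
}
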