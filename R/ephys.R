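# Normalized double-exponential synaptic kernel: 0 before onset, unit peak.
epsc_kernel <- function(t, tau_rise, tau_decay) {
  if (tau_rise <= 0 || tau_decay <= 0) stop_invalid("time constants must be positive")
  if (tau_rise >= tau_decay) stop_invalid("tau_rise must be smaller than tau_decay")
  k <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  k / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
}

#' Parameters of the synthetic optogenetic EPSC generator
#'
#' @param max_amp maximal EPSC amplitude, nA (positive number; the -70 mV
#'   trace is inward, i.e. negative).
#' @param i50 light intensity (normalized 0-1) at half-maximal amplitude.
#' @param hill Hill coefficient of the intensity dependence.
#' @param tau_rise,tau_decay AMPA EPSC kinetics, s.
#' @param ppr paired-pulse ratio planted on the second pulse.
#' @param isi inter-stimulus interval for paired pulses, s.
#' @param nmda `NULL`, or list(`amp` nA, `tau_rise`, `tau_decay` s) for the
#'   +50 mV companion trace (outward).
#' @param delay synaptic onset delay after the light pulse, s.
#' @param noise_sd recording noise SD, nA.
#' @param rate sampling rate, Hz.
#' @param trace_length s.
#' @param stim_onset time of the (first) light pulse, s.
#' @return list of class `SynapseParams`.
#' @export
synapse_params <- function(max_amp = 8.8, i50 = 0.2, hill = 2,
                           tau_rise = 0.0015, tau_decay = 0.008,
                           ppr = 0.73, isi = 0.05, nmda = NULL,
                           delay = 0.003, noise_sd = 0.02, rate = 10000,
                           trace_length = 0.4, stim_onset = 0.1) {
  check_number(max_amp, "max_amp", 0)
  check_number(i50, "i50", 1e-12)
  check_number(hill, "hill", 1e-12)
  if (tau_rise <= 0 || tau_decay <= 0) stop_invalid("time constants must be positive")
  if (!is.null(nmda) && (nmda$tau_rise <= 0 || nmda$tau_decay <= 0)) {
    stop_invalid("time constants must be positive")
  }
  check_number(ppr, "ppr", 0)
  structure(as.list(environment()), class = "SynapseParams")
}

#' Simulate light-evoked EPSC recordings over an intensity series
#'
#' Peak amplitude follows a saturating Hill function of light intensity,
#' `A(I) = max_amp * I^h / (I^h + i50^h)`. With two pulses the second EPSC
#' amplitude is `ppr` times the first and rides on the decay of the first.
#' When NMDA parameters are given, a +50 mV companion trace (outward, slow
#' kinetics) is produced per intensity.
#'
#' @param intensities sorted ascending, normalized 0-1.
#' @param params a [synapse_params()].
#' @param n_pulses 1 or 2 light pulses.
#' @param seed integer seed for the recording noise.
#' @return list of `EphysRecording` objects: `time` (s), `current` (nA),
#'   `holding_mV`, `intensity`, `stim_onsets` (s), and optionally
#'   `companion_p50` (the +50 mV recording).
#' @export
simulate_epsc <- function(intensities, params = synapse_params(),
                          n_pulses = 1, seed = 1L) {
  if (is.unsorted(intensities)) stop_invalid("intensities must be sorted ascending")
  if (!inherits(params, "SynapseParams")) stop_invalid("expected SynapseParams")
  n_t <- round(params$trace_length * params$rate)
  t <- (seq_len(n_t) - 1) / params$rate
  stims <- params$stim_onset + (seq_len(n_pulses) - 1) * params$isi
  with_seed(seed, {
    lapply(intensities, function(I) {
      a <- params$max_amp * I^params$hill / (I^params$hill + params$i50^params$hill)
      amps <- a * c(1, params$ppr)[seq_len(n_pulses)]
      sig <- numeric(n_t)
      for (p in seq_len(n_pulses)) {
        sig <- sig + amps[p] *
          epsc_kernel(t - stims[p] - params$delay, params$tau_rise, params$tau_decay)
      }
      rec <- structure(list(
        time = t, current = -sig + rnorm(n_t, 0, params$noise_sd),
        holding_mV = -70, intensity = I, stim_onsets = stims, rate = params$rate
      ), class = "EphysRecording")
      if (!is.null(params$nmda)) {
        an <- params$nmda$amp * I^params$hill / (I^params$hill + params$i50^params$hill)
        nsig <- an * epsc_kernel(t - stims[1] - params$delay,
                                 params$nmda$tau_rise, params$nmda$tau_decay)
        rec$companion_p50 <- structure(list(
          time = t, current = nsig + rnorm(n_t, 0, params$noise_sd),
          holding_mV = 50, intensity = I, stim_onsets = stims[1], rate = params$rate
        ), class = "EphysRecording")
      }
      rec
    })
  })
}

# Baseline mean and SD over a window preceding the (first) stimulus.
epsc_baseline <- function(rec, baseline_window) {
  if (is.null(baseline_window)) {
    baseline_window <- c(0, max(rec$stim_onsets[1] - 0.005, rec$time[2]))
  }
  sel <- rec$time >= baseline_window[1] & rec$time < baseline_window[2]
  if (!any(sel)) stop_invalid("baseline window precedes the recording")
  c(mean(rec$current[sel]), sd(rec$current[sel]))
}

#' Peak EPSC amplitude
#'
#' Baseline-subtracted extremum within 100 ms after the stimulus: most
#' negative deflection at negative holding potentials (inward current),
#' most positive at positive ones. Flagged when the deflection stays below
#' 3x the baseline noise SD.
#'
#' @param rec an `EphysRecording`.
#' @param stimulus_index which stimulus to analyze.
#' @param baseline_window c(lo, hi) s before the stimulus (default: from 0 to
#'   5 ms before the first stimulus).
#' @param post_window length of the search window, s.
#' @return list: `amplitude` (nA, positive magnitude), `t_peak` (s),
#'   `flagged` (below detection), `baseline`.
#' @export
epsc_peak <- function(rec, stimulus_index = 1, baseline_window = NULL,
                      post_window = 0.1) {
  b <- epsc_baseline(rec, baseline_window)
  s0 <- rec$stim_onsets[stimulus_index]
  sel <- rec$time >= s0 & rec$time < s0 + post_window
  y <- rec$current[sel] - b[1]
  inward <- rec$holding_mV < 0
  ext <- if (inward) min(y) else max(y)
  amp <- abs(ext)
  flagged <- amp <= 5 * b[2] || (if (inward) ext > 0 else ext < 0)
  list(amplitude = amp,
       t_peak = rec$time[sel][if (inward) which.min(y) else which.max(y)],
       flagged = flagged, baseline = b[1])
}

#' Input-output curve of EPSC amplitude versus light intensity
#'
#' @param recordings list of `EphysRecording` at different intensities.
#' @param ... passed to [epsc_peak()].
#' @return list: `curve` data.frame (`intensity`, `amplitude`, sorted;
#'   duplicate intensities averaged) and `saturated` (top two amplitudes
#'   within 10% of each other).
#' @export
input_output_curve <- function(recordings, ...) {
  if (length(recordings) < 3L) stop_invalid("need >= 3 intensities")
  df <- data.frame(
    intensity = vapply(recordings, function(r) r$intensity, 1),
    amplitude = vapply(recordings, function(r) epsc_peak(r, ...)$amplitude, 1)
  )
  agg <- aggregate(amplitude ~ intensity, df, mean)
  agg <- agg[order(agg$intensity), ]
  k <- nrow(agg)
  top2 <- agg$amplitude[c(k - 1, k)]
  saturated <- max(top2) > 0 && abs(diff(top2)) / max(top2) < 0.10
  list(curve = agg, saturated = saturated)
}

#' Paired-pulse ratio at a fixed inter-stimulus interval
#'
#' PPR = peak2 / peak1, where the second peak is measured after subtracting
#' the extrapolated mono-exponential decay of the first EPSC (log-linear fit
#' over the decay between the first peak and the second stimulus).
#'
#' @param rec an `EphysRecording` with two stimuli.
#' @param baseline_window passed to [epsc_peak()].
#' @return list: `ppr`, `peak1`, `peak2`, `tau_decay_fit` (s).
#' @export
paired_pulse_ratio <- function(rec, baseline_window = NULL) {
  if (length(rec$stim_onsets) < 2L) stop_invalid("recording needs two stimuli")
  b <- epsc_baseline(rec, baseline_window)
  p1 <- epsc_peak(rec, 1, baseline_window,
                  post_window = rec$stim_onsets[2] - rec$stim_onsets[1])
  if (p1$flagged) stop_degenerate("undetectable first EPSC: PPR undefined")
  sgn <- if (rec$holding_mV < 0) -1 else 1
  # mono-exponential fit of the first decay, from peak to just before stim 2
  sel <- rec$time > p1$t_peak & rec$time < rec$stim_onsets[2] - 0.002
  yd <- sgn * (rec$current[sel] - b[1]) # positive decaying magnitude
  ok <- yd > 3 * b[2] & yd > 0.05 * p1$amplitude
  if (sum(ok) >= 5) {
    tt <- rec$time[sel][ok] - p1$t_peak
    fit <- stats::lm.fit(cbind(1, tt), log(yd[ok]))
    a0 <- exp(fit$coefficients[1])
    tau <- -1 / fit$coefficients[2]
    decay <- function(t) ifelse(t > 0, a0 * exp(-pmin((t - 0) / tau, 700)), NA)
  } else {
    decay <- function(t) 0 # first EPSC already fully decayed
    tau <- NA_real_
  }
  s2 <- rec$stim_onsets[2]
  sel2 <- rec$time >= s2 & rec$time < s2 + (rec$stim_onsets[2] - rec$stim_onsets[1])
  y2 <- sgn * (rec$current[sel2] - b[1]) - decay(rec$time[sel2] - p1$t_peak)
  peak2 <- max(y2)
  list(ppr = peak2 / p1$amplitude, peak1 = p1$amplitude, peak2 = peak2,
       tau_decay_fit = tau)
}

#' AMPA/NMDA ratio
#'
#' AMPA peak amplitude at -70 mV divided by the NMDA-receptor-mediated
#' current measured on the +50 mV trace at a fixed delay after the stimulus
#' (50 ms by default, when the fast AMPA component has decayed).
#'
#' @param rec_m70 `EphysRecording` at -70 mV.
#' @param rec_p50 `EphysRecording` at +50 mV, same stimulus clock.
#' @param t_nmda measurement time after stimulus onset, s.
#' @param baseline_window passed to [epsc_peak()].
#' @return list: `ratio`, `ampa` (nA), `nmda` (nA), `flagged` (NMDA below
#'   noise; ratio `NA`).
#' @export
ampa_nmda_ratio <- function(rec_m70, rec_p50, t_nmda = 0.05,
                            baseline_window = NULL) {
  if (abs(rec_m70$stim_onsets[1] - rec_p50$stim_onsets[1]) > 1e-9) {
    stop_invalid("the two recordings are not on the same stimulus clock")
  }
  ampa <- epsc_peak(rec_m70, 1, baseline_window)
  b <- epsc_baseline(rec_p50, baseline_window)
  idx <- which.min(abs(rec_p50$time - (rec_p50$stim_onsets[1] + t_nmda)))
  nmda <- rec_p50$current[idx] - b[1]
  flagged <- nmda < 3 * b[2]
  list(ratio = if (flagged) NA_real_ else ampa$amplitude / nmda,
       ampa = ampa$amplitude, nmda = nmda, flagged = flagged)
}

#' EPSC onset delay
#'
#' Time from stimulus onset to the first crossing of 10% of the peak
#' amplitude (linear interpolation between samples).
#'
#' @param rec an `EphysRecording`.
#' @param frac crossing criterion as a fraction of peak.
#' @param baseline_window,post_window passed to [epsc_peak()].
#' @return delay in ms, or `NA` when no EPSC is detected.
#' @export
epsc_delay <- function(rec, frac = 0.1, baseline_window = NULL,
                       post_window = 0.1) {
  pk <- epsc_peak(rec, 1, baseline_window, post_window)
  if (pk$flagged) return(NA_real_)
  b <- epsc_baseline(rec, baseline_window)
  sgn <- if (rec$holding_mV < 0) -1 else 1
  s0 <- rec$stim_onsets[1]
  sel <- which(rec$time >= s0 & rec$time < s0 + post_window)
  y <- sgn * (rec$current[sel] - b[1])
  thr <- frac * pk$amplitude
  i <- which(y >= thr)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return((rec$time[sel[1]] - s0) * 1000)
  # linear interpolation between samples i-1 and i
  t0 <- rec$time[sel[i - 1]]; t1 <- rec$time[sel[i]]
  y0 <- y[i - 1]; y1 <- y[i]
  tc <- t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
  (tc - s0) * 1000
}

#' Excitation/inhibition ratio
#'
#' Quotient of the EPSC peak at the excitatory holding potential and the
#' outward current peak at the inhibitory-reversal-free potential
#' (typically 0 mV).
#'
#' @param rec_exc,rec_inh `EphysRecording`s at the two holding potentials.
#' @param ... passed to [epsc_peak()].
#' @return list: `ratio`, `exc`, `inh`, `flagged`.
#' @export
ei_ratio <- function(rec_exc, rec_inh, ...) {
  e <- epsc_peak(rec_exc, ...)
  i <- epsc_peak(rec_inh, ...)
  list(ratio = if (i$flagged || i$amplitude == 0) NA_real_ else
    e$amplitude / i$amplitude, exc = e$amplitude, inh = i$amplitude,
    flagged = e$flagged || i$flagged)
}

#' @importFrom stats aggregate dist
NULL
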