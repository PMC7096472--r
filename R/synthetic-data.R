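#' Experimental protocol specification for synthetic recordings
#'
#' Describes an ordered sequence of protocol segments (rest, cold-pressor,
#' neutral/pleasant/unpleasant elicitation, recovery) together with the
#' autonomic parameters that drive the heartbeat and skin-conductance
#' generators in each segment. This is the "stated world" every downstream
#' stage is validated against: the heartbeat generator is an integral pulse
#' frequency modulation (IPFM) model whose modulation carries LF (0.1 Hz)
#' and HF (0.25 Hz) components, and the electrodermal generator superimposes
#' Bateman-kernel skin-conductance responses (SCRs) on a slow tonic level.
#'
#' @param segments data.frame with one row per segment and columns
#'   `label` (one of rest, cpt, neutral, pleasant, unpleasant, recovery),
#'   `duration` (s), `mean_rr` (ms), `lf_amp`, `hf_amp` (dimensionless
#'   modulation amplitudes), `scr_rate` (SCRs per minute), `scr_amp`
#'   (microsiemens scale of SCR amplitudes), `tonic_level` (microsiemens).
#' @param seed integer seed attached to the protocol.
#' @param transition_s autonomic parameters ramp linearly over this many
#'   seconds at each segment boundary (default 10, mirroring the
#'   rest-to-elicitation transition of the experimental protocol).
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(segments, seed = 1L, transition_s = 10) {
  need <- c("label", "duration", "mean_rr", "lf_amp", "hf_amp",
            "scr_rate", "scr_amp", "tonic_level")
  check_that(is.data.frame(segments) && all(need %in% names(segments)),
             paste("segments must contain columns:", paste(need, collapse = ", ")))
  labs <- c("rest", "cpt", "neutral", "pleasant", "unpleasant", "recovery")
  check_that(all(segments$label %in% labs), "unknown segment label")
  check_that(all(segments$duration > 0), "segment durations must be > 0")
  check_that(all(segments$mean_rr >= 300 & segments$mean_rr <= 2000),
             "mean RR must lie in [300, 2000] ms")
  check_that(all(segments$lf_amp >= 0) && all(segments$hf_amp >= 0),
             "modulation amplitudes must be >= 0")
  check_that(all(segments$scr_rate >= 0), "SCR rates must be >= 0")
  check_that(all(segments$scr_amp >= 0), "SCR amplitude scale must be >= 0")
  structure(list(segments = segments, seed = as.integer(seed),
                 transition_s = transition_s),
            class = "protocol_spec")
}

#' Default experimental protocol
#'
#' Mirrors a cold-pressor plus affective-elicitation session: rest, CPT,
#' rest, three 90 s emotional video segments, recovery. Durations can be
#' scaled down for quick tests.
#'
#' @param scale multiplier applied to all durations (default 1).
#' @param seed integer seed.
#' @return a [protocol_spec()].
#' @export
default_protocol <- function(scale = 1, seed = 1L) {
  seg <- data.frame(
    label    = c("rest", "cpt", "rest", "neutral", "pleasant", "unpleasant", "recovery"),
    duration = c(240, 180, 180, 90, 90, 90, 240) * scale,
    mean_rr  = c(870, 790, 860, 865, 845, 840, 870),
    lf_amp   = c(0.05, 0.06, 0.05, 0.05, 0.055, 0.06, 0.05),
    hf_amp   = c(0.05, 0.03, 0.05, 0.05, 0.045, 0.04, 0.05),
    scr_rate = c(2, 8, 2, 2.5, 5, 6, 2),
    scr_amp  = c(0.15, 0.45, 0.15, 0.2, 0.35, 0.4, 0.15),
    tonic_level = c(2.0, 2.6, 2.2, 2.1, 2.3, 2.4, 2.0)
  )
  protocol_spec(seg, seed = seed)
}

protocol_duration <- function(protocol) sum(protocol$segments$duration)

# Per-segment parameter value at times t (s): piecewise constant with a
# linear ramp over the first `transition_s` seconds of each segment.
segment_param <- function(protocol, t, col) {
  edges <- c(0, cumsum(protocol$segments$duration))
  idx <- findInterval(pmin(t, edges[length(edges)] - 1e-12), edges,
                      rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  v <- protocol$segments[[col]][idx]
  tr <- protocol$transition_s %||% 0
  if (tr > 0) {
    into <- t - edges[idx]
    ramp <- idx > 1L & into < tr
    if (any(ramp)) {
      prev <- protocol$segments[[col]][idx[ramp] - 1L]
      w <- into[ramp] / tr
      v[ramp] <- prev * (1 - w) + v[ramp] * w
    }
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

segment_window <- function(protocol, label) {
  edges <- c(0, cumsum(protocol$segments$duration))
  i <- which(protocol$segments$label == label)
  check_that(length(i) >= 1L, paste("no segment labelled", label))
  cbind(start = edges[i], end = edges[i + 1L])
}

#' Generate heartbeat event times by integral pulse frequency modulation
#'
#' Integrates the modulation
#' \deqn{m(t) = \frac{1}{\mu_{RR}(t)}\left[1 + a_{LF}\sin(2\pi 0.1 t) +
#'   a_{HF}\sin(2\pi 0.25 t)\right]}
#' to unit threshold; each threshold crossing emits a beat. Segment-wise
#' \eqn{\mu_{RR}}, \eqn{a_{LF}}, \eqn{a_{HF}} come from the protocol, so the
#' RR spectrum concentrates power at 0.1 Hz (LF) and 0.25 Hz (HF) with known
#' amplitudes.
#'
#' @param protocol a [protocol_spec()].
#' @param f_lf,f_hf modulation frequencies (Hz).
#' @param dt integration step (s).
#' @param rr_noise_sd SD of the stochastic firing threshold (relative
#'   units): thresholds follow a unit-increment random walk with white
#'   jitter, adding white RR noise of roughly `rr_noise_sd * mean RR`.
#'   The default 0.03 yields resting RR variance of a few hundred ms^2,
#'   in the range reported for healthy adults; 0 gives the deterministic
#'   IPFM model.
#' @param seed seed for the threshold jitter; default the protocol seed.
#' @return numeric vector of beat times (s), strictly increasing.
#' @export
generate_rr <- function(protocol, f_lf = 0.1, f_hf = 0.25, dt = 0.005,
                        rr_noise_sd = 0.03, seed = NULL) {
  check_that(inherits(protocol, "protocol_spec"), "protocol must be a protocol_spec")
  check_that(rr_noise_sd >= 0, "rr_noise_sd must be >= 0")
  seed <- if (is.null(seed)) protocol$seed else seed
  total <- protocol_duration(protocol)
  t <- seq(0, total, by = dt)
  mu <- segment_param(protocol, t, "mean_rr") / 1000  # s
  check_that(all(mu > 0), "non-positive mean RR")
  a_lf <- segment_param(protocol, t, "lf_amp")
  a_hf <- segment_param(protocol, t, "hf_amp")
  m <- (1 + a_lf * sin(2 * pi * f_lf * t) + a_hf * sin(2 * pi * f_hf * t)) / mu
  acc <- cumsum(m) * dt
  n_beats <- floor(acc[length(acc)])
  if (n_beats < 1L) return(numeric(0))
  thresholds <- seq_len(n_beats)
  if (rr_noise_sd > 0)
    thresholds <- with_seed(substream_seed(seed, 3L), {
      cumsum(pmax(1 + rr_noise_sd * rnorm(n_beats), 0.1))
    })
  thresholds <- thresholds[thresholds <= acc[length(acc)]]
  # invert the integrated modulation at the firing thresholds
  beats <- approx(x = acc, y = t, xout = thresholds, ties = "ordered")$y
  beats[!is.na(beats)]
}

# Bateman double-exponential SCR kernel, unit driver response.
bateman_kernel <- function(t, tau0 = 0.7, tau1 = 3.0) {
  check_that(tau1 > tau0 && tau0 > 0, "require 0 < tau0 < tau1")
  (exp(-t / tau1) - exp(-t / tau0)) / (tau1 - tau0) * (t >= 0)
}

# Closed-form peak time of the Bateman kernel.
bateman_peak_time <- function(tau0 = 0.7, tau1 = 3.0) {
  tau0 * tau1 * log(tau1 / tau0) / (tau1 - tau0)
}

#' Generate a synthetic electrodermal activity series
#'
#' Slow tonic baseline (natural spline through per-segment levels) plus a
#' sparse driver: SCR event times drawn from a piecewise-constant-rate
#' Poisson process, gamma-distributed amplitudes, convolved with the Bateman
#' kernel \eqn{(e^{-t/\tau_1} - e^{-t/\tau_0})/(\tau_1-\tau_0)}.
#'
#' @param protocol a [protocol_spec()].
#' @param rate sampling rate (Hz), default 500 to mimic the acquisition
#'   hardware.
#' @param tau0,tau1 Bateman time constants (s); defaults 0.7 and 3.0.
#' @param noise_sd additive white measurement noise SD (microsiemens).
#' @param seed optional override of the protocol seed.
#' @return list with `samples`, `rate`, `t`, `tonic`, `phasic`,
#'   `scr_times`, `scr_amps`.
#' @export
generate_eda <- function(protocol, rate = 500, tau0 = 0.7, tau1 = 3.0,
                         noise_sd = 0.01, seed = NULL) {
  check_that(inherits(protocol, "protocol_spec"), "protocol must be a protocol_spec")
  check_that(all(protocol$segments$scr_amp >= 0), "negative SCR amplitude scale")
  seed <- if (is.null(seed)) protocol$seed else seed
  total <- protocol_duration(protocol)
  n <- round(total * rate)
  t <- (seq_len(n) - 1L) / rate

  seg <- protocol$segments
  edges <- c(0, cumsum(seg$duration))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  # spline through segment midpoints (flat-extended at the ends)
  tonic <- spline(x = c(0, mids, total),
                  y = c(seg$tonic_level[1], seg$tonic_level,
                        seg$tonic_level[nrow(seg)]),
                  xout = t, method = "natural")$y

  with_seed(seed, {
    scr_times <- numeric(0)
    scr_amps <- numeric(0)
    for (i in seq_len(nrow(seg))) {
      lambda <- seg$scr_rate[i] / 60  # events per second
      if (lambda <= 0) next
      k <- rpois(1L, lambda * seg$duration[i])
      if (k == 0L) next
      tt <- sort(runif(k, edges[i], edges[i + 1L]))
      aa <- rgamma(k, shape = 2, scale = seg$scr_amp[i] / 2)  # mean scr_amp
      scr_times <- c(scr_times, tt)
      scr_amps <- c(scr_amps, aa)
    }
    driver <- numeric(n)
    if (length(scr_times)) {
      idx <- pmin(pmax(round(scr_times * rate) + 1L, 1L), n)
      for (j in seq_along(idx)) driver[idx[j]] <- driver[idx[j]] + scr_amps[j]
    }
    # kernel normalized to unit peak so scr_amp is the SCR peak amplitude
    kern <- bateman_kernel(seq(0, 40, by = 1 / rate), tau0, tau1)
    kern <- kern / max(kern)
    phasic <- conv_fft(driver, kern)[seq_len(n)]
    noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    list(samples = tonic + phasic + noise, rate = rate, t = t,
         tonic = tonic, phasic = phasic,
         scr_times = scr_times, scr_amps = scr_amps)
  })
}

#' Generate a synthetic ECG from beat times
#'
#' Places a template QRS-like waveform (narrow biphasic pulse) at each beat
#' time on a flat baseline, with optional white noise. Morphology is
#' deliberately minimal: the purpose is exercising R-peak detection, not
#' clinical realism.
#'
#' @param beat_times beat (R-wave) times, s, increasing.
#' @param rate sampling rate, Hz (>= 100).
#' @param duration total duration (s); default covers the last beat + 1 s.
#' @param noise_sd additive white noise SD relative to unit R amplitude.
#' @param snr_db alternative to `noise_sd`: sets the noise so that the
#'   clean-signal-power to noise-power ratio equals this many dB.
#' @param seed integer seed for the noise.
#' @return list with `samples`, `rate`, `t`.
#' @export
generate_ecg <- function(beat_times, rate = 500, duration = NULL,
                         noise_sd = 0, snr_db = NULL, seed = 1L) {
  check_that(rate >= 100, "sampling rate below 100 Hz cannot resolve the QRS template")
  check_that(all(diff(beat_times) > 0), "beat times must be strictly increasing")
  if (is.null(duration)) duration <- max(beat_times) + 1
  n <- round(duration * rate)
  t <- (seq_len(n) - 1L) / rate
  # template: Gaussian R peak (sigma 8 ms) minus small flanking troughs
  tw <- seq(-0.05, 0.05, by = 1 / rate)
  templ <- exp(-0.5 * (tw / 0.008)^2) -
    0.25 * exp(-0.5 * ((tw - 0.025) / 0.012)^2) -
    0.15 * exp(-0.5 * ((tw + 0.025) / 0.012)^2)
  half <- (length(templ) - 1L) %/% 2L
  x <- numeric(n)
  centers <- round(beat_times * rate) + 1L
  for (c0 in centers) {
    i0 <- c0 - half; i1 <- c0 + half
    j0 <- max(1L, i0); j1 <- min(n, i1)
    if (j0 > j1) next
    x[j0:j1] <- x[j0:j1] + templ[(j0 - i0 + 1L):(j1 - i0 + 1L)]
  }
  if (!is.null(snr_db)) noise_sd <- sqrt(mean(x^2) / 10^(snr_db / 10))
  if (noise_sd > 0) x <- x + with_seed(seed, rnorm(n, 0, noise_sd))
  list(samples = x, rate = rate, t = t)
}

#' Generate a synthetic cohort of recordings
#'
#' Draws per-subject protocols by log-normal jitter around the template
#' protocol's positive parameters, applies the configured cold-pressor
#' effect to CPT segments (shortened mean RR, reduced HF modulation, raised
#' SCR rate and amplitude), and generates RR and EDA signals per subject.
#' Subject substreams are derived from the single cohort seed by a counter,
#' so results do not depend on generation order.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param protocol template [protocol_spec()]; default [default_protocol()].
#' @param effect list of CPT deltas applied on top of the template:
#'   `mean_rr` (ms, subtracted), `hf_amp` (subtracted), `scr_rate`
#'   (per-minute, added), `scr_amp` (added). `effect = NULL` or all-zero
#'   gives an exchangeable null cohort (the template CPT row is reset to the
#'   preceding rest parameters first).
#' @param jitter_sd log-scale SD of per-subject parameter jitter.
#' @param seed cohort seed.
#' @param eda_rate EDA sampling rate (Hz).
#' @return list of recordings; each has `subject`, `protocol`,
#'   `beat_times`, `eda` (as from [generate_eda()]).
#' @export
generate_cohort <- function(n_subjects, protocol = default_protocol(),
                            effect = list(mean_rr = 80, hf_amp = 0.02,
                                          scr_rate = 6, scr_amp = 0.3),
                            jitter_sd = 0.04, seed = 1L, eda_rate = 50) {
  check_that(n_subjects >= 2, "need at least 2 subjects")
  seg0 <- protocol$segments
  is_cpt <- seg0$label == "cpt"
  # null world: CPT rows inherit the first rest row's parameters
  ref <- seg0[match("rest", seg0$label), ]
  for (col in c("mean_rr", "lf_amp", "hf_amp", "scr_rate", "scr_amp", "tonic_level"))
    seg0[[col]][is_cpt] <- ref[[col]]
  if (is.null(effect)) effect <- list()
  eff <- modifyList(list(mean_rr = 0, hf_amp = 0, scr_rate = 0, scr_amp = 0),
                    effect)
  seg0$mean_rr[is_cpt] <- seg0$mean_rr[is_cpt] - eff$mean_rr
  seg0$hf_amp[is_cpt] <- pmax(0, seg0$hf_amp[is_cpt] - eff$hf_amp)
  seg0$scr_rate[is_cpt] <- seg0$scr_rate[is_cpt] + eff$scr_rate
  seg0$scr_amp[is_cpt] <- seg0$scr_amp[is_cpt] + eff$scr_amp

  lapply(seq_len(n_subjects), function(s) {
    sseed <- substream_seed(seed, s)
    seg <- with_seed(sseed, {
      sg <- seg0
      for (col in c("mean_rr", "scr_amp", "tonic_level")) {
        f <- rlnorm(1L, 0, jitter_sd)
        sg[[col]] <- pmin(pmax(sg[[col]] * f, if (col == "mean_rr") 300 else 0),
                          if (col == "mean_rr") 2000 else Inf)
      }
      sg$scr_rate <- sg$scr_rate * rlnorm(1L, 0, jitter_sd)
      sg$lf_amp <- sg$lf_amp * rlnorm(1L, 0, jitter_sd)
      sg$hf_amp <- sg$hf_amp * rlnorm(1L, 0, jitter_sd)
      sg
    })
    prot <- protocol_spec(seg, seed = sseed,
                          transition_s = protocol$transition_s %||% 10)
    beats <- generate_rr(prot)
    eda <- generate_eda(prot, rate = eda_rate, seed = substream_seed(sseed, 7L))
    list(subject = s, protocol = prot, beat_times = beats, eda = eda)
  })
}

#' Write / read a sampled recording as two-column CSV (time, value)
#' @param x list with `t` and `samples`.
#' @param path output file.
#' @return `path`, invisibly (`write_recording_csv`); a list with `t`,
#'   `samples`, `rate` (`read_recording_csv`).
#' @export
write_recording_csv <- function(x, path) {
  write.csv(data.frame(time = x$t, value = x$samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  d <- read.csv(path)
  check_that(ncol(d) >= 2, "expected two-column CSV (time, value)")
  rate <- 1 / median(diff(d[[1]]))
  list(t = d[[1]], samples = d[[2]], rate = rate)
}

#' Write beat or SCR event times as a one-column annotation file
#' @param times event times (s).
#' @param path output file.
#' @return `path`, invisibly; `read_annotations` returns the numeric times.
#' @export
write_annotations <- function(times, path) {
  writeLines(format(times, digits = 10, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) as.numeric(readLines(path))
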