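test_that("unmodulated deterministic IPFM emits exactly periodic beats", {
  prot <- flat_protocol(duration = 60, mean_rr = 1000)
  beats <- generate_rr(prot, rr_noise_sd = 0)
  expect_length(beats, 60L)
  expect_equal(diff(beats), rep(1, 59), tolerance = 1e-9)
})

test_that("IPFM beat count matches the integrated modulation", {
  for (mu in c(700, 1000, 1300)) {
    prot <- flat_protocol(duration = 120, mean_rr = mu, lf = 0.05, hf = 0.08)
    beats <- generate_rr(prot, rr_noise_sd = 0)
    expect_lte(abs(length(beats) - floor(120 * 1000 / mu)), 1L)
  }
})

test_that("HF modulation produces the dominant RR spectral peak at 0.25 Hz", {
  prot <- flat_protocol(duration = 300, mean_rr = 900, lf = 0, hf = 0.1)
  beats <- generate_rr(prot, rr_noise_sd = 0)
  x <- rr_resampled(beats, fs = 4)
  ps <- welch_psd(x, fs = 4)
  keep <- ps$f > 0.02                      # skip the DC region
  fpeak <- ps$f[keep][which.max(ps$p[keep])]
  expect_lt(abs(fpeak - 0.25), 0.02)
  # band concentration: >= 80% of non-DC power within +/- 0.03 Hz
  inband <- ps$f[keep] >= 0.22 & ps$f[keep] <= 0.28
  expect_gte(sum(ps$p[keep][inband]) / sum(ps$p[keep]), 0.8)
})

test_that("generators are reproducible under a fixed seed", {
  prot <- default_protocol(scale = 0.2, seed = 42)
  expect_identical(generate_rr(prot), generate_rr(prot))
  e1 <- generate_eda(prot, rate = 50)
  e2 <- generate_eda(prot, rate = 50)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$scr_times, e2$scr_times)
  c1 <- generate_cohort(3, protocol = prot, seed = 7)
  c2 <- generate_cohort(3, protocol = prot, seed = 7)
  expect_identical(c1[[2]]$beat_times, c2[[2]]$beat_times)
  expect_identical(c1[[3]]$eda$samples, c2[[3]]$eda$samples)
})

test_that("EDA generator: zero SCR rate returns the tonic baseline exactly", {
  prot <- flat_protocol(duration = 60, scr_rate = 0, tonic = 2)
  eda <- generate_eda(prot, rate = 50, noise_sd = 0)
  expect_equal(eda$samples, eda$tonic, tolerance = 1e-12)
  expect_equal(max(abs(eda$phasic)), 0)
})

test_that("single SCR peaks at the Bateman closed-form time", {
  prot <- flat_protocol(duration = 60, scr_rate = 0, tonic = 0)
  eda <- generate_eda(prot, rate = 50, noise_sd = 0)
  rate <- 50
  n <- length(eda$samples)
  drv <- numeric(n); drv[10 * rate + 1L] <- 1
  kern <- svbalance:::bateman_kernel(seq(0, 40, by = 1 / rate))
  ph <- svbalance:::conv_fft(drv, kern)[seq_len(n)]
  tpeak <- (which.max(ph) - 1) / rate
  expect_lt(abs(tpeak - (10 + svbalance:::bateman_peak_time())), 1 / rate + 1e-9)
})

test_that("EDA output is the exact sum of stored tonic and phasic parts", {
  prot <- default_protocol(scale = 0.2, seed = 3)
  eda <- generate_eda(prot, rate = 50, noise_sd = 0)
  expect_equal(eda$samples, eda$tonic + eda$phasic, tolerance = 1e-12)
  # doubling driver amplitudes doubles the phasic component
  seg2 <- prot$segments; seg2$scr_amp <- 2 * seg2$scr_amp
  prot2 <- protocol_spec(seg2, seed = prot$seed, transition_s = prot$transition_s)
  eda2 <- generate_eda(prot2, rate = 50, noise_sd = 0)
  # same seed => same event times, gamma amplitudes scale linearly in scale
  expect_equal(eda2$phasic, 2 * eda$phasic, tolerance = 1e-9)
})

test_that("ECG generator places R peaks at beat times and rejects low rates", {
  beats <- c(1, 2, 3)
  ecg <- generate_ecg(beats, rate = 500, duration = 4, noise_sd = 0)
  expect_length(ecg$samples, 2000L)
  for (b in beats) {
    win <- which(ecg$t > b - 0.2 & ecg$t < b + 0.2)
    expect_lt(abs(ecg$t[win][which.max(ecg$samples[win])] - b), 0.002 + 1e-9)
  }
  expect_error(generate_ecg(beats, rate = 50), "100 Hz")
  expect_error(generate_ecg(c(2, 1, 3)), "increasing")
})

test_that("protocol validation rejects out-of-range parameters", {
  seg <- default_protocol()$segments
  bad <- seg; bad$mean_rr[1] <- 100
  expect_error(protocol_spec(bad), "mean RR")
  bad <- seg; bad$duration[2] <- 0
  expect_error(protocol_spec(bad), "durations")
  bad <- seg; bad$scr_amp[1] <- -1
  expect_error(protocol_spec(bad), ">= 0")
})

test_that("cohort CPT effect shifts mean RR by the configured amount", {
  # configured 80 ms drop recovered from the generated beat trains
  cohort <- generate_cohort(8, protocol = default_protocol(scale = 0.5),
                            effect = list(mean_rr = 80), seed = 11)
  d <- vapply(cohort, function(rec) {
    w_rest <- segment_window(rec$protocol, "rest")[1, ]
    w_cpt <- segment_window(rec$protocol, "cpt")[1, ]
    u <- rec$beat_times
    rr <- diff(u); tt <- u[-1]
    mean(rr[tt >= w_rest[1] + 15 & tt < w_rest[2]]) -
      mean(rr[tt >= w_cpt[1] + 15 & tt < w_cpt[2]])
  }, numeric(1)) * 1000
  expect_lt(abs(median(d) - 80), 20)
})

test_that("recording and annotation round-trips preserve data", {
  prot <- flat_protocol(duration = 40, scr_rate = 3, scr_amp = 0.3)
  eda <- generate_eda(prot, rate = 50)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile()
  write_recording_csv(eda, f1)
  back <- read_recording_csv(f1)
  expect_equal(back$samples, eda$samples, tolerance = 1e-6)
  expect_equal(back$rate, 50, tolerance = 1e-6)
  write_annotations(c(1.25, 2.5, 3.75), f2)
  expect_equal(read_annotations(f2), c(1.25, 2.5, 3.75))
  unlink(c(f1, f2))
})
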