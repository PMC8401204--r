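# a bare synthetic FID with known content, for transform-level tests
make_fid <- function(freqs_hz, amps = rep(1, length(freqs_hz)), lw = 1,
                     n = 4096, acq = .acq_small) {
  dwell <- 1 / (acq$spectral_width * acq$spectrometer_freq)
  t <- (seq_len(n) - 1) * dwell
  sig <- Reduce(`+`, lapply(seq_along(freqs_hz), function(j)
    amps[j] * exp((2i * pi * freqs_hz[j] - pi * lw) * t)))
  structure(list(signal = sig,
                 acq = acquisition_params(n_points = n,
                                          spectral_width = acq$spectral_width),
                 sample = list(), provenance = list()),
            class = "nmr_fid")
}

test_that("apodization applies the exponential window", {
  fid <- make_fid(100, n = 16384)
  same <- apodize(fid, 0)
  expect_equal(same$signal, fid$signal)

  ap <- apodize(fid, 0.8)
  dwell <- 1 / (12 * 600)
  i1s <- round(1 / dwell) + 1L   # the point at t = 1 s
  expect_equal(abs(ap$signal[i1s]) / abs(fid$signal[i1s]), exp(-0.8 * pi),
               tolerance = 1e-6)
  expect_equal(ap$signal[1], fid$signal[1])
  expect_error(apodize(fid, -1), "non-negative")
})

test_that("apodization broadens lines but conserves their area", {
  fid <- make_fid(200, n = 16384)
  fwhm <- function(sp) {
    y <- Re(sp$intensity)
    i <- which.max(y)
    half <- y[i] / 2
    l <- max(which(y[1:i] < half))
    r <- i + min(which(y[(i + 1):length(y)] < half))
    # linear interpolation of the half-height crossings
    xl <- sp$ppm[l] + (half - y[l]) / (y[l + 1] - y[l]) *
      (sp$ppm[l + 1] - sp$ppm[l])
    xr <- sp$ppm[r - 1] + (half - y[r - 1]) / (y[r] - y[r - 1]) *
      (sp$ppm[r] - sp$ppm[r - 1])
    abs(xr - xl) * 600
  }
  sp0 <- fourier_transform(zero_fill(fid, 4))
  sp1 <- fourier_transform(zero_fill(apodize(fid, 0.8), 4))
  expect_equal(fwhm(sp1) - fwhm(sp0), 0.8, tolerance = 0.15)

  # peak area invariant under apodization (isolated line)
  a0 <- sum(Re(sp0$intensity)) * abs(diff(sp0$ppm[1:2]))
  a1 <- sum(Re(sp1$intensity)) * abs(diff(sp1$ppm[1:2]))
  expect_equal(a1 / a0, 1, tolerance = 0.005)
})

test_that("zero filling pads with zeros and scales the grid", {
  fid <- make_fid(100, n = 16384)
  zf <- zero_fill(fid, 4)
  expect_length(zf$signal, 65536)
  expect_true(all(zf$signal[16385:65536] == 0))
  expect_equal(zero_fill(fid, 1)$signal, fid$signal)
  expect_error(zero_fill(fid, 0), "positive integer")
})

test_that("the Fourier transform places lines at their frequencies", {
  # single decaying exponential: one Lorentzian at the injected offset
  sp <- fourier_transform(make_fid(150))
  expect_s3_class(sp, "nmr_spectrum")
  expect_true(all(diff(sp$ppm) < 0))
  pk <- sp$ppm[which.max(Re(sp$intensity))]
  expect_equal((pk - sp$acq$carrier_ppm) * 600, 150, tolerance = 1)

  # two-line FID: maxima within one digital-resolution step
  fid2 <- make_fid(c(-321.4, 567.9), n = 16384)
  sp2 <- fourier_transform(zero_fill(apodize(fid2, 0.8), 4))
  step_hz <- 12 * 600 / length(sp2$ppm)
  y <- Re(sp2$intensity)
  pk_i <- order(y, decreasing = TRUE)
  f_found <- sort((sp2$ppm[pk_i[y[pk_i] > max(y) / 2][1:2]] -
                     sp2$acq$carrier_ppm) * 600)
  expect_equal(f_found, c(-321.4, 567.9), tolerance = 1.5 * step_hz / 321)
})

test_that("the transform round-trips to the FID", {
  fid <- make_fid(c(100, -250), amps = c(1, 2))
  sp <- fourier_transform(fid)
  # invert: undo the axis reordering, inverse FFT, restore the first point
  Y <- rev(sp$intensity)
  n <- length(Y)
  Y <- c(Y[(n / 2 + 1):n], Y[1:(n / 2)])
  back <- stats::fft(Y, inverse = TRUE) / n
  back[1] <- back[1] * 2
  expect_lt(max(abs(back - fid$signal)), 1e-10 * max(abs(fid$signal)))
})

test_that("phase correction is a group action recovered automatically", {
  sp <- fourier_transform(zero_fill(apodize(
    make_fid(c(-2100, -500, 300, 1200, 2600)), 0.8), 2))
  expect_equal(phase_correct(sp, 0, 0)$intensity, sp$intensity)

  fwd <- phase_correct(sp, 35, 0)
  back <- phase_correct(fwd, -35, 0)
  expect_lt(max(abs(back$intensity - sp$intensity)),
            1e-12 * max(abs(sp$intensity)))

  # inject known phases, recover within 1 degree / 5 degrees
  distorted <- phase_correct(sp, 20, 30)
  rec <- auto_phase(distorted)
  expect_lt(abs(((rec$phi0 + 20 + 180) %% 360) - 180), 1)
  expect_lt(abs(rec$phi1 + 30), 5)
})

test_that("baseline correction removes smooth drift and keeps peak area", {
  n <- 16384
  fid <- make_fid(300, n = n / 4)
  sp <- fourier_transform(zero_fill(apodize(fid, 0.8), 4))
  sp$phase_state <- "phased"
  x <- seq(-1, 1, length.out = n)
  drift <- 40 * (x^3 - 0.5 * x + 0.2)
  pk_ppm <- sp$ppm[which.max(Re(sp$intensity))]
  win <- abs(sp$ppm - pk_ppm) < 0.3
  area0 <- sum(Re(sp$intensity)[win]) * abs(diff(sp$ppm[1:2]))

  spd <- sp
  spd$intensity <- Re(sp$intensity) + drift
  corr <- baseline_correct(spd)
  # drift removed: quiet zones are close to zero again
  quiet <- sp$ppm > 8 | sp$ppm < 1
  expect_lt(max(abs(Re(corr$intensity)[quiet])), 0.01 * max(abs(drift)))
  # the Lorentzian's area is recovered within 1 percent
  area1 <- sum(Re(corr$intensity)[win]) * abs(diff(sp$ppm[1:2]))
  expect_equal(area1 / area0, 1, tolerance = 0.01)

  # without drift the correction changes nearly nothing
  corr0 <- baseline_correct(sp)
  expect_lt(max(abs(Re(corr0$intensity) - Re(sp$intensity))),
            0.005 * max(Re(sp$intensity)))
})

test_that("shift calibration is a rigid translation to 1.4938 ppm", {
  spec <- one_met_spec("alanine", 400, ppm_offset = 0.010)
  fid <- simulate_spectrum(spec, .lib)
  sp <- process_spectrum(fid, phase = "none", calibrate = FALSE)
  cal <- calibrate_shift(sp)
  expect_true(cal$calibrated)
  # rigid: the axis moved as one block
  expect_equal(unique(round(sp$ppm - cal$ppm, 12)),
               round(sp$ppm[1] - cal$ppm[1], 12))
  step <- 12 / length(cal$ppm)
  off <- cal$provenance[[length(cal$provenance)]]$offset
  expect_equal(off, 0.010, tolerance = 2 * step / 0.01)

  # upfield doublet line now at the target
  y <- Re(cal$intensity)
  sel <- which(cal$ppm > 1.48 & cal$ppm < 1.51)
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[pk %in% sel]
  up <- min(cal$ppm[pk[order(y[pk], decreasing = TRUE)][1:2]])
  expect_equal(up, 1.4938, tolerance = 2 * step / 1.4938)

  # idempotence: recalibrating applies a negligible offset
  cal2 <- calibrate_shift(cal)
  off2 <- cal2$provenance[[length(cal2$provenance)]]$offset
  expect_lt(abs(off2), step)
})

test_that("calibration fails loudly without an alanine doublet", {
  spec <- one_met_spec("glucose", 5000, tsp = 0, noise = 0.004)
  fid <- simulate_spectrum(spec, .lib, acq = .acq_small)
  sp <- process_spectrum(fid, phase = "none", calibrate = FALSE)
  expect_error(calibrate_shift(sp), "calibration peak not found")
})

test_that("the processing chain logs its provenance in order", {
  fid <- simulate_spectrum(one_met_spec("alanine", 400), .lib,
                           acq = .acq_small)
  sp <- process_spectrum(fid, phase = "none")
  steps <- vapply(sp$provenance, `[[`, character(1), "step")
  expect_equal(steps, c("simulate", "apodize", "zero_fill",
                        "fourier_transform", "baseline_correct",
                        "calibrate_shift"))
})
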