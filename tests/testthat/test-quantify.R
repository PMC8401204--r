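# an analytic spectrum object (no FFT) for integration-level tests
analytic_spectrum <- function(f, n = 65536) {
  ppm <- seq(12, 0, length.out = n) - 1.21   # descending, carrier at 4.79
  structure(list(ppm = ppm, intensity = f(ppm), phase_state = "phased",
                 calibrated = TRUE,
                 acq = acquisition_params(), provenance = list()),
            class = "nmr_spectrum")
}

test_that("region integration recovers a known Lorentzian area", {
  hw <- 0.0015   # HWHM in ppm
  sp <- analytic_spectrum(function(p) (hw / pi) / ((p - 2.385)^2 + hw^2))
  ints <- integrate_regions(sp, .tab)
  # VAR177 contains 2.385; tail loss follows the closed-form capture
  cap <- lorentzian_capture(2.385, 1, cbind(.tab$ppm_end[177],
                                            .tab$ppm_start[177]),
                            2 * hw * 600)
  expect_equal(unname(ints["VAR177"]), cap, tolerance = 0.01)
  wide <- window_integral(sp, 2.0, 2.8)
  expect_equal(wide, 1, tolerance = 0.01)
})

test_that("an MA-only sample yields a single active window", {
  spec <- sample_spec(concentrations = zero_conc(), tsp_conc = 0,
                      noise_sd = 0, lipid_scale = 0,
                      macromolecule_scale = 0)
  fid <- simulate_spectrum(spec, .lib)
  sp <- process_spectrum(fid, phase = "none", baseline = FALSE,
                         calibrate = FALSE)
  ma <- ma_integral(sp, attr(.tab, "ma_window"))
  ints <- integrate_regions(sp, .tab)
  expect_gt(ma, 0)
  # the MA window is the only active one away from the residual water
  mid <- .tab$ppm_end > 0.8 & .tab$ppm_start < 3.0
  expect_lt(max(abs(ints[mid])), 0.02 * ma)
})

test_that("MA normalization is exact and scale invariant", {
  v <- c(1, 2, 4)
  expect_equal(normalize_to_ma(v, 1), v)
  expect_equal(normalize_to_ma(3 * v, 3 * 2), normalize_to_ma(v, 2))
  expect_error(normalize_to_ma(v, 0), "internal standard")
  expect_error(normalize_to_ma(v, -1), "internal standard")
})

test_that("TSP releases MA-normalized binder signal (competitor effect)", {
  bm <- binding_model()
  acq <- acquisition_params()
  i0 <- simulate_integrals(one_met_spec("lactate", 1500, tsp = 0), .lib,
                           bm, acq, .tab)
  i4 <- simulate_integrals(one_met_spec("lactate", 1500, tsp = 4), .lib,
                           bm, acq, .tab)
  # raw binder integral increases upon TSP addition
  expect_gt(i4$integrals[215], i0$integrals[215])
  # and the MA-normalized value without TSP understates the truth
  expect_lt(i0$integrals[215] / i0$ma_integral,
            i4$integrals[215] / i4$ma_integral)
})

test_that("calibration curves behave like the published MA line", {
  exact <- fit_calibration_curve(data.frame(conc = 1:8,
                                            integral = 2 * (1:8)))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)

  # 8-point ladder with 1 percent proportional noise, averaged over seeds
  r2 <- vapply(1:20, function(s) {
    set.seed(s)
    conc <- seq(10, 110, length.out = 8)
    y <- 3.1 * conc * (1 + rnorm(8, 0, 0.01))
    fit_calibration_curve(data.frame(conc, y))$r_squared
  }, numeric(1))
  expect_gt(mean(r2), 0.999)

  expect_error(fit_calibration_curve(data.frame(conc = c(5, 5, 5),
                                                integral = c(1, 2, 3))),
               "degenerate")
  expect_error(fit_calibration_curve(data.frame(conc = 1:2,
                                                integral = 1:2)),
               "3 calibration points")
})

test_that("percent RSD matches the hand formula", {
  expect_equal(percent_rsd(c(5, 5, 5)), 0)
  expect_equal(percent_rsd(c(1, 2)), 100 * sd(c(1, 2)) / 1.5)
  expect_equal(percent_rsd(c(1, 2)), 47.14, tolerance = 1e-4)
  expect_equal(percent_rsd(c(9, 10, 11)), 10)
  expect_error(percent_rsd(3), "two values")
  expect_error(percent_rsd(c(-1, 1)), "zero mean")
})

test_that("packaged QC lists reproduce the 237 to 221 reduction", {
  set.seed(42)
  vals <- matrix(rlnorm(10 * 237), 10, 237,
                 dimnames = list(NULL, sprintf("VAR%03d", 1:237)))
  fm <- feature_matrix(vals, data.frame(sample_id = paste0("s", 1:10),
                                        group = rep(c("control", "cancer"),
                                                    5)), .tab)
  out <- apply_qc_filters(fm, mode = "packaged")
  expect_equal(ncol(out$filtered$values), 221)
  expect_setequal(out$report$var_id,
                  c(1, 9, 21, 22, 24, 27, 29, 30, 31,
                    80, 209, 215, 216, 217, 218, 237))
})

test_that("computed QC applies the replicate and both-group rules", {
  set.seed(7)
  n <- 40
  p <- 6
  vals <- matrix(rlnorm(n * p, log(100), 0.05), n, p,
                 dimnames = list(NULL, sprintf("VAR%03d", 1:p)))
  grp <- rep(c("control", "cancer"), each = n / 2)
  # VAR002: noisy in both groups; VAR003: noisy in cancer only
  vals[, 2] <- rlnorm(n, log(100), 0.6)
  vals[grp == "cancer", 3] <- rlnorm(n / 2, log(100), 0.6)
  vals[grp == "control", 3] <- rlnorm(n / 2, log(100), 0.02)
  reps <- matrix(rlnorm(12 * p, log(100), 0.02), 12, p,
                 dimnames = list(NULL, colnames(vals)))
  reps[, 5] <- rlnorm(12, log(100), 0.5)   # replicate-unstable variable

  fm <- feature_matrix(vals, data.frame(sample_id = paste0("s", 1:n),
                                        group = grp), .tab[1:p, ])
  fr <- feature_matrix(reps, data.frame(sample_id = paste0("r", 1:12),
                                        group = "pool"), .tab[1:p, ])
  out <- apply_qc_filters(fm, fr, qc_config(), mode = "computed")
  expect_true(5 %in% out$report$var_id[out$report$reason ==
                                         "intrasample_rsd"])
  expect_true(2 %in% out$report$var_id[out$report$reason ==
                                         "intersample_rsd"])
  expect_false(3 %in% out$report$var_id)   # noisy in one group only: kept

  # thresholds at infinity remove nothing
  none <- apply_qc_filters(fm, fr, qc_config(1e9, 1e9), mode = "computed")
  expect_equal(ncol(none$filtered$values), p)

  # the two filters commute (order independence)
  only_intra <- apply_qc_filters(fm, fr, qc_config(10, 1e9),
                                 mode = "computed")$kept
  only_inter <- apply_qc_filters(fm, fr, qc_config(1e9, 30),
                                 mode = "computed")$kept
  both <- apply_qc_filters(fm, fr, qc_config(10, 30),
                           mode = "computed")$kept
  expect_setequal(both, intersect(only_intra, only_inter))
})

test_that("hemolytic samples are excluded by flag", {
  meta <- data.frame(sample_id = sprintf("s%03d", 1:276),
                     hemolytic = rep(c(TRUE, FALSE), c(44, 232)))
  out <- exclude_hemolytic(meta)
  expect_equal(out$n_kept, 232)
  expect_equal(out$n_excluded, 44)

  none <- exclude_hemolytic(data.frame(sample_id = 1:5,
                                       hemolytic = rep(FALSE, 5)))
  expect_equal(none$n_kept, 5)
  expect_warning(exclude_hemolytic(data.frame(sample_id = 1:2,
                                              hemolytic = c(TRUE, TRUE))),
                 "none kept")
  expect_error(exclude_hemolytic(data.frame(sample_id = 1:2)),
               "missing hemolysis flag")
})

test_that("the internal-standard relation is exact and symmetric", {
  expect_equal(quantify(1, 53.85, n_protons_region = 2), 53.85)
  expect_equal(quantify(0.5, 100, n_protons_region = 1, n_protons_ma = 2),
               100)
  expect_error(quantify(1, 53.85, n_protons_region = 0), "positive")
})

test_that("closed-loop quantification recovers a spiked concentration", {
  fid <- simulate_spectrum(one_met_spec("alanine", 500), .lib)
  sp <- process_spectrum(fid, phase = "none", calibrate = FALSE)
  got <- quantify_group(sp, .lib, .tab, "alanine", "beta-CH3")
  expect_equal(got, 500, tolerance = 0.01)
})
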