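test_that("a lactate-only sample shows the published doublet", {
  fid <- simulate_spectrum(one_met_spec("lactate", 1500, tsp = 4), .lib)
  sp <- process_spectrum(fid, phase = "none", calibrate = FALSE)
  y <- Re(sp$intensity)
  sel <- which(sp$ppm > 1.30 & sp$ppm < 1.40)
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[pk %in% sel]
  pk <- pk[order(y[pk], decreasing = TRUE)][1:2]
  sep_hz <- abs(diff(sp$ppm[pk])) * 600
  expect_equal(sep_hz, 6.9, tolerance = 0.12 / 6.9)
  expect_equal(mean(sp$ppm[pk]), 1.348, tolerance = 0.002 / 1.348)
})

test_that("an empty sample is flat outside the standards and water", {
  spec <- sample_spec(concentrations = zero_conc(), noise_sd = 0,
                      lipid_scale = 0, macromolecule_scale = 0)
  fid <- simulate_spectrum(spec, .lib)
  sp <- process_spectrum(fid, phase = "none", baseline = FALSE,
                         calibrate = FALSE)
  y <- Re(sp$intensity)
  ma_height <- max(y[sp$ppm > 5.9 & sp$ppm < 6.1])
  expect_gt(ma_height, 0)
  # flat except the TSP, MA and residual-water neighbourhoods
  quiet <- !(abs(sp$ppm - 0.00) < 0.3 | abs(sp$ppm - 6.01) < 0.15 |
               abs(sp$ppm - 4.79) < 0.5)
  expect_lt(max(abs(y[quiet])), 0.005 * ma_height)
  # and no metabolite region in the upfield half carries signal
  ints <- integrate_regions(sp, .tab)
  ma <- ma_integral(sp, attr(.tab, "ma_window"))
  mid <- .tab$ppm_end > 0.8 & .tab$ppm_start < 3.0
  expect_lt(max(abs(ints[mid])), 0.02 * ma)
})

test_that("region integrals are linear in concentration (noise off)", {
  i1 <- simulate_integrals(one_met_spec("glucose", 2500), .lib,
                           binding_model(), acquisition_params(), .tab)
  i2 <- simulate_integrals(one_met_spec("glucose", 5000), .lib,
                           binding_model(), acquisition_params(), .tab)
  nz <- which(i1$integrals > 1e-6)
  expect_gt(length(nz), 5)
  expect_equal(i2$integrals[nz] / i1$integrals[nz], rep(2, length(nz)),
               tolerance = 1e-9)

  # same doubling through the full spectral chain for one region
  f1 <- simulate_spectrum(one_met_spec("alanine", 250), .lib,
                          acq = .acq_small)
  f2 <- simulate_spectrum(one_met_spec("alanine", 500), .lib,
                          acq = .acq_small)
  v1 <- integrate_regions(process_spectrum(f1, phase = "none",
                                           baseline = FALSE,
                                           calibrate = FALSE), .tab)["VAR211"]
  v2 <- integrate_regions(process_spectrum(f2, phase = "none",
                                           baseline = FALSE,
                                           calibrate = FALSE), .tab)["VAR211"]
  expect_equal(unname(v2 / v1), 2, tolerance = 1e-3)
})

test_that("cohort generation is deterministic and honours group sizes", {
  cs <- cohort_spec(n_cancer = 3, n_control = 2, seed = 11L)
  a <- generate_cohort(cs, .lib, acq = .acq_small)
  b <- generate_cohort(cs, .lib, acq = .acq_small)
  expect_equal(a$samples, b$samples)
  expect_identical(a$fids[[1]]$signal, b$fids[[1]]$signal)
  expect_equal(table(a$samples$group)[["cancer"]], 3)
  expect_equal(table(a$samples$group)[["control"]], 2)

  # default cohort sizes reproduce the training design
  cs_def <- cohort_spec()
  expect_equal(cs_def$n_cancer, 80L)
  expect_equal(cs_def$n_control, 80L)
  expect_error(cohort_spec(n_cancer = 0), "n_cancer")
  expect_error(cohort_spec(effect_map = c(unobtainium = 2)),
               "not in the metabolite panel")
})

test_that("planted glucose effect is recovered by Monte Carlo", {
  cs <- cohort_spec(effect_map = default_effect_map(up = 1.3),
                    between_subject_cv = 0.1, seed = 5150L)
  co <- generate_cohort(cs, .lib, regions = .tab, output = "integrals")
  glu <- intersect(regions_for(.tab, "glucose"), 73:76)
  v <- rowSums(co$integrals[, sprintf("VAR%03d", glu), drop = FALSE])
  ratio <- mean(v[co$samples$group == "cancer"]) /
    mean(v[co$samples$group == "control"])
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.4)
})

test_that("technical replicates share composition but not noise", {
  pool <- sample_spec(noise_sd = 0.004)
  reps <- generate_replicates(3, pool, .lib, acq = .acq_small)
  expect_length(reps, 3)
  expect_false(identical(reps[[1]]$signal, reps[[2]]$signal))

  pool0 <- sample_spec(noise_sd = 0)
  reps0 <- generate_replicates(2, pool0, .lib, acq = .acq_small)
  i1 <- integrate_regions(process_spectrum(reps0[[1]], phase = "none",
                                           calibrate = FALSE), .tab)
  i2 <- integrate_regions(process_spectrum(reps0[[2]], phase = "none",
                                           calibrate = FALSE), .tab)
  expect_identical(i1, i2)
  expect_error(generate_replicates(1), "n >= 2")
})

test_that("a too-narrow spectral width is rejected", {
  acq_bad <- acquisition_params(spectral_width = 3, n_points = 4096,
                                carrier_ppm = 4.79)
  expect_error(simulate_spectrum(one_met_spec("formate", 30), .lib,
                                 acq = acq_bad), "spectral width")
})
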