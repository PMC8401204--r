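#' Synthesize a CPMG plasma FID
#'
#' Builds the complex time-domain signal of one plasma sample as a sum of
#' exponentially decaying cosinusoids: every proton-group stick line of the
#' spin library at its fast-exchange shift and CPMG-attenuated amplitude, a
#' TSP singlet near 0 ppm, the maleic-acid standard singlet near 6.01 ppm, a
#' residual water hump, broad lipid resonances that survive T2 editing
#' partially, a heavily T2-attenuated macromolecule background, an optional
#' hemolysis background, polynomial baseline drift and seeded Gaussian
#' noise.
#'
#' @param spec a [sample_spec()].
#' @param library a [load_spin_library()] object.
#' @param binding a [binding_model()].
#' @param acq an [acquisition_params()].
#' @return an `nmr_fid` object (complex signal plus metadata).
#' @export
simulate_spectrum <- function(spec, library = load_spin_library(),
                              binding = binding_model(),
                              acq = acquisition_params()) {
  sw_hz <- acq$spectral_width * acq$spectrometer_freq
  dwell <- 1 / sw_hz
  n <- acq$n_points
  t <- (seq_len(n) - 1L) * dwell

  f_all <- sample_bound_fractions(spec, binding)
  t2_obs <- function(f) 1 / ((1 - f) / binding$t2_free + f / binding$t2_bound)
  att <- function(f) exp(-acq$cpmg_total_echo / t2_obs(f))

  # (shift ppm, amplitude, linewidth Hz) of every line
  ppm <- numeric(0)
  amp <- numeric(0)
  lw <- numeric(0)
  for (i in seq_len(nrow(library))) {
    met <- library$metabolite[i]
    conc <- spec$concentrations[[met]]
    if (is.null(conc) || is.na(conc) || conc == 0) next
    f <- lookup0(f_all, met)
    dsh <- lookup0(binding$bound_shift_delta, met)
    centre <- library$shift_ppm[i] + f * dsh
    a0 <- conc * anomer_population(library[i, ]) * att(f)
    if (library$multiplicity[i] == "m") {
      ppm <- c(ppm, centre)
      amp <- c(amp, a0 * library$n_protons[i])
      lw <- c(lw, 1 + 0.5 * 12)  # unresolved envelope
    } else {
      pat <- multiplet_pattern(library$multiplicity[i], library$j_hz[[i]],
                               library$n_protons[i])
      ppm <- c(ppm, centre + pat$offset_hz / acq$spectrometer_freq)
      amp <- c(amp, a0 * pat$intensity)
      lw <- c(lw, rep(1, nrow(pat)))
    }
  }
  # internal standards
  ma_d <- lookup0(binding$bound_shift_delta, ".ma")
  tsp_d <- lookup0(binding$bound_shift_delta, ".tsp")
  ppm <- c(ppm, 6.010 + f_all[[".ma"]] * ma_d,
           0.000 + f_all[[".tsp"]] * tsp_d)
  amp <- c(amp, spec$ma_conc * 2 * att(f_all[[".ma"]]),
           spec$tsp_conc * 1000 * 9 * att(f_all[[".tsp"]]))
  lw <- c(lw, 1, 1)
  # residual water (presaturated for 3 s, so largely suppressed)
  ppm <- c(ppm, 4.790)
  amp <- c(amp, 4e3)
  lw <- c(lw, 20)
  # broad components: lipids (partially T2-edited) and protein hump
  lip <- lipid_components()
  lip_att <- exp(-acq$cpmg_total_echo / lip$t2_ms)
  ppm <- c(ppm, lip$shift_ppm)
  amp <- c(amp, spec$lipid_scale * lip$rel_intensity * lip_att)
  lw <- c(lw, lip$width_hz)
  mm_att <- exp(-acq$cpmg_total_echo / 8)
  ppm <- c(ppm, c(0.90, 1.30, 2.05, 3.05))
  amp <- c(amp, spec$macromolecule_scale * c(4e4, 8e4, 3e4, 2e4) * mm_att)
  lw <- c(lw, c(250, 300, 250, 250))
  if (isTRUE(spec$hemolytic)) {
    ppm <- c(ppm, c(3.65, 0.92))
    amp <- c(amp, c(800, 500))
    lw <- c(lw, c(60, 60))
  }
  # axis mis-calibration applied at source
  ppm <- ppm + spec$ppm_offset

  keep <- amp > 0
  ppm <- ppm[keep]
  amp <- amp[keep]
  lw <- lw[keep]
  f_hz <- (ppm - acq$carrier_ppm) * acq$spectrometer_freq
  if (any(abs(f_hz) > sw_hz / 2))
    stop("spectral width too narrow: lines at ",
         paste(round(ppm[abs(f_hz) > sw_hz / 2], 3), collapse = ", "),
         " ppm fall outside the window")

  sig <- complex(real = rep(0, n), imaginary = rep(0, n))
  for (j in seq_along(ppm)) {
    sig <- sig + amp[j] * exp((2i * pi * f_hz[j] - pi * lw[j]) * t)
  }

  # polynomial baseline drift synthesised in the frequency domain
  if (any(spec$baseline_coeffs != 0)) {
    x <- seq(-1, 1, length.out = n)
    drift <- outer(x, seq_along(spec$baseline_coeffs) - 1, `^`) %*%
      spec$baseline_coeffs
    # spectrum-domain drift: order as unshifted FFT bins, then invert;
    # factor 2 compensates the first-point halving convention
    dr <- c(drift[(n / 2 + 1):n], drift[1:(n / 2)])
    sig <- sig + stats::fft(dr, inverse = TRUE) / n * 2
  }

  if (spec$noise_sd > 0) {
    withr_seed <- spec$seed %% .Machine$integer.max
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(withr_seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    sig <- sig + complex(real = stats::rnorm(n, 0, spec$noise_sd),
                         imaginary = stats::rnorm(n, 0, spec$noise_sd))
  }

  structure(list(signal = sig, acq = acq,
                 sample = list(group = spec$group_label,
                               hemolytic = spec$hemolytic,
                               ma_conc = spec$ma_conc,
                               tsp_conc = spec$tsp_conc,
                               seed = spec$seed),
                 provenance = list(list(step = "simulate",
                                        n_lines = length(ppm)))),
            class = "nmr_fid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nmr_fid <- function(x, ...) {
  cat("CPMG FID:", length(x$signal), "complex points,",
      x$acq$spectrometer_freq, "MHz, group:", x$sample$group, "\n")
  invisible(x)
}

#' Generate a two-group cohort
#'
#' Draws per-subject metabolite concentrations as population means times
#' the group effect times log-normal between-subject noise (mean
#' preserving), assigns hemolysis flags, and synthesizes one sample per
#' subject.  All randomness derives from the cohort seed, so a fixed seed
#' reproduces the cohort exactly.
#'
#' @param cohort a [cohort_spec()].
#' @param library,binding,acq forwarded to [simulate_spectrum()].
#' @param base_spec template [sample_spec()] providing standards, albumin
#'   level and noise settings.
#' @param output `"fid"` for full time-domain samples or `"integrals"` for
#'   the fast analytic region-integral path (identical signal model without
#'   the lineshape synthesis; used for statistically heavy studies).
#' @param regions required for `output = "integrals"`.
#' @return list with `samples` (metadata data frame) and either `fids`
#'   (list of `nmr_fid`) or `integrals` (samples x 237 matrix) plus
#'   `ma_integrals`.
#' @export
generate_cohort <- function(cohort, library = load_spin_library(),
                            binding = binding_model(),
                            acq = acquisition_params(),
                            base_spec = sample_spec(),
                            output = c("fid", "integrals"),
                            regions = NULL) {
  output <- match.arg(output)
  if (output == "integrals" && is.null(regions))
    stop("regions are required for the integral output path")
  n <- cohort$n_cancer + cohort$n_control
  groups <- rep(c("control", "cancer"), c(cohort$n_control, cohort$n_cancer))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(cohort$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  seeds <- sample.int(.Machine$integer.max - 1L, n)
  hemo <- stats::runif(n) < cohort$hemolysis_rate
  base_conc <- base_spec$concentrations
  cv <- cohort$between_subject_cv
  sdlog <- sqrt(log(1 + cv^2))
  sdlog_lip <- sqrt(log(1 + cohort$lipid_cv^2))
  subj_mult <- matrix(stats::rlnorm(n * length(base_conc),
                                    meanlog = -sdlog^2 / 2, sdlog = sdlog),
                      nrow = n)
  lip_mult <- stats::rlnorm(n, -sdlog_lip^2 / 2, sdlog_lip)

  eff <- cohort$effect_map
  met_eff <- rep(1, length(base_conc))
  names(met_eff) <- names(base_conc)
  ek <- intersect(names(eff), names(base_conc))
  met_eff[ek] <- eff[ek]
  lip_eff <- if (".lipid" %in% names(eff)) eff[[".lipid"]] else 1

  meta <- data.frame(
    sample_id = sprintf("%s_%03d", cohort$cohort_label, seq_len(n)),
    group = groups, cohort = cohort$cohort_label,
    hemolytic = hemo, seed = seeds, stringsAsFactors = FALSE
  )

  specs <- vector("list", n)
  for (i in seq_len(n)) {
    conc <- base_conc * subj_mult[i, ]
    lsc <- base_spec$lipid_scale * lip_mult[i]
    if (groups[i] == "cancer") {
      conc <- conc * met_eff
      lsc <- lsc * lip_eff
    }
    specs[[i]] <- sample_spec(concentrations = conc,
                              tsp_conc = base_spec$tsp_conc,
                              ma_conc = base_spec$ma_conc,
                              hsa_conc = base_spec$hsa_conc,
                              group_label = groups[i], hemolytic = hemo[i],
                              noise_sd = base_spec$noise_sd,
                              lipid_scale = lsc,
                              macromolecule_scale = base_spec$macromolecule_scale,
                              baseline_coeffs = base_spec$baseline_coeffs,
                              seed = seeds[i])
  }

  if (output == "fid") {
    fids <- lapply(specs, simulate_spectrum, library = library,
                   binding = binding, acq = acq)
    list(samples = meta, fids = fids)
  } else {
    lines <- library_lines(library)
    sims <- lapply(specs, simulate_integrals, library = library,
                   binding = binding, acq = acq, regions = regions,
                   lines = lines)
    ints <- t(vapply(sims, `[[`, numeric(237), "integrals"))
    colnames(ints) <- sprintf("VAR%03d", 1:237)
    mas <- vapply(sims, `[[`, numeric(1), "ma_integral")
    list(samples = meta, integrals = ints, ma_integrals = mas)
  }
}

#' Technical replicates of a pooled sample
#'
#' Identical composition, independent technical noise realisations.
#'
#' @param n number of replicates (the robustness protocol uses 12).
#' @param pool_spec the shared [sample_spec()].
#' @param library,binding,acq forwarded to [simulate_spectrum()].
#' @param seed master seed for the replicate noise seeds.
#' @return list of `nmr_fid`.
#' @export
generate_replicates <- function(n = 12, pool_spec = sample_spec(),
                                library = load_spin_library(),
                                binding = binding_model(),
                                acq = acquisition_params(),
                                seed = 424242L) {
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seeds, function(s) {
    sp <- pool_spec
    sp$seed <- s
    sp$group_label <- "pool"
    simulate_spectrum(sp, library, binding, acq)
  })
}

#' Precompute the stick pattern of every library row
#'
#' @param library a spin library.
#' @return list of data frames (columns `offset_hz`, `intensity`), one per
#'   row; unresolved multiplets are a single stick.
#' @export
library_lines <- function(library) {
  lapply(seq_len(nrow(library)), function(i) {
    if (library$multiplicity[i] == "m")
      data.frame(offset_hz = 0, intensity = library$n_protons[i])
    else
      multiplet_pattern(library$multiplicity[i], library$j_hz[[i]],
                        library$n_protons[i])
  })
}

#' Analytic region integrals of a sample (fast path)
#'
#' Computes the same signal model as [simulate_spectrum()] directly at the
#' region-integral level: narrow metabolite stick lines deposit their full
#' intensity into the region containing them; broad lipid / background
#' Lorentzians are allocated by their closed-form area fraction per region;
#' seeded Gaussian noise is added with the standard deviation that
#' time-domain noise of `noise_sd` would produce on an integral of that
#' width after the standard processing chain.
#'
#' @param spec a [sample_spec()].
#' @param library,binding,acq as in [simulate_spectrum()].
#' @param regions a [build_region_table()] table.
#' @param lines optional [library_lines()] cache.
#' @return list with `integrals` (length 237) and `ma_integral`.
#' @export
simulate_integrals <- function(spec, library, binding, acq, regions,
                               lines = library_lines(library)) {
  f_all <- sample_bound_fractions(spec, binding)
  t2_obs <- function(f) 1 / ((1 - f) / binding$t2_free + f / binding$t2_bound)
  att <- function(f) exp(-acq$cpmg_total_echo / t2_obs(f))
  # intensity-to-area scale of the spectral path (area = amp * sw / 2 with
  # the half-first-point convention)
  scale <- acq$spectral_width / 2

  ints <- numeric(237)
  lo <- regions$ppm_end
  hi <- regions$ppm_start

  deposit_stick <- function(p, a) {
    hit <- which(p >= lo & p < hi)
    if (length(hit)) ints[hit] <<- ints[hit] + a * scale
  }
  deposit_broad <- function(centre, a, width_hz) {
    hw <- width_hz / 2 / acq$spectrometer_freq   # HWHM in ppm
    frac <- (atan((hi - centre) / hw) - atan((lo - centre) / hw)) / pi
    ints <<- ints + a * scale * frac
  }

  for (i in seq_len(nrow(library))) {
    met <- library$metabolite[i]
    conc <- spec$concentrations[[met]]
    if (is.null(conc) || is.na(conc) || conc == 0) next
    f <- lookup0(f_all, met)
    dsh <- lookup0(binding$bound_shift_delta, met)
    centre <- library$shift_ppm[i] + f * dsh + spec$ppm_offset
    a0 <- conc * anomer_population(library[i, ]) * att(f)
    if (library$multiplicity[i] == "m") {
      deposit_broad(centre, a0 * library$n_protons[i], 12)
    } else {
      pat <- lines[[i]]
      for (j in seq_len(nrow(pat)))
        deposit_stick(centre + pat$offset_hz[j] / acq$spectrometer_freq,
                      a0 * pat$intensity[j])
    }
  }
  lip <- lipid_components()
  lip_att <- exp(-acq$cpmg_total_echo / lip$t2_ms)
  for (j in seq_len(nrow(lip)))
    deposit_broad(lip$shift_ppm[j] + spec$ppm_offset,
                  spec$lipid_scale * lip$rel_intensity[j] * lip_att[j],
                  lip$width_hz[j])
  mm_att <- exp(-acq$cpmg_total_echo / 8)
  mm_p <- c(0.90, 1.30, 2.05, 3.05)
  mm_a <- spec$macromolecule_scale * c(4e4, 8e4, 3e4, 2e4) * mm_att
  for (j in seq_along(mm_p))
    deposit_broad(mm_p[j] + spec$ppm_offset, mm_a[j], 250)
  if (isTRUE(spec$hemolytic)) {
    deposit_broad(3.65 + spec$ppm_offset, 800, 60)
    deposit_broad(0.92 + spec$ppm_offset, 500, 60)
  }

  ma_int <- spec$ma_conc * 2 * att(f_all[[".ma"]]) * scale

  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(spec$seed %% .Machine$integer.max)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    sd_int <- integral_noise_sd(spec$noise_sd, hi - lo, acq)
    ints <- ints + stats::rnorm(237, 0, sd_int)
    maw <- attr(regions, "ma_window") %||% c(5.98, 6.04)
    ma_int <- ma_int + stats::rnorm(1, 0, integral_noise_sd(
      spec$noise_sd, diff(maw), acq))
  }
  list(integrals = ints, ma_integral = ma_int)
}

#' Standard deviation of a region integral induced by time-domain noise
#'
#' For complex white noise of standard deviation `sd` per point, the
#' processed spectrum (exponential apodization, zero filling, FFT) carries
#' per-point noise `sd * sqrt(sum(w^2))` with `w` the apodization window;
#' a trapezoidal integral over a window of `width` ppm then has standard
#' deviation `sd * sqrt(sum(w^2)) * sqrt(width * spectral_width / n_points)`.
#' @noRd
integral_noise_sd <- function(sd, width_ppm, acq) {
  t <- (seq_len(acq$n_points) - 1L) /
    (acq$spectral_width * acq$spectrometer_freq)
  w2 <- sum(exp(-2 * pi * acq$line_broadening * t))
  sd * sqrt(w2) * sqrt(width_ppm * acq$spectral_width / acq$n_points)
}
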