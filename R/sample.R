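#' Acquisition and processing parameters
#'
#' Defaults mirror a routine 600 MHz CPMG plasma experiment: 12 ppm
#' spectral width digitised into 16k complex points (2.276 s acquisition),
#' a 64 ms total spin-echo time built from 160 loops of 0.4 ms, 0.8 Hz
#' exponential line broadening and zero filling by a factor of four to 64k
#' points.
#'
#' @param spectrometer_freq proton frequency, MHz.
#' @param spectral_width ppm.
#' @param n_points complex time-domain points acquired.
#' @param cpmg_total_echo total spin-echo time, ms.
#' @param cpmg_echo_delay single echo delay, ms.
#' @param cpmg_loops number of echo loops.
#' @param line_broadening exponential apodization, Hz.
#' @param zero_fill_factor integer zero-filling factor.
#' @param carrier_ppm transmitter position (on the water resonance).
#' @param temperature_label free-text temperature annotation.
#' @return an `acquisition_params` object.
#' @export
acquisition_params <- function(spectrometer_freq = 600, spectral_width = 12,
                               n_points = 16384, cpmg_total_echo = 64,
                               cpmg_echo_delay = 0.4, cpmg_loops = 160,
                               line_broadening = 0.8, zero_fill_factor = 4,
                               carrier_ppm = 4.79,
                               temperature_label = "25 C") {
  if (abs(cpmg_loops * cpmg_echo_delay - cpmg_total_echo) > 1e-9)
    stop("cpmg_loops x cpmg_echo_delay must equal cpmg_total_echo")
  stopifnot(spectrometer_freq > 0, spectral_width > 0, n_points >= 2,
            line_broadening >= 0, zero_fill_factor >= 1)
  structure(list(spectrometer_freq = spectrometer_freq,
                 spectral_width = spectral_width,
                 n_points = as.integer(n_points),
                 cpmg_total_echo = cpmg_total_echo,
                 cpmg_echo_delay = cpmg_echo_delay,
                 cpmg_loops = as.integer(cpmg_loops),
                 line_broadening = line_broadening,
                 zero_fill_factor = as.integer(zero_fill_factor),
                 carrier_ppm = carrier_ppm,
                 temperature_label = temperature_label),
            class = "acquisition_params")
}

#' Typical fasting plasma concentrations (uM) for the 62 library metabolites
#'
#' Population means used as the baseline of the cohort simulator; values are
#' representative adult fasting plasma levels.
#' @return named numeric vector, uM.
#' @export
default_plasma_concentrations <- function() {
  c("1-methylhistidine" = 5, "2-aminobutyrate" = 20, "2-hydroxybutyrate" = 40,
    "2-hydroxy-3-methylbutyrate" = 10, "3-hydroxy-3-methylbutyrate" = 5,
    "3-methyl-2-oxobutyrate" = 15, "3-methyl-2-oxovalerate" = 10,
    "3-methylhistidine" = 5, "4-aminobutyrate" = 2,
    "4-methyl-2-oxovalerate" = 15, "alpha-ketoglutarate" = 10,
    "acetate" = 50, "acetoacetate" = 30, "alanine" = 400, "allantoin" = 3,
    "arginine" = 90, "asparagine" = 50, "aspartate" = 10, "beta-alanine" = 5,
    "beta-hydroxybutyrate" = 60, "betaine" = 40, "carnitine" = 40,
    "choline" = 10, "citrate" = 110, "creatine" = 35, "creatinine" = 75,
    "cysteine" = 30, "cystine" = 50, "formate" = 25, "fumarate" = 2,
    "glucose" = 5000, "glutamate" = 60, "glutamine" = 550, "glycerol" = 80,
    "glycine" = 250, "histidine" = 80, "hydroxyproline" = 12,
    "hypoxanthine" = 3, "isoleucine" = 60, "isopropanol" = 5,
    "lactate" = 1500, "leucine" = 120, "lysine" = 180, "mannose" = 50,
    "methionine" = 25, "myo-inositol" = 30, "N-acetylcysteine" = 2,
    "ornithine" = 60, "oxaloacetate" = 5, "phenylalanine" = 60,
    "proline" = 180, "pyroglutamate" = 30, "pyruvate" = 60, "sarcosine" = 2,
    "serine" = 110, "succinate" = 10, "taurine" = 60, "threonine" = 130,
    "tryptophan" = 55, "tyrosine" = 60, "uridine" = 4, "valine" = 230)
}

#' Broad lipid / lipoprotein components of the plasma background
#'
#' Centre, linewidth, relative intensity and transverse relaxation of the
#' broad fatty-acid-chain (FAC), phosphatidylcholine / sphingomyelin
#' headgroup and glyceryl resonances that survive CPMG editing partially.
#' `scale` multiplies the whole profile and is the quantity the cohort
#' effect map perturbs.
#' @return data frame of lipid components.
#' @export
lipid_components <- function() {
  data.frame(
    component = c("fac_ch3", "fac_ch2", "fac_ch2co_b", "fac_allylic",
                  "fac_ch2co", "fac_diallylic", "pc_headgroup",
                  "glyceryl", "olefinic"),
    shift_ppm = c(0.880, 1.295, 1.570, 2.020, 2.240, 2.770, 3.220,
                  4.100, 5.320),
    width_hz = c(18, 22, 20, 20, 20, 20, 14, 20, 22),
    rel_intensity = c(900, 2200, 300, 400, 250, 150, 450, 120, 300),
    t2_ms = c(90, 80, 70, 70, 70, 70, 120, 60, 70),
    stringsAsFactors = FALSE
  )
}

#' Specification of one NMR sample
#'
#' @param concentrations named uM vector of metabolite totals.
#' @param tsp_conc TSP concentration, mM (4 mM in the standard protocol).
#' @param ma_conc maleic-acid standard concentration, uM.
#' @param hsa_conc albumin site concentration, uM.
#' @param group_label `"control"`, `"cancer"` or `"pool"`.
#' @param hemolytic logical hemolysis flag.
#' @param noise_sd time-domain noise standard deviation (intensity units);
#'   the default is calibrated so that replicate MA-region integrals show a
#'   relative standard deviation near 2 percent.
#' @param lipid_scale multiplier on the [lipid_components()] profile.
#' @param macromolecule_scale multiplier on the residual protein hump.
#' @param baseline_coeffs polynomial drift coefficients (intensity units,
#'   constant first), evaluated on a -1..1 ppm-normalised axis.
#' @param ppm_offset rigid mis-calibration of the ppm axis applied to the
#'   simulated spectrum (used to exercise shift calibration).
#' @param seed integer seed for this sample's noise realisation.
#' @return a `sample_spec` object.
#' @export
sample_spec <- function(concentrations = default_plasma_concentrations(),
                        tsp_conc = 4, ma_conc = 53.85, hsa_conc = 600,
                        group_label = c("pool", "control", "cancer"),
                        hemolytic = FALSE, noise_sd = 0.004,
                        lipid_scale = 1, macromolecule_scale = 1,
                        baseline_coeffs = c(0, 0, 0), ppm_offset = 0,
                        seed = 1L) {
  group_label <- match.arg(group_label)
  stopifnot(all(concentrations >= 0), ma_conc > 0, tsp_conc >= 0,
            hsa_conc >= 0, noise_sd >= 0)
  structure(list(concentrations = concentrations, tsp_conc = tsp_conc,
                 ma_conc = ma_conc, hsa_conc = hsa_conc,
                 group_label = group_label, hemolytic = hemolytic,
                 noise_sd = noise_sd, lipid_scale = lipid_scale,
                 macromolecule_scale = macromolecule_scale,
                 baseline_coeffs = baseline_coeffs,
                 ppm_offset = ppm_offset, seed = as.integer(seed)),
            class = "sample_spec")
}

#' Default two-group effect map
#'
#' Multiplicative concentration effects applied to the cancer group:
#' glucose, isoleucine, leucine, glycerol and isopropanol are elevated and
#' the broad lipid profile is reduced.
#'
#' @param up effect applied to the elevated metabolites.
#' @param down effect applied to the lipid profile.
#' @return named numeric vector; the special key `.lipid` scales the
#'   [lipid_components()] profile.
#' @export
default_effect_map <- function(up = 1.3, down = 0.75) {
  c("glucose" = up, "isoleucine" = up, "leucine" = up, "glycerol" = up,
    "isopropanol" = up, ".lipid" = down)
}

#' Specification of a two-group cohort
#'
#' @param n_cancer,n_control group sizes (80 + 80 in the default training
#'   cohort; 34 + 38 in the validation cohort).
#' @param effect_map named multiplicative effects for the cancer group;
#'   keys are metabolite names or `.lipid` (see [default_effect_map()]).
#' @param between_subject_cv log-normal between-subject coefficient of
#'   variation of each metabolite concentration.
#' @param lipid_cv between-subject CV of the lipid profile scale.
#' @param hemolysis_rate fraction of subjects flagged hemolytic.
#' @param cohort_label annotation stored in the sample metadata.
#' @param seed integer master seed; every sample's randomness derives from
#'   it.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_cancer = 80, n_control = 80,
                        effect_map = default_effect_map(),
                        between_subject_cv = 0.1, lipid_cv = 0.25,
                        hemolysis_rate = 0, cohort_label = "training",
                        seed = 20210812L) {
  stopifnot(n_cancer >= 1, n_control >= 1, between_subject_cv >= 0,
            hemolysis_rate >= 0, hemolysis_rate <= 1)
  known <- c(names(default_plasma_concentrations()), ".lipid")
  bad <- setdiff(names(effect_map), known)
  if (length(bad))
    stop("effect map keys not in the metabolite panel: ",
         paste(bad, collapse = ", "))
  structure(list(n_cancer = as.integer(n_cancer),
                 n_control = as.integer(n_control),
                 effect_map = effect_map,
                 between_subject_cv = between_subject_cv,
                 lipid_cv = lipid_cv,
                 hemolysis_rate = hemolysis_rate,
                 cohort_label = cohort_label, seed = as.integer(seed)),
            class = "cohort_spec")
}
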