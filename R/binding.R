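#' Safe named lookup returning 0 for absent names
#' @noRd
lookup0 <- function(v, nm) {
  x <- v[nm]
  if (length(x) != 1 || is.na(x)) 0 else unname(x)
}

#' Default albumin dissociation constants (uM) for the binder metabolites
#'
#' TSP is the strongest competitor by far; maleic acid binds weakly; the
#' eight binder metabolites fall in between.  Affinities are only known
#' ordinally, so representative values are used (see the methods vignette).
#' @noRd
.default_kd <- c(
  "acetate" = 1200, "acetoacetate" = 1500, "lactate" = 900,
  "oxaloacetate" = 1300, "phenylalanine" = 700, "pyruvate" = 1000,
  "3-methyl-2-oxobutyrate" = 900, "beta-hydroxybutyrate" = 800
)

#' Bound-state chemical-shift offsets (ppm), fast-exchange averaged
#' @noRd
.default_dshift <- c(
  "acetate" = 0.010, "acetoacetate" = 0.012, "lactate" = 0.010,
  "oxaloacetate" = 0.010, "phenylalanine" = 0.015, "pyruvate" = 0.010,
  "3-methyl-2-oxobutyrate" = 0.012, "beta-hydroxybutyrate" = 0.010,
  ".ma" = 0.020, ".tsp" = 0.010
)

#' Competitive albumin-binding model
#'
#' Describes a single class of HSA binding sites for which TSP, maleic acid
#' and a subset of metabolites compete.  All ligands exchange fast on the
#' NMR timescale, so each species shows one population-averaged line whose
#' position and transverse relaxation rate interpolate between the free and
#' bound states.
#'
#' @param hsa_conc albumin site concentration, uM.
#' @param kd_tsp,kd_ma dissociation constants of TSP and maleic acid, uM.
#' @param kd_per_metabolite named uM vector; metabolites absent from it do
#'   not bind (Kd = Inf).
#' @param t2_free,t2_bound transverse relaxation times (ms) of free and
#'   albumin-bound small molecules.
#' @param bound_shift_delta named ppm vector of bound-state shift offsets
#'   (`.ma` and `.tsp` name the standards).
#' @return a `binding_model` object.
#' @export
binding_model <- function(hsa_conc = 600, kd_tsp = 5, kd_ma = 2000,
                          kd_per_metabolite = .default_kd,
                          t2_free = 2000, t2_bound = 10,
                          bound_shift_delta = .default_dshift) {
  stopifnot(hsa_conc >= 0, kd_tsp > 0, kd_ma > 0,
            t2_free > 0, t2_bound > 0)
  if (kd_tsp >= kd_ma || any(kd_tsp >= kd_per_metabolite))
    stop("TSP must be the strongest competitor (kd_tsp below every other Kd)")
  structure(list(hsa_conc = hsa_conc, kd_tsp = kd_tsp, kd_ma = kd_ma,
                 kd_per_metabolite = kd_per_metabolite,
                 t2_free = t2_free, t2_bound = t2_bound,
                 bound_shift_delta = bound_shift_delta),
            class = "binding_model")
}

#' Free albumin concentration under multi-ligand competition
#'
#' Solves the single-site-class mass balance
#' `P_free + sum_i L_i * P_free / (Kd_i + P_free) = P_total`
#' for the free protein concentration, with each ligand at total
#' concentration `L_i`.  The left side is strictly increasing in `P_free`,
#' so the root is unique; it is bracketed on `[0, P_total]` and refined to
#' a relative tolerance of 1e-12.
#'
#' @param ligand_totals numeric vector of total ligand concentrations (uM).
#' @param kds matching dissociation constants (uM; `Inf` for non-binders).
#' @param hsa_conc total protein site concentration (uM).
#' @return free protein concentration (uM).
#' @export
free_hsa <- function(ligand_totals, kds, hsa_conc) {
  stopifnot(length(ligand_totals) == length(kds),
            all(ligand_totals >= 0), all(kds > 0), hsa_conc >= 0)
  if (hsa_conc == 0) return(0)
  use <- is.finite(kds) & ligand_totals > 0
  L <- ligand_totals[use]
  K <- kds[use]
  f <- function(p) p + sum(L * p / (K + p)) - hsa_conc
  if (!length(L)) return(hsa_conc)
  r <- stats::uniroot(f, c(0, hsa_conc), tol = 1e-12 * max(hsa_conc, 1))
  if (abs(f(r$root)) > 1e-6 * max(hsa_conc, 1))
    stop("free-protein solve did not converge; residual ", f(r$root))
  r$root
}

#' Bound fraction of a metabolite competing with TSP for albumin
#'
#' Two-ligand special case of the competitive equilibrium: the metabolite
#' and TSP compete for a single class of HSA sites.  The returned fraction
#' is `P_free / (Kd_met + P_free)` at the solved free-protein concentration.
#'
#' @param met_conc metabolite total concentration (uM).
#' @param kd_met metabolite dissociation constant (uM; `Inf` = non-binder).
#' @param tsp_conc TSP total concentration (uM).
#' @param hsa_conc albumin site concentration (uM).
#' @param kd_tsp TSP dissociation constant (uM).
#' @return bound fraction in `[0, 1]`.
#' @examples
#' bound_fraction(100, 50, 0, 600, 20)       # no competitor: mostly bound
#' bound_fraction(100, 50, 4000, 600, 20)    # 4 mM TSP: displaced
#' @export
bound_fraction <- function(met_conc, kd_met, tsp_conc, hsa_conc, kd_tsp) {
  stopifnot(met_conc >= 0, tsp_conc >= 0, hsa_conc >= 0,
            kd_met > 0, kd_tsp > 0)
  if (!is.finite(kd_met)) return(0)
  p <- free_hsa(c(met_conc, tsp_conc), c(kd_met, kd_tsp), hsa_conc)
  p / (kd_met + p)
}

#' Fast-exchange observed shift and CPMG-attenuated amplitude
#'
#' Under fast exchange the observed line of a partially bound species sits
#' at the population-weighted shift and relaxes at the population-weighted
#' rate: `delta_obs = delta_free + f * ddelta_bound` and
#' `1/T2_obs = (1 - f)/T2_free + f/T2_bound`.  A CPMG echo train of total
#' duration TE then attenuates the line by `exp(-TE / T2_obs)`.
#'
#' @param group one row of a [load_spin_library()] data frame.
#' @param spec a [sample_spec()].
#' @param binding a [binding_model()].
#' @param acq an [acquisition_params()].
#' @return list with `shift_ppm` (effective centre) and `amplitude`
#'   (concentration x proton count x anomer population x CPMG attenuation).
#' @export
observed_signal <- function(group, spec, binding, acq) {
  met <- group$metabolite
  conc <- spec$concentrations[[met]]
  if (is.null(conc) || is.na(conc)) conc <- 0
  f <- lookup0(sample_bound_fractions(spec, binding), met)
  t2_obs <- 1 / ((1 - f) / binding$t2_free + f / binding$t2_bound)
  dsh <- lookup0(binding$bound_shift_delta, met)
  frac <- anomer_population(group)
  list(shift_ppm = group$shift_ppm + f * dsh,
       amplitude = conc * group$n_protons * frac *
         exp(-acq$cpmg_total_echo / t2_obs))
}

#' @noRd
anomer_population <- function(group) {
  if (is.na(group$anomer)) return(1)
  fr <- .anomer_fraction[[group$metabolite]]
  if (is.null(fr)) 1 else unname(fr[[group$anomer]])
}

#' Bound fractions of every species in a sample
#'
#' Solves the joint competition of TSP, maleic acid and all binder
#' metabolites present in the sample for the albumin pool, and returns the
#' per-species bound fractions (including `.tsp` and `.ma`).
#'
#' @param spec a [sample_spec()].
#' @param binding a [binding_model()].
#' @return named numeric vector of bound fractions.
#' @export
sample_bound_fractions <- function(spec, binding) {
  mets <- names(spec$concentrations)
  kds <- rep(Inf, length(mets))
  names(kds) <- mets
  known <- intersect(mets, names(binding$kd_per_metabolite))
  kds[known] <- binding$kd_per_metabolite[known]
  totals <- c(spec$concentrations, .tsp = spec$tsp_conc * 1000,
              .ma = spec$ma_conc)
  all_kds <- c(kds, .tsp = binding$kd_tsp, .ma = binding$kd_ma)
  p <- free_hsa(unname(totals), unname(all_kds), spec$hsa_conc)
  out <- p / (all_kds + p)
  out[!is.finite(all_kds)] <- 0
  out
}
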