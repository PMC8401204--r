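#' Trapezoidal integral of a spectrum over an arbitrary ppm window
#' @noRd
window_integral <- function(spectrum, lo, hi) {
  x <- rev(spectrum$ppm)              # ascending
  v <- rev(Re(spectrum$intensity))
  n <- length(x)
  if (lo < x[1] || hi > x[n]) stop("window outside the spectral width")
  # cumulative trapezoid, interpolated at the window edges
  ct <- c(0, cumsum((v[-1] + v[-n]) / 2 * diff(x)))
  at <- function(q) stats::approx(x, ct, xout = q)$y
  at(hi) - at(lo)
}

#' Integrate the 237 fixed regions
#'
#' Trapezoidal area of the real spectrum over each half-open region
#' `[ppm_end, ppm_start)`, returned in `var_id` order.
#'
#' @param spectrum a calibrated `nmr_spectrum`.
#' @param regions a [build_region_table()] table.
#' @return named numeric vector of 237 integrals (`VAR001` ...).
#' @export
integrate_regions <- function(spectrum, regions) {
  x <- rev(spectrum$ppm)
  v <- rev(Re(spectrum$intensity))
  n <- length(x)
  if (min(regions$ppm_end) < x[1] || max(regions$ppm_start) > x[n])
    stop("region outside the spectral width")
  ct <- c(0, cumsum((v[-1] + v[-n]) / 2 * diff(x)))
  lo <- stats::approx(x, ct, xout = regions$ppm_end)$y
  hi <- stats::approx(x, ct, xout = regions$ppm_start)$y
  out <- hi - lo
  names(out) <- sprintf("VAR%03d", regions$var_id)
  out
}

#' Integral of the maleic-acid standard window
#'
#' @param spectrum a calibrated `nmr_spectrum`.
#' @param ma_window ppm pair; defaults to the region table's MA window.
#' @return numeric MA integral.
#' @export
ma_integral <- function(spectrum, ma_window = c(5.98, 6.04)) {
  window_integral(spectrum, ma_window[1], ma_window[2])
}

#' Normalize region integrals to the internal standard
#'
#' @param integrals numeric vector of region integrals.
#' @param ma numeric MA-window integral; must be positive.
#' @return `integrals / ma`.
#' @export
normalize_to_ma <- function(integrals, ma) {
  if (!is.finite(ma) || ma <= 0) stop("internal standard missing")
  integrals / ma
}

#' Ordinary least-squares calibration line
#'
#' @param points data frame or matrix with concentration (uM) in the first
#'   column and integral in the second, or a two-column list.
#' @return a `calibration_fit` with slope, intercept, `r_squared` and the
#'   points.
#' @export
fit_calibration_curve <- function(points) {
  pts <- as.data.frame(points)
  names(pts)[1:2] <- c("conc", "integral")
  if (nrow(pts) < 3) stop("at least 3 calibration points required")
  if (length(unique(pts$conc)) < 2)
    stop("degenerate design: all concentrations equal")
  fit <- stats::lm(integral ~ conc, data = pts)
  ss_tot <- sum((pts$integral - mean(pts$integral))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = pts),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: integral = %.5g x conc + %.5g (R^2 = %.5f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Percent relative standard deviation
#'
#' `100 * sd(values) / mean(values)` (sample standard deviation).
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return %RSD.
#' @examples
#' percent_rsd(c(9, 10, 11))  # 10
#' @export
percent_rsd <- function(values) {
  if (length(values) < 2) stop("at least two values required")
  m <- mean(values)
  if (m == 0) stop("zero mean: %RSD undefined")
  100 * stats::sd(values) / m
}

#' Assemble a feature matrix
#'
#' @param values samples x 237 matrix of region integrals (MA-normalized or
#'   raw).
#' @param sample_meta data frame with at least `sample_id` and `group`.
#' @param regions the region table the columns refer to.
#' @param normalization `"raw"` or `"ma_normalized"`.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, sample_meta, regions,
                           normalization = c("ma_normalized", "raw")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("VAR%03d", seq_len(ncol(values)))
  stopifnot(nrow(values) == nrow(sample_meta))
  structure(list(values = values, sample_meta = sample_meta,
                 regions = regions, normalization = normalization),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "samples x", ncol(x$values),
      "regions (", x$normalization, ")\n")
  if ("group" %in% names(x$sample_meta))
    print(table(x$sample_meta$group))
  invisible(x)
}

#' QC filter configuration
#'
#' @param intrasample_rsd_max replicate %RSD threshold (default 10).
#' @param intersample_rsd_max cohort %RSD threshold (default 30).
#' @param require_both_groups remove on intersample variability only when
#'   both groups exceed the threshold.
#' @return a `qc_config`.
#' @export
qc_config <- function(intrasample_rsd_max = 10, intersample_rsd_max = 30,
                      require_both_groups = TRUE) {
  stopifnot(intrasample_rsd_max > 0, intersample_rsd_max > 0)
  structure(list(intrasample_rsd_max = intrasample_rsd_max,
                 intersample_rsd_max = intersample_rsd_max,
                 require_both_groups = require_both_groups),
            class = "qc_config")
}

#' Apply the replicate and cohort %RSD quality filters
#'
#' Removes variables whose replicate (intrasample) %RSD exceeds the first
#' threshold, and variables whose per-group (intersample) %RSD exceeds the
#' second threshold in both groups (or any group when
#' `require_both_groups = FALSE`).  With `mode = "packaged"` the packaged
#' exclusion lists of the region table's `qc_class` column are applied
#' instead of recomputing; this reproduces the published 237 -> 221 flow.
#'
#' @param matrix a [feature_matrix()] of cohort samples.
#' @param replicates a [feature_matrix()] of pool replicates (ignored in
#'   packaged mode).
#' @param qc a [qc_config()].
#' @param mode `"computed"` or `"packaged"`.
#' @return list with `filtered` (feature matrix), `report` (data frame of
#'   removed var ids, reasons and %RSD values) and `kept` (var ids).
#' @export
apply_qc_filters <- function(matrix, replicates = NULL, qc = qc_config(),
                             mode = c("computed", "packaged")) {
  mode <- match.arg(mode)
  vars <- colnames(matrix$values)
  var_ids <- as.integer(sub("VAR", "", vars))
  if (mode == "packaged") {
    qcc <- matrix$regions$qc_class[match(var_ids, matrix$regions$var_id)]
    drop_intra <- var_ids[qcc == "intrasample_excluded"]
    drop_inter <- var_ids[qcc == "intersample_excluded"]
    report <- data.frame(
      var_id = c(drop_intra, drop_inter),
      reason = rep(c("intrasample_rsd", "intersample_rsd"),
                   c(length(drop_intra), length(drop_inter))),
      rsd_value = NA_real_, stringsAsFactors = FALSE)
  } else {
    if (is.null(replicates)) stop("replicate set required for computed QC")
    rep_rsd <- apply(replicates$values, 2, percent_rsd)
    drop_intra <- var_ids[rep_rsd > qc$intrasample_rsd_max]
    grp <- matrix$sample_meta$group
    if (is.null(grp)) stop("missing group labels")
    groups <- unique(grp)
    g_rsd <- sapply(groups, function(g)
      apply(matrix$values[grp == g, , drop = FALSE], 2, percent_rsd))
    over <- g_rsd > qc$intersample_rsd_max
    hit <- if (qc$require_both_groups) apply(over, 1, all)
           else apply(over, 1, any)
    drop_inter <- setdiff(var_ids[hit], drop_intra)
    report <- data.frame(
      var_id = c(var_ids[var_ids %in% drop_intra],
                 var_ids[var_ids %in% drop_inter]),
      reason = rep(c("intrasample_rsd", "intersample_rsd"),
                   c(sum(var_ids %in% drop_intra),
                     sum(var_ids %in% drop_inter))),
      rsd_value = c(rep_rsd[var_ids %in% drop_intra],
                    apply(g_rsd, 1, max)[var_ids %in% drop_inter]),
      stringsAsFactors = FALSE)
  }
  drop <- union(drop_intra, drop_inter)
  keep <- setdiff(var_ids, drop)
  filtered <- matrix
  filtered$values <- matrix$values[, var_ids %in% keep, drop = FALSE]
  list(filtered = filtered, report = report, kept = keep)
}

#' Partition samples by hemolysis flag
#'
#' @param samples data frame with a logical `hemolytic` column.
#' @return list with `kept`, `excluded` and counts.
#' @export
exclude_hemolytic <- function(samples) {
  if (!"hemolytic" %in% names(samples)) stop("missing hemolysis flag")
  flag <- samples$hemolytic
  if (all(flag)) warning("all samples flagged hemolytic; none kept")
  list(kept = samples[!flag, , drop = FALSE],
       excluded = samples[flag, , drop = FALSE],
       n_kept = sum(!flag), n_excluded = sum(flag))
}

#' Absolute concentration from an MA-normalized integral
#'
#' Standard internal-standard relation: the normalized integral times the
#' standard concentration, corrected for the proton-count ratio
#' (maleic acid contributes 2 equivalent protons).
#'
#' @param normalized_value MA-normalized region integral.
#' @param ma_conc standard concentration, uM (53.85 in the protocol).
#' @param n_protons_region protons contributing to the region.
#' @param n_protons_ma protons of the standard (2).
#' @return concentration in uM.
#' @export
quantify <- function(normalized_value, ma_conc = 53.85, n_protons_region,
                     n_protons_ma = 2) {
  if (ma_conc <= 0 || n_protons_region <= 0 || n_protons_ma <= 0)
    stop("concentrations and proton counts must be positive")
  normalized_value * ma_conc * n_protons_ma / n_protons_region
}

#' Regions and proton count for quantifying one proton group
#'
#' Convenience lookup: the union of region ids assigned to a metabolite's
#' proton group, and the group's proton count, for closed-loop
#' quantification of single-metabolite samples.
#'
#' @param library a spin library.
#' @param metabolite,group names identifying the proton group(s); `group`
#'   may list several groups integrated jointly.
#' @return list with `vars` and `n_protons`.
#' @export
quant_regions <- function(library, metabolite, group) {
  i <- which(library$metabolite == metabolite & library$group %in% group)
  if (!length(i)) stop("unknown proton group ", metabolite, "/", group)
  list(vars = sort(unique(unlist(library$vars[i]))),
       n_protons = sum(library$n_protons[i]))
}

#' Lorentzian capture fraction of a line set within a ppm window set
#'
#' Fixed integration windows clip the tails of Lorentzian lines; the
#' clipped fraction follows in closed form from the Lorentzian CDF
#' `(1/pi) * atan(x / hwhm)`.  This fraction is used to correct
#' window-truncation bias when converting integrals to concentrations.
#'
#' @param line_ppm line positions.
#' @param line_intensity relative line intensities.
#' @param windows matrix-like with columns `lo`, `hi` (ppm).
#' @param linewidth_hz full Lorentzian linewidth at half height.
#' @param freq_mhz spectrometer frequency.
#' @return captured area fraction in (0, 1].
#' @export
lorentzian_capture <- function(line_ppm, line_intensity, windows,
                               linewidth_hz, freq_mhz = 600) {
  hw <- linewidth_hz / 2 / freq_mhz
  windows <- as.matrix(windows)
  cap <- 0
  for (j in seq_along(line_ppm)) {
    fr <- sum((atan((windows[, 2] - line_ppm[j]) / hw) -
                 atan((windows[, 1] - line_ppm[j]) / hw)) / pi)
    cap <- cap + line_intensity[j] * fr
  }
  cap / sum(line_intensity)
}

#' Closed-loop quantification of one proton group from a spectrum
#'
#' Integrates the union of the regions assigned to the group, normalizes to
#' the MA window integral, corrects both integrals for Lorentzian window
#' truncation, and converts to a concentration with [quantify()].
#'
#' @param spectrum calibrated `nmr_spectrum`.
#' @param library,regions spin library and region table.
#' @param metabolite,group proton group to quantify.
#' @param ma_conc standard concentration, uM.
#' @param linewidth_hz effective Lorentzian linewidth (natural width plus
#'   applied line broadening).
#' @return concentration estimate, uM.
#' @export
quantify_group <- function(spectrum, library, regions, metabolite, group,
                           ma_conc = 53.85, linewidth_hz = 1.8) {
  qr <- quant_regions(library, metabolite, group)
  idx <- match(qr$vars, regions$var_id)
  win <- cbind(regions$ppm_end[idx], regions$ppm_start[idx])
  ints <- integrate_regions(spectrum, regions)
  val <- sum(ints[sprintf("VAR%03d", qr$vars)])
  i <- which(library$metabolite == metabolite & library$group %in% group)
  line_ppm <- numeric(0)
  line_int <- numeric(0)
  for (k in i) {
    if (library$multiplicity[k] == "m") {
      pat <- data.frame(offset_hz = 0, intensity = library$n_protons[k])
    } else {
      pat <- multiplet_pattern(library$multiplicity[k], library$j_hz[[k]],
                               library$n_protons[k])
    }
    line_ppm <- c(line_ppm, library$shift_ppm[k] + pat$offset_hz / 600)
    line_int <- c(line_int, pat$intensity)
  }
  cap_met <- lorentzian_capture(line_ppm, line_int, win, linewidth_hz)
  maw <- attr(regions, "ma_window") %||% c(5.98, 6.04)
  cap_ma <- lorentzian_capture(6.010, 1, rbind(maw), linewidth_hz)
  ma <- ma_integral(spectrum, maw)
  quantify(normalize_to_ma(val, ma) * cap_ma / cap_met, ma_conc,
           qr$n_protons)
}
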