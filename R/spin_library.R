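#' Multiplicity grammar
#'
#' Composite multiplicity codes are parsed left-to-right; each `d` consumes
#' one J value, `t` one J applied twice, `q` one J applied three times and
#' `p` one J applied four times.  `s` consumes none and `m` denotes an
#' unresolved multiplet described only by an envelope width.
#' @noRd
.mult_grammar <- c(s = 0L, d = 1L, t = 1L, q = 1L, p = 1L,
                   dd = 2L, dt = 2L, dq = 2L,
                   ddd = 3L, ddt = 3L, m = 0L)

#' Number of J couplings required by a multiplicity code
#'
#' @param multiplicity a code such as `"s"`, `"d"`, `"dd"`, `"ddt"` or `"m"`.
#' @return integer count of J values the code consumes.
#' @export
n_j_required <- function(multiplicity) {
  if (!multiplicity %in% names(.mult_grammar))
    stop("unknown multiplicity code: ", multiplicity)
  unname(.mult_grammar[multiplicity])
}

#' The eight albumin-binding metabolites released by TSP
#' @noRd
.hsa_binders <- c("acetate", "acetoacetate", "lactate", "oxaloacetate",
                  "phenylalanine", "pyruvate", "3-methyl-2-oxobutyrate",
                  "beta-hydroxybutyrate")

#' Anomeric populations used when a sugar is present as two anomers.
#' Aqueous equilibrium fractions (alpha first).
#' @noRd
.anomer_fraction <- list(
  glucose = c(alpha = 0.36, beta = 0.64),
  mannose = c(alpha = 0.67, beta = 0.33)
)

#' Load the packaged 62-metabolite spin library
#'
#' Reads the packaged table of proton groups (one row per group, with the
#' multiplet centre in ppm, a first-order multiplicity code, the J couplings
#' in Hz, the proton count and the integration-region ids the group is
#' assigned to) and validates it against the multiplicity grammar.
#'
#' @param path path to a spin-library TSV; defaults to the packaged file.
#' @return an object of class `spin_library`: a data frame of proton groups
#'   with list columns `j_hz` and `vars`, plus per-metabolite attributes.
#' @examples
#' lib <- load_spin_library()
#' nlevels(factor(lib$metabolite))  # 62
#' @export
load_spin_library <- function(path = system.file("extdata", "spin_library.tsv",
                                                 package = "plasmaNMR")) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("metabolite", "group", "shift_ppm", "multiplicity", "j_hz",
            "n_protons", "vars", "hsa_binder")
  if (!all(need %in% names(raw)))
    stop("spin library file is missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  if (!"anomer" %in% names(raw)) raw$anomer <- ""

  lib <- data.frame(
    metabolite = raw$metabolite,
    group = raw$group,
    shift_ppm = as.numeric(raw$shift_ppm),
    multiplicity = raw$multiplicity,
    n_protons = as.numeric(raw$n_protons),
    hsa_binder = raw$hsa_binder %in% c("1", "TRUE", "true"),
    anomer = ifelse(is.na(raw$anomer) | raw$anomer == "", NA_character_,
                    raw$anomer),
    stringsAsFactors = FALSE
  )
  lib$j_hz <- lapply(raw$j_hz, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  lib$vars <- lapply(raw$vars, function(s)
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))

  validate_spin_library(lib)
  class(lib) <- c("spin_library", "data.frame")
  attr(lib, "binders") <- .hsa_binders
  attr(lib, "anomer_fraction") <- .anomer_fraction
  lib
}

#' @noRd
validate_spin_library <- function(lib) {
  for (i in seq_len(nrow(lib))) {
    id <- paste0(lib$metabolite[i], " / ", lib$group[i])
    m <- lib$multiplicity[i]
    if (!m %in% names(.mult_grammar))
      stop("spin library: unknown multiplicity '", m, "' in ", id)
    nj <- length(lib$j_hz[[i]])
    if (m != "m" && nj != .mult_grammar[[m]])
      stop("spin library: ", id, " has ", nj, " J values but code '", m,
           "' requires ", .mult_grammar[[m]])
    if (m == "m" && nj != 0L)
      stop("spin library: ", id, " is 'm' but lists J values")
    if (any(lib$j_hz[[i]] <= 0))
      stop("spin library: non-positive J in ", id)
    if (lib$shift_ppm[i] < 0 || lib$shift_ppm[i] > 10)
      stop("spin library: shift outside [0, 10] ppm in ", id)
    if (lib$n_protons[i] < 1)
      stop("spin library: n_protons < 1 in ", id)
    v <- lib$vars[[i]]
    if (any(v < 1L | v > 237L))
      stop("spin library: region id outside 1..237 in ", id)
  }
  mets <- unique(lib$metabolite)
  if (length(mets) != 62L)
    stop("spin library: expected 62 metabolites, found ", length(mets))
  bound <- vapply(split(lib$hsa_binder, lib$metabolite), all, logical(1))
  bad <- setdiff(.hsa_binders, names(bound)[bound])
  if (length(bad))
    stop("spin library: binder flag missing for: ", paste(bad, collapse = ", "))
  extra <- setdiff(names(bound)[bound], .hsa_binders)
  if (length(extra))
    stop("spin library: unexpected binder flag on: ",
         paste(extra, collapse = ", "))
  invisible(lib)
}

#' @export
print.spin_library <- function(x, ...) {
  cat("Spin library:", length(unique(x$metabolite)), "metabolites,",
      nrow(x), "proton groups\n")
  cat("Albumin binders:", paste(attr(x, "binders"), collapse = ", "), "\n")
  invisible(x)
}

#' Metabolite names in a spin library
#' @param lib a `spin_library`.
#' @return character vector of the distinct metabolite names.
#' @export
library_metabolites <- function(lib) unique(lib$metabolite)

#' Write a spin library back to TSV
#'
#' Inverse of [load_spin_library()]; the round trip is lossless.
#' @param lib a `spin_library`.
#' @param path output file.
#' @export
write_spin_library <- function(lib, path) {
  out <- data.frame(
    metabolite = lib$metabolite,
    group = lib$group,
    shift_ppm = format(lib$shift_ppm, trim = TRUE),
    multiplicity = lib$multiplicity,
    j_hz = vapply(lib$j_hz, function(j) paste(format(j, trim = TRUE),
                                              collapse = ";"), character(1)),
    n_protons = format(lib$n_protons, trim = TRUE),
    vars = vapply(lib$vars, paste, character(1), collapse = ","),
    hsa_binder = as.integer(lib$hsa_binder),
    anomer = ifelse(is.na(lib$anomer), "", lib$anomer),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Half width (Hz) of a proton group's multiplet envelope
#'
#' For coded multiplets this is half the sum of the expanded J splittings
#' (the outermost line offset); for `m` groups it is half the configured
#' envelope width.
#' @noRd
envelope_halfwidth_hz <- function(multiplicity, j_hz, m_width_hz = 12) {
  if (multiplicity == "m") return(m_width_hz / 2)
  if (multiplicity == "s") return(0)
  pat <- multiplet_pattern(multiplicity, j_hz, 1)
  max(abs(pat$offset_hz))
}
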