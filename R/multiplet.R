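#' First-order multiplet stick pattern
#'
#' Expands a multiplicity code and its J couplings into a symmetric stick
#' pattern around the multiplet centre.  Composite codes are parsed
#' left-to-right, each letter consuming one J value: `d` splits into two
#' lines separated by J, `t` into three lines with binomial 1:2:1 weights
#' (one J applied twice), `q` into four (1:3:3:1) and `p` into five
#' (1:4:6:4:1).  `s` is a single line and `m` (unresolved multiplet) is
#' returned as a single stick; its envelope width is handled by the
#' lineshape at simulation time.
#'
#' @param multiplicity multiplicity code (`s`, `d`, `t`, `q`, `p`, `m`,
#'   `dd`, `dt`, `dq`, `ddd`, `ddt`).
#' @param j_hz numeric vector of J couplings in Hz, one per consuming letter.
#' @param n_protons number of protons in the group; stick intensities sum to
#'   this value.
#' @return data frame with columns `offset_hz` (symmetric about 0, ascending)
#'   and `intensity`.
#' @examples
#' multiplet_pattern("d", 7.2, 3)       # two lines at -3.6 / +3.6 Hz
#' multiplet_pattern("dd", c(16.1, 7.8), 1)
#' @export
multiplet_pattern <- function(multiplicity, j_hz = numeric(0), n_protons = 1) {
  if (length(multiplicity) != 1L || !multiplicity %in% names(.mult_grammar))
    stop("unknown multiplicity code: ", multiplicity)
  if (n_protons <= 0) stop("n_protons must be positive")
  need <- .mult_grammar[[multiplicity]]
  if (multiplicity == "m") {
    if (length(j_hz)) stop("'m' groups take no J values")
  } else if (length(j_hz) != need) {
    stop("multiplicity '", multiplicity, "' requires ", need,
         " J value(s), got ", length(j_hz))
  }
  if (any(j_hz <= 0)) stop("J couplings must be positive")

  offs <- 0
  wts <- 1
  if (!multiplicity %in% c("s", "m")) {
    letters_ <- strsplit(multiplicity, "")[[1]]
    # binomial sub-patterns per letter; convolved by outer sums
    order_of <- c(d = 1L, t = 2L, q = 3L, p = 4L)
    for (k in seq_along(letters_)) {
      n_split <- order_of[[letters_[k]]]
      j <- j_hz[k]
      sub_off <- (seq_len(n_split + 1L) - 1L - n_split / 2) * j
      sub_wt <- choose(n_split, 0:n_split)
      offs <- as.vector(outer(offs, sub_off, `+`))
      wts <- as.vector(outer(wts, sub_wt, `*`))
    }
    # merge coincident lines
    key <- round(offs, 9)
    agg <- rowsum(wts, key)
    offs <- as.numeric(rownames(agg))
    wts <- agg[, 1]
    o <- order(offs)
    offs <- offs[o]
    wts <- wts[o]
  }
  data.frame(offset_hz = offs,
             intensity = wts / sum(wts) * n_protons,
             row.names = NULL)
}
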