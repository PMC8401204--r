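#' Write a spectrum as JCAMP-DX
#'
#' Minimal JCAMP-DX 4.24 writer (AFFN `(X++(Y..Y))` table, descending ppm,
#' real intensities).
#'
#' @param spectrum an `nmr_spectrum`.
#' @param path output file.
#' @param title record title.
#' @export
write_jcampdx <- function(spectrum, path, title = "simulated spectrum") {
  ppm <- spectrum$ppm
  y <- Re(spectrum$intensity)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    paste0("##.OBSERVE FREQUENCY=", spectrum$acq$spectrometer_freq),
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    paste0("##FIRSTX=", format(ppm[1], digits = 12)),
    paste0("##LASTX=", format(ppm[length(ppm)], digits = 12)),
    paste0("##NPOINTS=", length(ppm)),
    "##XYDATA=(X++(Y..Y))"), con)
  step <- 8L
  for (i in seq(1L, length(y), by = step)) {
    j <- min(i + step - 1L, length(y))
    writeLines(paste(c(format(ppm[i], digits = 12),
                       format(y[i:j], digits = 9)), collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}

#' Read a JCAMP-DX spectrum written by [write_jcampdx()]
#'
#' @param path input file.
#' @return an `nmr_spectrum` (real intensities; acquisition metadata
#'   limited to the spectrometer frequency).
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path)
  get1 <- function(key) {
    v <- grep(paste0("^##", key, "="), lines, value = TRUE)[1]
    sub(paste0("^##", key, "="), "", v)
  }
  first_x <- as.numeric(get1("FIRSTX"))
  last_x <- as.numeric(get1("LASTX"))
  npts <- as.integer(get1("NPOINTS"))
  freq <- suppressWarnings(as.numeric(get1("\\.OBSERVE FREQUENCY")))
  start <- grep("^##XYDATA", lines) + 1L
  end <- grep("^##END", lines) - 1L
  y <- numeric(0)
  for (ln in lines[start:end]) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    y <- c(y, v[-1])
  }
  if (length(y) != npts) stop("JCAMP-DX point count mismatch")
  ppm <- seq(first_x, last_x, length.out = npts)
  structure(list(ppm = ppm, intensity = y, phase_state = "phased",
                 calibrated = TRUE,
                 acq = list(spectrometer_freq = freq),
                 provenance = list(list(step = "read_jcampdx",
                                        path = path))),
            class = "nmr_spectrum")
}

#' Write / read a spectrum as two-column CSV (ppm, intensity)
#' @param spectrum an `nmr_spectrum`.
#' @param path file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = Re(spectrum$intensity)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(ppm = d$ppm, intensity = d$intensity,
                 phase_state = "phased", calibrated = TRUE,
                 acq = list(spectrometer_freq = 600),
                 provenance = list(list(step = "read_spectrum_csv",
                                        path = path))),
            class = "nmr_spectrum")
}

#' Write / read a raw FID as CSV (t, re, im)
#' @param fid an `nmr_fid`.
#' @param path file path.
#' @param acq acquisition parameters used when reading back.
#' @export
write_fid_csv <- function(fid, path) {
  n <- length(fid$signal)
  dwell <- 1 / (fid$acq$spectral_width * fid$acq$spectrometer_freq)
  utils::write.csv(data.frame(t = (seq_len(n) - 1L) * dwell,
                              re = Re(fid$signal), im = Im(fid$signal)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fid_csv
#' @export
read_fid_csv <- function(path, acq = acquisition_params()) {
  d <- utils::read.csv(path)
  structure(list(signal = complex(real = d$re, imaginary = d$im),
                 acq = acq, sample = list(),
                 provenance = list(list(step = "read_fid_csv",
                                        path = path))),
            class = "nmr_fid")
}

#' Write a feature matrix as CSV (sample_id, VAR001..VAR237)
#' @param fm a [feature_matrix()].
#' @param path file path.
#' @export
write_feature_matrix <- function(fm, path) {
  out <- data.frame(sample_id = fm$sample_meta$sample_id, fm$values,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
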