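#' Principal component analysis of a scaled feature matrix
#'
#' Thin wrapper around [stats::prcomp()] (no further centring or scaling:
#' supply an already scaled matrix) reporting scores, loadings and the
#' explained-variance fraction per component.
#'
#' @param x scaled matrix (samples x variables).
#' @param n_components number of components (must not exceed the rank).
#' @return a `pca_model` with `scores`, `loadings`, `explained` and the
#'   underlying `prcomp` fit.
#' @export
fit_pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  r <- min(nrow(x) - 1L, ncol(x))
  if (n_components > r)
    stop("n_components exceeds the matrix rank (", r, ")")
  fit <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x[, seq_len(n_components), drop = FALSE],
                 loadings = fit$rotation[, seq_len(n_components),
                                         drop = FALSE],
                 explained = expl[seq_len(n_components)],
                 prcomp = fit),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA:", ncol(x$scores), "components, explained variance",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + "), "\n")
  invisible(x)
}
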