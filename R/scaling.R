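#' Mean centering and Pareto scaling
#'
#' Pareto scaling divides each mean-centred column by the square root of
#' its sample standard deviation, damping the dominance of intense regions
#' while keeping some magnitude information.  Constant columns are left at
#' zero with a warning.
#'
#' @param x numeric matrix (samples x variables).
#' @param mode `"pareto"` or `"mean_center"`.
#' @return list with `scaled` matrix and `state` (a `scaling_state` holding
#'   the column means, standard deviations and mode).
#' @export
pareto_scale <- function(x, mode = c("pareto", "mean_center")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least two rows required")
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) warning("constant columns left at zero: ",
                             paste(colnames(x)[sds == 0], collapse = ", "))
  state <- structure(list(column_means = mu, column_sds = sds, mode = mode),
                     class = "scaling_state")
  list(scaled = apply_scaling(x, state), state = state)
}

#' Apply a stored scaling state to new data
#'
#' @param x matrix with the same columns as the training matrix.
#' @param state a `scaling_state` from [pareto_scale()].
#' @return scaled matrix.
#' @export
apply_scaling <- function(x, state) {
  x <- as.matrix(x)
  if (ncol(x) != length(state$column_means))
    stop("column mismatch: expected ", length(state$column_means),
         " variables")
  div <- switch(state$mode,
                pareto = sqrt(state$column_sds),
                mean_center = rep(1, length(state$column_sds)))
  div[div == 0] <- 1
  sweep(sweep(x, 2, state$column_means), 2, div, "/")
}
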