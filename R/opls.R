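#' Orthogonal partial least squares discriminant analysis
#'
#' Fits a two-class OPLS-DA model: iteratively extracts components of X
#' that are orthogonal to the class response (weights orthogonalized
#' against the y-correlated direction, Trygg-Wold style), deflates them,
#' and fits a single predictive PLS component on the filtered matrix.
#' With `n_ortho = 0` the model coincides with one-component PLS1.
#'
#' @param x numeric matrix (samples x variables) of MA-normalized region
#'   integrals (or any feature matrix).
#' @param labels two-class factor or character vector.
#' @param n_ortho number of orthogonal components (`"auto"` adds components
#'   while seven-fold cross-validated Q2 improves by more than `auto_tol`).
#' @param scale `"pareto"` (mean centre + Pareto, the standard protocol),
#'   `"mean_center"`, or `"none"` when `x` is already scaled.
#' @param positive_class label coded 1 (`"cancer"` when present, otherwise
#'   the last sorted level); the other class is coded 0.
#' @param auto_tol minimum Q2 gain per extra orthogonal component in auto
#'   mode.
#' @param cv_seed seed for the internal cross-validation of auto mode.
#' @return an object of class `opls_da` with predictive scores `t`,
#'   loadings `p`, weights `w`, regression coefficient `c`, orthogonal
#'   component list, cumulative `r2x`, `r2y`, the scaling state and class
#'   coding.
#' @seealso [predict.opls_da()], [vip_scores()], [s_plot()],
#'   [cross_validate()]
#' @export
opls_da <- function(x, labels, n_ortho = 1,
                    scale = c("pareto", "mean_center", "none"),
                    positive_class = NULL, auto_tol = 0.01,
                    cv_seed = 77L) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2) stop("exactly two classes required, got ",
                             length(cls))
  if (any(table(labels) < 2)) stop("each class needs at least 2 members")
  if (is.null(positive_class))
    positive_class <- if ("cancer" %in% cls) "cancer" else cls[2]
  negative_class <- setdiff(cls, positive_class)
  y <- as.numeric(as.character(labels) == positive_class)

  if (scale == "none") {
    xs <- x
    state <- structure(list(column_means = rep(0, ncol(x)),
                            column_sds = rep(1, ncol(x)), mode = "none"),
                       class = "scaling_state")
  } else {
    ps <- pareto_scale(x, mode = scale)
    xs <- ps$scaled
    state <- ps$state
  }

  if (identical(n_ortho, "auto")) {
    q_prev <- cross_validate(x, labels, folds = 7, seed = cv_seed,
                             n_ortho = 0, scale = scale,
                             positive_class = positive_class)$q2
    n_ortho <- 0
    repeat {
      q_next <- cross_validate(x, labels, folds = 7, seed = cv_seed,
                               n_ortho = n_ortho + 1, scale = scale,
                               positive_class = positive_class)$q2
      if (q_next - q_prev <= auto_tol || n_ortho >= 5) break
      n_ortho <- n_ortho + 1
      q_prev <- q_next
    }
  }

  core <- opls_core(xs, y, n_ortho)
  structure(c(core,
              list(scaling = state, labels = as.character(labels),
                   class_coding = stats::setNames(c(0, 1),
                                                  c(negative_class,
                                                    positive_class)),
                   positive_class = positive_class,
                   negative_class = negative_class,
                   x_scaled = xs, y = y,
                   var_names = colnames(x))),
            class = "opls_da")
}

#' Numerical core of the OPLS fit (scaled matrix, 0/1 response)
#' @noRd
opls_core <- function(xs, y, n_ortho) {
  yc <- y - mean(y)
  ssx <- sum(xs^2)
  ssy <- sum(yc^2)
  X <- xs
  ortho <- list()
  for (o in seq_len(n_ortho)) {
    w <- drop(crossprod(X, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t1 <- drop(X %*% w)
    p <- drop(crossprod(X, t1)) / sum(t1^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10 * sqrt(sum(p^2)) || nwo < 1e-12) break
    w_o <- w_o / nwo
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    ortho[[length(ortho) + 1L]] <- list(t = t_o, p = p_o, w = w_o)
  }
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(X %*% w)
  p <- drop(crossprod(X, t1)) / sum(t1^2)
  cc <- sum(t1 * yc) / sum(t1^2)
  r2y <- cc^2 * sum(t1^2) / ssy
  r2x_pred <- sum(t1^2) * sum(p^2) / ssx
  r2x_ortho <- vapply(ortho, function(z) sum(z$t^2) * sum(z$p^2) / ssx,
                      numeric(1))
  list(t = t1, p = p, w = w, c = cc, y_mean = mean(y),
       ortho = ortho, n_ortho = length(ortho),
       r2x = r2x_pred + sum(r2x_ortho), r2x_pred = r2x_pred,
       r2y = r2y, deflated_x = X)
}

#' @export
print.opls_da <- function(x, ...) {
  cat("OPLS-DA model: 1 predictive +", x$n_ortho, "orthogonal component(s)\n")
  cat(sprintf("  %d samples x %d variables; classes %s(0) / %s(1)\n",
              length(x$t), length(x$w), x$negative_class, x$positive_class))
  cat(sprintf("  R2X(cum) = %.3f, R2Y(cum) = %.3f\n", x$r2x, x$r2y))
  invisible(x)
}

#' @export
summary.opls_da <- function(object, ...) {
  vip <- vip_scores(object)
  out <- list(r2x = object$r2x, r2y = object$r2y,
              n_ortho = object$n_ortho,
              n_vip_selected = sum(vip > 0.8),
              class_coding = object$class_coding)
  class(out) <- "summary.opls_da"
  out
}

#' @export
print.summary.opls_da <- function(x, ...) {
  cat(sprintf("R2X(cum) %.3f  R2Y(cum) %.3f  orthogonal components %d\n",
              x$r2x, x$r2y, x$n_ortho))
  cat("variables with VIP > 0.80:", x$n_vip_selected, "\n")
  invisible(x)
}

#' @export
coef.opls_da <- function(object, ...) {
  stats::setNames(object$p, object$var_names)
}

#' @export
fitted.opls_da <- function(object, ...) {
  object$t * object$c + object$y_mean
}

#' @export
residuals.opls_da <- function(object, ...) {
  object$y - fitted(object)
}

#' Predict class membership for new samples
#'
#' Applies the stored training scaling (never refit), removes the
#' orthogonal components in training order, projects onto the predictive
#' weights and thresholds the predicted response at 0.5.  When `labels`
#' are supplied a full classification report (confusion counts,
#' specificity, sensitivity, AUC) is returned.
#'
#' @param object an `opls_da` model.
#' @param newdata matrix with the training variable set.
#' @param labels optional true labels for a `classifier_report`.
#' @param threshold decision threshold on the predicted 0/1 response.
#' @param ... unused.
#' @return data frame of scores/predictions, or a `classifier_report` when
#'   `labels` are given.
#' @export
predict.opls_da <- function(object, newdata, labels = NULL,
                            threshold = 0.5, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w)) {
    miss <- setdiff(object$var_names, colnames(newdata))
    stop("column mismatch; missing variables: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  X <- apply_scaling(newdata, object$scaling)
  for (z in object$ortho) {
    t_o <- drop(X %*% z$w)
    X <- X - tcrossprod(t_o, z$p)
  }
  t_new <- drop(X %*% object$w)
  y_hat <- t_new * object$c + object$y_mean
  pred <- ifelse(y_hat >= threshold, object$positive_class,
                 object$negative_class)
  res <- data.frame(score = t_new, y_hat = y_hat, predicted = pred,
                    stringsAsFactors = FALSE)
  if (is.null(labels)) return(res)
  classifier_report(res, as.character(labels), object$positive_class,
                    object$negative_class, threshold)
}

#' @noRd
classifier_report <- function(pred, truth, positive, negative, threshold) {
  tp <- sum(pred$predicted == positive & truth == positive)
  tn <- sum(pred$predicted == negative & truth == negative)
  fp <- sum(pred$predicted == positive & truth == negative)
  fn <- sum(pred$predicted == negative & truth == positive)
  roc <- pROC::roc(response = factor(truth, levels = c(negative, positive)),
                   predictor = pred$y_hat, quiet = TRUE,
                   direction = "<", levels = c(negative, positive))
  structure(list(confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 auc = as.numeric(pROC::auc(roc)),
                 predicted_scores = pred$y_hat, threshold = threshold,
                 roc = roc),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("specificity %.1f%%  sensitivity %.1f%%  AUC %.3f\n",
              x$specificity, x$sensitivity, x$auc))
  cat("confusion (tp tn fp fn):", x$confusion, "\n")
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP on the predictive component only: `sqrt(p) * |w_j| / ||w||`, so the
#' mean squared VIP equals 1 and `sum(VIP^2)` equals the number of
#' variables.  The customary selection threshold is 0.80.
#'
#' @param model an `opls_da` model.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  v <- sqrt(length(model$w)) * abs(model$w) / sqrt(sum(model$w^2))
  stats::setNames(v, model$var_names)
}

#' S-plot: covariance and correlation against the predictive score
#'
#' For each variable, the covariance and Pearson correlation between the
#' predictive score vector and the (scaled) variable.  A positive
#' covariance means the variable is elevated in the class coded 1; the
#' direction call translates the sign accordingly.  Zero-variance
#' variables yield `NA` correlation.
#'
#' @param model an `opls_da` model.
#' @param x optional scaled matrix (defaults to the training matrix).
#' @return data frame with `variable`, `covariance`, `correlation`,
#'   `direction` (e.g. `"increased in cancer"`).
#' @export
s_plot <- function(model, x = model$x_scaled) {
  t1 <- model$t
  n <- length(t1)
  covv <- drop(crossprod(x, t1 - mean(t1))) / (n - 1)
  sds <- apply(x, 2, stats::sd)
  corr <- ifelse(sds > 0, covv / (sds * stats::sd(t1)), NA_real_)
  dirn <- ifelse(covv > 0, paste("increased in", model$positive_class),
                 paste("decreased in", model$positive_class))
  data.frame(variable = model$var_names %||% seq_along(covv),
             covariance = covv, correlation = corr, direction = dirn,
             stringsAsFactors = FALSE)
}

#' Score plot of an OPLS-DA model
#'
#' Predictive score against the first orthogonal score (or sample index
#' when no orthogonal component exists), coloured by class.
#'
#' @param x an `opls_da` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.opls_da <- function(x, ...) {
  t_o <- if (x$n_ortho >= 1) x$ortho[[1]]$t else seq_along(x$t)
  col <- ifelse(x$labels == x$positive_class, "firebrick", "steelblue")
  graphics::plot(x$t, t_o, col = col, pch = 19,
                 xlab = "predictive score t[1]",
                 ylab = if (x$n_ortho >= 1) "orthogonal score t_o[1]"
                        else "sample index", ...)
  graphics::legend("topright", legend = names(x$class_coding),
                   col = c("steelblue", "firebrick"), pch = 19, bty = "n")
  invisible(x)
}
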