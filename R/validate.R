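#' Stratified seven-fold cross-validation of an OPLS-DA model
#'
#' Splits the samples into stratified folds, refits the model on each
#' training portion (scaling included, so no information leaks from the
#' held-out fold) and predicts the held-out responses.
#' `Q2 = 1 - PRESS / SS` over the held-out predictions; the per-fold
#' predictive loadings are retained for jack-knife variable selection.
#'
#' @param x feature matrix (unscaled).
#' @param labels two-class labels.
#' @param folds number of folds (7 in the standard protocol).
#' @param seed seed for the fold assignment.
#' @param n_ortho orthogonal components per fold model.
#' @param scale,positive_class forwarded to [opls_da()].
#' @return list with `q2`, `press`, `fold_loadings` (folds x variables),
#'   `fold_assignment`.
#' @export
cross_validate <- function(x, labels, folds = 7, seed = 77L, n_ortho = 1,
                           scale = "pareto", positive_class = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("two classes required")
  if (folds > min(table(labels)))
    stop("more folds than members of the smallest class")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  fold <- integer(nrow(x))
  for (g in cls) {
    idx <- which(labels == g)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  if (is.null(positive_class))
    positive_class <- if ("cancer" %in% cls) "cancer" else cls[2]
  y <- as.numeric(labels == positive_class)

  press <- 0
  loadings <- matrix(NA_real_, folds, ncol(x))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2)
      stop("fold ", f, " leaves a single-class training set")
    m <- opls_da(x[tr, , drop = FALSE], labels[tr], n_ortho = n_ortho,
                 scale = scale, positive_class = positive_class)
    pr <- predict(m, x[!tr, , drop = FALSE])
    press <- press + sum((y[!tr] - pr$y_hat)^2)
    loadings[f, ] <- m$p
  }
  ss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / ss, press = press, fold_loadings = loadings,
       fold_assignment = fold)
}

#' Jack-knife variable selection from cross-validation loadings
#'
#' Aligns the sign of each fold's predictive loading vector with the
#' full-model loadings, estimates a Tukey jack-knife standard error per
#' variable over the folds, and retains a variable when its jack-knife
#' confidence interval excludes zero, i.e. when the absolute full-model
#' loading exceeds the standard error scaled by the two-sided Student-t
#' critical value at `conf_level` (the jack-knife interval).
#'
#' @param full_loadings predictive loading vector of the full model.
#' @param fold_loadings folds x variables matrix from [cross_validate()].
#' @param conf_level confidence level of the jack-knife interval.
#' @return list with `retained` (indices), `se` (vector), `loading` and
#'   the applied `critical` multiplier.
#' @export
jackknife_select <- function(full_loadings, fold_loadings,
                             conf_level = 0.95) {
  g <- nrow(fold_loadings)
  if (g < 3) stop("at least 3 folds required for jack-knifing")
  signs <- vapply(seq_len(g), function(f) {
    s <- sum(fold_loadings[f, ] * full_loadings)
    if (s < 0) -1 else 1
  }, numeric(1))
  aligned <- fold_loadings * signs
  centre <- colMeans(aligned)
  se <- sqrt((g - 1) / g * colSums(sweep(aligned, 2, centre)^2))
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = g - 1)
  retained <- which(abs(full_loadings) > crit * se)
  list(retained = retained, se = se, loading = full_loadings,
       critical = crit)
}

#' Label-permutation test of an OPLS-DA model
#'
#' Refits the model (and its cross-validated Q2) under random permutations
#' of the class labels.  A sound model shows permuted R2Y far below the
#' real R2Y and permuted Q2 centred below zero.
#'
#' @param x feature matrix.
#' @param labels true labels.
#' @param n_perm number of permutations (>= 20).
#' @param seed seed for the permutations.
#' @param folds,n_ortho,scale forwarded to the refits.
#' @return list with `r2_perm`, `q2_perm`, `r2_real`, `q2_real`, and a
#'   `summary` (means and exceedance fractions).
#' @export
permutation_test <- function(x, labels, n_perm = 200, seed = 99L,
                             folds = 7, n_ortho = 1, scale = "pareto") {
  if (n_perm < 20) stop("at least 20 permutations required")
  x <- as.matrix(x)
  labels <- as.character(labels)
  real <- opls_da(x, labels, n_ortho = n_ortho, scale = scale)
  r2_real <- real$r2y
  q2_real <- cross_validate(x, labels, folds = folds, seed = seed,
                            n_ortho = n_ortho, scale = scale)$q2
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  r2p <- numeric(n_perm)
  q2p <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(perm_seeds[i])
    lp <- sample(labels)
    r2p[i] <- opls_da(x, lp, n_ortho = n_ortho, scale = scale)$r2y
    q2p[i] <- cross_validate(x, lp, folds = folds, seed = perm_seeds[i],
                             n_ortho = n_ortho, scale = scale)$q2
  }
  list(r2_perm = r2p, q2_perm = q2p, r2_real = r2_real, q2_real = q2_real,
       summary = c(mean_r2_perm = mean(r2p), mean_q2_perm = mean(q2p),
                   frac_r2_above = mean(r2p >= r2_real),
                   frac_q2_above = mean(q2p >= q2_real)))
}
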