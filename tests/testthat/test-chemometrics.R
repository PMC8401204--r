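test_that("Pareto scaling matches the hand formula", {
  x <- cbind(a = c(0, 2), b = c(3, 3))
  expect_warning(ps <- pareto_scale(x), "constant")
  expect_equal(ps$scaled[, "a"], c(-0.8409, 0.8409), tolerance = 1e-4)
  expect_equal(ps$scaled[, "b"], c(0, 0))

  set.seed(1)
  y <- matrix(rnorm(60), 10, 6)
  sc <- pareto_scale(y)$scaled
  expect_lt(max(abs(colMeans(sc))), 1e-12)
  # the stored state reproduces the scaled training matrix
  expect_equal(apply_scaling(y, pareto_scale(y)$state), sc)
})

test_that("PCA agrees with the SVD and separates planted clusters", {
  set.seed(3)
  x <- matrix(rnorm(60), 10, 6)
  xc <- scale(x, scale = FALSE)
  pc <- fit_pca(xc, 3)
  sv <- svd(xc)
  for (k in 1:3) {
    s <- sign(sum(pc$loadings[, k] * sv$v[, k]))
    expect_equal(pc$loadings[, k], s * sv$v[, k], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(pc$scores[, k], s * sv$u[, k] * sv$d[k], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_error(fit_pca(xc, 50), "rank")

  # rank-1 matrix: first component explains everything
  r1 <- tcrossprod(rnorm(8), rnorm(5)) + matrix(rnorm(40, 0, 1e-8), 8, 5)
  expect_gt(fit_pca(r1, 1)$explained[1], 1 - 1e-6)

  # two planted clusters are visible in the score plane
  pm <- planted_matrix(n_per = 30, p = 8, informative = 1:3, effect = 1.8,
                       cv = 0.05, seed = 9)
  sc <- pareto_scale(pm$x)$scaled
  pc2 <- fit_pca(sc, 2)
  expect_gt(silhouette_mean(pc2$scores, pm$labels), 0.3)
})

test_that("OPLS-DA without orthogonal components is PLS1", {
  set.seed(11)
  x <- matrix(rnorm(200), 20, 10)
  y <- rep(c(0, 1), each = 10)
  lab <- ifelse(y == 1, "cancer", "control")
  m <- opls_da(x, lab, n_ortho = 0, scale = "none")
  o <- pls1_oracle(x, y)
  expect_equal(m$w, o$w, tolerance = 1e-8)
  expect_equal(m$t, o$t, tolerance = 1e-8)
  expect_equal(m$p, o$p, tolerance = 1e-8)
  expect_equal(m$c, o$c, tolerance = 1e-8)
})

test_that("orthogonal filtering removes a pure confounder", {
  set.seed(21)
  n <- 20
  p <- 8
  y <- rep(c(0, 1), each = n / 2)
  yc <- y - mean(y)
  lab <- ifelse(y == 1, "cancer", "control")
  a <- rnorm(p)
  b <- a / 2 + rnorm(p)                 # overlaps the predictive direction
  ct <- rnorm(n)
  ct <- ct - mean(ct)
  ct <- ct - yc * sum(ct * yc) / sum(yc^2)  # exactly y-orthogonal scores
  x0 <- outer(yc, a) + matrix(rnorm(n * p, sd = 1e-9), n, p)
  x1 <- x0 + 3 * outer(ct, b)

  m0 <- opls_da(x0, lab, n_ortho = 1, scale = "none")
  m1 <- opls_da(x1, lab, n_ortho = 1, scale = "none")
  # the orthogonal component absorbs the confounder completely
  expect_lt(max(abs(m1$t - m0$t)), 1e-6)
  # while plain PLS1 scores move substantially
  p0 <- pls1_oracle(x0, y)
  p1 <- pls1_oracle(x1, y)
  expect_gt(max(abs(p1$t - p0$t)), 0.5)

  # predictive and orthogonal scores are mutually orthogonal
  expect_lt(abs(sum(m1$t * m1$ortho[[1]]$t)), 1e-8 * sum(m1$t^2))

  # with realistic noise the suppression is partial but still far better
  # than PLS1
  set.seed(22)
  noise <- matrix(rnorm(n * p, sd = 0.3), n, p)
  n0 <- opls_da(x0 + noise, lab, n_ortho = 1, scale = "none")
  n1 <- opls_da(x1 + noise, lab, n_ortho = 1, scale = "none")
  q0 <- pls1_oracle(x0 + noise, y)
  q1 <- pls1_oracle(x1 + noise, y)
  expect_lt(max(abs(n1$t - n0$t)), max(abs(q1$t - q0$t)))
})

test_that("a strongly separated cohort gives a high R2Y and Q2", {
  pm <- planted_matrix(n_per = 25, p = 15, informative = 1:5, effect = 2,
                       cv = 0.05, seed = 31)
  m <- opls_da(pm$x, pm$labels)
  expect_gt(m$r2y, 0.9)
  cv <- cross_validate(pm$x, pm$labels, folds = 7, seed = 1)
  expect_gt(cv$q2, 0.8)
  expect_error(opls_da(pm$x, rep("cancer", 50)), "two classes")
})

test_that("cross-validation is deterministic and honest under null labels", {
  pm <- planted_matrix(seed = 41)
  a <- cross_validate(pm$x, pm$labels, seed = 5)
  b <- cross_validate(pm$x, pm$labels, seed = 5)
  expect_equal(a$q2, b$q2)
  expect_equal(a$fold_assignment, b$fold_assignment)
  expect_error(cross_validate(pm$x[1:8, ], pm$labels[c(1:4, 21:24)],
                              folds = 7), "folds")

  # pure-noise labels: Q2 is not positive in expectation
  q2s <- vapply(1:40, function(s) {
    set.seed(s + 1000)
    x <- matrix(rnorm(30 * 8), 30, 8)
    lab <- sample(rep(c("control", "cancer"), 15))
    cross_validate(x, lab, folds = 5, seed = s)$q2
  }, numeric(1))
  expect_lt(mean(q2s), 0.05)
})

test_that("jack-knife selection keeps signal and rejects noise", {
  # a variable with zero loading in every fold is excluded
  fl <- matrix(0, 7, 3)
  fl[, 1] <- 1
  out <- jackknife_select(c(1, 0, 0), fl)
  expect_true(1 %in% out$retained)
  expect_false(2 %in% out$retained)

  hits_signal <- 0
  hits_noise <- 0
  runs <- 100
  for (s in seq_len(runs)) {
    pm <- planted_matrix(n_per = 20, p = 10, informative = 1, effect = 1.6,
                         cv = 0.08, seed = s + 500)
    m <- opls_da(pm$x, pm$labels)
    cv <- cross_validate(pm$x, pm$labels, folds = 7, seed = s)
    sel <- jackknife_select(m$p, cv$fold_loadings)$retained
    if (1 %in% sel) hits_signal <- hits_signal + 1
    if (!(10 %in% sel)) hits_noise <- hits_noise + 1
  }
  expect_gte(hits_signal / runs, 0.9)
  expect_gte(hits_noise / runs, 0.9)
})

test_that("two-stage variable bookkeeping mirrors the published flow", {
  # 221 QC-passed variables of which 143 fall below the jack-knife
  # threshold leave a 78-variable panel
  set.seed(51)
  p <- 221
  full <- c(rep(1, 78), rep(0.02, 143))
  fl <- matrix(rep(full, each = 7), 7, p) +
    matrix(rnorm(7 * p, 0, 0.05), 7, p)
  out <- jackknife_select(full, fl)
  expect_equal(length(out$retained), 78)
  expect_equal(p - length(out$retained), 143)
})

test_that("VIP scores obey the normalization identity", {
  pm <- planted_matrix(n_per = 20, p = 12, informative = 1:2, effect = 1.6,
                       cv = 0.08, seed = 61)
  m <- opls_da(pm$x, pm$labels)
  v <- vip_scores(m)
  expect_equal(sum(v^2), 12, tolerance = 1e-8)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)

  hits <- vapply(1:40, function(s) {
    pm <- planted_matrix(n_per = 20, p = 12, informative = 1, effect = 1.6,
                         cv = 0.08, seed = s + 700)
    v <- vip_scores(opls_da(pm$x, pm$labels))
    v[1] > 1 && v[1] > v[12]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the S-plot calls directions by the sign of the covariance", {
  pm <- planted_matrix(n_per = 30, p = 8, informative = 1, effect = 1.5,
                       cv = 0.05, seed = 71)
  pm$x[, 2] <- pm$x[, 2] *
    ifelse(pm$labels == "cancer", 0.6, 1)   # decreased variable
  m <- opls_da(pm$x, pm$labels)
  sp <- s_plot(m)
  expect_equal(sp$direction[1], "increased in cancer")
  expect_equal(sp$direction[2], "decreased in cancer")
  expect_true(all(abs(sp$correlation) <= 1 + 1e-12, na.rm = TRUE))

  # zero-variance variable: correlation reported missing
  x2 <- cbind(pm$x, VAR999 = 5)
  suppressWarnings(m2 <- opls_da(x2, pm$labels))
  expect_true(is.na(s_plot(m2)$correlation[9]))
})

test_that("permutation testing separates real from permuted labels", {
  pm <- planted_matrix(n_per = 20, p = 10, informative = 1:3, effect = 1.8,
                       cv = 0.06, seed = 81)
  pt <- permutation_test(pm$x, pm$labels, n_perm = 30, seed = 13)
  expect_lt(pt$summary[["mean_q2_perm"]], 0)
  expect_true(all(pt$q2_perm < pt$q2_real))
  expect_true(all(pt$r2_perm < pt$r2_real))

  pt2 <- permutation_test(pm$x, pm$labels, n_perm = 30, seed = 13)
  expect_equal(pt$q2_perm, pt2$q2_perm)

  # with random labels the real statistics sit inside the null
  set.seed(4242)
  xr <- matrix(rnorm(30 * 8), 30, 8)
  lr <- sample(rep(c("control", "cancer"), 15))
  pt0 <- permutation_test(xr, lr, n_perm = 49, seed = 21)
  frac <- pt0$summary[["frac_q2_above"]]
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.95)
})

test_that("prediction reports the standard classification metrics", {
  pm <- planted_matrix(n_per = 25, p = 10, informative = 1:4, effect = 2.5,
                       cv = 0.03, seed = 91)
  m <- opls_da(pm$x, pm$labels)
  rep_tr <- predict(m, pm$x, labels = pm$labels)
  expect_equal(rep_tr$sensitivity, 100)
  expect_equal(rep_tr$specificity, 100)
  expect_equal(rep_tr$auc, 1)

  # random scores give chance-level AUC
  set.seed(17)
  scores <- rnorm(200)
  truth <- sample(rep(c("control", "cancer"), 100))
  roc <- pROC::roc(response = factor(truth,
                                     levels = c("control", "cancer")),
                   predictor = scores, quiet = TRUE, direction = "<")
  expect_gt(as.numeric(pROC::auc(roc)), 0.42)
  expect_lt(as.numeric(pROC::auc(roc)), 0.58)

  expect_error(predict(m, pm$x[, 1:5]), "column mismatch")
})

test_that("scaling is fit on training data only (no leakage)", {
  pm <- planted_matrix(n_per = 25, p = 6, seed = 101)
  m_a <- opls_da(pm$x[1:40, ], pm$labels[1:40])
  m_b <- opls_da(pm$x[11:50, ], pm$labels[11:50])
  expect_false(isTRUE(all.equal(m_a$scaling$column_means,
                                m_b$scaling$column_means)))
  # prediction applies the stored state, never refits it
  pr <- predict(m_a, pm$x[41:50, ])
  manual <- apply_scaling(pm$x[41:50, ], m_a$scaling)
  for (z in m_a$ortho) manual <- manual - tcrossprod(drop(manual %*% z$w),
                                                     z$p)
  expect_equal(pr$score, drop(manual %*% m_a$w))
})
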