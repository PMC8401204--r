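# shared fixtures, built once per test run
.lib <- load_spin_library()
.tab <- build_region_table(.lib)
.acq_small <- acquisition_params(n_points = 4096)

zero_conc <- function() {
  stats::setNames(rep(0, 62), library_metabolites(.lib))
}

one_met_spec <- function(met, um, tsp = 4, noise = 0, ...) {
  cc <- zero_conc()
  cc[[met]] <- um
  sample_spec(concentrations = cc, tsp_conc = tsp, noise_sd = noise,
              lipid_scale = 0, macromolecule_scale = 0, ...)
}

# independent stick-pattern oracle: discrete convolution of elementary
# binomial patterns, one per letter of the code
conv_oracle <- function(code, j, n_protons) {
  sticks <- data.frame(off = 0, wt = 1)
  letters_ <- strsplit(code, "")[[1]]
  ord <- c(d = 1, t = 2, q = 3, p = 4)
  for (k in seq_along(letters_)) {
    m <- ord[[letters_[k]]]
    sub <- data.frame(off = ((0:m) - m / 2) * j[k], wt = choose(m, 0:m))
    sticks <- do.call(rbind, lapply(seq_len(nrow(sub)), function(r)
      data.frame(off = sticks$off + sub$off[r], wt = sticks$wt * sub$wt[r])))
  }
  agg <- aggregate(wt ~ off, data = transform(sticks, off = round(off, 9)),
                   sum)
  agg <- agg[order(agg$off), ]
  agg$wt <- agg$wt / sum(agg$wt) * n_protons
  agg
}

# independent one-component PLS1 oracle (NIPALS)
pls1_oracle <- function(X, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(X %*% w)
  p <- drop(crossprod(X, t1)) / sum(t1^2)
  cc <- sum(t1 * yc) / sum(t1^2)
  list(w = w, t = t1, p = p, c = cc)
}

# mean silhouette of binary labels on a score matrix
silhouette_mean <- function(scores, labels) {
  d <- as.matrix(dist(scores))
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# two-group feature matrix with planted informative columns (fast,
# integral-free synthetic data for chemometrics property tests)
planted_matrix <- function(n_per = 20, p = 10, informative = 1:2,
                           effect = 1.5, cv = 0.1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  mu <- rep(100, p)
  X <- matrix(rlnorm(n * p, meanlog = log(100), sdlog = sqrt(log(1 + cv^2))),
              n, p)
  lab <- rep(c("control", "cancer"), each = n_per)
  X[lab == "cancer", informative] <- X[lab == "cancer", informative] * effect
  colnames(X) <- sprintf("VAR%03d", seq_len(p))
  list(x = X, labels = lab)
}
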