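#' Pipeline configuration
#'
#' One auditable record of every tunable parameter; the defaults are the
#' standard protocol values (0.8 Hz line broadening, zero-fill factor 4,
#' 4 mM TSP, 53.85 uM MA, calibration at 1.4938 ppm, %RSD thresholds
#' 10 / 30, seven-fold cross-validation, VIP threshold 0.80).
#'
#' @param acq an [acquisition_params()].
#' @param tsp_mm,ma_um sample-prep standard concentrations.
#' @param qc a [qc_config()].
#' @param folds,n_perm,vip_threshold,n_ortho chemometrics settings.
#' @param calibration_target_ppm alanine-doublet calibration target.
#' @param seed master seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(acq = acquisition_params(), tsp_mm = 4,
                            ma_um = 53.85, qc = qc_config(), folds = 7,
                            n_perm = 200, vip_threshold = 0.80, n_ortho = 1,
                            calibration_target_ppm = 1.4938,
                            seed = 20210812L) {
  structure(list(acq = acq, tsp_mm = tsp_mm, ma_um = ma_um, qc = qc,
                 folds = folds, n_perm = n_perm,
                 vip_threshold = vip_threshold, n_ortho = n_ortho,
                 calibration_target_ppm = calibration_target_ppm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build an MA-normalized feature matrix from simulated samples
#'
#' Processes each FID through the standard chain, integrates the 237
#' regions, normalizes to the MA window and assembles a
#' [feature_matrix()].  The calibration offset applied to each spectrum is
#' recorded in the returned log.
#'
#' @param fids list of `nmr_fid`.
#' @param meta sample metadata data frame.
#' @param regions region table.
#' @param config a [pipeline_config()].
#' @return list with `matrix` (feature matrix), `ma` (vector of MA
#'   integrals) and `log` (per-sample calibration offsets).
#' @export
build_feature_matrix <- function(fids, meta, regions,
                                 config = pipeline_config()) {
  maw <- attr(regions, "ma_window") %||% c(5.98, 6.04)
  n <- length(fids)
  vals <- matrix(NA_real_, n, 237,
                 dimnames = list(meta$sample_id, sprintf("VAR%03d", 1:237)))
  mas <- numeric(n)
  offs <- numeric(n)
  for (i in seq_len(n)) {
    sp <- process_spectrum(fids[[i]], phase = "none",
                           calibration_target = config$calibration_target_ppm)
    last <- sp$provenance[[length(sp$provenance)]]
    offs[i] <- last$offset %||% NA_real_
    mas[i] <- ma_integral(sp, maw)
    vals[i, ] <- normalize_to_ma(integrate_regions(sp, regions), mas[i])
  }
  list(matrix = feature_matrix(vals, meta, regions, "ma_normalized"),
       ma = mas,
       log = data.frame(sample_id = meta$sample_id,
                        calibration_offset = offs))
}

#' Run the full classification workflow on feature matrices
#'
#' QC filtering (replicate and cohort %RSD), OPLS-DA training with
#' seven-fold cross-validation, jack-knife variable reduction, refit on the
#' reduced panel, VIP selection, S-plot direction calls, permutation
#' testing, and validation on an independent cohort.  All decisions
#' (scaling, QC, variable selection) are made on the training data only.
#'
#' @param training [feature_matrix()] of the training cohort.
#' @param validation optional [feature_matrix()] of the validation cohort.
#' @param replicates optional [feature_matrix()] of pool replicates for
#'   computed QC.
#' @param config a [pipeline_config()].
#' @param qc_mode `"packaged"` (published exclusion lists) or `"computed"`.
#' @param n_perm permutations (0 skips the permutation test).
#' @return a `workflow_result` list: QC report, trained models (full and
#'   reduced), Q2, jack-knife selection, VIP table, S-plot, permutation
#'   summary and validation report.
#' @export
run_workflow <- function(training, validation = NULL, replicates = NULL,
                         config = pipeline_config(),
                         qc_mode = c("packaged", "computed"),
                         n_perm = config$n_perm) {
  qc_mode <- match.arg(qc_mode)
  qc <- apply_qc_filters(training, replicates, config$qc, mode = qc_mode)
  xtr <- qc$filtered$values
  lab <- training$sample_meta$group

  model_full <- opls_da(xtr, lab, n_ortho = config$n_ortho)
  cv_full <- cross_validate(xtr, lab, folds = config$folds,
                            seed = config$seed, n_ortho = config$n_ortho)
  jk <- jackknife_select(model_full$p, cv_full$fold_loadings)
  if (!length(jk$retained)) {
    warning("jack-knife selection retained no variables; keeping all")
    jk$retained <- seq_len(ncol(xtr))
  }
  kept_vars <- colnames(xtr)[jk$retained]
  xred <- xtr[, jk$retained, drop = FALSE]

  model <- opls_da(xred, lab, n_ortho = config$n_ortho)
  cv <- cross_validate(xred, lab, folds = config$folds, seed = config$seed,
                       n_ortho = config$n_ortho)
  pca <- fit_pca(pareto_scale(xred)$scaled, n_components = 2)
  vip <- vip_scores(model)
  spl <- s_plot(model)
  train_report <- predict(model, xred, labels = lab)

  perm <- if (n_perm > 0)
    permutation_test(xred, lab, n_perm = n_perm, seed = config$seed,
                     folds = config$folds, n_ortho = config$n_ortho)
  else NULL

  val_report <- NULL
  if (!is.null(validation)) {
    xv <- validation$values[, colnames(xtr), drop = FALSE]
    xv <- xv[, jk$retained, drop = FALSE]
    val_report <- predict(model, xv, labels = validation$sample_meta$group)
  }

  structure(list(qc = qc, n_after_qc = ncol(xtr),
                 n_after_jackknife = length(kept_vars),
                 kept_vars = kept_vars,
                 model_full = model_full, q2_full = cv_full$q2,
                 model = model, q2 = cv$q2, pca = pca,
                 vip = vip, s_plot = spl,
                 vip_threshold = config$vip_threshold,
                 train_report = train_report,
                 permutation = perm, validation = val_report),
            class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("Workflow result\n")
  cat(sprintf("  QC: 237 -> %d variables; jack-knife: -> %d variables\n",
              x$n_after_qc, x$n_after_jackknife))
  cat(sprintf("  R2X(cum) %.3f  R2Y(cum) %.3f  Q2(cum) %.3f\n",
              x$model$r2x, x$model$r2y, x$q2))
  cat(sprintf("  training: specificity %.0f%%, sensitivity %.0f%%, AUC %.2f\n",
              x$train_report$specificity, x$train_report$sensitivity,
              x$train_report$auc))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation: mean R2 %.3f, mean Q2 %.3f\n",
                x$permutation$summary[["mean_r2_perm"]],
                x$permutation$summary[["mean_q2_perm"]]))
  if (!is.null(x$validation))
    cat(sprintf("  validation: specificity %.0f%%, sensitivity %.0f%%, AUC %.2f\n",
                x$validation$specificity, x$validation$sensitivity,
                x$validation$auc))
  invisible(x)
}

#' Simulate a complete study and write it to disk
#'
#' Writes training and validation cohort FIDs, pool replicates, sample
#' metadata and a seed manifest under `out_dir`.  Re-running with the same
#' configuration reproduces the files exactly.
#'
#' @param out_dir output directory (created if missing).
#' @param train,valid [cohort_spec()]s for the two cohorts.
#' @param n_replicates pool replicates.
#' @param config a [pipeline_config()].
#' @param library,binding spin library and binding model.
#' @return invisibly, the manifest data frame.
#' @export
cmd_simulate <- function(out_dir, train = cohort_spec(),
                         valid = cohort_spec(n_cancer = 34, n_control = 38,
                                             cohort_label = "validation",
                                             seed = 20210813L),
                         n_replicates = 12,
                         config = pipeline_config(),
                         library = load_spin_library(),
                         binding = binding_model()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  base <- sample_spec(tsp_conc = config$tsp_mm, ma_conc = config$ma_um)
  tr <- generate_cohort(train, library, binding, config$acq, base)
  va <- generate_cohort(valid, library, binding, config$acq, base)
  reps <- generate_replicates(n_replicates, base, library, binding,
                              config$acq, seed = config$seed)
  meta <- rbind(tr$samples, va$samples,
                data.frame(sample_id = sprintf("pool_%02d",
                                               seq_len(n_replicates)),
                           group = "pool", cohort = "pool",
                           hemolytic = FALSE,
                           seed = vapply(reps, function(f) f$sample$seed,
                                         numeric(1))))
  fids <- c(tr$fids, va$fids, reps)
  for (i in seq_len(nrow(meta)))
    write_fid_csv(fids[[i]], file.path(out_dir,
                                       paste0(meta$sample_id[i], ".csv")))
  utils::write.csv(meta, file.path(out_dir, "samples.csv"),
                   row.names = FALSE)
  manifest <- data.frame(key = c("train_seed", "valid_seed", "master_seed"),
                         value = c(train$seed, valid$seed, config$seed))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Run the workflow on a simulated study directory
#'
#' Reads the FIDs and metadata written by [cmd_simulate()], builds the
#' feature matrices and executes [run_workflow()]; writes the feature
#' matrix, QC report and a plain-text model summary under `out_dir`.
#'
#' @param spectra_dir directory produced by [cmd_simulate()].
#' @param out_dir output directory.
#' @param regions region table.
#' @param config a [pipeline_config()].
#' @param qc_mode forwarded to [run_workflow()].
#' @return the `workflow_result`, invisibly.
#' @export
cmd_run <- function(spectra_dir, out_dir, regions,
                    config = pipeline_config(),
                    qc_mode = "packaged") {
  meta <- utils::read.csv(file.path(spectra_dir, "samples.csv"),
                          stringsAsFactors = FALSE)
  read1 <- function(id) read_fid_csv(file.path(spectra_dir,
                                               paste0(id, ".csv")),
                                     acq = config$acq)
  sets <- split(meta, meta$cohort)
  fm <- lapply(sets, function(m)
    build_feature_matrix(lapply(m$sample_id, read1), m, regions, config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- run_workflow(fm$training$matrix,
                      validation = fm$validation$matrix,
                      replicates = fm$pool$matrix,
                      config = config, qc_mode = qc_mode)
  write_feature_matrix(fm$training$matrix,
                       file.path(out_dir, "training_features.csv"))
  utils::write.csv(res$qc$report, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(fm, `[[`, "log")),
                   file.path(out_dir, "calibration_log.csv"),
                   row.names = FALSE)
  sink(file.path(out_dir, "summary.txt"))
  print(res)
  sink()
  invisible(res)
}

#' Text report of a workflow result
#'
#' Prints the model metrics, the retained variables with VIP score and
#' S-plot direction, and the VIP table truncated at the selection
#' threshold.
#'
#' @param result a `workflow_result`.
#' @param vip_threshold VIP cut-off (default from the run configuration).
#' @return invisibly, the VIP table data frame.
#' @export
cmd_report <- function(result, vip_threshold = result$vip_threshold) {
  print(result)
  tab <- data.frame(variable = names(result$vip), vip = result$vip,
                    direction = result$s_plot$direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[tab$vip > vip_threshold, ]
  tab <- tab[order(-tab$vip), ]
  if (nrow(tab) == 0) {
    cat("no variables selected at VIP >", vip_threshold, "\n")
  } else {
    cat(sprintf("\n%d variables with VIP > %.2f:\n", nrow(tab),
                vip_threshold))
    print(tab, row.names = FALSE)
  }
  invisible(tab)
}
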