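#' Extract the 14-feature vector from one recording
#'
#' Runs the full per-subject chain and assembles the classifier features:
#' * `template_score` -- matched-filter similarity, 0.08-5 Hz band;
#' * `threshold_surface` -- area beyond the +/- 0.35 thresholds, 0.08-5 Hz;
#' * `dispen` -- dispersion entropy, 0.08-5 Hz;
#' * `h2` -- left-right nonlinear correlation, 0.08-5 Hz;
#' * `mde_s1` .. `mde_s10` -- multiscale dispersion entropy, scales 1-10,
#'   0.08-25 Hz band.
#'
#' Single-channel features are computed on each eye and averaged
#' (`config$channel_mode`). Any stage failure leaves `NA` in the affected
#' slot and a message in the `"flags"` attribute; nothing is silently
#' imputed.
#'
#' @param recording a `gaze_recording`.
#' @param config a [default_config()] list.
#' @return Object of class `feature_vector`: named numeric of length 14
#'   with attributes `id` and `label`.
#' @export
extract_features <- function(recording, config = default_config()) {
  stopifnot(inherits(recording, "gaze_recording"))
  fs <- recording$fs
  spec_low <- filter_spec(config$bands$low, fs, config$fir_order)
  spec_wide <- filter_spec(config$bands$wide, fs, config$fir_order)

  chans <- list(left = recording$left_x, right = recording$right_x)
  low <- lapply(chans, preprocess_channel, spec = spec_low, config = config)
  wide <- lapply(chans, preprocess_channel, spec = spec_wide, config = config)

  combine <- switch(config$channel_mode,
    mean = function(v) mean(unlist(v)),
    left = function(v) v$left,
    right = function(v) v$right,
    stop("unknown channel_mode", call. = FALSE))

  flags <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      flags <<- c(flags, paste0(name, ": ", conditionMessage(e)))
      NA_real_
    })
  }

  tpl <- ideal_template(fs, hold_s = config$template$hold_s,
                        rise_s = config$template$rise_s)
  en <- config$entropy

  template_score <- grab("template_score", combine(lapply(low, function(ch) {
    suppressWarnings(matched_filter_score(
      ch, template = tpl, fs = fs,
      min_separation = config$template$min_separation,
      n_extrema = config$template$n_extrema,
      select = config$template$select)$score)
  })))
  surface <- grab("threshold_surface", combine(lapply(low, function(ch) {
    threshold_surface(ch, fs, thr_pos = config$threshold,
                      thr_neg = -config$threshold)
  })))
  dispen <- grab("dispen", combine(lapply(low, function(ch) {
    dispersion_entropy(ch, m = en$m, c = en$c, d = en$d)
  })))
  h2 <- grab("h2", nonlinear_correlation_h2(low$left, low$right,
                                            n_bins = config$connectivity$n_bins))
  mde <- grab("mde", {
    per_chan <- lapply(wide, function(ch) {
      multiscale_profile(ch, "mde", m = en$m, c = en$c, d = en$d,
                         tau_max = config$tau_max,
                         band = config$bands$wide)$values
    })
    if (config$channel_mode == "mean") {
      (per_chan$left + per_chan$right) / 2
    } else per_chan[[config$channel_mode]]
  })
  if (length(mde) == 1 && is.na(mde)) mde <- rep(NA_real_, config$tau_max)

  out <- c(template_score = template_score, threshold_surface = surface,
           dispen = dispen, h2 = h2,
           stats::setNames(mde, paste0("mde_s", seq_len(config$tau_max))))
  structure(out, id = recording$id %||% NA_character_,
            label = recording$label, flags = flags,
            class = "feature_vector")
}

#' Feature table for a cohort
#'
#' Applies [extract_features()] to every recording and binds the results
#' into a data frame with `id` and `label` columns.
#'
#' @param recordings list of `gaze_recording` objects (as from
#'   [generate_cohort()] or [read_cohort()]).
#' @param config a [default_config()] list.
#' @return Data frame: `id`, `label`, then one column per feature.
#' @export
feature_table <- function(recordings, config = default_config()) {
  stopifnot(length(recordings) > 0)
  ids <- names(recordings) %||% paste0("subj_", seq_along(recordings))
  rows <- lapply(seq_along(recordings), function(i) {
    fv <- extract_features(recordings[[i]], config)
    cbind(data.frame(id = ids[i],
                     label = attr(fv, "label") %||% NA_character_),
          as.data.frame(as.list(unclass(fv))))
  })
  do.call(rbind, rows)
}

#' PCA reduction to a cumulative-variance target
#'
#' Standardizes the feature matrix (zero mean, unit variance per column;
#' constant columns are dropped with a warning), fits principal
#' components, and keeps the smallest number of components whose
#' cumulative explained variance reaches `variance_target`.
#'
#' @param features numeric matrix or data frame (subjects x features).
#' @param variance_target cumulative explained-variance fraction
#'   (default 0.95).
#' @return Object of class `pca_reduction`: `scores` (reduced matrix),
#'   `n_components`, `explained_variance` (cumulative at the kept count),
#'   `rotation`, `center`, `scale`, `dropped` (constant columns).
#' @export
reduce_pca <- function(features, variance_target = 0.95) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("`features` must be numeric", call. = FALSE)
  if (anyNA(X)) stop("`features` contains missing values; handle flagged slots first",
                     call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(X)
  Xs <- scale(X, center = ctr, scale = sds)
  pca <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- which(cumvar >= variance_target)[1]
  if (is.na(k)) k <- length(cumvar)
  structure(list(scores = pca$x[, seq_len(k), drop = FALSE],
                 n_components = k, explained_variance = cumvar[k],
                 cumulative_variance = cumvar,
                 rotation = pca$rotation[, seq_len(k), drop = FALSE],
                 center = ctr, scale = sds, dropped = dropped),
            class = "pca_reduction")
}

# Project new data through a fitted pca_reduction.
apply_pca <- function(model, newdata) {
  X <- as.matrix(newdata)
  X <- X[, names(model$center), drop = FALSE]
  scale(X, center = model$center, scale = model$scale) %*% model$rotation
}

# Seeded stratified fold assignment.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit and evaluate the PCA + linear-SVM classifier
#'
#' Stratified k-fold cross-validation (default 10-fold) with seeded
#' shuffling. Within every training fold -- and only there -- features are
#' standardized, PCA is fitted and truncated at `variance_target`
#' cumulative explained variance, and a linear support vector machine
#' (fixed cost `cost`) is trained; the held-out fold is projected through
#' the training-fold transforms and predicted. Metrics are reported on
#' the pooled held-out predictions, with dysmetria as the positive class;
#' per-fold accuracies and mean-fold accuracy are also returned.
#'
#' @param features numeric matrix / data frame (subjects x features).
#' @param labels factor or character vector; must contain both classes.
#' @param k_folds number of folds (default 10).
#' @param variance_target PCA cumulative-variance target (default 0.95).
#' @param seed fold-shuffling seed.
#' @param cost SVM regularization constant (default 1).
#' @param positive positive-class label (default `"dysmetric"`).
#' @return Object of class `classifier_report`: `accuracy`,
#'   `sensitivity`, `specificity` (pooled fractions),
#'   `mean_fold_accuracy`, `confusion` (2x2 counts), `folds` (per-fold
#'   data frame with accuracy, components kept, explained variance),
#'   `n`, `seed`.
#' @export
fit_evaluate <- function(features, labels, k_folds = 10,
                         variance_target = 0.95, seed = 1, cost = 1,
                         positive = "dysmetric") {
  X <- as.matrix(features)
  labels <- as.character(labels)
  if (anyNA(X)) stop("`features` contains missing values", call. = FALSE)
  if (length(unique(labels)) != 2) {
    stop("`labels` must contain exactly two classes", call. = FALSE)
  }
  if (!positive %in% labels) stop("positive class absent from `labels`", call. = FALSE)
  negative <- setdiff(unique(labels), positive)
  n <- nrow(X)
  fold <- stratified_folds(labels, k_folds, seed)
  pred <- character(n)
  fold_rows <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(labels[tr])) < 2) {
      stop("a training fold lost one class; reduce k_folds", call. = FALSE)
    }
    red <- suppressWarnings(reduce_pca(X[tr, , drop = FALSE], variance_target))
    svm_fit <- e1071::svm(x = red$scores,
                          y = factor(labels[tr], levels = c(positive, negative)),
                          kernel = "linear", cost = cost, scale = FALSE)
    if (any(te)) {
      pred[te] <- as.character(stats::predict(svm_fit,
                                              apply_pca(red, X[te, , drop = FALSE])))
    }
    fold_rows[[f]] <- data.frame(
      fold = f, n_test = sum(te),
      accuracy = if (any(te)) mean(pred[te] == labels[te]) else NA_real_,
      n_components = red$n_components,
      explained_variance = red$explained_variance)
  }
  folds <- do.call(rbind, fold_rows)
  tp <- sum(pred == positive & labels == positive)
  tn <- sum(pred == negative & labels == negative)
  fp <- sum(pred == positive & labels == negative)
  fn <- sum(pred == negative & labels == positive)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(predicted = c(positive, negative),
                                      actual = c(positive, negative)))
  structure(list(
    accuracy = (tp + tn) / n,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    mean_fold_accuracy = mean(folds$accuracy, na.rm = TRUE),
    confusion = confusion, folds = folds, n = n, seed = seed,
    positive = positive
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> n = %d | accuracy %.1f%% (sensitivity %.1f%%, specificity %.1f%%)\n",
    x$n, 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  components kept per fold: %s\n",
              paste(x$folds$n_components, collapse = " ")))
  invisible(x)
}

#' Run the full pipeline on a directory of recordings
#'
#' Reads every recording CSV in `input_dir` (with its JSON sidecar),
#' excludes recordings shorter than `config$min_duration` seconds (the
#' exclusion count is logged, mirroring the fixed minimum recording
#' length of the protocol), extracts features, compares groups
#' per feature, fits and evaluates the classifier, and writes
#' `features.csv`, `group_stats.csv`, `report.json` and `params.json`
#' to `out_dir`.
#'
#' @param input_dir directory of `*.csv` recordings + `*.json` sidecars.
#' @param out_dir output directory (created if needed).
#' @param config a [default_config()] list.
#' @param seed cross-validation seed.
#' @return Invisibly, a list with `features`, `group_stats`, `report`,
#'   `excluded` (ids), `config`.
#' @export
run_pipeline <- function(input_dir, out_dir, config = default_config(),
                         seed = 1) {
  recs <- read_cohort(input_dir)
  durations <- vapply(recs, function(r) r$duration, numeric(1))
  keep <- durations >= config$min_duration
  excluded <- names(recs)[!keep]
  if (length(excluded)) {
    message(length(excluded), " recording(s) below ", config$min_duration,
            " s excluded: ", paste(excluded, collapse = ", "))
  }
  recs <- recs[keep]
  if (!length(recs)) stop("no usable recordings", call. = FALSE)
  feats <- feature_table(recs, config)
  stats_tab <- compare_groups(feats)
  fm <- as.matrix(feats[, setdiff(names(feats), c("id", "label"))])
  report <- fit_evaluate(fm, feats$label,
                         k_folds = config$cv$k_folds,
                         variance_target = config$cv$variance_target,
                         seed = seed, cost = config$cv$cost)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(stats_tab, file.path(out_dir, "group_stats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = report$accuracy, sensitivity = report$sensitivity,
         specificity = report$specificity,
         mean_fold_accuracy = report$mean_fold_accuracy,
         confusion = report$confusion, folds = report$folds,
         n = report$n, seed = report$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(config = config, seed = seed,
                            n_excluded = length(excluded),
                            excluded = excluded),
                       file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(features = feats, group_stats = stats_tab, report = report,
                 excluded = excluded, config = config))
}
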