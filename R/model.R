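#' Stratified train/test split
#'
#' Splits a labeled feature table into training and test sets, stratified by
#' label so that each class contributes `ratio` of its samples (to within one
#' sample) to the training set.
#'
#' @param data tibble with a label column and feature columns.
#' @param ratio training fraction in `(0, 1)`.
#' @param seed integer seed.
#' @param label name of the label column (default `"hrd_truth"`).
#' @return list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, ratio = 0.7, seed = 1, label = "hrd_truth") {
  if (ratio <= 0 || ratio >= 1) {
    abort("`ratio` must lie strictly inside (0, 1).",
          class = "scarvalid_config_error")
  }
  y <- data[[label]]
  if (any(table(y) < 2)) {
    abort("each class needs at least 2 samples to split.",
          class = "scarvalid_config_error")
  }
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_len(nrow(data)), y), function(ix) {
    sample(ix, round(length(ix) * ratio))
  }), use.names = FALSE)
  list(train = data[sort(train_idx), , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), train_idx), , drop = FALSE])
}

feature_cols <- function(data, label = "hrd_truth") {
  setdiff(names(data), c("sample_id", "specimen_id", label, "purity",
                         "disease", "biomarker_truth"))
}

#' Train the gradient-boosted scar classifier
#'
#' Fits an extreme-gradient-boosting (XGB) tree ensemble on scar features
#' against the binary HRD truth label, producing scores in `[0, 1]` that
#' estimate the probability of a profile being HRD-positive. Hyperparameter
#' defaults are sized for cohorts of a few hundred samples: shallow trees
#' (depth 3) and a few hundred boosting rounds at a moderate learning rate.
#'
#' @param train tibble with `hrd_truth` ("positive"/"negative") and feature
#'   columns (as produced by [scar_feature_matrix()]).
#' @param nrounds,max_depth,eta xgboost hyperparameters.
#' @param cutoff initial positivity cutoff; typically recalibrated with
#'   [select_cutoff()].
#' @param seed integer seed; training is single-threaded and deterministic
#'   under the seed.
#' @param schema_version feature schema the model expects at predict time.
#' @return object of class `hrd_model`.
#' @export
train_hrd_model <- function(train, nrounds = 150, max_depth = 3, eta = 0.1,
                            cutoff = 0.7, seed = 1,
                            schema_version = attr(train, "schema_version") %||% "1.0") {
  y <- as.integer(train$hrd_truth == "positive")
  if (length(unique(y)) < 2) {
    abort("training set must contain both classes.",
          class = "scarvalid_config_error")
  }
  feats <- feature_cols(train)
  X <- as.matrix(train[, feats, drop = FALSE])
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(
    booster = booster,
    features = feats,
    schema_version = schema_version,
    cutoff = cutoff,
    meta = list(n_pos = sum(y == 1), n_neg = sum(y == 0), seed = seed,
                hyperparams = list(nrounds = nrounds, max_depth = max_depth,
                                   eta = eta))
  ), class = "hrd_model")
}

#' Serialize / restore a fitted HRD model
#'
#' The booster is stored in xgboost's raw format alongside the feature
#' schema, cutoff and training metadata.
#'
#' @param model an `hrd_model`.
#' @param path file path.
#' @return `write_hrd_model` returns `path` invisibly; `read_hrd_model`
#'   returns the restored `hrd_model`.
#' @export
write_hrd_model <- function(model, path) {
  obj <- list(raw = xgboost::xgb.save.raw(model$booster),
              features = model$features,
              schema_version = model$schema_version,
              cutoff = model$cutoff, meta = model$meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_hrd_model
#' @export
read_hrd_model <- function(path) {
  obj <- readRDS(path)
  structure(list(booster = xgboost::xgb.load.raw(obj$raw),
                 features = obj$features,
                 schema_version = obj$schema_version,
                 cutoff = obj$cutoff, meta = obj$meta),
            class = "hrd_model")
}

#' Score profiles with a fitted HRD model
#'
#' @param object an `hrd_model`.
#' @param newdata tibble of features ([scar_feature_matrix()] output).
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict.hrd_model <- function(object, newdata, ...) {
  sv <- attr(newdata, "schema_version")
  if (!is.null(sv) && !identical(sv, object$schema_version)) {
    abort(paste0("feature schema version ", sv,
                 " does not match the model's ", object$schema_version, "."),
          class = "scarvalid_input_error")
  }
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  as.numeric(predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Tidy a fitted HRD model into its feature importances
#'
#' @param x an `hrd_model`.
#' @param ... unused.
#' @return tibble with `feature`, `gain`, `cover`, `frequency`.
#' @export
#' @method tidy hrd_model
tidy.hrd_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  as_tibble(imp) |>
    rename(feature = "Feature", gain = "Gain", cover = "Cover",
           frequency = "Frequency")
}

#' One-row training summary of a fitted HRD model
#'
#' @param x an `hrd_model`.
#' @param ... unused.
#' @return one-row tibble of training metadata.
#' @export
#' @method glance hrd_model
glance.hrd_model <- function(x, ...) {
  tibble(n_pos = x$meta$n_pos, n_neg = x$meta$n_neg, cutoff = x$cutoff,
         nrounds = x$meta$hyperparams$nrounds,
         max_depth = x$meta$hyperparams$max_depth,
         eta = x$meta$hyperparams$eta,
         schema_version = x$schema_version)
}

#' @export
print.hrd_model <- function(x, ...) {
  cat("<hrd_model> gradient-boosted scar classifier\n")
  cat(sprintf("  trained on %d positive / %d negative samples\n",
              x$meta$n_pos, x$meta$n_neg))
  cat(sprintf("  %d features (schema %s), cutoff %.4f\n",
              length(x$features), x$schema_version, x$cutoff))
  invisible(x)
}

#' Calibrate the positivity cutoff to a target sensitivity
#'
#' Returns the largest threshold `t` such that the fraction of positive
#' samples with score `>= t` is at least `target_sensitivity`; ties resolve
#' toward the larger threshold. The production-style convention of a fixed
#' prespecified cutoff (e.g. 0.7) can be restored by overriding the model's
#' `cutoff` field.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels labels, `"positive"`/`"negative"` (or logical).
#' @param target_sensitivity required sensitivity among positives.
#' @return the calibrated cutoff.
#' @export
select_cutoff <- function(scores, labels, target_sensitivity = 0.9) {
  pos <- scores[labels == "positive" | labels == TRUE]
  if (!length(pos)) abort("no positive labels.", class = "scarvalid_config_error")
  cand <- sort(unique(pos), decreasing = TRUE)
  for (t in cand) {
    if (mean(pos >= t) >= target_sensitivity) return(t)
  }
  min(pos)
}

#' Three-state HRD call from a score
#'
#' A replicate that failed QC is `unknown` (reason `qc_fail`, score absent);
#' a valid replicate whose effective tumor purity is below the purity floor
#' (default 10%) is `unknown` (reason `low_purity`); otherwise the call is
#' `positive` when `score >= cutoff` (ties at the cutoff count positive) and
#' `negative` below it. A missing purity (e.g. a normal-tissue blank with no
#' tumor compartment) skips the purity gate.
#'
#' @param score score in `[0, 1]`, or `NA` when QC failed.
#' @param effective_purity effective tumor purity (possibly `NA`).
#' @param qc_valid logical QC flag.
#' @param cutoff positivity cutoff in `(0, 1)`.
#' @param purity_floor minimum effective purity for a determinate call.
#' @return tibble with columns `score`, `call`
#'   (`positive`/`negative`/`unknown`) and `reason` (`ok`/`low_purity`/
#'   `qc_fail`); vectorized over its first three arguments.
#' @export
make_call <- function(score, effective_purity, qc_valid, cutoff = 0.7,
                      purity_floor = 0.1) {
  if (cutoff <= 0 || cutoff >= 1) {
    abort("`cutoff` must lie strictly inside (0, 1).",
          class = "scarvalid_config_error")
  }
  n <- max(length(score), length(effective_purity), length(qc_valid))
  score <- rep_len(score, n)
  effective_purity <- rep_len(effective_purity, n)
  qc_valid <- rep_len(qc_valid, n)
  if (any(qc_valid & is.na(score) &
          (is.na(effective_purity) | effective_purity >= purity_floor))) {
    abort("score is absent for a valid replicate above the purity floor.",
          class = "scarvalid_input_error")
  }
  low_purity <- !is.na(effective_purity) & effective_purity < purity_floor
  reason <- dplyr::case_when(!qc_valid ~ "qc_fail",
                             low_purity ~ "low_purity",
                             TRUE ~ "ok")
  call <- dplyr::case_when(
    reason != "ok" ~ "unknown",
    score >= cutoff ~ "positive",
    TRUE ~ "negative"
  )
  tibble(score = ifelse(qc_valid, score, NA_real_), call = call,
         reason = reason)
}

#' Score and call every replicate in a manifest
#'
#' Extracts scar features from each valid replicate's observed profile,
#' scores them with the model, and applies [make_call()] with the model's
#' cutoff. Invalid replicates get `unknown` calls with no score.
#'
#' @param manifest replicate tibble with list-column `observed_profile` and
#'   columns `qc_valid`, `effective_purity`.
#' @param model an `hrd_model`.
#' @param genome the `genome_model` the profiles live on.
#' @param config the [feature_config()] used at training time.
#' @param purity_floor minimum effective purity for a determinate call.
#' @return the manifest with `score`, `call`, `reason` filled in.
#' @export
score_replicates <- function(manifest, model, genome,
                             config = feature_config(), purity_floor = 0.1) {
  valid <- which(manifest$qc_valid %in% TRUE)
  scores <- rep(NA_real_, nrow(manifest))
  if (length(valid)) {
    fx <- scar_feature_matrix(
      tibble(sample_id = manifest$replicate_id[valid],
             profile = manifest$observed_profile[valid]),
      genome, config)
    scores[valid] <- predict(model, fx)
  }
  res <- make_call(scores, manifest$effective_purity,
                   manifest$qc_valid %in% TRUE, cutoff = model$cutoff,
                   purity_floor = purity_floor)
  manifest$score <- res$score
  manifest$call <- res$call
  manifest$reason <- res$reason
  manifest
}
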