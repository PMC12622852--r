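#' Train and calibrate the scar classifier end to end
#'
#' Simulates a labeled cohort, extracts scar features, splits 7:3 stratified
#' by label, trains the gradient-boosted classifier on the training part,
#' and calibrates the positivity cutoff on the held-out part to the target
#' sensitivity (default 90%). The model's `cutoff` field holds the
#' calibrated value; pass `fixed_cutoff` to override it with a prespecified
#' threshold such as 0.7.
#'
#' @param genome a `genome_model`.
#' @param params a [scar_params()].
#' @param n_pos,n_neg cohort class sizes.
#' @param ratio training fraction.
#' @param target_sensitivity sensitivity target for cutoff calibration.
#' @param fixed_cutoff optional prespecified cutoff overriding calibration.
#' @param config a [feature_config()].
#' @param seed integer seed.
#' @return list with `model` (`hrd_model`), `holdout` (tibble of held-out
#'   scores and labels) and `holdout_auc`.
#' @export
train_hrd_caller <- function(genome = build_genome(), params = scar_params(),
                             n_pos = 200, n_neg = 200, ratio = 0.7,
                             target_sensitivity = 0.9, fixed_cutoff = NULL,
                             config = feature_config(), seed = 1) {
  cohort <- simulate_cohort(n_pos, n_neg, params, genome, seed = seed)
  fx <- scar_feature_matrix(cohort, genome, config)
  fx$hrd_truth <- cohort$hrd_truth
  attr(fx, "schema_version") <- config$schema_version
  parts <- split_train_test(fx, ratio, seed = sv_seed(seed, 71))
  model <- train_hrd_model(parts$train, seed = sv_seed(seed, 72),
                           schema_version = config$schema_version)
  scores <- predict(model, parts$test)
  model$cutoff <- select_cutoff(scores, parts$test$hrd_truth,
                                target_sensitivity)
  if (!is.null(fixed_cutoff)) model$cutoff <- fixed_cutoff
  holdout <- tibble(sample_id = parts$test$sample_id,
                    hrd_truth = parts$test$hrd_truth, score = scores)
  list(model = model, holdout = holdout, holdout_auc = auc_scores(scores, parts$test$hrd_truth))
}

#' Area under the ROC curve from scores and labels
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with ties counted half.
#'
#' @param scores numeric scores.
#' @param labels `"positive"`/`"negative"` labels (or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc_scores <- function(scores, labels) {
  pos <- labels == "positive" | labels == TRUE
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

pct <- function(x) round_half_up(100 * x, 2)

#' Run one validation study end to end
#'
#' Orchestrates simulate -> feature extraction -> score/call -> validation
#' statistics for one study design, optionally writing the manifest and
#' report tables to `out_dir`. Reruns with the same configuration and seed
#' are byte-identical.
#'
#' @param study study type, see [study_design()].
#' @param model a fitted `hrd_model`; trained internally when `NULL`.
#' @param design optional design overrides (see [generate_study_cohort()]).
#' @param params a [scar_params()].
#' @param genome a `genome_model`.
#' @param config a [feature_config()].
#' @param cutoff_override positivity cutoff applied at call time (default
#'   the prespecified 0.7); `NULL` keeps the model's calibrated cutoff.
#' @param seed integer seed for cohort generation.
#' @param out_dir optional output directory for TSV/CSV/JSON artifacts.
#' @param quiet suppress stage messages.
#' @return list of class `study_result` with `study`, `manifest` (scored),
#'   `specimens`, `stats` (study-specific tibbles) and `summary` (flat list
#'   of headline numbers, percentages on the 0-100 scale).
#' @export
run_study <- function(study = c("lob", "lod", "precision", "concordance",
                                "interference"),
                      model = NULL, design = NULL, params = scar_params(),
                      genome = build_genome(), config = feature_config(),
                      cutoff_override = 0.7, seed = 1, out_dir = NULL,
                      quiet = FALSE) {
  study <- match.arg(study)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "scarvalid_stage_error")
    })
  }
  if (is.null(model)) {
    say("[train] fitting scar classifier (seed %d)", sv_seed(seed, 7))
    model <- stage("train", train_hrd_caller(genome, params,
                                             seed = sv_seed(seed, 7))$model)
  }
  if (!is.null(cutoff_override)) model$cutoff <- cutoff_override
  say("[simulate] generating %s cohort (seed %d)", study, seed)
  cohort <- stage("simulate",
                  generate_study_cohort(study, design, params, genome, seed))
  say("[score] scoring %d replicates", nrow(cohort$manifest))
  manifest <- stage("score",
                    score_replicates(cohort$manifest, model, genome, config))
  say("[validate] computing %s statistics", study)
  stats <- stage("validate",
                 study_statistics(study, manifest, cohort$specimens))
  result <- structure(list(study = study, manifest = manifest,
                           specimens = cohort$specimens, model = model,
                           stats = stats$tables, summary = stats$summary,
                           seed = seed),
                      class = "study_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, file.path(out_dir, paste0(study, "_manifest.tsv")))
    for (nm in names(stats$tables)) {
      readr::write_csv(stats$tables[[nm]],
                       file.path(out_dir, paste0(study, "_", nm, ".csv")))
    }
    jsonlite::write_json(c(list(study = study, seed = seed), stats$summary),
                         file.path(out_dir, paste0(study, "_summary.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

study_statistics <- function(study, manifest, specimens) {
  switch(study,
    lob = {
      overall <- lob_fpr(manifest)
      per <- manifest |>
        group_by(.data$specimen_id) |>
        group_modify(~ lob_fpr(.x)) |>
        ungroup()
      report <- bind_rows(
        mutate(overall, analysis = "overall", specimen_id = "overall"),
        mutate(per, analysis = "sample")
      ) |>
        mutate(fpr_pct = pct(.data$estimate)) |>
        select("analysis", "specimen_id", "x", "n", "fpr_pct", "lower", "upper")
      list(tables = list(fpr = report),
           summary = list(fpr_pct = pct(overall$estimate),
                          n_valid = overall$n))
    },
    lod = {
      levels <- dilution_level_summary(manifest, specimens)
      lod <- determine_lod(levels)
      list(tables = list(levels = mutate(levels,
                                         hit_rate_pct = pct(.data$hit_rate),
                                         adjusted_tp_pct = pct(.data$mean_adjusted_tp)),
                         lod = mutate(lod$per_specimen,
                                      adjusted_tp_pct = pct(.data$mean_adjusted_tp))),
           summary = list(lod_tp_pct = pct(lod$lod),
                          n_replicates = nrow(manifest)))
    },
    concordance = {
      calls <- manifest |>
        filter(.data$qc_valid %in% TRUE) |>
        left_join(specimens[, c("specimen_id", "biomarker_truth")],
                  by = "specimen_id")
      tab <- contingency_table(calls)
      pn <- concordance_ppa_npa(tab)
      pn_u <- concordance_ppa_npa(tab, include_unknown_in_npa = TRUE)
      report <- bind_rows(pn, mutate(pn_u[pn_u$metric == "npa", ],
                                     metric = "npa_incl_unknown")) |>
        mutate(pct = pct(.data$estimate))
      list(tables = list(contingency = tab, agreement = report),
           summary = list(ppa_pct = pct(pn$estimate[pn$metric == "ppa"]),
                          npa_pct = pct(pn$estimate[pn$metric == "npa"]),
                          npa_incl_unknown_pct =
                            pct(pn_u$estimate[pn_u$metric == "npa"])))
    },
    precision = {
      rep_stats <- reproducibility(manifest)
      rpt <- repeatability(manifest)
      per <- rep_stats$per_specimen |>
        mutate(reproducibility_pct = pct(.data$estimate))
      pooled <- rep_stats$pooled |>
        mutate(reproducibility_pct = pct(.data$estimate))
      list(tables = list(per_specimen = per, pooled = pooled,
                         repeatability = mutate(rpt, pct = pct(rpt$estimate))),
           summary = list(
             pos_reproducibility_pct =
               pct(pooled$estimate[pooled$reference == "positive"]),
             neg_reproducibility_pct =
               pct(pooled$estimate[pooled$reference == "negative"]),
             repeatability_pct = pct(rpt$estimate)))
    },
    interference = {
      ia <- interference_agreement(manifest)
      list(tables = list(per_group = mutate(ia$per_group,
                                            pa_pct = pct(.data$estimate)),
                         overall = ia$overall),
           summary = list(overall_pa_pct = pct(ia$overall$estimate),
                          n_valid = ia$overall$n))
    }
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %s> %d replicates\n", x$study, nrow(x$manifest)))
  for (nm in names(x$summary)) cat(sprintf("  %s: %s\n", nm, x$summary[[nm]]))
  invisible(x)
}

#' Recompute printed validation statistics from transcribed counts
#'
#' Reads a fixture of count data transcribed from published validation
#' tables (shipped in `inst/extdata/printed_counts.tsv`) and recomputes
#' every count-derived statistic and Wilson interval, comparing each against
#' the printed value at printed precision (two decimals, half-up). Rows of
#' statistic `adjusted_tp` carry printed per-specimen adjusted tumor
#' purities; the `lod_median` row is checked against their median.
#'
#' @param counts_file TSV with columns `table_id`, `analysis`, `label`,
#'   `statistic`, `x`, `n`, `printed_pct`, `printed_lower`, `printed_upper`.
#' @return tibble with computed and printed values and a `pass` flag per
#'   comparison.
#' @export
verify_printed_tables <- function(counts_file = system.file(
  "extdata", "printed_counts.tsv", package = "scarvalid")) {
  x <- readr::read_tsv(counts_file, col_types = readr::cols(
    table_id = "c", analysis = "c", label = "c", statistic = "c",
    x = "d", n = "d", printed_pct = "d", printed_lower = "d",
    printed_upper = "d"))
  required <- c("table_id", "analysis", "label", "statistic", "x", "n",
                "printed_pct")
  if (!all(required %in% names(x))) {
    abort("counts fixture is missing required columns.",
          class = "scarvalid_input_error")
  }
  counted <- x[!x$statistic %in% c("adjusted_tp", "lod_median"), , drop = FALSE]
  ci <- wilson_ci(counted$x, counted$n)
  counted$computed_pct <- pct(ci$estimate)
  counted$computed_lower <- pct(ci$lower)
  counted$computed_upper <- pct(ci$upper)
  adj <- x[x$statistic == "adjusted_tp", , drop = FALSE]
  if (nrow(adj)) {
    # per-specimen adjusted TPs are inputs to the median, not derived here
    adj$computed_pct <- NA_real_
    adj$computed_lower <- NA_real_
    adj$computed_upper <- NA_real_
  }
  med <- x[x$statistic == "lod_median", , drop = FALSE]
  if (nrow(med)) {
    if (!nrow(adj)) {
      abort("lod_median requires adjusted_tp rows in the fixture.",
            class = "scarvalid_input_error")
    }
    med$computed_pct <- round_half_up(median(adj$printed_pct), 2)
    med$computed_lower <- NA_real_
    med$computed_upper <- NA_real_
  }
  out <- bind_rows(counted, adj, med)
  out$pass <- ifelse(
    out$statistic == "adjusted_tp", NA,
    out$computed_pct == out$printed_pct &
      (is.na(out$printed_lower) | out$computed_lower == out$printed_lower) &
      (is.na(out$printed_upper) | out$computed_upper == out$printed_upper))
  out
}
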