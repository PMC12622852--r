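#' Default study designs
#'
#' Returns the default design for one of the five validation studies. The
#' defaults mirror the factorial structures of the studies they emulate:
#' limit of blank (5 normal specimens x 12 replicates = 60), limit of
#' detection (3 HRD-positive specimens x 5 target-purity levels, 282
#' replicates), precision (22 specimens x 36 replicates over 3 sites = 792,
#' with two factor groups), concordance (101 surrogate-truth-positive + 130
#' surrogate-truth-negative specimens), and interference (11 spiked samples
#' plus a 6-sample necrosis series).
#'
#' @param study one of `"lob"`, `"lod"`, `"precision"`, `"concordance"`,
#'   `"interference"`.
#' @return a named list of design parameters; override entries via the
#'   `design` argument of [generate_study_cohort()].
#' @export
study_design <- function(study = c("lob", "lod", "precision", "concordance",
                                   "interference")) {
  study <- match.arg(study)
  switch(study,
    lob = list(
      n_specimens = 5, n_replicates = 12, qc_fail_rates = c(0, 0)
    ),
    lod = list(
      purities = c(S1 = 0.58, S2 = 0.63, S3 = 0.66),
      levels = list(S1 = c(0.2, 0.25, 0.3, 0.35, 0.4),
                    S2 = c(0.2, 0.3, 0.35, 0.4, 0.5),
                    S3 = c(0.2, 0.3, 0.35, 0.4, 0.5)),
      reps_per_level = c(19, 19, 19, 19, 18),
      qc_fail_rates = c(0, 0.05)
    ),
    precision = list(
      n_pos = 11, n_neg = 11, sites = 3, reps_per_run = 2,
      group1_n = 12,   # 3 reagent lots x 2 sequencers per site
      group2_n = 10,   # 2 reagent lots x 3 sequencing runs per site
      purities_pos = c(0.52, 0.49, 0.59, 0.40, 0.46, 0.76, 0.61, 0.42,
                       0.26, 0.21, 0.18),
      purities_neg = c(0.15, 0.64, 0.65, 0.17, 0.48, 0.25, 0.85, 0.61,
                       0.27, 0.61, 0.23),
      qc_fail_rates = c(0.005, 0.01)
    ),
    concordance = list(
      n_pos = 101, n_neg = 130, purity_range = c(0.08, 0.92),
      qc_fail_rates = c(0.002, 0.006)
    ),
    interference = list(
      qc_fail_rates = c(0.02, 0.025)
    )
  )
}

# replicate plan for the interference study: 11 spiked samples with control
# conditions plus a 6-sample necrosis series without controls
interference_plan <- function() {
  cond <- function(id, truth, substance, conc, n) {
    tibble(specimen_id = id, hrd_truth = truth, interferent = substance,
           concentration = conc, n = n)
  }
  bilirubin_set <- function(id, truth) bind_rows(
    cond(id, truth, "normal_control", NA_character_, 4),
    cond(id, truth, "dmso_control", NA_character_, 2),
    cond(id, truth, "conjugated_bilirubin", "0.8g/L", 2),
    cond(id, truth, "hemoglobin", "0.8g/L", 2),
    cond(id, truth, "triglycerides", "148mmol/L", 2)
  )
  lab_set <- function(id, truth, n_ctrl = 4, n_mib = 2, melanin = FALSE) bind_rows(
    cond(id, truth, "normal_control", NA_character_, n_ctrl),
    cond(id, truth, "ethanol", "5% elution volume", 2),
    if (melanin) cond(id, truth, "melanin", "0.2ug/ml", 2),
    cond(id, truth, "molecular_index_barcodes", "30% MIB volume", n_mib),
    cond(id, truth, "proteinase_k", "0.08mg/ml", 2)
  )
  bind_rows(
    bilirubin_set("I01", "positive"),
    bilirubin_set("I02", "negative"),
    bilirubin_set("I03", "negative"),
    lab_set("I04", "positive"),
    lab_set("I05", "positive", n_ctrl = 2, n_mib = 4, melanin = TRUE),
    lab_set("I06", "negative"),
    bind_rows(
      cond("I07", "negative", "normal_control", NA_character_, 2),
      cond("I07", "negative", "dmso_control", NA_character_, 2),
      cond("I07", "negative", "unconjugated_bilirubin", "0.2g/L", 2)
    ),
    bind_rows(
      cond("I08", "negative", "normal_control", NA_character_, 2),
      cond("I08", "negative", "hemoglobin", "2mg/ml", 2),
      cond("I08", "negative", "triglycerides", "37mmol/L", 2),
      cond("I08", "negative", "xylene", "0.0001%", 2)
    ),
    lab_set("I09", "positive", n_ctrl = 2, n_mib = 0, melanin = TRUE),
    lab_set("I10", "positive", n_ctrl = 2, n_mib = 4, melanin = TRUE),
    lab_set("I11", "negative", n_ctrl = 2, n_mib = 4, melanin = TRUE),
    cond(paste0("N", 1:6), rep(c("positive", "negative"), 3), "necrosis",
         paste0(c(5, 10, 15, 25, 40, 50), "%"), 2)
  ) |>
    filter(.data$n > 0)
}

blank_params <- function(params) {
  params$breakpoint_rate_neg <- min(params$breakpoint_rate_neg, 0.3)
  params$loh_fraction_neg <- 0
  params$oscillation_burst_rate_neg <- 0
  params$short_segment_bias_neg <- 0
  params
}

# one observed (non-diluted) replicate of a specimen
measure_replicate <- function(specimen, seed, replicate_id, keep_vafs = FALSE) {
  set.seed(seed)
  oprof <- observe_profile(specimen$profile, specimen$purity,
                           specimen$params$noise_sd)
  new_replicate(replicate_id, specimen$specimen_id,
                hrd_truth = specimen$hrd_truth, dilution_level = 1,
                purity = specimen$purity, effective_purity = specimen$purity,
                observed_profile = oprof,
                observed_vafs = if (keep_vafs) specimen$vafs)
}

specimen_table <- function(specimens) {
  tibble(
    specimen_id = vapply(specimens, `[[`, "", "specimen_id"),
    disease = vapply(specimens, `[[`, "", "disease"),
    hrd_truth = vapply(specimens, `[[`, "", "hrd_truth"),
    biomarker_truth = vapply(specimens, `[[`, "", "biomarker_truth"),
    purity = vapply(specimens, `[[`, 0, "purity"),
    profile = lapply(specimens, `[[`, "profile"),
    vafs = lapply(specimens, `[[`, "vafs")
  )
}

#' Generate a validation-study cohort
#'
#' Simulates the specimens and the full replicate manifest for one of the
#' five analytical-validation study designs, applies QC failures at the
#' design's rates, and returns everything needed for scoring and statistics.
#' Identical `(study, design, params, seed)` give byte-identical cohorts.
#'
#' @param study study type, see [study_design()].
#' @param design optional named list overriding entries of the default
#'   design.
#' @param params a [scar_params()] object.
#' @param genome a `genome_model`.
#' @param seed integer seed.
#' @return list of class `study_cohort` with elements `study`, `specimens`
#'   (tibble with `profile`/`vafs` list-columns) and `manifest` (replicate
#'   tibble with `observed_profile`/`observed_vafs` list-columns and
#'   `qc_valid` assigned).
#' @export
generate_study_cohort <- function(study = c("lob", "lod", "precision",
                                            "concordance", "interference"),
                                  design = NULL, params = scar_params(),
                                  genome = build_genome(), seed = 1) {
  study <- match.arg(study)
  d <- utils::modifyList(study_design(study), design %||% list())
  out <- switch(study,
    lob = cohort_lob(d, params, genome, seed),
    lod = cohort_lod(d, params, genome, seed),
    precision = cohort_precision(d, params, genome, seed),
    concordance = cohort_concordance(d, params, genome, seed),
    interference = cohort_interference(d, params, genome, seed)
  )
  out$manifest <- apply_perturbations(out$manifest,
                                      qc_fail_rates = d$qc_fail_rates,
                                      seed = sv_seed(seed, 999983))
  out$study <- study
  out$design <- d
  structure(out, class = "study_cohort")
}

cohort_lob <- function(d, params, genome, seed) {
  bp <- blank_params(params)
  specimens <- lapply(seq_len(d$n_specimens), function(i) {
    simulate_specimen(genome, "negative", bp, purity = 0,
                      seed = sv_seed(seed, i),
                      specimen_id = sprintf("B%02d", i),
                      disease = "normal tissue",
                      biomarker_truth = "HRR_wildtype")
  })
  manifest <- bind_rows(lapply(seq_along(specimens), function(i) {
    sp <- specimens[[i]]
    bind_rows(lapply(seq_len(d$n_replicates), function(j) {
      r <- measure_replicate(sp, sv_seed(seed, 1000 * i + j),
                             sprintf("%s_r%02d", sp$specimen_id, j))
      r$study <- "lob"
      r
    }))
  }))
  list(specimens = specimen_table(specimens), manifest = manifest)
}

cohort_lod <- function(d, params, genome, seed) {
  ids <- names(d$purities)
  specimens <- lapply(seq_along(ids), function(i) {
    simulate_specimen(genome, "positive", params, purity = d$purities[[i]],
                      seed = sv_seed(seed, 200 + i),
                      specimen_id = ids[i], disease = "breast")
  })
  names(specimens) <- ids
  rows <- list()
  for (i in seq_along(ids)) {
    sp <- specimens[[i]]
    lv <- d$levels[[ids[i]]]
    for (li in seq_along(lv)) {
      target <- lv[li]
      dil <- target / sp$purity
      if (dil > 1) {
        abort(sprintf("target purity %.2f exceeds specimen purity %.2f.",
                      target, sp$purity), class = "scarvalid_config_error")
      }
      nrep <- d$reps_per_level[li]
      for (j in seq_len(nrep)) {
        r <- dilute_replicate(sp, dil, sv_seed(seed, i * 10000 + li * 100 + j),
                              sprintf("%s_L%02d_r%02d", ids[i], li, j))
        r$study <- "lod"
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  list(specimens = specimen_table(specimens), manifest = bind_rows(rows))
}

precision_run_grid <- function(d) {
  if (d$sites != 3) {
    abort("the precision design uses exactly 3 sites.",
          class = "scarvalid_config_error")
  }
  if (d$reps_per_run != 2) {
    abort("the precision design uses 2 replicates per run.",
          class = "scarvalid_config_error")
  }
  g1 <- tidyr::expand_grid(site = 1:3, reagent_lot = 1:3, sequencer_or_run = 1:2)
  g2 <- tidyr::expand_grid(site = 1:3, reagent_lot = 1:2, sequencer_or_run = 1:3)
  g1$run_index <- seq_len(nrow(g1))
  g2$run_index <- seq_len(nrow(g2))
  list(group1 = g1, group2 = g2)
}

cohort_precision <- function(d, params, genome, seed) {
  grids <- precision_run_grid(d)
  n_spec <- d$n_pos + d$n_neg
  truths <- rep(c("positive", "negative"), c(d$n_pos, d$n_neg))
  purities <- c(d$purities_pos[seq_len(d$n_pos)], d$purities_neg[seq_len(d$n_neg)])
  diseases <- rep_len(c("breast", "ovary", "prostate", "lung", "skin", "colon"),
                      n_spec)
  specimens <- lapply(seq_len(n_spec), function(i) {
    simulate_specimen(genome, truths[i], params, purity = purities[i],
                      seed = sv_seed(seed, 300 + i),
                      specimen_id = sprintf("P%02d", i), disease = diseases[i])
  })
  group1_ids <- seq_len(min(d$group1_n, n_spec))
  rows <- list()
  for (i in seq_len(n_spec)) {
    sp <- specimens[[i]]
    grid <- if (i %in% group1_ids) grids$group1 else grids$group2
    for (g in seq_len(nrow(grid))) {
      for (k in seq_len(d$reps_per_run)) {
        r <- measure_replicate(sp, sv_seed(seed, i * 100000 + g * 100 + k),
                               sprintf("P%02d_s%d_r%02d_k%d", i,
                                       grid$site[g], grid$run_index[g], k))
        r$study <- "precision"
        r$site <- grid$site[g]
        r$reagent_lot <- grid$reagent_lot[g]
        r$sequencer_or_run <- grid$sequencer_or_run[g]
        r$run_index <- grid$run_index[g]
        r$rep_k <- k
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  list(specimens = specimen_table(specimens), manifest = bind_rows(rows))
}

cohort_concordance <- function(d, params, genome, seed) {
  n <- d$n_pos + d$n_neg
  truths <- rep(c("positive", "negative"), c(d$n_pos, d$n_neg))
  set.seed(sv_seed(seed, 400))
  purities <- runif(n, d$purity_range[1], d$purity_range[2])
  specimens <- lapply(seq_len(n), function(i) {
    simulate_specimen(genome, truths[i], params, purity = purities[i],
                      seed = sv_seed(seed, 400 + i),
                      specimen_id = sprintf("C%03d", i))
  })
  manifest <- bind_rows(lapply(seq_len(n), function(i) {
    r <- measure_replicate(specimens[[i]], sv_seed(seed, 40000 + i),
                           sprintf("C%03d_r1", i))
    r$study <- "concordance"
    r
  }))
  list(specimens = specimen_table(specimens), manifest = manifest)
}

cohort_interference <- function(d, params, genome, seed) {
  plan <- interference_plan()
  spec_info <- plan |> distinct(.data$specimen_id, .data$hrd_truth)
  set.seed(sv_seed(seed, 500))
  purities <- runif(nrow(spec_info), 0.3, 0.7)
  specimens <- lapply(seq_len(nrow(spec_info)), function(i) {
    simulate_specimen(genome, spec_info$hrd_truth[i], params,
                      purity = purities[i], seed = sv_seed(seed, 500 + i),
                      specimen_id = spec_info$specimen_id[i])
  })
  names(specimens) <- spec_info$specimen_id
  rows <- list()
  for (pi in seq_len(nrow(plan))) {
    sp <- specimens[[plan$specimen_id[pi]]]
    for (j in seq_len(plan$n[pi])) {
      r <- measure_replicate(sp, sv_seed(seed, 50000 + pi * 100 + j),
                             sprintf("%s_%s_r%d", sp$specimen_id,
                                     substr(plan$interferent[pi], 1, 4), j))
      r$study <- "interference"
      r$interferent <- plan$interferent[pi]
      r$concentration <- plan$concentration[pi]
      r$condition <- if (plan$interferent[pi] %in%
                           c("normal_control", "dmso_control")) "control" else "spiked"
      rows[[length(rows) + 1]] <- r
    }
  }
  list(specimens = specimen_table(specimens), manifest = bind_rows(rows))
}

#' Simulate a labeled training/evaluation cohort
#'
#' Draws HRD-positive and HRD-negative specimens with purities uniform in
#' `purity_range`, measures each once (so the classifier sees
#' purity-attenuated observed profiles, as it would in production), and
#' returns the labeled profile table ready for [scar_feature_matrix()].
#'
#' @param n_pos,n_neg class sizes.
#' @param params a [scar_params()].
#' @param genome a `genome_model`.
#' @param seed integer seed.
#' @param purity_range purity range for the uniform draw.
#' @return tibble with `sample_id`, `hrd_truth`, `purity` and list-column
#'   `profile` (the observed profile).
#' @export
simulate_cohort <- function(n_pos = 200, n_neg = 200, params = scar_params(),
                            genome = build_genome(), seed = 1,
                            purity_range = c(0.2, 0.9)) {
  truths <- rep(c("positive", "negative"), c(n_pos, n_neg))
  set.seed(sv_seed(seed, 600))
  purities <- runif(n_pos + n_neg, purity_range[1], purity_range[2])
  rows <- lapply(seq_along(truths), function(i) {
    sp <- simulate_specimen(genome, truths[i], params, purity = purities[i],
                            seed = sv_seed(seed, 600 + i),
                            specimen_id = sprintf("T%04d", i))
    set.seed(sv_seed(seed, 60000 + i))
    tibble(sample_id = sp$specimen_id, hrd_truth = truths[i],
           purity = purities[i],
           profile = list(observe_profile(sp$profile, sp$purity,
                                          params$noise_sd)))
  })
  bind_rows(rows)
}
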