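#' Round half away from zero
#'
#' Report-parity rounding: percentages are printed to 2 decimals with halves
#' rounded up, unlike base R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided Wilson interval obtained by inverting the score test, with the
#' exact normal quantile for the stated confidence and no continuity
#' correction. At the boundaries the closed form gives `lower = 0` for
#' `x = 0` and `lower = n / (n + z^2)` for `x = n`.
#'
#' @param x successes, `0 <= x <= n` (vectorized).
#' @param n trials, `n > 0`.
#' @param confidence two-sided confidence level.
#' @return tibble with columns `x`, `n`, `estimate`, `lower`, `upper`,
#'   `confidence`, `method`.
#' @examples
#' wilson_ci(90, 100)   # estimate 0.90, CI [0.8256, 0.9448]
#' @export
wilson_ci <- function(x, n, confidence = 0.95) {
  if (any(n <= 0)) abort("`n` must be positive.", class = "scarvalid_input_error")
  if (any(x < 0 | x > n)) {
    abort("need 0 <= x <= n.", class = "scarvalid_input_error")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(x = x, n = n, estimate = p,
         lower = pmax(center - half, 0), upper = pmin(center + half, 1),
         confidence = confidence, method = "wilson")
}

known_call <- function(call) call %in% c("positive", "negative")

#' Limit-of-blank false positive rate
#'
#' `FPR = sum(X * V) / sum(V)` over all replicates, where `V` is the validity
#' flag and `X` the positivity indicator; invalid replicates drop out of both
#' sums.
#'
#' @param replicates replicate tibble with `qc_valid` and `call` columns.
#' @param confidence confidence level for the Wilson interval.
#' @return one-row Wilson tibble (see [wilson_ci()]).
#' @export
lob_fpr <- function(replicates, confidence = 0.95) {
  v <- replicates$qc_valid %in% TRUE
  if (!any(v)) abort("no valid replicates.", class = "scarvalid_input_error")
  x <- sum(replicates$call[v] == "positive", na.rm = TRUE)
  wilson_ci(x, sum(v), confidence)
}

#' Dilution factor from SNP VAF shifts
#'
#' Estimates how far a diluted aliquot's allelic imbalance has collapsed
#' toward the germline expectation of 0.5. Over germline-heterozygous SNPs
#' that are allele-imbalanced in the undiluted sample (deviation from 0.5
#' greater than `min_dev`), the factor is the ratio of summed
#' coverage-weighted VAF deviations, diluted over undiluted, clamped to
#' `[0, 1]`.
#'
#' Coverage weighting makes the estimator copy-number consistent: at purity
#' `rho` a SNP in a segment of total copy number `t` has expected deviation
#' `rho * k / (rho * t + 2 * (1 - rho))` (with `k` the allelic imbalance of
#' the segment) while its expected coverage is proportional to
#' `rho * t + 2 * (1 - rho)`, so the product `|vaf - 0.5| * depth` scales
#' linearly in `rho` for every copy-number class and the ratio recovers the
#' mass dilution directly.
#'
#' @param vafs_undiluted,vafs_diluted VAF tibbles (`chrom`, `pos`, `vaf`,
#'   `depth`, `het_in_normal`) sharing SNP positions.
#' @param min_dev imbalance threshold on the undiluted deviation.
#' @param min_snps minimum usable SNP count.
#' @return a single factor in `[0, 1]`.
#' @export
dilution_factor <- function(vafs_undiluted, vafs_diluted, min_dev = 0.02,
                            min_snps = 50) {
  u <- vafs_undiluted[vafs_undiluted$het_in_normal,
                      c("chrom", "pos", "vaf", "depth")]
  d <- vafs_diluted[vafs_diluted$het_in_normal,
                    c("chrom", "pos", "vaf", "depth")]
  m <- inner_join(u, d, by = c("chrom", "pos"), suffix = c("_u", "_d"))
  dev_u <- abs(m$vaf_u - 0.5)
  keep <- dev_u > min_dev
  if (sum(keep) < min_snps) {
    abort(sprintf("only %d usable imbalanced SNPs (need >= %d).",
                  sum(keep), min_snps), class = "scarvalid_input_error")
  }
  f <- sum(abs(m$vaf_d[keep] - 0.5) * m$depth_d[keep]) /
    sum(dev_u[keep] * m$depth_u[keep])
  min(max(f, 0), 1)
}

#' Adjusted tumor purity
#'
#' The computational tumor purity of the undiluted specimen scaled by the
#' VAF-derived dilution factor.
#'
#' @param undiluted_tp undiluted computational tumor purity in `[0, 1]`.
#' @param factor dilution factor in `[0, 1]`.
#' @return product, in `[0, 1]`.
#' @export
adjusted_tp <- function(undiluted_tp, factor) {
  stopifnot(all(undiluted_tp >= 0 & undiluted_tp <= 1),
            all(factor >= 0 & factor <= 1))
  undiluted_tp * factor
}

#' Per-level dilution summaries for an LoD cohort
#'
#' For each specimen and dilution level: the number of valid replicates, the
#' number called positive, the empirical hit rate with its Wilson interval,
#' and the mean adjusted tumor purity (undiluted computational purity times
#' the replicate's VAF-derived dilution factor).
#'
#' @param manifest scored LoD manifest with `observed_vafs` list-column.
#' @param specimens specimen tibble with `specimen_id`, `purity` and a
#'   `vafs` list-column holding the undiluted VAF tables.
#' @param confidence confidence level.
#' @return tibble: `specimen_id`, `level`, `n_valid`, `n_hit`, `hit_rate`,
#'   `hit_lower`, `hit_upper`, `mean_adjusted_tp`.
#' @export
dilution_level_summary <- function(manifest, specimens, confidence = 0.95) {
  spec_purity <- setNames(specimens$purity, specimens$specimen_id)
  spec_vafs <- setNames(specimens$vafs, specimens$specimen_id)
  manifest$level <- manifest$effective_purity / manifest$purity
  groups <- split(seq_len(nrow(manifest)),
                  list(manifest$specimen_id, round(manifest$level, 6)),
                  drop = TRUE)
  rows <- lapply(groups, function(ix) {
    g <- manifest[ix, , drop = FALSE]
    sid <- g$specimen_id[1]
    v <- g$qc_valid %in% TRUE
    n_valid <- sum(v)
    n_hit <- sum(g$call[v] == "positive", na.rm = TRUE)
    adj <- vapply(which(v), function(i) {
      f <- dilution_factor(spec_vafs[[sid]], g$observed_vafs[[i]])
      adjusted_tp(spec_purity[[sid]], f)
    }, numeric(1))
    ci <- if (n_valid > 0) wilson_ci(n_hit, n_valid, confidence) else
      tibble(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    tibble(specimen_id = sid, level = g$level[1], n_valid = n_valid,
           n_hit = n_hit, hit_rate = ci$estimate, hit_lower = ci$lower,
           hit_upper = ci$upper, mean_adjusted_tp = mean(adj))
  })
  bind_rows(rows) |> arrange(.data$specimen_id, .data$level)
}

#' Determine the limit of detection from dilution-level summaries
#'
#' Per specimen, the smallest dilution level whose empirical hit rate meets
#' `hit_threshold` is selected and its mean adjusted tumor purity becomes
#' that specimen's LoD value; the overall LoD is the median across
#' determined specimens. A specimen with no passing level is reported as
#' not determined.
#'
#' @param levels output of [dilution_level_summary()] (columns
#'   `specimen_id`, `level`, `hit_rate`, `mean_adjusted_tp`).
#' @param hit_threshold required hit rate (default 0.95).
#' @return list with `per_specimen` (tibble `specimen_id`, `level`,
#'   `mean_adjusted_tp`, `determined`) and `lod` (the overall median).
#' @export
determine_lod <- function(levels, hit_threshold = 0.95) {
  per <- levels |>
    group_by(.data$specimen_id) |>
    group_modify(function(df, key) {
      pass <- df[!is.na(df$hit_rate) & df$hit_rate >= hit_threshold, , drop = FALSE]
      if (nrow(pass) == 0) {
        tibble(level = NA_real_, mean_adjusted_tp = NA_real_, determined = FALSE)
      } else {
        best <- pass[which.min(pass$level), , drop = FALSE]
        tibble(level = best$level, mean_adjusted_tp = best$mean_adjusted_tp,
               determined = TRUE)
      }
    }) |>
    ungroup()
  if (!any(per$determined)) {
    abort("no specimen reached the hit-rate threshold at any level.",
          class = "scarvalid_input_error")
  }
  list(per_specimen = per,
       lod = median(per$mean_adjusted_tp[per$determined]))
}

#' Contingency table of calls against surrogate truth
#'
#' @param calls tibble with columns `call` (`positive`/`negative`/`unknown`)
#'   and `biomarker_truth` (`LOF_REV` = positive truth, anything else
#'   negative truth); QC-invalid rows should be removed beforehand.
#' @return one-row tibble `a`, `b`, `c`, `d`, `unknown_pos`, `unknown_neg`.
#' @export
contingency_table <- function(calls) {
  tp <- calls$biomarker_truth == "LOF_REV"
  tibble(
    a = sum(calls$call == "positive" & tp),
    b = sum(calls$call == "positive" & !tp),
    c = sum(calls$call == "negative" & tp),
    d = sum(calls$call == "negative" & !tp),
    unknown_pos = sum(calls$call == "unknown" & tp),
    unknown_neg = sum(calls$call == "unknown" & !tp)
  )
}

#' Positive and negative percent agreement with Wilson intervals
#'
#' `PPA = a / (a + c)` and `NPA = d / (b + d)`; unknown-status samples are
#' excluded from both denominators by default. With
#' `include_unknown_in_npa`, the NPA denominator becomes
#' `b + d + unknown_neg`, the conservative reading in which unknowns count
#' against negative agreement.
#'
#' @param table one-row tibble or named list with `a`, `b`, `c`, `d` and
#'   optionally `unknown_pos`, `unknown_neg`.
#' @param include_unknown_in_npa see above.
#' @param confidence confidence level.
#' @return tibble with rows `ppa` and `npa` (Wilson columns plus `metric`).
#' @export
concordance_ppa_npa <- function(table, include_unknown_in_npa = FALSE,
                                confidence = 0.95) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  unk_neg <- if ("unknown_neg" %in% names(table)) table$unknown_neg else 0
  if (a + c == 0 || b + d == 0) {
    abort("empty truth margin.", class = "scarvalid_input_error")
  }
  npa_n <- b + d + if (include_unknown_in_npa) unk_neg else 0
  bind_rows(
    mutate(wilson_ci(a, a + c, confidence), metric = "ppa"),
    mutate(wilson_ci(d, npa_n, confidence), metric = "npa")
  ) |>
    select("metric", everything())
}

#' Majority-call reference status
#'
#' Positive when at least 50% of the known-status calls are positive (ties
#' at exactly 50% count positive, the verbatim rule).
#'
#' @param calls character vector of calls; unknowns are ignored.
#' @return `"positive"` or `"negative"`.
#' @export
majority_reference <- function(calls) {
  kn <- calls[known_call(calls)]
  if (!length(kn)) abort("all calls unknown.", class = "scarvalid_input_error")
  if (mean(kn == "positive") >= 0.5) "positive" else "negative"
}

#' Inter-run reproducibility
#'
#' Per specimen: the fraction of valid known-status replicates agreeing with
#' the specimen's majority-call reference status. Pooled rows aggregate
#' numerators and denominators over specimens with positive and with
#' negative reference status. Valid replicates with unknown status are
#' excluded from the denominator.
#'
#' @param manifest scored replicate tibble (`specimen_id`, `qc_valid`,
#'   `call`).
#' @param confidence confidence level.
#' @return list with `per_specimen` and `pooled` tibbles (Wilson columns).
#' @export
reproducibility <- function(manifest, confidence = 0.95) {
  per <- manifest |>
    filter(.data$qc_valid %in% TRUE, known_call(.data$call)) |>
    group_by(.data$specimen_id) |>
    summarise(reference = majority_reference(.data$call),
              x = sum(.data$call == majority_reference(.data$call)),
              n = dplyr::n(), .groups = "drop")
  ci <- wilson_ci(per$x, per$n, confidence)
  per <- bind_cols(per[, c("specimen_id", "reference")],
                   ci[, c("x", "n", "estimate", "lower", "upper")])
  pooled <- per |>
    group_by(.data$reference) |>
    summarise(x = sum(.data$x), n = sum(.data$n), .groups = "drop")
  pooled <- bind_cols(pooled[, "reference", drop = FALSE],
                      wilson_ci(pooled$x, pooled$n, confidence))
  list(per_specimen = per, pooled = pooled)
}

#' Intra-run repeatability
#'
#' Within-run pair agreement: among runs carrying two valid known-status
#' replicates of the same specimen, the fraction whose two calls agree.
#' Pairs with an invalid (or unknown-status) member drop out of numerator
#' and denominator.
#'
#' @param manifest scored replicate tibble with `specimen_id`, `run_index`,
#'   `rep_k`, `qc_valid`, `call`.
#' @param confidence confidence level.
#' @return one-row Wilson tibble for the pooled repeatability.
#' @export
repeatability <- function(manifest, confidence = 0.95) {
  pairs <- manifest |>
    filter(.data$qc_valid %in% TRUE, known_call(.data$call)) |>
    group_by(.data$specimen_id, .data$run_index) |>
    filter(n() == 2) |>
    summarise(agree = .data$call[1] == .data$call[2], .groups = "drop")
  if (nrow(pairs) == 0) {
    abort("no complete valid pairs.", class = "scarvalid_input_error")
  }
  wilson_ci(sum(pairs$agree), nrow(pairs), confidence)
}

#' Interfering-substance percent agreement
#'
#' The reference status of each specimen is the majority call over its valid
#' control-condition replicates; specimens lacking control replicates (e.g.
#' the necrosis series) take the majority over all their replicates and are
#' excluded from the overall figure but reported at sample level. Percent
#' agreement per (specimen, substance) group is the fraction of valid
#' known-status replicates matching the reference; the overall figure
#' aggregates all valid replicates of specimens with a control-based
#' reference.
#'
#' @param manifest scored replicate tibble with `specimen_id`, `interferent`,
#'   `concentration`, `condition`, `qc_valid`, `call`.
#' @param confidence confidence level.
#' @return list with `per_group` (tibble `specimen_id`, `interferent`,
#'   `concentration`, `x`, `n`, `estimate`, `in_overall`) and `overall`
#'   (one-row Wilson tibble).
#' @export
interference_agreement <- function(manifest, confidence = 0.95) {
  valid <- manifest |>
    filter(.data$qc_valid %in% TRUE, known_call(.data$call))
  refs <- valid |>
    group_by(.data$specimen_id) |>
    summarise(
      has_control = any(.data$condition == "control"),
      reference = if (any(.data$condition == "control")) {
        majority_reference(.data$call[.data$condition == "control"])
      } else {
        majority_reference(.data$call)
      },
      .groups = "drop")
  per_group <- valid |>
    left_join(refs, by = "specimen_id") |>
    group_by(.data$specimen_id, .data$interferent, .data$concentration) |>
    summarise(x = sum(.data$call == .data$reference[1]), n = n(),
              in_overall = .data$has_control[1], .groups = "drop") |>
    mutate(estimate = .data$x / .data$n)
  incl <- per_group[per_group$in_overall, , drop = FALSE]
  if (nrow(incl) == 0) {
    abort("no group has a control-based reference.",
          class = "scarvalid_input_error")
  }
  list(per_group = per_group,
       overall = wilson_ci(sum(incl$x), sum(incl$n), confidence))
}
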