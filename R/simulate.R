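#' @keywords internal
#' @noRd
sv_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 7919) %% 2147483647)
}

# total-CN state weights over 0..5, subset to the configured range
cn_state_weights <- function(hrd_truth, params) {
  w <- if (hrd_truth == "positive") {
    c(0.02, 0.10, 0.45, 0.24, 0.12, 0.07)
  } else {
    c(0.005, 0.04, 0.80, 0.10, 0.035, 0.02)
  }
  rng <- params$cn_state_range
  states <- max(0L, rng[1]):min(5L, rng[2])
  list(states = states, w = w[states + 1] / sum(w[states + 1]))
}

draw_segment_states <- function(n, hrd_truth, params) {
  sw <- cn_state_weights(hrd_truth, params)
  loh_frac <- if (hrd_truth == "positive") params$loh_fraction_pos else params$loh_fraction_neg
  total <- sample(sw$states, n, replace = TRUE, prob = sw$w)
  half <- floor(total / 2)
  loh <- runif(n) < loh_frac
  minor <- integer(n)
  idx <- which(!loh & half >= 1)
  # non-LOH segments keep at least one copy of the lesser allele
  minor[idx] <- vapply(half[idx], function(h) sample.int(h, 1L), integer(1))
  list(total = as.integer(total), minor = as.integer(minor))
}

# collapse adjacent same-arm segments with identical (total, minor)
merge_identical_segments <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  new_run <- c(TRUE, seg$total_cn[-1] != seg$total_cn[-nrow(seg)] |
                 seg$minor_cn[-1] != seg$minor_cn[-nrow(seg)])
  grp <- cumsum(new_run)
  data.frame(
    start = as.numeric(tapply(seg$start, grp, min)),
    end = as.numeric(tapply(seg$end, grp, max)),
    total_cn = as.integer(tapply(seg$total_cn, grp, function(x) x[1])),
    minor_cn = as.integer(tapply(seg$minor_cn, grp, function(x) x[1]))
  )
}

# replace the part of an arm tiling overlapped by a burst with the burst rows
carve_segments <- function(seg, burst) {
  b0 <- burst$start[1]
  b1 <- burst$end[nrow(burst)]
  left <- seg[seg$start < b0, , drop = FALSE]
  if (nrow(left)) left$end[nrow(left)] <- min(left$end[nrow(left)], b0)
  left <- left[left$end > left$start, , drop = FALSE]
  if (nrow(left)) left$end[nrow(left)] <- b0
  right <- seg[seg$end > b1, , drop = FALSE]
  if (nrow(right)) right$start[1] <- max(right$start[1], b1)
  right <- right[right$end > right$start, , drop = FALSE]
  if (nrow(right)) right$start[1] <- b1
  bind_rows(left, burst, right)
}

simulate_arm_segments <- function(arm_start, arm_end, hrd_truth, params) {
  rate <- if (hrd_truth == "positive") params$breakpoint_rate_pos else params$breakpoint_rate_neg
  bias <- if (hrd_truth == "positive") params$short_segment_bias_pos else params$short_segment_bias_neg
  arm_len <- arm_end - arm_start
  k <- rpois(1, rate * arm_len / 1e8)
  bp <- runif(k, arm_start, arm_end)
  comp <- bp[runif(k) < bias]
  if (length(comp)) comp <- comp + runif(length(comp), 5e5, 8e6)
  bp <- sort(unique(round(c(bp, comp))))
  bp <- bp[bp > arm_start & bp < arm_end]
  bounds <- c(arm_start, bp, arm_end)
  n <- length(bounds) - 1
  st <- draw_segment_states(n, hrd_truth, params)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             total_cn = st$total, minor_cn = st$minor)
}

make_oscillation_burst <- function(arm_start, arm_end, params) {
  len_rng <- params$oscillation_len_range
  L <- sample(len_rng[1]:len_rng[2], 1)
  widths <- runif(L, 3e5, 3e6)
  total_w <- sum(widths)
  arm_len <- arm_end - arm_start
  if (total_w > 0.8 * arm_len) widths <- widths * 0.8 * arm_len / total_w
  b0 <- runif(1, arm_start, arm_end - sum(widths))
  bounds <- round(b0 + c(0, cumsum(widths)))
  t0 <- sample(1:3, 1)
  totals <- rep(c(t0, t0 + 1L), length.out = L)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             total_cn = as.integer(totals),
             minor_cn = as.integer(pmin(1L, floor(totals / 2))))
}

#' Simulate an allele-specific copy-number profile
#'
#' Draws per-arm breakpoints from a Poisson process at the truth-dependent
#' rate, assigns allele-specific copy-number states (with the configured LOH
#' fraction), inserts oscillation bursts (alternating two-state runs), and
#' returns a maximal segmentation tiling every arm exactly.
#'
#' @param genome a `genome_model`.
#' @param hrd_truth `"positive"` or `"negative"`.
#' @param params a [scar_params()] object.
#' @return tibble with columns `chrom`, `arm`, `start`, `end`, `total_cn`,
#'   `minor_cn` (0-based half-open coordinates).
#' @export
simulate_profile <- function(genome, hrd_truth, params = scar_params()) {
  hrd_truth <- match.arg(hrd_truth, c("positive", "negative"))
  arms <- genome_arms(genome)
  segs <- lapply(seq_len(nrow(arms)), function(i) {
    simulate_arm_segments(arms$start[i], arms$end[i], hrd_truth, params)
  })
  osc_rate <- if (hrd_truth == "positive") params$oscillation_burst_rate_pos
              else params$oscillation_burst_rate_neg
  n_burst <- rpois(1, osc_rate)
  if (n_burst > 0) {
    target <- sample(nrow(arms), n_burst, replace = TRUE, prob = arms$arm_length)
    for (ai in target) {
      burst <- make_oscillation_burst(arms$start[ai], arms$end[ai], params)
      segs[[ai]] <- carve_segments(segs[[ai]], burst)
    }
  }
  out <- lapply(seq_len(nrow(arms)), function(i) {
    s <- merge_identical_segments(segs[[i]])
    s$chrom <- arms$chrom[i]
    s$arm <- arms$arm[i]
    s
  })
  bind_rows(out) |>
    select("chrom", "arm", "start", "end", "total_cn", "minor_cn")
}

#' Expected variant allele frequency of a heterozygous SNP
#'
#' For a germline-heterozygous SNP falling in a tumor segment with total copy
#' number `t` and `c_alt` copies of the alternate allele, at tumor purity
#' `rho`, the expected VAF is `(rho * c_alt + (1 - rho)) / (rho * t + 2 * (1 - rho))`:
#' the normal compartment contributes one alternate copy out of two.
#'
#' @param t total tumor copy number.
#' @param c_alt tumor copies carrying the alternate allele.
#' @param rho tumor purity in `[0, 1]`.
#' @return expected VAF in `[0, 1]`.
#' @export
expected_vaf <- function(t, c_alt, rho) {
  denom <- rho * t + 2 * (1 - rho)
  out <- (rho * c_alt + (1 - rho)) / denom
  out[denom <= 0] <- 0.5
  out
}

#' Simulate a SNP variant-allele-frequency table
#'
#' Germline-heterozygous SNP positions are placed at `params$snp_density` per
#' Mb (a small fraction are homozygous-reference sentinels flagged
#' `het_in_normal = FALSE`); the alternate allele is assigned at random to the
#' minor or major haplotype of the overlapping segment; read depth is Poisson
#' around `params$depth` scaled by local copy number; the VAF is a binomial
#' draw at the [expected_vaf()].
#'
#' @param genome a `genome_model`.
#' @param profile a copy-number profile tiling the genome.
#' @param purity tumor purity in `[0, 1]`.
#' @param params a [scar_params()] object.
#' @param positions optional tibble (`chrom`, `pos`, `het_in_normal`) to reuse
#'   existing SNP positions, e.g. when re-measuring a diluted aliquot.
#' @return tibble with columns `chrom`, `pos`, `vaf`, `depth`, `het_in_normal`.
#' @export
simulate_vafs <- function(genome, profile, purity, params = scar_params(),
                          positions = NULL) {
  if (is.null(positions)) {
    positions <- lapply(seq_len(nrow(genome)), function(i) {
      n <- rpois(1, genome$length[i] / 1e6 * params$snp_density)
      pos <- sort(unique(floor(runif(n, 0, genome$length[i]))))
      tibble(chrom = genome$chrom[i], pos = pos,
             het_in_normal = runif(length(pos)) < 0.95)
    })
    positions <- bind_rows(positions)
  }
  out <- positions[, c("chrom", "pos", "het_in_normal")]
  out$total_cn <- NA_integer_
  out$minor_cn <- NA_integer_
  for (ch in unique(out$chrom)) {
    seg <- profile[profile$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    ii <- out$chrom == ch
    idx <- findInterval(out$pos[ii], seg$start)
    idx[idx < 1] <- 1L
    out$total_cn[ii] <- seg$total_cn[idx]
    out$minor_cn[ii] <- seg$minor_cn[idx]
  }
  n <- nrow(out)
  alt_is_minor <- runif(n) < 0.5
  c_alt <- ifelse(alt_is_minor, out$minor_cn, out$total_cn - out$minor_cn)
  p_exp <- ifelse(out$het_in_normal, expected_vaf(out$total_cn, c_alt, purity), 0.002)
  denom <- purity * out$total_cn + 2 * (1 - purity)
  dp <- pmax(rpois(n, params$depth * pmax(denom, 0.1) / 2), 1L)
  x <- rbinom(n, dp, pmin(pmax(p_exp, 0), 1))
  tibble(chrom = out$chrom, pos = out$pos, vaf = x / dp, depth = as.integer(dp),
         het_in_normal = out$het_in_normal)
}

#' Simulate a tumor specimen
#'
#' Generates a ground-truth copy-number profile and an undiluted SNP VAF table
#' for one specimen. The truth label is fixed at creation and serves as the
#' recovery target for downstream classification tests.
#'
#' @inheritParams simulate_profile
#' @param purity computational tumor purity of the undiluted specimen, in
#'   `[0, 1]` (0 for normal-tissue blanks).
#' @param seed integer seed; identical inputs and seed give identical output.
#' @param specimen_id,disease identifiers carried through reports.
#' @param biomarker_truth surrogate-truth label; defaults to `"LOF_REV"` for
#'   positives and `"HRR_wildtype"` for negatives.
#' @return object of class `specimen`: a list with `specimen_id`, `disease`,
#'   `hrd_truth`, `biomarker_truth`, `purity`, `profile`, `vafs`, plus the
#'   `genome` and `params` needed to regenerate measurements.
#' @export
simulate_specimen <- function(genome, hrd_truth, params = scar_params(),
                              purity = 0.6, seed = 1, specimen_id = NULL,
                              disease = "unspecified", biomarker_truth = NULL) {
  if (nrow(genome) == 0) abort("empty genome.", class = "scarvalid_config_error")
  if (purity < 0 || purity > 1) {
    abort("`purity` must lie in [0, 1].", class = "scarvalid_config_error")
  }
  hrd_truth <- match.arg(hrd_truth, c("positive", "negative"))
  set.seed(seed)
  profile <- simulate_profile(genome, hrd_truth, params)
  vafs <- simulate_vafs(genome, profile, purity, params)
  structure(list(
    specimen_id = specimen_id %||% paste0("SP", seed),
    disease = disease,
    hrd_truth = hrd_truth,
    biomarker_truth = biomarker_truth %||%
      if (hrd_truth == "positive") "LOF_REV" else "HRR_wildtype",
    purity = purity,
    profile = profile,
    vafs = vafs,
    genome = genome,
    params = params,
    seed = seed
  ), class = "specimen")
}

#' Purity-attenuated observed profile
#'
#' Models what a copy-number caller recovers from a specimen at a given
#' effective tumor purity: each true segment boundary is detected with a
#' probability that rises with its log-ratio contrast (or, for copy-neutral
#' LOH boundaries, its allelic-imbalance contrast) relative to the noise
#' floor. Missed boundaries merge neighbouring segments, which inherit the
#' state of the longest member. At high purity the observed profile equals
#' the truth; as purity falls, low-contrast scars disappear first.
#'
#' @param profile truth profile (`chrom`, `arm`, `start`, `end`, `total_cn`,
#'   `minor_cn`).
#' @param effective_purity effective tumor purity in `[0, 1]`.
#' @param noise_sd log-ratio noise standard deviation.
#' @return observed profile tibble, same columns as the input.
#' @export
observe_profile <- function(profile, effective_purity, noise_sd = 0.05) {
  rho <- effective_purity
  ord <- order(match(profile$chrom, unique(profile$chrom)), profile$arm,
               profile$start)
  p <- profile[ord, , drop = FALSE]
  n <- nrow(p)
  if (n <= 1) return(as_tibble(p[, c("chrom", "arm", "start", "end",
                                     "total_cn", "minor_cn")]))
  key <- paste0(p$chrom, p$arm)
  ratio <- (rho * p$total_cn + 2 * (1 - rho)) / 2
  lr <- log2(pmax(ratio, 2^-4))
  e <- abs(0.5 - expected_vaf(p$total_cn, p$minor_cn, rho))
  c_lr <- abs(diff(lr))
  c_vaf <- abs(diff(e))
  p_det <- pmax(stats::pnorm((c_lr - 2 * noise_sd) / max(noise_sd, 1e-6)),
                stats::pnorm((c_vaf - 0.04) / 0.02))
  same_arm <- key[-1] == key[-n]
  detected <- runif(n - 1) < p_det
  grp <- cumsum(c(TRUE, !same_arm | detected))
  len <- p$end - p$start
  # the surviving segment group inherits the state of its longest member
  pick <- vapply(split(seq_len(n), grp), function(ix) ix[which.max(len[ix])],
                 integer(1))
  first <- which(!duplicated(grp))
  last <- c(first[-1] - 1L, n)
  out <- data.frame(chrom = p$chrom[first], arm = p$arm[first],
                    start = p$start[first], end = p$end[last],
                    total_cn = p$total_cn[pick], minor_cn = p$minor_cn[pick])
  # re-collapse adjacent same-arm groups left identical by state inheritance
  m <- nrow(out)
  if (m > 1) {
    k2 <- paste0(out$chrom, out$arm)
    dup <- c(FALSE, k2[-1] == k2[-m] &
               out$total_cn[-1] == out$total_cn[-m] &
               out$minor_cn[-1] == out$minor_cn[-m])
    g2 <- cumsum(!dup)
    f2 <- which(!duplicated(g2))
    l2 <- c(f2[-1] - 1L, m)
    out <- data.frame(chrom = out$chrom[f2], arm = out$arm[f2],
                      start = out$start[f2], end = out$end[l2],
                      total_cn = out$total_cn[f2], minor_cn = out$minor_cn[f2])
  }
  as_tibble(out)
}

# one-row replicate manifest skeleton; list-columns hold the observed data
new_replicate <- function(replicate_id, specimen_id, hrd_truth = NA_character_,
                          study = NA_character_, site = NA_integer_,
                          reagent_lot = NA_integer_,
                          sequencer_or_run = NA_integer_,
                          run_index = NA_integer_, rep_k = NA_integer_,
                          dilution_level = NA_real_,
                          interferent = NA_character_,
                          concentration = NA_character_,
                          condition = NA_character_, qc_valid = NA,
                          purity = NA_real_, effective_purity = NA_real_,
                          observed_profile = NULL, observed_vafs = NULL) {
  tibble(
    replicate_id = replicate_id, specimen_id = specimen_id,
    hrd_truth = hrd_truth, study = study, site = site,
    reagent_lot = reagent_lot, sequencer_or_run = sequencer_or_run,
    run_index = run_index, rep_k = rep_k, dilution_level = dilution_level,
    interferent = interferent, concentration = concentration,
    condition = condition, qc_valid = qc_valid, purity = purity,
    effective_purity = effective_purity, score = NA_real_,
    call = NA_character_, reason = NA_character_,
    observed_profile = list(observed_profile), observed_vafs = list(observed_vafs)
  )
}

#' Dilute a specimen with matched normal DNA
#'
#' Mixing tumor DNA of purity `rho` at mass fraction `dilution` with matched
#' normal DNA gives an effective purity of `dilution * rho` (mass balance).
#' The SNP VAFs are re-measured at the effective purity on the specimen's own
#' SNP positions, and the observed copy-number profile is attenuated
#' accordingly via [observe_profile()].
#'
#' @param specimen a [simulate_specimen()] object with `purity > 0`.
#' @param dilution tumor mass fraction in `(0, 1]`.
#' @param seed integer seed.
#' @param replicate_id identifier for the resulting replicate.
#' @return a one-row replicate tibble with list-columns `observed_profile`
#'   and `observed_vafs`; `qc_valid` is left pending assignment.
#' @export
dilute_replicate <- function(specimen, dilution, seed,
                             replicate_id = paste0(specimen$specimen_id, "_d")) {
  if (dilution <= 0 || dilution > 1) {
    abort("`dilution` must lie in (0, 1].", class = "scarvalid_config_error")
  }
  if (specimen$purity <= 0) {
    abort("specimen must have purity > 0 to be diluted.",
          class = "scarvalid_config_error")
  }
  set.seed(seed)
  eff <- dilution * specimen$purity
  ovafs <- simulate_vafs(specimen$genome, specimen$profile, eff,
                         specimen$params,
                         positions = specimen$vafs[, c("chrom", "pos", "het_in_normal")])
  oprof <- observe_profile(specimen$profile, eff, specimen$params$noise_sd)
  new_replicate(replicate_id, specimen$specimen_id,
                hrd_truth = specimen$hrd_truth,
                dilution_level = dilution, purity = specimen$purity,
                effective_purity = eff, observed_profile = oprof,
                observed_vafs = ovafs)
}

#' Default interferent effect table
#'
#' All nine assessed substances (plus control conditions and necrosis) default
#' to a null effect on the observed data; non-null hooks (`depth_factor`,
#' `noise_add`) exist for robustness experiments.
#'
#' @return named list of effect descriptors.
#' @export
default_interferent_effects <- function() {
  labels <- c("melanin", "proteinase_k", "molecular_index_barcodes", "ethanol",
              "hemoglobin", "triglycerides", "xylene", "conjugated_bilirubin",
              "unconjugated_bilirubin", "dmso_control", "normal_control",
              "necrosis")
  setNames(lapply(labels, function(x) list(depth_factor = 1, noise_add = 0)),
           labels)
}

#' Apply QC failures and interferent perturbations to replicates
#'
#' Library-construction (LC) and hybrid-capture (HC) quality-control failures
#' are independent Bernoulli draws with the given rates; a replicate is valid
#' only if it passes both gates. Interferent effects from the effect table
#' (null by default) perturb the observed VAF table of spiked replicates.
#'
#' @param replicates replicate tibble (rows from [dilute_replicate()] or a
#'   cohort manifest).
#' @param interferent optional interferent label(s) to assign; otherwise the
#'   existing `interferent` column is used.
#' @param qc_fail_rates length-2 numeric `(lc_rate, hc_rate)`.
#' @param seed optional integer seed.
#' @param effects effect table, see [default_interferent_effects()].
#' @return the replicate tibble with `qc_valid` set and effects applied.
#' @export
apply_perturbations <- function(replicates, interferent = NULL,
                                qc_fail_rates = c(0.005, 0.01), seed = NULL,
                                effects = default_interferent_effects()) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(interferent)) {
    replicates$interferent <- rep_len(interferent, nrow(replicates))
  }
  known <- replicates$interferent[!is.na(replicates$interferent)]
  if (length(setdiff(unique(known), names(effects)))) {
    abort(paste0("unknown interferent label(s): ",
                 paste(setdiff(unique(known), names(effects)), collapse = ", ")),
          class = "scarvalid_config_error")
  }
  n <- nrow(replicates)
  lc_fail <- runif(n) < qc_fail_rates[1]
  hc_fail <- runif(n) < qc_fail_rates[2]
  replicates$qc_valid <- !(lc_fail | hc_fail)
  for (i in seq_len(n)) {
    s <- replicates$interferent[i]
    if (is.na(s)) next
    eff <- effects[[s]]
    if (eff$depth_factor == 1 && eff$noise_add == 0) next
    v <- replicates$observed_vafs[[i]]
    if (is.null(v)) next
    v$depth <- pmax(as.integer(round(v$depth * eff$depth_factor)), 1L)
    if (eff$noise_add > 0) {
      v$vaf <- pmin(pmax(v$vaf + rnorm(nrow(v), 0, eff$noise_add), 0), 1)
    }
    replicates$observed_vafs[[i]] <- v
  }
  replicates
}
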