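test_that("simulated profiles tile every arm exactly", {
  gm <- small_genome()
  arms <- genome_arms(gm)
  for (seed in 1:10) {
    truth <- if (seed %% 2) "positive" else "negative"
    sp <- simulate_specimen(gm, truth, purity = 0.5, seed = seed)
    p <- sp$profile
    expect_true(all(p$end > p$start))
    for (i in seq_len(nrow(arms))) {
      seg <- p[p$chrom == arms$chrom[i] & p$arm == arms$arm[i], ]
      seg <- seg[order(seg$start), ]
      expect_equal(seg$start[1], arms$start[i])
      expect_equal(seg$end[nrow(seg)], arms$end[i])
      if (nrow(seg) > 1) {
        expect_equal(seg$start[-1], seg$end[-nrow(seg)])  # no gaps/overlaps
        same <- seg$total_cn[-1] == seg$total_cn[-nrow(seg)] &
          seg$minor_cn[-1] == seg$minor_cn[-nrow(seg)]
        expect_false(any(same))  # maximal segmentation
      }
    }
    expect_true(all(p$minor_cn <= p$total_cn - p$minor_cn))
  }
})

test_that("identical seed gives identical specimens and replicates", {
  gm <- small_genome()
  a <- simulate_specimen(gm, "positive", purity = 0.6, seed = 7)
  b <- simulate_specimen(gm, "positive", purity = 0.6, seed = 7)
  expect_identical(a$profile, b$profile)
  expect_identical(a$vafs, b$vafs)
  ra <- dilute_replicate(a, 0.5, seed = 3)
  rb <- dilute_replicate(b, 0.5, seed = 3)
  expect_identical(ra$observed_vafs[[1]], rb$observed_vafs[[1]])
  expect_identical(ra$observed_profile[[1]], rb$observed_profile[[1]])
})

test_that("het SNP VAF expectation follows the purity mixture formula", {
  # at purity 0 every het SNP is germline: expectation 0.5 whatever the CN
  expect_equal(expected_vaf(c(0, 1, 5), c(0, 0, 5), 0), rep(0.5, 3))
  # pure tumor, segment (2, 0), alt on the lost allele: expectation 0
  expect_equal(expected_vaf(2, 0, 1), 0)
  gm <- small_genome()
  sp0 <- simulate_specimen(gm, "positive", purity = 0, seed = 21)
  het <- sp0$vafs[sp0$vafs$het_in_normal, ]
  expect_lt(abs(mean(het$vaf) - 0.5), 0.01)
  expect_lt(abs(mean(abs(het$vaf - 0.5)) - sqrt(2 / (pi * mean(het$depth))) / 2) /
              mean(abs(het$vaf - 0.5)), 0.5)  # deviations are noise-scale only
})

test_that("dilution rescales effective purity multiplicatively", {
  gm <- small_genome()
  sp <- simulate_specimen(gm, "positive", purity = 0.6, seed = 5)
  expect_equal(dilute_replicate(sp, 0.5, seed = 1)$effective_purity, 0.3)
  sp2 <- simulate_specimen(gm, "positive", purity = 1.0, seed = 6)
  expect_equal(dilute_replicate(sp2, 0.2, seed = 1)$effective_purity, 0.2)
  expect_error(dilute_replicate(sp, 0, seed = 1), class = "scarvalid_config_error")
  expect_error(dilute_replicate(sp, 1.2, seed = 1), class = "scarvalid_config_error")
})

test_that("dilution at 1.0 leaves the VAF distribution unchanged", {
  gm <- build_genome(n_chrom = 8, chrom_length = 8e8)  # ~6,000 SNPs
  sp <- simulate_specimen(gm, "positive", purity = 0.6, seed = 9)
  r <- dilute_replicate(sp, 1.0, seed = 10)
  expect_equal(r$effective_purity, sp$purity)
  ks <- suppressWarnings(
    stats::ks.test(sp$vafs$vaf[sp$vafs$het_in_normal],
                   r$observed_vafs[[1]]$vaf[r$observed_vafs[[1]]$het_in_normal]))
  expect_gt(ks$p.value, 0.01)
})

test_that("LOH allelic imbalance scales linearly with effective purity", {
  gm <- build_genome(n_chrom = 8, chrom_length = 8e8)
  sp <- simulate_specimen(gm, "positive", purity = 0.8, seed = 31)
  loh <- sp$profile[sp$profile$minor_cn == 0 & sp$profile$total_cn == 2, ]
  dils <- c(0.25, 0.4, 0.55, 0.7, 0.85, 1)
  mean_dev <- vapply(seq_along(dils), function(i) {
    r <- dilute_replicate(sp, dils[i], seed = 40 + i)
    v <- r$observed_vafs[[1]]
    v <- v[v$het_in_normal, ]
    inside <- rep(FALSE, nrow(v))
    for (j in seq_len(nrow(loh))) {
      inside <- inside | (v$chrom == loh$chrom[j] & v$pos >= loh$start[j] &
                            v$pos < loh$end[j])
    }
    mean(abs(v$vaf[inside] - 0.5))
  }, numeric(1))
  fit <- stats::lm(mean_dev ~ I(dils * sp$purity))
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("QC failures are independent Bernoulli gates at the given rates", {
  reps <- new_replicate(sprintf("r%d", 1:10000), "s1")
  out <- apply_perturbations(reps, qc_fail_rates = c(0, 0), seed = 1)
  expect_true(all(out$qc_valid))
  out <- apply_perturbations(reps, qc_fail_rates = c(1, 0), seed = 1)
  expect_false(any(out$qc_valid))
  out <- apply_perturbations(reps, qc_fail_rates = c(0.005, 0.010), seed = 2)
  ci <- wilson_ci(sum(!out$qc_valid), nrow(out))
  expect_true(ci$lower <= 0.0149 && 0.0149 <= ci$upper)
  expect_error(apply_perturbations(reps, interferent = "unobtainium"),
               class = "scarvalid_config_error")
})

test_that("positive specimens carry more breakpoints than negatives", {
  gm <- small_genome()
  n <- 60
  set.seed(77)
  bp_of <- function(truth) vapply(seq_len(n), function(i) {
    sum(breakpoints_per_arm(simulate_profile(gm, truth, scar_params()),
                            gm)$breakpoints)
  }, numeric(1))
  pos <- bp_of("positive")
  neg <- bp_of("negative")
  tt <- stats::t.test(pos, neg, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("study cohorts have the documented shapes and are deterministic", {
  gm <- small_genome()
  lob <- generate_study_cohort("lob", genome = gm, seed = 3)
  expect_equal(nrow(lob$manifest), 60)
  expect_equal(nrow(lob$specimens), 5)
  expect_true(all(lob$manifest$qc_valid))
  lod <- generate_study_cohort("lod", genome = gm, seed = 3)
  expect_equal(nrow(lod$manifest), 282)
  expect_equal(length(unique(lod$manifest$specimen_id)), 3)
  prec <- generate_study_cohort("precision", genome = gm, seed = 3)
  expect_equal(nrow(prec$manifest), 792)
  per_spec <- table(prec$manifest$specimen_id)
  expect_true(all(per_spec == 36))
  per_cell <- dplyr::count(prec$manifest, specimen_id, site, reagent_lot,
                           sequencer_or_run)
  expect_true(all(per_cell$n == 2))
  expect_error(
    generate_study_cohort("precision", design = list(sites = 4), genome = gm),
    class = "scarvalid_config_error")
  prec2 <- generate_study_cohort("precision", genome = gm, seed = 3)
  expect_identical(prec$manifest, prec2$manifest)
})
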