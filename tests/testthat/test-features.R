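make_profile <- function(states, chrom = "chr1", arm = "p",
                         arm_start = 0, arm_end = 2.4e7) {
  n <- nrow(states)
  bounds <- seq(arm_start, arm_end, length.out = n + 1)
  tibble::tibble(chrom = chrom, arm = arm, start = bounds[-n - 1],
                 end = bounds[-1], total_cn = states$t, minor_cn = states$m)
}

test_that("breakpoint counting matches stated examples", {
  gm <- build_genome(n_chrom = 1, chrom_length = 1e8, centromere_frac = 0.4)
  # one segment per arm: no breakpoints
  flat <- tibble::tibble(chrom = "chr1", arm = c("p", "q"),
                         start = c(0, 4e7), end = c(4e7, 1e8),
                         total_cn = 2L, minor_cn = 1L)
  expect_equal(breakpoints_per_arm(flat, gm)$breakpoints, c(0L, 0L))
  # CN 2|3|2 on one arm: two breakpoints
  p <- rbind(make_profile(data.frame(t = c(2, 3, 2), m = 1), arm = "p",
                          arm_end = 4e7),
             tibble::tibble(chrom = "chr1", arm = "q", start = 4e7, end = 1e8,
                            total_cn = 2L, minor_cn = 1L))
  expect_equal(breakpoints_per_arm(p, gm)$breakpoints, c(2L, 0L))
  # copy-neutral LOH boundary counts on the allele-specific basis only
  cnloh <- rbind(make_profile(data.frame(t = c(2, 2), m = c(1, 0)), arm = "p",
                              arm_end = 4e7),
                 tibble::tibble(chrom = "chr1", arm = "q", start = 4e7,
                                end = 1e8, total_cn = 2L, minor_cn = 1L))
  expect_equal(breakpoints_per_arm(cnloh, gm)$breakpoints[1], 1L)
  expect_equal(breakpoints_per_arm(cnloh, gm, basis = "total")$breakpoints[1], 0L)
})

test_that("feature detectors match brute-force oracles on random profiles", {
  gm <- small_genome()
  for (seed in 1:100) {
    p <- random_profile(gm, seed)
    for (region in c("whole", "telomeric", "centromeric")) {
      expect_equal(breakpoints_per_arm(p, gm, region)$breakpoints,
                   brute_breakpoints(p, gm, region),
                   info = sprintf("breakpoints seed %d %s", seed, region))
      got <- segment_size_features(p, gm, region)
      expect_equal(got$value[1:6], brute_size_counts(p, gm, region),
                   info = sprintf("sizes seed %d %s", seed, region))
    }
    osc <- oscillation_features(p, gm, "whole")
    chains <- do.call(rbind, lapply(split(p, paste(p$chrom, p$arm)), function(seg) {
      seg <- seg[order(seg$start), ]
      ch <- brute_osc_chains(seg$total_cn)
      if (nrow(ch)) ch$chrom <- seg$chrom[1]
      ch
    }))
    expected_n3 <- if (is.null(chains)) 0 else sum(chains$len >= 3)
    expected_n5 <- if (is.null(chains)) 0 else sum(chains$len >= 5)
    expect_equal(osc$value[osc$feature == "osc_n_ge3"], expected_n3,
                 info = paste("osc n3 seed", seed))
    expect_equal(osc$value[osc$feature == "osc_n_ge5"], expected_n5,
                 info = paste("osc n5 seed", seed))
    for (ch in gm$chrom) {
      expected_longest <- if (is.null(chains) || !any(chains$chrom == ch)) 0 else
        max(chains$len[chains$chrom == ch])
      expect_equal(osc$value[osc$feature == paste0("osc_longest_", ch)],
                   expected_longest, info = paste("osc longest", ch, seed))
    }
  }
})

test_that("oscillation chains follow the alternating two-state definition", {
  gm <- build_genome(n_chrom = 1, chrom_length = 1e8, centromere_frac = 0.4)
  pad_q <- tibble::tibble(chrom = "chr1", arm = "q", start = 4e7, end = 1e8,
                          total_cn = 2L, minor_cn = 1L)
  # constant copy number: no oscillation anywhere
  flat <- rbind(make_profile(data.frame(t = rep(2, 4), m = rep(1, 4)),
                             arm_end = 4e7), pad_q)
  of <- oscillation_features(flat, gm)
  expect_true(all(of$value == 0))
  # 2,3,2,3,2 is one chain of length 5
  p5 <- rbind(make_profile(data.frame(t = c(2, 3, 2, 3, 2), m = 1),
                           arm_end = 4e7), pad_q)
  of5 <- oscillation_features(p5, gm)
  expect_equal(of5$value[of5$feature == "osc_longest_chr1"], 5)
  expect_equal(of5$value[of5$feature == "osc_n_ge3"], 1)
  expect_equal(of5$value[of5$feature == "osc_n_ge5"], 1)
  expect_equal(of5$value[of5$feature == "osc_segments_in_chains"], 5)
  # 2,3,4,3,2 has no two-state run longer than 3
  p3 <- rbind(make_profile(data.frame(t = c(2, 3, 4, 3, 2), m = 1),
                           arm_end = 4e7), pad_q)
  of3 <- oscillation_features(p3, gm)
  expect_equal(of3$value[of3$feature == "osc_longest_chr1"], 3)
  bf <- brute_osc_chains(c(2, 3, 4, 3, 2))
  expect_equal(max(bf$len), 3)
})

test_that("segment-size features handle degenerate windows and whole genome", {
  gm <- small_genome()
  arms <- genome_arms(gm)
  one_per_arm <- tibble::tibble(chrom = arms$chrom, arm = arms$arm,
                                start = arms$start, end = arms$end,
                                total_cn = 2L, minor_cn = 1L)
  sz <- segment_size_features(one_per_arm, gm)
  # 6e7 chromosomes split 0.4/0.6: arms are 24 and 36 Mb, all in 10-30/30-100
  expect_equal(sum(sz$value[1:6]), nrow(arms))
  expect_equal(sum(sz$value[7:12]), 1)  # fractions sum to 1 over the genome
  empty_tel <- segment_size_features(one_per_arm, gm, "telomeric", f_tel = 0)
  expect_true(all(empty_tel$value == 0))
})

test_that("gLOH counts sub-arm LOH and excludes whole-arm events", {
  gm <- build_genome(n_chrom = 2, chrom_length = 1e8, centromere_frac = 0.5)
  base <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 2), arm = rep(c("p", "q"), 2),
    start = rep(c(0, 5e7), 2), end = rep(c(5e7, 1e8), 2),
    total_cn = 2L, minor_cn = 1L)
  expect_equal(compute_gloh(base, gm), 0)
  # half the genome LOH in sub-arm pieces (60% of each arm)
  half <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 4),
    arm = rep(rep(c("p", "q"), each = 2), 2),
    start = rep(c(0, 2.5e7, 5e7, 7.5e7), 2),
    end = rep(c(2.5e7, 5e7, 7.5e7, 1e8), 2),
    total_cn = 2L, minor_cn = rep(c(0L, 1L), 4))
  expect_equal(compute_gloh(half, gm), 0.5)
  # a single whole-arm LOH event is excluded
  whole_arm <- base
  whole_arm$minor_cn[1] <- 0L
  expect_equal(compute_gloh(whole_arm, gm), 0)
  # homozygous deletion (total 0) is not LOH here
  del <- base
  del$total_cn[1] <- 0L
  del$minor_cn[1] <- 0L
  expect_equal(compute_gloh(del, gm), 0)
})

test_that("region additivity holds for breakpoints", {
  gm <- small_genome()
  for (seed in 101:115) {
    p <- random_profile(gm, seed)
    whole <- breakpoints_per_arm(p, gm, "whole")$breakpoints
    tel <- breakpoints_per_arm(p, gm, "telomeric")$breakpoints
    cen <- breakpoints_per_arm(p, gm, "centromeric")$breakpoints
    int <- breakpoints_per_arm(p, gm, "interstitial")$breakpoints
    expect_equal(tel + cen + int, whole)
  }
})

test_that("window intersections conserve region length", {
  gm <- small_genome()
  reg <- arm_regions(gm, 0.2, 0.2)
  for (seed in 201:210) {
    p <- random_profile(gm, seed)
    for (region in c("telomeric", "centromeric")) {
      sz <- segment_size_features(p, gm, region)
      w <- reg[reg$region == region, ]
      expect_equal(sum(sz$value[7:12]), 1)  # fractions fill the region
    }
  }
})

test_that("feature vector has the fixed schema and is order-invariant", {
  gm <- small_genome()
  schema <- feature_schema(build_genome())
  expect_gte(length(schema), 100)
  sp <- simulate_specimen(gm, "positive", purity = 0.7, seed = 3)
  f1 <- assemble_features(sp$profile, gm)
  expect_equal(names(f1), feature_schema(gm))
  expect_true(all(is.finite(unlist(f1))))
  f2 <- assemble_features(sp$profile, gm)
  expect_identical(f1, f2)
  shuffled <- sp$profile[sample(nrow(sp$profile)), ]
  f3 <- assemble_features(shuffled, gm)
  expect_equal(f1, f3)
  expect_error(feature_config(schema_version = "9.9"),
               class = "scarvalid_config_error")
})

test_that("mean breakpoint feature responds monotonically to the scar rate", {
  gm <- small_genome()
  rates <- c(2, 4, 6, 8, 10)
  set.seed(55)
  means <- vapply(rates, function(r) {
    pars <- scar_params(breakpoint_rate_pos = r)
    mean(vapply(1:50, function(i) {
      sum(breakpoints_per_arm(simulate_profile(gm, "positive", pars),
                              gm)$breakpoints)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(stats::cor(rates, means, method = "spearman"), 0.9)
  expect_true(all(diff(means) > 0))
})
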