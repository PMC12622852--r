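test_that("Wilson intervals reproduce published two-decimal bounds", {
  w <- wilson_ci(20, 20)
  expect_equal(round_half_up(100 * w$lower), 83.89)
  expect_equal(round_half_up(100 * w$upper), 100.00)
  w <- wilson_ci(35, 36)
  expect_equal(round_half_up(100 * w$lower), 85.83)
  expect_equal(round_half_up(100 * w$upper), 99.51)
  # closed-form boundary behavior
  w0 <- wilson_ci(0, 25)
  expect_equal(w0$lower, 0)
  z <- qnorm(0.975)
  wn <- wilson_ci(25, 25)
  expect_equal(wn$lower, 25 / (25 + z^2))
  expect_equal(wn$upper, 1)
  expect_error(wilson_ci(1, 0), class = "scarvalid_input_error")
  expect_error(wilson_ci(5, 3), class = "scarvalid_input_error")
})

test_that("Wilson closed form equals score-test inversion to 1e-9", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(1:500, 1)
    x <- sample(0:n, 1)
    w <- wilson_ci(x, n)
    inv <- wilson_by_inversion(x, n)
    expect_lt(abs(w$lower - inv["lower"]), 1e-9)
    expect_lt(abs(w$upper - inv["upper"]), 1e-9)
  }
})

make_calls <- function(call, qc = TRUE, specimen = "s1", run = NA_integer_) {
  tibble::tibble(specimen_id = specimen, run_index = run,
                 qc_valid = qc, call = call)
}

test_that("LoB FPR is validity-weighted", {
  reps <- make_calls(rep("negative", 60))
  f <- lob_fpr(reps)
  expect_equal(f$estimate, 0)
  expect_equal(f$n, 60)
  reps <- make_calls(c("positive", rep("negative", 9)))
  expect_equal(lob_fpr(reps)$estimate, 0.1)
  # invalid replicates leave both sums
  reps <- make_calls(rep("positive", 10), qc = rep(c(TRUE, FALSE), each = 5))
  f <- lob_fpr(reps)
  expect_equal(f$estimate, 1)
  expect_equal(f$n, 5)
  expect_error(lob_fpr(make_calls("positive", qc = FALSE)),
               class = "scarvalid_input_error")
})

test_that("dilution factor has the right fixed points and recovers dilutions", {
  gm <- small_genome()
  sp <- simulate_specimen(gm, "positive", purity = 0.7, seed = 13)
  expect_equal(dilution_factor(sp$vafs, sp$vafs), 1.0)
  flat <- sp$vafs
  flat$vaf <- 0.5
  expect_equal(dilution_factor(sp$vafs, flat), 0.0)
  few <- sp$vafs[1:30, ]
  expect_error(dilution_factor(few, few), class = "scarvalid_input_error")
  r <- dilute_replicate(sp, 0.5, seed = 14)
  expect_lt(abs(dilution_factor(sp$vafs, r$observed_vafs[[1]]) - 0.5), 0.05)
})

test_that("adjusted tumor purity is the clamped product", {
  expect_equal(adjusted_tp(0.6, 0.5), 0.3)
  expect_equal(adjusted_tp(0.37, 1.0), 0.37)
  expect_equal(adjusted_tp(0.8, 0), 0)
  expect_error(adjusted_tp(1.4, 0.5))
})

test_that("LoD selection picks the lowest passing level and the median", {
  levels <- tibble::tibble(
    specimen_id = rep(c("S1", "S2", "S3"), each = 2),
    level = rep(c(0.2, 0.3), 3),
    hit_rate = c(1, 1, 1, 1, 1, 1),
    mean_adjusted_tp = c(0.2304, 0.33, 0.2451, 0.34, 0.1221, 0.29))
  out <- determine_lod(levels)
  expect_equal(out$lod, 0.2304)  # median of 23.04 / 24.51 / 12.21
  expect_true(all(out$per_specimen$level == 0.2))
  # failing the lowest level moves up
  levels$hit_rate[1] <- 0.8
  out2 <- determine_lod(levels)
  expect_equal(out2$per_specimen$mean_adjusted_tp[
    out2$per_specimen$specimen_id == "S1"], 0.33)
  # single specimen: overall equals its own value
  one <- levels[levels$specimen_id == "S2", ]
  expect_equal(determine_lod(one)$lod, 0.2451)
  # monotone in the threshold: a stricter threshold never picks a lower level
  set.seed(3)
  for (i in 1:20) {
    lv <- tibble::tibble(specimen_id = "X", level = c(0.2, 0.3, 0.4, 0.5),
                         hit_rate = sort(runif(4)),
                         mean_adjusted_tp = c(0.2, 0.3, 0.4, 0.5))
    th <- sort(runif(2, 0, max(lv$hit_rate)))
    l1 <- determine_lod(lv, th[1])$per_specimen$level
    l2 <- determine_lod(lv, th[2])$per_specimen$level
    expect_gte(l2, l1)
  }
  none <- tibble::tibble(specimen_id = "Y", level = 0.2, hit_rate = 0.5,
                         mean_adjusted_tp = 0.2)
  expect_error(determine_lod(none), class = "scarvalid_input_error")
})

test_that("PPA/NPA match the published contingency table", {
  tab <- tibble::tibble(a = 90, b = 7, c = 10, d = 119,
                        unknown_pos = 1, unknown_neg = 2)
  pn <- concordance_ppa_npa(tab)
  ppa <- pn[pn$metric == "ppa", ]
  npa <- pn[pn$metric == "npa", ]
  expect_equal(round_half_up(100 * ppa$estimate), 90.00)
  expect_equal(round_half_up(100 * npa$estimate), 94.44)
  expect_equal(round_half_up(100 * c(ppa$lower, ppa$upper)), c(82.56, 94.48))
  expect_equal(round_half_up(100 * c(npa$lower, npa$upper)), c(88.98, 97.28))
  pn_u <- concordance_ppa_npa(tab, include_unknown_in_npa = TRUE)
  expect_equal(round_half_up(100 * pn_u$estimate[pn_u$metric == "npa"]), 92.97)
  perfect <- tibble::tibble(a = 5, b = 0, c = 0, d = 5)
  pnp <- concordance_ppa_npa(perfect)
  expect_equal(pnp$estimate, c(1, 1))
  expect_error(concordance_ppa_npa(tibble::tibble(a = 0, b = 1, c = 0, d = 1)),
               class = "scarvalid_input_error")
})

test_that("majority reference resolves the 50% tie to positive", {
  expect_equal(majority_reference(rep("positive", 36)), "positive")
  expect_equal(majority_reference(rep(c("positive", "negative"), c(18, 18))),
               "positive")
  expect_equal(majority_reference(rep(c("positive", "negative"), c(17, 19))),
               "negative")
  expect_equal(majority_reference(c("unknown", "negative")), "negative")
  expect_error(majority_reference(rep("unknown", 3)),
               class = "scarvalid_input_error")
})

precision_manifest <- function() {
  # 2 specimens x 3 runs x 2 replicates with one discordant and one
  # invalid replicate
  m <- tidyr::expand_grid(specimen_id = c("A", "B"), run_index = 1:3,
                          rep_k = 1:2)
  m$qc_valid <- TRUE
  m$call <- ifelse(m$specimen_id == "A", "positive", "negative")
  m$call[m$specimen_id == "A" & m$run_index == 2 & m$rep_k == 2] <- "negative"
  m$qc_valid[m$specimen_id == "B" & m$run_index == 3 & m$rep_k == 1] <- FALSE
  m
}

test_that("reproducibility pools agreement by reference status", {
  m <- precision_manifest()
  rs <- reproducibility(m)
  a <- rs$per_specimen[rs$per_specimen$specimen_id == "A", ]
  expect_equal(a$reference, "positive")
  expect_equal(c(a$x, a$n), c(5, 6))
  b <- rs$per_specimen[rs$per_specimen$specimen_id == "B", ]
  expect_equal(c(b$x, b$n), c(5, 5))  # invalid replicate excluded
  pooled <- rs$pooled
  expect_equal(pooled$estimate[pooled$reference == "negative"], 1)
  # pooled counts that mirror the published table give the published rates
  expect_equal(round_half_up(100 * wilson_ci(363, 364)$estimate), 99.73)
  expect_equal(round_half_up(100 * wilson_ci(389, 391)$estimate), 99.49)
})

test_that("repeatability counts only complete valid pairs", {
  m <- precision_manifest()
  r <- repeatability(m)
  # specimen A: 3 pairs, one discordant; specimen B: run 3 incomplete
  expect_equal(c(r$x, r$n), c(4, 5))
  expect_equal(round_half_up(100 * wilson_ci(368, 371)$estimate), 99.19)
  all_bad <- dplyr::mutate(m, qc_valid = FALSE)
  expect_error(repeatability(all_bad), class = "scarvalid_input_error")
})

test_that("agreement statistics ignore replicate order and invalid rows", {
  m <- precision_manifest()
  shuffled <- m[sample(nrow(m)), ]
  extra <- dplyr::bind_rows(shuffled,
                            tibble::tibble(specimen_id = "A", run_index = 9L,
                                           rep_k = 1L, qc_valid = FALSE,
                                           call = "positive"))
  expect_equal(reproducibility(m)$pooled, reproducibility(extra)$pooled)
  expect_equal(repeatability(m), repeatability(extra))
})

test_that("interference agreement uses control-based references", {
  m <- tibble::tibble(
    specimen_id = rep(c("S", "N"), c(6, 2)),
    interferent = c(rep("normal_control", 2), rep("melanin", 2),
                    rep("ethanol", 2), rep("necrosis", 2)),
    concentration = NA_character_,
    condition = c(rep("control", 2), rep("spiked", 6)),
    qc_valid = TRUE,
    call = c("positive", "positive", "positive", "positive", "positive",
             "negative", "positive", "negative"))
  ia <- interference_agreement(m)
  eth <- ia$per_group[ia$per_group$interferent == "ethanol", ]
  expect_equal(eth$estimate, 0.5)
  # necrosis group: no control, majority over own replicates, tie -> positive
  nec <- ia$per_group[ia$per_group$specimen_id == "N", ]
  expect_equal(nec$estimate, 0.5)
  expect_false(nec$in_overall)
  # overall excludes the necrosis group: 5/6
  expect_equal(ia$overall$x, 5)
  expect_equal(ia$overall$n, 6)
})

test_that("half-up rounding matches report conventions", {
  expect_equal(round_half_up(92.96875), 92.97)
  expect_equal(round_half_up(82.555), 82.56)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
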