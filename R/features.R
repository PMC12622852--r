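#' Feature-extraction configuration
#'
#' @param f_tel,f_cen telomeric / centromeric window extents as fractions of
#'   arm length.
#' @param breakpoint_basis `"allele_specific"` (a breakpoint is any change in
#'   the `(total_cn, minor_cn)` pair, so copy-neutral LOH boundaries count) or
#'   `"total"` (total copy number only).
#' @param schema_version feature schema version tag.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(f_tel = 0.2, f_cen = 0.2,
                           breakpoint_basis = c("allele_specific", "total"),
                           schema_version = "1.0") {
  breakpoint_basis <- match.arg(breakpoint_basis)
  if (!identical(schema_version, "1.0")) {
    abort(paste0("unknown feature schema version: ", schema_version),
          class = "scarvalid_config_error")
  }
  structure(list(f_tel = f_tel, f_cen = f_cen,
                 breakpoint_basis = breakpoint_basis,
                 schema_version = schema_version),
            class = "feature_config")
}

# annotate profile rows with arm labels, splitting segments that cross a
# centromere; validates that segments fall inside their chromosome
annotate_arms <- function(profile, genome) {
  if ("arm" %in% names(profile) && !anyNA(profile$arm)) return(profile)
  if (!all(profile$chrom %in% genome$chrom)) {
    abort("profile contains chromosomes absent from the genome model.",
          class = "scarvalid_input_error")
  }
  cen <- setNames(genome$centromere, genome$chrom)
  cpos <- unname(cen[profile$chrom])
  crosses <- profile$start < cpos & profile$end > cpos
  whole <- profile[!crosses, , drop = FALSE]
  whole$arm <- ifelse(whole$end <= cpos[!crosses], "p", "q")
  if (any(crosses)) {
    xs <- profile[crosses, , drop = FALSE]
    cp <- cpos[crosses]
    left <- xs; left$end <- cp; left$arm <- "p"
    right <- xs; right$start <- cp; right$arm <- "q"
    whole <- bind_rows(whole, left, right)
  }
  whole |>
    arrange(match(.data$chrom, genome$chrom), .data$start) |>
    select("chrom", "arm", everything())
}

# per-arm window lookup (named by arm_id) for one region
region_window_lookup <- function(genome, region, f_tel, f_cen) {
  arms <- genome_arms(genome)
  if (region == "whole") {
    return(list(start = setNames(arms$start, arms$arm_id),
                end = setNames(arms$end, arms$arm_id),
                arm_id = arms$arm_id))
  }
  tel_len <- round(arms$arm_length * f_tel)
  cen_len <- round(arms$arm_length * f_cen)
  is_p <- arms$arm == "p"
  if (region == "telomeric") {
    s <- ifelse(is_p, arms$start, arms$end - tel_len)
    e <- ifelse(is_p, arms$start + tel_len, arms$end)
  } else if (region == "centromeric") {
    s <- ifelse(is_p, arms$end - cen_len, arms$start)
    e <- ifelse(is_p, arms$end, arms$start + cen_len)
  } else {
    s <- ifelse(is_p, arms$start + tel_len, arms$start + cen_len)
    e <- ifelse(is_p, arms$end - cen_len, arms$end - tel_len)
  }
  list(start = setNames(s, arms$arm_id), end = setNames(e, arms$arm_id),
       arm_id = arms$arm_id)
}

region_windows <- function(genome, region, f_tel, f_cen) {
  w <- region_window_lookup(genome, region, f_tel, f_cen)
  arms <- genome_arms(genome)
  tibble(chrom = arms$chrom, arm = arms$arm, arm_id = arms$arm_id,
         region = region, start = unname(w$start), end = unname(w$end))
}

# ordered profile pre-processing shared by the extractors
prep_profile <- function(profile, genome) {
  profile <- annotate_arms(profile, genome)
  key <- paste0(profile$chrom, profile$arm)
  ord <- order(match(profile$chrom, genome$chrom), profile$arm, profile$start)
  profile <- profile[ord, , drop = FALSE]
  list(p = profile, key = key[ord])
}

# positions of same-arm state-change boundaries; returns list of vectors
bp_positions <- function(pp, basis) {
  p <- pp$p
  n <- nrow(p)
  if (n < 2) return(list(arm_id = character(), pos = numeric()))
  same_arm <- pp$key[-1] == pp$key[-n]
  changed <- if (basis == "total") {
    p$total_cn[-1] != p$total_cn[-n]
  } else {
    p$total_cn[-1] != p$total_cn[-n] | p$minor_cn[-1] != p$minor_cn[-n]
  }
  sel <- same_arm & changed
  list(arm_id = pp$key[-1][sel], pos = p$start[-1][sel])
}

bp_counts_in_window <- function(bp, win) {
  inside <- bp$pos >= win$start[bp$arm_id] & bp$pos < win$end[bp$arm_id]
  counts <- table(factor(bp$arm_id[inside], levels = win$arm_id))
  as.integer(counts)
}

#' Breakpoints per chromosome arm
#'
#' A breakpoint is a boundary between two adjacent same-arm segments that
#' differ in copy-number state; arm and centromere boundaries are never
#' breakpoints. Regional variants count only breakpoints whose genomic
#' position falls inside the telomeric or centromeric window of the arm.
#'
#' @param profile copy-number profile tibble (`chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`; an `arm` column is derived if absent).
#' @param genome a `genome_model`.
#' @param region `"whole"`, `"telomeric"`, `"centromeric"` or
#'   `"interstitial"`.
#' @param f_tel,f_cen window extents (fractions of arm length).
#' @param basis see [feature_config()].
#' @return tibble with one row per arm: `chrom`, `arm`, `arm_id`,
#'   `breakpoints`.
#' @export
breakpoints_per_arm <- function(profile, genome,
                                region = c("whole", "telomeric",
                                           "centromeric", "interstitial"),
                                f_tel = 0.2, f_cen = 0.2,
                                basis = c("allele_specific", "total")) {
  region <- match.arg(region)
  basis <- match.arg(basis)
  pp <- prep_profile(profile, genome)
  win <- region_window_lookup(genome, region, f_tel, f_cen)
  counts <- bp_counts_in_window(bp_positions(pp, basis), win)
  arms <- genome_arms(genome)
  tibble(chrom = arms$chrom, arm = arms$arm, arm_id = arms$arm_id,
         breakpoints = counts)
}

size_bin_breaks <- function() c(0, 1e6, 3e6, 1e7, 3e7, 1e8, Inf)
size_bin_labels <- function() c("lt1mb", "1to3mb", "3to10mb", "10to30mb",
                                "30to100mb", "ge100mb")

size_feature_values <- function(pp, win) {
  lo <- pmax(pp$p$start, win$start[pp$key])
  hi <- pmin(pp$p$end, win$end[pp$key])
  len <- hi - lo
  len <- len[len > 0]
  region_total <- sum(win$end - win$start)
  bin <- findInterval(len, size_bin_breaks()[-1]) + 1L
  counts <- tabulate(bin, nbins = 6)
  sums <- vapply(1:6, function(b) sum(len[bin == b]), numeric(1))
  fracs <- if (region_total > 0) sums / region_total else rep(0, 6)
  mlog <- if (length(len)) mean(log10(len)) else 0
  mdlog <- if (length(len)) median(log10(len)) else 0
  c(counts, fracs, mlog, mdlog)
}

#' Segment-size spectrum features
#'
#' Counts and genome-fraction per size bin (`<1`, `1-3`, `3-10`, `10-30`,
#' `30-100`, `>=100` Mb) plus mean and median log10 segment size. For the
#' telomeric/centromeric variants, segments are clipped to the window and
#' the clipped intersection lengths are binned; fractions are relative to
#' the region's total length. An empty region yields all-zero features.
#'
#' @inheritParams breakpoints_per_arm
#' @return tibble with columns `feature`, `value`.
#' @export
segment_size_features <- function(profile, genome,
                                  region = c("whole", "telomeric",
                                             "centromeric", "interstitial"),
                                  f_tel = 0.2, f_cen = 0.2) {
  region <- match.arg(region)
  pp <- prep_profile(profile, genome)
  win <- region_window_lookup(genome, region, f_tel, f_cen)
  tibble(feature = c(paste0("size_n_", size_bin_labels()),
                     paste0("size_frac_", size_bin_labels()),
                     "size_mean_log10", "size_median_log10"),
         value = size_feature_values(pp, win))
}

# maximal alternating two-state runs of length >= 3 over a total-CN
# sequence; returns matrix with columns start, end, len (sequence indices)
osc_chains_idx <- function(v) {
  n <- length(v)
  if (n < 3) return(matrix(integer(0), ncol = 3,
                           dimnames = list(NULL, c("start", "end", "len"))))
  len <- integer(n)
  len[1] <- 1L
  for (i in 2:n) {
    len[i] <- if (v[i] == v[i - 1]) 1L
      else if (i >= 3 && v[i] == v[i - 2] && len[i - 1] >= 2L) len[i - 1] + 1L
      else 2L
  }
  # a chain ends at i when the alternation does not extend to i + 1
  is_end <- len >= 3L & c(len[-1] != len[-n] + 1L, TRUE)
  ends <- which(is_end)
  cbind(start = ends - len[ends] + 1L, end = ends, len = len[ends])
}

osc_region_values <- function(pp, win, chroms, per_chrom = FALSE) {
  lo <- pmax(pp$p$start, win$start[pp$key])
  hi <- pmin(pp$p$end, win$end[pp$key])
  keep <- hi > lo
  key <- pp$key[keep]
  totals <- pp$p$total_cn[keep]
  chrom <- pp$p$chrom[keep]
  lens <- integer(0)
  chain_chrom <- character(0)
  covered <- 0L
  for (aid in unique(key)) {
    ii <- key == aid
    ch <- osc_chains_idx(totals[ii])
    if (nrow(ch)) {
      lens <- c(lens, ch[, "len"])
      chain_chrom <- c(chain_chrom, rep(chrom[ii][1], nrow(ch)))
      covered <- covered +
        length(unique(unlist(Map(seq, ch[, "start"], ch[, "end"]))))
    }
  }
  base <- c(n_ge3 = sum(lens >= 3), n_ge5 = sum(lens >= 5),
            n_ge10 = sum(lens >= 10), covered = covered,
            longest = if (length(lens)) max(lens) else 0L)
  if (!per_chrom) return(base)
  per <- vapply(chroms, function(ch) {
    x <- lens[chain_chrom == ch]
    if (length(x)) max(x) else 0L
  }, integer(1))
  list(per_chrom = per, base = base)
}

#' Copy-number oscillation features
#'
#' An oscillation chain is a maximal run of at least three consecutive
#' same-arm segments whose total copy numbers alternate between exactly two
#' distinct states (a, b, a, b, ...). Features report the longest chain per
#' chromosome, the number of chains of length >= 3 / 5 / 10, the number of
#' segments lying inside any chain (chains sharing a pivot segment count it
#' once), and the genome-wide longest chain. Regional variants evaluate
#' chains over the segments intersecting the telomeric or centromeric
#' windows.
#'
#' @inheritParams breakpoints_per_arm
#' @return tibble with columns `feature`, `value`.
#' @export
oscillation_features <- function(profile, genome,
                                 region = c("whole", "telomeric",
                                            "centromeric"),
                                 f_tel = 0.2, f_cen = 0.2) {
  region <- match.arg(region)
  pp <- prep_profile(profile, genome)
  win <- region_window_lookup(genome, region, f_tel, f_cen)
  if (region == "whole") {
    ov <- osc_region_values(pp, win, genome$chrom, per_chrom = TRUE)
    tibble(
      feature = c(paste0("osc_longest_", genome$chrom),
                  "osc_n_ge3", "osc_n_ge5", "osc_n_ge10",
                  "osc_segments_in_chains", "osc_longest"),
      value = c(as.numeric(ov$per_chrom),
                as.numeric(ov$base[c("n_ge3", "n_ge5", "n_ge10", "covered",
                                     "longest")]))
    )
  } else {
    ov <- osc_region_values(pp, win, genome$chrom)
    tibble(
      feature = c("osc_n_ge3", "osc_n_ge5", "osc_segments_in_chains",
                  "osc_longest"),
      value = as.numeric(ov[c("n_ge3", "n_ge5", "covered", "longest")])
    )
  }
}

#' Genome-wide LOH fraction (gLOH)
#'
#' Fraction of the genome in loss of heterozygosity (minor copy number 0
#' with at least one copy retained), excluding whole-arm events: a
#' contiguous run of LOH segments covering at least `arm_exclusion`
#' (default 90%) of its arm is not counted in the numerator. The
#' denominator is the full genome length.
#'
#' @inheritParams breakpoints_per_arm
#' @param arm_exclusion arm-fraction threshold above which an LOH run is
#'   treated as a whole-arm event and excluded.
#' @return a single fraction in `[0, 1]`.
#' @export
compute_gloh <- function(profile, genome, arm_exclusion = 0.9) {
  pp <- prep_profile(profile, genome)
  p <- pp$p
  arms <- genome_arms(genome)
  arm_len <- setNames(arms$arm_length, arms$arm_id)
  is_loh <- p$minor_cn == 0 & p$total_cn >= 1
  seg_len <- p$end - p$start
  n <- nrow(p)
  run <- cumsum(c(TRUE, is_loh[-1] != is_loh[-n] | pp$key[-1] != pp$key[-n]))
  run_len <- as.numeric(tapply(seg_len, run, sum))
  run_loh <- as.logical(tapply(is_loh, run, function(x) x[1]))
  run_arm <- as.character(tapply(pp$key, run, function(x) x[1]))
  keep <- run_loh & run_len < arm_exclusion * arm_len[run_arm]
  sum(run_len[keep]) / sum(genome$length)
}

#' Feature schema
#'
#' The fixed, ordered list of feature names produced by
#' [assemble_features()] for a given genome and configuration.
#'
#' @param genome a `genome_model`.
#' @param config a [feature_config()].
#' @return character vector of feature names in canonical order.
#' @export
feature_schema <- function(genome, config = feature_config()) {
  regions <- c("whole", "telomeric", "centromeric")
  bp_sum <- c("mean", "max", "total", "arms_ge1", "arms_ge3", "arms_ge5",
              "arms_ge10")
  nm <- character(0)
  for (r in regions) nm <- c(nm, paste0("bp_", bp_sum, "_", r))
  nm <- c(nm, paste0("bp_chr_", genome$chrom))
  for (r in regions) {
    nm <- c(nm, paste0(c(paste0("size_n_", size_bin_labels()),
                         paste0("size_frac_", size_bin_labels()),
                         "size_mean_log10", "size_median_log10"), "_", r))
  }
  nm <- c(nm, paste0(c(paste0("osc_longest_", genome$chrom),
                       "osc_n_ge3", "osc_n_ge5", "osc_n_ge10",
                       "osc_segments_in_chains", "osc_longest"), "_whole"))
  for (r in c("telomeric", "centromeric")) {
    nm <- c(nm, paste0(c("osc_n_ge3", "osc_n_ge5", "osc_segments_in_chains",
                         "osc_longest"), "_", r))
  }
  c(nm, "gloh")
}

assemble_feature_values <- function(profile, genome, config, wins, arms) {
  pp <- prep_profile(profile, genome)
  vals <- numeric(0)
  bp <- bp_positions(pp, config$breakpoint_basis)
  whole_counts <- NULL
  for (r in c("whole", "telomeric", "centromeric")) {
    x <- bp_counts_in_window(bp, wins[[r]])
    if (r == "whole") whole_counts <- x
    vals <- c(vals, mean(x), max(x), sum(x), sum(x >= 1), sum(x >= 3),
              sum(x >= 5), sum(x >= 10))
  }
  per_chrom <- tapply(whole_counts, arms$chrom, sum)
  vals <- c(vals, as.numeric(per_chrom[genome$chrom]))
  for (r in c("whole", "telomeric", "centromeric")) {
    vals <- c(vals, size_feature_values(pp, wins[[r]]))
  }
  ov <- osc_region_values(pp, wins$whole, genome$chrom, per_chrom = TRUE)
  vals <- c(vals, as.numeric(ov$per_chrom),
            as.numeric(ov$base[c("n_ge3", "n_ge5", "n_ge10", "covered",
                                 "longest")]))
  for (r in c("telomeric", "centromeric")) {
    o <- osc_region_values(pp, wins[[r]], genome$chrom)
    vals <- c(vals, as.numeric(o[c("n_ge3", "n_ge5", "covered", "longest")]))
  }
  c(vals, compute_gloh(profile, genome))
}

#' Assemble the scar feature vector for one profile
#'
#' Concatenates the three scar feature families (breakpoints per arm,
#' segment-size spectrum, oscillation) over the three regions (genome-wide,
#' telomeric, centromeric), per-arm breakpoint summaries and per-chromosome
#' counts, plus the gLOH fraction, in the deterministic order given by
#' [feature_schema()]. All values are finite; absent signal encodes 0.
#'
#' @inheritParams feature_schema
#' @param profile copy-number profile tibble.
#' @return a one-row tibble whose columns are the schema features.
#' @export
assemble_features <- function(profile, genome, config = feature_config()) {
  wins <- lapply(setNames(nm = c("whole", "telomeric", "centromeric")),
                 region_window_lookup, genome = genome, f_tel = config$f_tel,
                 f_cen = config$f_cen)
  arms <- genome_arms(genome)
  vals <- assemble_feature_values(profile, genome, config, wins, arms)
  nm <- feature_schema(genome, config)
  stopifnot(length(vals) == length(nm), all(is.finite(vals)))
  out <- as_tibble(as.data.frame(t(vals)))
  names(out) <- nm
  attr(out, "schema_version") <- config$schema_version
  out
}

#' Feature matrix for a set of profiles
#'
#' @param profiles either a tibble with a `sample_id` column and a
#'   list-column of profiles (default name `profile`), or a named list of
#'   profile tibbles.
#' @param genome a `genome_model`.
#' @param config a [feature_config()].
#' @param profile_col name of the list-column holding profiles.
#' @return tibble: one row per sample, `sample_id` plus the schema features.
#' @export
scar_feature_matrix <- function(profiles, genome, config = feature_config(),
                                profile_col = "profile") {
  if (is_tibble(profiles) || is.data.frame(profiles)) {
    ids <- profiles$sample_id %||% profiles$specimen_id
    plist <- profiles[[profile_col]]
  } else {
    ids <- names(profiles)
    plist <- profiles
  }
  wins <- lapply(setNames(nm = c("whole", "telomeric", "centromeric")),
                 region_window_lookup, genome = genome, f_tel = config$f_tel,
                 f_cen = config$f_cen)
  arms <- genome_arms(genome)
  mat <- vapply(plist, assemble_feature_values, genome = genome,
                config = config, wins = wins, arms = arms,
                FUN.VALUE = numeric(length(feature_schema(genome, config))))
  out <- as_tibble(as.data.frame(t(mat)))
  names(out) <- feature_schema(genome, config)
  out <- bind_cols(tibble(sample_id = ids), out)
  attr(out, "schema_version") <- config$schema_version
  out
}
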