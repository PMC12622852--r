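# shared fixtures: a small genome for fast tests, brute-force feature
# oracles, and a lazily trained classifier reused across test files

small_genome <- function() build_genome(n_chrom = 6, chrom_length = 6e7)

# independent random profile generator (not the package simulator): random
# boundaries and states per arm, no constraint that adjacent states differ
random_profile <- function(genome, seed, max_breaks = 8) {
  set.seed(seed)
  arms <- genome_arms(genome)
  rows <- lapply(seq_len(nrow(arms)), function(i) {
    k <- sample(0:max_breaks, 1)
    bp <- sort(unique(round(runif(k, arms$start[i] + 1, arms$end[i] - 1))))
    bounds <- c(arms$start[i], bp, arms$end[i])
    n <- length(bounds) - 1
    total <- sample(0:4, n, replace = TRUE)
    minor <- vapply(total, function(t) {
      if (t < 1) 0L else sample(0:(t %/% 2), 1)
    }, integer(1))
    data.frame(chrom = arms$chrom[i], arm = arms$arm[i],
               start = bounds[-n - 1], end = bounds[-1],
               total_cn = total, minor_cn = minor)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# brute-force breakpoint count: scan every adjacent same-arm pair
brute_breakpoints <- function(profile, genome, region = "whole",
                              f_tel = 0.2, f_cen = 0.2) {
  arms <- genome_arms(genome)
  win <- if (region == "whole") {
    data.frame(arm_id = arms$arm_id, start = arms$start, end = arms$end)
  } else {
    w <- arm_regions(genome, f_tel, f_cen)
    w <- w[w$region == region, c("arm_id", "start", "end")]
    as.data.frame(w)
  }
  counts <- integer(nrow(arms))
  for (i in seq_len(nrow(arms))) {
    seg <- profile[profile$chrom == arms$chrom[i] & profile$arm == arms$arm[i], ]
    seg <- seg[order(seg$start), ]
    wrow <- win[win$arm_id == arms$arm_id[i], ]
    cnt <- 0L
    if (nrow(seg) > 1) {
      for (j in 2:nrow(seg)) {
        if (seg$total_cn[j] != seg$total_cn[j - 1] ||
            seg$minor_cn[j] != seg$minor_cn[j - 1]) {
          pos <- seg$start[j]
          if (pos >= wrow$start && pos < wrow$end) cnt <- cnt + 1L
        }
      }
    }
    counts[i] <- cnt
  }
  counts
}

# brute-force size-bin counts of window-clipped segment lengths
brute_size_counts <- function(profile, genome, region = "whole",
                              f_tel = 0.2, f_cen = 0.2) {
  arms <- genome_arms(genome)
  win <- if (region == "whole") {
    data.frame(arm_id = arms$arm_id, start = arms$start, end = arms$end)
  } else {
    w <- arm_regions(genome, f_tel, f_cen)
    w <- w[w$region == region, c("arm_id", "start", "end")]
    as.data.frame(w)
  }
  counts <- numeric(6)
  breaks <- c(0, 1e6, 3e6, 1e7, 3e7, 1e8, Inf)
  for (r in seq_len(nrow(profile))) {
    aid <- paste0(profile$chrom[r], profile$arm[r])
    wrow <- win[win$arm_id == aid, ]
    lo <- max(profile$start[r], wrow$start)
    hi <- min(profile$end[r], wrow$end)
    len <- hi - lo
    if (len <= 0) next
    for (b in 1:6) {
      if (len >= breaks[b] && len < breaks[b + 1]) counts[b] <- counts[b] + 1
    }
  }
  counts
}

# brute-force oscillation chains: enumerate every sub-run, keep alternating
# two-state runs of length >= 3 not contained in a longer one
brute_osc_chains <- function(v) {
  n <- length(v)
  is_alt <- function(x) {
    if (length(x) < 3) return(FALSE)
    if (length(unique(x)) != 2) return(FALSE)
    all(x[-(1:2)] == x[-((length(x) - 1):length(x))]) &&
      all(x[-1] != x[-length(x)])
  }
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 >= 3 && is_alt(v[i:j])) runs[[length(runs) + 1]] <- c(i, j)
    }
  }
  if (!length(runs)) {
    return(data.frame(start = integer(), end = integer(), len = integer()))
  }
  maximal <- Filter(function(r) {
    !any(vapply(runs, function(s) {
      (s[1] < r[1] && s[2] >= r[2]) || (s[1] <= r[1] && s[2] > r[2])
    }, logical(1)))
  }, runs)
  data.frame(start = vapply(maximal, `[`, 0L, 1),
             end = vapply(maximal, `[`, 0L, 2),
             len = vapply(maximal, function(r) r[2] - r[1] + 1L, 0L))
}

# Wilson bounds by direct root-finding inversion of the score test
wilson_by_inversion <- function(x, n, confidence = 0.95) {
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- x / n
  score <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  lower <- if (x == 0) 0 else if (x == n)
    uniroot(score, c(1e-12, 1 - 1e-12), tol = 1e-14)$root else
    uniroot(score, c(1e-12, phat), tol = 1e-14)$root
  upper <- if (x == n) 1 else if (x == 0)
    uniroot(score, c(1e-12, 1 - 1e-12), tol = 1e-14)$root else
    uniroot(score, c(phat, 1 - 1e-12), tol = 1e-14)$root
  c(lower = lower, upper = upper)
}

# lazily trained classifier shared across tests (moderate cohort size)
.test_cache <- new.env(parent = emptyenv())

# models are genome-specific (per-chromosome features), so cache by genome
cached_model <- function(genome = small_genome()) {
  key <- paste0("model_", nrow(genome))
  if (is.null(.test_cache[[key]])) {
    tr <- train_hrd_caller(genome = genome, n_pos = 80, n_neg = 80, seed = 101)
    .test_cache[[key]] <- tr
  }
  .test_cache[[key]]$model
}

cached_training <- function(genome = small_genome()) {
  invisible(cached_model(genome))
  .test_cache[[paste0("model_", nrow(genome))]]
}
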