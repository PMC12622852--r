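#' Build a genome model
#'
#' Constructs the spatial frame used by the simulator and the feature
#' extractor: a set of chromosomes, each with a length and a centromere
#' position splitting it into a p arm `[0, centromere)` and a q arm
#' `[centromere, length)`. All coordinates are 0-based half-open base pairs.
#'
#' The default is a deterministic toy genome of 22 chromosomes of 100 Mb with
#' the centromere at 40% of each chromosome; real-genome coordinates can be
#' supplied through `chromosomes`.
#'
#' @param n_chrom number of chromosomes (ignored when `chromosomes` given).
#' @param chrom_length chromosome length in bp.
#' @param centromere_frac centromere position as a fraction of length,
#'   strictly inside (0, 1).
#' @param chromosomes optional tibble/data.frame with columns `chrom`,
#'   `length`, `centromere` overriding the regular defaults.
#' @return A tibble of class `genome_model` with columns `chrom`, `length`,
#'   `centromere`.
#' @examples
#' gm <- build_genome()
#' nrow(gm)            # 22
#' sum(gm$length)      # 2.2e9
#' @export
build_genome <- function(n_chrom = 22, chrom_length = 1e8,
                         centromere_frac = 0.4, chromosomes = NULL) {
  if (is.null(chromosomes)) {
    if (n_chrom < 1) abort("`n_chrom` must be >= 1.", class = "scarvalid_config_error")
    if (any(chrom_length <= 0)) {
      abort("chromosome lengths must be positive.", class = "scarvalid_config_error")
    }
    if (any(centromere_frac <= 0 | centromere_frac >= 1)) {
      abort("`centromere_frac` must lie strictly inside (0, 1).",
            class = "scarvalid_config_error")
    }
    chromosomes <- tibble(
      chrom = paste0("chr", seq_len(n_chrom)),
      length = as.numeric(rep_len(chrom_length, n_chrom)),
      centromere = round(as.numeric(rep_len(chrom_length, n_chrom)) *
                           rep_len(centromere_frac, n_chrom))
    )
  } else {
    chromosomes <- as_tibble(chromosomes)
    stopifnot(all(c("chrom", "length", "centromere") %in% names(chromosomes)))
  }
  if (anyDuplicated(chromosomes$chrom)) {
    abort("chromosome names must be unique.", class = "scarvalid_config_error")
  }
  if (any(chromosomes$length <= 0) ||
      any(chromosomes$centromere <= 0 | chromosomes$centromere >= chromosomes$length)) {
    abort("need length > 0 and 0 < centromere < length for every chromosome.",
          class = "scarvalid_config_error")
  }
  structure(chromosomes, class = c("genome_model", class(chromosomes)))
}

#' Arm table of a genome model
#'
#' One row per chromosome arm with its half-open coordinate span.
#'
#' @param genome a `genome_model` from [build_genome()].
#' @return tibble with columns `chrom`, `arm` ("p"/"q"), `arm_id`, `start`,
#'   `end`, `arm_length`.
#' @export
genome_arms <- function(genome) {
  p <- tibble(chrom = genome$chrom, arm = "p", start = 0, end = genome$centromere)
  q <- tibble(chrom = genome$chrom, arm = "q", start = genome$centromere,
              end = genome$length)
  bind_rows(p, q) |>
    mutate(arm_id = paste0(.data$chrom, .data$arm),
           arm_length = .data$end - .data$start) |>
    arrange(match(.data$chrom, genome$chrom), .data$arm)
}

#' Telomeric / centromeric arm windows
#'
#' Splits each arm into a telomeric window (the distal fraction `f_tel` of the
#' arm, anchored at the telomere), a centromeric window (the proximal fraction
#' `f_cen`, anchored at the centromere), and the interstitial remainder. On a
#' p arm the telomere is at coordinate 0; on a q arm it is at the chromosome
#' end. Windows are disjoint provided `f_tel + f_cen <= 1`.
#'
#' @param genome a `genome_model`.
#' @param f_tel,f_cen window extents as fractions of arm length (defaults 0.2).
#' @return tibble with columns `chrom`, `arm`, `arm_id`, `region`
#'   ("telomeric", "centromeric", "interstitial"), `start`, `end`.
#' @export
arm_regions <- function(genome, f_tel = 0.2, f_cen = 0.2) {
  if (f_tel < 0 || f_cen < 0 || f_tel + f_cen > 1) {
    abort("need f_tel >= 0, f_cen >= 0 and f_tel + f_cen <= 1.",
          class = "scarvalid_config_error")
  }
  arms <- genome_arms(genome)
  tel_len <- round(arms$arm_length * f_tel)
  cen_len <- round(arms$arm_length * f_cen)
  # telomere sits at `start` for p arms, at `end` for q arms
  is_p <- arms$arm == "p"
  tel_start <- ifelse(is_p, arms$start, arms$end - tel_len)
  tel_end <- ifelse(is_p, arms$start + tel_len, arms$end)
  cen_start <- ifelse(is_p, arms$end - cen_len, arms$start)
  cen_end <- ifelse(is_p, arms$end, arms$start + cen_len)
  int_start <- ifelse(is_p, tel_end, cen_end)
  int_end <- ifelse(is_p, cen_start, tel_start)
  bind_rows(
    tibble(chrom = arms$chrom, arm = arms$arm, arm_id = arms$arm_id,
           region = "telomeric", start = tel_start, end = tel_end),
    tibble(chrom = arms$chrom, arm = arms$arm, arm_id = arms$arm_id,
           region = "centromeric", start = cen_start, end = cen_end),
    tibble(chrom = arms$chrom, arm = arms$arm, arm_id = arms$arm_id,
           region = "interstitial", start = int_start, end = int_end)
  ) |>
    arrange(.data$arm_id, .data$start)
}
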