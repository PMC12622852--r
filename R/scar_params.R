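#' Scar-process simulation parameters
#'
#' Bundles the rates that control how scarred (HRD-positive) and quiet
#' (HRD-negative) copy-number profiles are generated. The positive/negative
#' contrast is expressed in three feature families: breakpoint density per
#' arm, short-segment excess, and oscillation bursts, plus a differing target
#' genome fraction in loss of heterozygosity (LOH, minor copy number 0).
#'
#' @param breakpoint_rate_pos,breakpoint_rate_neg expected breakpoints per
#'   100 Mb per arm for HRD-positive / negative genomes.
#' @param oscillation_burst_rate_pos,oscillation_burst_rate_neg expected
#'   number of oscillation bursts per genome.
#' @param oscillation_len_range integer pair, burst length range in segments.
#' @param short_segment_bias_pos,short_segment_bias_neg probability that a
#'   breakpoint spawns a companion breakpoint < 10 Mb away, creating a short
#'   segment.
#' @param loh_fraction_pos,loh_fraction_neg target genome fraction with
#'   minor copy number 0.
#' @param cn_state_range integer pair, minimum and maximum total copy number.
#' @param noise_sd log-ratio noise standard deviation; controls how easily a
#'   low-contrast copy-number transition is missed at low tumor purity.
#' @param snp_density heterozygous-SNP density per Mb.
#' @param depth mean sequencing depth at a SNP in a diploid region.
#' @return list of class `scar_params`.
#' @export
scar_params <- function(breakpoint_rate_pos = 8,
                        breakpoint_rate_neg = 1.5,
                        oscillation_burst_rate_pos = 6,
                        oscillation_burst_rate_neg = 0.3,
                        oscillation_len_range = c(4L, 10L),
                        short_segment_bias_pos = 0.4,
                        short_segment_bias_neg = 0.05,
                        loh_fraction_pos = 0.35,
                        loh_fraction_neg = 0.05,
                        cn_state_range = c(0L, 5L),
                        noise_sd = 0.05,
                        snp_density = 1,
                        depth = 500) {
  p <- list(
    breakpoint_rate_pos = breakpoint_rate_pos,
    breakpoint_rate_neg = breakpoint_rate_neg,
    oscillation_burst_rate_pos = oscillation_burst_rate_pos,
    oscillation_burst_rate_neg = oscillation_burst_rate_neg,
    oscillation_len_range = as.integer(oscillation_len_range),
    short_segment_bias_pos = short_segment_bias_pos,
    short_segment_bias_neg = short_segment_bias_neg,
    loh_fraction_pos = loh_fraction_pos,
    loh_fraction_neg = loh_fraction_neg,
    cn_state_range = as.integer(cn_state_range),
    noise_sd = noise_sd,
    snp_density = snp_density,
    depth = depth
  )
  rates <- c(p$breakpoint_rate_pos, p$breakpoint_rate_neg,
             p$oscillation_burst_rate_pos, p$oscillation_burst_rate_neg,
             p$short_segment_bias_pos, p$short_segment_bias_neg,
             p$loh_fraction_pos, p$loh_fraction_neg, p$snp_density, p$depth)
  if (any(rates < 0)) abort("all rates must be >= 0.", class = "scarvalid_config_error")
  if (p$breakpoint_rate_pos <= p$breakpoint_rate_neg) {
    abort("`breakpoint_rate_pos` must exceed `breakpoint_rate_neg`.",
          class = "scarvalid_config_error")
  }
  if (p$cn_state_range[1] < 0 || p$cn_state_range[2] < p$cn_state_range[1]) {
    abort("`cn_state_range` must be a non-decreasing pair with min >= 0.",
          class = "scarvalid_config_error")
  }
  structure(p, class = "scar_params")
}
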