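#' Read and write segmented copy-number profiles
#'
#' The package's profile dialect is a TSV with columns `sample_id`, `chrom`,
#' `start`, `end`, `total_cn`, `minor_cn`. Coordinates are 0-based half-open
#' in memory and 1-based inclusive on disk. `read_profiles()` validates each
#' sample: segments must be sorted and non-overlapping; violations are
#' reported with the offending line numbers.
#'
#' @param profiles long tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`), 0-based half-open.
#' @param path file path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles`
#'   returns the long profile tibble.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles[, c("sample_id", "chrom", "start", "end", "total_cn",
                      "minor_cn")]
  out$start <- format_bp(out$start + 1)
  out$end <- format_bp(out$end)
  readr::write_tsv(out, path)
  invisible(path)
}

format_bp <- function(x) sprintf("%.0f", x)

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", chrom = "c", start = "d", end = "d",
    total_cn = "i", minor_cn = "i"))
  if (nrow(x) == 0) {
    abort("empty profile file.", class = "scarvalid_input_error")
  }
  x$start <- x$start - 1
  x$.line <- seq_len(nrow(x)) + 1L
  for (key in split(seq_len(nrow(x)), paste(x$sample_id, x$chrom))) {
    seg <- x[key, , drop = FALSE]
    ord <- order(seg$start)
    seg <- seg[ord, , drop = FALSE]
    n <- nrow(seg)
    if (n > 1) {
      overlap <- which(seg$start[-1] < seg$end[-n])
      if (length(overlap)) {
        i <- overlap[1]
        abort(sprintf(
          "overlapping segments on %s of %s (lines %d and %d).",
          seg$chrom[1], seg$sample_id[1], seg$.line[i], seg$.line[i + 1]),
          class = "scarvalid_input_error")
      }
    }
    if (any(seg$end <= seg$start)) {
      i <- which(seg$end <= seg$start)[1]
      abort(sprintf("non-positive segment on line %d.", seg$.line[i]),
            class = "scarvalid_input_error")
    }
    if (any(seg$minor_cn > seg$total_cn - seg$minor_cn)) {
      i <- which(seg$minor_cn > seg$total_cn - seg$minor_cn)[1]
      abort(sprintf("minor_cn exceeds the lesser allele count on line %d.",
                    seg$.line[i]), class = "scarvalid_input_error")
    }
  }
  x$.line <- NULL
  x
}

#' Export profiles in standard SEG format
#'
#' Writes `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean = log2(total_cn / 2)` with total copy number 0 floored at a
#' seg.mean of -4; coordinates 1-based inclusive. `num.mark` is approximated
#' as one mark per Mb (minimum 1) since the simulator has no probe grid.
#'
#' @inheritParams write_profiles
#' @export
export_seg <- function(profiles, path) {
  out <- tibble(
    ID = profiles$sample_id,
    chrom = profiles$chrom,
    loc.start = format_bp(profiles$start + 1),
    loc.end = format_bp(profiles$end),
    num.mark = pmax(1L, as.integer(round((profiles$end - profiles$start) / 1e6))),
    seg.mean = round(pmax(log2(pmax(profiles$total_cn, 0) / 2), -4), 4)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write SNP VAF tables
#'
#' TSV with columns `sample_id`, `chrom`, `pos` (0-based), `vaf`, `depth`,
#' `het_in_normal`.
#'
#' @param vafs tibble with the columns above.
#' @param path file path.
#' @export
write_vafs <- function(vafs, path) {
  out <- vafs[, c("sample_id", "chrom", "pos", "vaf", "depth",
                  "het_in_normal")]
  out$vaf <- fmt_num(out$vaf)
  readr::write_tsv(out, path)
  invisible(path)
}

# fixed six-decimal formatting keeps write -> read -> write byte-stable
fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.6f", x))

#' @rdname write_vafs
#' @export
read_vafs <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", chrom = "c", pos = "d", vaf = "d", depth = "i",
    het_in_normal = "l"))
  bad <- which(x$vaf < 0 | x$vaf > 1 | x$depth <= 0)
  if (length(bad)) {
    abort(sprintf("invalid VAF/depth on line %d.", bad[1] + 1L),
          class = "scarvalid_input_error")
  }
  x
}

manifest_scalar_cols <- function() {
  c("replicate_id", "specimen_id", "hrd_truth", "study", "site",
    "reagent_lot", "sequencer_or_run", "run_index", "rep_k",
    "dilution_level", "interferent", "concentration", "condition",
    "qc_valid", "purity", "effective_purity", "score", "call", "reason")
}

#' Read and write replicate manifests
#'
#' One replicate per row with the documented stable column set; list-columns
#' holding observed data are not serialized.
#'
#' @param manifest replicate tibble.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  cols <- intersect(manifest_scalar_cols(), names(manifest))
  out <- manifest[, cols]
  for (cl in intersect(c("dilution_level", "purity", "effective_purity",
                         "score"), cols)) {
    out[[cl]] <- fmt_num(out[[cl]])
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    replicate_id = "c", specimen_id = "c", hrd_truth = "c", study = "c",
    site = "i", reagent_lot = "i", sequencer_or_run = "i", run_index = "i",
    rep_k = "i", dilution_level = "d", interferent = "c",
    concentration = "c", condition = "c", qc_valid = "l", purity = "d",
    effective_purity = "d", score = "d", call = "c", reason = "c"))
  if (nrow(x) == 0) {
    abort("empty cohort: the manifest contains no replicates.",
          class = "scarvalid_input_error")
  }
  x
}

#' Read a study-design configuration from YAML
#'
#' @param path YAML file with a `study` entry plus design overrides.
#' @return named list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$study)) {
    abort("config must name a `study`.", class = "scarvalid_config_error")
  }
  cfg
}
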