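#' Configuration for MLPA copy-state calling
#'
#' @param delta Call threshold as a fraction of the baseline dosage: a
#'   relative peak-area ratio at or above `1 + delta` is called
#'   `duplicated`, at or below `1 - delta` `deleted`.  Default 0.30, the
#'   conventional 30 percent rule; thresholds are inclusive so the rule is
#'   honored exactly at the boundary.
#' @param intra_normalization `"reference_probe_mean"` (default) divides
#'   every peak area by the mean of that sample's reference-probe areas
#'   before inter-sample comparison, making calls invariant to per-sample
#'   amplification scale; `"none"` skips the step.
#' @return A list of class `azf_calling_config`.
#' @export
calling_config <- function(delta = 0.30,
                           intra_normalization = c("reference_probe_mean", "none")) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1)
    validation_error("delta", "must be a single number in (0, 1)")
  structure(
    list(delta = delta,
         intra_normalization = match.arg(intra_normalization)),
    class = "azf_calling_config"
  )
}

# check a wide peak table: sample_id + one numeric column per panel probe
check_peak_table <- function(peaks, panel, what = "peak table") {
  peaks <- as_tibble(peaks)
  if (!"sample_id" %in% names(peaks))
    validation_error("sample_id", paste(what, "needs a sample_id column"))
  missing <- setdiff(panel$probe_id, names(peaks))
  if (length(missing) > 0)
    validation_error("areas", sprintf(
      "%s is missing probe columns: %s", what, toString(head(missing, 5))))
  areas <- as.matrix(peaks[panel$probe_id])
  if (any(is.na(areas)) || any(areas < 0))
    validation_error("areas", paste(what, "has missing or negative peak areas"))
  ref <- areas[, panel$probe_id[panel$is_reference], drop = FALSE]
  if (nrow(ref) > 0 && any(ref <= 0))
    validation_error("areas", paste(what, "has zero reference-probe areas"))
  peaks
}

#' Intra-sample normalization of MLPA peak areas
#'
#' Divides each sample's peak areas by the mean of that sample's
#' reference-probe areas (or returns the input untouched when the config
#' selects no intra-sample normalization).  This removes per-sample
#' amplification scale before peaks are compared across samples.
#'
#' @param peaks Wide peak table: a tibble with a `sample_id` column and one
#'   non-negative numeric column per panel probe.
#' @param panel Probe panel (see [azf_panel()]).
#' @param config Calling configuration from [calling_config()].
#' @return A tibble of the same shape with normalized areas.
#' @export
normalize_peaks <- function(peaks, panel, config = calling_config()) {
  peaks <- check_peak_table(peaks, panel)
  if (config$intra_normalization == "none") return(peaks)
  ref_ids <- panel$probe_id[panel$is_reference]
  ref_mean <- rowMeans(as.matrix(peaks[ref_ids]))
  if (any(ref_mean <= 0))
    validation_error("areas", "non-positive reference-probe mean")
  peaks[panel$probe_id] <- as_tibble(as.matrix(peaks[panel$probe_id]) / ref_mean)
  peaks
}

#' Relative peak areas against a reference-sample set
#'
#' Computes, for every probe, the subject's (normalized) peak area divided
#' by the mean of the reference samples' (normalized) areas for that probe
#' -- the dimensionless relative peak area `r`, approximately equal to
#' copies / baseline copies.
#'
#' @inheritParams normalize_peaks
#' @param refs Wide peak table of reference (copy-normal) samples;
#'   conventionally five of them.
#' @return A long tibble `sample_id`, `probe_id`, `area` (raw input),
#'   `ratio`.
#' @export
probe_ratios <- function(peaks, refs, panel, config = calling_config()) {
  raw <- check_peak_table(peaks, panel)
  refs <- check_peak_table(refs, panel, what = "reference set")
  if (nrow(refs) < 1) validation_error("refs", "needs at least one reference sample")
  peaks_n <- normalize_peaks(raw, panel, config)
  refs_n <- normalize_peaks(refs, panel, config)
  ref_mean <- colMeans(as.matrix(refs_n[panel$probe_id]))
  if (any(ref_mean <= 0))
    validation_error("refs", paste(
      "zero reference mean for probe:",
      toString(panel$probe_id[ref_mean <= 0])))
  ratio_mat <- sweep(as.matrix(peaks_n[panel$probe_id]), 2, ref_mean, "/")
  tibble(
    sample_id = rep(raw$sample_id, each = length(panel$probe_id)),
    probe_id = rep(panel$probe_id, times = nrow(raw)),
    area = as.vector(t(as.matrix(raw[panel$probe_id]))),
    ratio = as.vector(t(ratio_mat))
  )
}

#' Call a per-probe copy state from a relative peak area
#'
#' Applies the 30 percent rule (inclusive thresholds): `duplicated` when
#' `r >= 1 + delta`, `deleted` when `r <= 1 - delta`, otherwise `normal`.
#' Estimated copies are `round(r * baseline_copies)` with ties rounded half
#' away from zero; the integer is advisory (classification works on dosage
#' patterns, not these integers).
#'
#' @param ratio Numeric vector of relative peak areas (`r >= 0`).
#' @param baseline_copies Integer vector of baseline copies, recycled.
#' @param config Calling configuration from [calling_config()].
#' @return A tibble `state` (ordered factor deleted < normal < duplicated)
#'   and `estimated_copies`.
#' @examples
#' call_probe_state(c(0.65, 1.0, 1.3), 4)
#' @export
call_probe_state <- function(ratio, baseline_copies, config = calling_config()) {
  if (any(ratio < 0, na.rm = TRUE))
    validation_error("ratio", "relative peak areas must be >= 0")
  state <- dplyr::case_when(
    ratio <= 1 - config$delta ~ "deleted",
    ratio >= 1 + config$delta ~ "duplicated",
    .default = "normal"
  )
  tibble(
    state = factor(state, levels = c("deleted", "normal", "duplicated"),
                   ordered = TRUE),
    estimated_copies = as.integer(round_half_away(ratio * baseline_copies))
  )
}

#' Normalize, ratio and call a batch of samples
#'
#' Composes [normalize_peaks()], [probe_ratios()] and [call_probe_state()]
#' over every sample: the full path from raw peak areas to per-probe copy
#' states.  Reference probes are carried through with their ratios but are
#' never assigned a CNV state.
#'
#' @inheritParams probe_ratios
#' @return A tibble of class `azf_calls`: `sample_id`, `probe_id`,
#'   `target_locus`, `region`, `is_reference`, `baseline_copies`, `area`,
#'   `ratio`, `state` (`NA` for reference probes), `estimated_copies`.
#' @examples
#' panel <- azf_panel()
#' cohort <- simulate_cohort(simulation_config(seed = 7, n_control = 3,
#'   n_azoospermia = 0, n_oligozoospermia = 0, sigma_area = 0))
#' calls <- call_samples(cohort$peaks, cohort$references, panel)
#' @export
call_samples <- function(peaks, refs, panel, config = calling_config()) {
  ratios <- probe_ratios(peaks, refs, panel, config)
  out <- ratios |>
    left_join(
      panel |> select("probe_id", "target_locus", "region",
                      "is_reference", "baseline_copies"),
      by = "probe_id"
    )
  called <- call_probe_state(out$ratio, out$baseline_copies, config)
  out$state <- called$state
  out$state[out$is_reference] <- NA
  out$estimated_copies <- called$estimated_copies
  out <- out |>
    select("sample_id", "probe_id", "target_locus", "region", "is_reference",
           "baseline_copies", "area", "ratio", "state", "estimated_copies")
  class(out) <- c("azf_calls", class(out))
  attr(out, "delta") <- config$delta
  out
}

#' Write a call table as TSV
#'
#' Columns `sample_id probe_id area ratio state estimated_copies`, the
#' package's on-disk interface for per-probe results.
#'
#' @param calls An `azf_calls` tibble from [call_samples()].
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  calls |>
    mutate(state = as.character(.data$state)) |>
    select("sample_id", "probe_id", "area", "ratio", "state",
           "estimated_copies") |>
    readr::write_tsv(path, na = "NA")
  invisible(path)
}
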