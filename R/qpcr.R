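#' Delta-delta-Ct relative quantification
#'
#' Computes, per sample and assay, `delta_ct` (mean target Ct minus mean
#' reference-gene Ct over the replicate set), `delta_delta_ct` (relative to
#' the calibrator sample of the same assay) and the relative quantity
#' `rq = base^(-delta_delta_ct)` with the classic amplification-efficiency
#' assumption `base = 2`.  Replicates are aggregated by mean with the SD of
#' the replicate-wise Ct differences reported; no outlier rejection is
#' applied.
#'
#' @param ct Long Ct tibble with columns `sample_id`, `assay_id`,
#'   `replicate`, `ct_target`, `ct_reference` (reference gene, e.g. ACTB).
#' @param calibrator Sample id used as calibrator; either a single id
#'   shared by all assays or a named character vector `assay_id ->
#'   sample_id`.
#' @param n_replicates Required replicate count per sample and assay
#'   (default 3); incomplete replicate sets are an error.
#' @param base Amplification base (default 2, i.e. perfect doubling).
#' @param ct_range Admissible Ct range; values outside are an error.
#' @return A tibble `sample_id`, `assay_id`, `delta_ct`, `delta_delta_ct`,
#'   `rq`, `replicate_sd`.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("S1", "CAL"), each = 3), assay_id = "DAZ",
#'   replicate = rep(1:3, 2),
#'   ct_target = c(24, 24, 24, 23, 23, 23), ct_reference = 20)
#' ddct_quantify(ct, calibrator = "CAL") # S1 has rq 0.5
#' @export
ddct_quantify <- function(ct, calibrator, n_replicates = 3, base = 2,
                          ct_range = c(0, 45)) {
  ct <- as_tibble(ct)
  needed <- c("sample_id", "assay_id", "replicate", "ct_target", "ct_reference")
  missing <- setdiff(needed, names(ct))
  if (length(missing) > 0)
    validation_error("ct", paste("missing columns:", toString(missing)))
  vals <- c(ct$ct_target, ct$ct_reference)
  if (any(is.na(vals)))
    validation_error("ct", "missing Ct value")
  if (any(vals <= ct_range[1] | vals >= ct_range[2]))
    validation_error("ct", sprintf("Ct outside (%g, %g)", ct_range[1], ct_range[2]))

  per <- ct |>
    group_by(.data$sample_id, .data$assay_id) |>
    summarise(
      n = n(),
      delta_ct = mean(.data$ct_target) - mean(.data$ct_reference),
      replicate_sd = sd(.data$ct_target - .data$ct_reference),
      .groups = "drop"
    )
  if (any(per$n != n_replicates))
    abort(sprintf("expected %d replicates per sample and assay", n_replicates))

  cal <- if (length(calibrator) == 1 && is.null(names(calibrator)))
    setNames(rep(calibrator, length(unique(per$assay_id))), unique(per$assay_id))
  else calibrator
  per |>
    group_by(.data$assay_id) |>
    group_modify(function(d, g) {
      cal_id <- cal[[as.character(g$assay_id)]] %||%
        abort(paste("no calibrator for assay", g$assay_id))
      i <- match(cal_id, d$sample_id)
      if (is.na(i)) abort(paste("calibrator sample missing for assay", g$assay_id))
      d |> mutate(delta_delta_ct = .data$delta_ct - d$delta_ct[i],
                  rq = base^(-.data$delta_delta_ct))
    }) |>
    ungroup() |>
    select("sample_id", "assay_id", "delta_ct", "delta_delta_ct", "rq",
           "replicate_sd")
}

#' Concordance of a qPCR relative quantity with an MLPA call
#'
#' The expected relative quantity at an assayed region is the MLPA
#' estimated copy number divided by the baseline copy number.  A result is
#' concordant when the observed `rq` falls within a relative tolerance band
#' of the expectation (default +/-30 percent, mirroring the MLPA call
#' band); an expected quantity of zero (target fully deleted) uses the
#' absolute band `rq <= tolerance` instead, since a relative band around
#' zero is empty.
#'
#' @param rq Observed relative quantities.
#' @param mlpa_copies MLPA estimated copies at the assayed region.
#' @param baseline_copies Baseline copies of the region.
#' @param tolerance Relative tolerance (default 0.30).
#' @return A tibble `expected_rq`, `concordant`.
#' @examples
#' qpcr_concordance(0.5, mlpa_copies = 2, baseline_copies = 4) # concordant
#' qpcr_concordance(0.5, mlpa_copies = 3, baseline_copies = 2) # discordant
#' @export
qpcr_concordance <- function(rq, mlpa_copies, baseline_copies, tolerance = 0.30) {
  n <- max(length(rq), length(mlpa_copies), length(baseline_copies))
  rq <- rep_len(rq, n)
  expected <- rep_len(mlpa_copies, n) / rep_len(baseline_copies, n)
  if (any(is.na(expected)) || any(expected < 0))
    validation_error("mlpa_copies", "expected rq must be a non-negative number")
  concordant <- ifelse(expected > 0,
                       abs(rq - expected) <= tolerance * expected + 1e-9,
                       rq <= tolerance + 1e-9)
  tibble(expected_rq = expected, concordant = concordant)
}
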