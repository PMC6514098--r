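#' MLPA probe panels for the AZF regions
#'
#' A probe panel is a tibble with one row per MLPA probe and columns
#' `probe_id`, `target_locus`, `region` (one of `"AZFa"`, `"AZFb"`, `"AZFc"`
#' or `"reference"`), `position_bp` (1-based chrY coordinate, `NA` for
#' autosomal reference probes; ordinal use only), `baseline_copies` (total
#' copies of the target on an unrearranged Y; the family total for multicopy
#' targets such as DAZ) and `is_reference`.
#'
#' `azf_panel()` returns the default panel: 42 AZF-targeting probes spread
#' over the USP9Y, DDX3Y, RBMY1J, RBMY1, PRY, EIF1AY, KDM5D, HSFY, DAZ,
#' BPY2, CDY1, GOLGA2LY, CSPG4LY, TTTY4, TTTY17 and TTTY3 loci, plus eight
#' autosomal reference probes used for intra-sample normalization.  The
#' probe identities are a synthesized stand-in for a commercial AZF
#' probe-mix; a panel file for a real kit can be substituted via
#' [read_probe_panel()].
#'
#' @return A validated probe-panel tibble.
#' @examples
#' panel <- azf_panel()
#' sum(!panel$is_reference) # 42 AZF probes
#' @export
azf_panel <- function() {
  fam <- function(locus, region, n, baseline, start, step = 25000) {
    tibble(
      probe_id = sprintf("%s_%02d", locus, seq_len(n)),
      target_locus = locus,
      region = region,
      position_bp = as.integer(start + step * (seq_len(n) - 1L)),
      baseline_copies = as.integer(baseline),
      is_reference = FALSE
    )
  }
  azf <- bind_rows(
    fam("USP9Y",    "AZFa", 3L, 1L, 12701000L),
    fam("DDX3Y",    "AZFa", 3L, 1L, 12904000L),
    fam("HSFY",     "AZFb", 2L, 2L, 20581000L),
    fam("RBMY1J",   "AZFb", 1L, 1L, 21511000L),
    fam("RBMY1",    "AZFb", 4L, 6L, 21534000L),
    fam("KDM5D",    "AZFb", 1L, 1L, 21868000L),
    fam("PRY",      "AZFb", 2L, 2L, 22102000L),
    fam("EIF1AY",   "AZFb", 2L, 1L, 22740000L),
    fam("DAZ",      "AZFc", 4L, 4L, 23202000L, 650000),
    fam("BPY2",     "AZFc", 4L, 3L, 23551000L, 950000),
    fam("CDY1",     "AZFc", 3L, 2L, 23704000L, 1100000),
    fam("GOLGA2LY", "AZFc", 3L, 2L, 23860000L, 900000),
    fam("CSPG4LY",  "AZFc", 2L, 2L, 24012000L, 800000),
    fam("TTTY4",    "AZFc", 3L, 3L, 24166000L, 700000),
    fam("TTTY17",   "AZFc", 3L, 3L, 24310000L, 750000),
    fam("TTTY3",    "AZFc", 2L, 2L, 24455000L, 850000)
  )
  ref_loci <- c("ACTB", "TBP", "RPP30", "ZNF80", "B2M", "RPPH1", "TERT", "CFTR")
  refs <- tibble(
    probe_id = paste0("REF_", ref_loci),
    target_locus = ref_loci,
    region = "reference",
    position_bp = NA_integer_,
    baseline_copies = 2L,
    is_reference = TRUE
  )
  validate_probe_panel(bind_rows(azf, refs))
}

#' Validate a probe-panel tibble
#'
#' Checks the panel invariants: unique probe ids, known regions,
#' `baseline_copies >= 1`, and at least two reference probes (needed for
#' intra-sample normalization).
#'
#' @param panel A probe-panel tibble (see [azf_panel()]).
#' @return The panel, invisibly coerced to a tibble, if valid; otherwise a
#'   validation error naming the offending field.
#' @export
validate_probe_panel <- function(panel) {
  panel <- as_tibble(panel)
  needed <- c("probe_id", "target_locus", "region", "position_bp",
              "baseline_copies", "is_reference")
  missing <- setdiff(needed, names(panel))
  if (length(missing) > 0)
    validation_error("panel", paste("missing columns:", toString(missing)))
  if (anyDuplicated(panel$probe_id))
    validation_error("probe_id", paste(
      "duplicated:", toString(unique(panel$probe_id[duplicated(panel$probe_id)]))))
  bad_region <- setdiff(unique(panel$region), c("AZFa", "AZFb", "AZFc", "reference"))
  if (length(bad_region) > 0)
    validation_error("region", paste("unknown region:", toString(bad_region)))
  if (any(panel$is_reference & panel$region != "reference") ||
      any(!panel$is_reference & panel$region == "reference"))
    validation_error("is_reference", "inconsistent with region column")
  if (any(is.na(panel$baseline_copies)) || any(panel$baseline_copies < 1))
    validation_error("baseline_copies", "must be an integer >= 1 for every probe")
  if (sum(panel$is_reference) < 2)
    validation_error("is_reference", "panel needs at least 2 reference probes")
  panel
}

#' Read or write a probe-panel definition file
#'
#' Panels are stored either as a JSON array of probe objects or as TSV with
#' header `probe_id target_locus region position_bp baseline_copies
#' is_reference`; the format is chosen by file extension (`.json` vs
#' anything else).  `write_probe_panel()` followed by `read_probe_panel()`
#' round-trips the panel exactly.
#'
#' @param path Path to the panel file.
#' @return `read_probe_panel()` returns a validated panel tibble.
#' @export
read_probe_panel <- function(path) {
  if (!file.exists(path)) abort(paste("panel file not found:", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    panel <- as_tibble(jsonlite::fromJSON(path))
  } else {
    panel <- readr::read_tsv(path, col_types = readr::cols(
      probe_id = "c", target_locus = "c", region = "c",
      position_bp = "i", baseline_copies = "i", is_reference = "l"
    ))
  }
  panel$position_bp <- as.integer(panel$position_bp)
  panel$baseline_copies <- as.integer(panel$baseline_copies)
  validate_probe_panel(panel)
}

#' @param panel A probe-panel tibble.
#' @rdname read_probe_panel
#' @export
write_probe_panel <- function(panel, path) {
  panel <- validate_probe_panel(panel)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(panel, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    readr::write_tsv(panel, path, na = "NA")
  }
  invisible(path)
}

# family-level view of a panel: one row per non-reference target locus
panel_families <- function(panel) {
  panel |>
    filter(!.data$is_reference) |>
    group_by(target_locus = .data$target_locus) |>
    summarise(
      region = .data$region[1],
      baseline_copies = .data$baseline_copies[1],
      n_probes = n(),
      .groups = "drop"
    ) |>
    arrange(match(.data$target_locus, unique(panel$target_locus)))
}
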