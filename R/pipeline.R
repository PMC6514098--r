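#' Run the full AZF CNV study pipeline
#'
#' End-to-end orchestration: per-probe calling, class assignment (with
#' digest resolution where available), the virtual STS-PCR comparison,
#' qPCR delta-delta-Ct concordance for any supplied Ct tables, and the
#' case-control association report.  Inputs are either an in-memory
#' [simulate_cohort()] object or the equivalent TSV files.  When `out_dir`
#' is given, every stage's report is written as TSV alongside a JSON run
#' manifest naming each input with an MD5 content hash; report files are
#' byte-identical across re-runs with identical inputs.
#'
#' @param cohort An `azf_cohort`, or `NULL` to read from files.
#' @param peaks,references,samples,digest,ct Paths to the corresponding TSV
#'   files (ignored when `cohort` is given; `digest`/`ct` optional).
#' @param panel,catalogue Panel and catalogue objects, or paths to their
#'   definition files.
#' @param config Calling configuration.
#' @param out_dir Optional output directory for the report bundle.
#' @return A list of class `azf_pipeline_result` with elements `calls`,
#'   `classification`, `samples` (sheet with assigned classes),
#'   `inheritance`, `sts`, `qpcr`, `association`.
#' @export
run_azf_pipeline <- function(cohort = NULL, peaks = NULL, references = NULL,
                             samples = NULL, digest = NULL, ct = NULL,
                             panel = azf_panel(), catalogue = NULL,
                             config = calling_config(), out_dir = NULL) {
  inputs <- list()
  if (is.character(panel)) { inputs$panel <- panel; panel <- read_probe_panel(panel) }
  if (is.character(catalogue)) {
    inputs$catalogue <- catalogue
    catalogue <- read_cnv_catalogue(catalogue, panel)
  }
  if (is.null(catalogue)) catalogue <- azf_catalogue(panel)
  read_maybe <- function(x, name) {
    if (is.null(x) || !is.character(x)) return(x)
    if (!file.exists(x)) abort(paste("input file not found:", x))
    inputs[[name]] <<- x
    readr::read_tsv(x, show_col_types = FALSE)
  }
  if (is.null(cohort)) {
    peaks <- read_maybe(peaks, "peaks")
    references <- read_maybe(references, "references")
    sheet <- read_maybe(samples, "samples")
    digest <- read_maybe(digest, "digest")
    ct <- read_maybe(ct, "ct")
    fathers <- tibble(father_id = character(), proband_id = character())
  } else {
    peaks <- cohort$peaks
    references <- cohort$references
    sheet <- cohort$samples
    digest <- cohort$digest
    ct <- cohort$ct
    fathers <- cohort$fathers
  }
  if (is.null(peaks) || is.null(references) || is.null(sheet))
    abort("need peaks, references and a sample sheet (or a cohort object)")

  calls <- call_samples(peaks, references, panel, config)
  classification <- classify_samples(calls, panel, catalogue, digest, config)
  sheet <- sheet |>
    left_join(classification |> select("sample_id", "assigned_class"),
              by = "sample_id")

  # de novo checks for probands with a generated father
  inheritance <- tibble(sample_id = character(), father_id = character(),
                        status = character())
  if (nrow(fathers) > 0) {
    cls <- setNames(classification$assigned_class, classification$sample_id)
    inheritance <- fathers |>
      transmute(sample_id = .data$proband_id, father_id = .data$father_id,
                status = inheritance_status(cls[.data$proband_id],
                                            cls[.data$father_id]))
  }

  sts <- compare_sts_mlpa(catalogue)

  qpcr <- NULL
  if (!is.null(ct) && nrow(ct) > 0) {
    fams <- panel_families(panel)
    calibrators <- ct |>
      distinct(.data$assay_id) |>
      mutate(cal = map_chr(.data$assay_id, function(a) {
        ids <- unique(ct$sample_id[ct$assay_id == a])
        refs <- ids[grepl("^REF", ids)]
        if (length(refs) > 0) refs[1] else ids[1]
      }))
    qpcr <- ddct_quantify(ct, setNames(calibrators$cal, calibrators$assay_id))
    # reference samples can appear as qPCR calibrators: call them too
    ref_calls <- call_samples(references, references, panel, config)
    fam_calls <- bind_rows(as_tibble(calls), as_tibble(ref_calls)) |>
      distinct(.data$sample_id, .data$probe_id, .keep_all = TRUE) |>
      filter(!.data$is_reference) |>
      group_by(sample_id = .data$sample_id, assay_id = .data$target_locus) |>
      summarise(mean_ratio = mean(.data$ratio),
                baseline = .data$baseline_copies[1], .groups = "drop") |>
      mutate(mlpa_copies = as.integer(round_half_away(.data$mean_ratio * .data$baseline)))
    qpcr <- qpcr |>
      left_join(fam_calls |> select("sample_id", "assay_id", "mlpa_copies",
                                    "baseline"),
                by = c("sample_id", "assay_id"))
    conc <- qpcr_concordance(qpcr$rq, qpcr$mlpa_copies, qpcr$baseline)
    qpcr$expected_rq <- conc$expected_rq
    qpcr$concordant <- conc$concordant
  }

  association <- association_report(
    sheet |> filter(.data$group %in% c("control", "azoospermia",
                                       "oligozoospermia")),
    catalogue)

  result <- structure(
    list(calls = calls, classification = classification, samples = sheet,
         inheritance = inheritance, sts = sts, qpcr = qpcr,
         association = association),
    class = "azf_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_reports(result, inputs, out_dir)
  result
}

write_pipeline_reports <- function(result, inputs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_calls(result$calls, file.path(out_dir, "calls.tsv"))
  write_classification(result$classification,
                       file.path(out_dir, "classification.tsv"))
  write_sts_comparison(result$sts, file.path(out_dir, "sts_comparison.tsv"))
  if (!is.null(result$qpcr))
    readr::write_tsv(result$qpcr, file.path(out_dir, "qpcr.tsv"), na = "NA")
  if (nrow(result$inheritance) > 0)
    readr::write_tsv(result$inheritance, file.path(out_dir, "inheritance.tsv"))
  readr::write_tsv(render_association(result$association),
                   file.path(out_dir, "association.tsv"))
  jsonlite::write_json(
    tidy(result$association),
    file.path(out_dir, "association_full.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("azfcnv")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = imap(inputs, function(path, name)
      list(path = path, md5 = unname(tools::md5sum(path))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.azf_pipeline_result <- function(x, ...) {
  cat("AZF CNV pipeline result:", nrow(x$samples), "samples,",
      sum(x$samples$assigned_class != "NO_CNV", na.rm = TRUE),
      "CNV carriers\n")
  invisible(x)
}
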