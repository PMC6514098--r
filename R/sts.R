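#' The ten EAA/EMQN STS markers
#'
#' The sequence-tagged-site markers recommended for conventional AZF
#' deletion screening: sY84 and sY86 for AZFa, sY127 and sY134 for AZFb,
#' and sY254, sY255, sY1192, sY1191, sY1291 and sY1189 for AZFc.
#'
#' @return A tibble `marker`, `region`.
#' @export
sts_markers <- function() {
  tibble(
    marker = c("sY84", "sY86", "sY127", "sY134",
               "sY254", "sY255", "sY1192", "sY1191", "sY1291", "sY1189"),
    region = c("AZFa", "AZFa", "AZFb", "AZFb", rep("AZFc", 6))
  )
}

#' Predict the STS-PCR presence/absence pattern of a CNV class
#'
#' A marker is absent exactly when the class deletes the genomic segment
#' carrying it; duplications leave every marker present (STS-PCR is blind
#' to extra copies) and a complex class shows the pattern of its deletion
#' component.
#'
#' @param catalogue A CNV catalogue.
#' @param class_id Optional class names to restrict to (default: all).
#' @return A wide tibble: `class_id` plus one `+`/`-` column per marker.
#' @examples
#' predict_sts_pattern(azf_catalogue(), "b2/b4 del")
#' @export
predict_sts_pattern <- function(catalogue, class_id = NULL) {
  if (!is.null(class_id)) {
    missing <- setdiff(class_id, catalogue$class_id)
    if (length(missing) > 0)
      abort(paste("unknown class:", toString(missing)))
    catalogue <- catalogue |> filter(.data$class_id %in% !!class_id)
  }
  markers <- sts_markers()$marker
  pat <- map(catalogue$sts, function(x) ifelse(x[markers] == 1, "+", "-"))
  out <- bind_cols(
    tibble(class_id = catalogue$class_id),
    as_tibble(do.call(rbind, pat))
  )
  names(out) <- c("class_id", markers)
  out
}

#' Compare virtual STS-PCR against MLPA over a catalogue
#'
#' Runs the STS predictor over every class and scores what conventional
#' STS-PCR would report: `identified` (a non-trivial pattern that maps back
#' uniquely to the class among the deletion classes), `missed` (a CNV with
#' an all-present pattern, i.e. invisible to presence/absence PCR), or
#' `misclassified_as_simple_deletion` (a complex class whose pattern equals
#' that of a simple deletion class).  The three outcomes partition the
#' catalogue.
#'
#' @param catalogue A CNV catalogue.
#' @return An object of class `azf_sts_comparison`: a list with `by_class`
#'   (class_id, category, pattern columns, `sts_outcome`) and `summary`
#'   (outcome, n, fraction, pct -- percentages to one decimal).
#' @examples
#' cmp <- compare_sts_mlpa(azf_catalogue())
#' glance(cmp)
#' @export
compare_sts_mlpa <- function(catalogue) {
  pat <- predict_sts_pattern(catalogue)
  key <- apply(as.matrix(pat[-1]), 1, paste, collapse = "")
  trivial <- !grepl("-", key, fixed = TRUE)
  del_keys <- key[catalogue$category == "deletion"]
  outcome <- character(nrow(catalogue))
  for (i in seq_len(nrow(catalogue))) {
    if (trivial[i]) {
      outcome[i] <- "missed"
    } else if (catalogue$category[i] == "complex" &&
               key[i] %in% del_keys) {
      outcome[i] <- "misclassified_as_simple_deletion"
    } else if (sum(del_keys == key[i]) <= 1) {
      outcome[i] <- "identified"
    } else {
      # two deletion classes sharing a pattern cannot be told apart
      outcome[i] <- "missed"
    }
  }
  by_class <- bind_cols(pat["class_id"],
                        tibble(category = catalogue$category),
                        pat[-1],
                        tibble(sts_outcome = outcome))
  lv <- c("identified", "missed", "misclassified_as_simple_deletion")
  summary <- tibble(outcome = lv) |>
    left_join(count(tibble(outcome = outcome), .data$outcome), by = "outcome") |>
    mutate(
      n = coalesce(.data$n, 0L),
      fraction = if (nrow(catalogue) > 0) .data$n / nrow(catalogue) else 0,
      pct = round(100 * .data$fraction, 1)
    )
  structure(list(by_class = by_class, summary = summary,
                 n_classes = nrow(catalogue)),
            class = "azf_sts_comparison")
}

#' @export
print.azf_sts_comparison <- function(x, ...) {
  cat("Virtual STS-PCR vs MLPA over", x$n_classes, "CNV classes\n")
  print(x$summary)
  invisible(x)
}

#' Write the STS comparison as TSV
#'
#' One row per class, one `+`/`-` column per marker and a final
#' `sts_outcome` column.
#'
#' @param comparison An `azf_sts_comparison` object.
#' @param path Output path.
#' @export
write_sts_comparison <- function(comparison, path) {
  readr::write_tsv(comparison$by_class |> select(-"category"), path)
  invisible(path)
}
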