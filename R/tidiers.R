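#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an association report
#'
#' Drops the list columns and returns one plain row per (label, case group)
#' with counts, OR, CI and p-values at full precision.
#'
#' @param x An `azf_association` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.azf_association <- function(x, ...) {
  as_tibble(x)[c("label", "label_type", "category", "case_group",
                 "a", "b", "c", "d", "or", "ci_lo", "ci_hi",
                 "p_chi2", "p_chi2_yates", "p_fisher", "test_used", "p")]
}

#' @describeIn tidy.azf_association One-row summary: rows reported, defined
#'   ORs, and nominally significant tests at p < 0.05 (no multiplicity
#'   adjustment).
#' @export
glance.azf_association <- function(x, ...) {
  tibble(
    n_rows = nrow(x),
    n_defined_or = sum(!is.na(x$or)),
    n_significant = sum(x$p < 0.05, na.rm = TRUE)
  )
}

#' Tidy the virtual STS-PCR comparison
#'
#' @param x An `azf_sts_comparison` object.
#' @param ... Unused.
#' @return `tidy()`: the per-class pattern/outcome tibble; `glance()`: one
#'   row with outcome counts and percentages (one decimal).
#' @export
tidy.azf_sts_comparison <- function(x, ...) as_tibble(x$by_class)

#' @rdname tidy.azf_sts_comparison
#' @export
glance.azf_sts_comparison <- function(x, ...) {
  s <- x$summary
  tibble(
    n_classes = x$n_classes,
    n_identified = s$n[s$outcome == "identified"],
    n_missed = s$n[s$outcome == "missed"],
    n_misclassified = s$n[s$outcome == "misclassified_as_simple_deletion"],
    pct_identified = s$pct[s$outcome == "identified"],
    pct_missed = s$pct[s$outcome == "missed"],
    pct_misclassified = s$pct[s$outcome == "misclassified_as_simple_deletion"]
  )
}

#' Tidy a classification result
#'
#' @param x An `azf_classification` tibble.
#' @param ... Unused.
#' @return A plain tibble without the candidates list column.
#' @export
tidy.azf_classification <- function(x, ...) {
  as_tibble(x) |> select(-"candidates")
}

#' @rdname tidy.azf_classification
#' @export
glance.azf_classification <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    n_no_cnv = sum(x$assigned_class == "NO_CNV"),
    n_carriers = sum(x$assigned_class %not_in%
                       c("NO_CNV", "UNCLASSIFIED", "AMBIGUOUS")),
    n_unclassified = sum(x$assigned_class == "UNCLASSIFIED"),
    n_ambiguous = sum(x$assigned_class == "AMBIGUOUS")
  )
}
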