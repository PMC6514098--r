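#' Reference-cohort carrier counts
#'
#' Per-class carrier counts from the case-control MLPA survey the package's
#' defaults emulate: 402 fertile controls and 423 spermatogenic-failure
#' patients (197 azoospermia, 226 oligozoospermia).  These counts are the
#' default class frequencies of the cohort simulator and the inputs for the
#' desk-scale association reports.
#'
#' @return `azf_class_counts()`: a tibble `class_id`, `control`,
#'   `azoospermia`, `oligozoospermia` with one row per catalogue class.
#' @examples
#' counts <- azf_class_counts()
#' colSums(counts[-1])
#' @export
azf_class_counts <- function() {
  tibble::tribble(
    ~class_id,                     ~control, ~azoospermia, ~oligozoospermia,
    "b2/b4 del",                    0L,  9L, 14L,
    "gr/gr del",                   20L, 14L, 18L,
    "b2/b3 del",                   24L,  8L,  8L,
    "b1/b3 del",                    2L,  0L,  5L,
    "AZFb del",                     0L,  1L,  0L,
    "RBMY1J del",                   0L,  0L,  1L,
    "AZFa del",                     0L,  2L,  0L,
    "AZFb + c del",                 0L,  7L,  0L,
    "b2/b4 dup",                    2L,  0L,  3L,
    "gr/gr dup",                    5L,  7L,  6L,
    "b2/b3 dup",                    1L,  3L,  1L,
    "b2/b3 trip",                   0L,  0L,  1L,
    "BPY2 partial dup-Type I",      2L,  1L,  1L,
    "BPY2 partial dup-Type II",     2L,  1L,  0L,
    "Type I + gr/gr dup",           0L,  0L,  1L,
    "b2/b4 dup + gr/gr dup",        0L,  0L,  2L,
    "RBMY1J dup",                   0L,  0L,  1L,
    "AZFa partial dup Type I",      4L,  1L,  0L,
    "AZFa partial dup Type II",     0L,  0L,  1L,
    "b2/b3 del + DAZ1/2 dup",       2L,  3L,  8L,
    "b2/b3 del + gr/gr dup",        6L,  2L,  6L,
    "b2/b3 del + gr/gr trip",       2L,  0L,  5L,
    "two gr/gr dels + b2/b4 dup",   2L,  3L,  0L,
    "gr/gr del + b2/b3 trip",       2L,  0L,  1L
  )
}

#' @description
#' `azf_composite_counts()` returns the published composite carrier counts
#' (any CNV, any deletion, any duplication, any AZFc duplication) for the
#' same cohort, as printed in the source survey's summary table.  Note the
#' printed oligozoospermia column of that table is internally inconsistent
#' with the per-class counts (82 vs a class-count sum of 83 for any CNV,
#' 65 vs 66 for any deletion); the printed values are reported here
#' verbatim, while [simulate_cohort()] necessarily reproduces the
#' per-class sums.
#'
#' @rdname azf_class_counts
#' @export
azf_composite_counts <- function() {
  tibble::tribble(
    ~composite,              ~control, ~spermatogenic_failure, ~azoospermia, ~oligozoospermia,
    "any_cnv",                76L, 145L, 62L, 82L,
    "any_deletion",           60L, 115L, 49L, 65L,
    "any_duplication",        16L,  30L, 13L, 17L,
    "any_duplication_azfc",   12L,  27L, 12L, 15L
  )
}

#' Default covariate parameters for the simulated cohort
#'
#' Age and BMI means and standard deviations and ever-smoking proportions
#' per study group, matching the reference cohort's demographics table.
#'
#' @return A named list with elements `age`, `bmi` (each a list of
#'   `c(mean, sd)` per group) and `smoking` (ever-smoker proportion per
#'   group).
#' @export
azf_covariate_params <- function() {
  list(
    age = list(control = c(28.52, 3.72), azoospermia = c(29.40, 3.54),
               oligozoospermia = c(27.67, 3.45)),
    bmi = list(control = c(22.98, 3.00), azoospermia = c(21.86, 3.30),
               oligozoospermia = c(21.63, 2.46)),
    smoking = c(control = 233 / 402, azoospermia = 114 / 197,
                oligozoospermia = 137 / 226)
  )
}
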