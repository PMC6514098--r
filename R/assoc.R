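#' Odds ratio with Wald confidence interval for a 2x2 table
#'
#' For case carriers `a`, case non-carriers `b`, control carriers `c` and
#' control non-carriers `d`, the odds ratio is `(a*d)/(b*c)` and the 95
#' percent Wald interval `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c +
#' 1/d))`.  Any zero cell makes the estimator degenerate: both OR and CI
#' are returned as `NA` (rendered as an en dash in reports), with no
#' continuity correction applied.
#'
#' @param a,b,c,d Cell counts (vectors recycled to common length).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble `or`, `ci_lo`, `ci_hi`.
#' @examples
#' odds_ratio_wald(11, 412, 2, 400) # OR 5.34, CI 1.18-24.24
#' @export
odds_ratio_wald <- function(a, b, c, d, conf_level = 0.95) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- as.numeric(rep_len(a, n)); b <- as.numeric(rep_len(b, n))
  c <- as.numeric(rep_len(c, n)); d <- as.numeric(rep_len(d, n))
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  or <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(or = or, ci_lo = exp(log(or) - z * se), ci_hi = exp(log(or) + z * se))
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities of tables no more probable than the observed one (the
#' usual two-sided convention).  A table with a zero margin has a single
#' admissible configuration and p = 1.
#'
#' @inheritParams odds_ratio_wald
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_exact_2x2(2, 0, 0, 2) # 1/3
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (m1 == 0 || m2 == 0 || k == 0 || b[i] + d[i] == 0) return(1)
    support <- max(0, k - m2):min(k, m1)
    probs <- dhyper(support, m1, m2, k)
    p_obs <- dhyper(a[i], m1, m2, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree of
#' freedom; with `correct = TRUE` the Yates continuity correction subtracts
#' `N/2` from `|ad - bc|` (floored at zero).  All four margins must be
#' positive.
#'
#' @inheritParams odds_ratio_wald
#' @param correct Apply the Yates continuity correction.
#' @return A tibble `statistic`, `p`.
#' @examples
#' pearson_chi2(145, 278, 76, 326)
#' @export
pearson_chi2 <- function(a, b, c, d, correct = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  margins <- cbind(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("chi-squared test undefined for a zero margin")
  num <- abs(a * d - b * c)
  if (correct) num <- pmax(0, num - N / 2)
  stat <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  tibble(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# composite membership: which assigned classes belong to a composite
composite_members <- function(composite, catalogue) {
  switch(
    composite,
    any_cnv = catalogue$class_id,
    any_deletion = catalogue$class_id[catalogue$category %in% c("deletion", "complex")],
    any_duplication = catalogue$class_id[catalogue$category == "duplication"],
    any_duplication_azfc = catalogue$class_id[
      catalogue$category == "duplication" &
        map_lgl(catalogue$region_scope, function(x) "AZFc" %in% x)],
    abort(paste("unknown composite:", composite))
  )
}

# normalize case-group labels
case_group_label <- function(x) {
  x <- dplyr::recode(x, SF = "spermatogenic_failure", sf = "spermatogenic_failure")
  bad <- setdiff(x, c("spermatogenic_failure", "azoospermia", "oligozoospermia"))
  if (length(bad) > 0) abort(paste("unknown case group:", toString(bad)))
  x
}

#' Build a case-control 2x2 table for a class or composite
#'
#' @param samples Classified sample sheet: a tibble with `group` (one of
#'   `control`, `azoospermia`, `oligozoospermia`) and `assigned_class` per
#'   sample.
#' @param target A catalogue `class_id`, or one of the composites
#'   `"any_cnv"`, `"any_deletion"` (deletion or complex classes),
#'   `"any_duplication"` (duplication-only classes),
#'   `"any_duplication_azfc"`.
#' @param case_group `"spermatogenic_failure"` (alias `"SF"`, the union of
#'   the two patient groups), `"azoospermia"` or `"oligozoospermia"`.
#' @param catalogue Catalogue used to resolve composite membership.
#' @return A tibble `a`, `b`, `c`, `d`: case carriers, case non-carriers,
#'   control carriers, control non-carriers.
#' @export
assoc_table <- function(samples, target, case_group = "spermatogenic_failure",
                        catalogue = azf_catalogue()) {
  samples <- as_tibble(samples)
  bad <- setdiff(unique(samples$group),
                 c("control", "azoospermia", "oligozoospermia"))
  if (length(bad) > 0) abort(paste("unknown group label:", toString(bad)))
  case_group <- case_group_label(case_group)
  members <- if (target %in% c("any_cnv", "any_deletion", "any_duplication",
                               "any_duplication_azfc"))
    composite_members(target, catalogue) else target
  carrier <- samples$assigned_class %in% members
  in_case <- if (case_group == "spermatogenic_failure")
    samples$group %in% c("azoospermia", "oligozoospermia")
  else samples$group == case_group
  in_control <- samples$group == "control"
  tibble(
    a = sum(carrier & in_case), b = sum(!carrier & in_case),
    c = sum(carrier & in_control), d = sum(!carrier & in_control)
  )
}

#' Case-control association report over classes and composites
#'
#' One row per (class, case group) and per (composite, case group): the
#' 2x2 counts, the Wald odds ratio and CI, Pearson chi-squared p-values
#' with and without continuity correction, the two-sided Fisher exact p,
#' and `test_used` -- Fisher when any expected cell count is below 5, else
#' the uncorrected chi-squared (both p-values are always reported so any
#' convention can be audited).  No multiple-testing adjustment is applied.
#'
#' @inheritParams assoc_table
#' @param case_groups Case groups to report (default all three).
#' @param composites Composite definitions to append (default all four);
#'   `character(0)` for classes only.
#' @return A tibble of class `azf_association` with columns `label`,
#'   `label_type`, `category`, `case_group`, `a`, `b`, `c`, `d`, `or`,
#'   `ci_lo`, `ci_hi`, `p_chi2`, `p_chi2_yates`, `p_fisher`, `test_used`,
#'   `p`.
#' @export
association_report <- function(samples, catalogue = azf_catalogue(),
                               case_groups = c("spermatogenic_failure",
                                               "azoospermia",
                                               "oligozoospermia"),
                               composites = c("any_cnv", "any_deletion",
                                              "any_duplication",
                                              "any_duplication_azfc")) {
  case_groups <- case_group_label(case_groups)
  targets <- bind_rows(
    tibble(label = catalogue$class_id, label_type = "class",
           category = catalogue$category),
    tibble(label = composites, label_type = "composite",
           category = NA_character_)
  )
  rows <- tidyr::crossing(targets, case_group = case_groups) |>
    arrange(match(.data$label, targets$label))
  counts <- pmap(list(rows$label, rows$case_group), function(label, cg) {
    assoc_table(samples, label, cg, catalogue)
  }) |> bind_rows()
  out <- bind_cols(rows, counts)
  or_tbl <- odds_ratio_wald(out$a, out$b, out$c, out$d)
  margins_ok <- (out$a + out$b) > 0 & (out$c + out$d) > 0 &
    (out$a + out$c) > 0 & (out$b + out$d) > 0
  chi <- chi_y <- rep(NA_real_, nrow(out))
  if (any(margins_ok)) {
    chi[margins_ok] <- pearson_chi2(out$a[margins_ok], out$b[margins_ok],
                                    out$c[margins_ok], out$d[margins_ok])$p
    chi_y[margins_ok] <- pearson_chi2(out$a[margins_ok], out$b[margins_ok],
                                      out$c[margins_ok], out$d[margins_ok],
                                      correct = TRUE)$p
  }
  fis <- fisher_exact_2x2(out$a, out$b, out$c, out$d)
  N <- out$a + out$b + out$c + out$d
  expected_min <- with(out, pmin((a + b) * (a + c), (a + b) * (b + d),
                                 (c + d) * (a + c), (c + d) * (b + d))) / N
  use_fisher <- !margins_ok | expected_min < 5
  out <- out |>
    mutate(
      or = or_tbl$or, ci_lo = or_tbl$ci_lo, ci_hi = or_tbl$ci_hi,
      p_chi2 = chi, p_chi2_yates = chi_y, p_fisher = fis,
      test_used = ifelse(use_fisher, "fisher", "chi2"),
      p = ifelse(use_fisher, fis, chi)
    )
  class(out) <- c("azf_association", class(out))
  out
}

#' Render an association report with publication conventions
#'
#' ORs and CI bounds to two decimals, p-values in scientific notation with
#' three significant digits, undefined estimates as an en dash.
#'
#' @param report An `azf_association` tibble.
#' @return A character-formatted tibble `label case_group n_case n_control
#'   OR CI95 P test_used`.
#' @export
render_association <- function(report) {
  dash <- "–"
  report |>
    mutate(
      n_case = .data$a, n_control = .data$c,
      OR = ifelse(is.na(.data$or), dash, sprintf("%.2f", .data$or)),
      CI95 = ifelse(is.na(.data$or), dash,
                    sprintf("(%.2f%s%.2f)", .data$ci_lo, dash, .data$ci_hi)),
      P = ifelse(is.na(.data$p), dash, sprintf("%.3g", .data$p))
    ) |>
    select("label", "case_group", "n_case", "n_control", "OR", "CI95", "P",
           "test_used") |>
    as_tibble()
}

#' Covariate balance between cases and controls
#'
#' Equal-variance two-sample t-tests for the numeric covariates (age, BMI)
#' and a chi-squared test without continuity correction for smoking, per
#' case group against controls, with group means and SDs (or proportions)
#' reported.
#'
#' @param samples Sample sheet with `group`, `age`, `bmi` and a binary
#'   `smoking` column.
#' @param case_groups Case groups to compare against controls.
#' @return A tibble `variable`, `case_group`, `control_mean`, `control_sd`,
#'   `case_mean`, `case_sd`, `statistic`, `p`.
#' @export
covariate_balance <- function(samples,
                              case_groups = c("spermatogenic_failure",
                                              "azoospermia",
                                              "oligozoospermia")) {
  samples <- as_tibble(samples)
  case_groups <- case_group_label(case_groups)
  ctrl <- samples |> filter(.data$group == "control")
  if (nrow(ctrl) < 2) abort("control group has fewer than 2 samples")
  map(case_groups, function(cg) {
    cases <- if (cg == "spermatogenic_failure")
      samples |> filter(.data$group %in% c("azoospermia", "oligozoospermia"))
    else samples |> filter(.data$group == cg)
    if (nrow(cases) < 2) abort(paste("case group", cg, "has fewer than 2 samples"))
    num <- map(c("age", "bmi"), function(v) {
      tt <- t.test(cases[[v]], ctrl[[v]], var.equal = TRUE)
      tibble(variable = v, case_group = cg,
             control_mean = mean(ctrl[[v]]), control_sd = sd(ctrl[[v]]),
             case_mean = mean(cases[[v]]), case_sd = sd(cases[[v]]),
             statistic = unname(tt$statistic), p = tt$p.value)
    }) |> bind_rows()
    tab <- rbind(c(sum(cases$smoking), sum(!cases$smoking)),
                 c(sum(ctrl$smoking), sum(!ctrl$smoking)))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    bind_rows(num, tibble(
      variable = "smoking", case_group = cg,
      control_mean = mean(ctrl$smoking), control_sd = NA_real_,
      case_mean = mean(cases$smoking), case_sd = NA_real_,
      statistic = unname(ct$statistic),
      p = ct$p.value
    ))
  }) |> bind_rows()
}
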