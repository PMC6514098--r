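test_that("Wald odds ratios reproduce published 2x2 arithmetic", {
  r <- odds_ratio_wald(11, 412, 2, 400)
  expect_equal(round(r$or, 2), 5.34)
  expect_equal(round(r$ci_lo, 2), 1.18)
  expect_equal(round(r$ci_hi, 2), 24.24)

  expect_equal(odds_ratio_wald(5, 5, 5, 5)$or, 1)

  # zero cells make the estimator undefined, not an error
  z <- odds_ratio_wald(9, 188, 0, 402)
  expect_true(is.na(z$or) && is.na(z$ci_lo))
  expect_true(is.na(odds_ratio_wald(0, 10, 5, 5)$or))
})

test_that("OR transposition symmetry holds whenever both are defined", {
  set.seed(7)
  for (i in 1:100) {
    t <- sample(1:30, 4, replace = TRUE)
    expect_equal(odds_ratio_wald(t[1], t[2], t[3], t[4])$or *
                   odds_ratio_wald(t[3], t[4], t[1], t[2])$or, 1)
  }
})

test_that("Fisher's exact p matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact_2x2(0, 0, 3, 5), 1)  # zero margin
  expect_equal(fisher_exact_2x2(11, 412, 2, 400),
               fisher_enumerate(11, 412, 2, 400), tolerance = 1e-10)
  set.seed(13)
  for (i in 1:50) {
    t <- sample(0:12, 4, replace = TRUE)
    p <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(p, fisher_enumerate(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
    if (all(rowSums(matrix(t, 2, byrow = TRUE)) > 0) &&
        all(colSums(matrix(t, 2, byrow = TRUE)) > 0)) {
      ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
      expect_equal(p, ft, tolerance = 1e-9)
    }
  }
})

test_that("Pearson chi-squared follows the closed form", {
  r <- pearson_chi2(145, 278, 76, 326)
  expect_equal(r$statistic, 24.8391, tolerance = 1e-4)
  expect_equal(r$statistic,
               unname(stats::chisq.test(matrix(c(145, 278, 76, 326), 2,
                                               byrow = TRUE),
                                        correct = FALSE)$statistic))
  # proportional table: statistic 0, p 1
  expect_equal(pearson_chi2(10, 10, 20, 20)$statistic, 0)
  expect_equal(pearson_chi2(10, 10, 20, 20)$p, 1)
  # Yates correction shrinks the statistic
  expect_lt(pearson_chi2(145, 278, 76, 326, correct = TRUE)$statistic,
            r$statistic)
  expect_error(pearson_chi2(0, 0, 5, 5), "zero margin")
})

test_that("2x2 tables from a classified cohort reproduce the study counts", {
  cohort <- exact_cohort()
  sheet <- cohort$samples |> dplyr::rename(assigned_class = true_class)
  t1 <- assoc_table(sheet, "b2/b3 del + DAZ1/2 dup", "SF", default_catalogue)
  expect_equal(unlist(t1), c(a = 11, b = 412, c = 2, d = 400))
  t2 <- assoc_table(sheet, "any_cnv", "spermatogenic_failure", default_catalogue)
  expect_equal(unlist(t2), c(a = 145, b = 278, c = 76, d = 326))
  # empty cohort: all zero
  t0 <- assoc_table(sheet[0, ], "any_cnv", "SF", default_catalogue)
  expect_equal(unlist(t0), c(a = 0, b = 0, c = 0, d = 0))
  expect_error(assoc_table(sheet |> dplyr::mutate(group = "cases"),
                           "any_cnv", "SF"), "unknown group")
  expect_error(assoc_table(sheet, "any_cnv", "nonsense"), "unknown case group")
})

test_that("composite sums over class counts reproduce the summary table", {
  counts <- azf_class_counts() |>
    dplyr::left_join(default_catalogue |>
                       dplyr::select(class_id, category, region_scope),
                     by = "class_id")
  sf <- counts$azoospermia + counts$oligozoospermia
  expect_equal(sum(counts$control), 76)
  expect_equal(sum(sf), 145)
  del <- counts$category %in% c("deletion", "complex")
  expect_equal(sum(counts$control[del]), 60)
  expect_equal(sum(sf[del]), 115)
  dup <- counts$category == "duplication"
  expect_equal(sum(counts$control[dup]), 16)
  expect_equal(sum(sf[dup]), 30)
  azfc_dup <- dup & purrr::map_lgl(counts$region_scope, ~ "AZFc" %in% .x)
  expect_equal(sum(counts$control[azfc_dup]), 12)
  expect_equal(sum(sf[azfc_dup]), 27)
})

test_that("the association report matches the published composite ORs", {
  cohort <- exact_cohort()
  sheet <- cohort$samples |> dplyr::rename(assigned_class = true_class)
  rep <- association_report(sheet, default_catalogue)
  td <- tidy(rep)
  row <- function(label, cg) td[td$label == label & td$case_group == cg, ]

  any_sf <- row("any_cnv", "spermatogenic_failure")
  expect_equal(round(any_sf$or, 2), 2.24)
  expect_equal(round(any_sf$ci_lo, 2), 1.62)
  expect_equal(round(any_sf$ci_hi, 2), 3.08)
  expect_equal(round(row("any_deletion", "spermatogenic_failure")$or, 2), 2.13)
  expect_equal(round(row("any_cnv", "azoospermia")$or, 2), 1.97)

  daz <- row("b2/b3 del + DAZ1/2 dup", "spermatogenic_failure")
  expect_equal(round(daz$or, 2), 5.34)
  # both test p-values are always emitted; sparse rows fall back to Fisher
  expect_true(all(!is.na(rep$p_fisher)))
  expect_equal(row("b2/b3 trip", "spermatogenic_failure")$test_used, "fisher")

  # rows with no carriers anywhere have undefined ORs
  no_carrier <- sheet |> dplyr::mutate(assigned_class = "NO_CNV")
  rep0 <- association_report(no_carrier, default_catalogue)
  expect_true(all(is.na(rep0$or)))

  # rendering conventions
  shown <- render_association(rep)
  expect_equal(shown$OR[shown$label == "any_cnv" &
                          shown$case_group == "spermatogenic_failure"], "2.24")
  expect_true(any(shown$OR == "–"))
})

test_that("covariate balance computes t and chi-squared comparisons", {
  set.seed(31)
  sheet <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:120),
    group = rep(c("control", "azoospermia", "oligozoospermia"), each = 40),
    age = rnorm(120, 28.5, 3.6),
    bmi = rnorm(120, 22, 3),
    smoking = rbinom(120, 1, 0.58) == 1
  )
  bal <- covariate_balance(sheet)
  expect_equal(nrow(bal), 9)
  expect_true(all(bal$p >= 0 & bal$p <= 1))

  # identical case and control groups: p = 1 everywhere
  dupd <- dplyr::bind_rows(
    sheet |> dplyr::filter(group == "control"),
    sheet |> dplyr::filter(group == "control") |>
      dplyr::mutate(group = "azoospermia", sample_id = paste0(sample_id, "b")))
  bal_id <- covariate_balance(dupd, case_groups = "azoospermia")
  expect_equal(bal_id$p, rep(1, 3))

  expect_error(covariate_balance(sheet[1:41, ]), "fewer than 2")
})

test_that("the smoking comparison at published proportions is non-significant", {
  tab <- matrix(c(233, 169, 251, 172), 2, byrow = TRUE)
  p <- stats::chisq.test(tab, correct = FALSE)$p.value
  expect_gt(p, 0.05)
  expect_equal(round(p, 2), 0.69)
})
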