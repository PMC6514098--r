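classify_cohort <- function(cohort, digest = cohort$digest) {
  calls <- call_samples(cohort$peaks, cohort$references, default_panel)
  classify_samples(calls, default_panel, default_catalogue, digest = digest)
}

test_that("every catalogue class round-trips at zero noise", {
  counts <- azf_class_counts()
  counts$control <- 1L
  counts$azoospermia <- 0L
  counts$oligozoospermia <- 0L
  cfg <- simulation_config(seed = 11, n_control = 24, n_azoospermia = 0,
                           n_oligozoospermia = 0, class_counts = counts,
                           sigma_area = 0)
  cohort <- simulate_cohort(cfg, default_panel, default_catalogue)
  cls <- classify_cohort(cohort)
  truth <- cohort$samples |>
    dplyr::left_join(cls, by = "sample_id")
  expect_equal(truth$assigned_class, truth$true_class)
  expect_equal(sum(truth$assigned_class %in% default_catalogue$class_id), 24)
})

test_that("an all-normal sample is NO_CNV and ordering does not matter", {
  cohort <- simulate_class_cohort("NO_CNV", 2, sigma_area = 0, seed = 3)
  calls <- call_samples(cohort$peaks, cohort$references, default_panel)
  cls <- classify_samples(calls, default_panel, default_catalogue)
  expect_true(all(cls$assigned_class == "NO_CNV"))

  shuffled <- calls[sample.int(nrow(calls)), ]
  cls2 <- classify_samples(shuffled, default_panel, default_catalogue)
  expect_equal(
    cls2$assigned_class[match(cls$sample_id, cls2$sample_id)],
    cls$assigned_class)
})

test_that("digest-dependent class is flagged without digest and resolved with it", {
  cohort <- simulate_class_cohort("b2/b3 del + DAZ1/2 dup", 3,
                                  sigma_area = 0, seed = 9)
  without <- classify_cohort(cohort, digest = NULL)
  carriers <- cohort$samples$sample_id[
    cohort$samples$true_class == "b2/b3 del + DAZ1/2 dup"]
  w <- without[without$sample_id %in% carriers, ]
  expect_true(all(w$assigned_class == "b2/b3 del + DAZ1/2 dup"))
  expect_true(all(w$digest_needed))
  expect_true(all(is.na(w$digest_consistent)))

  with_dg <- classify_cohort(cohort)
  wd <- with_dg[with_dg$sample_id %in% carriers, ]
  expect_true(all(wd$digest_consistent))
})

test_that("a digest contradicting the class is reported inconsistent", {
  cohort <- simulate_class_cohort("b2/b3 del + DAZ1/2 dup", 1,
                                  sigma_area = 0, seed = 10)
  carrier <- cohort$samples$sample_id[
    cohort$samples$true_class == "b2/b3 del + DAZ1/2 dup"]
  flipped <- cohort$digest |>
    dplyr::mutate(tmp = intensity_daz12, intensity_daz12 = intensity_daz34,
                  intensity_daz34 = tmp) |>
    dplyr::select(-tmp)
  cls <- classify_cohort(cohort, digest = flipped)
  expect_false(cls$digest_consistent[cls$sample_id == carrier])
})

test_that("a compound pattern matching no class is UNCLASSIFIED with candidates", {
  # AZFa duplication plus complete AZFc deletion: no such catalogue class
  copies <- class_copy_vector("b2/b4 del", default_panel, default_catalogue)
  azfa <- default_panel$probe_id[default_panel$region == "AZFa"]
  copies[azfa] <- copies[azfa] * 2L
  peaks <- simulate_peak_table(copies, default_panel, sigma_area = 0)
  refs <- simulate_class_cohort("NO_CNV", 1, sigma_area = 0, seed = 5)$references
  calls <- call_samples(peaks, refs, default_panel)
  cls <- classify_samples(calls, default_panel, default_catalogue)
  expect_equal(cls$assigned_class, "UNCLASSIFIED")
  expect_gte(nrow(cls$candidates[[1]]), 2)
})

test_that("two identical signatures under different names give AMBIGUOUS", {
  dupd <- dplyr::bind_rows(
    default_catalogue,
    default_catalogue[default_catalogue$class_id == "gr/gr del", ] |>
      dplyr::mutate(class_id = "gr/gr del (alias)"))
  cohort <- simulate_class_cohort("gr/gr del", 1, sigma_area = 0, seed = 6)
  carrier <- cohort$samples$sample_id[cohort$samples$true_class == "gr/gr del"]
  calls <- call_samples(cohort$peaks, cohort$references, default_panel)
  cls <- classify_samples(calls, default_panel, dupd)
  row <- cls[cls$sample_id == carrier, ]
  expect_equal(row$assigned_class, "AMBIGUOUS")
  expect_gte(row$n_candidates, 2)
})

test_that("noisy carriers are assigned correctly at least 99 percent of the time", {
  # spot-check the two classes separated only by one BPY2 copy step;
  # the full 24-class sweep runs in the acceptance suite
  for (cl in c("BPY2 partial dup-Type I", "BPY2 partial dup-Type II")) {
    cohort <- simulate_class_cohort(cl, 200, sigma_area = 0.05,
                                    seed = 100 + nchar(cl))
    cls <- classify_cohort(cohort)
    truth <- cohort$samples |> dplyr::left_join(cls, by = "sample_id")
    expect_gte(mean(truth$assigned_class == truth$true_class), 0.99)
  }
})

test_that("DAZ subset resolution follows proportional largest-remainder", {
  expect_equal(resolve_daz_subsets(1, 1, 4),
               tibble::tibble(copies_daz12 = 2L, copies_daz34 = 2L))
  expect_equal(resolve_daz_subsets(1, 0, 2),
               tibble::tibble(copies_daz12 = 2L, copies_daz34 = 0L))
  expect_equal(resolve_daz_subsets(2, 1, 6),
               tibble::tibble(copies_daz12 = 4L, copies_daz34 = 2L))
  expect_error(resolve_daz_subsets(0, 0, 2), "zero")
  expect_error(resolve_daz_subsets(-1, 1, 2), "intensity")

  # conservation: the split always sums to the total
  set.seed(42)
  for (i in 1:200) {
    i12 <- runif(1, 0, 5); i34 <- runif(1, 0, 5); tot <- sample(0:12, 1)
    s <- resolve_daz_subsets(i12, i34, tot)
    expect_equal(s$copies_daz12 + s$copies_daz34, tot)
    expect_true(s$copies_daz12 >= 0 && s$copies_daz34 >= 0)
  }
})

test_that("inheritance status distinguishes de novo from inherited", {
  expect_equal(inheritance_status("RBMY1J del", "NO_CNV"), "de_novo")
  expect_equal(inheritance_status("gr/gr del", "gr/gr del"), "inherited")
  expect_equal(inheritance_status("gr/gr del", "UNCLASSIFIED"), "indeterminate")
  expect_equal(inheritance_status("NO_CNV", "NO_CNV"), "indeterminate")
  expect_equal(inheritance_status("gr/gr del", "b2/b3 del"), "de_novo")
})
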