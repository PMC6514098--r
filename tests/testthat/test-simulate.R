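test_that("the default cohort has the study's group sizes and references", {
  cohort <- exact_cohort()
  expect_equal(sum(cohort$samples$group == "control"), 402)
  expect_equal(sum(cohort$samples$group == "azoospermia"), 197)
  expect_equal(sum(cohort$samples$group == "oligozoospermia"), 226)
  expect_equal(nrow(cohort$references), 5)
  expect_equal(nrow(cohort$peaks),
               nrow(cohort$samples) + nrow(cohort$fathers))
})

test_that("exact counts place exactly the configured carriers per group", {
  g <- draw_genotypes(simulation_config(seed = 8))
  counts <- azf_class_counts()
  for (grp in c("control", "azoospermia", "oligozoospermia")) {
    tab <- table(g$true_class[g$group == grp])
    for (i in seq_len(nrow(counts))) {
      expected <- counts[[grp]][i]
      got <- tab[counts$class_id[i]]
      expect_equal(unname(ifelse(is.na(got), 0L, got)), expected,
                   label = paste(grp, counts$class_id[i]))
    }
  }
  expect_equal(sum(g$true_class[g$group == "control"] == "gr/gr del"), 20)
})

test_that("all-zero frequencies give an all-NO_CNV cohort", {
  counts <- azf_class_counts()
  counts$control <- counts$azoospermia <- counts$oligozoospermia <- 0L
  g <- draw_genotypes(simulation_config(seed = 2, class_counts = counts))
  expect_true(all(g$true_class == "NO_CNV"))
})

test_that("probability mode recovers the configured rate within 3 SE", {
  counts <- azf_class_counts()
  counts$control <- counts$azoospermia <- counts$oligozoospermia <- 0L
  counts$control[counts$class_id == "gr/gr del"] <- 500L  # p = 0.05 of 10000
  cfg <- simulation_config(seed = 19, n_control = 10000, n_azoospermia = 0,
                           n_oligozoospermia = 0, class_counts = counts,
                           exact_counts = FALSE)
  g <- draw_genotypes(cfg)
  p_hat <- mean(g$true_class == "gr/gr del")
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("counts exceeding the group size are rejected", {
  counts <- azf_class_counts()
  counts$control[1] <- 500L
  expect_error(simulation_config(class_counts = counts), "exceed")
})

test_that("copy vectors expand signatures and keep the DAZ split", {
  cv <- class_copy_vector("NO_CNV", default_panel, default_catalogue)
  expect_equal(unname(cv[default_panel$probe_id]),
               default_panel$baseline_copies)
  expect_equal(attr(cv, "daz_split"), c(2L, 2L))

  b24 <- class_copy_vector("b2/b4 del", default_panel, default_catalogue)
  azfc <- default_panel$probe_id[default_panel$region == "AZFc"]
  expect_true(all(b24[azfc] == 0))
  expect_equal(attr(b24, "daz_split"), c(0L, 0L))

  expect_error(class_copy_vector("nope", default_panel, default_catalogue),
               "unknown class")
})

test_that("peak simulation is exact at zero noise through the calling chain", {
  cv <- class_copy_vector("gr/gr del", default_panel, default_catalogue)
  peaks <- simulate_peak_table(cv, default_panel, sigma_area = 0)
  refs <- simulate_class_cohort("NO_CNV", 1, sigma_area = 0, seed = 5)$references
  calls <- call_samples(peaks, refs, default_panel)
  daz <- calls |> dplyr::filter(target_locus == "DAZ")
  expect_true(all(daz$ratio == 0.5))
  expect_true(all(daz$state == "deleted"))
  expect_true(all(daz$estimated_copies == 2L))
})

test_that("simulation is deterministic under the seed at every stage", {
  counts <- azf_class_counts()
  counts$control <- counts$azoospermia <- counts$oligozoospermia <- 0L
  counts$control[counts$class_id %in% c("gr/gr del", "RBMY1J dup",
                                        "b2/b3 del + DAZ1/2 dup")] <- 3L
  cfg <- simulation_config(seed = 123, n_control = 30, n_azoospermia = 10,
                           n_oligozoospermia = 10, class_counts = counts)
  a <- simulate_cohort(cfg, default_panel, default_catalogue)
  b <- simulate_cohort(cfg, default_panel, default_catalogue)
  expect_identical(a$samples, b$samples)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$references, b$references)
  expect_identical(a$digest, b$digest)
  expect_identical(a$ct, b$ct)
  c <- simulate_cohort(simulation_config(seed = 124, n_control = 30,
                                         n_azoospermia = 10,
                                         n_oligozoospermia = 10,
                                         class_counts = counts),
                       default_panel, default_catalogue)
  expect_false(identical(a$peaks, c$peaks))
})

test_that("truth covers every sample once and fathers exist for novel carriers", {
  cohort <- exact_cohort()
  expect_false(anyDuplicated(cohort$samples$sample_id) > 0)
  novel <- default_catalogue$class_id[default_catalogue$novel]
  novel_carriers <- cohort$samples$sample_id[cohort$samples$true_class %in% novel]
  expect_setequal(cohort$fathers$proband_id, novel_carriers)
  expect_true(all(cohort$fathers$true_class == "NO_CNV"))
  expect_true(all(cohort$fathers$father_id %in% cohort$peaks$sample_id))
})

test_that("cohort files round-trip through the TSV interface", {
  cohort <- simulate_class_cohort("gr/gr del", 3, sigma_area = 0.05, seed = 44)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(
    dir, c("samples.tsv", "peaks.tsv", "references.tsv", "digest.tsv",
           "ct.tsv", "truth.tsv", "config.json")))))
  peaks <- readr::read_tsv(file.path(dir, "peaks.tsv"), show_col_types = FALSE)
  expect_equal(as.data.frame(peaks), as.data.frame(cohort$peaks),
               tolerance = 1e-12)
})
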