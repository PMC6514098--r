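test_that("default panel has 42 AZF probes and validates", {
  expect_equal(sum(!default_panel$is_reference), 42)
  expect_gte(sum(default_panel$is_reference), 2)
  expect_false(anyDuplicated(default_panel$probe_id) > 0)
  expect_true(all(default_panel$baseline_copies >= 1))
  expect_setequal(unique(default_panel$region),
                  c("AZFa", "AZFb", "AZFc", "reference"))
})

test_that("panel files round-trip through both formats and reject bad input", {
  for (ext in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_probe_panel(default_panel, path)
    expect_equal(read_probe_panel(path), default_panel)
  }
  # shipped fixture file equals the in-code default
  shipped <- system.file("extdata", "azf_panel.tsv", package = "azfcnv")
  expect_equal(sum(!read_probe_panel(shipped)$is_reference), 42)

  expect_error(read_probe_panel(withr::local_tempfile()), "not found")
  dup <- mini_panel()
  dup$probe_id[2] <- "DAZ_A"
  expect_error(validate_probe_panel(dup), "probe_id")
  bad <- mini_panel()
  bad$baseline_copies[1] <- 0L
  expect_error(validate_probe_panel(bad), "baseline_copies")
  one_ref <- mini_panel()[1:2, ]
  expect_error(validate_probe_panel(one_ref), "reference")
})

test_that("a minimal hand-built panel round-trips write-then-load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_panel(mini_panel(), path)
  expect_equal(read_probe_panel(path), mini_panel())
  expect_equal(nrow(read_probe_panel(path)), 3)
})

test_that("default catalogue has the expected taxonomy", {
  cc <- catalogue_counts(default_catalogue)
  expect_equal(nrow(default_catalogue), 24)
  expect_equal(cc$n[cc$category == "deletion"], 8)
  expect_equal(cc$n[cc$category == "duplication"], 11)
  expect_equal(cc$n[cc$category == "complex"], 5)
  expect_equal(sum(default_catalogue$classical), 4)
  expect_setequal(
    default_catalogue$class_id[default_catalogue$classical],
    c("AZFa del", "AZFb del", "b2/b4 del", "AZFb + c del"))
  expect_equal(sum(default_catalogue$novel), 11)
  novel <- default_catalogue |> dplyr::filter(novel) |> dplyr::count(category)
  expect_equal(novel$n[novel$category == "deletion"], 1)
  expect_equal(novel$n[novel$category == "duplication"], 7)
  expect_equal(novel$n[novel$category == "complex"], 3)
})

test_that("signatures are self-consistent with their categories", {
  probes <- default_panel[!default_panel$is_reference, ]
  baseline <- setNames(probes$baseline_copies, probes$probe_id)
  for (i in seq_len(nrow(default_catalogue))) {
    sig <- default_catalogue$signature[[i]]
    delta <- sig - baseline[names(sig)]
    cat_i <- default_catalogue$category[i]
    if (cat_i == "deletion") expect_true(all(delta <= 0))
    if (cat_i == "duplication") {
      expect_true(all(delta >= 0))
      expect_true(all(default_catalogue$sts[[i]] == 1))
    }
    if (cat_i == "complex") {
      daz_effect <- default_catalogue$daz12[i] != default_catalogue$daz34[i]
      expect_true(any(delta < 0))
      expect_true(any(delta > 0) || daz_effect)
    }
  }
})

test_that("catalogue JSON round-trips and load-time validation works", {
  path <- withr::local_tempfile(fileext = ".json")
  write_cnv_catalogue(default_catalogue, path)
  reread <- read_cnv_catalogue(path, default_panel)
  expect_equal(reread, default_catalogue)
  # write(load(x)) round-trips bit-identically
  path2 <- withr::local_tempfile(fileext = ".json")
  write_cnv_catalogue(reread, path2)
  expect_identical(readLines(path), readLines(path2))

  # empty catalogue
  empty_path <- withr::local_tempfile(fileext = ".json")
  writeLines("[]", empty_path)
  empty <- read_cnv_catalogue(empty_path, default_panel)
  expect_equal(nrow(empty), 0)
  expect_true(all(catalogue_counts(empty)$n == 0))

  # a deletion class that raises a probe is rejected
  bad <- default_catalogue[default_catalogue$class_id == "gr/gr del", ]
  sig <- bad$signature[[1]]
  sig["DAZ_01"] <- 9L
  bad$signature[[1]] <- sig
  expect_error(validate_cnv_catalogue(bad, default_panel), "raises a probe")

  # a signature referencing an unknown probe is rejected
  bad2 <- default_catalogue[1, ]
  sig2 <- bad2$signature[[1]]
  names(sig2)[1] <- "NOT_A_PROBE"
  bad2$signature[[1]] <- sig2
  expect_error(validate_cnv_catalogue(bad2, default_panel), "unknown probes")
})

test_that("all default classes are pairwise distinguishable", {
  report <- catalogue_consistency(default_catalogue, default_panel)
  expect_equal(nrow(report), 0)
  expect_equal(attr(report, "n_pairs_checked"), choose(24, 2))
})

test_that("a duplicated class is flagged; a DAZ-subset-only twin is digest-dependent", {
  dupd <- dplyr::bind_rows(default_catalogue, default_catalogue[2, ] |>
                             dplyr::mutate(class_id = "gr/gr del (alias)"))
  report <- catalogue_consistency(dupd, default_panel)
  expect_equal(nrow(report), 1)
  expect_equal(report$status, "indistinguishable")

  twin <- default_catalogue[default_catalogue$class_id == "b2/b3 del + DAZ1/2 dup", ] |>
    dplyr::mutate(class_id = "b2/b3 del + DAZ3/4 dup", daz12 = 0L, daz34 = 4L)
  report2 <- catalogue_consistency(dplyr::bind_rows(default_catalogue, twin))
  expect_equal(report2$status, "digest_dependent")
})
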