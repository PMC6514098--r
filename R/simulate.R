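#' Configuration for the synthetic-cohort simulator
#'
#' Defines the study conditions the simulator emulates: a 402-control /
#' 197-azoospermia / 226-oligozoospermia cohort carrying the catalogue
#' classes at the reference-cohort frequencies ([azf_class_counts()]),
#' measured with multiplicative log-normal peak-area noise, five
#' copy-normal reference samples, triplicate qPCR with Ct noise, and
#' covariates drawn at the reference demographics.
#'
#' @param seed Integer seed; every downstream draw is deterministic in it.
#' @param n_control,n_azoospermia,n_oligozoospermia Group sizes (defaults
#'   402, 197, 226).
#' @param class_counts Tibble `class_id`, `control`, `azoospermia`,
#'   `oligozoospermia` of carrier counts (`exact_counts = TRUE`) or the
#'   counts whose group-size quotients serve as carrier probabilities
#'   (`exact_counts = FALSE`).
#' @param exact_counts If `TRUE` (default) each (group, class) receives
#'   exactly the configured count of carriers, remainder copy-normal; if
#'   `FALSE`, carriers are drawn independently at the implied frequencies.
#' @param sigma_area SD of the multiplicative log-normal peak-area noise
#'   (default 0.05).
#' @param sigma_ct SD of the qPCR Ct replicate noise in cycles
#'   (default 0.1).
#' @param covariate_params Age/BMI means and SDs and smoking proportions
#'   per group, as from [azf_covariate_params()].
#' @param n_reference_samples Copy-normal reference samples (default 5).
#' @param base_area Nominal peak area of a baseline-dosage probe; calls are
#'   scale-invariant, so this only sets the fluorescence scale.
#' @param base_ct Nominal target Ct of a baseline-dosage region;
#'   `base_ct - log2(copies/baseline)` is simulated, capped at 40 cycles
#'   for zero copies.
#' @return A list of class `azf_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_control = 402,
                              n_azoospermia = 197,
                              n_oligozoospermia = 226,
                              class_counts = azf_class_counts(),
                              exact_counts = TRUE,
                              sigma_area = 0.05,
                              sigma_ct = 0.1,
                              covariate_params = azf_covariate_params(),
                              n_reference_samples = 5,
                              base_area = 1000,
                              base_ct = 26) {
  if (sigma_area < 0 || sigma_ct < 0)
    validation_error("sigma", "noise SDs must be >= 0")
  sizes <- c(control = n_control, azoospermia = n_azoospermia,
             oligozoospermia = n_oligozoospermia)
  for (g in names(sizes)) {
    if (sum(class_counts[[g]]) > sizes[[g]])
      validation_error("class_counts", sprintf(
        "carrier counts for %s exceed the group size (%d > %d)",
        g, sum(class_counts[[g]]), sizes[[g]]))
  }
  structure(
    list(seed = seed, n_control = n_control, n_azoospermia = n_azoospermia,
         n_oligozoospermia = n_oligozoospermia, class_counts = class_counts,
         exact_counts = exact_counts, sigma_area = sigma_area,
         sigma_ct = sigma_ct, covariate_params = covariate_params,
         n_reference_samples = n_reference_samples, base_area = base_area,
         base_ct = base_ct),
    class = "azf_sim_config"
  )
}

#' Draw per-sample genotypes at the configured class frequencies
#'
#' With exact counts each (group, class) pair receives exactly the
#' configured number of carriers, assigned to a random subset of the group;
#' in probability mode each sample independently draws a class with
#' probability count / group size.  Deterministic under the config seed.
#'
#' @param config An `azf_sim_config`.
#' @return A tibble `sample_id`, `group`, `true_class` (catalogue class or
#'   `"NO_CNV"`).
#' @export
draw_genotypes <- function(config) {
  sizes <- c(control = config$n_control, azoospermia = config$n_azoospermia,
             oligozoospermia = config$n_oligozoospermia)
  prefix <- c(control = "CTL", azoospermia = "AZO", oligozoospermia = "OLI")
  with_seed(child_seed(config$seed, 1), {
    map(names(sizes), function(g) {
      n <- sizes[[g]]
      cls <- rep("NO_CNV", n)
      if (n > 0 && nrow(config$class_counts) > 0) {
        if (config$exact_counts) {
          k <- config$class_counts[[g]]
          carriers <- rep(config$class_counts$class_id, k)
          idx <- sample.int(n, length(carriers))
          cls[idx] <- carriers
        } else {
          p <- config$class_counts[[g]] / n
          if (sum(p) > 1) validation_error("class_counts", "probabilities exceed 1")
          cls <- sample(c(config$class_counts$class_id, "NO_CNV"), n,
                        replace = TRUE, prob = c(p, 1 - sum(p)))
        }
      }
      tibble(sample_id = sprintf("%s%04d", prefix[[g]], seq_len(n)),
             group = g, true_class = cls)
    }) |> bind_rows()
  })
}

#' Expand a class into a per-probe copy-number vector
#'
#' The class signature gives the copies at every non-reference probe;
#' reference probes sit at their baseline.  The DAZ1/2 vs DAZ3/4 split is
#' attached as attribute `daz_split` for digest simulation (`c(2, 2)` for
#' a copy-normal chromosome).
#'
#' @param class_id A catalogue class or `"NO_CNV"`.
#' @param panel Probe panel.
#' @param catalogue CNV catalogue.
#' @return Named integer vector of copies per panel probe.
#' @export
class_copy_vector <- function(class_id, panel, catalogue = azf_catalogue(panel)) {
  copies <- setNames(panel$baseline_copies, panel$probe_id)
  split <- c(2L, 2L)
  if (!identical(class_id, "NO_CNV")) {
    i <- match(class_id, catalogue$class_id)
    if (is.na(i)) abort(paste("unknown class:", class_id))
    sig <- catalogue$signature[[i]]
    copies[names(sig)] <- sig
    if (!is.na(catalogue$daz12[i]))
      split <- c(catalogue$daz12[i], catalogue$daz34[i])
  }
  attr(copies, "daz_split") <- split
  copies
}

# deterministic per-probe nominal areas: fixed spread, independent of seed
probe_base_areas <- function(panel, base_area) {
  base_area * (0.6 + 0.8 * ((seq_along(panel$probe_id) * 7) %% 11) / 10)
}

#' Simulate one MLPA peak table from a copy vector
#'
#' `area = base_area_probe * (copies / baseline) * exp(eps)` with
#' `eps ~ N(0, sigma_area^2)` independently per probe; reference probes sit
#' at baseline dosage.
#'
#' @param copy_vector Named copies per probe, as from [class_copy_vector()].
#' @param panel Probe panel.
#' @param sigma_area Log-normal noise SD.
#' @param seed Optional seed for a standalone deterministic draw; inside
#'   [simulate_cohort()] the cohort seed governs instead.
#' @param base_area Nominal baseline-dosage area.
#' @return A one-row wide peak tibble (`sample_id = "sim"` plus one column
#'   per probe).
#' @export
simulate_peak_table <- function(copy_vector, panel, sigma_area = 0.05,
                                seed = NULL, base_area = 1000) {
  if (sigma_area < 0) validation_error("sigma_area", "must be >= 0")
  draw <- function() {
    dose <- copy_vector[panel$probe_id] / panel$baseline_copies
    areas <- probe_base_areas(panel, base_area) * dose *
      exp(rnorm(nrow(panel), 0, sigma_area))
    bind_cols(tibble(sample_id = "sim"),
              as_tibble(as.list(setNames(areas, panel$probe_id))))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# matrix version: one row per sample (rows of `copies`: samples x probes)
simulate_peak_matrix <- function(sample_ids, copies, panel, sigma_area, base_area) {
  dose <- sweep(copies, 2, panel$baseline_copies, "/")
  noise <- matrix(rnorm(length(dose), 0, sigma_area), nrow(dose))
  areas <- sweep(dose * exp(noise), 2, probe_base_areas(panel, base_area), "*")
  colnames(areas) <- panel$probe_id
  bind_cols(tibble(sample_id = sample_ids), as_tibble(areas))
}

#' Simulate a complete synthetic study
#'
#' Generates genotypes at the configured frequencies, expands them to copy
#' vectors, simulates peak tables for all subjects, copy-normal reference
#' samples, copy-normal fathers for every carrier of a novel class (for de
#' novo checks), sY587 digest tables for carriers of digest-dependent
#' classes, triplicate Ct tables for one carrier of each class STS-PCR
#' cannot confirm (duplications, complex classes and the RBMY1J deletion,
#' with two copy-normal calibrator samples), and covariates at the
#' reference demographics.  Everything is deterministic under the config
#' seed.
#'
#' @param config An `azf_sim_config`.
#' @param panel Probe panel.
#' @param catalogue CNV catalogue.
#' @return A list of class `azf_cohort`: `samples` (sample sheet with
#'   `true_class` truth column and covariates), `fathers`, `peaks` (subjects
#'   and fathers), `references`, `digest`, `ct`, `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(seed = 42, n_control = 20,
#'   n_azoospermia = 10, n_oligozoospermia = 10,
#'   class_counts = azf_class_counts()[0, ]))
#' nrow(cohort$samples)
#' @export
simulate_cohort <- function(config = simulation_config(), panel = azf_panel(),
                            catalogue = azf_catalogue(panel)) {
  genotypes <- draw_genotypes(config)
  copy_vectors <- map(set_names_unique(catalogue$class_id), function(id)
    class_copy_vector(id, panel, catalogue))
  copy_vectors[["NO_CNV"]] <- class_copy_vector("NO_CNV", panel, catalogue)

  # covariates
  samples <- with_seed(child_seed(config$seed, 2), {
    cp <- config$covariate_params
    genotypes |>
      mutate(
        age = map_dbl(.data$group, function(g)
          rnorm(1, cp$age[[g]][1], cp$age[[g]][2])),
        bmi = map_dbl(.data$group, function(g)
          rnorm(1, cp$bmi[[g]][1], cp$bmi[[g]][2])),
        smoking = map_int(.data$group, function(g)
          rbinom(1, 1, cp$smoking[[g]])) == 1
      )
  })

  # fathers: copy-normal, generated for carriers of novel classes
  novel <- catalogue$class_id[catalogue$novel]
  probands <- samples$sample_id[samples$true_class %in% novel]
  samples$father_id <- ifelse(samples$sample_id %in% probands,
                              paste0(samples$sample_id, "_F"), NA_character_)
  fathers <- tibble(
    father_id = samples$father_id[!is.na(samples$father_id)],
    proband_id = samples$sample_id[!is.na(samples$father_id)],
    true_class = "NO_CNV"
  )

  # peak tables (subjects then fathers), references
  copies_of <- function(ids) do.call(rbind, map(ids, function(cl)
    unname(copy_vectors[[cl]][panel$probe_id])))
  peaks <- with_seed(child_seed(config$seed, 3), {
    simulate_peak_matrix(
      c(samples$sample_id, fathers$father_id),
      copies_of(c(samples$true_class, fathers$true_class)),
      panel, config$sigma_area, config$base_area
    )
  })
  references <- with_seed(child_seed(config$seed, 4), {
    simulate_peak_matrix(
      sprintf("REF%02d", seq_len(config$n_reference_samples)),
      copies_of(rep("NO_CNV", config$n_reference_samples)),
      panel, config$sigma_area, config$base_area
    )
  })

  # sY587 digest for carriers of digest-dependent classes
  digest_classes <- catalogue$class_id[catalogue$digest_needed]
  digest_samples <- samples |> filter(.data$true_class %in% digest_classes)
  digest <- with_seed(child_seed(config$seed, 5), {
    if (nrow(digest_samples) == 0) {
      tibble(sample_id = character(), intensity_daz12 = numeric(),
             intensity_daz34 = numeric())
    } else {
      splits <- do.call(rbind, map(digest_samples$true_class, function(cl)
        attr(copy_vectors[[cl]], "daz_split")))
      tibble(
        sample_id = digest_samples$sample_id,
        intensity_daz12 = splits[, 1] *
          exp(rnorm(nrow(splits), 0, config$sigma_area)),
        intensity_daz34 = splits[, 2] *
          exp(rnorm(nrow(splits), 0, config$sigma_area))
      )
    }
  })

  # qPCR Ct tables: one carrier per class STS-PCR cannot confirm
  sts_cmp <- compare_sts_mlpa(catalogue)
  unconfirmed <- sts_cmp$by_class$class_id[sts_cmp$by_class$sts_outcome != "identified"]
  fams <- panel_families(panel)
  ct <- with_seed(child_seed(config$seed, 6), {
    ct_for <- function(sample, assay_fam, copies, baseline) {
      target <- if (copies == 0) 40 else config$base_ct - log2(copies / baseline)
      tibble(
        sample_id = sample, assay_id = assay_fam, replicate = 1:3,
        ct_target = target + rnorm(3, 0, config$sigma_ct),
        ct_reference = 20 + rnorm(3, 0, config$sigma_ct)
      )
    }
    rows <- map(unconfirmed, function(cl) {
      carrier <- samples$sample_id[samples$true_class == cl][1]
      if (is.na(carrier)) return(NULL)
      cv <- copy_vectors[[cl]]
      fam_copies <- vapply(fams$target_locus, function(f)
        cv[panel$probe_id[panel$target_locus == f][1]], numeric(1))
      assay_fam <- fams$target_locus[
        which.max(abs(fam_copies / fams$baseline_copies - 1))]
      baseline <- fams$baseline_copies[fams$target_locus == assay_fam]
      ct_for(carrier, assay_fam, fam_copies[[assay_fam]], baseline)
    })
    rows <- bind_rows(rows)
    if (nrow(rows) > 0) {
      # two copy-normal calibrator samples per assayed region
      cals <- map(unique(rows$assay_id), function(f) {
        baseline <- fams$baseline_copies[fams$target_locus == f]
        bind_rows(ct_for("REF01", f, baseline, baseline),
                  ct_for("REF02", f, baseline, baseline))
      })
      rows <- bind_rows(rows, bind_rows(cals))
    }
    rows
  })
  if (nrow(ct) == 0)
    ct <- tibble(sample_id = character(), assay_id = character(),
                 replicate = integer(), ct_target = numeric(),
                 ct_reference = numeric())

  structure(
    list(samples = samples, fathers = fathers, peaks = peaks,
         references = references, digest = digest, ct = ct, config = config),
    class = "azf_cohort"
  )
}

set_names_unique <- function(x) setNames(x, x)

#' @export
print.azf_cohort <- function(x, ...) {
  cat("Synthetic AZF MLPA cohort:",
      nrow(x$samples), "subjects (",
      sum(x$samples$group == "control"), "control /",
      sum(x$samples$group == "azoospermia"), "azoospermia /",
      sum(x$samples$group == "oligozoospermia"), "oligozoospermia ),",
      nrow(x$fathers), "fathers,",
      nrow(x$references), "reference samples\n")
  cat("sigma_area =", x$config$sigma_area,
      "| seed =", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `samples.tsv`, `peaks.tsv`, `references.tsv`, `digest.tsv`,
#' `ct.tsv`, `truth.tsv` and a `config.json` echo into a directory.
#'
#' @param cohort An `azf_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f), na = "NA")
  w(cohort$samples |> select(-"true_class"), "samples.tsv")
  w(cohort$peaks, "peaks.tsv")
  w(cohort$references, "references.tsv")
  w(cohort$digest, "digest.tsv")
  w(cohort$ct, "ct.tsv")
  w(bind_rows(
    cohort$samples |> select("sample_id", "group", "true_class"),
    cohort$fathers |> transmute(sample_id = .data$father_id, group = "father",
                                true_class = .data$true_class)
  ), "truth.tsv")
  cfg <- cohort$config
  cfg$class_counts <- as.list(cfg$class_counts)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
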