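#' The AZF rearrangement-class catalogue
#'
#' A CNV catalogue is a tibble with one row per named AZF rearrangement
#' class and columns:
#' \describe{
#'   \item{class_id}{canonical class name, e.g. `"gr/gr del"`,
#'     `"b2/b3 del + DAZ1/2 dup"`.}
#'   \item{category}{`"deletion"`, `"duplication"` or `"complex"`.}
#'   \item{region_scope}{list column of affected regions.}
#'   \item{classical}{one of the four classical deletions (AZFa, AZFb,
#'     AZFb+c, b2/b4) screened by EAA/EMQN guidelines.}
#'   \item{novel}{class first described by the MLPA survey the default
#'     frequencies emulate.}
#'   \item{digest_needed}{whether naming the class requires the sY587
#'     restriction digest that separates DAZ1/2 from DAZ3/4 copies.}
#'   \item{daz12, daz34}{expected copies of each DAZ doublet under the
#'     class (`NA` when the class does not touch AZFc).}
#'   \item{signature}{list column: named integer vector, expected copies
#'     for every non-reference probe.}
#'   \item{sts}{list column: named 0/1 vector over the ten EAA/EMQN STS
#'     markers, 1 = fragment amplifies (present).}
#' }
#'
#' `azf_catalogue()` builds the default 24-class catalogue (8 deletions,
#' 11 duplications, 5 complex classes) on a given panel.  Copy numbers for
#' the partial-duplication subtypes are schematic: they are chosen so that
#' every class has a distinguishing dosage pattern, not from breakpoint
#' maps.
#'
#' @param panel Probe panel the signatures are expressed on
#'   (default [azf_panel()]).
#' @return A validated catalogue tibble.
#' @examples
#' cat24 <- azf_catalogue()
#' table(cat24$category)
#' @export
azf_catalogue <- function(panel = azf_panel()) {
  # family-level copy numbers per class; omitted families sit at baseline
  cls <- function(class_id, category, scope, copies, daz = c(NA, NA),
                  sts_absent = character(), classical = FALSE, novel = FALSE,
                  digest_needed = FALSE) {
    tibble(
      class_id = class_id, category = category,
      region_scope = list(scope), classical = classical, novel = novel,
      digest_needed = digest_needed,
      daz12 = as.integer(daz[1]), daz34 = as.integer(daz[2]),
      family_copies = list(copies), sts_absent = list(sts_absent)
    )
  }
  azfb0 <- c(RBMY1J = 0, RBMY1 = 0, PRY = 0, EIF1AY = 0, KDM5D = 0, HSFY = 0)
  azfc0 <- c(DAZ = 0, BPY2 = 0, CDY1 = 0, GOLGA2LY = 0, CSPG4LY = 0,
             TTTY4 = 0, TTTY17 = 0, TTTY3 = 0)
  azfc_sts <- c("sY254", "sY255", "sY1192", "sY1191", "sY1291", "sY1189")
  defs <- bind_rows(
    ## -- deletions (8) ----------------------------------------------------
    cls("b2/b4 del", "deletion", "AZFc", azfc0, daz = c(0, 0),
        sts_absent = azfc_sts, classical = TRUE),
    cls("gr/gr del", "deletion", "AZFc",
        c(DAZ = 2, CDY1 = 1, BPY2 = 2, GOLGA2LY = 1, TTTY4 = 2),
        daz = c(0, 2), sts_absent = "sY1291"),
    cls("b2/b3 del", "deletion", "AZFc",
        c(DAZ = 2, CDY1 = 1, BPY2 = 2, CSPG4LY = 1, TTTY17 = 2, TTTY3 = 1),
        daz = c(2, 0), sts_absent = "sY1191"),
    cls("b1/b3 del", "deletion", "AZFc",
        c(DAZ = 2, CDY1 = 1, BPY2 = 1, GOLGA2LY = 1, CSPG4LY = 1,
          TTTY4 = 1, TTTY17 = 1, TTTY3 = 1),
        daz = c(2, 0), sts_absent = c("sY1191", "sY1291")),
    cls("AZFb del", "deletion", "AZFb", azfb0,
        sts_absent = c("sY127", "sY134"), classical = TRUE),
    cls("RBMY1J del", "deletion", "AZFb", c(RBMY1J = 0), novel = TRUE),
    cls("AZFa del", "deletion", "AZFa", c(USP9Y = 0, DDX3Y = 0),
        sts_absent = c("sY84", "sY86"), classical = TRUE),
    cls("AZFb + c del", "deletion", c("AZFb", "AZFc"), c(azfb0, azfc0),
        daz = c(0, 0), sts_absent = c("sY127", "sY134", azfc_sts),
        classical = TRUE),
    ## -- duplications (11) ------------------------------------------------
    cls("b2/b4 dup", "duplication", "AZFc",
        c(DAZ = 8, BPY2 = 6, CDY1 = 4, GOLGA2LY = 4, CSPG4LY = 4,
          TTTY4 = 6, TTTY17 = 6, TTTY3 = 4), daz = c(4, 4)),
    cls("gr/gr dup", "duplication", "AZFc",
        c(DAZ = 6, CDY1 = 3, BPY2 = 4, GOLGA2LY = 3, TTTY4 = 4),
        daz = c(4, 2)),
    cls("b2/b3 dup", "duplication", "AZFc",
        c(DAZ = 6, CDY1 = 3, BPY2 = 4, CSPG4LY = 3, TTTY17 = 4, TTTY3 = 3),
        daz = c(4, 2)),
    cls("b2/b3 trip", "duplication", "AZFc",
        c(DAZ = 8, CDY1 = 4, BPY2 = 5, CSPG4LY = 4, TTTY17 = 5, TTTY3 = 4),
        daz = c(6, 2)),
    cls("BPY2 partial dup-Type I", "duplication", "AZFc", c(BPY2 = 4),
        daz = c(2, 2), novel = TRUE),
    cls("BPY2 partial dup-Type II", "duplication", "AZFc", c(BPY2 = 5),
        daz = c(2, 2), novel = TRUE),
    cls("Type I + gr/gr dup", "duplication", "AZFc",
        c(DAZ = 6, CDY1 = 3, BPY2 = 6, GOLGA2LY = 3, TTTY4 = 4),
        daz = c(4, 2), novel = TRUE),
    cls("b2/b4 dup + gr/gr dup", "duplication", "AZFc",
        c(DAZ = 10, CDY1 = 5, BPY2 = 7, GOLGA2LY = 5, CSPG4LY = 4,
          TTTY4 = 7, TTTY17 = 6, TTTY3 = 4), daz = c(6, 4), novel = TRUE),
    cls("RBMY1J dup", "duplication", "AZFb", c(RBMY1J = 2), novel = TRUE),
    cls("AZFa partial dup Type I", "duplication", "AZFa", c(USP9Y = 2),
        novel = TRUE),
    cls("AZFa partial dup Type II", "duplication", "AZFa",
        c(USP9Y = 2, DDX3Y = 2), novel = TRUE),
    ## -- complex deletion + duplication (5) -------------------------------
    cls("b2/b3 del + DAZ1/2 dup", "complex", "AZFc",
        c(DAZ = 4, CDY1 = 1, BPY2 = 2, CSPG4LY = 1, TTTY17 = 2, TTTY3 = 1),
        daz = c(4, 0), sts_absent = "sY1191", digest_needed = TRUE),
    cls("b2/b3 del + gr/gr dup", "complex", "AZFc",
        c(DAZ = 4, CDY1 = 2, BPY2 = 3, GOLGA2LY = 3, CSPG4LY = 1,
          TTTY4 = 4, TTTY17 = 2, TTTY3 = 1),
        daz = c(4, 0), sts_absent = "sY1191", novel = TRUE),
    cls("b2/b3 del + gr/gr trip", "complex", "AZFc",
        c(DAZ = 6, CDY1 = 3, BPY2 = 4, GOLGA2LY = 4, CSPG4LY = 1,
          TTTY4 = 5, TTTY17 = 2, TTTY3 = 1),
        daz = c(6, 0), sts_absent = "sY1191", novel = TRUE),
    cls("two gr/gr dels + b2/b4 dup", "complex", "AZFc",
        c(DAZ = 0, CDY1 = 0, BPY2 = 2, GOLGA2LY = 0, CSPG4LY = 4,
          TTTY4 = 2, TTTY17 = 6, TTTY3 = 4),
        daz = c(0, 0), sts_absent = "sY1291"),
    cls("gr/gr del + b2/b3 trip", "complex", "AZFc",
        c(DAZ = 6, CDY1 = 3, BPY2 = 4, GOLGA2LY = 1, CSPG4LY = 4,
          TTTY4 = 2, TTTY17 = 5, TTTY3 = 4),
        daz = c(4, 2), sts_absent = "sY1291", novel = TRUE)
  )
  markers <- sts_markers()$marker
  fams <- panel_families(panel)
  probes <- panel |> filter(!.data$is_reference)
  defs |>
    mutate(
      signature = map(.data$family_copies, function(fc) {
        unknown <- setdiff(names(fc), fams$target_locus)
        if (length(unknown) > 0)
          validation_error("signature", paste("unknown target locus:", toString(unknown)))
        copies <- setNames(fams$baseline_copies, fams$target_locus)
        copies[names(fc)] <- fc
        setNames(as.integer(copies[probes$target_locus]), probes$probe_id)
      }),
      sts = map(.data$sts_absent, function(ab) {
        setNames(as.integer(markers %not_in% ab), markers)
      })
    ) |>
    select(-"family_copies", -"sts_absent") |>
    validate_cnv_catalogue(panel = panel)
}

#' Validate a CNV-catalogue tibble
#'
#' Enforces the category invariants: a deletion class never raises a probe
#' above its baseline, a duplication class never lowers one (and its STS
#' pattern is all-present), and a complex class has at least one probe
#' below baseline and either one above or a DAZ-subset effect.  Every
#' signature must cover exactly the panel's non-reference probes.
#'
#' @param catalogue A catalogue tibble (see [azf_catalogue()]).
#' @param panel The probe panel the signatures refer to.
#' @return The validated catalogue.
#' @export
validate_cnv_catalogue <- function(catalogue, panel = azf_panel()) {
  catalogue <- as_tibble(catalogue)
  if (nrow(catalogue) == 0) return(catalogue)
  if (anyDuplicated(catalogue$class_id))
    validation_error("class_id", "duplicated class names")
  probes <- panel |> filter(!.data$is_reference)
  baseline <- setNames(probes$baseline_copies, probes$probe_id)
  for (i in seq_len(nrow(catalogue))) {
    sig <- catalogue$signature[[i]]
    id <- catalogue$class_id[i]
    unknown <- setdiff(names(sig), names(baseline))
    if (length(unknown) > 0)
      validation_error("signature", sprintf(
        "class '%s' references unknown probes: %s", id, toString(unknown)))
    if (!setequal(names(sig), names(baseline)))
      validation_error("signature", sprintf(
        "class '%s' must cover every non-reference probe", id))
    if (any(sig < 0))
      validation_error("signature", sprintf("class '%s' has negative copies", id))
    delta <- sig - baseline[names(sig)]
    cat_i <- catalogue$category[i]
    daz_effect <- !is.na(catalogue$daz12[i]) && !is.na(catalogue$daz34[i]) &&
      (catalogue$daz12[i] != catalogue$daz34[i])
    if (cat_i == "deletion" && any(delta > 0))
      validation_error("signature", sprintf(
        "deletion class '%s' raises a probe above baseline", id))
    if (cat_i == "duplication") {
      if (any(delta < 0))
        validation_error("signature", sprintf(
          "duplication class '%s' lowers a probe below baseline", id))
      if (any(catalogue$sts[[i]] == 0))
        validation_error("sts_pattern", sprintf(
          "duplication class '%s' must have an all-present STS pattern", id))
    }
    if (cat_i == "complex" &&
        (!any(delta < 0) || !(any(delta > 0) || daz_effect)))
      validation_error("signature", sprintf(
        "complex class '%s' needs a deleted probe and a duplicated probe or DAZ-subset effect", id))
    if (cat_i %not_in% c("deletion", "duplication", "complex"))
      validation_error("category", sprintf("class '%s': unknown category", id))
    sts <- catalogue$sts[[i]]
    if (!setequal(names(sts), sts_markers()$marker))
      validation_error("sts_pattern", sprintf(
        "class '%s' must define all ten EAA/EMQN markers", id))
  }
  catalogue
}

#' Count catalogue classes by category
#'
#' @param catalogue A catalogue tibble.
#' @return A tibble with one row per category (`deletion`, `duplication`,
#'   `complex`) and the number of classes, zero-filled.
#' @export
catalogue_counts <- function(catalogue) {
  tibble(category = c("deletion", "duplication", "complex")) |>
    left_join(count(catalogue, .data$category), by = "category") |>
    mutate(n = coalesce(.data$n, 0L))
}

#' Read or write a CNV-catalogue definition file
#'
#' Catalogues are stored as JSON: an array of class objects with the
#' per-probe `signature` map, the `sts_pattern` map over the ten EAA/EMQN
#' markers, the optional `daz_subset` map, and the category flags.
#' `write_cnv_catalogue()` followed by `read_cnv_catalogue()` round-trips
#' the catalogue exactly.
#'
#' @param path Path to the catalogue JSON file.
#' @param panel Panel used to validate probe references.
#' @return `read_cnv_catalogue()` returns a validated catalogue tibble.
#' @export
read_cnv_catalogue <- function(path, panel = azf_panel()) {
  if (!file.exists(path)) abort(paste("catalogue file not found:", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (length(raw) == 0) {
    return(tibble(
      class_id = character(), category = character(),
      region_scope = list(), classical = logical(), novel = logical(),
      digest_needed = logical(), daz12 = integer(), daz34 = integer(),
      signature = list(), sts = list()
    ))
  }
  catalogue <- map(raw, function(x) {
    daz <- x$daz_subset %||% list(`DAZ1/2` = NA, `DAZ3/4` = NA)
    tibble(
      class_id = x$class_id, category = x$category,
      region_scope = list(unlist(x$region_scope)),
      classical = isTRUE(x$classical), novel = isTRUE(x$novel),
      digest_needed = isTRUE(x$digest_needed),
      daz12 = as.integer(daz[["DAZ1/2"]]), daz34 = as.integer(daz[["DAZ3/4"]]),
      signature = list(vapply(x$signature, function(v) as.integer(v), integer(1))),
      sts = list(vapply(x$sts_pattern, function(v) as.integer(v), integer(1)))
    )
  }) |> bind_rows()
  validate_cnv_catalogue(catalogue, panel = panel)
}

#' @param catalogue A catalogue tibble.
#' @rdname read_cnv_catalogue
#' @export
write_cnv_catalogue <- function(catalogue, path) {
  out <- map(seq_len(nrow(catalogue)), function(i) {
    x <- list(
      class_id = catalogue$class_id[i],
      category = catalogue$category[i],
      region_scope = as.list(catalogue$region_scope[[i]]),
      classical = catalogue$classical[i],
      novel = catalogue$novel[i],
      digest_needed = catalogue$digest_needed[i],
      signature = as.list(catalogue$signature[[i]]),
      sts_pattern = as.list(catalogue$sts[[i]])
    )
    if (!is.na(catalogue$daz12[i]))
      x$daz_subset <- list(`DAZ1/2` = catalogue$daz12[i],
                           `DAZ3/4` = catalogue$daz34[i])
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Check that catalogue classes are mutually distinguishable
#'
#' Compares every pair of classes on their probe signature and DAZ-subset
#' split.  Pairs with identical signatures and identical splits are
#' `indistinguishable`; pairs with identical signatures that differ only in
#' the DAZ1/2 vs DAZ3/4 split are `digest_dependent` (they can only be told
#' apart by the sY587 restriction digest).  Report-only: no error is raised.
#'
#' @param catalogue A catalogue tibble.
#' @param panel The probe panel (unused beyond validation; kept so reports
#'   can be regenerated from files alone).
#' @return A tibble `class_a`, `class_b`, `status` holding only the flagged
#'   pairs, with attribute `n_pairs_checked`.
#' @export
catalogue_consistency <- function(catalogue, panel = azf_panel()) {
  n <- nrow(catalogue)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        same_sig <- identical(
          unname(catalogue$signature[[i]][sort(names(catalogue$signature[[i]]))]),
          unname(catalogue$signature[[j]][sort(names(catalogue$signature[[j]]))]))
        if (!same_sig) next
        same_daz <- identical(c(catalogue$daz12[i], catalogue$daz34[i]),
                              c(catalogue$daz12[j], catalogue$daz34[j]))
        out[[length(out) + 1]] <- tibble(
          class_a = catalogue$class_id[i],
          class_b = catalogue$class_id[j],
          status = if (same_daz) "indistinguishable" else "digest_dependent"
        )
      }
    }
  }
  res <- if (length(out) > 0) bind_rows(out) else
    tibble(class_a = character(), class_b = character(), status = character())
  attr(res, "n_pairs_checked") <- if (n >= 2) n * (n - 1) / 2 else 0
  res
}
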