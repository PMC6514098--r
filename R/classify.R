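#' Classify samples into catalogue CNV classes
#'
#' Matches each sample's per-probe calls against every catalogue class.
#' Matching works at the target-locus (family) level: the observed family
#' dosage is the mean relative peak area over the family's probes, and a
#' class is *compatible* with a sample when every family's observed dosage
#' lies within a band around the class's expected dosage (half a copy or 20
#' percent of the expected ratio, whichever is wider -- multicopy families
#' get the relative band, single-copy families the half-copy band).  Among
#' compatible classes (the copy-normal state counts as one) the class with
#' the smallest probe-count-weighted squared dosage distance is assigned.
#'
#' Sentinels: an all-baseline sample is `NO_CNV`; a sample no class is
#' compatible with is `UNCLASSIFIED` (candidates ranked by per-family state
#' agreement are listed); distance ties are `AMBIGUOUS` unless a provided
#' sY587 digest resolves them.  Classes whose definition asserts a specific
#' DAZ1/2 vs DAZ3/4 composition carry `digest_needed = TRUE`; when a digest
#' table is supplied their band-intensity split is checked against the
#' class (`digest_consistent`), otherwise the dosage-equivalent class is
#' reported with `digest_needed = TRUE` and `digest_consistent = NA`.
#'
#' @param calls An `azf_calls` tibble from [call_samples()].
#' @param panel Probe panel the calls were made on.
#' @param catalogue CNV catalogue (default [azf_catalogue()]).
#' @param digest Optional sY587 digest tibble with columns `sample_id`,
#'   `intensity_daz12`, `intensity_daz34`.
#' @param config Calling configuration (supplies the state threshold used
#'   in candidate scoring).
#' @return A tibble of class `azf_classification`: `sample_id`,
#'   `assigned_class`, `category`, `matched_probes`, `n_candidates`,
#'   `digest_needed`, `digest_consistent` and a `candidates` list column of
#'   per-class scores.
#' @export
classify_samples <- function(calls, panel, catalogue = azf_catalogue(panel),
                             digest = NULL, config = calling_config()) {
  unknown <- setdiff(unique(calls$probe_id), panel$probe_id)
  if (length(unknown) > 0)
    abort(paste("calls reference unknown probes:", toString(head(unknown, 5))))
  fams <- panel_families(panel)
  n_fam <- nrow(fams)
  probe_fam <- setNames(panel$target_locus, panel$probe_id)

  obs <- calls |>
    filter(!.data$is_reference) |>
    group_by(.data$sample_id, target_locus = .data$target_locus) |>
    summarise(mean_ratio = mean(.data$ratio), .groups = "drop")
  sample_ids <- unique(calls$sample_id)
  if (length(sample_ids) == 0) {
    return(empty_classification())
  }
  M <- matrix(NA_real_, length(sample_ids), n_fam,
              dimnames = list(sample_ids, fams$target_locus))
  M[cbind(match(obs$sample_id, sample_ids),
          match(obs$target_locus, fams$target_locus))] <- obs$mean_ratio
  if (any(is.na(M)))
    abort("calls must cover every non-reference panel probe for every sample")

  # expected family dosage per class (+ copy-normal pseudo-class), copies/baseline
  class_ids <- c(catalogue$class_id, "NO_CNV")
  first_probe <- vapply(split(panel$probe_id[!panel$is_reference],
                              probe_fam[panel$probe_id[!panel$is_reference]]),
                        `[`, character(1), 1)[fams$target_locus]
  C <- rbind(
    do.call(rbind, map(catalogue$signature, function(sig) unname(sig[first_probe]))),
    fams$baseline_copies
  )
  if (nrow(catalogue) == 0) C <- matrix(fams$baseline_copies, 1)
  E <- sweep(C, 2, fams$baseline_copies, "/")
  band <- pmax(matrix(rep(0.5 / fams$baseline_copies, each = nrow(E)), nrow(E)),
               0.2 * E)
  w <- fams$n_probes

  exp_state <- state_of(E, config$delta)          # classes x families
  daz_col <- match("DAZ", fams$target_locus)

  digest <- if (!is.null(digest)) as_tibble(digest) else NULL
  res <- map(seq_along(sample_ids), function(s) {
    m <- M[s, ]
    obs_state <- state_of(m, config$delta)
    dist <- colSums(w * (t(E) - m)^2)
    score <- colSums(w * (t(exp_state) == obs_state))
    compatible <- apply(abs(t(E) - m) <= t(band), 2, all)
    cand <- tibble(class_id = class_ids, distance = unname(dist),
                   score = unname(score), compatible = unname(compatible))
    dg <- NULL
    if (!is.null(digest) && sample_ids[s] %in% digest$sample_id)
      dg <- digest[match(sample_ids[s], digest$sample_id), ]

    if (!any(compatible)) {
      top <- cand |> arrange(desc(.data$score), .data$distance) |> head(3)
      return(classification_row(sample_ids[s], "UNCLASSIFIED", NA_character_,
                                max(score), nrow(top), FALSE, NA, top))
    }
    comp <- cand |> filter(.data$compatible) |> arrange(.data$distance)
    tied <- comp |> filter(.data$distance <= comp$distance[1] + 1e-9)
    pick <- NULL
    if (nrow(tied) == 1) {
      pick <- tied$class_id[1]
    } else {
      # try digest disambiguation among distance-tied candidates
      if (!is.null(dg) && !is.na(daz_col)) {
        total <- as.integer(round_half_away(m[daz_col] * fams$baseline_copies[daz_col]))
        split <- resolve_daz_subsets(dg$intensity_daz12, dg$intensity_daz34, total)
        hits <- tied$class_id[vapply(tied$class_id, function(id) {
          i <- match(id, catalogue$class_id)
          !is.na(i) && !is.na(catalogue$daz12[i]) &&
            catalogue$daz12[i] == split$copies_daz12 &&
            catalogue$daz34[i] == split$copies_daz34
        }, logical(1))]
        if (length(hits) == 1) pick <- hits
      }
      if (is.null(pick))
        return(classification_row(sample_ids[s], "AMBIGUOUS", NA_character_,
                                  max(tied$score), nrow(tied), FALSE, NA, tied))
    }
    i <- match(pick, catalogue$class_id)
    needs <- !is.na(i) && catalogue$digest_needed[i]
    consistent <- NA
    if (!is.na(i) && !is.null(dg) && !is.na(catalogue$daz12[i]) && !is.na(daz_col)) {
      total <- as.integer(round_half_away(m[daz_col] * fams$baseline_copies[daz_col]))
      if (total > 0 || dg$intensity_daz12 + dg$intensity_daz34 > 0) {
        split <- resolve_daz_subsets(dg$intensity_daz12, dg$intensity_daz34, total)
        consistent <- split$copies_daz12 == catalogue$daz12[i] &&
          split$copies_daz34 == catalogue$daz34[i]
      }
    }
    classification_row(
      sample_ids[s],
      if (pick == "NO_CNV") "NO_CNV" else pick,
      if (is.na(i)) NA_character_ else catalogue$category[i],
      cand$score[match(pick, cand$class_id)],
      nrow(tied), needs, consistent, comp
    )
  }) |> bind_rows()
  class(res) <- c("azf_classification", class(res))
  res
}

# dosage ratio -> state code matrix/vector (1 deleted, 2 normal, 3 duplicated)
state_of <- function(r, delta) {
  s <- matrix(2L, nrow = NROW(r), ncol = NCOL(r))
  s[r <= 1 - delta] <- 1L
  s[r >= 1 + delta] <- 3L
  if (is.matrix(r)) s else as.vector(s)
}

classification_row <- function(sample_id, assigned, category, matched,
                               n_candidates, digest_needed, digest_consistent,
                               candidates) {
  tibble(
    sample_id = sample_id, assigned_class = assigned, category = category,
    matched_probes = as.integer(matched), n_candidates = as.integer(n_candidates),
    digest_needed = digest_needed, digest_consistent = digest_consistent,
    candidates = list(candidates |> select(any_of(c("class_id", "distance", "score"))))
  )
}

empty_classification <- function() {
  res <- tibble(
    sample_id = character(), assigned_class = character(),
    category = character(), matched_probes = integer(),
    n_candidates = integer(), digest_needed = logical(),
    digest_consistent = logical(), candidates = list()
  )
  class(res) <- c("azf_classification", class(res))
  res
}

#' Split total DAZ copies into DAZ1/2 and DAZ3/4 subsets
#'
#' Allocates the total DAZ copy number to the two doublets in proportion to
#' the sY587 digest band intensities, rounding to integers that sum to the
#' total by the largest-remainder rule (ties favor DAZ1/2).
#'
#' @param intensity_daz12,intensity_daz34 Non-negative band intensities of
#'   the sY587 allele carried by each doublet.
#' @param total_copies Total DAZ copies to allocate (integer, `>= 0`).
#' @return A tibble `copies_daz12`, `copies_daz34`.
#' @examples
#' resolve_daz_subsets(1, 1, 4) # 2 and 2
#' resolve_daz_subsets(2, 1, 6) # 4 and 2
#' @export
resolve_daz_subsets <- function(intensity_daz12, intensity_daz34, total_copies) {
  n <- max(length(intensity_daz12), length(intensity_daz34), length(total_copies))
  i12 <- rep_len(intensity_daz12, n); i34 <- rep_len(intensity_daz34, n)
  tot <- rep_len(as.integer(total_copies), n)
  if (any(i12 < 0) || any(i34 < 0))
    validation_error("intensity", "band intensities must be >= 0")
  if (any(tot < 0)) validation_error("total_copies", "must be >= 0")
  if (any(i12 + i34 == 0 & tot > 0))
    abort("both sY587 band intensities are zero for a sample with DAZ copies")
  share12 <- ifelse(tot == 0, 0, tot * i12 / (i12 + i34))
  share34 <- ifelse(tot == 0, 0, tot * i34 / (i12 + i34))
  c12 <- floor(share12); c34 <- floor(share34)
  left <- tot - c12 - c34
  give12 <- left > 0 & (share12 - c12 >= share34 - c34)
  c12 <- c12 + left * give12
  c34 <- c34 + left * (!give12)
  tibble(copies_daz12 = as.integer(c12), copies_daz34 = as.integer(c34))
}

#' De novo status of a proband's CNV against the father
#'
#' @param proband_class,father_class Assigned classes (as from
#'   [classify_samples()]); vectors are recycled to common length.
#' @return Character vector: `"de_novo"` when the proband carries a class
#'   the father does not (father copy-normal or a different class),
#'   `"inherited"` when both carry the identical class, `"indeterminate"`
#'   when either sample is UNCLASSIFIED/AMBIGUOUS or the proband carries no
#'   CNV.
#' @export
inheritance_status <- function(proband_class, father_class) {
  n <- max(length(proband_class), length(father_class))
  p <- rep_len(proband_class, n); f <- rep_len(father_class, n)
  dplyr::case_when(
    p %in% c("UNCLASSIFIED", "AMBIGUOUS") |
      f %in% c("UNCLASSIFIED", "AMBIGUOUS") ~ "indeterminate",
    p == "NO_CNV" ~ "indeterminate",
    p == f ~ "inherited",
    .default = "de_novo"
  )
}

#' Write a classification report as TSV
#'
#' Columns `sample_id assigned_class digest_needed digest_consistent
#' candidates` (candidates rendered as a comma-separated ranked list).
#'
#' @param classification An `azf_classification` tibble.
#' @param path Output path.
#' @export
write_classification <- function(classification, path) {
  classification |>
    mutate(candidates = map_chr(.data$candidates, function(x)
      paste(x$class_id, collapse = ","))) |>
    select("sample_id", "assigned_class", "digest_needed",
           "digest_consistent", "candidates") |>
    readr::write_tsv(path, na = "NA")
  invisible(path)
}
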