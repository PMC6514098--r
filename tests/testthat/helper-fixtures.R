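# Shared in-code fixtures; everything is built at test time, nothing binary.

default_panel <- azf_panel()
default_catalogue <- azf_catalogue(default_panel)

# minimal panel: one AZF probe plus two reference probes
mini_panel <- function() {
  tibble::tibble(
    probe_id = c("DAZ_A", "REF_1", "REF_2"),
    target_locus = c("DAZ", "R1", "R2"),
    region = c("AZFc", "reference", "reference"),
    position_bp = c(23200000L, NA, NA),
    baseline_copies = c(4L, 2L, 2L),
    is_reference = c(FALSE, TRUE, TRUE)
  )
}

# simulate a batch of carriers of one class (or NO_CNV) and classify them
simulate_class_cohort <- function(class_id, n, sigma_area, seed,
                                  panel = default_panel,
                                  catalogue = default_catalogue) {
  counts <- azf_class_counts()
  counts$control <- 0L
  counts$azoospermia <- 0L
  counts$oligozoospermia <- 0L
  if (class_id != "NO_CNV")
    counts$control[counts$class_id == class_id] <- as.integer(n)
  cfg <- simulation_config(seed = seed, n_control = n, n_azoospermia = 0,
                           n_oligozoospermia = 0, class_counts = counts,
                           sigma_area = sigma_area)
  simulate_cohort(cfg, panel, catalogue)
}

# exact-frequency noise-free default cohort (shared by several test files)
exact_cohort <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- simulate_cohort(
        simulation_config(seed = 20240101, sigma_area = 0),
        default_panel, default_catalogue)
    cached
  }
})

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins from factorial first principles (independent of dhyper)
fisher_enumerate <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  logp <- vapply(support, function(x) {
    lfactorial(m1) - lfactorial(x) - lfactorial(m1 - x) +
      lfactorial(m2) - lfactorial(k - x) - lfactorial(m2 - (k - x)) -
      (lfactorial(m1 + m2) - lfactorial(k) - lfactorial(m1 + m2 - k))
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[match(a, support)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
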