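#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_int map_lgl map2 pmap imap
#' @importFrom stats rnorm rbinom sd setNames dhyper pchisq qnorm t.test
#'   chisq.test complete.cases
#' @importFrom utils head modifyList
NULL

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop with a field-naming validation error
validation_error <- function(field, msg) {
  abort(sprintf("invalid %s: %s", field, msg), class = "azfcnv_validation_error")
}

`%not_in%` <- function(x, table) !(x %in% table)

# run code with a locally seeded RNG, restoring any prior RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stream-specific child seed, kept inside 32-bit integer range
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483647
}
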