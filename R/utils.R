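#' @importFrom rlang %||% abort
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr across all_of bind_rows count group_by left_join mutate
#'   summarise ungroup
NULL

# The six social-media-based hospital service quality factors.
FACTOR_NAMES <- c("service", "professionalism", "process", "environment",
                  "impression", "popularity")

# Factors whose subcategories are functional (f1-f29); the remaining two
# (impression, popularity) carry emotional codes e1-e10.
FUNCTIONAL_FACTORS <- c("service", "professionalism", "process", "environment")

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), matching
#' the presentation convention used for the percentage tables in this package.
#' Base [round()] uses round-half-even, which disagrees on exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(76.5)   # 77
#' round_half_up(35.8607, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stop with a classed usage/validation error.
hm_abort <- function(msg, class = "hospmine_error") {
  abort(msg, class = class)
}
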