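#' Intent classes and their workspace directions
#'
#' Nine movement intents are used throughout the pipeline: code 0 is rest and
#' codes 1--8 are isometric/planar movement directions spaced 45 degrees apart
#' and arranged clockwise, with code 3 pointing along +x ("right").  Under this
#' convention code 1 points along +y, code 5 along -y and code 7 along -x.
#'
#' @return A tibble with one row per intent code and columns `code` (integer
#'   0--8), `angle` (direction angle in radians, `NA` for rest) and `dx`, `dy`
#'   (unit direction components, 0 for rest).
#' @examples
#' intent_directions()
#' @export
intent_directions <- function() {
  code <- 0:8
  angle <- c(NA_real_, (pi / 2) - (0:7) * (pi / 4))
  dx <- ifelse(is.na(angle), 0, cos(angle))
  dy <- ifelse(is.na(angle), 0, sin(angle))
  # snap values that are exactly on the axes to +-1/0
  dx <- round(dx, 12)
  dy <- round(dy, 12)
  tibble::tibble(code = as.integer(code), angle = angle, dx = dx, dy = dy)
}

#' Unit direction vector of an intent code
#'
#' @param code Integer intent code in 0--8.
#' @return Numeric length-2 vector `(dx, dy)`; `(0, 0)` for rest.
#' @export
intent_direction <- function(code) {
  if (length(code) != 1 || is.na(code) || !code %in% 0:8) {
    rlang::abort("`code` must be a single intent code in 0..8.")
  }
  dirs <- intent_directions()
  row <- dirs[dirs$code == as.integer(code), ]
  c(row$dx, row$dy)
}

#' Map a planar direction to the nearest intent code
#'
#' Picks the code among 1--8 whose direction maximizes the dot product with
#' `v`; ties are broken toward the lowest code.  The quantization error between
#' `v` and the chosen direction is at most 22.5 degrees (half the 45-degree
#' sector width).
#'
#' @param v Numeric length-2 direction vector (need not be unit length).
#' @return Integer intent code in 1--8.
#' @export
nearest_intent <- function(v) {
  stopifnot(is.numeric(v), length(v) == 2)
  n <- sqrt(sum(v^2))
  if (n == 0) rlang::abort("Cannot quantize a zero direction vector.")
  dirs <- intent_directions()
  active <- dirs[dirs$code > 0, ]
  dots <- active$dx * v[1] + active$dy * v[2]
  as.integer(active$code[which.max(dots)])
}
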