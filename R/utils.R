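#' @keywords internal
#' @noRd
abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "airtrapcad_error")))
}

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 83.75 -> 83.8), matching
#' the usual presentation of diagnostic percentages.  Base `round()` rounds
#' half to even, which would print 83.7 here.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Bilinear interpolation of matrix `field` at real-valued (row, col)
# positions; positions are clamped to the matrix extent.
#' @noRd
bilinear <- function(field, r, c) {
  nr <- nrow(field)
  nc <- ncol(field)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0
  fc <- c - c0
  f00 <- field[cbind(r0, c0)]
  f10 <- field[cbind(r0 + 1L, c0)]
  f01 <- field[cbind(r0, c0 + 1L)]
  f11 <- field[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * f00 + fr * (1 - fc) * f10 +
    (1 - fr) * fc * f01 + fr * fc * f11
}

# Evaluate an expression with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
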