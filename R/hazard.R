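#' Division hazards: sharp and soft thresholds
#'
#' The baseline model fires division exactly when the protein count reaches
#' X (a sharp threshold); the adder property holds if and only if the
#' threshold is sharp. The soft alternative replaces it by a finite,
#' monotonically increasing division propensity \eqn{h(x) = c (x/X)^H} for
#' \eqn{x \ge 1} (and 0 at x = 0), the simplest monotone family that
#' converges pointwise to the sharp threshold as the steepness H grows.
#'
#' @param X threshold (positive integer).
#' @param H steepness exponent (> 0; soft hazard only).
#' @param c propensity scale at x = X, per unit time (soft hazard only).
#' @return an object of class \code{division_hazard}.
#' @examples
#' division_hazard(hazard_sharp(65), 64:66)
#' division_hazard(hazard_soft(65, H = 4, c = 1), c(0, 32, 65))
#' @export
hazard_sharp <- function(X) {
  if (X < 1 || X != round(X)) stop("'X' must be a positive integer")
  structure(list(kind = "sharp", X = as.integer(X)), class = "division_hazard")
}

#' @rdname hazard_sharp
#' @export
hazard_soft <- function(X, H = 4, c = 1) {
  if (X < 1 || X != round(X)) stop("'X' must be a positive integer")
  if (H <= 0) stop("'H' must be positive")
  if (c <= 0) stop("'c' must be positive")
  structure(list(kind = "soft", X = as.integer(X), H = H, c = c),
            class = "division_hazard")
}

#' @rdname hazard_sharp
#' @param h_spec a \code{division_hazard}.
#' @param x protein count(s); non-negative integer(s).
#' @return division propensity per unit time; \code{Inf} signals immediate
#'   division (sharp hazard at or above X).
#' @export
division_hazard <- function(h_spec, x) {
  if (!inherits(h_spec, "division_hazard")) stop("'h_spec' must be a division_hazard")
  if (any(x < 0) || any(x != round(x))) stop("'x' must be non-negative integers")
  if (h_spec$kind == "sharp") {
    ifelse(x >= h_spec$X, Inf, 0)
  } else {
    ifelse(x == 0, 0, h_spec$c * (x / h_spec$X)^h_spec$H)
  }
}
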