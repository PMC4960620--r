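#' Deviation mechanisms from the adder principle
#'
#' Four phenomenological modifications of the baseline model that break the
#' independence of the added volume from the newborn size:
#' \itemize{
#'   \item \code{partial_degradation}: a fraction \code{retention_kappa} of
#'     the final protein count survives division and is partitioned
#'     binomially between the daughters (negative added-volume vs newborn
#'     size correlation).
#'   \item \code{volume_dependent_burst}: the mean burst size scales with the
#'     instantaneous volume, \eqn{b(V) = b_0 V / V_{ref}} (negative
#'     correlation).
#'   \item \code{saturating_rate}: the burst arrival rate saturates at large
#'     volume, \eqn{r(V) = k_m V / (1 + V/V_{sat})} (positive correlation).
#'   \item \code{soft_threshold}: division fires through the finite hazard of
#'     \code{\link{hazard_soft}} instead of a sharp threshold (positive
#'     correlation).
#' }
#'
#' @param retention_kappa fraction of the division-time protein count
#'   retained (0..1).
#' @param V_ref reference volume at which the burst mean equals the law's
#'   own mean.
#' @param V_sat half-saturation volume (> 0).
#' @param H,c soft-threshold steepness and scale (see
#'   \code{\link{hazard_soft}}).
#' @return an object of class \code{mechanism_spec}.
#' @examples
#' mechanism_partial_degradation(0.5)
#' mechanism_saturating_rate(V_sat = 5)
#' @export
mechanism_baseline <- function() {
  structure(list(kind = "baseline"), class = "mechanism_spec")
}

#' @rdname mechanism_baseline
#' @export
mechanism_partial_degradation <- function(retention_kappa = 0.5) {
  if (retention_kappa < 0 || retention_kappa > 1)
    stop("'retention_kappa' must lie in [0, 1]")
  structure(list(kind = "partial_degradation", retention_kappa = retention_kappa),
            class = "mechanism_spec")
}

#' @rdname mechanism_baseline
#' @export
mechanism_volume_dependent_burst <- function(V_ref = 1) {
  if (V_ref <= 0) stop("'V_ref' must be positive")
  structure(list(kind = "volume_dependent_burst", V_ref = V_ref),
            class = "mechanism_spec")
}

#' @rdname mechanism_baseline
#' @export
mechanism_saturating_rate <- function(V_sat = 5) {
  if (V_sat <= 0) stop("'V_sat' must be positive")
  structure(list(kind = "saturating_rate", V_sat = V_sat),
            class = "mechanism_spec")
}

#' @rdname mechanism_baseline
#' @export
mechanism_soft_threshold <- function(H = 4, c = 1) {
  if (H <= 0 || c <= 0) stop("'H' and 'c' must be positive")
  structure(list(kind = "soft_threshold", H = H, c = c),
            class = "mechanism_spec")
}

#' @export
print.mechanism_spec <- function(x, ...) {
  extra <- switch(x$kind,
    baseline = "",
    partial_degradation = sprintf(" (kappa = %g)", x$retention_kappa),
    volume_dependent_burst = sprintf(" (V_ref = %g)", x$V_ref),
    saturating_rate = sprintf(" (V_sat = %g)", x$V_sat),
    soft_threshold = sprintf(" (H = %g, c = %g)", x$H, x$c))
  cat("Mechanism:", x$kind, extra, "\n", sep = "")
  invisible(x)
}

mechanism_kinds <- c("baseline", "partial_degradation",
                     "volume_dependent_burst", "saturating_rate",
                     "soft_threshold")

as_mechanism <- function(kind, args = list()) {
  kind <- match.arg(kind, mechanism_kinds)
  do.call(switch(kind,
                 baseline = mechanism_baseline,
                 partial_degradation = mechanism_partial_degradation,
                 volume_dependent_burst = mechanism_volume_dependent_burst,
                 saturating_rate = mechanism_saturating_rate,
                 soft_threshold = mechanism_soft_threshold),
          args)
}
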