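#' Model parameters for the timekeeper first-passage model
#'
#' A newborn cell of size \code{V_b} grows exponentially, \eqn{V(t) = V_b
#' e^{\alpha t}}. A timekeeper protein is expressed in stochastic bursts
#' arriving at rate \eqn{r(t) = k_m V(t)} (the volume-proportional rate that
#' keeps concentrations constant in a growing cell), and cell division fires
#' when the accumulated copy number first reaches the threshold \code{X}.
#'
#' @param k_m transcription (burst-arrival) rate in the concentration sense,
#'   per unit time per unit volume; > 0.
#' @param alpha exponential growth rate, per unit time; >= 0 (0 only as the
#'   homogeneous-Poisson limit).
#' @param burst a \code{\link{burst_geometric}} / \code{burst_law} object.
#' @param X division threshold in molecules; positive integer.
#' @param V_b newborn cell size (abstract size units; length and volume are
#'   proportional for rod-shaped cells at fixed width); > 0.
#' @return an object of class \code{model_params}.
#' @examples
#' p <- model_params(k_m = 0.13, alpha = 0.03, burst = burst_geometric(5),
#'                   X = 65, V_b = 1)
#' cumulative_rate(p, 10)
#' @export
model_params <- function(k_m, alpha, burst, X, V_b) {
  if (!is.numeric(k_m) || length(k_m) != 1L || !is.finite(k_m) || k_m <= 0)
    stop("'k_m' must be a positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("'alpha' must be a non-negative number")
  if (!inherits(burst, "burst_law")) stop("'burst' must be a burst_law object")
  if (!is.numeric(X) || length(X) != 1L || X < 1 || X != round(X))
    stop("'X' must be a positive integer")
  if (!is.numeric(V_b) || length(V_b) != 1L || !is.finite(V_b) || V_b <= 0)
    stop("'V_b' must be a positive number")
  structure(list(k_m = k_m, alpha = alpha, burst = burst,
                 X = as.integer(X), V_b = V_b),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Timekeeper FPT model: k_m = %g, alpha = %g, X = %d, V_b = %g\n",
              x$k_m, x$alpha, x$X, x$V_b))
  print(x$burst)
  invisible(x)
}

#' Cumulative burst-arrival rate R(t) and its inverse
#'
#' \eqn{R(t) = \int_0^t k_m V(s) ds = (k_m V_b/\alpha)(e^{\alpha t} - 1)}
#' is the expected number of burst arrivals by time \code{t}; it is the
#' time change mapping the inhomogeneous arrival process to a unit-rate
#' Poisson process. For \code{alpha = 0} it reduces to \eqn{k_m V_b t}.
#'
#' @param params a \code{\link{model_params}} object.
#' @param t time(s) since birth; >= 0.
#' @return expected arrival count(s), non-negative and increasing in t.
#' @export
cumulative_rate <- function(params, t) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (params$alpha == 0) params$k_m * params$V_b * t
  else (params$k_m * params$V_b / params$alpha) * expm1(params$alpha * t)
}

#' @rdname cumulative_rate
#' @param u expected arrival count(s); >= 0.
#' @return \code{inverse_cumulative_rate}: time(s) t with R(t) = u.
#' @export
inverse_cumulative_rate <- function(params, u) {
  if (any(u < 0)) stop("'u' must be non-negative")
  if (params$alpha == 0) u / (params$k_m * params$V_b)
  else log1p(params$alpha * u / (params$k_m * params$V_b)) / params$alpha
}
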