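#' Replication-initiation variant of the timekeeper model
#'
#' Instead of timing division directly, the timekeeper accumulates per origin
#' of replication: with theta origins the next initiation requires theta * X
#' molecules (origins fire synchronously), after which the timekeeper pool is
#' reset (degraded or deactivated) and the origin number doubles. Division
#' follows each initiation after the constant delay \eqn{T = C + D} and
#' halves both the cell size and the origin number; timekeeper partitioning
#' noise at division is neglected.
#'
#' @param base a \code{\link{model_params}} object (threshold X is the
#'   per-origin requirement).
#' @param theta initial number of origins of replication (>= 1).
#' @param T_CD constant initiation-to-division delay, same time units as
#'   1/alpha; >= 0.
#' @param origin_prefactor multiplicative prefactor applied to the analytic
#'   mean added volume between divisions (default 1).
#' @return an object of class \code{initiation_model_params}.
#' @examples
#' p <- model_params(0.13, 0.03, burst_geometric(5), 65, 1)
#' ip <- initiation_model_params(p, theta = 1, T_CD = 60)
#' initiation_mean_added_volume(ip)
#' @export
initiation_model_params <- function(base, theta = 1L, T_CD, origin_prefactor = 1) {
  if (!inherits(base, "model_params")) stop("'base' must be model_params")
  if (theta < 1 || theta != round(theta)) stop("'theta' must be a positive integer")
  if (T_CD < 0) stop("'T_CD' must be non-negative")
  structure(list(base = base, theta = as.integer(theta), T_CD = T_CD,
                 origin_prefactor = origin_prefactor),
            class = "initiation_model_params")
}

#' Mean added volume between divisions in the initiation model
#'
#' The per-origin volume added between consecutive initiation events has the
#' same mean as the baseline added volume; the constant initiation-to-
#' division delay inflates the division-to-division mean by \eqn{e^{\alpha
#' T}}: \eqn{\langle \Delta V^* \rangle = \langle \Delta V \rangle e^{\alpha
#' T_{CD}}}. Since the baseline mean is linear in \eqn{\alpha}, this is
#' linear in \eqn{\alpha} for small growth rates and exponential for large
#' ones.
#'
#' @param ip an \code{\link{initiation_model_params}} object.
#' @return the mean division-to-division added volume.
#' @export
initiation_mean_added_volume <- function(ip) {
  if (!inherits(ip, "initiation_model_params"))
    stop("'ip' must be initiation_model_params")
  av <- added_volume_distribution(ip$base)
  ip$origin_prefactor * deltaV_moments(av)$mean * exp(ip$base$alpha * ip$T_CD)
}

#' Exact simulation of the initiation-triggered model
#'
#' Event-driven and exact: burst waits are drawn by inverting the cumulative
#' arrival rate from the current state, and scheduled divisions interleave
#' with bursts. The per-origin timekeeper level gains B/theta per burst and
#' triggers initiation at X; the per-origin cell volume V/theta is continuous
#' across divisions (both halve) and halves at initiations (origin doubling),
#' so the per-origin added volume between initiations is the initiation-level
#' analogue of the baseline added volume.
#'
#' @param ip an \code{\link{initiation_model_params}} object.
#' @param n_cycles number of division-to-division cycles to record.
#' @param burn_in initial divisions discarded before recording.
#' @param max_pending maximum number of initiations awaiting their division;
#'   exceeding it (initiations outpacing divisions) raises an error.
#' @return list of class \code{initiation_sim} with \code{cycles} (columns
#'   \code{V_b}, \code{V_d}, \code{delta_V}, \code{fpt}, \code{generation})
#'   and \code{initiations} (per-initiation volume \code{V}, origin count
#'   \code{theta}, per-origin volume \code{w} and per-origin added volume
#'   \code{delta_per_origin}).
#' @export
sample_initiation_model <- function(ip, n_cycles, burn_in = 10L,
                                    max_pending = 64L) {
  if (!inherits(ip, "initiation_model_params"))
    stop("'ip' must be initiation_model_params")
  if (n_cycles < 1) stop("'n_cycles' must be >= 1")
  p <- ip$base
  if (p$alpha <= 0) stop("the simulator requires alpha > 0")
  n_div_target <- n_cycles + burn_in + 1L

  t <- 0; V <- p$V_b; theta <- ip$theta; y <- 0
  pending <- numeric(0)                      # scheduled division times
  div_t <- numeric(n_div_target); div_V <- numeric(n_div_target)  # pre-halving
  n_div <- 0L
  ini_w <- numeric(0); ini_V <- numeric(0); ini_theta <- integer(0)
  guard <- 0L
  while (n_div < n_div_target) {
    guard <- guard + 1L
    if (guard > 5e7L) stop("initiation simulation did not terminate")
    w_burst <- log1p(p$alpha * stats::rexp(1L) / (p$k_m * V)) / p$alpha
    t_next_div <- if (length(pending)) pending[1] else Inf
    if (t + w_burst < t_next_div) {
      t <- t + w_burst
      V <- V * exp(p$alpha * w_burst)
      y <- y + rburst(p$burst, 1L) / theta
      if (y >= p$X) {                        # initiation event
        ini_w <- c(ini_w, V / theta); ini_V <- c(ini_V, V)
        ini_theta <- c(ini_theta, theta)
        y <- 0
        theta <- theta * 2L
        pending <- c(pending, t + ip$T_CD)
        if (length(pending) > max_pending)
          stop("initiations outpaced divisions beyond the configured queue depth")
      }
    } else {                                 # division event
      V <- V * exp(p$alpha * (t_next_div - t))
      t <- t_next_div
      pending <- pending[-1]
      n_div <- n_div + 1L
      div_t[n_div] <- t; div_V[n_div] <- V
      V <- V / 2
      theta <- max(theta %/% 2L, 1L)
    }
  }
  keep <- (burn_in + 1L):(n_div_target - 1L)
  cycles <- data.frame(
    V_b = div_V[keep] / 2,
    V_d = div_V[keep + 1L],
    delta_V = div_V[keep + 1L] - div_V[keep] / 2,
    fpt = div_t[keep + 1L] - div_t[keep],
    generation = seq_along(keep))
  m <- length(ini_w)
  initiations <- data.frame(
    V = ini_V, theta = ini_theta, w = ini_w,
    delta_per_origin = c(ini_w[-1] - ini_w[-m] / 2, NA))
  if (burn_in > 0 && m > burn_in)
    initiations <- initiations[-seq_len(burn_in), ]
  structure(list(cycles = cycles, initiations = initiations, params = ip),
            class = "initiation_sim")
}
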