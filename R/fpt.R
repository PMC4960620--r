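#' First-passage-time (division-time) distribution
#'
#' Division time is the first-passage time (FPT) of the protein copy number
#' to the threshold X. Burst arrivals form an inhomogeneous Poisson process
#' with cumulative rate \code{\link{cumulative_rate}}; the time of the n-th
#' arrival, \eqn{T_n}, has density \eqn{r(t) R(t)^{n-1} e^{-R(t)}/(n-1)!},
#' and the FPT density is the mixture of these over the burst-count pmf
#' \eqn{P(N = n)}.
#'
#' @param params a \code{\link{model_params}} object.
#' @param tail_bound neglected mass allowed in the burst-count series
#'   truncation (default 1e-10).
#' @return object of class \code{fpt_distribution}.
#' @examples
#' p <- model_params(0.13, 0.03, burst_geometric(5), 65, 1)
#' d <- fpt_distribution(p)
#' fpt_pdf(d, 40)
#' fpt_moments(d)$mean
#' @export
fpt_distribution <- function(params, tail_bound = 1e-10) {
  if (!inherits(params, "model_params")) stop("'params' must be model_params")
  pmf <- burst_count_pmf(params$X, params$burst, tail_bound = tail_bound)
  structure(list(params = params, pmf = pmf, n_max = max(pmf$n),
                 tail_mass_bound = pmf$tail_mass),
            class = "fpt_distribution")
}

#' @export
print.fpt_distribution <- function(x, ...) {
  cat(sprintf("FPT distribution (mixture of %d arrival-time laws, tail %.2g)\n",
              length(x$pmf$n), x$tail_mass_bound))
  print(x$params)
  invisible(x)
}

#' @rdname fpt_distribution
#' @param dist an \code{fpt_distribution}.
#' @param t time(s) since birth; >= 0.
#' @export
fpt_pdf <- function(dist, t) {
  if (any(t < 0)) stop("'t' must be non-negative")
  p <- dist$params
  R <- cumulative_rate(p, t)
  log_r <- log(p$k_m * p$V_b) + p$alpha * t
  out <- numeric(length(t))
  # assembled in log space per mixture term: r(t) overflows in the far tail
  # while the Poisson weight underflows, and their product must stay finite
  for (i in seq_along(dist$pmf$n)) {
    lt <- log_r + stats::dpois(dist$pmf$n[i] - 1L, R, log = TRUE)
    lt[is.nan(lt)] <- -Inf
    out <- out + dist$pmf$prob[i] * exp(lt)
  }
  out
}

#' @rdname fpt_distribution
#' @export
fpt_cdf <- function(dist, t) {
  if (any(t < 0)) stop("'t' must be non-negative")
  R <- cumulative_rate(dist$params, t)
  out <- numeric(length(t))
  for (i in seq_along(dist$pmf$n))
    out <- out + dist$pmf$prob[i] *
      stats::pgamma(R, shape = dist$pmf$n[i], rate = 1)
  out
}

#' @rdname fpt_distribution
#' @param prob probabilities in (0, 1) for the quantile function.
#' @export
fpt_quantile <- function(dist, prob) {
  if (any(prob <= 0 | prob >= 1)) stop("'prob' must lie strictly in (0, 1)")
  nn <- dist$pmf$n; pp <- dist$pmf$prob
  G <- function(u) {
    out <- 0
    for (i in seq_along(nn)) out <- out + pp[i] * stats::pgamma(u, nn[i], rate = 1)
    out
  }
  # Invert in the time-changed coordinate u = R(t): G is V_b-free.
  lo_all <- stats::qgamma(min(prob), shape = min(nn), rate = 1)
  hi_all <- stats::qgamma(max(prob) * (1 - dist$tail_mass_bound) +
                            dist$tail_mass_bound, shape = max(nn), rate = 1) + 1
  u <- vapply(prob, function(p1) {
    stats::uniroot(function(u) G(u) - p1, lower = lo_all, upper = hi_all,
                   tol = 1e-12, extendInt = "upX")$root
  }, numeric(1))
  inverse_cumulative_rate(dist$params, u)
}

#' @rdname fpt_distribution
#' @param n number of random draws.
#' @return \code{rfpt}: exact samples from the FPT law via the time change
#'   (N from its pmf, then the N-th arrival of a unit Poisson process mapped
#'   through the inverse cumulative rate).
#' @export
rfpt <- function(dist, n) {
  N <- sample(dist$pmf$n, n, replace = TRUE, prob = dist$pmf$prob)
  u <- stats::rgamma(n, shape = N, rate = 1)
  inverse_cumulative_rate(dist$params, u)
}

#' Moments of the division time
#'
#' Computed by default in the added-volume domain through the exact time
#' change \eqn{FPT = \alpha^{-1}\log(1 + v/V_b)} applied to the Gamma-mixture
#' law of the added volume, which avoids quadrature of a long-tailed time
#' integrand; \code{method = "time"} integrates \eqn{t^k f_{FPT}(t)} directly
#' and is retained as an independent cross-check. For \code{alpha = 0}
#' (homogeneous-Poisson limit) the Erlang-mixture closed form is used.
#'
#' @param dist an \code{fpt_distribution}.
#' @param order highest raw moment to compute (1, 2 or 3).
#' @param method \code{"volume"} (default) or \code{"time"}.
#' @return list with \code{raw} moments, \code{mean}, \code{var}, \code{cv2}.
#' @export
fpt_moments <- function(dist, order = 3L, method = c("volume", "time")) {
  method <- match.arg(method)
  if (!order %in% 1:3) stop("'order' must be 1, 2 or 3")
  p <- dist$params
  if (p$alpha == 0) {
    cm <- count_moments(dist$pmf)
    rate <- p$k_m * p$V_b
    raw <- cm$rising[seq_len(order)] / rate^seq_len(order)
  } else if (method == "volume") {
    # integrate in the unit-rate coordinate w = lambda * v so the integrand
    # keeps O(1) scale for any alpha (v itself shrinks like alpha as the
    # growth rate vanishes)
    lam <- p$k_m / p$alpha
    nn <- dist$pmf$n; pr <- dist$pmf$prob
    gw <- function(w) {
      out <- 0
      for (i in seq_along(nn)) out <- out + pr[i] * stats::dgamma(w, nn[i], rate = 1)
      out
    }
    raw <- vapply(seq_len(order), function(k) {
      quad(function(w) (log1p(w / (lam * p$V_b)) / p$alpha)^k * gw(w))
    }, numeric(1))
  } else {
    raw <- vapply(seq_len(order), function(k) {
      quad(function(t) t^k * fpt_pdf(dist, t))
    }, numeric(1))
  }
  out <- list(raw = raw, mean = raw[1])
  if (order >= 2) {
    out$var <- raw[2] - raw[1]^2
    out$cv2 <- out$var / raw[1]^2
  }
  out
}

# Quadrature on [0, Inf) that fails loudly instead of returning silent NaN.
quad <- function(f) {
  r <- tryCatch(stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0,
                                 subdivisions = 400L),
                error = function(e) e)
  if (inherits(r, "error"))
    stop("numerical quadrature failed: ", conditionMessage(r))
  if (r$message != "OK")
    stop("numerical quadrature did not converge: ", r$message)
  r$value
}
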