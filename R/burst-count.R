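#' Distribution of the number of bursts needed to cross the threshold
#'
#' \code{N} is the minimum number of burst events for the accumulated protein
#' count \eqn{S_n = B_1 + ... + B_n} to reach the threshold \code{X}:
#' \eqn{P(N = n) = P(S_n \ge X) - P(S_{n-1} \ge X)}. The tail-difference
#' identity is evaluated with the negative-binomial survival function for
#' geometric bursts (numerically stable) and by direct convolution with
#' absorption at \code{X} for tabulated laws.
#'
#' The series is truncated adaptively: \code{n_max} grows until the neglected
#' mass is below \code{tail_bound} (default 1e-10), with a hard cap of 10000
#' terms that raises an error rather than returning a silently truncated pmf.
#'
#' @param X division threshold (positive integer).
#' @param burst a \code{burst_law}.
#' @param n_max optional fixed truncation order; default adaptive.
#' @param tail_bound maximum neglected probability mass (adaptive mode).
#' @return object of class \code{burst_count_pmf} with fields \code{n},
#'   \code{prob}, \code{tail_mass}, \code{X}, \code{burst}.
#' @examples
#' burst_count_pmf(65, burst_geometric(5))
#' @export
burst_count_pmf <- function(X, burst, n_max = NULL, tail_bound = 1e-10) {
  if (!is.numeric(X) || length(X) != 1L || X < 1 || X != round(X))
    stop("'X' must be a positive integer")
  if (!inherits(burst, "burst_law")) stop("'burst' must be a burst_law")
  X <- as.integer(X)
  cap <- 10000L

  sn_tail <- sn_tail_fun(burst, X)   # function(n) -> P(S_n >= X)
  if (!is.null(n_max)) {
    if (n_max < 1) stop("'n_max' must be >= 1")
    nn <- seq_len(n_max)
    a <- sn_tail(nn)
    prob <- diff(c(0, a))
    tail <- 1 - a[length(a)]
  } else {
    nn <- integer(0); a_prev <- 0; prob <- numeric(0)
    n <- 0L
    repeat {
      n <- n + 1L
      if (n > cap) stop("burst-count series exceeded 10000 terms before ",
                        "reaching the requested tail bound")
      a_n <- sn_tail(n)
      nn <- c(nn, n)
      prob <- c(prob, a_n - a_prev)
      a_prev <- a_n
      if (1 - a_n < tail_bound) break
    }
    tail <- 1 - a_prev
  }
  prob[prob < 0] <- 0   # guard against roundoff at machine level
  structure(list(n = nn, prob = prob, tail_mass = max(tail, 0),
                 X = X, burst = burst),
            class = "burst_count_pmf")
}

# Returns a (vectorized over n) evaluator of P(S_n >= X) for a burst law.
sn_tail_fun <- function(burst, X) {
  if (burst$kind == "geometric") {
    if (burst$support == "shifted") {
      p <- 1 / burst$mean_b
      # S_n = n + NegBinom(n, p); P(S_n >= X) = 1 - P(NB <= X - 1 - n)
      function(n) ifelse(n >= X, 1,
                         stats::pnbinom(X - 1 - n, size = n, prob = p,
                                        lower.tail = FALSE))
    } else {
      p <- 1 / (1 + burst$mean_b)
      function(n) stats::pnbinom(X - 1, size = n, prob = p, lower.tail = FALSE)
    }
  } else if (burst$kind == "deterministic") {
    v <- burst$value
    function(n) as.numeric(n * v >= X)
  } else {
    # tabulated: convolve the sub-distribution on {0, ..., X-1}; mass >= X is
    # absorbed, so 1 - sum(q_n) = P(S_n >= X).
    size <- burst$size; pr <- burst$prob
    function(n) {
      n_req <- max(n)
      out <- numeric(n_req)
      q <- c(1, numeric(X - 1))          # q[k+1] = P(S_0 = k, S_0 < X)
      for (i in seq_len(n_req)) {
        qn <- numeric(X)
        for (j in seq_along(size)) {
          s <- size[j]
          if (s < X) {
            idx <- seq_len(X - s)
            qn[idx + s] <- qn[idx + s] + pr[j] * q[idx]
          }
        }
        q <- qn
        out[i] <- 1 - sum(q)
      }
      out[n]
    }
  }
}

#' @export
print.burst_count_pmf <- function(x, ...) {
  cat(sprintf("Burst-count pmf: X = %d, %d terms, tail mass %.3g\n",
              x$X, length(x$n), x$tail_mass))
  invisible(x)
}

# Rising-factorial moments E[N (N+1) ... (N+j-1)], j = 1..jmax, plus raw
# moments E[N^j], j = 1..3. These drive all added-volume moments because
# E[DeltaV^j] = E[(N)_j^rising] / lambda^j for a Gamma(N, lambda) mixture.
count_moments <- function(pmf, jmax = 4L) {
  n <- pmf$n; p <- pmf$prob
  rising <- vapply(seq_len(jmax), function(j) {
    f <- rep(1, length(n))
    for (k in 0:(j - 1)) f <- f * (n + k)
    sum(p * f)
  }, numeric(1))
  raw <- vapply(1:3, function(j) sum(p * n^j), numeric(1))
  list(rising = rising, raw = raw, tail_mass = pmf$tail_mass)
}
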