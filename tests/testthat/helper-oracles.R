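# Shared fixtures and independent oracles, built in code at test time.

# Reference parameter set: k_m = 0.13 / min, alpha = 0.03 / min, X = 65
# molecules, geometric bursts with mean 5.
ref_params <- function(V_b = 1, alpha = 0.03, k_m = 0.13, X = 65, b = 5)
  model_params(k_m = k_m, alpha = alpha, burst = burst_geometric(b),
               X = X, V_b = V_b)

# Brute-force oracle for the burst-count pmf: exhaustive convolution of the
# full burst-size pmf (no absorption trick, no closed forms), P(N = n) =
# P(S_{n-1} < X) - P(S_n < X).  Deliberately independent of the package's
# tail-difference implementation.
oracle_burst_count <- function(X, size, prob, n_max = 12L) {
  big <- X + max(size) * n_max + 1L
  q <- c(1, numeric(big))                  # pmf of S_0 on 0..big
  p_lt_prev <- 1                           # P(S_0 < X), X >= 1
  pn <- numeric(n_max)
  for (n in seq_len(n_max)) {
    qn <- numeric(big + 1L)
    for (j in seq_along(size)) {
      s <- size[j]
      idx <- seq_len(big + 1L - s)
      qn[idx + s] <- qn[idx + s] + prob[j] * q[idx]
    }
    q <- qn
    p_lt <- sum(q[seq_len(X)])
    pn[n] <- p_lt_prev - p_lt
    p_lt_prev <- p_lt
  }
  pn
}

# Truncated tabulated version of a geometric law (for oracle comparisons).
truncated_geometric <- function(mean_b, support = "shifted", kmax = 64L) {
  if (support == "shifted") {
    k <- 1:kmax; p <- 1 / mean_b
    pr <- p * (1 - p)^(k - 1)
  } else {
    k <- 0:kmax; p <- 1 / (1 + mean_b)
    pr <- p * (1 - p)^k
  }
  list(size = k, prob = pr / sum(pr))
}

skewness <- function(x) mean((x - mean(x))^3) / stats::var(x)^1.5
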