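#' Bin single-cell records by newborn size
#'
#' Bins are half-open [lo, hi) except the last, which is closed, matching the
#' usual binning of single-cell size data. Records outside all bins are
#' counted and reported, never silently dropped; bins with fewer than
#' \code{min_n} records are flagged and should be excluded from trend tests.
#'
#' @param records a cell-cycle table (from \code{\link{sample_cycles}} or
#'   \code{\link{read_cycle_table}}) with a \code{V_b} column.
#' @param edges strictly increasing bin edges on newborn size.
#' @param quantity column summarized per bin: \code{"delta_V"}, \code{"fpt"}
#'   or \code{"V_d"}.
#' @param min_n bins with fewer records are flagged.
#' @param n_boot if > 0, a percentile-bootstrap 95\% CI for the per-bin CV2.
#' @return object of class \code{binned_stat}: a list with \code{table}
#'   (lower, upper, n, mean, variance, cv2, ci_low, ci_high, flagged),
#'   \code{out_of_range} count and \code{quantity}.
#' @examples
#' p <- model_params(0.13, 0.03, burst_geometric(5), 65, 1)
#' set.seed(1)
#' rec <- sample_cycles(p, 500, V_b = runif(500, 2, 3.5))
#' bin_by_newborn_size(rec, seq(2, 3.5, length.out = 6))
#' @export
bin_by_newborn_size <- function(records, edges,
                                quantity = c("delta_V", "fpt", "V_d"),
                                min_n = 2L, n_boot = 0L) {
  quantity <- match.arg(quantity)
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("'edges' must be strictly increasing with at least two values")
  if (!all(c("V_b", quantity) %in% names(records)))
    stop("'records' must contain columns V_b and ", quantity)
  nb <- length(edges) - 1L
  idx <- findInterval(records$V_b, edges, rightmost.closed = TRUE)
  idx[idx == 0L | idx > nb] <- NA_integer_
  vals <- records[[quantity]]
  tab <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                    n = 0L, mean = NA_real_, variance = NA_real_,
                    cv2 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    flagged = TRUE)
  for (b in seq_len(nb)) {
    x <- vals[!is.na(idx) & idx == b]
    tab$n[b] <- length(x)
    if (length(x) >= 1L) tab$mean[b] <- mean(x)
    if (length(x) >= 2L) {
      tab$variance[b] <- stats::var(x)
      tab$cv2[b] <- tab$variance[b] / tab$mean[b]^2
      if (n_boot > 0L) {
        ci <- cv2_bootstrap(x, n_boot = max(n_boot, 200L), enforce_min = FALSE)
        tab$ci_low[b] <- ci$ci_low; tab$ci_high[b] <- ci$ci_high
      }
    }
    tab$flagged[b] <- tab$n[b] < min_n
  }
  structure(list(table = tab, out_of_range = sum(is.na(idx)),
                 quantity = quantity),
            class = "binned_stat")
}

#' @export
print.binned_stat <- function(x, ...) {
  cat(sprintf("Binned %s by newborn size (%d bins, %d out-of-range records)\n",
              x$quantity, nrow(x$table), x$out_of_range))
  print(x$table, digits = 4)
  invisible(x)
}

#' Bootstrap confidence interval for the coefficient of variation squared
#'
#' CV2 = sample variance / sample mean squared, with a percentile bootstrap
#' 95\% CI (percentile rather than BCa: simple and stable for ratio
#' statistics at the sample sizes used here).
#'
#' @param values numeric sample (>= 10 values).
#' @param n_boot number of bootstrap resamples (>= 200; default 1000).
#' @param enforce_min enforce the minimum sample and resample counts
#'   (relaxed internally for small bins).
#' @return list with \code{cv2}, \code{ci_low}, \code{ci_high},
#'   \code{n_boot}.
#' @examples
#' set.seed(1)
#' cv2_bootstrap(rexp(500), n_boot = 500)
#' @export
cv2_bootstrap <- function(values, n_boot = 1000L, enforce_min = TRUE) {
  if (enforce_min && length(values) < 10L)
    stop("'values' must contain at least 10 observations")
  if (enforce_min && n_boot < 200L) stop("'n_boot' must be >= 200")
  n <- length(values)
  cv2 <- stats::var(values) / mean(values)^2
  m <- matrix(sample(values, n * n_boot, replace = TRUE), nrow = n_boot)
  mu <- rowMeans(m)
  v <- (rowMeans(m * m) - mu^2) * n / (n - 1)
  bs <- v / mu^2
  ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  list(cv2 = cv2, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot)
}

#' Distribution-collapse diagnostic
#'
#' Pairwise two-sample Kolmogorov-Smirnov comparison of added-size (or any)
#' samples, optionally after rescaling each sample by its own mean. A
#' "collapsed" verdict means no pair rejects at the (conservative, because
#' multiple pairs are compared) 1\% level: the scale-invariance signature in
#' which mean-rescaled distributions from different growth conditions
#' coincide.
#'
#' @param samples list of >= 2 numeric samples, each of size >= 100.
#' @param rescale divide each sample by its own mean before comparing.
#' @param level significance level for the collapse verdict.
#' @return list with \code{distance} and \code{p_value} matrices,
#'   \code{max_distance}, \code{min_p_value}, \code{collapsed}.
#' @export
collapse_distance <- function(samples, rescale = TRUE, level = 0.01) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("'samples' must be a list of at least two samples")
  if (any(vapply(samples, length, 1L) < 100L))
    stop("each sample must contain at least 100 values")
  xs <- if (rescale) lapply(samples, function(s) s / mean(s)) else samples
  k <- length(xs)
  D <- matrix(0, k, k); P <- matrix(1, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    kt <- suppressWarnings(stats::ks.test(xs[[i]], xs[[j]]))
    D[i, j] <- D[j, i] <- unname(kt$statistic)
    P[i, j] <- P[j, i] <- kt$p.value
  }
  off <- upper.tri(D)
  list(distance = D, p_value = P, max_distance = max(D[off]),
       min_p_value = min(P[off]), collapsed = all(P[off] > level))
}

#' Adder trend test: added volume vs newborn size
#'
#' Spearman rank correlation of (newborn size, added volume) pairs against a
#' permutation null (distribution-free, chosen over a parametric slope test).
#' The verdict is \code{"adder"} when the observed correlation lies inside
#' the central 99\% permutation band, otherwise the sign of the correlation.
#'
#' @param records data.frame with columns \code{V_b} and \code{delta_V}
#'   (>= 1000 rows for reliable sign verdicts).
#' @param n_perm number of permutations (>= 999).
#' @param level two-sided significance level of the band.
#' @return list with \code{rho}, \code{band} (null quantiles),
#'   \code{verdict} in \{"adder", "positive", "negative"\}, \code{n_perm}.
#' @export
adder_trend_test <- function(records, n_perm = 999L, level = 0.01) {
  if (!all(c("V_b", "delta_V") %in% names(records)))
    stop("'records' must contain columns V_b and delta_V")
  if (n_perm < 999L) stop("'n_perm' must be >= 999")
  rx <- rank(records$V_b); ry <- rank(records$delta_V)
  rho <- stats::cor(rx, ry)
  null <- vapply(seq_len(n_perm), function(i) stats::cor(rx, sample(ry)),
                 numeric(1))
  band <- stats::quantile(null, c(level / 2, 1 - level / 2), names = FALSE)
  verdict <- if (rho >= band[1] && rho <= band[2]) "adder"
             else if (rho > 0) "positive" else "negative"
  list(rho = rho, band = band, verdict = verdict, n_perm = n_perm)
}
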