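#' Exact stochastic simulation of single cell cycles
#'
#' The baseline sampler is exact, with no time discretization: in the
#' added-volume coordinate the burst arrivals form a homogeneous Poisson
#' process with rate \eqn{\lambda = k_m/\alpha} per size unit, so the volume
#' added between consecutive bursts is exponential. Bursts accumulate from
#' the inherited count until the division rule fires; the division time is
#' recovered by the logarithmic time change \eqn{t = \alpha^{-1}\log(V_d /
#' V_b)}. The saturating-rate mechanism uses exact Poisson thinning of the
#' unsaturated proposal process, and the soft threshold uses exact
#' competing-exponential steps between burst arrival and division hazard.
#'
#' @param params a \code{\link{model_params}} with \code{alpha > 0}.
#' @param n number of independent cycles to draw.
#' @param mechanism a \code{\link{mechanism_baseline}} / \code{mechanism_spec}.
#' @param carryover inherited protein count(s) at birth; must be below the
#'   threshold. The default \code{NULL} lets the mechanism decide: 0 for all
#'   mechanisms except \code{partial_degradation}, where a single newborn of
#'   size \code{V_b} inherits Binomial(X, kappa * V_b / (2 m)) molecules,
#'   with m the baseline mean added volume. This is the
#'   concentration-equilibrated inheritance: an undegraded pool produced at a
#'   volume-proportional rate settles to a fixed birth concentration over
#'   generations, so the inherited count scales with newborn size (m is the
#'   stationary mean newborn size at the adder fixed point). Within
#'   lineages, \code{\link{sample_lineages}} instead propagates the realized
#'   count, Binomial(round(kappa * final_count), 1/2).
#' @param V_b optional newborn size(s) overriding \code{params$V_b}; recycled
#'   to length \code{n}.
#' @return data.frame with one row per cycle: \code{V_b}, \code{V_d},
#'   \code{delta_V}, \code{fpt}, \code{alpha}, \code{n_bursts},
#'   \code{final_count}, \code{carryover_in}, \code{mechanism}.
#' @examples
#' p <- model_params(0.13, 0.03, burst_geometric(5), 65, 1)
#' set.seed(1)
#' head(sample_cycles(p, 5))
#' @export
sample_cycles <- function(params, n, mechanism = mechanism_baseline(),
                          carryover = NULL, V_b = NULL) {
  if (!inherits(params, "model_params")) stop("'params' must be model_params")
  if (!inherits(mechanism, "mechanism_spec")) stop("'mechanism' must be a mechanism_spec")
  if (params$alpha <= 0) stop("the simulator requires alpha > 0")
  if (n < 0) stop("'n' must be non-negative")
  vb <- rep_len(if (is.null(V_b)) params$V_b else V_b, n)
  co <- if (is.null(carryover)) default_carryover(params, mechanism, vb)
        else rep_len(carryover, n)
  if (any(vb <= 0)) stop("newborn sizes must be positive")
  if (any(co < 0)) stop("'carryover' must be non-negative")
  if (mechanism$kind != "soft_threshold" && any(co >= params$X))
    stop("'carryover' must be below the division threshold X")
  if (n == 0L) return(empty_cycle_table())

  out <- switch(mechanism$kind,
    baseline = ,
    partial_degradation = cycles_threshold(params, vb, co),
    volume_dependent_burst = cycles_volume_burst(params, vb, co, mechanism),
    saturating_rate = cycles_saturating(params, vb, co, mechanism),
    soft_threshold = cycles_soft(params, vb, co, mechanism))
  out$carryover_in <- co
  out$mechanism <- mechanism$kind
  out
}

#' @rdname sample_cycles
#' @export
sample_cycle <- function(params, mechanism = mechanism_baseline(),
                         carryover = NULL, V_b = NULL) {
  sample_cycles(params, 1L, mechanism, carryover, V_b)
}

# Mechanism-defined inherited count for isolated cycles (see sample_cycles).
default_carryover <- function(params, mechanism, vb) {
  if (mechanism$kind != "partial_degradation") return(rep_len(0L, length(vb)))
  m <- deltaV_moments(added_volume_distribution(params))$mean
  pr <- pmin(mechanism$retention_kappa * vb / (2 * m), 1 - 1 / params$X)
  pmin(stats::rbinom(length(vb), params$X, pr), params$X - 1L)
}

empty_cycle_table <- function() {
  data.frame(V_b = numeric(0), V_d = numeric(0), delta_V = numeric(0),
             fpt = numeric(0), alpha = numeric(0), n_bursts = integer(0),
             final_count = numeric(0), carryover_in = numeric(0),
             mechanism = character(0))
}

finish_cycles <- function(params, vb, dv, nb, fc) {
  data.frame(V_b = vb, V_d = vb + dv, delta_V = dv,
             fpt = log1p(dv / vb) / params$alpha, alpha = params$alpha,
             n_bursts = nb, final_count = fc)
}

# Sharp threshold (baseline / partial degradation share the within-cycle
# dynamics; carryover is where they differ across generations).  Burst
# counts are sampled mechanistically burst-by-burst; given N the added
# volume is the sum of N exponential inter-burst gaps, i.e. Gamma(N, lambda).
cycles_threshold <- function(params, vb, co) {
  n <- length(vb)
  need <- params$X - co
  nb <- integer(n)
  tot <- numeric(n)
  active <- which(need > 0)
  guard <- 0L
  while (length(active)) {
    guard <- guard + 1L
    if (guard > 1e6L) stop("burst accumulation did not terminate")
    B <- rburst(params$burst, length(active))
    nb[active] <- nb[active] + 1L
    tot[active] <- tot[active] + B
    need[active] <- need[active] - B
    active <- active[need[active] > 0]
  }
  dv <- stats::rgamma(n, shape = nb, rate = params$k_m / params$alpha)
  finish_cycles(params, vb, dv, nb, co + tot)
}

# Mechanism (ii): the geometric burst mean is re-evaluated at the volume at
# the moment of each burst, b(V) = b0 * V / V_ref.
cycles_volume_burst <- function(params, vb, co, mech) {
  if (params$burst$kind != "geometric")
    stop("volume_dependent_burst requires a geometric burst law")
  n <- length(vb)
  lam <- params$k_m / params$alpha
  b0 <- params$burst$mean_b
  shifted <- params$burst$support == "shifted"
  dv <- numeric(n); nb <- integer(n); fc <- numeric(n)
  for (i in seq_len(n)) {
    u <- 0; x <- co[i]; k <- 0L
    while (x < params$X) {
      u <- u + stats::rexp(1L, lam)
      bm <- b0 * (vb[i] + u) / mech$V_ref
      x <- x + if (shifted) 1L + stats::rgeom(1L, 1 / max(bm, 1)) else
        stats::rgeom(1L, 1 / (1 + bm))
      k <- k + 1L
      if (k > 1e6L) stop("burst accumulation did not terminate")
    }
    dv[i] <- u; nb[i] <- k; fc[i] <- x
  }
  finish_cycles(params, vb, dv, nb, fc)
}

# Mechanism (iii): r(V) = k_m V / (1 + V/V_sat).  Proposals arrive from the
# unsaturated process (rate lambda per unit added volume) and are accepted
# with probability 1/(1 + V/V_sat) -- exact thinning, no Euler stepping.
cycles_saturating <- function(params, vb, co, mech) {
  n <- length(vb)
  lam <- params$k_m / params$alpha
  dv <- numeric(n); nb <- integer(n); fc <- numeric(n)
  for (i in seq_len(n)) {
    u <- 0; x <- co[i]; k <- 0L; guard <- 0L
    while (x < params$X) {
      u <- u + stats::rexp(1L, lam)
      guard <- guard + 1L
      if (guard > 1e7L) stop("thinning did not terminate")
      if (stats::runif(1L) < 1 / (1 + (vb[i] + u) / mech$V_sat)) {
        x <- x + rburst(params$burst, 1L)
        k <- k + 1L
      }
    }
    dv[i] <- u; nb[i] <- k; fc[i] <- x
  }
  finish_cycles(params, vb, dv, nb, fc)
}

# Mechanism (iv): between bursts the protein count is constant, so division
# (rate h(x)) and the next burst (inhomogeneous rate k_m V(t)) compete as
# exponentials; the burst wait is drawn exactly by inverting the cumulative
# rate from the current time.
cycles_soft <- function(params, vb, co, mech) {
  n <- length(vb)
  hz <- hazard_soft(params$X, mech$H, mech$c)
  dv <- numeric(n); nb <- integer(n); fc <- numeric(n)
  for (i in seq_len(n)) {
    t <- 0; x <- co[i]; k <- 0L; guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 1e6L) stop("soft-threshold simulation did not terminate")
      V_now <- vb[i] * exp(params$alpha * t)
      w_burst <- log1p(params$alpha * stats::rexp(1L) /
                         (params$k_m * V_now)) / params$alpha
      h <- division_hazard(hz, x)
      if (!is.finite(h)) break
      w_div <- if (h > 0) stats::rexp(1L, h) else Inf
      if (w_div < w_burst) { t <- t + w_div; break }
      t <- t + w_burst
      x <- x + rburst(params$burst, 1L)
      k <- k + 1L
    }
    dv[i] <- vb[i] * expm1(params$alpha * t)
    nb[i] <- k; fc[i] <- x
  }
  finish_cycles(params, vb, dv, nb, fc)
}

#' Multi-generation lineages
#'
#' Follows one daughter per lineage for \code{n_generations}: each cycle is
#' drawn with \code{\link{sample_cycles}}, the newborn size of the next
#' generation is half the division size (symmetric halving), and the protein
#' carryover is 0 in the baseline or Binomial(round(kappa * final_count),
#' 1/2) under partial degradation.
#'
#' @inheritParams sample_cycles
#' @param n_lineages number of independent lineages.
#' @param n_generations generations per lineage.
#' @param V_b0 founding newborn size (default \code{params$V_b}).
#' @param division_ratio fraction of the division size inherited by the
#'   followed daughter (0.5 = symmetric halving; exposed for sensitivity
#'   checks only).
#' @return data.frame as \code{\link{sample_cycles}} plus \code{lineage_id}
#'   and \code{generation}.
#' @export
sample_lineages <- function(params, n_lineages, n_generations,
                            mechanism = mechanism_baseline(),
                            V_b0 = NULL, division_ratio = 0.5) {
  if (n_lineages < 1 || n_generations < 1)
    stop("'n_lineages' and 'n_generations' must be >= 1")
  if (division_ratio <= 0 || division_ratio >= 1)
    stop("'division_ratio' must lie in (0, 1)")
  vb <- rep_len(if (is.null(V_b0)) params$V_b else V_b0, n_lineages)
  co <- rep_len(0L, n_lineages)
  gens <- vector("list", n_generations)
  for (g in seq_len(n_generations)) {
    rec <- sample_cycles(params, n_lineages, mechanism,
                         carryover = co, V_b = vb)
    rec$lineage_id <- seq_len(n_lineages)
    rec$generation <- g
    gens[[g]] <- rec
    vb <- rec$V_d * division_ratio
    co <- if (mechanism$kind == "partial_degradation") {
      stats::rbinom(n_lineages, round(mechanism$retention_kappa * rec$final_count),
                    division_ratio)
    } else rep_len(0L, n_lineages)
  }
  out <- do.call(rbind, gens)
  out <- out[order(out$lineage_id, out$generation), ]
  rownames(out) <- NULL
  out[, c("lineage_id", "generation", setdiff(names(out),
                                              c("lineage_id", "generation")))]
}

#' Newborn-size scan for deviation-mechanism correlations
#'
#' Draws \code{n_cells} independent single cycles with newborn sizes uniform
#' on \code{V_b_range}, the protocol used to diagnose the sign of the added
#' volume vs newborn size correlation under each mechanism.
#'
#' @inheritParams sample_cycles
#' @param n_cells number of cells (>= 1000 recommended for sign tests).
#' @param V_b_range interval for the uniform newborn-size draw.
#' @param n_bins number of uniform bins for the binned summary.
#' @return list with \code{records} (the per-cell table) and \code{binned}
#'   (a \code{\link{bin_by_newborn_size}} summary of delta_V).
#' @export
mechanism_correlation_experiment <- function(params, mechanism, n_cells = 10000L,
                                             V_b_range = c(1, 7), n_bins = 13L) {
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (length(V_b_range) != 2L || diff(V_b_range) <= 0)
    stop("'V_b_range' must be an increasing interval")
  vb <- stats::runif(n_cells, V_b_range[1], V_b_range[2])
  rec <- sample_cycles(params, n_cells, mechanism, V_b = vb)
  edges <- seq(V_b_range[1], V_b_range[2], length.out = n_bins + 1L)
  list(records = rec,
       binned = bin_by_newborn_size(rec, edges, quantity = "delta_V"))
}
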