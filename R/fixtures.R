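#' Generate the canonical simulated datasets
#'
#' Writes three groups of reproducible fixtures used throughout the test
#' protocols: (a) a baseline single-cycle table at the reference parameter
#' set (k_m = 0.13 per min, alpha = 0.03 per min, X = 65 molecules, geometric
#' bursts with mean 5), (b) newborn-size scans for the baseline and all four
#' deviation mechanisms with newborn sizes uniform on [1, 7], and (c)
#' added-volume tables at three growth rates (0.01, 0.03, 0.06 per min) for
#' the mean-rescaled collapse diagnostic. All files are bitwise reproducible
#' from the seed.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param n cycles per table.
#' @return invisibly, the paths written.
#' @export
generate_fixtures <- function(dir, seed = 1L, n = 10000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  params <- model_params(0.13, 0.03, burst_geometric(5), 65, 1)
  paths <- character(0)
  raw <- list(k_m = 0.13, alpha = 0.03, X = 65, V_b = 1,
              burst = list(kind = "geometric", mean_b = 5), n = n)

  p <- file.path(dir, "baseline_cycles.csv")
  write_cycle_table(sample_cycles(params, n), p, config = raw, seed = seed)
  paths <- c(paths, p)

  mechs <- list(baseline = mechanism_baseline(),
                partial_degradation = mechanism_partial_degradation(0.5),
                volume_dependent_burst = mechanism_volume_dependent_burst(1),
                saturating_rate = mechanism_saturating_rate(5),
                soft_threshold = mechanism_soft_threshold(4, 1))
  for (nm in names(mechs)) {
    p <- file.path(dir, paste0("mechanism_", nm, ".csv"))
    ex <- mechanism_correlation_experiment(params, mechs[[nm]], n_cells = n)
    write_cycle_table(ex$records, p, config = c(raw, list(mechanism = nm)),
                      seed = seed)
    paths <- c(paths, p)
  }

  for (a in c(0.01, 0.03, 0.06)) {
    p <- file.path(dir, sprintf("collapse_alpha_%s.csv", format(a)))
    pa <- model_params(0.13, a, burst_geometric(5), 65, 1)
    write_cycle_table(sample_cycles(pa, n), p,
                      config = utils::modifyList(raw, list(alpha = a)),
                      seed = seed)
    paths <- c(paths, p)
  }
  invisible(paths)
}
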