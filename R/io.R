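#' Read a run configuration
#'
#' Configurations are flat YAML (JSON is valid YAML) with keys \code{k_m},
#' \code{alpha}, \code{burst} (\code{kind}, \code{mean_b}, \code{value},
#' \code{size}/\code{prob}), \code{X}, \code{V_b}, \code{mechanism}
#' (\code{kind} plus its parameters), \code{experiment}, \code{n},
#' \code{seed}, \code{output}. Missing keys take the defaults below; the
#' fully resolved configuration is echoed into every output file for
#' provenance.
#'
#' @param path path to a YAML/JSON config file.
#' @return a resolved \code{run_config} list with elements \code{params}
#'   (\code{\link{model_params}}), \code{mechanism}, \code{experiment},
#'   \code{n}, \code{seed}, \code{output} and \code{raw} (the resolved
#'   key-value list that is serialized into outputs).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  resolve_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a (possibly partial) named list of configuration values.
#' @export
resolve_run_config <- function(config = list()) {
  def <- list(k_m = 0.13, alpha = 0.03,
              burst = list(kind = "geometric", mean_b = 5, support = "shifted"),
              X = 65, V_b = 1,
              mechanism = list(kind = "baseline"),
              experiment = "simulate", n = 10000L, seed = 1L,
              n_generations = 1L, theta = 1L, T_CD = 0,
              V_b_range = c(1, 7), output = "adderfpt_run")
  cfg <- utils::modifyList(def, config)
  burst <- switch(cfg$burst$kind,
    geometric = burst_geometric(cfg$burst$mean_b,
                                support = cfg$burst$support %||% "shifted"),
    deterministic = burst_deterministic(cfg$burst$value),
    tabulated = burst_tabulated(cfg$burst$size, cfg$burst$prob),
    stop("unknown burst kind: ", cfg$burst$kind))
  params <- model_params(cfg$k_m, cfg$alpha, burst, cfg$X, cfg$V_b)
  mech_args <- cfg$mechanism[setdiff(names(cfg$mechanism), "kind")]
  mechanism <- as_mechanism(cfg$mechanism$kind, mech_args)
  structure(list(params = params, mechanism = mechanism,
                 experiment = cfg$experiment, n = as.integer(cfg$n),
                 seed = as.integer(cfg$seed), output = cfg$output, raw = cfg),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_comment_lines <- function(raw, seed = NULL) {
  flat <- unlist(raw)
  if (!is.null(seed)) flat <- c(flat, seed = seed)
  c("# adderfpt output", paste0("# ", names(flat), " = ",
                                vapply(flat, format, "", digits = 17)))
}

#' Write / read cell-cycle tables
#'
#' Comma-separated, '.' decimal, mandatory header row, UTF-8, no quoting of
#' numerics. Numeric columns are written with 17 significant digits so a
#' write/read round trip reproduces the values bitwise. The resolved
#' configuration (when given) is embedded as leading '#' comment lines.
#'
#' @param records a cell-cycle data.frame.
#' @param path output path.
#' @param config optional \code{run_config} (or raw list) echoed as comments.
#' @param seed optional seed echoed alongside the config.
#' @export
write_cycle_table <- function(records, path, config = NULL, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config)) {
    raw <- if (inherits(config, "run_config")) config$raw else config
    writeLines(config_comment_lines(raw, seed), con)
  }
  fmt <- records
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  utils::write.table(fmt, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cycle_table
#' @return \code{read_cycle_table}: the records data.frame (comment lines
#'   are skipped).
#' @export
read_cycle_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export a distribution table
#'
#' Two-column delimited text (value, density) with a commented header naming
#' the model and parameters.
#'
#' @param x evaluation points.
#' @param density density (or pmf) values at \code{x}.
#' @param path output path.
#' @param label name of the distribution written into the header.
#' @param params optional \code{\link{model_params}} described in the header.
#' @export
write_distribution_table <- function(x, density, path, label = "distribution",
                                     params = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# adderfpt ", label, " table"), con)
  if (!is.null(params))
    writeLines(sprintf("# k_m = %.17g, alpha = %.17g, X = %d, V_b = %.17g, burst = %s",
                       params$k_m, params$alpha, params$X, params$V_b,
                       params$burst$kind), con)
  utils::write.table(
    data.frame(value = sprintf("%.17g", x), density = sprintf("%.17g", density)),
    con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary statistics of a cell-cycle table
#'
#' @param records a cell-cycle data.frame.
#' @return list of sample mean, CV2 and skewness of delta_V and fpt, plus the
#'   record count.
#' @export
cycle_summary <- function(records) {
  stat <- function(x) {
    if (length(x) < 2L) return(list(mean = NA, cv2 = NA, skewness = NA))
    m <- mean(x); v <- stats::var(x)
    list(mean = m, cv2 = v / m^2,
         skewness = mean((x - m)^3) / v^1.5)
  }
  list(n = nrow(records), delta_V = stat(records$delta_V),
       fpt = stat(records$fpt))
}
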