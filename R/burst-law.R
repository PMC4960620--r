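#' Burst-size laws
#'
#' Protein is produced in bursts; each burst delivers an integer number of
#' molecules drawn independently from a common law with mean \code{b}.
#' Three families are supported: geometric (the canonical law for bursty
#' expression from short-lived transcripts), deterministic (a fixed burst
#' size), and an arbitrary finite pmf on non-negative integers.
#'
#' The geometric law comes in two variants. The default, \code{"shifted"},
#' lives on \{1, 2, ...\} so every transcription event yields at least one
#' protein; \code{"nonnegative"} lives on \{0, 1, ...\}. Both are
#' parameterized by their mean \code{mean_b}.
#'
#' @param mean_b mean burst size (molecules); must be >= 1 for the shifted
#'   variant, > 0 for the non-negative variant.
#' @param support \code{"shifted"} (support \{1,2,...\}) or
#'   \code{"nonnegative"} (support \{0,1,...\}).
#' @return an object of class \code{burst_law}.
#' @examples
#' burst_geometric(5)
#' burst_deterministic(1)
#' burst_tabulated(c(1, 2), c(0.5, 0.5))
#' @export
burst_geometric <- function(mean_b, support = c("shifted", "nonnegative")) {
  support <- match.arg(support)
  if (!is.numeric(mean_b) || length(mean_b) != 1L || !is.finite(mean_b))
    stop("'mean_b' must be a finite number")
  if (support == "shifted" && mean_b < 1)
    stop("shifted geometric burst law requires mean_b >= 1")
  if (support == "nonnegative" && mean_b <= 0)
    stop("non-negative geometric burst law requires mean_b > 0")
  structure(list(kind = "geometric", mean_b = mean_b, support = support),
            class = c("burst_geometric", "burst_law"))
}

#' @rdname burst_geometric
#' @param value fixed burst size (positive integer) for the deterministic law.
#' @export
burst_deterministic <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || value < 1 ||
      value != round(value))
    stop("'value' must be a positive integer")
  structure(list(kind = "deterministic", value = as.integer(value)),
            class = c("burst_deterministic", "burst_law"))
}

#' @rdname burst_geometric
#' @param size integer burst sizes (non-negative, distinct) for the tabulated
#'   law.
#' @param prob probabilities matching \code{size}; must sum to 1 within 1e-12.
#' @export
burst_tabulated <- function(size, prob) {
  if (length(size) != length(prob) || length(size) < 1L)
    stop("'size' and 'prob' must be non-empty vectors of equal length")
  if (any(size < 0) || any(size != round(size)))
    stop("tabulated burst sizes must be non-negative integers")
  if (any(duplicated(size))) stop("tabulated burst sizes must be distinct")
  if (any(prob < 0)) stop("probabilities must be non-negative")
  if (abs(sum(prob) - 1) > 1e-12) stop("probabilities must sum to 1 (within 1e-12)")
  if (sum(prob[size > 0]) <= 0)
    stop("burst law with all mass at 0: threshold can never be reached")
  o <- order(size)
  structure(list(kind = "tabulated", size = as.integer(size[o]), prob = prob[o]),
            class = c("burst_tabulated", "burst_law"))
}

#' Mean of a burst-size law
#' @param law a \code{burst_law}.
#' @return the mean burst size b.
#' @export
burst_mean <- function(law) {
  switch(law$kind,
         geometric = law$mean_b,
         deterministic = law$value,
         tabulated = sum(law$size * law$prob),
         stop("unknown burst law"))
}

#' Draw burst sizes
#' @param law a \code{burst_law}.
#' @param n number of draws.
#' @param mean_b optional mean overriding the law's own (geometric only);
#'   used by the volume-dependent-burst mechanism.
#' @return integer vector of burst sizes.
#' @export
rburst <- function(law, n, mean_b = NULL) {
  if (law$kind == "geometric") {
    b <- if (is.null(mean_b)) law$mean_b else mean_b
    if (law$support == "shifted") {
      if (any(b < 1)) stop("shifted geometric requires mean >= 1")
      1L + stats::rgeom(n, 1 / b)
    } else {
      stats::rgeom(n, 1 / (1 + b))
    }
  } else if (law$kind == "deterministic") {
    if (!is.null(mean_b)) stop("mean override only applies to geometric bursts")
    rep.int(law$value, n)
  } else {
    if (!is.null(mean_b)) stop("mean override only applies to geometric bursts")
    sample(law$size, n, replace = TRUE, prob = law$prob)
  }
}

#' @export
print.burst_law <- function(x, ...) {
  cat("Burst-size law:", x$kind)
  if (x$kind == "geometric")
    cat(sprintf(" (mean b = %g, support %s)", x$mean_b,
                if (x$support == "shifted") "{1,2,...}" else "{0,1,...}"))
  if (x$kind == "deterministic") cat(sprintf(" (size %d)", x$value))
  if (x$kind == "tabulated")
    cat(sprintf(" (support {%s})", paste(x$size, collapse = ",")))
  cat("\n")
  invisible(x)
}
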