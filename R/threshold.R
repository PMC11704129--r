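#' Persistence-threshold configuration
#'
#' @param selector `"max_gap"` (default) selects the midpoint of the widest
#'   gap in the sorted persistence values (the diagonal, persistence 0, is
#'   included as the lower anchor, so a diagram whose values form a single
#'   tight cluster keeps all of them); `"fixed"` uses `fixed_value`.
#' @param fixed_value Scalar threshold, required iff `selector = "fixed"`.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(selector = c("max_gap", "fixed"),
                             fixed_value = NULL) {
  selector <- match.arg(selector)
  if (selector == "fixed" && (!is.numeric(fixed_value) || length(fixed_value) != 1L))
    stop("'fixed_value' must be a scalar when selector = \"fixed\"")
  if (selector != "fixed" && !is.null(fixed_value))
    stop("'fixed_value' is only meaningful with selector = \"fixed\"")
  structure(list(selector = selector, fixed_value = fixed_value),
            class = "threshold_config")
}

#' Automatic persistence threshold
#'
#' Chooses the persistence cutoff that separates the meaningful cycles of a
#' diagram from low-persistence noise. With the default `max_gap` selector
#' the sorted persistence values are scanned together with the zero anchor
#' (the diagram diagonal), and the threshold is the midpoint of the widest
#' gap between consecutive values; when several gaps tie, the one at higher
#' persistence is used. The result is invariant to permutations of the
#' input, lies in `[0, max(values))`, and never empties a diagram whose
#' values are all equal (the gap from zero then wins, so every cycle stays
#' selected).
#'
#' Intensities are assumed normalized to \[0, 1\], so persistences live on
#' the same scale.
#'
#' @param values Numeric vector of positive persistence values (a multiset;
#'   order is irrelevant).
#' @param config A [threshold_config()].
#' @return Scalar threshold; cycles with persistence strictly greater than
#'   it are the selected ones.
#' @examples
#' optimal_threshold(c(0.90, 0.85, 0.05, 0.04))  # 0.45
#' @export
optimal_threshold <- function(values, config = threshold_config()) {
  if (!length(values)) stop("cannot choose a threshold for an empty diagram")
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0))
    stop("persistence values must be positive finite numbers")
  if (config$selector == "fixed") return(config$fixed_value)
  s <- c(0, sort(values))
  gaps <- diff(s)
  k <- max(which(gaps == max(gaps)))  # ties: prefer the high-persistence gap
  (s[k] + s[k + 1]) / 2
}
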