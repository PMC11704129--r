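#' Betti-1 number of a level-set cubical complex
#'
#' Brute-force computation of the number of independent 1-dimensional holes
#' of the level-set complex at threshold `t`, via the Euler characteristic
#' V - E + F and connected-component counting. For the sublevel direction
#' the complex contains the pixels with intensity `<= t` and the
#' edges/squares whose pixel maximum is `<= t`; for the superlevel
#' direction, pixels `>= t` and cells whose minimum is `>= t`.
#'
#' This routine is deliberately independent of the persistence algorithm
#' (it never touches the dual-graph reduction) so it can serve as an oracle
#' in tests: at any threshold, the number of diagram pairs alive must equal
#' this count.
#'
#' @param image An [intensity_image()] or matrix.
#' @param t Threshold in \[0, 1\].
#' @param direction `"sublevel"` or `"superlevel"`.
#' @return Integer Betti-1 count.
#' @export
betti1_at_threshold <- function(image, t, direction = c("sublevel", "superlevel")) {
  direction <- match.arg(direction)
  u <- as_intensity_image(image, normalize = FALSE)$values
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1)
    stop("'t' must be a scalar in [0, 1]")
  H <- nrow(u); W <- ncol(u)
  inc <- if (direction == "sublevel") u <= t else u >= t
  V <- sum(inc)
  if (V == 0L) return(0L)
  E <- sum(inc[-H, ] & inc[-1, ]) + sum(inc[, -W] & inc[, -1])
  F <- sum(inc[-H, -W] & inc[-1, -W] & inc[-H, -1] & inc[-1, -1])
  b0 <- count_components4(inc)
  as.integer(b0 - (V - E + F))
}

# 4-connected component count by iterative flood fill (plain R on purpose:
# the oracle must not share code with the compiled persistence path).
count_components4 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0L
  idx <- which(mask)
  for (s in idx) {
    i0 <- (s - 1L) %% H + 1L; j0 <- (s - 1L) %/% H + 1L
    if (seen[i0, j0]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% H + 1L; j <- (p - 1L) %/% H + 1L
      for (d in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (d[1] >= 1L && d[1] <= H && d[2] >= 1L && d[2] <= W &&
            mask[d[1], d[2]] && !seen[d[1], d[2]]) {
          seen[d[1], d[2]] <- TRUE
          queue <- c(queue, (d[2] - 1L) * H + d[1])
        }
      }
    }
  }
  ncomp
}

# Number of diagram pairs alive at threshold t. A sublevel class is alive
# for t in [birth, death); a superlevel class for t in (death, birth].
pairs_alive_at <- function(diagram, t) {
  p <- diagram$pairs
  if (diagram$direction == "sublevel") sum(p$birth <= t & p$death > t)
  else sum(p$birth >= t & p$death < t)
}
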