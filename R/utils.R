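# Small numerical helpers shared across modules.

#' Trapezoidal integral of y over x
#' @param x numeric vector of abscissae (monotone increasing)
#' @param y numeric vector of ordinates, same length as x
#' @return scalar integral
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Centered moving average with shrinking windows at the edges
#' @param x numeric vector
#' @param k odd window length in samples
#' @keywords internal
moving_average <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  half <- k %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Centered rolling minimum with shrinking windows at the edges
#' @keywords internal
rolling_min <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    min(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}
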