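#' Periodic depolarizing pulse train
#'
#' Stimulation protocol used throughout: `count` rectangular current pulses
#' of height `amplitude` and duration `width` ms, delivered at `frequency`
#' Hz starting at `onset` ms.  The reference habituation protocols are 40
#' pulses at 1 or 0.2 Hz with amplitude 4.5 starting at 20 s (20.3 s for the
#' trace-reproduction runs).
#'
#' @param onset time of the first pulse onset (ms).
#' @param frequency pulse rate (Hz, > 0).
#' @param count number of pulses (integer >= 0).
#' @param amplitude pulse current height (model units, >= 0).
#' @param width pulse duration (ms); must be shorter than the inter-pulse
#'   interval `1000/frequency`.
#' @return An object of class `pulse_train`.
#' @examples
#' pulse_train(onset = 20000, frequency = 1, count = 40)
#' @export
pulse_train <- function(onset = 20000, frequency = 1, count = 40,
                        amplitude = 4.5, width = 20) {
  if (!is.finite(frequency) || frequency <= 0) stop("frequency must be > 0")
  if (!is.finite(width) || width <= 0) stop("width must be > 0")
  if (width >= 1000 / frequency) {
    stop("pulse width (", width, " ms) must be shorter than the ",
         "inter-pulse interval (", 1000 / frequency, " ms)")
  }
  if (!is.finite(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  if (!is.finite(count) || count < 0 || count != round(count)) {
    stop("count must be a nonnegative integer")
  }
  if (!is.finite(onset) || onset < 0) stop("onset must be >= 0")
  structure(list(onset = onset, frequency = frequency, count = as.integer(count),
                 amplitude = amplitude, width = width),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("pulse train: %d pulses at %g Hz, amplitude %g, width %g ms, onset %g ms\n",
              x$count, x$frequency, x$amplitude, x$width, x$onset))
  invisible(x)
}

#' Pulse onset times
#'
#' @param train a [pulse_train()].
#' @return Numeric vector of pulse onset times (ms):
#'   `onset + k * 1000/frequency` for `k = 0 .. count-1`.
#' @examples
#' range(stimulus_times(pulse_train(20300, 1, 40)))  # 20300 ... 59300
#' @export
stimulus_times <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  if (train$count == 0) return(numeric(0))
  train$onset + (seq_len(train$count) - 1) * 1000 / train$frequency
}

#' Instantaneous drive current of a pulse train
#'
#' Pulse windows are half-open: the drive equals `amplitude` for
#' `t` in `[onset_k, onset_k + width)` and 0 otherwise.
#'
#' @param train a [pulse_train()].
#' @param t time(s) in ms; vectorized.
#' @return Numeric drive current at each `t`.
#' @examples
#' tr <- pulse_train(20000, 1, 40)
#' drive_at(tr, c(19999, 20000, 20019.9, 20020))  # 0, 4.5, 4.5, 0
#' @export
drive_at <- function(train, t) {
  stopifnot(inherits(train, "pulse_train"))
  if (train$count == 0) return(numeric(length(t)))
  period <- 1000 / train$frequency
  rel <- t - train$onset
  k <- floor(rel / period)
  in_pulse <- rel >= 0 & k < train$count & (rel - k * period) < train$width
  ifelse(in_pulse, train$amplitude, 0)
}
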