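#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF: a gamma density peaking near 6 s minus a scaled gamma
#' undershoot peaking near 16 s (shape/rate 6/1 and 16/1, undershoot ratio
#' 1/6). The sampled kernel is normalised to unit sum so that convolving a
#' unit-height boxcar yields a plateau of 1 and GLM betas stay in the input
#' signal's units.
#'
#' @param tr_s sampling interval in seconds.
#' @param duration_s length of the sampled kernel in seconds (default 32).
#' @return Numeric vector of HRF values sampled at `tr_s`.
#' @export
#' @examples
#' h <- hrf_double_gamma(2)
#' which.max(h)  # peak near 6 s
hrf_double_gamma <- function(tr_s, duration_s = 32) {
  stopifnot(tr_s > 0, duration_s > tr_s)
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Convolve a stimulus time course with the canonical HRF
#'
#' @param x stimulus vector sampled at `tr_s` (e.g. a unit-height boxcar).
#' @param tr_s sampling interval in seconds.
#' @return Vector of `length(x)` convolved values.
#' @export
hrf_convolve <- function(x, tr_s) {
  h <- hrf_double_gamma(tr_s)
  out <- stats::convolve(x, rev(h), type = "open")
  out[seq_along(x)]
}

# Unit-height boxcar over [onset, onset + duration) seconds sampled at frame
# start times 0, tr, 2 tr, ...; frames whose start time falls inside a block
# are 1.
boxcar <- function(onsets_s, durations_s, tr_s, frame_count) {
  t0 <- (seq_len(frame_count) - 1) * tr_s
  x <- numeric(frame_count)
  for (b in seq_along(onsets_s)) {
    x[t0 >= onsets_s[b] & t0 < onsets_s[b] + durations_s[b]] <- 1
  }
  x
}
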