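#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma BOLD impulse response (response gamma with shape 6,
#' scale 1 s; undershoot gamma with shape 16, scale 1 s; undershoot ratio
#' 1/6), the kernel conventionally called the "canonical HRF".
#'
#' @param t time in seconds (vector, >= 0 values contribute).
#' @param peak_delay,under_delay gamma shape parameters (seconds to peak /
#'   undershoot for unit scale).
#' @param peak_disp,under_disp gamma scale (dispersion) parameters, seconds.
#' @param ratio undershoot amplitude relative to the peak gamma.
#' @return numeric vector of HRF values (unnormalised).
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, under_delay = 16,
                             peak_disp = 1, under_disp = 1, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = under_delay / under_disp,
                          scale = under_disp)
  h[t < 0] <- 0
  h
}

# boxcar sampled at TR for the given blocks (0-based half-open volume bins)
boxcar_regressor <- function(onsets, durations, n_volumes, tr) {
  box <- numeric(n_volumes)
  for (i in seq_along(onsets)) {
    v0 <- ceiling(onsets[i] / tr - 1e-9)
    v1 <- floor((onsets[i] + durations[i]) / tr + 1e-9)
    if (v1 > v0) box[(v0 + 1):min(v1, n_volumes)] <- 1
  }
  box
}

# convolve a boxcar with the canonical HRF, sampled at TR.  The kernel is
# normalised to unit area so a sustained block plateaus at the boxcar height:
# planted amplitudes keep their BOLD-unit meaning.
convolve_hrf <- function(box, tr, hrf_length = 32) {
  h <- hrf_double_gamma(seq(0, hrf_length, by = tr))
  h <- h / sum(h)
  n <- length(box)
  out <- stats::convolve(box, rev(h), type = "open")[seq_len(n)]
  out
}

#' Task regressor for a blocked design
#'
#' HRF-convolved boxcar over the blocks of the given condition(s).
#'
#' @param design a [session_design()].
#' @param conditions character vector of condition labels to include.
#' @return numeric vector of length `n_volumes`.
#' @export
condition_regressor <- function(design, conditions) {
  b <- design$blocks[design$blocks$condition %in% conditions, , drop = FALSE]
  a <- design$acquisition
  box <- boxcar_regressor(b$onset, b$duration, a$n_volumes, a$tr)
  convolve_hrf(box, a$tr)
}
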