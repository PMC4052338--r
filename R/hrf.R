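#' Canonical double-gamma hemodynamic response
#'
#' Parameters of the canonical difference-of-gammas HRF shared by the neural
#' observation model and the GLM: a peak gamma minus a scaled undershoot
#' gamma. Defaults: peak delay 6 s, undershoot delay 16 s, both dispersions
#' 1 s, peak:undershoot ratio 6, kernel length 32 s.
#'
#' @param peak_delay_s,undershoot_delay_s Delays (s) of the two gammas.
#' @param peak_dispersion_s,undershoot_dispersion_s Dispersions (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel support in seconds (>= 24 s).
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                     ratio = 6, length_s = 32) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0,
            peak_dispersion_s > 0, undershoot_dispersion_s > 0,
            ratio > 0)
  if (length_s < 24)
    stop("HRF kernel length must be at least 24 s", call. = FALSE)
  structure(
    list(peak_delay_s = peak_delay_s,
         undershoot_delay_s = undershoot_delay_s,
         peak_dispersion_s = peak_dispersion_s,
         undershoot_dispersion_s = undershoot_dispersion_s,
         ratio = ratio, length_s = length_s),
    class = "hrf_spec"
  )
}

#' Sample the HRF kernel on a micro-time grid
#'
#' @param spec An [hrf_spec()].
#' @param dt_s Sampling step in seconds.
#' @return Numeric kernel, peak-normalized to 1; integrates to a positive
#'   value.
#' @export
hrf_kernel <- function(spec, dt_s) {
  stopifnot(inherits(spec, "hrf_spec"), dt_s > 0)
  t <- seq(0, spec$length_s, by = dt_s)
  h <- dgamma(t, shape = spec$peak_delay_s / spec$peak_dispersion_s,
              scale = spec$peak_dispersion_s) -
    dgamma(t, shape = spec$undershoot_delay_s / spec$undershoot_dispersion_s,
           scale = spec$undershoot_dispersion_s) / spec$ratio
  h / max(h)
}
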