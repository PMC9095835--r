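#' Canonical frequency band table
#'
#' The seven analysis bands used throughout the pipeline: delta 2-3.5,
#' theta 3.5-7.5, alpha1 8-10, alpha2 10-12.5, beta 13-30, gamma1 30-55 and
#' gamma2 65-90 Hz. Bands are half-open intervals `[low, high)` on the 0.5 Hz
#' analysis grid, so a grid frequency belongs to at most one band; the
#' 55-65 Hz line-noise notch and the other inter-band gaps (7.5-8, 12.5-13,
#' 55-65, >= 90 Hz) belong to no band and are excluded from "total power
#' across all defined bands".
#'
#' @return A data.frame with columns `band` (ordered factor levels in the
#'   canonical order), `low`, `high` (Hz) and `center` (Hz, midpoint).
#' @examples
#' frequency_bands()
#' @export
frequency_bands <- function() {
  data.frame(
    band = band_names(),
    low = c(2, 3.5, 8, 10, 13, 30, 65),
    high = c(3.5, 7.5, 10, 12.5, 30, 55, 90),
    center = c(2.75, 5.5, 9, 11.25, 21.5, 42.5, 77.5),
    stringsAsFactors = FALSE
  )
}

#' Canonical band names in order
#' @return Character vector of the seven band labels.
#' @export
band_names <- function() {
  c("delta", "theta", "alpha1", "alpha2", "beta", "gamma1", "gamma2")
}

#' Grid frequencies belonging to a band
#'
#' Half-open membership `low <= f < high` on an arbitrary frequency grid.
#'
#' @param freqs numeric vector of grid frequencies (Hz)
#' @param low,high band edges (Hz)
#' @return logical vector marking member frequencies
#' @keywords internal
band_mask <- function(freqs, low, high) {
  freqs >= low - 1e-9 & freqs < high - 1e-9
}
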