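#' Hemodynamic response function specification
#'
#' The canonical double-gamma HRF: a gamma-density peak minus a scaled
#' gamma-density undershoot,
#' \deqn{h(t) = g(t; \delta_p/\sigma_p, \sigma_p) - r \, g(t; \delta_u/\sigma_u, \sigma_u)}
#' where \eqn{g(t; k, \theta)} is the gamma density with shape \eqn{k} and
#' scale \eqn{\theta}. Defaults are the field-standard peak delay 6 s,
#' undershoot delay 16 s, dispersions 1 s and undershoot ratio 1/6, which
#' put the response maximum near 5 s. The response is normalized so that
#' its maximum over a dense grid equals 1.
#'
#' @param peak_delay,undershoot_delay delays in seconds (`> 0`); the gamma
#'   shapes are `delay / dispersion`.
#' @param peak_dispersion,undershoot_dispersion dispersions in seconds (`> 0`).
#' @param undershoot_ratio relative amplitude of the undershoot (`>= 0`).
#' @return An object of class `hrf_spec`.
#' @examples
#' spec <- hrf_spec()
#' t <- seq(0, 30, by = 0.1)
#' h <- sample_hrf(spec, t)
#' t[which.max(h)]  # about 5 s
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6) {
  if (peak_delay <= 0 || undershoot_delay <= 0)
    stop("HRF delays must be positive")
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0)
    stop("HRF dispersions must be positive")
  if (undershoot_ratio < 0)
    stop("undershoot_ratio must be >= 0")
  spec <- structure(list(kind = "double-gamma",
                         peak_delay = peak_delay,
                         undershoot_delay = undershoot_delay,
                         peak_dispersion = peak_dispersion,
                         undershoot_dispersion = undershoot_dispersion,
                         undershoot_ratio = undershoot_ratio,
                         normalize = "peak-to-one"),
                    class = "hrf_spec")
  spec$peak_value <- hrf_raw_peak(spec)
  spec
}

hrf_raw <- function(spec, t) {
  stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                scale = spec$peak_dispersion) -
    spec$undershoot_ratio *
      stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                    scale = spec$undershoot_dispersion)
}

# Peak over a dense grid, used to scale the maximum response to one.
hrf_raw_peak <- function(spec) {
  tmax <- max(50, 3 * spec$undershoot_delay)
  grid <- seq(0, tmax, by = 0.001)
  max(hrf_raw(spec, grid))
}

#' Sample the HRF on a time grid
#'
#' @param spec an [hrf_spec].
#' @param t numeric vector of times in seconds (`>= 0`).
#' @return `h(t)`, peak-normalized to a maximum of 1 (over a dense grid).
#' @export
sample_hrf <- function(spec, t) {
  stopifnot(inherits(spec, "hrf_spec"))
  if (any(t < 0)) stop("HRF sample times must be >= 0")
  peak <- spec$peak_value %||% hrf_raw_peak(spec)
  hrf_raw(spec, t) / peak
}
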