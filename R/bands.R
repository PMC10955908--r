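#' Canonical LFP frequency band scheme
#'
#' Returns the ordered set of canonical subthalamic LFP frequency bands used as
#' classifier features: delta (0-3 Hz), theta (3-7 Hz), alpha (7-13 Hz),
#' low beta (13-20 Hz), high beta (20-30 Hz), low gamma (30-90 Hz),
#' high gamma (90-200 Hz) and high-frequency oscillations (HFO, 200-350 Hz).
#' Band edges are half-open `[f_low, f_high)` so the bands partition the axis.
#'
#' When `fs` is below 700 Hz the scheme is truncated at the Nyquist frequency
#' `fs/2`: bands lying entirely above Nyquist are dropped and a band straddling
#' it is clipped. At 250 Hz this yields seven bands ending with high gamma
#' (90-125 Hz).
#'
#' @param fs Sampling rate in Hz. The default 1024 Hz keeps all eight bands.
#' @return A data.frame with columns `band`, `f_low`, `f_high` (Hz), of class
#'   `band_scheme`.
#' @examples
#' band_scheme()          # 8 bands up to 350 Hz
#' band_scheme(250)       # 7 bands, high gamma clipped to 125 Hz
#' @export
band_scheme <- function(fs = 1024) {
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  full <- data.frame(
    band  = c("delta", "theta", "alpha", "low_beta", "high_beta",
              "low_gamma", "high_gamma", "hfo"),
    f_low  = c(0, 3, 7, 13, 20, 30, 90, 200),
    f_high = c(3, 7, 13, 20, 30, 90, 200, 350),
    stringsAsFactors = FALSE
  )
  nyq <- fs / 2
  keep <- full$f_low < nyq
  sch <- full[keep, , drop = FALSE]
  sch$f_high <- pmin(sch$f_high, nyq)
  rownames(sch) <- NULL
  class(sch) <- c("band_scheme", "data.frame")
  sch
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("Band scheme: %d bands, %g-%g Hz\n",
              nrow(x), min(x$f_low), max(x$f_high)))
  print.data.frame(x, ...)
  invisible(x)
}

validate_band_scheme <- function(scheme, fs = NULL) {
  stopifnot(is.data.frame(scheme),
            all(c("band", "f_low", "f_high") %in% names(scheme)))
  if (any(scheme$f_high <= scheme$f_low))
    stop("band scheme has empty or inverted bands")
  if (nrow(scheme) > 1 &&
      any(scheme$f_low[-1] != scheme$f_high[-nrow(scheme)]))
    stop("band scheme must be contiguous under the half-open convention")
  if (!is.null(fs) && any(scheme$f_high > fs / 2 + 1e-9))
    stop(sprintf("band '%s' exceeds the Nyquist frequency %g Hz",
                 scheme$band[which.max(scheme$f_high)], fs / 2))
  invisible(scheme)
}

#' Sleep stage codes
#'
#' The five raw hypnogram stage codes: `W` (awake), `N1`, `N2`, `N3`
#' (non-REM 1-3) and `R` (REM), in canonical order.
#'
#' @return Character vector of the five stage codes.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")
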