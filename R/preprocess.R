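#' Bipolar derivations from a 4-contact recording
#'
#' Converts the four monopolar DBS contact signals into three sequential
#' bipolar derivations, `LFP01 = C0 - C1`, `LFP12 = C1 - C2`,
#' `LFP23 = C2 - C3`. Any component common to all contacts (reference drift,
#' line or amplifier artifact) cancels exactly.
#'
#' @param session An `lfp_session`, or a samples x 4 numeric matrix.
#' @return A samples x 3 matrix with columns `LFP01`, `LFP12`, `LFP23`.
#' @export
bipolar_derive <- function(session) {
  x <- if (inherits(session, "lfp_session")) session$contacts else as.matrix(session)
  if (ncol(x) != 4)
    stop(sprintf("bipolar derivation requires exactly 4 contacts, got %d",
                 ncol(x)))
  d <- x[, 1:3, drop = FALSE] - x[, 2:4, drop = FALSE]
  colnames(d) <- c("LFP01", "LFP12", "LFP23")
  d
}

#' Select the derivation with peak beta activity
#'
#' Picks the bipolar derivation with maximal mean beta-band (13-30 Hz) Welch
#' power over the whole recording, mirroring clinical contact selection by
#' peak beta-spectrum activity in the STN. Ties (and all-zero inputs) resolve
#' to the first channel in column order.
#'
#' @param derived Samples x channels matrix (e.g. from [bipolar_derive()]).
#' @param fs Sampling rate in Hz.
#' @param band Frequency range in Hz used for selection, default `c(13, 30)`.
#' @return The selected channel as a numeric vector, with attributes
#'   `channel` (its name) and `beta_power` (the per-channel mean band power).
#' @export
select_channel <- function(derived, fs, band = c(13, 30)) {
  derived <- as.matrix(derived)
  if (ncol(derived) < 1) stop("need at least one derivation")
  pw <- vapply(seq_len(ncol(derived)), function(j) {
    sp <- compute_spectrogram(derived[, j], fs)
    sel <- sp$freq >= band[1] & sp$freq < band[2]
    mean(sp$power[, sel])
  }, 0)
  names(pw) <- colnames(derived)
  if (all(pw == 0))
    warning("all channels have zero beta power; selecting the first by order")
  k <- which.max(pw)   # which.max takes the first maximum: fixed-order tie-break
  out <- derived[, k]
  attr(out, "channel") <- colnames(derived)[k]
  attr(out, "beta_power") <- pw
  out
}

#' Fourier-domain resampling
#'
#' Resamples a signal to a lower rate by exact spectral truncation: the FFT of
#' the full signal is cut at the new Nyquist frequency and inverted at the new
#' length. This is anti-aliased by construction (content above `target_fs/2`
#' is removed exactly) and leaves passband tones untouched.
#'
#' @param x Numeric signal vector sampled at `fs`.
#' @param fs Original sampling rate (Hz).
#' @param target_fs Target rate (Hz), strictly below `fs`;
#'   `length(x) * target_fs / fs` must be a whole number (whole-second
#'   signals with integer rates always satisfy this).
#' @return Numeric vector of length `length(x) * target_fs / fs`.
#' @export
resample_signal <- function(x, fs, target_fs) {
  if (target_fs >= fs) stop("target_fs must be strictly below fs")
  n <- length(x)
  m_real <- n * target_fs / fs
  m <- round(m_real)
  if (abs(m - m_real) > 1e-8)
    stop("length(x) * target_fs / fs must be a whole number of samples")
  X <- stats::fft(x)
  keep <- m %/% 2                       # positive-frequency bins kept
  Y <- complex(length.out = m)
  Y[1] <- X[1]
  Y[2:(keep + 1)] <- X[2:(keep + 1)]
  Y[m:(m - keep + 2)] <- X[n:(n - keep + 2)]
  if (m %% 2 == 0) Y[keep + 1] <- Re(X[keep + 1])  # new Nyquist bin made real
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Downsample a session or signal with Nyquist-aware band truncation
#'
#' Anti-aliased resampling to `target_fs` via [resample_signal()]. For a
#' session, all four contacts are resampled and the returned session carries
#' the new rate, so any subsequent [band_scheme()] call truncates the feature
#' bands at the new Nyquist frequency (e.g. at 250 Hz only seven bands remain,
#' ending with high gamma 90-125 Hz).
#'
#' @param x An `lfp_session` or a numeric signal vector.
#' @param target_fs Target sampling rate in Hz (e.g. 125, 250, 400, 700).
#' @param fs Current rate; required only when `x` is a bare vector.
#' @return Same type as `x`, at `target_fs`.
#' @export
downsample <- function(x, target_fs, fs = NULL) {
  if (inherits(x, "lfp_session")) {
    if (target_fs >= x$fs) stop("target_fs must be strictly below fs")
    contacts <- apply(x$contacts, 2, resample_signal, fs = x$fs,
                      target_fs = target_fs)
    colnames(contacts) <- colnames(x$contacts)
    x$contacts <- contacts
    x$fs <- target_fs
    x
  } else {
    if (is.null(fs)) stop("fs is required when downsampling a bare signal")
    resample_signal(x, fs, target_fs)
  }
}

#' Time-evolving power spectral density of one channel
#'
#' Estimates a spectrogram with 15-s time and 0.5-Hz frequency resolution:
#' the PSD of 2-s Hamming windows sliding by 1 s (hence 0.5 Hz bin spacing)
#' is averaged within consecutive non-overlapping 15-s frames (the 15 windows
#' whose start falls inside each frame). Frames missing any window (at the
#' recording end) are dropped. PSD scaling is one-sided density
#' (power / Hz), so the integral over frequency recovers the signal variance.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate (Hz); windows are `2 * fs` samples.
#' @return Object of class `spectrogram`: list with `power`
#'   (frames x frequency bins, non-negative), `freq` (Hz, spacing 0.5),
#'   `frame_seconds = 15` and `fs`.
#' @export
compute_spectrogram <- function(x, fs) {
  n <- length(x)
  win_len <- as.integer(2 * fs)
  if (n < win_len) stop("signal shorter than one 2-s analysis window")
  hop <- as.integer(fs)
  w <- signal::hamming(win_len)
  scale <- 2 / (fs * sum(w^2))          # one-sided density normalization
  starts <- seq(0L, n - win_len, by = hop)        # sample offsets, 1 Hz grid
  nwin <- length(starts)
  nbin <- win_len %/% 2 + 1L
  # windows per 15-s frame: those starting in [15k, 15k+15) seconds
  nframe <- nwin %/% 15L
  if (nframe == 0) stop("signal shorter than one 15-s frame")
  power <- matrix(0, nframe, nbin)
  chunk <- 512L
  psd_acc <- matrix(0, nbin, nwin)
  for (lo in seq(1L, nwin, by = chunk)) {
    hi <- min(lo + chunk - 1L, nwin)
    seg <- vapply(starts[lo:hi], function(s) x[(s + 1L):(s + win_len)] * w,
                  numeric(win_len))
    X <- stats::mvfft(seg)[seq_len(nbin), , drop = FALSE]
    p <- scale * (Re(X)^2 + Im(X)^2)
    p[1, ] <- p[1, ] / 2                # DC not doubled
    p[nbin, ] <- p[nbin, ] / 2          # Nyquist not doubled
    psd_acc[, lo:hi] <- p
  }
  for (k in seq_len(nframe))
    power[k, ] <- rowMeans(psd_acc[, ((k - 1L) * 15L + 1L):(k * 15L),
                                   drop = FALSE])
  structure(list(power = power,
                 freq = seq(0, fs / 2, by = 0.5),
                 frame_seconds = 15, fs = fs),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d x 15-s frames, %d bins (0-%g Hz at 0.5 Hz)\n",
              nrow(x$power), length(x$freq), max(x$freq)))
  invisible(x)
}

#' Per-epoch band powers
#'
#' Averages spectrogram PSD bins into canonical band powers per 30-s epoch:
#' for each epoch (two consecutive 15-s frames) and band, the mean of PSD bins
#' with `f_low <= f < f_high`. The DC bin (0 Hz) is excluded from the delta
#' band, since DC offset reflects referencing, not physiology. Epochs whose
#' frames are incomplete (recording tail) are dropped and reported via the
#' `dropped` attribute.
#'
#' @param spec A [compute_spectrogram()] result.
#' @param scheme A [band_scheme()]; all bands must lie at or below Nyquist and
#'   contain at least one retained bin.
#' @param hypnogram A [hypnogram()] aligned with the recording start.
#' @return Data.frame with `epoch` (0-based), `stage`, and one column per
#'   band; attribute `dropped` lists dropped epoch indices.
#' @export
band_powers <- function(spec, scheme, hypnogram) {
  stopifnot(inherits(spec, "spectrogram"), inherits(hypnogram, "hypnogram"))
  validate_band_scheme(scheme, fs = spec$fs)
  ne <- length(hypnogram$stages)
  nframe <- nrow(spec$power)
  complete <- which(2 * seq_len(ne) <= nframe)  # epochs with both frames
  dropped <- setdiff(seq_len(ne), complete) - 1L
  bins <- lapply(seq_len(nrow(scheme)), function(i) {
    sel <- which(spec$freq >= scheme$f_low[i] & spec$freq < scheme$f_high[i] &
                   spec$freq > 0)               # DC bin excluded
    if (!length(sel))
      stop(sprintf("band '%s' contains no frequency bins after truncation",
                   scheme$band[i]))
    sel
  })
  out <- matrix(0, length(complete), nrow(scheme),
                dimnames = list(NULL, scheme$band))
  for (k in seq_along(complete)) {
    e <- complete[k]
    fr <- spec$power[c(2 * e - 1L, 2 * e), , drop = FALSE]
    out[k, ] <- vapply(bins, function(sel) mean(fr[, sel]), 0)
  }
  res <- data.frame(epoch = complete - 1L,
                    stage = hypnogram$stages[complete],
                    stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(out))
  attr(res, "dropped") <- dropped
  res
}

#' Per-subject feature normalization
#'
#' Normalizes each band-power feature independently per subject: subtract the
#' subject's mean and divide by the subject's standard deviation
#' (`scale = "sd"`, the default z-score) or variance (`scale = "var"`).
#' Normalization statistics are returned so they can be reused on held-out
#' epochs of the same subject (train-only statistics avoid leakage).
#' Zero-variance features fall back to a divisor of 1 with a warning.
#'
#' @param features Data.frame with columns `subject`, `stage`, and band
#'   columns (as from [extract_features()]).
#' @param stats Optional statistics from a previous call (its `stats`
#'   attribute), applied as-is instead of being recomputed.
#' @param scale `"sd"` (default) or `"var"`.
#' @param log_power If `TRUE`, features are log10-transformed before
#'   normalization.
#' @return The data.frame with band columns normalized; attribute `stats`
#'   holds per-subject, per-band `center` and `scale`.
#' @export
normalize_features <- function(features, stats = NULL,
                               scale = c("sd", "var"), log_power = FALSE) {
  scale <- match.arg(scale)
  bands <- feature_bands(features)
  out <- features
  if (log_power)
    for (b in bands) out[[b]] <- log10(pmax(out[[b]], .Machine$double.xmin))
  if (is.null(stats)) {
    stats <- list(scale_type = scale, log_power = log_power, subjects = list())
    for (s in unique(out$subject)) {
      rows <- out$subject == s
      if (sum(rows) < 2)
        stop(sprintf("subject %s has fewer than 2 epochs", s))
      ctr <- vapply(bands, function(b) mean(out[[b]][rows]), 0)
      scl <- vapply(bands, function(b) {
        v <- if (scale == "sd") stats::sd(out[[b]][rows])
             else stats::var(out[[b]][rows])
        v
      }, 0)
      zero <- !is.finite(scl) | scl == 0
      if (any(zero)) {
        warning(sprintf("zero-variance feature(s) %s for subject %s; divisor 1",
                        paste(bands[zero], collapse = ", "), s))
        scl[zero] <- 1
      }
      stats$subjects[[as.character(s)]] <- list(center = ctr, scale = scl)
    }
  } else {
    if (!identical(stats$scale_type, scale) && !missing(scale))
      scale <- stats$scale_type
  }
  for (s in unique(out$subject)) {
    st <- stats$subjects[[as.character(s)]]
    if (is.null(st))
      stop(sprintf("no stored normalization statistics for subject %s", s))
    rows <- out$subject == s
    for (b in bands)
      out[[b]] <- replace(out[[b]], rows,
                          (out[[b]][rows] - st$center[[b]]) / st$scale[[b]])
  }
  attr(out, "stats") <- stats
  out
}

# Band columns of a feature data.frame = everything except the metadata.
feature_bands <- function(features) {
  setdiff(names(features), c("subject", "epoch", "stage"))
}

#' Extract raw band-power features from a session
#'
#' Runs the full preprocessing chain on one recording: optional anti-aliased
#' downsampling, sequential bipolar referencing, selection of the derivation
#' with peak beta activity, Hamming-window spectrogram (15 s x 0.5 Hz) and
#' per-epoch band powers under the Nyquist-truncated [band_scheme()].
#' Features are *not* normalized here; apply [normalize_features()] with
#' training-split statistics to avoid leakage.
#'
#' @param session An `lfp_session`.
#' @param fs_target Optional downsampling rate (Hz) applied before
#'   preprocessing.
#' @param scheme Optional band scheme override; default
#'   `band_scheme(fs)` at the working rate.
#' @return Data.frame with `subject`, `epoch`, `stage` and one column per
#'   band (raw power, uV^2/Hz); attribute `channel` names the selected
#'   derivation.
#' @export
extract_features <- function(session, fs_target = NULL, scheme = NULL) {
  stopifnot(inherits(session, "lfp_session"))
  if (!is.null(fs_target)) session <- downsample(session, fs_target)
  fs <- session$fs
  if (is.null(scheme)) scheme <- band_scheme(fs)
  der <- bipolar_derive(session)
  ch <- select_channel(der, fs)
  sp <- compute_spectrogram(as.numeric(ch), fs)
  bp <- band_powers(sp, scheme, session$hypnogram)
  out <- cbind(data.frame(subject = session$subject_id,
                          stringsAsFactors = FALSE), bp)
  attr(out, "channel") <- attr(ch, "channel")
  attr(out, "dropped") <- attr(bp, "dropped")
  out
}

#' Extract features for a whole cohort
#'
#' Applies [extract_features()] to each session and row-binds the results.
#'
#' @param sessions List of `lfp_session` objects.
#' @param fs_target Optional downsampling rate (Hz).
#' @return Combined raw feature data.frame.
#' @export
extract_cohort_features <- function(sessions, fs_target = NULL) {
  do.call(rbind, lapply(sessions, extract_features, fs_target = fs_target))
}
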