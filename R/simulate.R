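#' Default sleep-stage transition matrix
#'
#' A 5-state Markov transition matrix over 30-s epochs constructed as
#' `s * I + (1 - s) * 1 %o% pi`, i.e. with probability `s` the stage persists
#' and with probability `1 - s` it redraws from the target stationary
#' distribution `pi`. By construction `pi` is exactly the chain's stationary
#' distribution, so prevalences are controlled analytically. The default `pi`
#' emulates the Parkinsonian pattern: much NREM2, very scarce NREM3
#' (deep restorative sleep is strongly reduced in PD), moderate wake and REM.
#'
#' @param pi Target stationary distribution over `sleep_stages()`; must sum
#'   to 1. Default `c(W = .30, N1 = .10, N2 = .45, N3 = .03, R = .12)`.
#' @param persist Self-persistence probability `s` in `[0, 1)`; default 0.92
#'   gives mean stage bouts of about 6 minutes.
#' @return A 5 x 5 row-stochastic matrix with stage dimnames.
#' @seealso [stationary_distribution()]
#' @export
default_transition_matrix <- function(pi = c(W = 0.30, N1 = 0.10, N2 = 0.45,
                                             N3 = 0.03, R = 0.12),
                                      persist = 0.92) {
  stopifnot(length(pi) == 5, abs(sum(pi) - 1) < 1e-8, all(pi >= 0),
            persist >= 0, persist < 1)
  stages <- sleep_stages()
  P <- persist * diag(5) + (1 - persist) * matrix(rep(pi, each = 5), 5)
  dimnames(P) <- list(stages, stages)
  P
}

#' Default stage-dependent band-power profiles
#'
#' Mean log10 band-power offsets (relative to a neutral epoch) for each sleep
#' stage and canonical frequency band. These are free simulation parameters,
#' not measurements; they plant a physiologically plausible structure:
#' prominent low-gamma (and secondarily high-gamma) elevation while awake,
#' delta dominance deepening from NREM2 to NREM3 with suppressed beta/gamma,
#' theta elevation in NREM1 and REM, and distinct high-beta levels separating
#' NREM1, NREM2&3 and REM.
#'
#' @return A 5 x 8 numeric matrix, rows `sleep_stages()`, columns the bands of
#'   [band_scheme()].
#' @export
default_stage_profiles <- function() {
  bands <- band_scheme()$band
  m <- rbind(
    W  = c(-0.30, -0.10,  0.20,  0.10,  0.10,  0.70,  0.35,  0.10),
    N1 = c( 0.10,  0.45, -0.30,  0.10,  0.30, -0.15, -0.10, -0.10),
    N2 = c( 0.50,  0.20, -0.20,  0.30, -0.25, -0.30, -0.20, -0.20),
    N3 = c( 0.90,  0.30, -0.30, -0.20, -0.50, -0.50, -0.40, -0.30),
    R  = c(-0.35,  0.10,  0.05, -0.30,  0.60,  0.15, -0.15, -0.10)
  )
  colnames(m) <- bands
  m
}

default_band_rms <- function() {
  c(delta = 0.6, theta = 0.4, alpha = 0.3, low_beta = 0.25, high_beta = 0.25,
    low_gamma = 0.3, high_gamma = 0.25, hfo = 0.2)
}

# Slight spatial gradient so the middle bipolar pair carries the strongest
# beta, emulating contact selection by peak beta activity in the STN.
default_contact_gains <- function() {
  bands <- band_scheme()$band
  g <- matrix(1, 4, length(bands), dimnames = list(paste0("C", 0:3), bands))
  g[, c("low_beta", "high_beta")] <- c(0.8, 1.2, 1.2, 0.8)
  g
}

#' Simulation configuration for synthetic STN LFP sleep recordings
#'
#' Bundles every parameter of the synthetic cohort: number of subjects,
#' session length, sampling rate, the stage transition matrix, stage-dependent
#' band-power profiles, 1/f background, per-contact gains and the common-mode
#' artifact level.
#'
#' @param n_subjects Number of subjects in the cohort (default 10).
#' @param session_hours Session length in hours (default 8, a nocturnal
#'   recording).
#' @param fs Sampling rate in Hz; must exceed 700 Hz so all eight bands
#'   (up to 350 Hz) are representable. Default 1024.
#' @param transition_matrix Row-stochastic 5 x 5 stage transition matrix per
#'   30-s epoch.
#' @param stage_profiles 5 x n_bands matrix of mean log10 band-power offsets.
#' @param jitter_sd Per-epoch, per-band log10 power jitter SD (default 0.1).
#' @param background_slope Exponent of the 1/f^slope Gaussian background
#'   (default 1.5).
#' @param band_rms Baseline RMS of each narrowband component relative to the
#'   unit-RMS background.
#' @param contact_gains 4 x n_bands multiplicative gains per contact.
#' @param common_mode_fraction Common-mode artifact RMS as a fraction of the
#'   mean contact RMS (default 0.2), injected identically on all 4 contacts.
#' @param crossfade_s Crossfade duration (s) across epoch boundaries
#'   (default 0.5).
#' @param seed Integer base seed; fixed seed implies bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10, session_hours = 8, fs = 1024,
                       transition_matrix = default_transition_matrix(),
                       stage_profiles = default_stage_profiles(),
                       jitter_sd = 0.1,
                       background_slope = 1.5,
                       band_rms = default_band_rms(),
                       contact_gains = default_contact_gains(),
                       common_mode_fraction = 0.2,
                       crossfade_s = 0.5,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, session_hours > 0, fs > 0, jitter_sd >= 0,
            common_mode_fraction >= 0, crossfade_s >= 0)
  P <- as.matrix(transition_matrix)
  if (nrow(P) != 5 || ncol(P) != 5 || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition_matrix must be a 5 x 5 row-stochastic matrix")
  dimnames(P) <- list(sleep_stages(), sleep_stages())
  profiles <- as.matrix(stage_profiles)
  if (nrow(profiles) != 5)
    stop("stage_profiles must have one row per sleep stage")
  bands <- band_scheme()$band
  if (is.null(colnames(profiles))) colnames(profiles) <- bands[seq_len(ncol(profiles))]
  if (!all(bands %in% colnames(profiles)))
    stop("stage_profiles must provide an offset for every band of the scheme")
  if (fs <= 2 * max(band_scheme()$f_high))
    stop(sprintf("fs = %g Hz cannot represent bands up to %g Hz (need fs > %g)",
                 fs, max(band_scheme()$f_high), 2 * max(band_scheme()$f_high)))
  cfg <- list(n_subjects = as.integer(n_subjects),
              session_hours = session_hours, fs = fs,
              transition_matrix = P, stage_profiles = profiles,
              jitter_sd = jitter_sd, background_slope = background_slope,
              band_rms = band_rms, contact_gains = as.matrix(contact_gains),
              common_mode_fraction = common_mode_fraction,
              crossfade_s = crossfade_s, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic LFP cohort config: %d subjects x %g h at %g Hz\n",
              x$n_subjects, x$session_hours, x$fs))
  cat("Stationary stage distribution:\n")
  print(round(stationary_distribution(x$transition_matrix), 3))
  invisible(x)
}

#' Stationary distribution of a stage transition matrix
#'
#' Computes the stationary distribution of a row-stochastic Markov matrix by
#' eigen-decomposition of its transpose (left eigenvector of eigenvalue 1).
#'
#' @param P Row-stochastic square matrix.
#' @return Named numeric vector summing to 1.
#' @export
stationary_distribution <- function(P) {
  P <- as.matrix(P)
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("P must be row-stochastic")
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  names(v) <- rownames(P)
  v
}

#' Simulate a hypnogram
#'
#' Draws a Markov-chain sequence of 30-s sleep-stage labels from the
#' configuration's transition matrix, starting awake.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`); fixed seed gives an
#'   identical label sequence on repeat calls.
#' @param start Initial stage (default `"W"`).
#' @return Object of class `hypnogram`: list with `stages` (character vector
#'   of codes, one per 30-s epoch) and `epoch_seconds = 30`.
#' @export
simulate_hypnogram <- function(config, seed = config$seed, start = "W") {
  stopifnot(inherits(config, "sim_config"), start %in% sleep_stages())
  n_epochs <- floor(config$session_hours * 3600 / 30)
  P <- config$transition_matrix
  stages <- sleep_stages()
  lab <- character(n_epochs)
  with_seed(seed, {
    cur <- match(start, stages)
    for (e in seq_len(n_epochs)) {
      lab[e] <- stages[cur]
      cur <- sample.int(5L, 1L, prob = P[cur, ])
    }
  })
  hypnogram(lab)
}

#' Construct a hypnogram object
#'
#' @param stages Character vector of stage codes (one per 30-s epoch), each in
#'   `sleep_stages()`.
#' @param epoch_seconds Epoch length, fixed at 30 s.
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_seconds = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), sleep_stages())
  if (length(bad))
    stop(sprintf("unknown sleep stage label(s): %s", paste(bad, collapse = ", ")))
  if (epoch_seconds != 30) stop("epoch_seconds is fixed at 30")
  structure(list(stages = stages, epoch_seconds = 30), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = sleep_stages()))
  cat(sprintf("Hypnogram: %d epochs of 30 s (%.1f h)\n",
              length(x$stages), length(x$stages) / 120))
  print(round(prop.table(tab), 3))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

# Gaussian noise with power spectral density proportional to f^-slope,
# synthesized in the frequency domain, normalized to unit variance.
# slope = 0 reduces to white noise.
spectral_noise <- function(n, slope) {
  if (slope == 0) return(rnorm(n))
  m <- n %/% 2
  f <- seq_len(m) # positive frequency bins (arbitrary units)
  mag <- f^(-slope / 2)
  # random phases/amplitudes for positive freqs, Hermitian symmetry for real ifft
  re <- rnorm(m) * mag; im <- rnorm(m) * mag
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(m + 1)] <- spec
  full[n:(n - m + 2)] <- Conj(spec[seq_len(m - 1)])
  if (n %% 2 == 0) full[m + 1] <- complex(real = re[m], imaginary = 0)
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / sqrt(drop(crossprod(x)) / n)     # zero-mean by construction (no DC term)
}

# Butterworth band-pass designed directly in second-order sections.
# The single-polynomial form from signal::butter is numerically unstable for
# narrow low-frequency bands (rounded poles drift outside the unit circle),
# so the analog prototype poles are band-transformed and bilinear-mapped into
# biquads, which stay stable. `lo`/`hi` are normalized to Nyquist = 1.
butter_sos <- function(lo, hi, order = 4) {
  stopifnot(lo > 0, hi > lo, hi < 1)
  Wl <- tan(pi * lo / 2); Wh <- tan(pi * hi / 2)   # prewarped analog edges
  w0sq <- Wl * Wh; bw <- Wh - Wl
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # analog LP poles
  t <- 0.5 * bw * p
  pb <- c(t + sqrt(t^2 - w0sq), t - sqrt(t^2 - w0sq))   # LP -> BP poles
  zd <- (1 + pb) / (1 - pb)                             # bilinear transform
  if (any(Mod(zd) >= 1)) stop("unstable band-pass design")
  # pair conjugate poles into real-coefficient biquads; zeros at z = +/-1
  zp <- zd[Im(zd) > 0]
  sos <- lapply(zp, function(z)
    list(b = c(1, 0, -1), a = c(1, -2 * Re(z), Mod(z)^2)))
  # unit gain at the digital centre frequency
  wc <- 2 / pi * atan(sqrt(w0sq))
  zc <- exp(1i * pi * wc)
  H <- prod(vapply(sos, function(s)
    (zc^2 - 1) / (zc^2 + s$a[2] * zc + s$a[3]), complex(1)))
  sos[[1]]$b <- sos[[1]]$b / Mod(H)
  sos
}

sos_filter <- function(sos, x) {
  sos_filter_cpp(vapply(sos, `[[`, numeric(3), "b"),
                 vapply(sos, `[[`, numeric(3), "a"), x)
}

#' Synthesize a multi-contact LFP recording from a hypnogram
#'
#' Generates a 4-contact recording whose spectral content follows the
#' hypnogram: each contact is a unit-RMS 1/f^slope Gaussian background plus,
#' per frequency band, band-pass-filtered white noise (4th-order Butterworth)
#' whose epoch-wise amplitude follows the active stage's log-power offset plus
#' jitter. Epoch transitions are crossfaded to avoid edge discontinuities. A
#' common-mode component (identical on all contacts, at
#' `common_mode_fraction` of the mean contact RMS) is added last, so bipolar
#' referencing is consequential. Output is bit-identical for a fixed seed.
#'
#' @param hypnogram A [hypnogram()].
#' @param config A [sim_config()]; `config$fs` must support all configured
#'   bands (`f_high <= fs/2`).
#' @param subject_id Subject identifier stored in the session.
#' @param seed Integer seed (default `config$seed`).
#' @return Object of class `lfp_session`: list with `subject_id`, `fs`,
#'   `contacts` (n x 4 matrix, columns `C0..C3`) and `hypnogram`.
#' @export
synthesize_lfp <- function(hypnogram, config, subject_id = "S01",
                           seed = config$seed) {
  stopifnot(inherits(hypnogram, "hypnogram"), inherits(config, "sim_config"))
  fs <- config$fs
  scheme <- band_scheme(fs)
  if (any(scheme$f_high > fs / 2))
    stop("requested band exceeds the Nyquist frequency fs/2")
  bands <- scheme$band
  ne <- length(hypnogram$stages)
  epoch_len <- as.integer(30 * fs)
  n <- ne * epoch_len
  stage_idx <- match(hypnogram$stages, sleep_stages())
  fade <- as.integer(round(config$crossfade_s * fs))

  nyq <- fs / 2
  coefs <- lapply(seq_len(nrow(scheme)), function(i)
    butter_sos(max(scheme$f_low[i], 0.25) / nyq,
               min(scheme$f_high[i], nyq * 0.999) / nyq))

  contacts <- matrix(0, n, 4, dimnames = list(NULL, paste0("C", 0:3)))
  with_seed(seed, {
    # epoch x band log10 jitter, shared across contacts (a property of the
    # brain state, not of the sensor)
    jitter <- matrix(rnorm(ne * length(bands), sd = config$jitter_sd),
                     ne, length(bands))
    for (ci in 1:4) {
      bg <- spectral_noise(n, config$background_slope)
      white <- rnorm(n)
      sig <- bg
      for (bi in seq_along(bands)) {
        base <- config$band_rms[[bands[bi]]] * config$contact_gains[ci, bands[bi]]
        if (base <= 0) next
        comp <- sos_filter(coefs[[bi]], white)
        comp <- comp * (base / sqrt(drop(crossprod(comp)) / length(comp)))
        gains <- 10^((config$stage_profiles[stage_idx, bands[bi]] +
                        jitter[, bi]) / 2)
        sig <- sig + apply_epoch_gains(comp, gains, epoch_len, fade)
      }
      contacts[, ci] <- sig
    }
    if (config$common_mode_fraction > 0) {
      cm <- spectral_noise(n, config$background_slope)
      rms <- mean(apply(contacts, 2, stats::sd))
      contacts <- contacts + config$common_mode_fraction * rms * cm
    }
  })
  structure(list(subject_id = subject_id, fs = fs, contacts = contacts,
                 hypnogram = hypnogram),
            class = "lfp_session")
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf("LFP session %s: 4 contacts, %.1f h at %g Hz (%d epochs)\n",
              x$subject_id, nrow(x$contacts) / x$fs / 3600, x$fs,
              length(x$hypnogram$stages)))
  invisible(x)
}

#' Simulate one subject's session (hypnogram + LFP)
#'
#' @param config A [sim_config()].
#' @param subject Subject index (used to derive the per-subject seed and id).
#' @return An `lfp_session`.
#' @export
simulate_session <- function(config, subject = 1L) {
  sid <- sprintf("S%02d", subject)
  hyp <- simulate_hypnogram(config, seed = child_seed(config$seed, subject))
  synthesize_lfp(hyp, config, subject_id = sid,
                 seed = child_seed(config$seed, subject + 1000L))
}

#' Simulate a cohort of sessions
#'
#' @param config A [sim_config()].
#' @return List of `lfp_session`, one per subject.
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects), function(s) simulate_session(config, s))
}
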