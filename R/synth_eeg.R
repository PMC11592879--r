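#' Configuration for the synthetic ictal EEG generator
#'
#' Describes a seizure recording with a planted lateralized energy
#' elevation. Outside the ictal interval homologous channels have equal
#' expected energy; inside it, the focus-side temporal chain carries
#' `energy_ratio` times the contralateral energy and the parasagittal
#' chain carries a halved asymmetry (ratio `1 + (energy_ratio - 1)/2`),
#' reflecting temporal-lobe seizure topography. Midline channels are
#' symmetric throughout.
#'
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz (default 500).
#' @param ictal_interval Numeric `(start_s, end_s)` within `[0, duration]`.
#' @param focus_side `"LEFT"` or `"RIGHT"`.
#' @param energy_ratio Planted focus/contralateral ictal energy ratio (> 0;
#'   values > 1 plant a detectable focus, 1 is symmetric).
#' @param ictal_gain Amplitude gain of the seizure relative to background
#'   (applies to all channels; the asymmetry rides on top of it).
#' @param noise_sd Background signal standard deviation (arbitrary units,
#'   think microvolts).
#' @param band Passband in Hz of the band-limited noise model.
#' @param seed Integer seed; all randomness in [gen_ictal_eeg()] flows
#'   through it.
#' @return An object of class `synth_eeg_config`.
#' @export
synth_eeg_config <- function(duration = 20, fs = 500,
                             ictal_interval = c(5, 15),
                             focus_side = c("LEFT", "RIGHT"),
                             energy_ratio = 4, ictal_gain = 3,
                             noise_sd = 10, band = c(4, 30), seed = 1L) {
  focus_side <- match.arg(focus_side)
  stopifnot(fs > 0, duration > 0, energy_ratio > 0, noise_sd > 0,
            ictal_gain > 0, length(ictal_interval) == 2,
            length(band) == 2, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  if (ictal_interval[1] < 0 || ictal_interval[2] > duration ||
      ictal_interval[1] >= ictal_interval[2]) {
    stop("ictal_interval must satisfy 0 <= start < end <= duration")
  }
  structure(list(n_channels = 18L, fs = fs, duration = duration,
                 ictal_interval = ictal_interval, focus_side = focus_side,
                 energy_ratio = energy_ratio, ictal_gain = ictal_gain,
                 noise_sd = noise_sd, band = band, seed = as.integer(seed)),
            class = "synth_eeg_config")
}

#' Generate a synthetic ictal EEG recording with a planted focus side
#'
#' Each channel is independent band-limited Gaussian noise (Butterworth
#' band-pass of white noise, default 4-30 Hz) modulated by a per-channel
#' amplitude envelope: 1 outside the seizure, and inside it
#' `ictal_gain` times the square root of the channel's planted energy
#' ratio. Expected pair energy ratios over the ictal interval therefore
#' equal the planted ratios exactly; realized ratios fluctuate with
#' finite-sample error.
#'
#' @param cfg A [synth_eeg_config()].
#' @return An `eeg_recording`: list with `signals` (18 x samples matrix,
#'   rownames = montage), `fs`, `channel_names`, `ictal_intervals` (list of
#'   length-2 vectors), and `truth` (the planted `focus_side` and
#'   `energy_ratio`).
#' @export
#' @examples
#' rec <- gen_ictal_eeg(synth_eeg_config(duration = 4, seed = 7))
#' dim(rec$signals)
gen_ictal_eeg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_eeg_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration * cfg$fs)
  chans <- tle_montage()
  bf <- signal::butter(4, cfg$band * 2 / cfg$fs, type = "pass")

  ict <- rep(FALSE, n)
  i0 <- floor(cfg$ictal_interval[1] * cfg$fs) + 1L
  i1 <- min(n, ceiling(cfg$ictal_interval[2] * cfg$fs))
  ict[i0:i1] <- TRUE

  # planted ictal energy ratio per channel relative to its homolog
  pairs <- symmetric_pair_table()
  ratio_of <- setNames(rep(1, 18), chans)
  temporal_r <- cfg$energy_ratio
  parasag_r <- 1 + (cfg$energy_ratio - 1) / 2
  focus_col <- if (cfg$focus_side == "LEFT") "left" else "right"
  other_col <- if (cfg$focus_side == "LEFT") "right" else "left"
  ratio_of[pairs[[focus_col]][1:4]] <- temporal_r
  ratio_of[pairs[[focus_col]][5:8]] <- parasag_r
  ratio_of[pairs[[other_col]]] <- 1

  signals <- matrix(0, nrow = 18, ncol = n, dimnames = list(chans, NULL))
  for (ch in seq_len(18)) {
    x <- signal::filtfilt(bf, rnorm(n))
    env <- rep(1, n)
    env[ict] <- cfg$ictal_gain * sqrt(ratio_of[ch])
    signals[ch, ] <- cfg$noise_sd * env * x
  }

  structure(list(signals = signals, fs = cfg$fs, channel_names = chans,
                 ictal_intervals = list(cfg$ictal_interval),
                 truth = list(focus_side = cfg$focus_side,
                              energy_ratio = cfg$energy_ratio)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d ictal interval(s)\n",
              nrow(x$signals), ncol(x$signals), x$fs, length(x$ictal_intervals)))
  invisible(x)
}
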