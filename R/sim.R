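#' ERP component description
#'
#' Parameterizes one event-related potential component as a half-cycle
#' sinusoidal peak: its signed amplitude (the peak value at the strongest
#' electrode), its frequency (which sets the lobe width to half a cycle),
#' the sample index of the peak center, the maximum latency jitter, and a
#' scalp topography of per-channel gains.
#'
#' @param amplitude Peak value in signal units; sign carries polarity
#'   (negative for N100-like components).
#' @param frequency Component frequency in Hz (> 0); the rendered lobe spans
#'   half a cycle, `round(sampling_rate / (2 * frequency))` samples.
#' @param center_frame 1-based sample index of the peak center.
#' @param jitter_frames Non-negative integer; trial-to-trial latency jitter is
#'   drawn uniformly on `[-jitter_frames, jitter_frames]` (default 5).
#' @param topography Optional numeric vector of per-channel gains in `[-1, 1]`
#'   scaling the component at each electrode. `NULL` (default) resolves at
#'   simulation time to [erp_topography()], an average-referenced
#'   anterior-posterior cosine gradient. A channel-uniform topography is
#'   invisible to node-space-normalized connectivity (see the methods
#'   vignette), so gains should vary across channels.
#'
#' @return An object of class `erp_component`.
#' @seealso [erp_n100()], [erp_p300()], [render_component()]
#' @export
erp_component <- function(amplitude, frequency, center_frame,
                          jitter_frames = 5L, topography = NULL) {
  if (!is.numeric(frequency) || frequency <= 0) {
    stop("`frequency` must be positive", call. = FALSE)
  }
  if (!is.numeric(center_frame) || center_frame < 1 ||
      center_frame != round(center_frame)) {
    stop("`center_frame` must be a positive integer sample index",
         call. = FALSE)
  }
  if (!is.numeric(jitter_frames) || jitter_frames < 0 ||
      jitter_frames != round(jitter_frames)) {
    stop("`jitter_frames` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(amplitude = as.numeric(amplitude), frequency = as.numeric(frequency),
         center_frame = as.integer(center_frame),
         jitter_frames = as.integer(jitter_frames), topography = topography),
    class = "erp_component"
  )
}

#' @export
print.erp_component <- function(x, ...) {
  cat(sprintf("<erp_component> amplitude %g, %g Hz, center frame %d, jitter +/-%d\n",
              x$amplitude, x$frequency, x$center_frame, x$jitter_frames))
  invisible(x)
}

#' Default N100 and P300 components
#'
#' The two components used throughout the simulation study: an N100 with
#' amplitude -5 at 15 Hz centered at frame 25 (~100 ms) and a P300 with
#' amplitude 5 at 5 Hz centered at frame 75 (~300 ms), both with +/-5 frames
#' of latency jitter.
#'
#' @param ... Passed on to [erp_component()] to override defaults.
#' @return An `erp_component`.
#' @export
erp_n100 <- function(...) {
  args <- utils::modifyList(
    list(amplitude = -5, frequency = 15, center_frame = 25L), list(...))
  do.call(erp_component, args)
}

#' @rdname erp_n100
#' @export
erp_p300 <- function(...) {
  args <- utils::modifyList(
    list(amplitude = 5, frequency = 5, center_frame = 75L), list(...))
  do.call(erp_component, args)
}

#' Default ERP scalp topography
#'
#' Average-referenced anterior-posterior cosine gradient:
#' `cos(pi * (i - 1) / (n - 1))` for channel index i. The gains sum to
#' (approximately) zero across the scalp, as ERP topographies do under an
#' average reference, and change smoothly between neighboring electrodes.
#'
#' @param n_channels Number of electrodes.
#' @return Numeric vector of length `n_channels` in `[-1, 1]`.
#' @export
erp_topography <- function(n_channels) {
  cos(pi * (seq_len(n_channels) - 1) / (n_channels - 1))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic EEG generator. Defaults reproduce the
#' study conditions of the simulation experiments: 31 electrodes, 200 samples
#' over a 0.8-s epoch (250 samples/s, so frames 25 and 75 map to about 100 ms
#' and 300 ms), background amplitude 10, no components, one trial, no added
#' noise.
#'
#' @param n_channels Number of electrodes (default 31).
#' @param sampling_rate Samples per second (default 250).
#' @param epoch_duration Epoch length in seconds (default 0.8).
#' @param background_amplitude Scale of the 1/f background: each channel is
#'   scaled so its peak-to-peak range equals `2 * background_amplitude`
#'   (default 10).
#' @param components List of [erp_component()] objects (default empty).
#' @param n_trials Number of trials averaged per participant (default 1).
#' @param noise_sigma Standard deviation of Gaussian white noise added per
#'   channel and sample after trial averaging (default 0).
#' @param spectral_exponent Exponent alpha of the background power spectrum
#'   `P(f) ~ 1/f^alpha` (default 1).
#' @param alpha_bump_amplitude Relative amplitude of an optional 10-Hz
#'   spectral bump in the background (default 0, i.e. off).
#'
#' @return An object of class `sim_config`. `n_samples` is derived as
#'   `round(sampling_rate * epoch_duration)`.
#' @export
#' @examples
#' cfg <- sim_config(components = list(erp_n100(), erp_p300()), n_trials = 50)
#' cfg$n_samples
sim_config <- function(n_channels = 31L, sampling_rate = 250,
                       epoch_duration = 0.8, background_amplitude = 10,
                       components = list(), n_trials = 1L, noise_sigma = 0,
                       spectral_exponent = 1, alpha_bump_amplitude = 0) {
  if (n_channels < 2 || n_channels != round(n_channels)) {
    stop("`n_channels` must be an integer >= 2", call. = FALSE)
  }
  if (sampling_rate <= 0 || epoch_duration <= 0) {
    stop("`sampling_rate` and `epoch_duration` must be positive",
         call. = FALSE)
  }
  n_samples <- as.integer(round(sampling_rate * epoch_duration))
  if (n_samples < 2) stop("epoch too short: fewer than 2 samples", call. = FALSE)
  if (n_trials < 1 || n_trials != round(n_trials)) {
    stop("`n_trials` must be a positive integer", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative", call. = FALSE)
  if (background_amplitude < 0) {
    stop("`background_amplitude` must be non-negative", call. = FALSE)
  }
  for (cm in components) {
    if (!inherits(cm, "erp_component")) {
      stop("`components` must be a list of `erp_component` objects",
           call. = FALSE)
    }
    if (cm$center_frame > n_samples) {
      stop("component center frame lies outside the epoch", call. = FALSE)
    }
    if (!is.null(cm$topography) && length(cm$topography) != n_channels) {
      stop("component topography length must equal `n_channels`",
           call. = FALSE)
    }
  }
  structure(
    list(n_channels = as.integer(n_channels),
         n_samples = n_samples,
         sampling_rate = as.numeric(sampling_rate),
         epoch_duration = as.numeric(epoch_duration),
         background_amplitude = as.numeric(background_amplitude),
         components = components,
         n_trials = as.integer(n_trials),
         noise_sigma = as.numeric(noise_sigma),
         spectral_exponent = as.numeric(spectral_exponent),
         alpha_bump_amplitude = as.numeric(alpha_bump_amplitude)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d ch x %d samples @ %g Hz, background %g, ",
                     "%d component(s), %d trial(s), noise sigma %g\n"),
              x$n_channels, x$n_samples, x$sampling_rate,
              x$background_amplitude, length(x$components), x$n_trials,
              x$noise_sigma))
  invisible(x)
}

# One channel of 1/f^alpha background: frequency-domain shaping of white
# Gaussian noise, then peak-to-peak scaling to 2 * amplitude.
shaped_noise <- function(n_samples, sampling_rate, amplitude,
                         spectral_exponent, alpha_bump_amplitude) {
  w <- stats::rnorm(n_samples)
  if (amplitude == 0) return(numeric(n_samples))
  T <- n_samples
  k <- seq_len(T) - 1L
  f <- pmin(k, T - k) * sampling_rate / T     # two-sided frequency axis, Hz
  shape <- numeric(T)
  nz <- f > 0
  shape[nz] <- 1 / f[nz]^(spectral_exponent / 2)
  if (alpha_bump_amplitude > 0) {
    shape[nz] <- shape[nz] +
      alpha_bump_amplitude * exp(-(f[nz] - 10)^2 / (2 * 2^2))
  }
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / T
  ptp <- diff(range(x))
  if (ptp == 0) return(x)
  x * (2 * amplitude / ptp)
}

#' Simulate background EEG
#'
#' Generates one epoch of ERP-free background activity: per-channel
#' independent Gaussian noise shaped in the frequency domain to a
#' `1/f^alpha` power spectrum (mimicking the broadband spectrum of resting
#' human EEG, optionally with a 10-Hz alpha bump), scaled so each channel's
#' peak-to-peak range equals `2 * background_amplitude`.
#'
#' Uses the current R random number generator state; call `set.seed()` first
#' for reproducibility.
#'
#' @param config A [sim_config()].
#' @return An [eeg_epoch()] of dimension `n_channels x n_samples`.
#' @export
#' @examples
#' set.seed(1)
#' bg <- simulate_background(sim_config())
#' dim(bg)
simulate_background <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a `sim_config`", call. = FALSE)
  }
  data <- t(vapply(seq_len(config$n_channels), function(i) {
    shaped_noise(config$n_samples, config$sampling_rate,
                 config$background_amplitude, config$spectral_exponent,
                 config$alpha_bump_amplitude)
  }, numeric(config$n_samples)))
  eeg_epoch(data, config$sampling_rate)
}

#' Render one ERP component waveform
#'
#' The component is a single half-cycle sinusoidal lobe at the component
#' frequency: its support spans `L = max(1, round(sampling_rate /
#' (2 * frequency)))` samples centered at `center_frame + jitter_offset`
#' (truncated at the epoch edges), and the peak sample equals `amplitude`
#' exactly.
#'
#' @param component An [erp_component()].
#' @param n_samples Epoch length in samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param jitter_offset Integer latency offset in samples; must satisfy
#'   `abs(jitter_offset) <= component$jitter_frames`.
#' @return Numeric vector of length `n_samples`, zero outside the lobe.
#' @export
#' @examples
#' w <- render_component(erp_p300(), 200, 250)
#' w[75]          # peak value 5 at the center frame
#' sum(w != 0)    # half-cycle width: round(250 / (2 * 5)) = 25 samples
render_component <- function(component, n_samples, sampling_rate,
                             jitter_offset = 0L) {
  if (!inherits(component, "erp_component")) {
    stop("`component` must be an `erp_component`", call. = FALSE)
  }
  if (abs(jitter_offset) > component$jitter_frames) {
    stop("`jitter_offset` exceeds the component's `jitter_frames`",
         call. = FALSE)
  }
  out <- numeric(n_samples)
  if (component$amplitude == 0) return(out)
  L <- max(1L, as.integer(round(sampling_rate / (2 * component$frequency))))
  k <- seq_len(L) - 1L
  v <- sin(pi * (k + 0.5) / L)
  v <- v / max(v) * component$amplitude
  s <- component$center_frame + jitter_offset + (k - floor((L - 1) / 2))
  ok <- s >= 1L & s <= n_samples
  out[s[ok]] <- v[ok]
  out
}

#' Simulate one participant's averaged epoch
#'
#' For each of `n_trials`: a fresh background draw plus every configured ERP
#' component rendered with an independently drawn latency jitter (uniform
#' integer on `[-jitter_frames, jitter_frames]`, shared by all channels
#' within the trial) and projected onto the scalp through the component's
#' topography. Trials are averaged, then Gaussian white noise of standard
#' deviation `noise_sigma` is added independently per channel and sample.
#'
#' RNG stream order (fixed, so that seeded runs with and without components
#' consume the noise and background streams identically): (1) the additive
#' noise matrix, (2) per-trial background, (3) per-trial jitter offsets.
#'
#' @inheritParams simulate_background
#' @return An [eeg_epoch()].
#' @export
#' @examples
#' set.seed(7)
#' ep <- simulate_participant(sim_config(components = list(erp_p300()),
#'                                       n_trials = 20))
simulate_participant <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a `sim_config`", call. = FALSE)
  }
  n <- config$n_channels
  T <- config$n_samples
  noise <- if (config$noise_sigma > 0) {
    matrix(stats::rnorm(n * T, sd = config$noise_sigma), n, T)
  } else {
    matrix(0, n, T)
  }
  acc <- matrix(0, n, T)
  for (trial in seq_len(config$n_trials)) {
    ep <- simulate_background(config)$data
    for (cm in config$components) {
      off <- if (cm$jitter_frames > 0) {
        sample.int(2L * cm$jitter_frames + 1L, 1L) - cm$jitter_frames - 1L
      } else 0L
      w <- render_component(cm, T, config$sampling_rate, off)
      gain <- if (is.null(cm$topography)) erp_topography(n) else cm$topography
      ep <- ep + outer(gain, w)
    }
    acc <- acc + ep
  }
  eeg_epoch(acc / config$n_trials + noise, config$sampling_rate)
}

#' Simulate a two-group cohort study
#'
#' Generates the manifest of the simulation experiments: one group of
#' participants whose epochs contain the configured ERP components and one
#' ERP-free control group. Each participant receives an independent child
#' seed spawned from `seed`, so the whole manifest is reproducible.
#'
#' @param n_per_group Integer vector of length 2: participants in the ERP
#'   group and in the control group (default `c(20, 20)`).
#' @param config_erp [sim_config()] for the ERP group; defaults to the study
#'   conditions with N100 and P300 components.
#' @param config_control [sim_config()] for the control group; must share
#'   `n_channels`, `n_samples` and `sampling_rate` with `config_erp`.
#' @param groups Character vector of length 2 naming the groups.
#' @param condition Condition label attached to every epoch.
#' @param seed Optional integer master seed.
#'
#' @return A tibble manifest with columns `group`, `participant`,
#'   `condition` and `epoch` (a list column of [eeg_epoch()] objects).
#' @export
#' @examples
#' man <- simulate_study(c(4, 4), sim_config(n_channels = 8,
#'                       components = list(erp_p300()), n_trials = 5),
#'                       sim_config(n_channels = 8), seed = 1)
#' man
simulate_study <- function(n_per_group = c(20L, 20L),
                           config_erp = sim_config(
                             components = list(erp_n100(), erp_p300())),
                           config_control = sim_config(),
                           groups = c("erp", "control"),
                           condition = "task", seed = NULL) {
  if (length(n_per_group) != 2L || any(n_per_group < 0)) {
    stop("`n_per_group` must be two non-negative integers", call. = FALSE)
  }
  same <- config_erp$n_channels == config_control$n_channels &&
    config_erp$n_samples == config_control$n_samples &&
    config_erp$sampling_rate == config_control$sampling_rate
  if (!same) {
    stop("the two configurations must share channel count, epoch length and sampling rate",
         call. = FALSE)
  }
  total <- sum(n_per_group)
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- if (total > 0) sample.int(.Machine$integer.max, total) else integer()
  rows <- vector("list", total)
  idx <- 0L
  for (g in 1:2) {
    cfg <- if (g == 1L) config_erp else config_control
    for (p in seq_len(n_per_group[g])) {
      idx <- idx + 1L
      set.seed(child_seeds[idx])
      rows[[idx]] <- tibble::tibble(
        group = groups[g],
        participant = sprintf("%s_%02d", groups[g], p),
        condition = condition,
        epoch = list(simulate_participant(cfg))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(group = character(), participant = character(),
                          condition = character(), epoch = list())
  }
  check_cohort(out)
  out
}
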