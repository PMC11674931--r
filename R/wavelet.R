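#' Morlet mother wavelet
#'
#' Evaluates `psi(t) = pi^(-1/4) * exp(1i * omega0 * t) * exp(-t^2 / 2)`
#' pointwise: a complex sinusoid at the central frequency `omega0` under a
#' Gaussian envelope.
#'
#' @param t Numeric vector of time points.
#' @param omega0 Central (angular) frequency of the wavelet; default 6, the
#'   conventional choice balancing time and frequency localization.
#' @return Complex vector of the same length as `t`.
#' @export
#' @examples
#' morlet(0)            # pi^(-1/4)
morlet <- function(t, omega0 = 6) {
  if (!is.numeric(omega0) || omega0 <= 0) {
    stop("`omega0` must be positive", call. = FALSE)
  }
  pi^(-1 / 4) * exp(1i * omega0 * t) * exp(-t^2 / 2)
}

#' Default Morlet scale grid
#'
#' Logarithmically spaced scales whose pseudo-frequencies
#' `f = omega0 / (2 * pi * a)` cover `freq_range`. Returned in increasing
#' scale order (decreasing frequency).
#'
#' @param n_scales Number of scales (default 32).
#' @param freq_range Two-element pseudo-frequency range in Hz (default 1-40,
#'   spanning the conventional EEG bands).
#' @param omega0 Wavelet central frequency.
#' @return Increasing positive numeric vector of length `n_scales`.
#' @export
morlet_scales <- function(n_scales = 32L, freq_range = c(1, 40), omega0 = 6) {
  if (n_scales < 1) stop("`n_scales` must be positive", call. = FALSE)
  f <- exp(seq(log(max(freq_range)), log(min(freq_range)),
               length.out = n_scales))
  omega0 / (2 * pi * f)
}

#' Continuous wavelet transform with the Morlet wavelet
#'
#' Discretizes `W_x(a, b) = a^(-1/2) integral x(t) conj(psi((t - b) / a)) dt`
#' as a direct convolution per scale, with spacing `1 / sampling_rate` and
#' zero padding at the epoch boundaries (no cone-of-influence masking).
#'
#' @param signal Real vector, length >= 2.
#' @param sampling_rate Sampling rate in Hz.
#' @param scales Positive increasing vector of scales in seconds; default
#'   [morlet_scales()].
#' @param omega0 Wavelet central frequency (default 6).
#' @return An object of class `cwt_result`: list with `coefficients`
#'   (complex, scales x times), `scales`, `times` and `omega0`.
#' @export
#' @examples
#' fs <- 100; t <- seq(0, 2, by = 1 / fs)
#' res <- cwt_morlet(cos(2 * pi * 10 * t), fs)
#' # power concentrates at the scale closest to omega0 / (2 * pi * 10)
cwt_morlet <- function(signal, sampling_rate, scales = morlet_scales(),
                       omega0 = 6) {
  if (length(signal) < 2L) stop("`signal` must have length >= 2", call. = FALSE)
  if (length(scales) == 0L) stop("`scales` must be non-empty", call. = FALSE)
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE)) {
    stop("`scales` must be strictly positive and increasing", call. = FALSE)
  }
  T <- length(signal)
  dt <- 1 / sampling_rate
  coef <- matrix(0i, length(scales), T)
  for (s in seq_along(scales)) {
    a <- scales[s]
    half <- min(T - 1L, max(1L, ceiling(5 * a / dt)))  # Gaussian support ~5 sd
    tt <- (-half:half) * dt
    psi <- Conj(morlet(tt / a, omega0)) / sqrt(a)
    # zero-padded convolution: W(b) = sum_t x(t) psi*((t-b)/a) dt
    full <- stats::convolve(signal, rev(psi), type = "open") * dt
    coef[s, ] <- full[(half + 1):(half + T)]
  }
  structure(
    list(coefficients = coef, scales = scales,
         times = (seq_len(T) - 1) * dt, omega0 = omega0),
    class = "cwt_result"
  )
}

#' @export
print.cwt_result <- function(x, ...) {
  cat(sprintf("<cwt_result> %d scales x %d times, omega0 = %g\n",
              length(x$scales), length(x$times), x$omega0))
  invisible(x)
}

#' Windowed wavelet power of a multichannel epoch
#'
#' The comparison baseline to FAST connectivity metrics: for each of
#' `n_windows` disjoint temporal windows, the total spectral power
#' `sum |W_x(a, b)|^2` accumulated over all channels, all scales, and the
#' time points inside the window.
#'
#' @param epoch An [eeg_epoch()].
#' @param n_windows Number of disjoint windows (default 10).
#' @param scales Morlet scale grid; default [morlet_scales()].
#' @param omega0 Wavelet central frequency.
#' @return Numeric vector of length `n_windows`.
#' @export
windowed_power <- function(epoch, n_windows = 10L, scales = morlet_scales(),
                           omega0 = 6) {
  stopifnot_epoch(epoch)
  T <- ncol(epoch$data)
  parts <- partition_windows(T, n_windows)
  pow <- numeric(T)
  for (i in seq_len(nrow(epoch$data))) {
    res <- cwt_morlet(epoch$data[i, ], epoch$sampling_rate, scales, omega0)
    pow <- pow + colSums(Mod(res$coefficients)^2)
  }
  vapply(parts, function(idx) sum(pow[idx]), numeric(1))
}

#' Heatmap of wavelet power
#'
#' @param object A [cwt_morlet()] result.
#' @param ... Ignored.
#' @return A ggplot of `|W_x(a, b)|^2` over time and pseudo-frequency.
#' @exportS3Method ggplot2::autoplot
autoplot.cwt_result <- function(object, ...) {
  df <- tibble::tibble(
    time = rep(object$times, times = length(object$scales)),
    frequency = rep(object$omega0 / (2 * pi * object$scales),
                    each = length(object$times)),
    power = as.vector(t(Mod(object$coefficients)^2))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "pseudo-frequency (Hz)",
                  fill = "power") +
    ggplot2::theme_minimal()
}
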