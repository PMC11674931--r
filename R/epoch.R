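#' Multichannel EEG epoch
#'
#' Lightweight container for one participant's channels-by-samples signal
#' matrix together with its sampling rate and channel labels. All analysis
#' functions in fastconn accept and return this class.
#'
#' @param data Numeric matrix, channels in rows, samples in columns. At least
#'   2 channels and 2 samples; all values finite.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param channel_labels Optional character vector of channel names; defaults
#'   to `"ch01"`, `"ch02"`, ...
#'
#' @return An object of class `eeg_epoch`: a list with elements `data`,
#'   `sampling_rate` and `channel_labels`.
#' @export
#' @examples
#' ep <- eeg_epoch(matrix(rnorm(40), 4, 10), sampling_rate = 250)
#' ep
eeg_epoch <- function(data, sampling_rate, channel_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix", call. = FALSE)
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stop("an epoch needs at least 2 channels and 2 samples", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("epoch values must be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` length must match the number of channels",
         call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         channel_labels = as.character(channel_labels)),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' @export
dim.eeg_epoch <- function(x) dim(x$data)

is_eeg_epoch <- function(x) inherits(x, "eeg_epoch")

stopifnot_epoch <- function(x, arg = "epoch") {
  if (!is_eeg_epoch(x)) {
    stop(sprintf("`%s` must be an `eeg_epoch` (see `eeg_epoch()`)", arg),
         call. = FALSE)
  }
  invisible(x)
}

# All epochs in a cohort tibble must agree on shape and sampling rate.
check_cohort <- function(manifest) {
  if (!is.data.frame(manifest) ||
      !all(c("group", "participant", "condition", "epoch") %in%
             names(manifest))) {
    stop(paste("a cohort manifest is a data frame with columns",
               "`group`, `participant`, `condition`, `epoch`"), call. = FALSE)
  }
  if (nrow(manifest) == 0L) return(invisible(manifest))
  dims <- vapply(manifest$epoch, function(e) {
    stopifnot_epoch(e)
    c(dim(e$data), e$sampling_rate)
  }, numeric(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      any(dims[3, ] != dims[3, 1])) {
    stop("all epochs in a manifest must share channel count, length and sampling rate",
         call. = FALSE)
  }
  invisible(manifest)
}
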