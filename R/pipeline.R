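#' Windowed FAST connectivity of one epoch
#'
#' Convenience wrapper producing windowed connectivity matrices directly from
#' a filter and an epoch. Mathematically identical to
#' `window_average(build_tensor(filter, epoch), n_windows)` but computed
#' through a closed-form cross-product identity, so large window counts (up
#' to one window per sample) stay cheap.
#'
#' @param filter Static support matrix (cohort FAST filter, a participant's
#'   own long-term matrix, or [ones_filter()]).
#' @param epoch An [eeg_epoch()].
#' @param n_windows Number of disjoint temporal windows.
#' @return A `windowed_connectivity` object (see [window_average()]).
#' @export
fast_connectivity <- function(filter, epoch, n_windows = 10L) {
  stopifnot_epoch(epoch)
  check_conn_matrix(filter)
  nz <- normalize_nodes(epoch)
  if (nrow(filter) != nrow(nz$data)) {
    stop("`filter` shape must match the epoch channel count", call. = FALSE)
  }
  T <- ncol(nz$data)
  mats <- windowed_matrices(filter, nz, n_windows)
  parts <- partition_windows(T, n_windows)
  fs <- epoch$sampling_rate
  bounds <- t(vapply(parts, function(idx) c((min(idx) - 1) / fs, max(idx) / fs),
                     numeric(2)))
  colnames(bounds) <- c("start", "end")
  structure(list(matrices = mats, bounds = bounds, sampling_rate = fs),
            class = "windowed_connectivity")
}

#' Per-participant windowed network metrics for a whole cohort
#'
#' Applies the chosen filtering mode and reduces every participant's epoch to
#' windowed network metrics (and optionally the wavelet-power baseline),
#' returning the long-format table that [run_comparison()] tests.
#'
#' @param manifest Cohort manifest tibble (columns `group`, `participant`,
#'   `condition`, `epoch`).
#' @param filter_mode `"fast"` (one cohort-average filter pooled over all
#'   rows of the manifest), `"individual"` (each participant's own absolute
#'   correlation matrix) or `"unfiltered"` (all-ones off-diagonal support).
#' @param n_windows Number of disjoint temporal windows (default 10).
#' @param metrics Network metrics to compute (see [connectivity_metrics()]).
#' @param include_wavelet Also compute the windowed Morlet power baseline as
#'   metric `"wavelet_power"` (default `FALSE`).
#' @param band Band label stamped on the rows (default `"broadband"`).
#' @return A tibble with columns `participant`, `group`, `condition`, `band`,
#'   `metric`, `window`, `window_start`, `window_end`, `value`.
#' @export
participant_metrics <- function(manifest,
                                filter_mode = c("fast", "individual",
                                                "unfiltered"),
                                n_windows = 10L,
                                metrics = c("mean_edge_weight", "clustering"),
                                include_wavelet = FALSE,
                                band = "broadband") {
  check_cohort(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  filter_mode <- match.arg(filter_mode)
  n <- nrow(manifest$epoch[[1]]$data)
  cohort_filter <- if (filter_mode == "fast") fast_filter(manifest) else NULL
  purrr::pmap_dfr(
    manifest,
    function(group, participant, condition, epoch, ...) {
      filt <- switch(filter_mode,
                     fast = cohort_filter,
                     individual = pearson_connectivity(epoch),
                     unfiltered = ones_filter(n))
      wc <- fast_connectivity(filt, epoch, n_windows)
      tab <- connectivity_metrics(wc, metrics)
      if (include_wavelet) {
        pw <- windowed_power(epoch, n_windows)
        tab <- dplyr::bind_rows(tab, tibble::tibble(
          metric = "wavelet_power",
          window = seq_len(n_windows),
          window_start = wc$bounds[, "start"],
          window_end = wc$bounds[, "end"],
          value = pw
        ))
      }
      dplyr::mutate(tab, participant = participant, group = group,
                    condition = condition, band = band,
                    .before = 1)
    }
  )
}

#' Two-group comparison of windowed connectivity metrics
#'
#' The full statistical pipeline of the method: build the filter, reduce
#' every participant to windowed network metrics, then at every temporal
#' window test the two groups with a two-sided Wilcoxon rank-sum test,
#' attach Cohen's d effect sizes, and apply Benjamini-Hochberg FDR
#' correction across windows separately within each
#' `(metric, condition, band)` family.
#'
#' @inheritParams participant_metrics
#' @param q Numeric vector of FDR levels (default `c(0.05, 0.10)`); each
#'   level adds a logical column `significant_<q>`.
#' @param groups Optional length-2 character vector fixing the
#'   (control, patient) order for the Cohen's d sign convention; defaults to
#'   the order of first appearance in the manifest. `cohens_d` is computed as
#'   (first group minus second group) / pooled SD, so negative values mean
#'   larger metric values in the second group.
#' @return A `fast_comparison` tibble with one row per
#'   `(metric, condition, band, window)`: columns `window_start`, `p_raw`,
#'   `p_adjusted`, `cohens_d` and one `significant_*` column per `q`.
#' @export
#' @examples
#' man <- simulate_study(c(5, 5),
#'   sim_config(n_channels = 8, epoch_duration = 0.2,
#'              components = list(erp_p300(center_frame = 25L)), n_trials = 5),
#'   sim_config(n_channels = 8, epoch_duration = 0.2), seed = 1)
#' run_comparison(man, n_windows = 5)
run_comparison <- function(manifest,
                           filter_mode = c("fast", "individual", "unfiltered"),
                           n_windows = 10L,
                           metrics = c("mean_edge_weight", "clustering"),
                           include_wavelet = FALSE,
                           q = c(0.05, 0.10),
                           groups = NULL,
                           band = "broadband") {
  check_cohort(manifest)
  filter_mode <- match.arg(filter_mode)
  gr <- unique(manifest$group)
  if (length(gr) != 2L) {
    stop("the manifest must contain exactly two groups", call. = FALSE)
  }
  if (!is.null(groups)) {
    if (!setequal(groups, gr)) {
      stop("`groups` must name the two groups present in the manifest",
           call. = FALSE)
    }
    gr <- groups
  }
  counts <- table(manifest$group)
  if (any(counts < 2L)) {
    stop("each group needs at least 2 participants", call. = FALSE)
  }
  tab <- participant_metrics(manifest, filter_mode, n_windows, metrics,
                             include_wavelet, band)
  fam <- dplyr::group_by(tab, .data$metric, .data$condition, .data$band,
                         .data$window, .data$window_start)
  tested <- dplyr::summarise(
    fam,
    p_raw = ranksum_test(.data$value[.data$group == gr[1]],
                         .data$value[.data$group == gr[2]]),
    cohens_d = suppressWarnings(
      cohens_d(.data$value[.data$group == gr[1]],
               .data$value[.data$group == gr[2]])),
    .groups = "drop"
  )
  adj <- dplyr::group_by(tested, .data$metric, .data$condition, .data$band)
  adj <- dplyr::mutate(adj, p_adjusted = stats::p.adjust(.data$p_raw, "BH"))
  for (qq in q) {
    col <- sprintf("significant_%02d", round(100 * qq))
    adj <- dplyr::mutate(
      adj, !!col := bh_fdr(.data$p_raw, qq)$significant)
  }
  out <- dplyr::arrange(dplyr::ungroup(adj), .data$metric, .data$condition,
                        .data$band, .data$window)
  out <- dplyr::relocate(out, "p_adjusted", .after = "p_raw")
  attr(out, "filter_mode") <- filter_mode
  attr(out, "n_windows") <- n_windows
  attr(out, "groups") <- gr
  class(out) <- c("fast_comparison", class(out))
  out
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a comparison table
#'
#' @param x A [run_comparison()] result.
#' @param ... Ignored.
#' @return The underlying tibble, stripped of the extra class.
#' @exportS3Method generics::tidy
tidy.fast_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fast_comparison")
  out
}

#' One-row summary of a comparison
#'
#' @param x A [run_comparison()] result.
#' @param ... Ignored.
#' @return A one-row tibble: filter mode, number of windows/families, raw
#'   and FDR-significant window counts, minimum adjusted p-value.
#' @exportS3Method generics::glance
glance.fast_comparison <- function(x, ...) {
  sig_cols <- grep("^significant_", names(x), value = TRUE)
  out <- tibble::tibble(
    filter_mode = attr(x, "filter_mode"),
    n_windows = attr(x, "n_windows"),
    n_tests = nrow(x),
    n_raw_05 = sum(x$p_raw <= 0.05),
    min_p_adjusted = min(x$p_adjusted)
  )
  for (cl in sig_cols) out[[paste0("n_", cl)]] <- sum(x[[cl]])
  out
}

#' Plot adjusted p-values over temporal windows
#'
#' @param object A [run_comparison()] result.
#' @param q Reference significance level drawn as a dashed line.
#' @param ... Ignored.
#' @return A ggplot: `-log10` adjusted p-value per window, faceted by metric
#'   and condition.
#' @exportS3Method ggplot2::autoplot
autoplot.fast_comparison <- function(object, q = 0.05, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$window_start, -log10(.data$p_adjusted),
                               colour = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(q), linetype = "dashed") +
    ggplot2::facet_grid(ggplot2::vars(.data$metric),
                        ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "window start (s)", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
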