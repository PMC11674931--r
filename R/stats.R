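#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; tie-corrected normal approximation (with continuity
#' correction) otherwise. Samples whose pooled spread is zero up to
#' floating-point rounding (relative 1e-9) are treated as fully tied and
#' return p = 1, so analytically constant metrics never produce spurious
#' rejections from round-off noise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
#' @examples
#' ranksum_test(c(1, 2, 3, 4), c(5, 6, 7, 8))   # 2/70
ranksum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  # Samples indistinguishable up to floating-point rounding (e.g. the
  # analytically constant unfiltered mean edge weight) carry no evidence:
  # return 1 rather than rank pure round-off noise.
  rng <- range(c(a, b))
  if (diff(rng) <= 1e-9 * max(abs(rng), 1)) return(1)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 20L
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(controls) - mean(patients)) / s_p`
#' with the pooled standard deviation using `n - 1` weights. The sign
#' convention: a negative value indicates larger metric values in the
#' patient (second) group.
#'
#' @param controls,patients Numeric vectors, each of length >= 2.
#' @return Scalar effect size; `NA` with a warning when the pooled standard
#'   deviation is zero (degenerate samples).
#' @export
#' @examples
#' cohens_d(rnorm(10), rnorm(10, 1))   # around -1
cohens_d <- function(controls, patients) {
  n1 <- length(controls); n2 <- length(patients)
  if (n1 < 2L || n2 < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  sp <- sqrt(((n1 - 1) * stats::var(controls) +
                (n2 - 1) * stats::var(patients)) / (n1 + n2 - 2))
  if (sp == 0) {
    warning("zero pooled standard deviation: effect size undefined")
    return(NA_real_)
  }
  (mean(controls) - mean(patients)) / sp
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Standard step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' reject all hypotheses with `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k q / m}`. Adjusted p-values are
#' `min_{j >= k} m p_(j) / j`, capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param q Target false discovery rate, in `(0, 1)` (default 0.05).
#' @return A tibble with columns `p_raw`, `p_adjusted` and `significant`
#'   (the step-up rejections at level `q`), in the input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.20), q = 0.05)
bh_fdr <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("`q` must lie in (0, 1)", call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below) > 0) reject[ord[seq_len(max(below))]] <- TRUE
  tibble::tibble(
    p_raw = p_values,
    p_adjusted = stats::p.adjust(p_values, method = "BH"),
    significant = reject
  )
}

#' Windows of clinical interest
#'
#' A temporal window is of clinical interest when the binding-task
#' comparison is FDR-significant at level `q` while the shape-task
#' comparison shows no evidence of a difference (raw p-value at or above
#' `shape_alpha`): the signature of a selective binding deficit.
#'
#' @param binding,shape Comparison tables from [run_comparison()] (or any
#'   tables with columns `metric`, `band`, `window`, `p_raw`,
#'   `p_adjusted`), aligned on `(metric, band, window)`.
#' @param q FDR level applied to the binding table (default 0.05).
#' @param shape_alpha Raw significance level used to declare absence of a
#'   shape-task difference (default 0.05).
#' @return A tibble of the qualifying `(metric, band, window)` rows with the
#'   binding-task p-values.
#' @export
clinical_interest <- function(binding, shape, q = 0.05, shape_alpha = 0.05) {
  key <- c("metric", "band", "window")
  for (tb in list(binding, shape)) {
    if (!all(c(key, "p_raw", "p_adjusted") %in% names(tb))) {
      stop("tables need columns metric, band, window, p_raw, p_adjusted",
           call. = FALSE)
    }
  }
  b <- dplyr::arrange(tibble::as_tibble(binding), .data$metric, .data$band,
                      .data$window)
  s <- dplyr::arrange(tibble::as_tibble(shape), .data$metric, .data$band,
                      .data$window)
  if (nrow(b) != nrow(s) ||
      !identical(b[key], s[key])) {
    stop("binding and shape tables are not aligned on (metric, band, window)",
         call. = FALSE)
  }
  fdr_sig <- unlist(lapply(
    split(seq_len(nrow(b)), interaction(b$metric, b$band, drop = TRUE)),
    function(rows) {
      out <- logical(length(rows))
      out[bh_fdr(b$p_raw[rows], q)$significant] <- TRUE
      rows[out]
    }), use.names = FALSE)
  sig <- rep(FALSE, nrow(b))
  sig[fdr_sig] <- TRUE
  keep <- sig & s$p_raw >= shape_alpha
  dplyr::select(b[keep, , drop = FALSE], dplyr::all_of(key), "p_raw",
                "p_adjusted")
}
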