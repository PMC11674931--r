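# Disjoint, ordered partition of 1:T into n_windows contiguous runs covering
# all samples; sizes differ by at most one, the remainder going to the last
# windows.
partition_windows <- function(T, n_windows) {
  if (n_windows < 1 || n_windows != round(n_windows)) {
    stop("`n_windows` must be a positive integer", call. = FALSE)
  }
  if (n_windows > T) {
    stop("`n_windows` cannot exceed the number of samples", call. = FALSE)
  }
  sizes <- rep(T %/% n_windows, n_windows)
  r <- T %% n_windows
  if (r > 0) sizes[(n_windows - r + 1):n_windows] <- sizes[(n_windows - r + 1):n_windows] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(seq.int, starts, ends)
}

#' Average a connectivity tensor over disjoint temporal windows
#'
#' Splits the T slices of a connectivity tensor into `n_windows`
#' non-overlapping contiguous windows covering the whole epoch and averages
#' the slices elementwise within each window. `n_windows = T` returns the
#' per-sample slices themselves: maximum temporal resolution.
#'
#' @param tensor An `n x n x T` array from [build_tensor()].
#' @param n_windows Number of windows, between 1 and T.
#' @return An object of class `windowed_connectivity`: list with `matrices`
#'   (list of `n x n` window means), `bounds` (two-column matrix of window
#'   start/end times in seconds) and `sampling_rate`.
#' @export
#' @examples
#' set.seed(1)
#' ep <- simulate_background(sim_config(n_channels = 5, epoch_duration = 0.2))
#' th <- build_tensor(ones_filter(5), ep)
#' wc <- window_average(th, 10)
#' length(wc$matrices)
window_average <- function(tensor, n_windows) {
  if (!is.array(tensor) || length(dim(tensor)) != 3L) {
    stop("`tensor` must be an n x n x T array", call. = FALSE)
  }
  T <- dim(tensor)[3]
  fs <- attr(tensor, "sampling_rate")
  parts <- partition_windows(T, n_windows)
  mats <- lapply(parts, function(idx) {
    m <- apply(tensor[, , idx, drop = FALSE], c(1, 2), mean)
    (m + t(m)) / 2   # guard against asymmetric rounding
  })
  bounds <- t(vapply(parts, function(idx) {
    if (is.null(fs)) c(min(idx) - 1, max(idx)) else
      c((min(idx) - 1) / fs, max(idx) / fs)
  }, numeric(2)))
  colnames(bounds) <- c("start", "end")
  structure(list(matrices = mats, bounds = bounds, sampling_rate = fs),
            class = "windowed_connectivity")
}

#' @export
print.windowed_connectivity <- function(x, ...) {
  cat(sprintf("<windowed_connectivity> %d windows of %d x %d matrices\n",
              length(x$matrices), nrow(x$matrices[[1]]), ncol(x$matrices[[1]])))
  invisible(x)
}

#' Mean edge weight
#'
#' The full double sum of the weight matrix (the zero diagonal included)
#' divided by `n^2`. On a FAST connectivity window this equals, up to the
#' `2 / n^2` factor, the Dirichlet energy of the filtered instantaneous
#' profile, averaged over the window.
#'
#' @param matrix Square symmetric non-negative matrix with zero diagonal.
#' @return Non-negative scalar.
#' @export
#' @examples
#' mean_edge_weight(ones_filter(4) * 0.5)   # 0.5 * 4 * 3 / 16
mean_edge_weight <- function(matrix) {
  check_conn_matrix(matrix)
  sum(matrix) / nrow(matrix)^2
}

#' Average weighted clustering coefficient
#'
#' One-nth of the trace of the cubed weight matrix:
#' `(1/n) sum_i (M^3)_ii = (1/n) sum_i sum_{j,k} M_ij M_ik M_jk`. Each
#' diagonal entry of the cube sums the products of weights around all ordered
#' triangles through node i; no degree normalization or binarization is
#' applied, so the statistic grows with the cube of a uniform rescaling.
#'
#' @inheritParams mean_edge_weight
#' @return Non-negative scalar.
#' @export
#' @examples
#' avg_weighted_clustering(ones_filter(5))  # (n-1)(n-2) = 12
avg_weighted_clustering <- function(matrix) {
  check_conn_matrix(matrix)
  n <- nrow(matrix)
  m2 <- matrix %*% matrix
  sum(m2 * t(matrix)) / n   # trace(M^3) = sum(M^2 * t(M))
}

#' Strongest edges of a connectivity matrix
#'
#' Extracts the top fraction of unique undirected edges by weight:
#' `ceiling(fraction * n (n - 1) / 2)` edges, sorted by decreasing weight
#' with ties broken by lexicographic `(i, j)` order, so the result is
#' deterministic.
#'
#' @inheritParams mean_edge_weight
#' @param fraction Fraction of edges to keep, in `(0, 1]`.
#' @return A tibble with columns `node_i`, `node_j` (labels if the matrix has
#'   dimnames, indices otherwise) and `weight`, in descending weight order.
#' @export
#' @examples
#' set.seed(1)
#' C <- pearson_connectivity(simulate_background(sim_config(n_channels = 6)))
#' top_fraction_edges(C, 0.1)
top_fraction_edges <- function(matrix, fraction) {
  check_conn_matrix(matrix)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(matrix)
  idx <- which(upper.tri(matrix), arr.ind = TRUE)
  w <- matrix[idx]
  ord <- order(-w, idx[, 1], idx[, 2])
  keep <- ord[seq_len(ceiling(fraction * n * (n - 1) / 2))]
  labs <- rownames(matrix)
  tibble::tibble(
    node_i = if (is.null(labs)) idx[keep, 1] else labs[idx[keep, 1]],
    node_j = if (is.null(labs)) idx[keep, 2] else labs[idx[keep, 2]],
    weight = w[keep]
  )
}

#' Elementwise mean of connectivity tensors across participants
#'
#' @param tensors Non-empty list of identically shaped `n x n x T` arrays.
#' @return An array of the same shape: the participant-average tensor.
#' @export
group_mean_tensor <- function(tensors) {
  if (!is.list(tensors) || length(tensors) == 0L) {
    stop("`tensors` must be a non-empty list", call. = FALSE)
  }
  d <- dim(tensors[[1]])
  for (th in tensors) {
    if (!is.array(th) || !identical(dim(th), d)) {
      stop("all tensors must share the same shape", call. = FALSE)
    }
  }
  out <- Reduce(`+`, tensors) / length(tensors)
  attributes(out) <- attributes(tensors[[1]])
  out
}

#' Windowed network metrics of one participant
#'
#' Reduces a `windowed_connectivity` to a tidy table of scalar network
#' metrics per temporal window.
#'
#' @param windowed A [window_average()] result.
#' @param metrics Character vector among `"mean_edge_weight"` and
#'   `"clustering"`.
#' @return A tibble with columns `metric`, `window`, `window_start`,
#'   `window_end`, `value`.
#' @export
connectivity_metrics <- function(windowed,
                                 metrics = c("mean_edge_weight", "clustering")) {
  if (!inherits(windowed, "windowed_connectivity")) {
    stop("`windowed` must be a `windowed_connectivity`", call. = FALSE)
  }
  metrics <- match.arg(metrics, several.ok = TRUE)
  funs <- list(mean_edge_weight = mean_edge_weight,
               clustering = avg_weighted_clustering)
  purrr::map_dfr(metrics, function(m) {
    tibble::tibble(
      metric = m,
      window = seq_along(windowed$matrices),
      window_start = windowed$bounds[, "start"],
      window_end = windowed$bounds[, "end"],
      value = vapply(windowed$matrices, funs[[m]], numeric(1))
    )
  })
}
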