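#' Long-term connectivity: absolute Pearson correlation matrix
#'
#' The long-term, stable connectivity estimate of one participant: the
#' absolute value of the Pearson correlation between every pair of channels
#' computed over the full epoch, with a zero main diagonal. These matrices
#' are the ingredients of the cohort [fast_filter()].
#'
#' @param epoch An [eeg_epoch()].
#' @return Symmetric numeric matrix with entries in `[0, 1]`, zero diagonal,
#'   dimnames set to the channel labels.
#' @export
#' @examples
#' set.seed(1)
#' C <- pearson_connectivity(simulate_background(sim_config(n_channels = 5)))
#' range(C)
pearson_connectivity <- function(epoch) {
  stopifnot_epoch(epoch)
  x <- epoch$data
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    bad <- epoch$channel_labels[which(v == 0)]
    stop(sprintf("correlation undefined: zero-variance channel(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  C <- abs(stats::cor(t(x)))
  diag(C) <- 0
  dimnames(C) <- list(epoch$channel_labels, epoch$channel_labels)
  C
}

check_conn_matrix <- function(m, arg = "matrix", tol = 1e-10) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square numeric matrix", arg), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  }
  if (any(m < -tol)) {
    stop(sprintf("`%s` must be non-negative", arg), call. = FALSE)
  }
  if (max(abs(diag(m))) > tol) {
    stop(sprintf("`%s` must have a zero main diagonal", arg), call. = FALSE)
  }
  invisible(m)
}

#' Cohort FAST filter
#'
#' Averages the long-term connectivity estimates of a cohort elementwise:
#' `c_ij^FAST = sum_P c_ij^P / N` over participants P. The result is a single
#' static support matrix, shared by every participant, that emphasizes
#' connections that are consistently strong across the whole cohort and
#' down-weights idiosyncratic (likely spurious) ones.
#'
#' For two-condition designs the recommended filter pools every participant
#' and both conditions; pass the full manifest. Any explicit subset of
#' matrices can be averaged for methodological experiments.
#'
#' @param x Either a list of connectivity matrices (all the same shape), or a
#'   cohort manifest tibble (columns `group`, `participant`, `condition`,
#'   `epoch`) whose epochs are first passed through [pearson_connectivity()].
#' @return Symmetric matrix with entries in `[0, 1]` and zero diagonal.
#' @export
#' @examples
#' m <- matrix(c(0, .5, .5, 0), 2, 2)
#' fast_filter(list(m, m))          # idempotent on identical inputs
fast_filter <- function(x) {
  if (is.data.frame(x)) {
    check_cohort(x)
    if (nrow(x) == 0L) stop("empty manifest", call. = FALSE)
    x <- lapply(x$epoch, pearson_connectivity)
  }
  if (!is.list(x) || length(x) == 0L) {
    stop("`x` must be a non-empty list of connectivity matrices or a manifest",
         call. = FALSE)
  }
  d <- dim(x[[1]])
  for (m in x) {
    check_conn_matrix(m)
    if (!identical(dim(m), d)) {
      stop("all matrices must have the same shape", call. = FALSE)
    }
  }
  Reduce(`+`, x) / length(x)
}

#' Node-space normalization
#'
#' Standardizes the signal across channels at every time step: subtracts the
#' instantaneous mean over channels and divides by the instantaneous sample
#' standard deviation over channels (divisor `n - 1`). Time steps where all
#' channels are equal (zero node-space variance) are zeroed and flagged in
#' `valid`, so no NaN propagates downstream.
#'
#' A consequence of this normalization is that any component added uniformly
#' to all channels cancels exactly, and `sum_{i,j} (x_i(t) - x_j(t))^2 =
#' 2 n (n - 1)` at every valid t.
#'
#' @param epoch An [eeg_epoch()] with at least 2 channels.
#' @return An object of class `normalized_epoch`: list with `data` (n x T
#'   matrix), `valid` (logical length T) and `sampling_rate`.
#' @export
#' @examples
#' ep <- eeg_epoch(rbind(1:4, c(2, 1, 4, 3), c(0, 0, 1, 2)), 10)
#' nz <- normalize_nodes(ep)
#' colMeans(nz$data)   # ~0 at every valid time step
normalize_nodes <- function(epoch) {
  stopifnot_epoch(epoch)
  x <- epoch$data
  n <- nrow(x)
  mu <- colMeans(x)
  centered <- sweep(x, 2, mu)
  s <- sqrt(colSums(centered^2) / (n - 1))
  valid <- s > 0
  out <- matrix(0, n, ncol(x), dimnames = dimnames(x))
  if (any(valid)) {
    out[, valid] <- sweep(centered[, valid, drop = FALSE], 2, s[valid], "/")
  }
  structure(list(data = out, valid = valid, sampling_rate = epoch$sampling_rate),
            class = "normalized_epoch")
}

#' @export
print.normalized_epoch <- function(x, ...) {
  cat(sprintf("<normalized_epoch> %d channels x %d samples (%d valid)\n",
              nrow(x$data), ncol(x$data), sum(x$valid)))
  invisible(x)
}

# Registry of instantaneous bivariate node functions F_V(x_i(t), x_j(t)).
.node_functions <- list(
  squared_difference = function(xi, xj) (xi - xj)^2
)

#' Instantaneous filtered connectivity tensor
#'
#' Builds the n x n x T stack of instantaneous connectivity slices: slice t
#' has entry `(i, j) = filter_ij * F_V(xt_i(t), xt_j(t))` for `i != j` and 0
#' on the diagonal, where `xt` is the node-space-normalized epoch. With the
#' shipped `"squared_difference"` node function and the cohort filter this is
#' the FAST connectivity tensor; with a participant's own
#' [pearson_connectivity()] matrix it is the individual-filter (GVD) variant,
#' and with an all-ones off-diagonal filter the unfiltered control.
#'
#' Time steps flagged invalid by [normalize_nodes()] yield all-zero slices.
#'
#' @param filter Square connectivity matrix matching the epoch's channels.
#' @param epoch An [eeg_epoch()] (or an already-computed `normalized_epoch`).
#' @param node_function Name of a registered node function; currently
#'   `"squared_difference"`.
#' @return Numeric array `n x n x T` with attributes `sampling_rate` and
#'   `node_function`.
#' @export
#' @examples
#' set.seed(1)
#' ep <- simulate_background(sim_config(n_channels = 6, epoch_duration = 0.1))
#' th <- build_tensor(ones_filter(6), ep)
#' dim(th)
build_tensor <- function(filter, epoch, node_function = "squared_difference") {
  fv <- .node_functions[[node_function]]
  if (is.null(fv)) {
    stop(sprintf("unsupported node function: '%s' (available: %s)",
                 node_function,
                 paste(names(.node_functions), collapse = ", ")),
         call. = FALSE)
  }
  nz <- if (inherits(epoch, "normalized_epoch")) epoch else normalize_nodes(epoch)
  check_conn_matrix(filter)
  n <- nrow(nz$data)
  if (nrow(filter) != n) {
    stop("`filter` shape must match the epoch channel count", call. = FALSE)
  }
  T <- ncol(nz$data)
  out <- array(0, c(n, n, T))
  for (t in seq_len(T)) {
    if (!nz$valid[t]) next
    xt <- nz$data[, t]
    slice <- filter * outer(xt, xt, fv)
    diag(slice) <- 0
    out[, , t] <- slice
  }
  attr(out, "sampling_rate") <- nz$sampling_rate
  attr(out, "node_function") <- node_function
  out
}

#' All-ones off-diagonal support
#'
#' The "unfiltered" control support: 1 everywhere except a zero main
#' diagonal. On node-space-normalized signals it makes the summed
#' squared-difference connectivity identically `2 n (n - 1)` at every valid
#' time step, which is why unfiltered mean edge weights carry no temporal
#' information.
#'
#' @param n Number of nodes.
#' @return An `n x n` matrix of ones with zero diagonal.
#' @export
ones_filter <- function(n) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  m
}

#' Graph Dirichlet energy
#'
#' The literal double sum `sum_{i,j} w_ij (x_i - x_j)^2 = 2 x' L x`, a
#' measure of how much the signal varies across strongly weighted edges
#' (small values mean the signal is smooth over the graph).
#'
#' @param weights Square symmetric non-negative weight matrix, zero diagonal.
#' @param x Numeric signal vector, one value per node.
#' @return Non-negative scalar.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
#' dirichlet_energy(w, c(1, 0, 0))   # both (1,2) and (2,1) terms: 2
dirichlet_energy <- function(weights, x) {
  check_conn_matrix(weights, "weights")
  if (length(x) != nrow(weights)) {
    stop("`x` length must match the weight matrix dimension", call. = FALSE)
  }
  sum(weights * outer(x, x, "-")^2)
}

# Fast equivalent of apply(build_tensor(...), 3, sum) / windowed means,
# via sum_ij w_ij (x_i - x_j)^2 = 2 (x' D x - x' W x), D = diag(rowSums(W)).
# Used by the pipeline; equivalence with the tensor route is tested.
energy_series <- function(filter, normalized) {
  X <- normalized$data
  d <- rowSums(filter)
  2 * (colSums(X * (d * X)) - colSums(X * (filter %*% X)))
}

# Windowed mean slices without materializing the tensor:
# mean_t[(x_i - x_j)^2] = q_i + q_j - 2 S_ij / m, with S = X X', q = diag(S)/m.
windowed_matrices <- function(filter, normalized, n_windows) {
  X <- normalized$data
  T <- ncol(X)
  parts <- partition_windows(T, n_windows)
  lapply(parts, function(idx) {
    m <- length(idx)
    Xw <- X[, idx, drop = FALSE]
    S <- tcrossprod(Xw) / m
    q <- diag(S)
    A <- outer(q, q, "+") - 2 * S
    out <- filter * A
    diag(out) <- 0
    dimnames(out) <- dimnames(filter)
    out
  })
}
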