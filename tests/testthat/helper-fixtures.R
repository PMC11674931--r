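# Shared fixture builders; everything is generated in code at test time.

rand_epoch <- function(n = 5, T = 20, fs = 100) {
  eeg_epoch(matrix(rnorm(n * T), n, T), fs)
}

# Random valid connectivity matrix: symmetric, zero diagonal, entries [0, 1].
rand_conn <- function(n = 5) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 6L, sampling_rate = 100, epoch_duration = 0.4,
         background_amplitude = 5), list(...))
  do.call(sim_config, args)
}

# Two-group null manifest (no ERP anywhere), scaled down.
null_manifest <- function(n_per_group = 4, seed = 1, ...) {
  cfg <- tiny_config(...)
  simulate_study(c(n_per_group, n_per_group), cfg, cfg,
                 groups = c("a", "b"), seed = seed)
}
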