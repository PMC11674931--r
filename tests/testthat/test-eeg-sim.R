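test_that("background epochs have the configured shape and seeded determinism", {
  cfg <- sim_config()
  expect_equal(cfg$n_samples, 200L)
  set.seed(11)
  bg <- simulate_background(cfg)
  expect_equal(dim(bg), c(31L, 200L))
  set.seed(11)
  bg2 <- simulate_background(cfg)
  expect_identical(bg$data, bg2$data)
  set.seed(12)
  bg3 <- simulate_background(cfg)
  expect_true(any(bg3$data != bg$data))
})

test_that("zero background amplitude yields an all-zero epoch", {
  set.seed(1)
  bg <- simulate_background(tiny_config(background_amplitude = 0))
  expect_true(all(bg$data == 0))
})

test_that("background scale is per-channel peak-to-peak and exactly linear", {
  cfg1 <- tiny_config(background_amplitude = 3)
  cfg2 <- tiny_config(background_amplitude = 7.5)
  set.seed(5)
  a <- simulate_background(cfg1)
  ptp <- apply(a$data, 1, function(x) diff(range(x)))
  expect_equal(ptp, rep(6, 6), ignore_attr = TRUE)
  set.seed(5)
  b <- simulate_background(cfg2)
  expect_equal(b$data, a$data * 2.5)
})

test_that("background spectrum decays with frequency", {
  set.seed(2)
  cfg <- sim_config(n_channels = 2, sampling_rate = 200, epoch_duration = 40)
  bg <- simulate_background(cfg)
  spec <- Mod(stats::fft(bg$data[1, ]))^2
  T <- cfg$n_samples
  f <- (seq_len(T) - 1) * cfg$sampling_rate / T
  lowband <- mean(spec[f >= 1 & f <= 5])
  highband <- mean(spec[f >= 40 & f <= 80])
  expect_gt(lowband / highband, 5)
})

test_that("rendered components have the stated peak, width and edge truncation", {
  # P300: amplitude 5, 5 Hz at 250 samples/s -> 25-sample half cycle
  w <- render_component(erp_p300(), 200, 250)
  expect_equal(w[75], 5)
  expect_equal(which.max(w), 75L)
  expect_equal(sum(w != 0), round(250 / (2 * 5)))

  # brute-force support count across parameter grid
  for (f in c(2, 5, 9, 15, 30)) {
    for (fs in c(100, 250)) {
      cm <- erp_component(3, f, 60L, jitter_frames = 0L)
      w <- render_component(cm, 150, fs)
      expect_equal(sum(w != 0), max(1, round(fs / (2 * f))),
                   info = sprintf("f=%g fs=%g", f, fs))
    }
  }

  # negative polarity and zero amplitude
  wn <- render_component(erp_n100(), 200, 250)
  expect_equal(min(wn), -5)
  expect_true(all(render_component(erp_component(0, 5, 10L), 50, 100) == 0))

  # truncation: center near the epoch start keeps only in-range samples
  we <- render_component(erp_component(2, 1, 2L, jitter_frames = 0L), 30, 100)
  expect_equal(length(we), 30L)
  expect_lt(sum(we != 0), round(100 / 2))
})

test_that("jitter offsets shift the peak by exactly the offset and are bounded", {
  cm <- erp_component(4, 10, 50L, jitter_frames = 5L)
  for (off in -5:5) {
    w <- render_component(cm, 100, 200, off)
    expect_equal(which.max(w), 50L + off)
  }
  expect_error(render_component(cm, 100, 200, 6L), "jitter")
})

test_that("a single noiseless trial reproduces the background stream", {
  cfg <- tiny_config(n_trials = 1L, noise_sigma = 0)
  set.seed(21)
  a <- simulate_participant(cfg)
  set.seed(21)
  b <- simulate_background(cfg)
  expect_identical(a$data, b$data)
})

test_that("added noise matches its nominal standard deviation", {
  cfg <- sim_config(n_channels = 50L, sampling_rate = 250,
                    epoch_duration = 1.6, background_amplitude = 0,
                    noise_sigma = 2)
  set.seed(31)
  ep <- simulate_participant(cfg)   # 50 x 400 = 2e4 pure-noise values
  expect_equal(sd(ep$data), 2, tolerance = 0.05)
})

test_that("trial averaging shrinks the background as 1/sqrt(n_trials)", {
  sd_for <- function(k) {
    cfg <- tiny_config(n_channels = 20L, epoch_duration = 1,
                       n_trials = as.integer(k))
    mean(replicate(8, sd(simulate_participant(cfg)$data)))
  }
  set.seed(41)
  s1 <- sd_for(1); s4 <- sd_for(4); s16 <- sd_for(16)
  expect_equal(s4 / s1, 0.5, tolerance = 0.12)
  expect_equal(s16 / s1, 0.25, tolerance = 0.12)
})

test_that("ERP contribution is additive over the background (fixed latency)", {
  comp <- list(erp_component(5, 5, 25L, jitter_frames = 0L),
               erp_component(-3, 10, 10L, jitter_frames = 0L))
  cfg_with <- tiny_config(components = comp, n_trials = 3L)
  cfg_without <- tiny_config(n_trials = 3L)
  set.seed(51)
  a <- simulate_participant(cfg_with)
  set.seed(51)
  b <- simulate_participant(cfg_without)
  expected <- Reduce(`+`, lapply(comp, function(cm) {
    outer(erp_topography(6), render_component(cm, 40, 100))
  }))
  expect_equal(a$data - b$data, expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("jittered ERP support never strays beyond jitter_frames", {
  cm <- erp_component(5, 10, 20L, jitter_frames = 5L)
  cfg_with <- tiny_config(components = list(cm), n_trials = 1L,
                          background_amplitude = 0)
  for (s in 1:20) {
    set.seed(s)
    ep <- simulate_participant(cfg_with)
    nz <- which(colSums(abs(ep$data)) > 0)
    L <- round(100 / (2 * 10))
    lo <- 20 - 5 - floor((L - 1) / 2)
    hi <- 20 + 5 + ceiling((L - 1) / 2)
    expect_true(all(nz >= lo & nz <= hi))
  }
})

test_that("custom topographies scale the component per channel", {
  topo <- c(1, 0, -1, 0.5, 0, 0)
  cm <- erp_component(2, 5, 20L, jitter_frames = 0L, topography = topo)
  cfg <- tiny_config(components = list(cm), background_amplitude = 0)
  set.seed(1)
  ep <- simulate_participant(cfg)
  w <- render_component(cm, 40, 100)
  expect_equal(ep$data, outer(topo, w), ignore_attr = TRUE)
})

test_that("study manifests have the requested structure and determinism", {
  cfg_e <- tiny_config(components = list(erp_component(2, 5, 20L)))
  cfg_c <- tiny_config()
  man <- simulate_study(c(3, 2), cfg_e, cfg_c, seed = 7)
  expect_equal(nrow(man), 5L)
  expect_equal(as.vector(table(man$group)[c("erp", "control")]), c(3L, 2L))
  expect_true(all(vapply(man$epoch, function(e) all(dim(e) == c(6, 40)),
                         logical(1))))
  man2 <- simulate_study(c(3, 2), cfg_e, cfg_c, seed = 7)
  expect_identical(
    lapply(man$epoch, `[[`, "data"), lapply(man2$epoch, `[[`, "data"))

  expect_equal(nrow(simulate_study(c(0, 0), cfg_e, cfg_c, seed = 1)), 0L)
  expect_error(
    simulate_study(c(2, 2), cfg_e, tiny_config(n_channels = 4L), seed = 1),
    "share")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_channels = 1), "n_channels")
  expect_error(sim_config(n_trials = 0), "n_trials")
  expect_error(sim_config(noise_sigma = -1), "noise_sigma")
  expect_error(sim_config(components = list(erp_component(1, 5, 900L))),
               "outside")
  expect_error(erp_component(1, -2, 10L), "frequency")
  expect_error(erp_component(1, 5, 10L, jitter_frames = -1), "jitter")
})
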