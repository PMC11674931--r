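test_that("absolute Pearson matrix matches the direct summation formula", {
  set.seed(1)
  x <- matrix(rnorm(15), 3, 5)
  ep <- eeg_epoch(x, 100)
  C <- pearson_connectivity(ep)
  # term-by-term evaluation of the correlation sum
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    oracle[i, j] <- abs(sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)))
  }
  expect_equal(unname(C), oracle, tolerance = 1e-12)
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(0, 3), ignore_attr = TRUE)
})

test_that("perfectly correlated and anti-correlated channels give entry 1", {
  x <- rnorm(30)
  ep <- eeg_epoch(rbind(x, x + 0, -x), 100)
  C <- pearson_connectivity(ep)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], 1)   # modulus of the correlation
})

test_that("zero-variance channels are rejected by name", {
  ep <- eeg_epoch(rbind(rnorm(10), rep(2, 10)), 100,
                  channel_labels = c("Fz", "Cz"))
  expect_error(pearson_connectivity(ep), "Cz")
})

test_that("the FAST filter is the elementwise participant mean", {
  set.seed(2)
  m1 <- rand_conn(4)
  expect_identical(fast_filter(list(m1)), m1)
  m2 <- rand_conn(4)
  expect_equal(fast_filter(list(m1, m2)), (m1 + m2) / 2)

  mats <- replicate(5, rand_conn(6), simplify = FALSE)
  avg <- fast_filter(mats)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    oracle[i, j] <- mean(vapply(mats, function(m) m[i, j], numeric(1)))
  }
  expect_equal(avg, oracle, tolerance = 1e-14)

  expect_identical(fast_filter(list(m1, m1, m1)), m1)  # idempotent
  expect_error(fast_filter(list()), "non-empty")
  expect_error(fast_filter(list(m1, rand_conn(5))), "shape")
})

test_that("a manifest yields the mean of per-participant correlation matrices", {
  set.seed(3)
  man <- null_manifest(3)
  f <- fast_filter(man)
  oracle <- Reduce(`+`, lapply(man$epoch, pearson_connectivity)) / nrow(man)
  expect_equal(f, oracle)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("node-space normalization is a per-timestep z-score with n-1 divisor", {
  set.seed(4)
  ep <- rand_epoch(5, 12)
  nz <- normalize_nodes(ep)
  expect_true(all(nz$valid))
  expect_lt(max(abs(colMeans(nz$data))), 1e-10)
  sds <- apply(nz$data, 2, sd)
  expect_lt(max(abs(sds - 1)), 1e-8)

  # hand evaluation for the column (1, 2, 3, 4): mean 2.5, sd sqrt(5/3)
  ep4 <- eeg_epoch(cbind(c(1, 2, 3, 4), c(0, 0, 0, 1)), 10)
  nz4 <- normalize_nodes(ep4)
  expect_equal(nz4$data[, 1], (c(1, 2, 3, 4) - 2.5) / sqrt(5 / 3),
               ignore_attr = TRUE)
})

test_that("constant columns are invalid-masked and zeroed", {
  ep <- eeg_epoch(cbind(c(1, 1, 1), c(1, 2, 3)), 10)
  nz <- normalize_nodes(ep)
  expect_equal(nz$valid, c(FALSE, TRUE))
  expect_equal(nz$data[, 1], rep(0, 3), ignore_attr = TRUE)
})

test_that("dirichlet energy equals the literal double sum and x'Lx", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  expect_equal(dirichlet_energy(w, c(1, 0, 0)), 2)   # both ordered terms
  expect_equal(dirichlet_energy(rand_conn(6), rep(3.7, 6)), 0)

  set.seed(5)
  for (rep in 1:5) {
    W <- rand_conn(7)
    x <- rnorm(7)
    L <- diag(rowSums(W)) - W
    expect_equal(dirichlet_energy(W, x), 2 * drop(t(x) %*% L %*% x),
                 tolerance = 1e-11)
  }
})

test_that("tensor slices implement filter times squared difference", {
  set.seed(6)
  ep <- rand_epoch(6, 15)
  nz <- normalize_nodes(ep)
  W <- rand_conn(6)
  th <- build_tensor(W, ep)
  expect_equal(dim(th), c(6L, 6L, 15L))

  # loop oracle on a few slices
  for (t in c(1, 7, 15)) {
    slice <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6) {
      if (i != j) slice[i, j] <- W[i, j] * (nz$data[i, t] - nz$data[j, t])^2
    }
    expect_equal(th[, , t], slice, tolerance = 1e-12)
  }

  # slice-sum identity: sum_ij slice_t equals the double-sum Dirichlet
  # energy (itself 2 x'Lx) at every t
  for (t in 1:15) {
    expect_equal(sum(th[, , t]), dirichlet_energy(W, nz$data[, t]),
                 tolerance = 1e-9)
  }
})

test_that("the all-ones support makes every valid slice sum to 2n(n-1)", {
  set.seed(7)
  n <- 8
  th <- build_tensor(ones_filter(n), rand_epoch(n, 20))
  sums <- apply(th, 3, sum)
  expect_equal(sums, rep(2 * n * (n - 1), 20), tolerance = 1e-9)
})

test_that("zero filters, invalid timesteps and unknown node functions", {
  ep <- rand_epoch(4, 6)
  z <- matrix(0, 4, 4)
  expect_true(all(build_tensor(z, ep) == 0))

  epc <- eeg_epoch(cbind(c(1, 1, 1), c(1, 2, 3), c(2, 0, 1)), 10)
  th <- build_tensor(ones_filter(3), epc)
  expect_true(all(th[, , 1] == 0))   # constant column -> zero slice
  expect_true(any(th[, , 2] != 0))

  expect_error(build_tensor(ones_filter(4), ep, "phase_lock"), "unsupported")
})

test_that("channel relabeling permutes filter and tensor consistently", {
  set.seed(8)
  ep <- rand_epoch(5, 10)
  W <- rand_conn(5)
  perm <- sample(5)
  ep_p <- eeg_epoch(ep$data[perm, ], ep$sampling_rate)
  th <- build_tensor(W, ep)
  th_p <- build_tensor(W[perm, perm], ep_p)
  expect_equal(th_p[, , 4], th[perm, perm, 4], tolerance = 1e-12)
})

test_that("windowed fast path equals the explicit tensor route", {
  set.seed(9)
  ep <- rand_epoch(6, 23)
  W <- rand_conn(6)
  for (nw in c(1, 4, 23)) {
    a <- fast_connectivity(W, ep, nw)
    b <- window_average(build_tensor(W, ep), nw)
    expect_equal(a$matrices, b$matrices, tolerance = 1e-11)
    expect_equal(a$bounds, b$bounds)
  }
})
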