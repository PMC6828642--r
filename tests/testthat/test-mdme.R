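test_that("forward model matches its closed form at hand-computed points", {
  pr <- mdme_protocol(saturation_delays_ms = c(1e-9, 1000, 1e6),
                      echo_times_ms = c(1e-9, 13))
  sig <- mdme_forward(2000, 150, 80, b1 = 1, protocol = pr)
  # TD = 1000, TE ~ 0: 80 * (1 - 1.5 * exp(-0.5)) = 7.2163...
  expect_equal(sig$signal[1, 2, 1], 80 * abs(1 - 1.5 * exp(-0.5)),
               tolerance = 1e-6)
  # full recovery: TD -> inf, TE ~ 0 gives PD
  expect_equal(sig$signal[1, 3, 1], 80, tolerance = 1e-3)
  # TD -> 0 gives |1 - 1.5| * PD = 0.5 * PD under magnitude convention
  expect_equal(sig$signal[1, 1, 1], 40, tolerance = 1e-6)
  expect_error(mdme_forward(-1, 100, 80, protocol = pr), "positive")
})

test_that("signal is monotone in TE everywhere and in TD past the null", {
  pr <- mdme_protocol(saturation_delays_ms = seq(100, 5000, by = 100),
                      echo_times_ms = seq(10, 200, by = 10))
  for (t1 in c(900, 1500, 2100)) {
    sig <- mdme_forward(t1, 150, 80, protocol = pr)$signal[1, , ]
    # decreasing in TE at every delay
    expect_true(all(apply(sig, 1, function(r) all(diff(r) < 0))))
    # increasing in TD on the recovery branch TD > T1 * log(k)
    null_td <- t1 * log(1.5)
    branch <- pr$saturation_delays_ms > null_td
    expect_true(all(diff(sig[branch, 1]) > 0))
  }
})

test_that("noise injection is seeded and respects its model", {
  pr <- mdme_protocol()
  sig <- mdme_forward(rep(1500, 50), rep(120, 50), rep(80, 50), protocol = pr)
  expect_identical(add_noise(sig, 0, "rician", seed = 1), sig)
  a <- add_noise(sig, 2, "rician", seed = 5)
  b <- add_noise(sig, 2, "rician", seed = 5)
  c <- add_noise(sig, 2, "rician", seed = 6)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
  expect_true(all(a$signal >= 0))
  expect_error(add_noise(sig, -1), ">= 0")
})

test_that("rician noise on a zero signal has the Rayleigh mean", {
  pr <- mdme_protocol(saturation_delays_ms = c(100, 200),
                      echo_times_ms = c(10, 20))
  n <- 25000  # x 4 grid points = 1e5 samples
  zero <- mdme_forward(rep(1000, n), rep(100, n), rep(1e-9, n), protocol = pr)
  noisy <- add_noise(zero, 3, "rician", seed = 17)
  expect_equal(mean(noisy$signal), 3 * sqrt(pi / 2), tolerance = 0.01)
})

test_that("noiseless round-trip recovers T1, T2, PD across the bin ranges", {
  pr <- mdme_protocol()
  grid <- expand.grid(t1 = seq(800, 2200, length.out = 8),
                      t2 = seq(80, 220, length.out = 8))
  sig <- mdme_forward(grid$t1, grid$t2, rep(80, nrow(grid)), protocol = pr)
  fit <- fit_qmaps(sig, pr)
  expect_true(all(fit$converged))
  expect_lt(max(abs(fit$t1 - grid$t1) / grid$t1), 1e-3)
  expect_lt(max(abs(fit$t2 - grid$t2) / grid$t2), 1e-3)
  expect_lt(max(abs(fit$pd - 80) / 80), 1e-3)
  expect_lt(max(fit$residual), 1e-8)
})

test_that("T1 recovery at SNR 50 has median relative error below 2%", {
  pr <- mdme_protocol()
  set.seed(99)
  n <- 500
  t1 <- runif(n, 800, 2200); t2 <- runif(n, 80, 220); pd <- rep(80, n)
  sig <- add_noise(mdme_forward(t1, t2, pd, protocol = pr),
                   sigma = 80 / 50, model = "rician", seed = 7)
  fit <- fit_qmaps(sig, pr)
  expect_lt(median(abs(fit$t1 - t1) / t1), 0.02)
})

test_that("fit error does not increase with SNR", {
  pr <- mdme_protocol()
  set.seed(5)
  n <- 300
  t1 <- runif(n, 900, 2100); t2 <- runif(n, 90, 210); pd <- rep(80, n)
  clean <- mdme_forward(t1, t2, pd, protocol = pr)
  err <- vapply(c(10, 50, 250), function(snr) {
    fit <- fit_qmaps(add_noise(clean, 80 / snr, "rician", seed = 31), pr)
    median(abs(fit$t1 - t1) / t1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("degenerate voxels are flagged, not silently clamped", {
  pr <- mdme_protocol()
  sig <- mdme_forward(c(1500, 1500), c(120, 120), c(80, 1e-20), protocol = pr)
  sig$signal[2, , ] <- 0
  fit <- fit_qmaps(sig, pr)
  expect_true(fit$converged[[1]])
  expect_false(fit$converged[[2]])
  expect_true(is.na(fit$t1[[2]]))
  expect_true(is.finite(fit$t1[[1]]))
})

test_that("known B1 is honoured and B1 fitting recovers a coarse estimate", {
  pr <- mdme_protocol()
  t1 <- rep(c(1000, 1600), 5); t2 <- rep(130, 10); pd <- rep(80, 10)
  b1 <- rep(1.1, 10)
  sig <- mdme_forward(t1, t2, pd, b1 = b1, protocol = pr)
  # fitting with the true B1 supplied recovers the parameters
  fit <- fit_qmaps(sig, pr, options = list(b1 = 1.1))
  expect_lt(max(abs(fit$t1 - t1) / t1), 1e-3)
  # fitting B1 jointly lands on the coarse-grid value
  fitb <- fit_qmaps(sig, pr, options = list(fit_b1 = TRUE))
  expect_lt(max(abs(fitb$b1 - 1.1)), 0.026)
})
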