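test_that("Morlet kernel has the prescribed width and normalization", {
  k <- morlet_kernel(30, 14, 1000)
  expect_equal(attr(k, "sigma_t"), 14 / (2 * pi * 30))     # ~74.3 ms
  expect_equal(attr(k, "sigma_t"), 0.0743, tolerance = 1e-3)
  expect_equal(length(k) / 1000, 0.446, tolerance = 0.01)  # ~446 ms support
  expect_equal(sum(Mod(k)^2), 1, tolerance = 1e-9)
  # doubling the sampling rate keeps sigma_t, doubles the sample count
  k2 <- morlet_kernel(30, 14, 2000)
  expect_equal(attr(k2, "sigma_t"), attr(k, "sigma_t"))
  expect_equal(length(k2), 2 * length(k), tolerance = 2)
  expect_equal(sum(Mod(k2)^2), 1, tolerance = 1e-9)
})

make_sine_epochs <- function(f, fs = 500, amp = 1, n_trials = 2,
                             phase = 0) {
  times <- -1 + (seq_len(3 * fs + 1) - 1) / fs
  x <- amp * cos(2 * pi * f * times + phase)
  data <- array(rep(x, each = n_trials), c(n_trials, 1, length(times)))
  epochs_from_array(data, sample_rate = fs, t0 = -1, channels = "Cz")
}

test_that("a pure sinusoid is a matched filter for its own frequency", {
  ep <- make_sine_epochs(40)
  tfr <- tfr_decompose(ep, freqs = 30:60, tmin = -0.2, tmax = 0.2)
  prof <- apply(Mod(tfr$coeffs[1, 1, , ]), 1, mean)
  expect_equal(tfr$freqs[which.max(prof)], 40)
  # calibrated amplitude scale: |coeff| ~ signal amplitude
  expect_equal(max(prof), 1, tolerance = 0.01)
})

test_that("unit sinusoids give the same coefficient magnitude at every grid frequency", {
  mags <- vapply(c(30, 40, 50, 60), function(f) {
    ep <- make_sine_epochs(f)
    tfr <- tfr_decompose(ep, freqs = f, tmin = -0.05, tmax = 0.05)
    mean(Mod(tfr$coeffs[1, 1, 1, ]))
  }, numeric(1))
  expect_true(all(abs(mags / mags[1] - 1) < 0.01))
})

test_that("coefficient phase advances at the analytic rate", {
  fs <- 500
  ep <- make_sine_epochs(40, fs = fs, phase = 0.7)
  tfr <- tfr_decompose(ep, freqs = 40, tmin = -0.2, tmax = 0.2)
  ph <- Arg(tfr$coeffs[1, 1, 1, ])
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi       # unwrap steps
  slope <- mean(dph) * fs
  expect_equal(slope, 2 * pi * 40, tolerance = 2 * pi * 40 * 1e-3)
  # phase at t = 0 equals the signal phase
  i0 <- which.min(abs(tfr$times))
  expect_equal(unname(Arg(tfr$coeffs[1, 1, 1, i0])), 0.7, tolerance = 1e-3)
})

test_that("off-frequency attenuation matches a discrete-Fourier oracle of the kernel", {
  fs <- 500
  ep <- make_sine_epochs(40, fs = fs)
  tfr <- tfr_decompose(ep, freqs = c(40, 45), tmin = -0.05, tmax = 0.05)
  ratio <- mean(Mod(tfr$coeffs[1, 1, 2, ])) / mean(Mod(tfr$coeffs[1, 1, 1, ]))
  # oracle: response of each calibrated kernel to a 40 Hz tone, evaluated
  # as a discrete Fourier sum of the kernel itself
  resp <- vapply(c(40, 45), function(fk) {
    k <- morlet_kernel(fk, 14, fs)
    tt <- (seq_along(k) - (length(k) + 1) / 2) / fs
    0.5 * Mod(sum((k / attr(k, "gain")) * exp(-2i * pi * 40 * tt)))
  }, numeric(1))
  expect_equal(ratio, resp[2] / resp[1], tolerance = 0.01)
})

test_that("decomposition is linear and shift-equivariant", {
  set.seed(5)
  fs <- 200
  n <- 3 * fs + 1
  x <- array(rnorm(2 * n), c(2, 1, n))
  y <- array(rnorm(2 * n), c(2, 1, n))
  epx <- epochs_from_array(x, fs); epy <- epochs_from_array(y, fs)
  epz <- epochs_from_array(2 * x - 3 * y, fs)
  fr <- c(35, 50)
  tz <- tfr_decompose(epz, freqs = fr)
  tx <- tfr_decompose(epx, freqs = fr)
  ty <- tfr_decompose(epy, freqs = fr)
  expect_equal(tz$coeffs, 2 * tx$coeffs - 3 * ty$coeffs, tolerance = 1e-9)
  # shifting the signal by k samples shifts coefficients by k samples
  k <- 15
  xs <- array(0, dim(x)); xs[, , (k + 1):n] <- x[, , 1:(n - k)]
  ts_ <- tfr_decompose(epochs_from_array(xs, fs), freqs = fr)
  inner <- 400:500
  expect_equal(ts_$coeffs[, , , inner + k], tx$coeffs[, , , inner],
               tolerance = 1e-9)
})

test_that("FFT convolution equals direct convolution", {
  set.seed(8)
  fs <- 200
  n <- 3 * fs + 1
  x <- rnorm(n)
  ep <- epochs_from_array(array(rep(x, each = 2), c(2, 1, n)), fs)
  tfr <- tfr_decompose(ep, freqs = 42)
  k <- morlet_kernel(42, 14, fs)
  kc <- k / attr(k, "gain")
  half <- (length(k) - 1) / 2
  direct <- vapply(seq_len(n), function(i) {
    js <- max(1, i - half):min(n, i + half)
    sum(x[js] * kc[i - js + half + 1])
  }, complex(1))
  expect_equal(as.vector(tfr$coeffs[1, 1, 1, ]), direct, tolerance = 1e-9)
})

test_that("validity mask flags epoch-edge samples and errors are explicit", {
  fs <- 200
  ep <- make_sine_epochs(40, fs = fs)
  tfr <- tfr_decompose(ep, freqs = c(30, 60))
  half30 <- (length(morlet_kernel(30, 14, fs)) - 1) / 2 / fs
  expect_false(tfr$valid[1, 1])
  expect_true(all(tfr$valid[, tfr$times > -1 + half30 + 0.01 &
                              tfr$times < 2 - half30 - 0.01]))
  # baseline and analysis windows lie inside the valid region
  expect_true(all(tfr$valid[, tfr$times >= -0.5 & tfr$times <= 1.6]))
  short <- epochs_from_array(array(rnorm(40), c(2, 1, 20)), 200)
  expect_error(tfr_decompose(short, freqs = 30), "longer epochs")
  bad <- make_sine_epochs(40); bad$data[1, 1, 5] <- NaN
  expect_error(tfr_decompose(bad, freqs = 40), "non-finite")
  expect_error(tfr_decompose(make_sine_epochs(40), freqs = 40,
                             channels = "F9"), "F9")
})
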