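test_that("reference narrow signals carry the standard centers", {
  expect_equal(signal5()$centers, c(8.73, 21.54, 53.15))
  expect_equal(signal1()$centers, c(1.44, 21.54, 323.45))
  ## signal5's adjacent-peak ratios are both ~2.47
  ctr <- signal5()$centers
  expect_equal(round(ctr[2] / ctr[1], 2), 2.47)
  expect_equal(round(ctr[3] / ctr[2], 2), 2.47)
})

test_that("spectra are index-space Gaussians snapped to the grid", {
  t2g <- build_t2_grid()
  spec <- synthetic_spec(100, 1, width_std = 2)
  f <- make_spectrum(spec, t2g)
  jc <- which.max(f)
  expect_equal(t2g$constants[jc], 100, tolerance = 0.03)
  ## symmetric in index space around the center bin
  expect_equal(f[jc - (1:5)], f[jc + (1:5)], tolerance = 1e-12)
  expect_equal(max(f), 1)
  expect_error(make_spectrum(synthetic_spec(1e6), t2g), "inside")
})

test_that("forward simulation is the physical multiexponential decay", {
  tg <- build_time_grid(1, 200)
  t2g <- build_t2_grid(1, 1000, 64)
  ## single delta of mass 1 at T -> s(t) = exp(-t/T)
  j <- 30
  f <- replace(numeric(64), j, 1)
  tr <- forward_simulate(f, tg, t2g)
  Tj <- t2g$constants[j]
  expect_equal(tr$amplitudes, exp(-tg$times / Tj), tolerance = 1e-12)
  i_near <- which.min(abs(tg$times - Tj))
  expect_equal(tr$amplitudes[i_near], exp(-tg$times[i_near] / Tj))
  ## linear superposition
  f2 <- replace(numeric(64), 50, 0.5)
  both <- forward_simulate(f + f2, tg, t2g)
  expect_equal(both$amplitudes,
               tr$amplitudes + forward_simulate(f2, tg, t2g)$amplitudes,
               tolerance = 1e-12)
  ## first echo below total mass, approaching it as dt -> 0
  fmix <- make_spectrum(synthetic_spec(c(20, 100), width_std = 3), t2g)
  s1 <- forward_simulate(fmix, build_time_grid(1, 5), t2g)$amplitudes[1]
  s2 <- forward_simulate(fmix, build_time_grid(0.001, 5), t2g)$amplitudes[1]
  expect_lt(s1, sum(fmix))
  expect_lt(s2, sum(fmix))
  expect_lt(sum(fmix) - s2, sum(fmix) - s1)
  expect_equal(s2, sum(fmix), tolerance = 1e-3)
  ## clean decay is strictly decreasing
  expect_true(all(diff(tr$amplitudes) < 0))
})

test_that("noise injection is seeded, scaled and self-consistent", {
  tg <- build_time_grid(0.1, 4096)
  t2g <- build_t2_grid()
  truth <- make_spectrum(signal4(), t2g)
  clean <- forward_simulate(truth, tg, t2g)
  ## Inf target returns the input unchanged
  expect_identical(add_noise(clean, Inf, 1), clean)
  ## identical seeds give bitwise-identical noise
  n1 <- add_noise(clean, 100, 3)
  n2 <- add_noise(clean, 100, 3)
  expect_identical(n1$amplitudes, n2$amplitudes)
  expect_false(identical(n1$amplitudes, add_noise(clean, 100, 4)$amplitudes))
  ## amplitude decomposition holds
  expect_equal(n1$amplitudes, clean$amplitudes + n1$noise_component)
  ## round trip: the SNR estimator recovers the target within 15%
  ests <- vapply(1:20, function(sd_i) add_noise(clean, 100, sd_i)$realized_snr, 0)
  expect_lt(abs(mean(ests) - 100) / 100, 0.15)
  expect_error(add_noise(clean, -10, 1), "> 0")
})

test_that("the two-peak series walks the moving peak toward the fixed one", {
  ser <- two_peak_series(2, 1000)
  expect_length(ser, 12)
  ratios <- attr(ser, "ratios")
  expect_equal(round(ratios[1], 2), 2.96)
  expect_equal(round(ratios[12], 2), 1.14)
  expect_true(all(diff(ratios) < 0))
  for (sp in ser) {
    expect_true(81.54 %in% sp$centers)
    expect_equal(sp$amplitudes, c(1, 1))
  }
})

test_that("the broad reference peak is a unimodal slow decay", {
  t2g <- build_t2_grid()
  f <- make_spectrum(broad_peak_spec(1000), t2g)
  expect_equal(nrow(find_peaks(f)), 1)
  tg <- build_time_grid()
  s <- forward_simulate(f, tg, t2g)$amplitudes
  ## decays to a few percent of the first echo by ten times the center T2
  ## (the slow tail reflects the bump's spread toward long T2) and keeps
  ## falling to the end of the acquisition window
  i10 <- which.min(abs(tg$times - 10 * 150))
  expect_lt(s[i10] / s[1], 0.05)
  expect_lt(s[length(s)] / s[1], 0.02)
  expect_true(all(diff(s) < 0))
})

test_that("noise-free inversion reproduces the measurements", {
  fx <- small_fixture(m = 200, n = 48, bins = c(15, 30))
  sp <- solve_inversion(inversion_model(fx$K, fx$s, 1e-12, 1e-12),
                        solver_options(tol = 1e-10, maxit = 300))
  expect_lt(sqrt(sum((drop(fx$K$matrix %*% sp$f) - fx$s)^2)) /
              sqrt(sum(fx$s^2)), 1e-6)
})

test_that("the simulate-invert-detect pipeline is reproducible bit for bit", {
  st <- standard_setup()
  run <- function() {
    sim <- simulate_train(signal4(2, 1000, 7), st$tg, st$t2g)
    fit <- invert_echo_train(sim$train, st$t2g, snr = 1000, kernel = st$kern)
    find_peaks(fit)
  }
  expect_identical(run(), run())
})
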