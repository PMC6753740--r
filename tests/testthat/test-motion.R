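test_that("trace loading validates input and resamples to a uniform rate", {
  f <- tempfile()
  writeLines(c("# surrogate trace", "0 0", "1 1"), f)
  tr <- load_trace(f, rate = 40)
  expect_s3_class(tr, "breathing_trace")
  expect_equal(trace_duration(tr), 1)
  expect_equal(tr$position, seq(0, 1, by = 1 / 40) / 1)  # linear ramp

  # shuffled times rejected
  writeLines(c("0 0", "2 1", "1 0.5"), f)
  expect_error(load_trace(f), class = "proton4d_domain_error")
  writeLines("0 0", f)
  expect_error(load_trace(f), class = "proton4d_domain_error")
  writeLines(c("0 0", "1 NaN"), f)
  expect_error(load_trace(f), class = "proton4d_domain_error")

  # non-uniform input: resampled trace reproduces the original samples
  # at the original times (linear interpolation identity)
  t0 <- c(0, 0.3, 0.45, 1.2, 2.0)
  y0 <- c(0, 1, 0.2, 0.8, 0.1)
  writeLines(paste(t0, y0, sep = ","), f)
  tr2 <- load_trace(f, rate = 40)
  expect_equal(approx(tr2$time, tr2$position, xout = t0)$y, y0,
               tolerance = 1e-12)

  # comma-delimited round trip through write_trace
  tr3 <- synth_trace("sin4", duration = 5)
  p <- write_trace(tr3, tempfile())
  expect_equal(load_trace(p)$position, tr3$position, tolerance = 1e-8)
})

test_that("preprocessing smooths, scales to the target RMS, and zeroes the quiescent baseline", {
  tt <- seq(0, 60, by = 1 / 40)
  raw <- breathing_trace(tt, 0.5 * sin(2 * pi * tt / 4) + 2, 40)
  out <- preprocess_trace(raw)
  # a 1-cm peak-to-peak sinusoid is already at the target RMS
  expect_equal(out$meta$scale_factor, 1, tolerance = 0.01)
  rms <- sqrt(mean((out$position - mean(out$position))^2))
  expect_equal(rms, 1 / (2 * sqrt(2)), tolerance = 1e-6)
  expect_equal(quantile(out$position, 0.05, names = FALSE), 0,
               tolerance = 1e-9)

  # idempotence: re-preprocessing changes nothing material
  out2 <- preprocess_trace(out)
  expect_equal(out2$meta$scale_factor, 1, tolerance = 0.01)
  expect_lt(max(abs(out2$position - out$position)), 0.02)

  # RMS recomputation oracle on an irregular trace
  irr <- preprocess_trace(synth_trace("irregular", duration = 60, seed = 3))
  expect_equal(sqrt(mean((irr$position - mean(irr$position))^2)),
               1 / (2 * sqrt(2)), tolerance = 1e-6)

  expect_error(preprocess_trace(breathing_trace(tt, rep(1, length(tt)), 40)),
               class = "proton4d_domain_error")
  short <- breathing_trace(seq(0, 1, 1 / 40), sin(seq(0, 1, 1 / 40)), 40)
  expect_error(preprocess_trace(short), class = "proton4d_domain_error")
})

test_that("synthetic traces match the sin^4 closed form and are seed-reproducible", {
  tr <- synth_trace("sin4", peak_to_peak = 1, period = 5, duration = 20)
  expect_equal(min(tr$position), 0)
  expect_equal(max(tr$position), 1, tolerance = 1e-6)
  expect_equal(tr$position, sin(pi * tr$time / 5)^4, tolerance = 1e-12)
  # periodicity
  i <- seq_len(sum(tr$time <= 15))
  expect_equal(tr$position[tr$time >= 5][i], tr$position[i],
               tolerance = 1e-9)

  # RMS about the mean of sin^4 with A = 1 vs numeric quadrature
  m1 <- stats::integrate(function(t) sin(pi * t / 5)^4, 0, 5)$value / 5
  m2 <- stats::integrate(function(t) sin(pi * t / 5)^8, 0, 5)$value / 5
  rms_quad <- sqrt(m2 - m1^2)
  dense <- synth_trace("sin4", duration = 500, rate = 200)
  expect_equal(sqrt(mean((dense$position - mean(dense$position))^2)),
               rms_quad, tolerance = 1e-4)

  # determinism contract
  a <- synth_trace("irregular", duration = 30, seed = 12)
  b <- synth_trace("irregular", duration = 30, seed = 12)
  c <- synth_trace("irregular", duration = 30, seed = 13)
  expect_identical(a$position, b$position)
  expect_false(identical(a$position, c$position))

  # zero jitter converges to the sin^4 closed form pointwise
  z <- synth_trace("irregular", amplitude_cv = 0, period_cv = 0,
                   baseline_sd = 0, duration = 20, seed = 5)
  expect_equal(z$position, sin(pi * z$time / 5)^4, tolerance = 1e-9)

  expect_error(synth_trace("sin4", peak_to_peak = -1),
               class = "proton4d_domain_error")
})

test_that("displacement maps the surrogate to one lateral axis in mm and tiles beyond the recording", {
  tt <- seq(0, 10, by = 1 / 40)
  tr <- breathing_trace(tt, 0.5 * sin(2 * pi * tt / 5)^2, 40)
  mp <- motion_model(tr, "parallel")
  mo <- motion_model(tr, "orthogonal")
  d <- displacement_at(mp, 1.25)
  expect_equal(drop(d), c(dx_mm = 5, dy_mm = 0, dz_mm = 0))
  expect_equal(drop(displacement_at(mo, 1.25)),
               c(dx_mm = 0, dy_mm = 5, dz_mm = 0))
  expect_equal(drop(displacement_at(mp, 0)), c(dx_mm = 0, dy_mm = 0, dz_mm = 0))

  # tiling: y(t + duration) = y(t); error mode refuses extrapolation
  ts <- c(0.4, 2.9, 7.3)
  expect_equal(displacement_at(mp, ts + 10), displacement_at(mp, ts),
               tolerance = 1e-9)
  me <- motion_model(tr, "parallel", extend = "error")
  expect_error(displacement_at(me, 11), class = "proton4d_domain_error")

  # amplitude scale
  m2 <- motion_model(tr, "parallel", amplitude_scale = 2)
  expect_equal(unname(displacement_at(m2, 1.25)[, 1]), 10)
})
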