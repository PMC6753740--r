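test_that("cumulative DVHs are monotone, start at 100%, and match brute force", {
  g <- dose_grid(c(0, 0, 0), 0.1, c(4, 1, 1),
                 array(c(90, 95, 100, 105), dim = c(4, 1, 1)))
  mask <- array(TRUE, dim = c(4, 1, 1))
  dvh <- compute_dvh(g, mask, bin_width = 0.5)
  expect_equal(dvh$volume_pct[1], 100)
  expect_true(all(diff(dvh$volume_pct) <= 0))
  # brute-force volume fractions at specific levels
  for (lev in c(0, 90, 92, 95.1, 100, 104.9, 106)) {
    i <- which.min(abs(dvh$dose - lev))
    expect_equal(dvh$volume_pct[i],
                 100 * mean(c(90, 95, 100, 105) >= dvh$dose[i]))
  }
  expect_error(compute_dvh(g, array(FALSE, dim = c(4, 1, 1))),
               class = "proton4d_domain_error")
  expect_error(compute_dvh(g, array(TRUE, dim = c(2, 2, 1))),
               class = "proton4d_domain_error")

  # random fields: monotonicity + endpoint normalization property
  set.seed(33)
  for (rep in 1:5) {
    vals <- array(runif(125, 0, 120), dim = c(5, 5, 5))
    gg <- dose_grid(c(0, 0, 0), 0.1, c(5, 5, 5), vals)
    m <- array(runif(125) > 0.3, dim = c(5, 5, 5))
    if (!any(m)) next
    d <- compute_dvh(gg, m)
    expect_equal(d$volume_pct[1], 100)
    expect_true(all(diff(d$volume_pct) <= 0))
  }
})

test_that("V97, D5-D95, and spillage agree with sort-based oracles to 1e-9", {
  set.seed(41)
  vals <- array(runif(1000, 50, 130), dim = c(10, 10, 10))
  g <- dose_grid(c(0, 0, 0), 0.1, c(10, 10, 10), vals)
  ctv <- array(FALSE, dim = c(10, 10, 10)); ctv[3:8, 3:8, 3:8] <- TRUE
  itv <- array(FALSE, dim = c(10, 10, 10)); itv[2:9, 2:9, 2:9] <- TRUE
  q <- quality_metrics(g, ctv, itv, 100)

  d <- vals[ctv]
  expect_equal(q$v97, 100 * sum(d >= 97) / length(d), tolerance = 1e-9)
  hi_oracle <- (quantile(d, 0.95, names = FALSE, type = 7) -
                quantile(d, 0.05, names = FALSE, type = 7))
  expect_equal(q$homogeneity_index, hi_oracle, tolerance = 1e-9)
  spill_oracle <- 0.001 * sum(vals >= 100 & !itv)
  expect_equal(q$spillage_cm3, spill_oracle, tolerance = 1e-9)
  expect_true(is.na(q$delivery_time))  # absent, not zero
})

test_that("quality metrics on constructed fields behave in closed form", {
  u <- dose_grid(c(0, 0, 0), 0.1, c(6, 6, 6),
                 array(100, dim = c(6, 6, 6)))
  mask <- array(TRUE, dim = c(6, 6, 6))
  q <- quality_metrics(u, mask, mask, 100)
  expect_equal(q$v97, 100)
  expect_equal(q$homogeneity_index, 0)
  expect_equal(q$spillage_cm3, 0)  # nothing outside the ITV

  # two-level field: half at 100, half at 0
  v <- array(rep(c(100, 0), each = 108), dim = c(6, 6, 6))
  q2 <- quality_metrics(dose_grid(c(0, 0, 0), 0.1, c(6, 6, 6), v),
                        mask, mask, 100)
  expect_equal(q2$v97, 50)

  # halving the dose: V97 collapses, HI (in % of D_rx) halves
  h <- u; h$values <- u$values / 2
  qh <- quality_metrics(h, mask, mask, 100)
  expect_equal(qh$v97, 0)
  expect_equal(qh$homogeneity_index, 0)
  w <- dose_grid(c(0, 0, 0), 0.1, c(6, 6, 6),
                 array(seq(90, 110, length.out = 216), dim = c(6, 6, 6)))
  qw <- quality_metrics(w, mask, mask, 100)
  wh <- w; wh$values <- w$values / 2
  qwh <- quality_metrics(wh, mask, mask, 100)
  expect_equal(qwh$homogeneity_index, qw$homogeneity_index / 2,
               tolerance = 1e-12)
})

test_that("SEM uses the sample SD over sqrt(n) and is undefined for n < 2", {
  expect_equal(sem(c(1, 2, 3)), 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(sem(c(1, 2, 3)), 0.5774, tolerance = 1e-4)
  expect_true(is.na(sem(5)))
  expect_true(is.na(sem(numeric(0))))
})

test_that("sweeps run the factorial grid with one shared no-mitigation cell and aggregate across traces", {
  geo <- target_geometry(ctv_radius = 0.6, itv_margin = 0.4,
                         center_depth = 15)
  xs <- c(-2.98, 0, 2.98)
  gr <- expand.grid(x = xs, y = xs)
  plan <- toy_plan(rep(gr$x, 2), rep(gr$y, 2), rep(0.02, 18),
                   rep(1:2, each = 9), geometry = geo)
  plan$layers$depth_cm <- c(15.6, 15.0)
  plan$layers$energy_mev <- range_to_energy(plan$layers$depth_cm)
  traces <- list(a = preprocess_trace(synth_trace("irregular", duration = 60,
                                                  seed = 1)),
                 b = preprocess_trace(synth_trace("irregular", duration = 60,
                                                  seed = 2)))
  sw <- run_sweep(plan, traces, axes = "orthogonal",
                  gate_levels = 0.3, max_mu_levels = 0.01,
                  combine_gates = 0.3,
                  config = accumulation_config(spacing = 0.2, margin = 1))
  # cells: none, gate-only, repaint-only, combined; x 2 traces
  expect_equal(nrow(sw$results), 8)
  expect_equal(sum(is.na(sw$results$gate) & is.na(sw$results$max_mu)), 2)
  expect_equal(nrow(sw$aggregates), 4)
  nm <- sw$aggregates[is.na(sw$aggregates$gate) & is.na(sw$aggregates$max_mu), ]
  rows <- sw$results[is.na(sw$results$gate) & is.na(sw$results$max_mu), ]
  expect_equal(nm$v97_mean, mean(rows$v97))
  expect_equal(nm$v97_sem, sd(rows$v97) / sqrt(2))
  expect_equal(nm$n, 2)

  # single trace: means equal the cell value, SEM reported absent
  sw1 <- run_sweep(plan, traces[1], axes = "orthogonal",
                   cells = data.frame(gate = NA_real_, max_mu = NA_real_),
                   config = accumulation_config(spacing = 0.2, margin = 1))
  expect_equal(sw1$aggregates$v97_mean, sw1$results$v97)
  expect_true(is.na(sw1$aggregates$v97_sem))
})
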