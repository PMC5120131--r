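# Fiber population, activation function, stochastic firing, spread stats.

test_that("activation function is exact on affine and quadratic profiles", {
  x <- seq(0, 3, by = 0.01)
  lin <- activation_function(2 + 5 * x, dx = 0.01)
  expect_equal(lin, rep(0, length(x) - 2), tolerance = 1e-7)
  quad <- activation_function(x^2, dx = 0.01)
  expect_equal(quad, rep(2, length(x) - 2), tolerance = 1e-6)
  expect_error(activation_function(c(1, 2), 0.01), "three")
})

test_that("activation matches the analytic second derivative of a point
           source", {
  # straight fiber along x at perpendicular distance a from a point source:
  # V = c / sqrt(x^2 + a^2), V'' = c (2 x^2 - a^2) / (x^2 + a^2)^(5/2)
  a <- 1.5; sigma <- 1.43; I <- 1e-4
  x <- seq(-3, 3, by = 0.01)
  cc <- I / (4 * pi * sigma * 1e-3)   # potential at 1 mm, volts
  v <- cc / sqrt(x^2 + a^2)
  d2 <- activation_function(v, dx = 0.01)
  xi <- x[-c(1, length(x))]
  d2_an <- cc * (2 * xi^2 - a^2) / (xi^2 + a^2)^(5 / 2)
  expect_lt(max(abs(d2 - d2_an) / max(abs(d2_an))), 0.01)
})

test_that("fiber placement has 10 ordered nodes and scales per the rule", {
  m <- fx_npsm_model()
  fb <- place_fibers(m, n_fibers = 200)
  expect_equal(dim(fb$nodes), c(200, 10, 3))
  expect_true(all(diff(fb$arc_mm) > 0))
  seg <- sqrt(rowSums((fb$nodes[, 9, ] - fb$nodes[, 10, ])^2))
  expect_equal(seg, rep(fb$internode, 200), tolerance = 1e-9)

  spec <- cochlea_spec(8.5, 6.0, 5.0)
  ms <- loft_cochlea(fx_template(), spec)
  fbs <- place_fibers(ms, n_fibers = 200)
  # peripheral anchor scales with (k1, k2, k3)
  expect_equal(fbs$nodes[, 10, 1], fb$nodes[, 10, 1] * spec$k1,
               tolerance = 1e-9)
  expect_equal(fbs$nodes[, 10, 2], fb$nodes[, 10, 2] * spec$k2,
               tolerance = 1e-9)
  expect_equal(fbs$nodes[, 10, 3], fb$nodes[, 10, 3] * spec$k3,
               tolerance = 1e-9)
  # internode distance does not scale
  segs <- sqrt(rowSums((fbs$nodes[, 5, ] - fbs$nodes[, 6, ])^2))
  expect_equal(segs, rep(fb$internode, 200), tolerance = 1e-9)
  expect_error(place_fibers(m, n_fibers = 0))
})

test_that("threshold draws match the prescribed distributions", {
  thr <- threshold_model(1e4, calibration = 1, seed = 8)
  expect_true(all(thr$a_thr > 0))
  expect_lt(abs(sd(thr$a_thr) / mean(thr$a_thr) - 0.30), 0.01)
  expect_lt(abs(mean(thr$a_thr) - 1), 0.02)
  expect_true(all(thr$rs >= 0.03 & thr$rs <= 0.10))
  # clipping is active on both sides
  expect_gt(mean(thr$rs == 0.03), 0)
  expect_gt(mean(thr$rs == 0.10), 0)
  expect_identical(threshold_model(100, seed = 8)$a_thr,
                   threshold_model(100, seed = 8)$a_thr)
})

test_that("firing probability is Phi-shaped around the fiber threshold", {
  thr <- threshold_model(5000, calibration = 2, seed = 3)
  # at exactly the per-fiber threshold: P = 0.5 for every fiber
  p_at <- firing_probabilities(thr$a_thr, thr)
  expect_equal(p_at, rep(0.5, 5000))
  # zero activation: probability below 0.5 and tiny for small RS
  p0 <- firing_probabilities(rep(0, 5000), thr)
  expect_true(all(p0 < 0.5))
  # population at the median threshold fires half the time; at the mean
  # threshold slightly more (right-skewed log-normal): Phi(sdlog/2) ~ 0.557
  p_med <- mean(firing_probabilities(rep(median(thr$a_thr), 5000), thr))
  expect_lt(abs(p_med - 0.5), 0.02)
  p_mean <- mean(firing_probabilities(rep(mean(thr$a_thr), 5000), thr))
  sdlog <- sqrt(log(1 + 0.3^2))
  expect_lt(abs(p_mean - pnorm(sdlog / 2)), 0.03)
})

test_that("zero and uniform fields excite no fibers", {
  vol <- fx_npsm_vol()
  m <- fx_npsm_model()
  fb <- place_fibers(m, n_fibers = 150)
  f <- solve_potential(vol, stimulus = stimulus_config(10))
  zero <- f; zero$v[] <- 0
  unif <- f; unif$v[] <- 0.42
  thr <- threshold_model(150, calibration = 1, seed = 1)
  for (fld in list(zero, unif)) {
    ep <- excitation_profile(fld, fb, thr)
    expect_equal(sum(ep$fired), 0)
    expect_true(all(ep$site_class == "none"))
  }
})

test_that("excited fibers classify by the strongest supra-threshold node", {
  vol <- fx_npsm_vol()
  fb <- place_fibers(fx_npsm_model(), n_fibers = 400)
  f <- solve_potential(vol, stimulus = stimulus_config(10))
  act <- cochleavc:::fiber_node_activation(f, fb)
  thr <- threshold_model(400, calibration = calibrate_activation(act),
                         seed = 2)
  ep <- excitation_profile(f, fb, thr, activation = act)
  expect_gt(sum(ep$fired), 0)
  expect_true(all(ep$site_class[!ep$fired] == "none"))
  expect_true(all(ep$site_class[ep$fired] %in% c("peripheral", "central")))
  # stochastic mode is seeded and consistent in expectation
  e1 <- excitation_profile(f, fb, thr, draw = TRUE, seed = 7,
                           activation = act)
  e2 <- excitation_profile(f, fb, thr, draw = TRUE, seed = 7,
                           activation = act)
  expect_identical(e1$fired, e2$fired)
})

test_that("summed activity matches the binomial expectation", {
  fb_arc <- seq(0.5, 20, length.out = 300)
  prof <- tibble::tibble(fiber = 1:300, arc_mm = fb_arc,
                         probability = c(rep(0, 100), rep(1, 100),
                                         rep(0.3, 100)),
                         fired = FALSE, site_class = "none")
  class(prof) <- c("excitation_profile", class(prof))
  det <- summed_activity(prof)
  expect_equal(det$total, 100 + 30)
  expect_equal(sum(det$by_position$count), det$total)
  st <- summed_activity(prof, repetitions = 200, seed = 4)
  se <- sqrt(sum(prof$probability * (1 - prof$probability)) / 200)
  expect_lt(abs(st$total - det$total), 3 * se)
  expect_error(summed_activity(prof, repetitions = 0))
})

test_that("spread statistics match a closed-form Gaussian profile", {
  arc <- seq(0, 25, by = 0.02)
  mu <- 12; s <- 2.5
  st <- spread_from_profile(arc, exp(-(arc - mu)^2 / (2 * s^2)))
  # amplitude 3 dB: |V| >= 10^(-3/20) peak -> width 2 s sqrt(2 ln 10^(3/20))
  bw_an <- 2 * s * sqrt(2 * log(10^(3 / 20)))
  expect_lt(abs(st$peak_mm - mu), 0.05)
  expect_lt(abs(st$bandwidth_mm - bw_an) / bw_an, 0.02)
  expect_false(st$flat)
})

test_that("spread statistics are field-scale invariant and flag flat
           profiles", {
  vol <- fx_npsm_vol()
  fb <- place_fibers(fx_npsm_model(), n_fibers = 600)
  f <- solve_potential(vol, stimulus = stimulus_config(10))
  s1 <- spread_statistics(f, fb)
  f2 <- f; f2$v <- 5 * f$v
  s2 <- spread_statistics(f2, fb)
  expect_equal(s1$peak_mm, s2$peak_mm)
  expect_equal(s1$bandwidth_mm, s2$bandwidth_mm)
  expect_false(s1$flat)
  flat <- f; flat$v[] <- 1
  expect_warning(sf <- spread_statistics(flat, fb), "flat")
  expect_true(sf$flat)
  expect_equal(sf$bandwidth_mm, diff(range(fb$arc_mm)))
})
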