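# Procrustes registration, transform algebra, electrode mapping and
# spacing correction.

rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

mk_markers <- function(m, frame = "x") {
  tibble::tibble(marker_id = c("A1", "A2", "B1", "B2", "H1", "H2"),
                 x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3], frame = frame)
}

test_that("procrustes recovers identity and known similarity transforms", {
  src <- markers_from_spec(npsm_spec())
  fit0 <- procrustes_fit(src, src)
  expect_equal(fit0$R, diag(3), tolerance = 1e-12)
  expect_equal(fit0$s, 1, tolerance = 1e-12)
  expect_equal(fit0$rms, 0, tolerance = 1e-10)

  R0 <- rot_z(0.7) %*% matrix(c(1, 0, 0, 0, cos(0.3), sin(0.3),
                                0, -sin(0.3), cos(0.3)), 3, 3)
  t0 <- c(4, -2, 11)
  X <- marker_matrix(src)
  Y <- sweep(1.3 * X %*% t(R0), 2, t0, "+")
  fit <- procrustes_fit(src, mk_markers(Y))
  expect_equal(fit$R, R0, tolerance = 1e-9)
  expect_equal(fit$s, 1.3, tolerance = 1e-9)
  expect_equal(fit$t, t0, tolerance = 1e-8)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
})

test_that("procrustes agrees with the vegan oracle on a random case", {
  skip_if_not_installed("vegan")
  set.seed(11)
  X <- marker_matrix(markers_from_spec(npsm_spec()))
  Y <- sweep(0.8 * X %*% t(rot_z(1.1)), 2, c(1, 2, 3), "+") +
    matrix(rnorm(18, 0, 0.05), 6)
  fit <- procrustes_fit(mk_markers(X), mk_markers(Y))
  vg <- vegan::procrustes(Y, X, scale = TRUE, symmetric = FALSE)
  expect_equal(unname(fit$s), unname(vg$scale), tolerance = 1e-6)
  expect_equal(unname(fit$R), unname(t(vg$rotation)), tolerance = 1e-6)
  expect_equal(apply_transform(fit, X),
               unname(vg$scale * X %*% vg$rotation +
                        matrix(vg$translation, 6, 3, byrow = TRUE)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("residual RMS tracks the marker noise scale", {
  set.seed(4)
  X <- marker_matrix(markers_from_spec(npsm_spec()))
  rms <- replicate(100, {
    Y <- sweep(X %*% t(rot_z(runif(1, 0, 2 * pi))), 2, rnorm(3, 0, 5), "+") +
      matrix(rnorm(18, 0, 0.15), 6)
    procrustes_fit(mk_markers(X), mk_markers(Y))$rms
  })
  # registration absorbs 7 of the 18 coordinate dof; the per-point 3D
  # residual RMS is sd * sqrt(11/6)
  expect_gt(mean(rms), 0.15 * sqrt(11 / 6) * 0.85)
  expect_lt(mean(rms), 0.15 * sqrt(11 / 6) * 1.15)
})

test_that("degenerate (collinear) configurations raise a rank error", {
  X <- cbind(seq_len(6), 2 * seq_len(6), 3 * seq_len(6))
  expect_error(procrustes_fit(mk_markers(X), mk_markers(X + 1)),
               "rank|collinear")
})

test_that("transform composition and inversion are exact", {
  set.seed(5)
  X <- marker_matrix(markers_from_spec(npsm_spec()))
  tf1 <- procrustes_fit(mk_markers(X),
                        mk_markers(sweep(1.2 * X %*% t(rot_z(0.4)), 2,
                                         c(1, 1, 1), "+")))
  tf2 <- procrustes_fit(mk_markers(X),
                        mk_markers(sweep(0.7 * X %*% t(rot_z(-0.9)), 2,
                                         c(-3, 2, 0), "+")))
  p <- matrix(rnorm(30), 10)
  expect_equal(apply_transform(compose_transforms(tf2, tf1), p),
               apply_transform(tf2, apply_transform(tf1, p)),
               tolerance = 1e-10)
  rt <- apply_transform(invert_transform(tf1), apply_transform(tf1, p))
  expect_lt(max(abs(rt - p)), 1e-9)
})

test_that("electrode mapping chains the frame transforms correctly", {
  p <- fx_patient()
  pts <- matrix(rnorm(66), 22)
  # identical frames: unchanged
  same <- p$markers$cad
  expect_equal(map_electrodes_to_cad(pts, same, same, same), pts,
               tolerance = 1e-9, ignore_attr = TRUE)
  # pure translation chain
  shift <- function(mk, v) dplyr::mutate(mk, x_mm = .data$x_mm + v[1],
                                         y_mm = .data$y_mm + v[2],
                                         z_mm = .data$z_mm + v[3])
  post <- shift(same, c(5, 0, 0))
  out <- map_electrodes_to_cad(pts, same, post, same)
  expect_equal(out, pts - matrix(c(5, 0, 0), 22, 3, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
  # synthetic three-frame chain (exact, noise-free markers)
  anat <- marker_matrix(p$markers$anatomy)
  tfA <- list(R = rot_z(0.5), t = c(2, -1, 3), s = 1)
  class(tfA) <- "similarity_transform"
  tfB <- list(R = rot_z(-1.2), t = c(0, 4, -2), s = 1)
  class(tfB) <- "similarity_transform"
  preop <- mk_markers(apply_transform(tfA, anat))
  postop <- mk_markers(apply_transform(tfB, anat))
  truth <- as.matrix(p$array_truth[, c("x_mm", "y_mm", "z_mm")])
  raw <- apply_transform(tfB, truth)
  mapped <- map_electrodes_to_cad(raw, preop, postop, p$markers$cad)
  expect_equal(mapped, truth, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("spacing correction is a fixed point on exact-spacing curves", {
  m <- fx_npsm_model()
  truth <- as.matrix(canonical_electrode_positions(m)[, 2:4])
  corr <- correct_positions(truth, df = 21)   # interpolating spline
  expect_lt(max(sqrt(rowSums((as.matrix(corr[, 2:4]) - truth)^2))), 0.03)
  # apical anchor is the reference: contact 22 invariant (up to the dense
  # resampling of the fitted curve)
  expect_lt(sqrt(sum((as.matrix(corr[22, 2:4]) - truth[22, ])^2)), 2e-3)
})

test_that("spacing correction restores spec gaps and reduces jitter error", {
  m <- fx_npsm_model()
  spec <- electrode_array_spec()
  truth <- as.matrix(canonical_electrode_positions(m)[, 2:4])
  set.seed(9)
  raw_err <- corr_err <- numeric(10)
  for (i in 1:10) {
    raw <- truth + matrix(rnorm(66, 0, 0.3), 22)
    corr <- as.matrix(correct_positions(raw)[, 2:4])
    gaps <- sqrt(rowSums(diff(corr)^2))
    # chordal gaps: never longer than the arc gaps set by construction, and
    # shorter only by the chord-vs-arc sagitta (< 0.02 mm at the apical
    # curvature)
    expect_true(all(gaps <= spec$gaps + 1e-6))
    expect_lt(max(spec$gaps - gaps), 0.02)
    raw_err[i] <- mean(sqrt(rowSums((raw - truth)^2)))
    corr_err[i] <- mean(sqrt(rowSums((corr - truth)^2)))
  }
  expect_lt(mean(corr_err), mean(raw_err))
})

test_that("electrode CSV writer round-trips", {
  arr <- canonical_electrode_positions(fx_npsm_model())
  f <- withr::local_tempfile(fileext = ".csv")
  write_electrodes(arr, f)
  back <- read_electrodes(f)
  expect_equal(as.matrix(back[, 2:4]), as.matrix(arr[, 2:4]),
               tolerance = 1e-9)
  expect_equal(attr(back, "array_spec")$model, "CI24RE")
})
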