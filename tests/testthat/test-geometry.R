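# Template construction, landmark scaling, lofting, voxelization.

test_that("intermediate control sections are exact vertex-wise midpoints", {
  tpl <- fx_template()
  for (th in c(90, 270, 450, 630)) {
    lo <- tpl$sections[[as.character(th - 90)]]
    hi <- tpl$sections[[as.character(th + 90)]]
    mid <- tpl$sections[[as.character(th)]]
    for (comp in names(mid)) {
      expect_equal(mid[[comp]], (lo[[comp]] + hi[[comp]]) / 2,
                   tolerance = 0)
    }
  }
  expect_equal(tpl$angles, seq(0, 810, by = 90))
})

test_that("control polygons are simple and mutually disjoint", {
  tpl <- fx_template()
  for (sec in tpl$sections) {
    for (p in sec) expect_true(polygon_is_simple(p))
    # rectangles: disjointness via bounding boxes
    bbs <- lapply(sec, function(p) c(range(p[, 1]), range(p[, 2])))
    nm <- names(sec)
    for (i in seq_along(bbs)) {
      for (j in seq_len(i - 1)) {
        overlap <- bbs[[i]][1] < bbs[[j]][2] - 1e-9 &&
                   bbs[[j]][1] < bbs[[i]][2] - 1e-9 &&
                   bbs[[i]][3] < bbs[[j]][4] - 1e-9 &&
                   bbs[[j]][3] < bbs[[i]][4] - 1e-9
        expect_false(overlap, label = paste(nm[i], "overlaps", nm[j]))
      }
    }
  }
})

test_that("scala tympani cross-section area is non-increasing base to apex", {
  tpl <- fx_template()
  areas <- vapply(tpl$sections, function(s) polygon_area(s$scala_tympani),
                  numeric(1))
  expect_true(all(diff(areas) <= 1e-12))
  expect_gte(areas[["0"]], areas[["720"]])
})

test_that("landmark scaling reproduces published patient P1 and the template", {
  p1 <- tibble::tibble(
    marker_id = c("A1", "A2", "B1", "B2", "H1", "H2"),
    x_mm = c(0, 9.61, 2, 2, 5, 5),
    y_mm = c(0, 0, 0, 7.00, 1, 1),
    z_mm = c(0, 0, 3, 3, 0, 4.94))
  spec <- scale_from_landmarks(p1)
  expect_equal(spec$A, 9.61)
  expect_equal(spec$B, 7.00)
  expect_equal(spec$H, 4.94)
  expect_equal(spec$k1, 9.61 / 10.083)

  tpl_mk <- markers_from_spec(npsm_spec())
  spec0 <- scale_from_landmarks(tpl_mk)
  expect_equal(c(spec0$k1, spec0$k2, spec0$k3), c(1, 1, 1))

  degen <- p1
  degen[degen$marker_id == "A2", c("x_mm", "y_mm", "z_mm")] <-
    degen[degen$marker_id == "A1", c("x_mm", "y_mm", "z_mm")]
  expect_error(scale_from_landmarks(degen), "degenerate|invalid")
})

test_that("canonical markers measure back to the requested A/B/H", {
  spec <- cochlea_spec(9.0, 6.5, 4.5)
  mk <- marker_matrix(markers_from_spec(spec))
  expect_equal(sqrt(sum((mk["A1", ] - mk["A2", ])^2)), 9.0)
  expect_equal(sqrt(sum((mk["B1", ] - mk["B2", ])^2)), 6.5)
  expect_equal(sqrt(sum((mk["H1", ] - mk["H2", ])^2)), 4.5)
})

test_that("loft passes through control polygons and scales anisotropically", {
  m <- fx_npsm_model()
  tpl <- fx_template()
  for (th in c(0, 90, 450, 810)) {
    sec <- section_at(m, th)
    for (comp in names(sec)) {
      expect_equal(sec[[comp]], tpl$sections[[as.character(th)]][[comp]],
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
  # doubling k3 doubles the z extent, x/y extents unchanged
  d <- template_dimensions()
  m2 <- loft_cochlea(tpl, cochlea_spec(d$A, d$B, 2 * d$H))
  bb1 <- model_bbox(m); bb2 <- model_bbox(m2)
  expect_equal(bb2[2, 3] - bb2[1, 3], 2 * (bb1[2, 3] - bb1[1, 3]),
               tolerance = 1e-9)
  expect_equal(bb2[, 1], bb1[, 1], tolerance = 1e-9)
  expect_equal(bb2[, 2], bb1[, 2], tolerance = 1e-9)
})

test_that("pairwise distances scale exactly with the k factors per axis", {
  spec <- cochlea_spec(8.5, 6.0, 5.0)
  m0 <- fx_npsm_model()
  m1 <- loft_cochlea(fx_template(), spec)
  th <- seq(10, 700, by = 37)
  p0 <- centerline_points(m0, th)
  p1 <- centerline_points(m1, th)
  expect_equal(p1[, 1], p0[, 1] * spec$k1, tolerance = 1e-12)
  expect_equal(p1[, 2], p0[, 2] * spec$k2, tolerance = 1e-12)
  expect_equal(p1[, 3], p0[, 3] * spec$k3, tolerance = 1e-12)
})

test_that("voxelization labels every in-domain cell and partitions the domain", {
  vol <- fx_npsm_vol()
  counts <- label_counts(vol)
  expect_equal(sum(counts$cells), length(vol$labels))
  expect_true(all(vol$labels %in% seq_along(vol$label_levels)))
  # membranes present (at least one cell thick) despite coarse spacing
  expect_gt(counts$cells[counts$label == "basilar_membrane"], 0)
  expect_gt(counts$cells[counts$label == "reissner_membrane"], 0)
})

test_that("patient-scaled voxel model has the requested extent and volume", {
  tb <- load_cohort_dimensions()
  spec <- cochlea_spec(tb$A_mm[1], tb$B_mm[1], tb$H_mm[1])  # P1
  m <- loft_cochlea(fx_template(), spec)
  vol <- suppressWarnings(voxelize(m, spacing = 0.3, ratio = 1.6))
  duct <- match(c("scala_tympani", "scala_vestibuli", "scala_media",
                  "basilar_membrane", "reissner_membrane"), vol$label_levels)
  sel <- which(array(vol$labels %in% duct, dim(vol$labels)), arr.ind = TRUE)
  x_ext <- diff(range(vol$x[sel[, 1]]))
  expect_lt(abs(x_ext - spec$A), 2 * 0.3 + 0.05)   # one cell each side

  # duct volume ratio to the template tracks k1*k2*k3 (5%)
  vol0 <- suppressWarnings(voxelize(fx_npsm_model(), spacing = 0.3,
                                    ratio = 1.6))
  cellvol <- function(v) {
    cv <- outer(outer(v$dx, v$dy), v$dz)
    sum(cv[v$labels %in% duct])
  }
  ratio <- cellvol(vol) / cellvol(vol0)
  expect_rel(ratio, spec$k1 * spec$k2 * spec$k3, 0.05)
})

test_that("scala tympani labelled volume converges under grid refinement", {
  m <- fx_npsm_model()
  stv <- function(sp) {
    v <- suppressWarnings(voxelize(m, spacing = sp, ratio = 1.6))
    cv <- outer(outer(v$dx, v$dy), v$dz)
    sum(cv[v$labels == match("scala_tympani", v$label_levels)])
  }
  a <- stv(0.3); b <- stv(0.15)
  expect_lt(abs(a - b) / b, 0.10)
})

test_that("volume VTK export round-trips the label array", {
  vol <- fx_npsm_vol()
  f <- withr::local_tempfile(fileext = ".vtk")
  write_volume_vtk(vol, f)
  lines <- readLines(f)
  expect_match(lines[2], "scala_tympani")
  labs <- as.integer(strsplit(lines[length(lines)], " ")[[1]]) + 1L
  expect_equal(labs, as.integer(vol$labels))
})
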