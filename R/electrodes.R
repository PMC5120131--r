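# Electrode arrays: manufacturer dimensions, canonical trajectories,
# spline smoothing with spacing correction, and placement into the voxel
# volume.

#' Electrode array model specification
#'
#' Dimensions of the two supported 22-contact arrays: CI24RE (length 17 mm,
#' diameters 0.8 mm basal to 0.5 mm apical) and CI422 Slim-Straight
#' (insertion depth 20 mm, 0.6 to 0.3 mm). Per-gap contact spacing defaults
#' to uniform length / 21 (the manufacturer gap table is not public) and can
#' be overridden.
#'
#' @param model `"CI24RE"` or `"CI422"`.
#' @param gaps Optional vector of 21 inter-contact arc gaps (mm).
#' @return An `electrode_array_spec` list.
#' @export
electrode_array_spec <- function(model = c("CI24RE", "CI422"), gaps = NULL) {
  model <- match.arg(model)
  dims <- switch(model,
    CI24RE = list(length = 17, d_basal = 0.8, d_apical = 0.5),
    CI422  = list(length = 20, d_basal = 0.6, d_apical = 0.3))
  n <- 22L
  if (is.null(gaps)) gaps <- rep(dims$length / (n - 1), n - 1)
  stopifnot(length(gaps) == n - 1, all(gaps > 0),
            sum(gaps) <= dims$length + 1e-9)
  structure(c(dims, list(model = model, contact_count = n, gaps = gaps)),
            class = "electrode_array_spec")
}

# Dense lateral-wall trajectory (scaled model frame) with its arc length.
.wall_curve <- function(cmodel, offset) {
  th <- seq(0, cmodel$theta_max, by = 1)
  pts <- lateral_wall_path(cmodel, th, offset = offset)
  list(theta = th, pts = pts, s = path_arc_length(pts))
}

#' Canonical electrode positions along the lateral scala-tympani wall
#'
#' Places the 22 contacts at the spec's arc-length gaps along the lateral
#' wall of the scala tympani, inserted from the round window (0 degrees);
#' this is the standard-position array used for the template model and the
#' ground-truth trajectory of the synthetic cohort.
#'
#' @param cmodel A `cochlea_model`.
#' @param spec An [electrode_array_spec()].
#' @param insertion_offset Arc distance (mm) of the most basal contact from
#'   the round window.
#' @return An `electrode_array` tibble: columns `contact`, `x_mm`, `y_mm`,
#'   `z_mm` (contact 1 most basal), with the spec attached as an attribute.
#' @export
canonical_electrode_positions <- function(cmodel,
                                          spec = electrode_array_spec(),
                                          insertion_offset = 0.6) {
  wc <- .wall_curve(cmodel, offset = spec$d_basal / 2 + 0.05)
  s_targets <- insertion_offset + c(0, cumsum(spec$gaps))
  if (max(s_targets) > max(wc$s)) stop("array longer than the lateral wall")
  pos <- apply(wc$pts, 2, function(cc) stats::approx(wc$s, cc, s_targets)$y)
  new_electrode_array(pos, spec)
}

new_electrode_array <- function(pos, spec) {
  out <- tibble::tibble(contact = 1:22, x_mm = pos[, 1], y_mm = pos[, 2],
                        z_mm = pos[, 3])
  attr(out, "array_spec") <- spec
  class(out) <- c("electrode_array", class(out))
  out
}

#' Arc-length gaps between consecutive contacts
#'
#' @param array An `electrode_array` (or 22 x 3 matrix).
#' @return Numeric vector of 21 chordal gaps (mm).
#' @export
contact_gaps <- function(array) {
  pts <- if (is.data.frame(array)) {
    as.matrix(array[, c("x_mm", "y_mm", "z_mm")])
  } else {
    as.matrix(array)
  }
  sqrt(rowSums(diff(pts)^2))
}

#' Smooth and spacing-correct mapped electrode positions
#'
#' Fits a cubic smoothing spline through the 22 mapped contact estimates
#' (per coordinate, against the cumulative chordal parameter), anchors the
#' most apical contact (22) at its smoothed position, and re-places contacts
#' 21..1 backwards along the smoothed curve at the spec's arc-length gaps.
#'
#' @param mapped 22 x 3 matrix or tibble of contact estimates in the model
#'   frame, ordered basal to apical.
#' @param spec An [electrode_array_spec()].
#' @param df Equivalent degrees of freedom of the smoothing spline; the
#'   default leaves residuals at about the CBCT half-voxel (0.15 mm) for
#'   typical jitter.
#' @return An `electrode_array` tibble of corrected positions.
#' @export
correct_positions <- function(mapped, spec = electrode_array_spec(), df = 8) {
  pts <- if (is.data.frame(mapped)) {
    as.matrix(mapped[, c("x_mm", "y_mm", "z_mm")])
  } else {
    as.matrix(mapped)
  }
  stopifnot(nrow(pts) == 22)
  t0 <- path_arc_length(pts)
  if (max(t0) < 1e-6) stop("zero-length electrode curve")
  fits <- lapply(1:3, function(a) stats::smooth.spline(t0, pts[, a], df = df))
  # densely resample the smoothed curve, extended basally so the backward
  # stepping from the apical anchor always stays on the curve
  tt <- seq(-0.15 * max(t0), max(t0), length.out = 4000)
  dense <- sapply(fits, function(f) stats::predict(f, tt)$y)
  s <- path_arc_length(dense)
  if (any(diff(s) <= 0)) stop("degenerate (self-folding) fitted curve")
  s22 <- stats::approx(tt, s, t0[22])$y
  s_targets <- s22 - rev(c(0, cumsum(rev(spec$gaps))))
  if (min(s_targets) < 0) stop("corrected array extends beyond the fitted curve")
  pos <- sapply(1:3, function(a) stats::approx(s, dense[, a], s_targets)$y)
  new_electrode_array(pos, spec)
}

#' Read / write electrode position CSV files
#'
#' Columns `contact` (1-22, basal to apical), `x_mm`, `y_mm`, `z_mm` and
#' optionally `frame`; the array model name travels in a `# array:` header
#' comment.
#'
#' @param path File path.
#' @param array An `electrode_array` (for writing).
#' @return `read_electrodes()` returns an `electrode_array` tibble.
#' @export
read_electrodes <- function(path) {
  first <- readLines(path, n = 1)
  model <- if (grepl("^# array:", first)) sub("^# array:\\s*", "", first) else "CI24RE"
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  pos <- as.matrix(tb[order(tb$contact), c("x_mm", "y_mm", "z_mm")])
  new_electrode_array(pos, electrode_array_spec(model))
}

#' @rdname read_electrodes
#' @export
write_electrodes <- function(array, path) {
  spec <- attr(array, "array_spec")
  writeLines(paste0("# array: ", spec$model), path)
  readr::write_csv(tibble::as_tibble(array), path, append = TRUE,
                   col_names = TRUE)
  invisible(array)
}

#' Insert an electrode array into a labelled volume
#'
#' Labels the silicone carrier (a tapered tube along the array curve) and the
#' 22 platinum contacts (bands slightly proud of the carrier, each at least
#' one cell), records the per-contact cell sets with volume-proportional
#' weights used for current injection and recording, and flags contacts whose
#' center does not lie in the scala tympani.
#'
#' @param vol A `labeled_volume`.
#' @param array An `electrode_array`.
#' @return The volume with updated labels and a `contact_cells` field.
#' @export
add_electrode_array <- function(vol, array) {
  spec <- attr(array, "array_spec")
  pts <- as.matrix(array[, c("x_mm", "y_mm", "z_mm")])

  centers_ijk <- nearest_cell(vol, pts)
  lab_at <- vol$label_levels[vol$labels[centers_ijk]]
  outside <- which(!(lab_at %in% c("scala_tympani", "basilar_membrane")))
  if (length(outside) > 0) {
    warning("contact(s) ", paste(outside, collapse = ", "),
            " not centered in the scala tympani (nearest label: ",
            paste(unique(lab_at[outside]), collapse = ", "), ")")
  }

  # dense curve through the contacts for the carrier tube
  t0 <- path_arc_length(pts)
  tt <- seq(0, max(t0), by = 0.1)
  dense <- sapply(1:3, function(a) stats::approx(t0, pts[, a], tt)$y)
  r_b <- spec$d_basal / 2; r_a <- spec$d_apical / 2
  r_t <- r_b + (r_a - r_b) * tt / max(tt)

  # candidate cells near the curve
  bb <- apply(dense, 2, range)
  m <- max(r_b, vol$spacing) + 0.1
  ix <- which(vol$x >= bb[1, 1] - m & vol$x <= bb[2, 1] + m)
  iy <- which(vol$y >= bb[1, 2] - m & vol$y <= bb[2, 2] + m)
  iz <- which(vol$z >= bb[1, 3] - m & vol$z <= bb[2, 3] + m)
  cand <- as.matrix(expand.grid(i = ix, j = iy, k = iz))
  cpos <- cbind(vol$x[cand[, 1]], vol$y[cand[, 2]], vol$z[cand[, 3]])
  dmin <- rep(Inf, nrow(cand))
  rmin <- rep(0, nrow(cand))
  for (q in seq_along(tt)) {
    dq <- sqrt((cpos[, 1] - dense[q, 1])^2 + (cpos[, 2] - dense[q, 2])^2 +
               (cpos[, 3] - dense[q, 3])^2)
    upd <- dq < dmin
    dmin[upd] <- dq[upd]
    rmin[upd] <- r_t[q]
  }
  sil <- match("silicone", LABEL_LEVELS)
  elec <- match("electrode", LABEL_LEVELS)
  in_tube <- dmin <= rmin
  lin <- cell_index(vol, cand[, 1], cand[, 2], cand[, 3])
  ext <- match("exterior", LABEL_LEVELS)
  gnd <- match("ground", LABEL_LEVELS)
  settable <- !(vol$labels[lin] %in% c(ext, gnd))
  vol$labels[lin[in_tube & settable]] <- sil

  # contacts: bands proud of the carrier surface (rings), never wide enough
  # to bridge the inter-contact gap, assigned to the nearest contact center;
  # every contact keeps at least its nearest cell
  r_carrier_c <- r_b + (r_a - r_b) * t0 / max(t0)
  r_outer <- pmin(r_carrier_c + 0.12, 0.45)
  r_inner <- pmax(r_carrier_c - 0.25, 0)
  dcon <- sapply(1:22, function(s) {
    sqrt((cpos[, 1] - pts[s, 1])^2 + (cpos[, 2] - pts[s, 2])^2 +
         (cpos[, 3] - pts[s, 3])^2)
  })
  nearest_con <- max.col(-dcon)
  dnear <- dcon[cbind(seq_len(nrow(cand)), nearest_con)]
  is_contact <- dnear <= r_outer[nearest_con] & dnear >= r_inner[nearest_con]
  vol$labels[lin[is_contact & settable]] <- elec

  cellvol <- vol$dx[cand[, 1]] * vol$dy[cand[, 2]] * vol$dz[cand[, 3]]
  contact_cells <- lapply(1:22, function(s) {
    sel <- which(is_contact & settable & nearest_con == s)
    if (length(sel) == 0) {
      ci <- centers_ijk[s, , drop = FALSE]
      li <- cell_index(vol, ci[1], ci[2], ci[3])
      vol$labels[li] <<- elec
      return(list(idx = li, w = 1))
    }
    w <- cellvol[sel] / sum(cellvol[sel])
    list(idx = lin[sel], w = w)
  })
  vol$contact_cells <- contact_cells
  vol$electrode_array <- array
  vol
}
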