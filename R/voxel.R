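# Discretization: labelled rectilinear voxel grid.
#
# The grid is tensor-product with graded spacing: uniform fine cells inside
# the cochlea bounding box, geometrically coarsening outside it up to the
# grounded domain boundary. Every cell carries one integer tissue label.

LABEL_LEVELS <- c("exterior", "bone", "nerve", "scala_tympani",
                  "scala_vestibuli", "scala_media", "basilar_membrane",
                  "reissner_membrane", "silicone", "electrode", "ground")

#' Grounding configuration
#'
#' @param mode `"sphere50"` (0 V Dirichlet on a bony sphere of radius
#'   `radius` mm surrounding the cochlea) or `"far_field"` (0 V on the outer
#'   boundary of a domain padded to `pad` times `radius`, approximating a
#'   ground at infinity).
#' @param radius Ground-sphere radius in mm (default 50; must exceed the
#'   cochlear extent).
#' @param pad Padding factor for the far-field domain (>= 2 recommended).
#' @param weights Optional named weights (summing to 1) used by
#'   [weighted_ground_potential()].
#' @return A `grounding_config` list.
#' @export
grounding_config <- function(mode = c("sphere50", "far_field"), radius = 50,
                             pad = 3, weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(radius > 0, pad >= 1)
  if (!is.null(weights)) {
    stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-9)
  }
  structure(list(mode = mode, radius = radius, pad = pad, weights = weights),
            class = "grounding_config")
}

# One graded axis: uniform `spacing` over [lo, hi], geometric growth (factor
# `ratio`) outwards until `bound` is covered on both sides. Returns cell edges.
graded_axis <- function(lo, hi, spacing, bound_lo, bound_hi, ratio = 1.4) {
  core <- seq(lo, hi, by = spacing)
  if (core[length(core)] < hi - 1e-9) core <- c(core, hi)
  up <- core[length(core)]; d <- spacing
  while (up < bound_hi) { d <- d * ratio; up <- up + d; core <- c(core, up) }
  lo_e <- core[1]; d <- spacing; lower <- numeric(0)
  while (lo_e > bound_lo) { d <- d * ratio; lo_e <- lo_e - d; lower <- c(lo_e, lower) }
  c(lower, core)
}

#' Voxelize a lofted cochlea model into a labelled volume
#'
#' Point-in-compartment labelling of cell centers on a graded rectilinear
#' grid. Cells outside all compartments but inside the grounded domain are
#' bone; the outermost in-domain shell is the ground surface. Membranes are
#' guaranteed at least one cell thick (with a warning when the requested
#' spacing cannot resolve them).
#'
#' @param model A `cochlea_model`.
#' @param spacing Fine cell size (mm) inside the cochlea bounding box;
#'   default 0.3 mm, the CBCT voxel size.
#' @param grounding A [grounding_config()].
#' @param ratio Geometric coarsening ratio outside the cochlea box.
#' @param margin Margin (mm) added around the duct for the fine region.
#' @return An object of class `labeled_volume` with cell-center coordinate
#'   vectors `x`, `y`, `z`, cell sizes `dx`, `dy`, `dz`, an integer `labels`
#'   array (levels in `label_levels`), and grid metadata.
#' @export
voxelize <- function(model, spacing = 0.3,
                     grounding = grounding_config(), ratio = 1.5,
                     margin = 1.2) {
  stopifnot(spacing > 0)
  bb <- model_bbox(model, margin = margin)
  ctr <- colMeans(bb)
  half <- if (grounding$mode == "far_field") {
    grounding$radius * grounding$pad
  } else {
    grounding$radius * 1.02
  }
  edges <- lapply(1:3, function(a) {
    graded_axis(bb[1, a], bb[2, a], spacing,
                ctr[a] - half, ctr[a] + half, ratio = ratio)
  })
  cent <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  size <- lapply(edges, diff)
  nx <- length(cent[[1]]); ny <- length(cent[[2]]); nz <- length(cent[[3]])

  lab <- array(match("bone", LABEL_LEVELS), dim = c(nx, ny, nz))

  # domain mask: inside ground sphere (sphere50) or whole box (far_field)
  if (grounding$mode == "sphere50") {
    r2 <- outer(outer((cent[[1]] - ctr[1])^2, (cent[[2]] - ctr[2])^2, "+"),
                (cent[[3]] - ctr[3])^2, "+")
    lab[r2 > grounding$radius^2] <- match("exterior", LABEL_LEVELS)
  }

  # cochlea labelling inside the (scaled) bounding box
  ix <- which(cent[[1]] >= bb[1, 1] & cent[[1]] <= bb[2, 1])
  iy <- which(cent[[2]] >= bb[1, 2] & cent[[2]] <= bb[2, 2])
  iz <- which(cent[[3]] >= bb[1, 3] & cent[[3]] <= bb[2, 3])
  grid_pts <- as.matrix(expand.grid(x = cent[[1]][ix], y = cent[[2]][iy],
                                    z = cent[[3]][iz]))
  min_th <- spacing / model$spec$k3
  bm_th <- 0.05 * duct_height(0)   # thickest membrane point
  if (min_th > bm_th) {
    warning("spacing ", spacing, " mm cannot resolve the membranes; ",
            "membrane labels dilated to one cell thickness")
  }
  pl <- label_points(model, grid_pts, min_membrane_thick = min_th,
                     detail = TRUE)
  sel <- pl$label != "bone"
  mem_t <- array(NA_real_, dim = c(nx, ny, nz))   # true thickness, mm, scaled
  if (any(sel)) {
    idx <- as.matrix(expand.grid(i = ix, j = iy, k = iz))[sel, , drop = FALSE]
    lab[idx] <- match(pl$label[sel], LABEL_LEVELS)
    mem_t[idx] <- pl$mem_thick[sel] * model$spec$k3
  }

  vol <- structure(list(x = cent[[1]], y = cent[[2]], z = cent[[3]],
                        dx = size[[1]], dy = size[[2]], dz = size[[3]],
                        labels = lab, label_levels = LABEL_LEVELS,
                        mem_thick = mem_t,
                        spacing = spacing, center = ctr,
                        grounding = grounding, spec = model$spec,
                        contact_cells = NULL),
                   class = "labeled_volume")
  mark_ground(vol)
}

# Mark the outermost in-domain shell as the ground surface.
mark_ground <- function(vol) {
  lab <- vol$labels
  ext <- match("exterior", LABEL_LEVELS)
  gnd <- match("ground", LABEL_LEVELS)
  d <- dim(lab)
  if (vol$grounding$mode == "far_field") {
    lab[c(1, d[1]), , ] <- gnd
    lab[, c(1, d[2]), ] <- gnd
    lab[, , c(1, d[3])] <- gnd
  } else {
    indom <- lab != ext
    nb_ext <- array(FALSE, d)
    shift_or <- function(m, a, s) {
      out <- array(TRUE, d)   # beyond the box counts as exterior
      src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      n <- d[a]
      if (s == 1) { dst[[a]] <- 1:(n - 1); src[[a]] <- 2:n }
      else        { dst[[a]] <- 2:n;       src[[a]] <- 1:(n - 1) }
      out[dst[[1]], dst[[2]], dst[[3]]] <- !indom[src[[1]], src[[2]], src[[3]]]
      out
    }
    for (a in 1:3) for (s in c(1, -1)) nb_ext <- nb_ext | shift_or(lab, a, s)
    lab[indom & nb_ext] <- gnd
  }
  vol$labels <- lab
  vol
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d cells (fine spacing %.3g mm, %s)\n",
              d[1], d[2], d[3], x$spacing, x$grounding$mode))
  tb <- table(factor(x$label_levels[x$labels], levels = x$label_levels))
  print(tb[tb > 0])
  invisible(x)
}

#' Tabulate label counts of a labelled volume
#'
#' @param vol A `labeled_volume`.
#' @return Tibble with columns `label` and `cells`.
#' @export
label_counts <- function(vol) {
  tb <- table(factor(vol$label_levels[vol$labels], levels = vol$label_levels))
  tibble::tibble(label = names(tb), cells = as.integer(tb))
}

# Linear index helpers for the (nx, ny, nz) array.
cell_index <- function(vol, i, j, k) {
  d <- dim(vol$labels)
  (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
}

# Nearest cell (i, j, k) to each row of a point matrix.
nearest_cell <- function(vol, pts) {
  near <- function(coord, v) {
    i <- findInterval(v, coord, all.inside = TRUE)
    i + (v - coord[i] > coord[pmin(i + 1, length(coord))] - v)
  }
  cbind(i = near(vol$x, pts[, 1]), j = near(vol$y, pts[, 2]),
        k = near(vol$z, pts[, 3]))
}

#' Export a labelled volume as a VTK rectilinear-grid text file
#'
#' Legacy-format ASCII VTK with the integer label array and a comment block
#' mapping integers to tissue names.
#'
#' @param vol A `labeled_volume`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume_vtk <- function(vol, path) {
  d <- dim(vol$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("labels:", paste(seq_along(vol$label_levels) - 1,
                                      vol$label_levels, sep = "=",
                                      collapse = " ")),
               "ASCII", "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("X_COORDINATES %d float", d[1]),
               paste(format(vol$x, trim = TRUE), collapse = " "),
               sprintf("Y_COORDINATES %d float", d[2]),
               paste(format(vol$y, trim = TRUE), collapse = " "),
               sprintf("Z_COORDINATES %d float", d[3]),
               paste(format(vol$z, trim = TRUE), collapse = " "),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(vol$labels) - 1L, collapse = " "), con)
  invisible(path)
}
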