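# Lofting: sweep the control cross-sections around the modiolar axis with
# vertex-wise cubic-spline interpolation over insertion angle, then apply the
# anisotropic (k1, k2, k3) scaling along (x, y, z).

#' Loft the template into a continuous cochlea model
#'
#' Interpolates every compartment polygon vertex across the control sections
#' with a natural cubic spline over insertion angle theta (degrees), giving a
#' continuous compartment model over the full 0-810 degree sweep; the model
#' carries the patient scale factors and is evaluated lazily (sections,
#' point-membership labelling).
#'
#' @param template A [build_template()] object.
#' @param spec A [cochlea_spec()]; `npsm_spec()` gives the unscaled template
#'   model.
#' @return An object of class `cochlea_model`.
#' @export
loft_cochlea <- function(template = build_template(), spec = npsm_spec()) {
  angles <- template$angles
  comps <- names(template$sections[[1]])
  splines <- lapply(comps, function(cn) {
    polys <- lapply(template$sections, `[[`, cn)
    nv <- nrow(polys[[1]])
    per_vertex <- lapply(seq_len(nv), function(j) {
      u <- vapply(polys, function(p) p[j, 1], numeric(1))
      v <- vapply(polys, function(p) p[j, 2], numeric(1))
      list(u = stats::splinefun(angles, u, method = "natural"),
           v = stats::splinefun(angles, v, method = "natural"))
    })
    per_vertex
  })
  names(splines) <- comps
  structure(list(spec = spec, template = template, splines = splines,
                 theta_max = max(angles)),
            class = "cochlea_model")
}

#' @export
print.cochlea_model <- function(x, ...) {
  cat(sprintf("<cochlea_model %s> A=%.2f B=%.2f H=%.2f mm, sweep %d deg\n",
              x$spec$model_kind, x$spec$A, x$spec$B, x$spec$H, x$theta_max))
  invisible(x)
}

#' Cross-section polygons of a lofted model at an arbitrary angle
#'
#' @param model A `cochlea_model`.
#' @param theta Insertion angle in degrees (0 to 810).
#' @param scaled If `TRUE`, the in-plane u coordinate is scaled by the radial
#'   factor at that angle and v by k3; if `FALSE` (default) the template-frame
#'   section is returned.
#' @return Named list of polygons (matrices with columns `u`, `v`).
#' @export
section_at <- function(model, theta, scaled = FALSE) {
  out <- lapply(model$splines, function(sv) {
    m <- t(vapply(sv, function(s) c(s$u(theta), s$v(theta)), numeric(2)))
    colnames(m) <- c("u", "v")
    m
  })
  if (scaled) {
    kr <- radial_scale(model$spec, theta)
    out <- lapply(out, function(p) {
      p[, "u"] <- p[, "u"] * kr
      p[, "v"] <- p[, "v"] * model$spec$k3
      p
    })
  }
  out
}

# Effective radial scale at angle theta: a point at angle theta has
# (x, y) = u * (cos, sin)(theta) scaled by (k1, k2), so its radial distance
# scales by sqrt((k1 cos)^2 + (k2 sin)^2).
radial_scale <- function(spec, theta) {
  t <- theta * pi / 180
  sqrt((spec$k1 * cos(t))^2 + (spec$k2 * sin(t))^2)
}

# Rectangle bounds (u_lo, u_hi, v_lo, v_hi) of a compartment at angles th
# (vectorized). Relies on the rectangle vertex layout of the template.
.comp_bounds <- function(model, comp, th) {
  sv <- model$splines[[comp]]
  u1 <- sv[[1]]$u(th); u2 <- sv[[2]]$u(th)
  v1 <- sv[[1]]$v(th); v3 <- sv[[3]]$v(th)
  list(u_lo = pmin(u1, u2), u_hi = pmax(u1, u2),
       v_lo = pmin(v1, v3), v_hi = pmax(v1, v3))
}

#' Label 3D points by cochlear compartment
#'
#' Points are mapped back to the template frame (dividing by k1, k2, k3),
#' converted to cylindrical coordinates about the modiolar (z) axis, and
#' tested against the lofted compartment rectangles on every candidate turn.
#'
#' @param model A `cochlea_model`.
#' @param pts Numeric matrix with columns x, y, z (mm, model frame).
#' @param min_membrane_thick Minimum axial thickness (mm, template frame)
#'   enforced for the two membranes, used by the voxelizer to keep membranes
#'   at least one cell thick on coarse grids. `0` disables the dilation.
#' @param detail If `TRUE`, also return the true (pre-dilation) local
#'   membrane thickness for membrane-labelled points.
#' @return Character vector: compartment name or `"bone"`; with
#'   `detail = TRUE` a list with elements `label` and `mem_thick` (mm,
#'   template frame, `NA` off the membranes).
#' @export
label_points <- function(model, pts, min_membrane_thick = 0, detail = FALSE) {
  spec <- model$spec
  tx <- pts[, 1] / spec$k1
  ty <- pts[, 2] / spec$k2
  tz <- pts[, 3] / spec$k3
  r <- sqrt(tx^2 + ty^2)
  phi <- atan2(ty, tx) * 180 / pi
  phi <- ifelse(phi < 0, phi + 360, phi)
  lab <- rep(NA_character_, nrow(pts))
  mem_thick <- rep(NA_real_, nrow(pts))
  # priority: membranes before scalae, duct before nerve
  order_comps <- c("basilar_membrane", "reissner_membrane", "scala_media",
                   "scala_tympani", "scala_vestibuli", "nerve")
  # the fluid scalae extend a short basal hook (below the round window)
  # before the 0-degree sweep start; the organized duct structures do not
  theta_min <- c(basilar_membrane = 0, reissner_membrane = 0,
                 scala_media = 0, scala_tympani = -HOOK_DEG,
                 scala_vestibuli = -HOOK_DEG, nerve = 0)
  for (m in -1:2) {
    th <- phi + 360 * m
    ok_turn <- th <= model$theta_max + 1e-9 & th >= -HOOK_DEG - 1e-9
    if (!any(ok_turn)) next
    for (comp in order_comps) {
      idx <- which(ok_turn & th >= theta_min[[comp]] - 1e-9 & is.na(lab))
      if (length(idx) == 0) next
      b <- .comp_bounds(model, comp, th[idx])
      thick <- b$v_hi - b$v_lo
      if (min_membrane_thick > 0 &&
          comp %in% c("basilar_membrane", "reissner_membrane")) {
        # dilate toward the scala media (where the organ of Corti sits, for
        # the basilar membrane), keeping the scala tympani / vestibuli
        # boundaries resolution-invariant
        grow <- pmax(0, min_membrane_thick - thick)
        if (comp == "basilar_membrane") b$v_hi <- b$v_hi + grow
        else b$v_lo <- b$v_lo - grow
      }
      hit <- r[idx] >= b$u_lo & r[idx] <= b$u_hi &
             tz[idx] >= b$v_lo & tz[idx] <= b$v_hi
      lab[idx[hit]] <- comp
      if (comp %in% c("basilar_membrane", "reissner_membrane")) {
        mem_thick[idx[hit]] <- thick[hit]
      }
    }
  }
  lab[is.na(lab)] <- "bone"
  if (detail) list(label = lab, mem_thick = mem_thick) else lab
}

#' Duct centerline of a lofted model
#'
#' The conical-helix centerline through the scala-tympani centroids of the
#' cross-sections, in the scaled model frame.
#'
#' @param model A `cochlea_model`.
#' @param theta Vector of insertion angles (degrees).
#' @return Matrix with columns x, y, z (mm).
#' @export
centerline_points <- function(model, theta) {
  b <- .comp_bounds(model, "scala_tympani", theta)
  u <- (b$u_lo + b$u_hi) / 2
  v <- (b$v_lo + b$v_hi) / 2
  t <- theta * pi / 180
  cbind(x = model$spec$k1 * u * cos(t),
        y = model$spec$k2 * u * sin(t),
        z = model$spec$k3 * v)
}

# Lateral scala-tympani wall path (scaled frame): the canonical electrode
# trajectory runs just inside the outer ST wall at mid scala-tympani height,
# offset inward by `offset` mm (carrier radius + clearance).
lateral_wall_path <- function(model, theta, offset = 0.45) {
  b <- .comp_bounds(model, "scala_tympani", theta)
  u <- b$u_hi - offset / pmax(radial_scale(model$spec, theta), 1e-9)
  v <- (b$v_lo + b$v_hi) / 2
  t <- theta * pi / 180
  cbind(x = model$spec$k1 * u * cos(t),
        y = model$spec$k2 * u * sin(t),
        z = model$spec$k3 * v)
}

# Cumulative arc length (mm) along a path given by angle samples.
path_arc_length <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(d))
}

#' Bounding box of the lofted duct
#'
#' @param model A `cochlea_model`.
#' @param margin Margin added on every side (mm).
#' @return 2 x 3 matrix (rows min/max; columns x, y, z).
#' @export
model_bbox <- function(model, margin = 0) {
  th <- seq(-HOOK_DEG, model$theta_max, by = 2)
  b <- .comp_bounds(model, "scala_tympani", th)
  bv <- .comp_bounds(model, "scala_vestibuli", th)
  bn <- .comp_bounds(model, "nerve", th)
  u <- pmax(b$u_hi, bv$u_hi)
  t <- th * pi / 180
  x <- model$spec$k1 * u * cos(t)
  y <- model$spec$k2 * u * sin(t)
  z_lo <- model$spec$k3 * pmin(b$v_lo, bn$v_lo)
  z_hi <- model$spec$k3 * pmax(bv$v_hi, bn$v_hi)
  rbind(min = c(min(x) - margin, min(y) - margin, min(z_lo) - margin),
        max = c(max(x) + margin, max(y) + margin, max(z_hi) + margin))
}
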