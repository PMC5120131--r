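# Canonical cross-section template of the cochlear duct.
#
# The template is a fixture: a spiral duct whose lateral-wall radius follows a
# log-spiral R0 * exp(-lambda * theta) chosen so that the basal diameters of
# the unscaled model are exactly A = 10.083 mm (x axis) and B = 7.679 mm
# (y axis), and whose basal-turn-to-helicotrema height is H = 7.427 mm.
# Compartments in each radial cross-section are axis-aligned rectangles in the
# (u, v) half-plane (u = distance from the modiolar axis, v = z), stacked
# bottom-to-top: scala tympani, basilar membrane, scala media, Reissner
# membrane, scala vestibuli, with the auditory-nerve canal adjacent to the
# inner duct wall.

#' Template (unscaled) cochlear dimensions
#'
#' The fixed dimensions of the template cochlea: the largest basal diameter
#' `A` measured through the modiolar axis, the perpendicular basal diameter
#' `B`, and the basal-turn-center to helicotrema height `H`, all in mm, plus
#' the total insertion-angle sweep in degrees.
#'
#' @return A named list with elements `A`, `B`, `H` (mm) and `theta_max`
#'   (degrees).
#' @export
template_dimensions <- function() {
  list(A = 10.083, B = 7.679, H = 7.427, theta_max = 810)
}

# Angular extent (degrees) of the basal fluid hook: the scala tympani and
# vestibuli continue below the round window before the 0-degree sweep start.
HOOK_DEG <- 20

# Lateral-wall (duct outer edge) radius at insertion angle theta (degrees).
lateral_wall_radius <- function(theta) {
  d <- template_dimensions()
  a <- d$B / d$A                      # exp(-lambda * 90 deg)
  lambda <- -log(a) / 90              # per degree
  R0 <- d$A / (1 + a^2)
  R0 * exp(-lambda * theta)
}

# Duct cross-section width (radial, mm) and height (axial, mm) at theta.
duct_width  <- function(theta) 1.7 * exp(-theta * log(1.7 / 0.42) / 810)
duct_height <- function(theta) 1.9 * exp(-theta * log(1.9 / 0.62) / 810)

# Centerline height of the duct cross-section (mm); linear rise over the
# sweep so that the apex sits exactly H above the basal-turn center.
centerline_z <- function(theta) {
  d <- template_dimensions()
  d$H * theta / d$theta_max
}

# Vertical compartment split, as fractions of duct height relative to the
# section center. The organ of Corti is merged into the basilar membrane and
# the spiral ligament into bone (they carry no separate conductivity).
.compartment_vfrac <- list(
  scala_tympani     = c(-0.50, -0.06),
  basilar_membrane  = c(-0.06, -0.01),
  scala_media       = c(-0.01,  0.22),
  reissner_membrane = c( 0.22,  0.26),
  scala_vestibuli   = c( 0.26,  0.50)
)

# Names of the duct compartments (the region swept by the lofted sections).
duct_compartments <- function() names(.compartment_vfrac)

# All template compartments, including the nerve canal.
template_compartments <- function() c(duct_compartments(), "nerve")

# One cross-section, built analytically: a named list of closed 4-vertex
# polygons (matrices with columns u, v; first vertex not repeated).
.analytic_section <- function(theta) {
  u_out <- lateral_wall_radius(theta)
  w <- duct_width(theta)
  h <- duct_height(theta)
  u_in <- u_out - w
  zc <- centerline_z(theta)
  rect <- function(u0, u1, v0, v1) {
    cbind(u = c(u0, u1, u1, u0), v = c(v0, v0, v1, v1))
  }
  polys <- lapply(.compartment_vfrac, function(f) {
    rect(u_in, u_out, zc + f[1] * h, zc + f[2] * h)
  })
  # Nerve canal: hugging the inner duct wall, biased toward the scala-tympani
  # side (where the spiral lamina carries the fibers), never reaching the
  # modiolar axis.
  # collapses to zero width near the apex where the duct approaches the axis
  n_lo <- max(min(0.30, u_in), u_in - 1.2)
  polys$nerve <- rect(n_lo, u_in, zc - 0.45 * h, zc + 0.15 * h)
  polys
}

#' Build the cross-section template of the cochlear duct
#'
#' Control cross-sections every 90 degrees of insertion angle from 0 to 810
#' degrees. Sections at 0, 180, 360, 540 and 720 degrees are primary shapes;
#' the intermediate sections (90, 270, 450, 630 and 810 degrees) are exact
#' vertex-wise linear midpoints of their two neighbouring primary sections
#' (an auxiliary apical profile beyond the sweep provides the second
#' neighbour of the 810-degree section).
#'
#' @return An object of class `cochlea_template`: a list with `angles`
#'   (degrees) and `sections`, one named list of closed 4-vertex polygons
#'   (columns `u`, `v`, mm) per angle.
#' @export
build_template <- function() {
  primary_angles <- seq(0, 900, by = 180)   # 900 deg is the virtual apex aid
  primary <- lapply(primary_angles, .analytic_section)
  names(primary) <- primary_angles
  angles <- seq(0, 810, by = 90)
  sections <- lapply(angles, function(th) {
    if (th %% 180 == 0) return(primary[[as.character(th)]])
    lo <- primary[[as.character(th - 90)]]
    hi <- primary[[as.character(th + 90)]]
    purrr::map2(lo, hi, function(p, q) (p + q) / 2)
  })
  names(sections) <- angles
  structure(list(angles = angles, sections = sections),
            class = "cochlea_template")
}

#' Area of a closed polygon
#'
#' Shoelace formula; the vertex matrix must not repeat the first vertex.
#'
#' @param poly Two-column matrix of vertices.
#' @return Absolute area in the squared unit of the vertices.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# TRUE if a polygon is simple (no two non-adjacent edges intersect).
# Adequate for the small fixture polygons used here.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  inter <- function(p, q) {
    d1 <- p[2, ] - p[1, ]; d2 <- q[2, ] - q[1, ]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((q[1, 1] - p[1, 1]) * d2[2] - (q[1, 2] - p[1, 2]) * d2[1]) / den
    s <- ((q[1, 1] - p[1, 1]) * d1[2] - (q[1, 2] - p[1, 2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && s > 1e-9 && s < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next
      if (inter(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.cochlea_template <- function(x, ...) {
  cat("<cochlea_template> ", length(x$angles), " control sections (",
      min(x$angles), "-", max(x$angles), " deg), compartments: ",
      paste(names(x$sections[[1]]), collapse = ", "), "\n", sep = "")
  invisible(x)
}
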