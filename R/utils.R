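# Small internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Template-frame cylindrical coordinates of model-frame points.
template_cylindrical <- function(spec, pts) {
  tx <- pts[, 1] / spec$k1
  ty <- pts[, 2] / spec$k2
  tz <- pts[, 3] / spec$k3
  phi <- atan2(ty, tx) * 180 / pi
  phi <- ifelse(phi < 0, phi + 360, phi)
  list(r = sqrt(tx^2 + ty^2), phi = phi, z = tz, x = tx, y = ty)
}
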