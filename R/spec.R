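# Cochlear size descriptors and landmark handling.
#
# A cochlea is summarized by three scalars measured on preoperative CBCT:
#   A  largest basal diameter through the modiolar axis (round window rim A1
#      to the opposite lateral wall A2),
#   B  basal diameter perpendicular to A (B1 to B2),
#   H  height from the basal-turn modiolar center H1 to the helicotrema H2.
# Dividing by the template dimensions gives the anisotropic scale factors
# k1 = A / 10.083, k2 = B / 7.679, k3 = H / 7.427 applied along x, y, z.

MARKER_IDS <- c("A1", "A2", "B1", "B2", "H1", "H2")

#' Cochlea size specification
#'
#' @param A,B,H Cochlear dimensions in mm (all > 0).
#' @param model_kind One of `"NPSM"` (template), `"NPSM2"` (cohort average)
#'   or `"PSM"` (patient specific); informational tag.
#' @return An object of class `cochlea_spec` with fields `A`, `B`, `H`,
#'   scale factors `k1`, `k2`, `k3` and `model_kind`.
#' @export
cochlea_spec <- function(A, B, H, model_kind = "PSM") {
  stopifnot(is.finite(A), is.finite(B), is.finite(H), A > 0, B > 0, H > 0)
  model_kind <- match.arg(model_kind, c("NPSM", "NPSM2", "PSM"))
  d <- template_dimensions()
  structure(list(A = A, B = B, H = H,
                 k1 = A / d$A, k2 = B / d$B, k3 = H / d$H,
                 model_kind = model_kind),
            class = "cochlea_spec")
}

#' Template cochlea specification (scale factors all 1)
#' @return A `cochlea_spec` with the template dimensions and kind `"NPSM"`.
#' @export
npsm_spec <- function() {
  d <- template_dimensions()
  s <- cochlea_spec(d$A, d$B, d$H)
  s$model_kind <- "NPSM"
  s
}

#' @export
print.cochlea_spec <- function(x, ...) {
  cat(sprintf("<cochlea_spec %s> A=%.3f B=%.3f H=%.3f mm (k=%.3f/%.3f/%.3f)\n",
              x$model_kind, x$A, x$B, x$H, x$k1, x$k2, x$k3))
  invisible(x)
}

# Landmark tibble -> named 6 x 3 matrix, validating presence and finiteness.
marker_matrix <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "x_mm", "y_mm", "z_mm") %in% names(markers)))
  missing <- setdiff(MARKER_IDS, markers$marker_id)
  if (length(missing) > 0) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(markers[match(MARKER_IDS, markers$marker_id),
                         c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- MARKER_IDS
  if (!all(is.finite(m))) stop("non-finite landmark coordinates")
  m
}

#' Derive a cochlea specification from the six landmark points
#'
#' Computes A = |A1-A2|, B = |B1-B2|, H = |H1-H2| from a landmark table and
#' returns the corresponding [cochlea_spec()].
#'
#' @param markers Data frame with columns `marker_id` (A1, A2, B1, B2, H1,
#'   H2), `x_mm`, `y_mm`, `z_mm`.
#' @param model_kind Passed to [cochlea_spec()].
#' @return A `cochlea_spec`.
#' @export
scale_from_landmarks <- function(markers, model_kind = "PSM") {
  m <- marker_matrix(markers)
  dist3 <- function(p, q) sqrt(sum((m[p, ] - m[q, ])^2))
  A <- dist3("A1", "A2"); B <- dist3("B1", "B2"); H <- dist3("H1", "H2")
  if (min(A, B, H) < 1e-6) {
    stop("invalid landmarks: coincident marker pair (degenerate measurement)")
  }
  cochlea_spec(A, B, H, model_kind = model_kind)
}

#' Canonical landmark positions of a model in its own frame
#'
#' A1/A2 sit on the lateral wall along x, B1/B2 along y (projected onto the
#' basal plane z = 0), H1 at the basal-turn modiolar center (origin) and H2
#' at the helicotrema on the modiolar axis, so that |A1-A2| = A, |B1-B2| = B
#' and |H1-H2| = H exactly.
#'
#' @param spec A `cochlea_spec` (defaults to the template).
#' @param frame Frame tag stored in the `frame` column.
#' @return Tibble with columns `marker_id`, `x_mm`, `y_mm`, `z_mm`, `frame`.
#' @export
markers_from_spec <- function(spec = npsm_spec(), frame = "cad") {
  r <- lateral_wall_radius(c(0, 180, 90, 270))
  tibble::tibble(
    marker_id = MARKER_IDS,
    x_mm = c(spec$k1 * r[1], -spec$k1 * r[2], 0, 0, 0, 0),
    y_mm = c(0, 0, spec$k2 * r[3], -spec$k2 * r[4], 0, 0),
    z_mm = c(0, 0, 0, 0, 0, spec$H),
    frame = frame
  )
}

#' Read / write landmark CSV files
#'
#' Columns: `marker_id` (A1..H2), `x_mm`, `y_mm`, `z_mm`, `scan`
#' (`preop`/`postop`) or `frame`.
#'
#' @param path File path.
#' @return `read_landmarks()` returns a tibble; `write_landmarks()` returns
#'   the input invisibly.
#' @export
read_landmarks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @param markers Landmark tibble.
#' @rdname read_landmarks
#' @export
write_landmarks <- function(markers, path) {
  readr::write_csv(markers, path)
  invisible(markers)
}
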