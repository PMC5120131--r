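# Landmark-based similarity registration between the preoperative,
# postoperative and CAD (model) coordinate frames.
#
# With exactly two labelled six-point sets, generalized Procrustes analysis
# reduces to ordinary orthogonal Procrustes with uniform scaling: the
# closed-form Kabsch solution with a determinant correction that forbids
# reflections.

#' Least-squares similarity transform between two labelled marker sets
#'
#' Finds translation, proper rotation and uniform scale minimizing the sum of
#' squared distances between corresponding markers (matched by `marker_id`).
#'
#' @param source,target Landmark tibbles (columns `marker_id`, `x_mm`,
#'   `y_mm`, `z_mm`) with the same six labels.
#' @return A `similarity_transform`: list with `R` (3 x 3 proper rotation),
#'   `t` (translation, mm), `s` (scale > 0) and `rms` (residual RMS, mm),
#'   mapping source points y = s R x + t onto the target frame.
#' @export
procrustes_fit <- function(source, target) {
  X <- marker_matrix(source)
  Y <- marker_matrix(target)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  nx <- sum(Xc^2)
  if (nx < 1e-12) stop("degenerate source configuration (all markers coincide)")
  sv <- svd(crossprod(Xc, Yc))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("rank-deficient (collinear) marker configuration")
  }
  dsign <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, dsign))
  R <- sv$v %*% D %*% t(sv$u)
  s <- sum(sv$d * c(1, 1, dsign)) / nx
  if (s <= 0) stop("non-positive scale in Procrustes fit")
  t_vec <- unname(my) - s * as.numeric(R %*% mx)
  fit <- structure(list(R = R, t = t_vec, s = s), class = "similarity_transform")
  res <- apply_transform(fit, X) - Y
  fit$rms <- sqrt(mean(rowSums(res^2)))
  fit
}

#' Apply, compose and invert similarity transforms
#'
#' @param tf,tf1,tf2 `similarity_transform` objects.
#' @param pts Point matrix (columns x, y, z).
#' @return `apply_transform()`: transformed points; `compose_transforms()`:
#'   the transform equivalent to applying `tf1` then `tf2`;
#'   `invert_transform()`: the inverse transform.
#' @export
apply_transform <- function(tf, pts) {
  out <- tf$s * (as.matrix(pts)[, 1:3, drop = FALSE] %*% t(tf$R))
  sweep(out, 2, tf$t, "+")
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(tf2, tf1) {
  structure(list(R = tf2$R %*% tf1$R,
                 t = tf2$s * as.numeric(tf2$R %*% tf1$t) + tf2$t,
                 s = tf2$s * tf1$s),
            class = "similarity_transform")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  structure(list(R = t(tf$R),
                 t = -as.numeric(t(tf$R) %*% tf$t) / tf$s,
                 s = 1 / tf$s),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.4f, |t| = %.3f mm%s\n", x$s,
              sqrt(sum(x$t^2)),
              if (!is.null(x$rms)) sprintf(", residual RMS %.4f mm", x$rms)
              else ""))
  invisible(x)
}

#' Map electrode position estimates into the model (CAD) frame
#'
#' Chains the landmark-based similarity transforms postop -> preop -> CAD and
#' applies the composition to the raw contact estimates.
#'
#' @param raw_positions 22 x 3 matrix or tibble (columns `x_mm`, `y_mm`,
#'   `z_mm`) of contact estimates in the postoperative frame, ordered basal
#'   to apical.
#' @param preop,postop,cad Landmark tibbles for the three frames.
#' @return 22 x 3 matrix of contact positions in the CAD frame.
#' @export
map_electrodes_to_cad <- function(raw_positions, preop, postop, cad) {
  pts <- if (is.data.frame(raw_positions)) {
    as.matrix(raw_positions[, c("x_mm", "y_mm", "z_mm")])
  } else {
    as.matrix(raw_positions)
  }
  tf <- compose_transforms(procrustes_fit(preop, cad),
                           procrustes_fit(postop, preop))
  out <- apply_transform(tf, pts)
  colnames(out) <- c("x_mm", "y_mm", "z_mm")
  out
}
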