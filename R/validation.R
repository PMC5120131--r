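# Validation against measured voltage matrices: the bias-removed RMS error,
# conductivity-ratio optimization, and homogeneous-model conductivity
# fitting.

#' Bias-removed RMS error between two voltage matrices
#'
#' For every stimulating contact s the per-column mean over the N - 1
#' recorded contacts is subtracted from both matrices (removing any common
#' offset between measurement and model), squared differences are
#' accumulated over all off-diagonal pairs (s, k != s), normalized by
#' N (N - 1), and the square root returned, in mV.
#'
#' @param measured,predicted `voltage_matrix` objects of identical size.
#' @return RMS error in mV.
#' @export
rms_error <- function(measured, predicted) {
  M <- unclass(measured); P <- unclass(predicted)
  if (!all(dim(M) == dim(P))) stop("voltage matrices differ in shape")
  n <- nrow(M)
  if (n < 2) stop("need at least two contacts")
  Mc <- sweep(M, 2, colMeans(M, na.rm = TRUE))
  Pc <- sweep(P, 2, colMeans(P, na.rm = TRUE))
  d2 <- (Mc - Pc)^2
  sqrt(sum(d2[row(d2) != col(d2)]) / (n * (n - 1)))
}

#' Optimize the scala-tympani / bone conductivity ratio
#'
#' Simulates the voltage matrix for every ratio on the grid (scala-tympani
#' conductivity held at its default while bone = sigma_ST / R), scores each
#' against the measured matrix with [rms_error()], and returns the grid
#' minimizer; ties break toward the larger R.
#'
#' @param vol A `labeled_volume` with electrodes (the patient geometry).
#' @param measured A `voltage_matrix` (mV).
#' @param grid Candidate R values (default [default_R_grid()]).
#' @param sigma Base [conductivity_table()]; its `bone` entry is overridden
#'   per grid point.
#' @param current_uA Stimulus amplitude.
#' @param contacts Contacts to simulate (default all).
#' @param predictions Optional precomputed list of `voltage_matrix`
#'   predictions, one per grid value, bypassing the forward solves.
#' @return An object of class `r_opt`: list with `r_min`, `rms_min_mV`, the
#'   error `curve` (tibble R / rms_mV) and the predicted matrix at the
#'   optimum.
#' @export
optimize_R <- function(vol, measured, grid = default_R_grid(),
                       sigma = conductivity_table(), current_uA = 106.5,
                       contacts = NULL, predictions = NULL) {
  stopifnot(length(grid) >= 1, all(grid > 0))
  contacts <- contacts %||% seq_len(nrow(measured))
  if (is.null(predictions)) {
    predictions <- lapply(grid, function(R) {
      sig <- sigma
      sig["bone"] <- sig["scala_tympani"] / R
      simulate_voltage_matrix(vol, sig, current_uA = current_uA,
                              contacts = contacts)
    })
  }
  stopifnot(length(predictions) == length(grid))
  errs <- vapply(predictions, rms_error, numeric(1), measured = measured)
  if (any(!is.finite(errs))) stop("non-finite error on the R grid")
  best <- max(which(errs == min(errs)))   # ties toward larger R
  structure(list(r_min = grid[best], rms_min_mV = errs[best],
                 curve = tibble::tibble(R = grid, rms_mV = errs),
                 prediction = predictions[[best]]),
            class = "r_opt")
}

#' @export
print.r_opt <- function(x, ...) {
  cat(sprintf("<r_opt> R_min = %.3f (RMS error %.4f mV over %d grid points)\n",
              x$r_min, x$rms_min_mV, nrow(x$curve)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the R-optimization error curve
#' @param x An `r_opt` object.
#' @param ... Unused.
#' @return Tibble with columns `R`, `rms_mV`, `minimum` (logical).
#' @export
tidy.r_opt <- function(x, ...) {
  dplyr::mutate(x$curve, minimum = .data$R == x$r_min)
}

#' One-row summary of an R optimization
#' @param x An `r_opt` object.
#' @param ... Unused.
#' @return Tibble with `r_min`, `rms_min_mV`, `n_grid`, `grid_min`, `grid_max`.
#' @export
glance.r_opt <- function(x, ...) {
  tibble::tibble(r_min = x$r_min, rms_min_mV = x$rms_min_mV,
                 n_grid = nrow(x$curve), grid_min = min(x$curve$R),
                 grid_max = max(x$curve$R))
}

#' Fit the homogeneous-model conductivity to measured matrices
#'
#' One-dimensional minimization of the mean bias-removed RMS error of the
#' point-source model over sigma in [0.1, 5] S/m, across one or more
#' patients.
#'
#' @param measured List of `voltage_matrix` objects (one per patient), or a
#'   single matrix.
#' @param arrays List of `electrode_array`s (contact positions per patient).
#' @param current_uA Stimulus amplitude.
#' @param interval Search interval for sigma (S/m).
#' @return List with `sigma` (S/m) and `rms_mV` (mean error at the optimum).
#' @export
fit_hm_sigma <- function(measured, arrays, current_uA = 106.5,
                         interval = c(0.1, 5)) {
  if (inherits(measured, "voltage_matrix")) measured <- list(measured)
  if (inherits(arrays, "electrode_array") || is.matrix(arrays)) {
    arrays <- list(arrays)
  }
  stopifnot(length(measured) >= 1, length(measured) == length(arrays))
  obj <- function(sig) {
    mean(mapply(function(mm, arr) {
      rms_error(mm, hm_voltage_matrix(arr, sig, current_uA))
    }, measured, arrays))
  }
  op <- stats::optimize(obj, interval = interval)
  list(sigma = op$minimum, rms_mV = op$objective)
}

#' Score several model predictions against one measured matrix
#'
#' @param measured A `voltage_matrix`.
#' @param predictions Named list of predicted `voltage_matrix` objects
#'   (e.g. HM, NPSM, NPSM2, PSM, optPSM). `NULL` entries are flagged with
#'   `NA` scores rather than failing.
#' @param patient Optional patient id recycled into the output.
#' @return Tibble with columns `patient`, `model`, `rms_error_mV`.
#' @export
compare_models <- function(measured, predictions, patient = NA_character_) {
  stopifnot(length(names(predictions)) == length(predictions))
  rms <- vapply(predictions, function(p) {
    if (is.null(p)) NA_real_ else rms_error(measured, p)
  }, numeric(1))
  tibble::tibble(patient = patient, model = names(predictions),
                 rms_error_mV = unname(rms))
}
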