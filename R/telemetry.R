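# Intra-cochlear voltage matrices: forward simulation and emulated
# back-telemetry measurements.
#
# Entry [k, s] of a voltage matrix is the potential (mV) at recording
# contact k while contact s is stimulated; the diagonal is excluded from all
# statistics because self-recordings are dominated by the electrode-tissue
# interface rather than the anatomy.

#' Construct a voltage matrix
#'
#' @param m N x N numeric matrix (mV); the diagonal is set to `NA`.
#' @return A `voltage_matrix`.
#' @export
voltage_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), nrow(m) >= 2)
  diag(m) <- NA_real_
  if (any(!is.finite(m[row(m) != col(m)]))) {
    stop("off-diagonal entries must be finite")
  }
  dimnames(m) <- list(recording = seq_len(nrow(m)),
                      stimulating = seq_len(ncol(m)))
  structure(m, class = c("voltage_matrix", "matrix"))
}

#' @export
print.voltage_matrix <- function(x, ...) {
  cat(sprintf("<voltage_matrix> %d contacts (mV, diagonal excluded)\n", nrow(x)))
  print(round(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], 3))
  invisible(x)
}

#' Simulate the intra-cochlear voltage matrix
#'
#' Stimulates every contact in turn (one pair of triangular solves per
#' contact on the prefactorized operator) and records the potential at all
#' contacts; entry [k, s] is the recording at k while stimulating s, in mV.
#'
#' @param vol A `labeled_volume` with an electrode array.
#' @param sigma A [conductivity_table()].
#' @param current_uA Stimulus amplitude (microamperes).
#' @param contacts Which contacts to stimulate/record (default all 22).
#' @return A `voltage_matrix` (mV).
#' @export
simulate_voltage_matrix <- function(vol, sigma = conductivity_table(),
                                    current_uA = 106.5,
                                    contacts = seq_along(vol$contact_cells)) {
  pf <- vc_prepare(vol, sigma)
  n <- length(contacts)
  out <- matrix(NA_real_, n, n)
  for (jj in seq_len(n)) {
    f <- solve_potential(vol, sigma,
                         stimulus_config(contacts[jj], current_uA),
                         factor = pf)
    out[, jj] <- contact_potentials(f)[contacts] * 1000   # V -> mV
  }
  voltage_matrix(out)
}

#' Emulate a noisy telemetry measurement of a voltage matrix
#'
#' Entrywise multiplicative Gaussian noise (mean 1, SD `noise_cv`), seeded
#' for reproducibility. Stands in for patient back-telemetry.
#'
#' @param true_matrix A `voltage_matrix`.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A `voltage_matrix`.
#' @export
synthesize_measurement <- function(true_matrix, noise_cv = 0.05, seed = 1) {
  stopifnot(noise_cv >= 0)
  m <- unclass(true_matrix)
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(length(m), 1, noise_cv), nrow(m), ncol(m)))
  voltage_matrix(m * noise)
}

#' Tidy a voltage matrix into long format
#'
#' @param x A `voltage_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `stimulating`, `recording`, `mV` (diagonal
#'   rows dropped).
#' @export
tidy.voltage_matrix <- function(x, ...) {
  n <- nrow(x)
  out <- tibble::tibble(
    stimulating = rep(seq_len(n), each = n),
    recording = rep(seq_len(n), times = n),
    mV = as.vector(unclass(x))
  )
  out[out$stimulating != out$recording, ]
}

#' Read / write voltage-matrix CSV files
#'
#' First column `recording`, remaining columns `s1..sN` (stimulating
#' contacts); diagonal cells are written as `NA`; values in mV.
#'
#' @param path File path.
#' @param x A `voltage_matrix` (for writing).
#' @return `read_voltage_matrix()` returns a `voltage_matrix`.
#' @export
read_voltage_matrix <- function(path) {
  tb <- utils::read.csv(path, check.names = FALSE)
  voltage_matrix(as.matrix(tb[, -1]))
}

#' @rdname read_voltage_matrix
#' @export
write_voltage_matrix <- function(x, path) {
  df <- data.frame(recording = seq_len(nrow(x)), unclass(x),
                   check.names = FALSE)
  names(df)[-1] <- paste0("s", seq_len(ncol(x)))
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(x)
}

#' Homogeneous-model voltage matrix from contact positions alone
#'
#' The point-source model evaluated pairwise over the contact positions:
#' entry [k, s] = I / (4 pi sigma d(k, s)) in mV.
#'
#' @param array An `electrode_array` (or matrix of positions, mm).
#' @param sigma_hm Homogeneous medium conductivity (S/m).
#' @param current_uA Stimulus amplitude (microamperes).
#' @return A `voltage_matrix` (mV).
#' @export
hm_voltage_matrix <- function(array, sigma_hm = 1.43, current_uA = 106.5) {
  pts <- if (is.data.frame(array)) {
    as.matrix(array[, c("x_mm", "y_mm", "z_mm")])
  } else {
    as.matrix(array)
  }
  n <- nrow(pts)
  out <- matrix(NA_real_, n, n)
  for (s in seq_len(n)) {
    out[-s, s] <- homogeneous_potential(pts[s, , drop = FALSE], sigma_hm,
                                        current_uA * 1e-6,
                                        pts[-s, , drop = FALSE]) * 1000
  }
  voltage_matrix(out)
}
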