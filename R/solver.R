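# Quasi-static volume-conduction solve on the labelled voxel grid.
#
# Finite-volume 7-point discretization of div(sigma grad V) = 0 with
# harmonic-mean face conductivities (so thin membranes behave as series
# resistors), total current I injected uniformly over the active contact
# cells, homogeneous Dirichlet (0 V) on the ground shell and natural
# zero-flux conditions elsewhere. The SPD system is factorized once with
# sparse Cholesky (CHOLMOD) and reused across stimulating contacts.

#' Stimulus configuration
#'
#' @param contact Active (stimulating) contact index, 1 (most basal) to 22
#'   (most apical).
#' @param current_uA Injected current in microamperes (default 106.5, the
#'   clinical telemetry stimulus level).
#' @param phase_us,gap_us Biphasic pulse metadata (microseconds); carried for
#'   reporting, unused by the stationary solve.
#' @return A `stimulus_config` list; current is stored in amperes.
#' @export
stimulus_config <- function(contact = 1, current_uA = 106.5,
                            phase_us = 25, gap_us = 8) {
  stopifnot(current_uA > 0, contact >= 1, contact <= 22)
  structure(list(contact = as.integer(contact), I = current_uA * 1e-6,
                 phase_us = phase_us, gap_us = gap_us),
            class = "stimulus_config")
}

#' Analytic homogeneous (point-source) potential
#'
#' Superposition of point-current-source potentials in an infinite
#' homogeneous medium: V(p) = sum_i I_i / (4 pi sigma |p - p_i|).
#'
#' @param sources Matrix of source positions (columns x, y, z, mm); one row
#'   per source.
#' @param sigma Medium conductivity (S/m).
#' @param I Injected current (A); scalar or one value per source.
#' @param points Query points (matrix, columns x, y, z, mm).
#' @return Potential in volts at each query point.
#' @export
homogeneous_potential <- function(sources, sigma, I, points) {
  stopifnot(sigma > 0)
  sources <- rbind(sources)
  I <- rep_len(I, nrow(sources))
  v <- numeric(nrow(points))
  for (s in seq_len(nrow(sources))) {
    d <- sqrt((points[, 1] - sources[s, 1])^2 +
              (points[, 2] - sources[s, 2])^2 +
              (points[, 3] - sources[s, 3])^2) * 1e-3   # mm -> m
    if (any(d < 1e-12)) stop("query point coincides with a source (singular)")
    v <- v + I[s] / (4 * pi * sigma * d)
  }
  v
}

# Per-cell conductivity, with a sheet-resistance-preserving correction for
# membrane cells dilated to one cell thickness: a cell of axial size dz
# containing a membrane of true thickness t gets the series-equivalent
# sigma_eff = dz / (t / sigma_membrane + (dz - t) / sigma_fluid), so the
# trans-membrane resistance is independent of grid resolution.
effective_sigma_cells <- function(vol, sigma) {
  lev <- sigma_by_level(sigma)
  sig_cell <- array(lev[vol$labels], dim = dim(vol$labels))
  for (mem in c("basilar_membrane", "reissner_membrane")) {
    ml <- match(mem, LABEL_LEVELS)
    sel <- which(vol$labels == ml)
    if (length(sel) == 0) next
    k <- ((sel - 1L) %/% (dim(vol$labels)[1] * dim(vol$labels)[2])) + 1L
    dz <- vol$dz[k]
    t <- pmin(vol$mem_thick[sel], dz)
    fluid <- if (mem == "basilar_membrane") "scala_tympani" else "scala_media"
    sig_cell[sel] <- dz / (t / sigma[[mem]] + (dz - t) / sigma[[fluid]])
  }
  sig_cell
}

# Assemble the SPD system for a labelled volume and conductivity table:
# A (dsCMatrix) over the unknown cells, the unknown-id array, and the
# per-cell conductivities reused by flux integration.
vc_system <- function(vol, sigma) {
  sig_cell <- effective_sigma_cells(vol, sigma)
  d <- dim(vol$labels)
  ext <- match("exterior", LABEL_LEVELS)
  gnd <- match("ground", LABEL_LEVELS)
  unknown <- vol$labels != ext & vol$labels != gnd
  id <- array(0L, d)
  id[unknown] <- seq_len(sum(unknown))
  idg <- id
  idg[vol$labels == gnd] <- -1L

  sz <- list(vol$dx, vol$dy, vol$dz)
  ii <- jj <- xx <- list()
  t <- 1
  for (a in 1:3) {
    n <- d[a]
    sl <- function(rng) {
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ix[[a]] <- rng
      ix
    }
    lo <- sl(1:(n - 1)); hi <- sl(2:n)
    id1 <- idg[lo[[1]], lo[[2]], lo[[3]]]
    id2 <- idg[hi[[1]], hi[[2]], hi[[3]]]
    s1 <- sig_cell[lo[[1]], lo[[2]], lo[[3]]]
    s2 <- sig_cell[hi[[1]], hi[[2]], hi[[3]]]
    # face area / separation, in meters (coords are mm)
    other <- setdiff(1:3, a)
    area_grid <- outer(sz[[other[1]]], sz[[other[2]]]) * 1e-6   # m^2
    h1 <- sz[[a]][1:(n - 1)] * 1e-3 / 2
    h2 <- sz[[a]][2:n] * 1e-3 / 2
    dm <- d; dm[a] <- n - 1
    # resistance of the two half-cells in series (harmonic face conductance)
    r12 <- sweep(array(0, dm), a, h1, "+") / s1 +
           sweep(array(0, dm), a, h2, "+") / s2
    area <- aperm(array(rep(area_grid, dm[a]),
                        dim = c(dm[other[1]], dm[other[2]], dm[a])),
                  perm = order(c(other, a)))
    G <- area / r12
    ok <- id1 != 0 & id2 != 0 & is.finite(G)
    u1 <- id1[ok]; u2 <- id2[ok]; g <- G[ok]
    both <- u1 > 0 & u2 > 0
    # off-diagonals
    ii[[t]] <- c(u1[both], u2[both]); jj[[t]] <- c(u2[both], u1[both])
    xx[[t]] <- c(-g[both], -g[both]); t <- t + 1
    # diagonal contributions (including faces to ground cells)
    d1 <- u1 > 0; d2 <- u2 > 0
    ii[[t]] <- c(u1[d1], u2[d2]); jj[[t]] <- c(u1[d1], u2[d2])
    xx[[t]] <- c(g[d1], g[d2]); t <- t + 1
  }
  n_unk <- sum(unknown)
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_unk, n_unk))
  list(A = Matrix::forceSymmetric(A), id = id, unknown = unknown,
       sig_cell = sig_cell)
}

# Injection vector: current I spread over the active contact's cells with
# volume-proportional weights (the same weights define contact recording, so
# the discrete operator is reciprocal).
vc_rhs <- function(vol, sys, contact, I) {
  cc <- vol$contact_cells
  if (is.null(cc)) stop("volume has no electrode array (see add_electrode_array)")
  cells <- cc[[contact]]
  if (length(cells$idx) == 0) stop("active contact has no cells in the volume")
  b <- numeric(nrow(sys$A))
  ids <- sys$id[cells$idx]
  if (any(ids == 0)) stop("contact cells outside the solvable domain")
  b[ids] <- b[ids] + I * cells$w
  b
}

#' Solve the quasi-static potential for monopolar stimulation
#'
#' @param vol A `labeled_volume` containing an electrode array
#'   ([add_electrode_array()]).
#' @param sigma A [conductivity_table()].
#' @param stimulus A [stimulus_config()].
#' @param factor Optional prefactorized system from [vc_prepare()]; reuse it
#'   when solving many stimulating contacts on the same volume and
#'   conductivities.
#' @return A `potential_field`: the potential array `v` (volts; `NA` outside
#'   the domain, 0 on the ground shell) plus solver metadata (`residual`,
#'   relative; `n_unknowns`).
#' @export
solve_potential <- function(vol, sigma = conductivity_table(),
                            stimulus = stimulus_config(), factor = NULL) {
  pf <- factor %||% vc_prepare(vol, sigma)
  b <- vc_rhs(vol, pf$sys, stimulus$contact, stimulus$I)
  x <- as.numeric(Matrix::solve(pf$chol, b))
  res <- sqrt(sum((as.numeric(pf$sys$A %*% x) - b)^2)) / sqrt(sum(b^2))
  v <- array(NA_real_, dim = dim(vol$labels))
  v[pf$sys$unknown] <- x
  v[vol$labels == match("ground", LABEL_LEVELS)] <- 0
  structure(list(v = v, vol = vol, sigma = sigma, stimulus = stimulus,
                 residual = res, n_unknowns = length(x)),
            class = "potential_field")
}

#' Prefactorize the volume-conduction system
#'
#' Assembles and Cholesky-factorizes the discrete operator once, so repeated
#' solves (one per stimulating contact, 22 per voltage matrix) cost only a
#' pair of triangular solves each.
#'
#' @inheritParams solve_potential
#' @return An opaque factor object accepted by `solve_potential(factor = )`.
#' @export
vc_prepare <- function(vol, sigma = conductivity_table()) {
  sys <- vc_system(vol, sigma)
  ch <- Matrix::Cholesky(sys$A, LDL = FALSE, super = TRUE)
  list(sys = sys, chol = ch)
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf(
    "<potential_field> contact %d, I = %.4g uA, %d unknowns, residual %.2e\n",
    x$stimulus$contact, x$stimulus$I * 1e6, x$n_unknowns, x$residual))
  invisible(x)
}

#' Trilinear sampling of a potential field
#'
#' @param field A `potential_field`.
#' @param points Matrix of query points (columns x, y, z, mm).
#' @return Potential in volts at each point (NA outside the grid).
#' @export
sample_field <- function(field, points) {
  interp_rectilinear(field$vol$x, field$vol$y, field$vol$z, field$v, points)
}

# Trilinear interpolation on a rectilinear grid of cell centers.
interp_rectilinear <- function(xs, ys, zs, v, pts) {
  locate <- function(coord, p) {
    i <- findInterval(p, coord, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(coord) - 1L)
    w <- (p - coord[i]) / (coord[i + 1] - coord[i])
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  lx <- locate(xs, pts[, 1]); ly <- locate(ys, pts[, 2]); lz <- locate(zs, pts[, 3])
  out <- numeric(nrow(pts))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (cx * lx$w + (1 - cx) * (1 - lx$w)) *
         (cy * ly$w + (1 - cy) * (1 - ly$w)) *
         (cz * lz$w + (1 - cz) * (1 - lz$w))
    vals <- v[cbind(lx$i + cx, ly$i + cy, lz$i + cz)]
    vals[is.na(vals)] <- 0
    out <- out + w * vals
  }
  out
}

#' Record potentials at the electrode contacts
#'
#' Uses the same volume-proportional cell weights as current injection, so
#' the simulated transimpedance matrix is reciprocal up to solver tolerance.
#'
#' @param field A `potential_field`.
#' @return Numeric vector, volts, one value per contact.
#' @export
contact_potentials <- function(field) {
  vol <- field$vol
  vapply(vol$contact_cells, function(cc) {
    sum(field$v[cc$idx] * cc$w)
  }, numeric(1))
}

#' Convex combination of potential fields from different grounding modes
#'
#' @param fields List of `potential_field`s on identical grids.
#' @param weights Non-negative weights summing to 1.
#' @return A `potential_field` with the combined potential.
#' @export
weighted_ground_potential <- function(fields, weights) {
  stopifnot(length(fields) == length(weights), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  ref <- fields[[1]]
  for (f in fields[-1]) {
    if (!identical(dim(f$v), dim(ref$v)) ||
        max(abs(f$vol$x - ref$vol$x)) > 1e-9 ||
        max(abs(f$vol$y - ref$vol$y)) > 1e-9 ||
        max(abs(f$vol$z - ref$vol$z)) > 1e-9) {
      stop("fields must share an identical grid")
    }
  }
  v <- Reduce(`+`, Map(function(f, w) {
    a <- f$v
    a[is.na(a)] <- 0
    a * w
  }, fields, as.list(weights)))
  v[is.na(ref$v)] <- NA_real_
  out <- ref
  out$v <- v
  out$residual <- max(vapply(fields, `[[`, numeric(1), "residual"))
  out
}

#' Export a potential field as a VTK rectilinear-grid text file
#'
#' @param field A `potential_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  vol <- field$vol
  d <- dim(field$v)
  v <- field$v
  v[is.na(v)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("potential (V), contact %d, I %.6g A",
                       field$stimulus$contact, field$stimulus$I),
               "ASCII", "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("X_COORDINATES %d float", d[1]),
               paste(format(vol$x, trim = TRUE), collapse = " "),
               sprintf("Y_COORDINATES %d float", d[2]),
               paste(format(vol$y, trim = TRUE), collapse = " "),
               sprintf("Z_COORDINATES %d float", d[3]),
               paste(format(vol$z, trim = TRUE), collapse = " "),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS potential float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(format(as.vector(v), trim = TRUE, digits = 7),
                   collapse = " "), con)
  invisible(path)
}

#' Contact-sampled potentials as a tidy table
#'
#' @param field A `potential_field`.
#' @return Tibble with columns `contact`, `mV`, `stimulating` (logical).
#' @export
contact_potential_table <- function(field) {
  v <- contact_potentials(field) * 1000
  tibble::tibble(contact = seq_along(v), mV = v,
                 stimulating = seq_along(v) == field$stimulus$contact)
}
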