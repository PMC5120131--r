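# Stochastic auditory-nerve population coupled to the potential field.
#
# Each fiber has 10 nodes: k = 10 (most peripheral, under the basilar
# membrane) down to k = 1 (central axon end in the modiolar trunk); nodes
# 10..6 are dendritic, node 5 the soma, nodes 4..1 axonal. The activation
# function is the discrete second difference of the extracellular potential
# along the fiber; firing is thresholded through a log-normal threshold and
# normal relative-spread draw per fiber.

#' Place an auditory-nerve fiber population
#'
#' Distributes `n_fibers` fibers along the full cochlear sweep. Each fiber
#' starts just below the basilar membrane near the inner duct wall, runs
#' radially inward through the nerve canal and bends down the modiolus.
#' Node anchor positions scale with the patient factors (k1, k2, k3); the
#' internode spacing is the same fixed value for every model.
#'
#' @param cmodel A `cochlea_model`.
#' @param n_fibers Number of fibers (default 7000).
#' @param internode Internode distance in mm (default 0.35), constant across
#'   models.
#' @return A `fiber_population`: list with `nodes` (n_fibers x 10 x 3 array,
#'   mm; slice j holds node k = j), `arc_mm` (fiber position along the
#'   basilar membrane, base to apex), `theta_deg`, and parameters.
#' @export
place_fibers <- function(cmodel, n_fibers = 7000, internode = 0.35) {
  stopifnot(n_fibers >= 1, internode > 0)
  theta <- seq(1, cmodel$theta_max - 1, length.out = n_fibers)
  # anchor: most peripheral node, just below the basilar membrane at the
  # inner third of the duct width
  bbm <- .comp_bounds(cmodel, "basilar_membrane", theta)
  bst <- .comp_bounds(cmodel, "scala_tympani", theta)
  u0 <- bbm$u_lo + 0.25 * (bbm$u_hi - bbm$u_lo)
  v0 <- bbm$v_lo - 0.15 * (bbm$v_lo - bst$v_lo)
  spec <- cmodel$spec
  t <- theta * pi / 180
  anchor <- cbind(spec$k1 * u0 * cos(t), spec$k2 * u0 * sin(t),
                  spec$k3 * v0)
  # direction: radially inward toward the modiolar axis, tilting downward
  # so the axonal nodes descend the modiolar trunk
  inward <- cbind(-cos(t), -sin(t), numeric(n_fibers))
  down <- cbind(numeric(n_fibers), numeric(n_fibers), rep(-1, n_fibers))
  nodes <- array(NA_real_, dim = c(n_fibers, 10, 3))
  for (j in 0:9) {
    k <- 10 - j   # node index: j steps from the peripheral anchor
    frac <- j / 9
    dir <- (1 - frac) * inward + frac * down
    dir <- dir / sqrt(rowSums(dir^2))
    if (j == 0) {
      nodes[, 10, ] <- anchor
    } else {
      nodes[, k, ] <- nodes[, k + 1, ] + internode * dir
    }
  }
  arc <- path_arc_length(centerline_points(cmodel, theta))
  structure(list(nodes = nodes, arc_mm = arc, theta_deg = theta,
                 n_fibers = n_fibers, internode = internode,
                 spec = spec),
            class = "fiber_population")
}

#' @export
print.fiber_population <- function(x, ...) {
  cat(sprintf("<fiber_population> %d fibers x 10 nodes, internode %.2f mm\n",
              x$n_fibers, x$internode))
  invisible(x)
}

#' Activation function along a sampled potential profile
#'
#' Discrete second spatial difference (V[i-1] - 2 V[i] + V[i+1]) / dx^2 of
#' the extracellular potential along the fiber, evaluated on a fine
#' (default 10 um) sampling and reported in V/mm^2.
#'
#' @param v Potential samples in volts, ordered along the fiber.
#' @param dx Sample spacing in mm (default 0.01 = 10 um).
#' @return Second-difference values (V/mm^2) at the interior sample points;
#'   the two boundary points are dropped.
#' @export
activation_function <- function(v, dx = 0.01) {
  n <- length(v)
  if (n < 3) stop("need at least three potential samples")
  (v[-c(1, 2)] - 2 * v[-c(1, n)] + v[-c(n - 1, n)]) / dx^2
}

# Sample the field along every fiber at `dx` (mm) resolution and return the
# activation function aggregated at the 10 node positions:
# a matrix n_fibers x 10 (V/mm^2), column j = node k = j.
fiber_node_activation <- function(field, fibers, dx = 0.01) {
  nodes <- fibers$nodes
  nf <- dim(nodes)[1]
  # arc-length positions of the nodes along the fiber polyline
  seg <- sqrt(apply((nodes[, 9:1, , drop = FALSE] -
                     nodes[, 10:2, , drop = FALSE])^2, c(1, 2), sum))
  s_nodes <- cbind(0, t(apply(seg, 1, cumsum)))   # nf x 10, from node 10
  total <- s_nodes[, 10]
  ns <- max(3, ceiling(max(total) / dx) + 1)
  s_samp <- outer(total, seq(0, 1, length.out = ns))   # nf x ns
  # sample points: linear interpolation along the 9-segment polyline
  pts <- array(NA_real_, dim = c(nf, ns, 3))
  for (sgi in 1:9) {
    lo <- s_nodes[, sgi]; hi <- s_nodes[, sgi + 1]
    sel <- s_samp >= lo & (if (sgi == 9) s_samp <= hi + 1e-9 else s_samp < hi)
    w <- (s_samp - lo) / pmax(hi - lo, 1e-12)
    for (a in 1:3) {
      val <- nodes[, 11 - sgi, a] + w * (nodes[, 10 - sgi, a] -
                                         nodes[, 11 - sgi, a])
      slab <- pts[, , a]
      slab[sel] <- val[sel]
      pts[, , a] <- slab
    }
  }
  v <- sample_field(field, cbind(as.vector(pts[, , 1]),
                                 as.vector(pts[, , 2]),
                                 as.vector(pts[, , 3])))
  v <- matrix(v, nf, ns)
  dxs <- total / (ns - 1)                     # per-fiber sample spacing, mm
  d2 <- (v[, -c(1, 2), drop = FALSE] - 2 * v[, -c(1, ns), drop = FALSE] +
         v[, -c(ns - 1, ns), drop = FALSE]) / dxs^2
  # aggregate to nodes: the interior sample nearest each node position
  acts <- matrix(NA_real_, nf, 10)
  for (k in 1:10) {
    idx <- pmin(pmax(round(s_nodes[, 11 - k] / dxs), 1), ns - 2)
    acts[, k] <- d2[cbind(seq_len(nf), idx)]
  }
  acts
}

#' Stochastic threshold model for a fiber population
#'
#' Per-fiber firing thresholds drawn from a log-normal distribution with
#' SD/mean ratio 0.3 and mean equal to `calibration` (the activation level
#' mapped to "0 dB"), and relative spreads from a normal distribution with
#' mean 0.0635 and SD 0.04, clipped to [0.03, 0.10].
#'
#' @param n_fibers Number of fibers.
#' @param calibration Mean threshold in activation units (V/mm^2); see
#'   [calibrate_activation()].
#' @param seed Integer seed.
#' @param cv SD/mean ratio of the threshold distribution.
#' @param rs_mean,rs_sd,rs_clip Relative-spread distribution parameters.
#' @return A `threshold_model`: list with `a_thr` and `rs` vectors.
#' @export
threshold_model <- function(n_fibers, calibration = 1, seed = 1, cv = 0.3,
                            rs_mean = 0.0635, rs_sd = 0.04,
                            rs_clip = c(0.03, 0.10)) {
  stopifnot(calibration > 0, n_fibers >= 1)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(calibration) - sdlog^2 / 2
  draws <- withr::with_seed(seed, {
    list(a_thr = stats::rlnorm(n_fibers, meanlog, sdlog),
         rs = pmin(pmax(stats::rnorm(n_fibers, rs_mean, rs_sd), rs_clip[1]),
                   rs_clip[2]))
  })
  structure(c(draws, list(calibration = calibration, cv = cv, seed = seed)),
            class = "threshold_model")
}

#' Calibration constant for activation units
#'
#' Half the maximum node-10 activation over the population at the reference
#' stimulus, so the mean firing threshold sits 6 dB below the activation
#' peak.
#'
#' @param activation Node activation matrix from the reference field
#'   (n_fibers x 10).
#' @return Positive scalar (V/mm^2).
#' @export
calibrate_activation <- function(activation) {
  a10 <- pmax(activation[, 10], 0)
  calib <- max(a10) / 2
  if (!is.finite(calib) || calib <= 0) stop("degenerate activation profile")
  calib
}

#' Firing probability of each fiber
#'
#' P = Phi((A - A_thr) / (A_thr * RS)) with Phi the standard normal CDF,
#' using the node-10 activation only; the activation input is the
#' depolarizing (positive) part of the second difference.
#'
#' @param activation Node activation matrix (n_fibers x 10, V/mm^2) or a
#'   vector of node-10 activations.
#' @param thresholds A [threshold_model()].
#' @return Probability per fiber.
#' @export
firing_probabilities <- function(activation, thresholds) {
  a <- if (is.matrix(activation)) activation[, 10] else activation
  a <- pmax(a, 0)
  stats::pnorm((a - thresholds$a_thr) / (thresholds$a_thr * thresholds$rs))
}

#' Excitation profile of the population for one stimulus
#'
#' A fiber is excited if any node's (positive-part) activation exceeds its
#' threshold (deterministic mode) or by a seeded Bernoulli draw on the
#' node-10 firing probability (stochastic mode). The excitation site is
#' peripheral if the strongest supra-threshold node is dendritic
#' (k = 10..6), central if somatic/axonal (k = 5..1).
#'
#' @param field A `potential_field`.
#' @param fibers A `fiber_population`.
#' @param thresholds A [threshold_model()].
#' @param draw If `TRUE`, stochastic Bernoulli excitation on node-10
#'   probabilities; if `FALSE` (default) deterministic any-node
#'   thresholding.
#' @param seed Seed for the stochastic mode.
#' @param activation Optional precomputed node activation matrix.
#' @return An `excitation_profile` tibble: `fiber`, `arc_mm`, `probability`,
#'   `fired`, `site_class` (`"peripheral"`, `"central"`, `"none"`).
#' @export
excitation_profile <- function(field, fibers, thresholds, draw = FALSE,
                               seed = 1, activation = NULL) {
  act <- activation %||% fiber_node_activation(field, fibers)
  act <- pmax(act, 0)
  p10 <- firing_probabilities(act, thresholds)
  over <- act > thresholds$a_thr   # any-node comparison, common threshold
  if (draw) {
    fired <- withr::with_seed(seed,
      stats::runif(fibers$n_fibers) < p10)
  } else {
    fired <- rowSums(over) > 0
  }
  best <- apply(act, 1, which.max)
  site <- ifelse(!fired, "none", ifelse(best >= 6, "peripheral", "central"))
  structure(tibble::tibble(fiber = seq_len(fibers$n_fibers),
                           arc_mm = fibers$arc_mm,
                           probability = p10, fired = fired,
                           site_class = site),
            class = c("excitation_profile", "tbl_df", "tbl", "data.frame"))
}

#' Summed neuronal activity
#'
#' Expected (deterministic) or Monte-Carlo (stochastic) count of firing
#' fibers, total and binned along the basilar-membrane arc.
#'
#' @param profile An `excitation_profile`.
#' @param repetitions Bernoulli repetitions for the stochastic mode
#'   (`NULL` = deterministic expectation sum(P)).
#' @param seed Seed for the stochastic mode.
#' @param bin_mm Arc bin width (mm) for the per-position counts.
#' @return List with `total` (expected or mean count) and `by_position`
#'   (tibble `arc_mm`, `count`).
#' @export
summed_activity <- function(profile, repetitions = NULL, seed = 1,
                            bin_mm = 1) {
  p <- profile$probability
  if (is.null(repetitions)) {
    total <- sum(p)
    w <- p
  } else {
    stopifnot(repetitions >= 1)
    draws <- withr::with_seed(seed,
      matrix(stats::runif(length(p) * repetitions), length(p)) < p)
    total <- mean(colSums(draws))
    w <- rowMeans(draws)
  }
  bins <- floor(profile$arc_mm / bin_mm) * bin_mm + bin_mm / 2
  by_pos <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(arc_mm = bins, w = w), .data$arc_mm),
    count = sum(.data$w), .groups = "drop")
  list(total = total, by_position = by_pos)
}

#' Peak location and 3 dB bandwidth of the voltage distribution at the nerve
#'
#' Samples |V| at the most peripheral node (k = 10) of every fiber against
#' its basilar-membrane arc position; the peak location is the arc position
#' of the maximum and the 3 dB bandwidth the contiguous arc extent around
#' the peak where |V| >= 10^(-3/20) of the peak (amplitude convention).
#'
#' @param field A `potential_field`.
#' @param fibers A `fiber_population`.
#' @return List with `peak_mm`, `bandwidth_mm`, `flat` (TRUE when the whole
#'   profile stays above the 3 dB line) and the sampled `profile` tibble.
#' @export
spread_statistics <- function(field, fibers) {
  v <- abs(sample_field(field, fibers$nodes[, 10, ]))
  spread_from_profile(fibers$arc_mm, v)
}

#' Peak location and 3 dB bandwidth of a sampled profile
#'
#' The workhorse behind [spread_statistics()], usable on any sampled
#' magnitude profile.
#'
#' @param arc Strictly increasing positions (mm).
#' @param v Non-negative profile values at those positions.
#' @return Same structure as [spread_statistics()].
#' @export
spread_from_profile <- function(arc, v) {
  stopifnot(length(arc) == length(v), all(diff(arc) > 0))
  ipk <- which.max(v)
  thr <- v[ipk] * 10^(-3 / 20)
  above <- v >= thr
  lo <- ipk
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ipk
  while (hi < length(v) && above[hi + 1]) hi <- hi + 1
  flat <- lo == 1 && hi == length(v)
  if (flat) {
    warning("flat profile: 3 dB bandwidth spans the full arc extent")
  }
  list(peak_mm = arc[ipk], bandwidth_mm = arc[hi] - arc[lo], flat = flat,
       profile = tibble::tibble(arc_mm = arc, abs_V = v))
}
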