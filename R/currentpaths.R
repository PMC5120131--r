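# Current-path analysis: where does the injected current leave the cochlear
# duct? The duct boundary surface (all faces between duct-region cells --
# scalae, membranes, carrier, contacts -- and surrounding tissue) is
# partitioned into three labelled exit regions:
#   modiolus      faces into the auditory-nerve canal,
#   basal_end     faces through the basal cap of the duct (the round-window
#                 end, the half-plane where the spiral sweep starts),
#   lateral_wall  every remaining face into bone.

# Angular extent (degrees of insertion angle) of the basal-end exit region.
BASAL_END_DEG <- 25

.duct_levels <- function() {
  match(c("scala_tympani", "scala_vestibuli", "scala_media",
          "basilar_membrane", "reissner_membrane", "silicone", "electrode"),
        LABEL_LEVELS)
}

#' Fractions of injected current leaving through each exit region
#'
#' Integrates the outward normal current density J = -sigma grad V over the
#' duct boundary, using the same face conductances as the solver so the
#' discrete fluxes are exactly conservative.
#'
#' @param field A `potential_field` from [solve_potential()].
#' @return Tibble with columns `region`, `current_A`, `fraction`; fractions
#'   are normalized by the injected current and must sum to 1 within 1%.
#' @export
current_path_fractions <- function(field) {
  vol <- field$vol
  spec <- vol$spec
  sig_cell <- effective_sigma_cells(vol, field$sigma)
  v <- field$v
  v[is.na(v)] <- 0
  d <- dim(vol$labels)
  duct <- array(vol$labels %in% .duct_levels(), dim = d)
  ext <- match("exterior", LABEL_LEVELS)
  nrv <- match("nerve", LABEL_LEVELS)
  sz <- list(vol$dx, vol$dy, vol$dz)
  coords <- list(vol$x, vol$y, vol$z)

  totals <- c(modiolus = 0, basal_end = 0, lateral_wall = 0)
  for (a in 1:3) {
    n <- d[a]
    sl <- function(rng) {
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ix[[a]] <- rng
      ix
    }
    lo <- sl(1:(n - 1)); hi <- sl(2:n)
    duct1 <- duct[lo[[1]], lo[[2]], lo[[3]]]
    duct2 <- duct[hi[[1]], hi[[2]], hi[[3]]]
    lab1 <- vol$labels[lo[[1]], lo[[2]], lo[[3]]]
    lab2 <- vol$labels[hi[[1]], hi[[2]], hi[[3]]]
    boundary <- xor(duct1, duct2) & lab1 != ext & lab2 != ext
    if (!any(boundary)) next
    idxb <- which(boundary, arr.ind = TRUE)
    # orient: cell "a" is the duct cell, "b" the outside cell
    first_is_duct <- duct1[boundary]
    ia <- idxb; ib <- idxb
    ia[, a] <- ia[, a] + ifelse(first_is_duct, 0L, 1L)
    ib[, a] <- ib[, a] + ifelse(first_is_duct, 1L, 0L)
    s1 <- sig_cell[ia]; s2 <- sig_cell[ib]
    h1 <- sz[[a]][ia[, a]] * 1e-3 / 2
    h2 <- sz[[a]][ib[, a]] * 1e-3 / 2
    other <- setdiff(1:3, a)
    area <- sz[[other[1]]][ia[, other[1]]] *
            sz[[other[2]]][ia[, other[2]]] * 1e-6
    G <- area / (h1 / s1 + h2 / s2)
    flux <- G * (v[ia] - v[ib])   # outward from the duct

    out_lab <- vol$labels[ib]
    region <- rep("lateral_wall", length(flux))
    region[out_lab == nrv] <- "modiolus"
    # basal end: the duct boundary over the first degrees of the sweep (the
    # round-window end of the duct); the angular extent is a fixture property
    pa <- cbind(coords[[1]][ia[, 1]], coords[[2]][ia[, 2]], coords[[3]][ia[, 3]])
    ca <- template_cylindrical(spec, pa)
    basal <- out_lab != nrv & (ca$phi < BASAL_END_DEG |
                               ca$phi > 360 - HOOK_DEG - 5) &
      ca$z < 1.3 * duct_height(0)
    region[basal] <- "basal_end"
    for (rg in names(totals)) totals[rg] <- totals[rg] + sum(flux[region == rg])
  }
  I <- field$stimulus$I
  frac <- totals / I
  if (abs(sum(frac) - 1) > 0.01) {
    stop(sprintf("current conservation violated: exit fractions sum to %.4f",
                 sum(frac)))
  }
  tibble::tibble(region = names(totals),
                 current_A = unname(totals),
                 fraction = unname(frac))
}
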