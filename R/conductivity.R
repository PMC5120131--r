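# Tissue conductivities (S/m) and the scala-tympani / bone ratio R.

.default_sigma <- c(
  electrode         = 1000,
  scala_media       = 1.67,
  scala_tympani     = 1.43,
  scala_vestibuli   = 1.43,
  basilar_membrane  = 0.0625,
  reissner_membrane = 0.00098,
  nerve             = 0.3,
  bone              = 0.02,
  silicone          = 0.099
)

#' Tissue conductivity table
#'
#' Default values (S/m): electrodes 1000, scala media 1.67, scala tympani
#' 1.43, scala vestibuli 1.43, basilar membrane 0.0625, Reissner membrane
#' 0.00098, nerve 0.3, bone 0.02, silicone 0.099. The grounded outer shell
#' conducts as bone. The single fitted parameter is the ratio
#' R = sigma_ST / sigma_bone; setting `R` keeps sigma_ST fixed and adjusts
#' sigma_bone.
#'
#' @param ... Named conductivity overrides (S/m), e.g. `bone = 0.05`.
#' @param R Optional conductivity ratio; if given, `bone` is set to
#'   `scala_tympani / R` (after any overrides of `scala_tympani`).
#' @return A `conductivity_table` (named numeric vector, S/m).
#' @export
conductivity_table <- function(..., R = NULL) {
  sig <- .default_sigma
  over <- list(...)
  if (length(over) > 0) {
    stopifnot(!is.null(names(over)), all(names(over) %in% names(sig)))
    sig[names(over)] <- as.numeric(over)
  }
  if (!is.null(R)) {
    stopifnot(R > 0)
    sig["bone"] <- sig["scala_tympani"] / R
  }
  if (any(sig <= 0)) stop("all conductivities must be > 0")
  structure(sig, class = "conductivity_table")
}

#' Conductivity ratio R = sigma_ST / sigma_bone of a table
#' @param sigma A `conductivity_table`.
#' @return The dimensionless ratio.
#' @export
conductivity_ratio <- function(sigma) {
  unname(sigma["scala_tympani"] / sigma["bone"])
}

#' The default 20-point optimization grid for R
#'
#' Linearly spaced over \[9.16, 71.5\]: the endpoints are the ratios of the
#' scala-tympani conductivity 1.43 S/m to the two bone conductivities used in
#' the literature (0.156 and 0.02 S/m).
#'
#' @param n Number of grid points.
#' @return Numeric vector of R values.
#' @export
default_R_grid <- function(n = 20) seq(9.16, 71.5, length.out = n)

# Per-cell conductivity lookup vector aligned with LABEL_LEVELS.
sigma_by_level <- function(sigma) {
  v <- c(exterior = NA_real_, sigma[c("bone", "nerve", "scala_tympani",
                                      "scala_vestibuli", "scala_media",
                                      "basilar_membrane", "reissner_membrane",
                                      "silicone", "electrode")],
         ground = unname(sigma["bone"]))
  names(v) <- LABEL_LEVELS
  v
}

#' @export
print.conductivity_table <- function(x, ...) {
  cat("<conductivity_table> S/m  (R =", format(conductivity_ratio(x)), ")\n")
  print(unclass(x))
  invisible(x)
}
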