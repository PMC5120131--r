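# YAML configuration for the pipeline and the command-line entry point.
#
# Units at the configuration surface follow clinical reporting: lengths mm,
# conductivities S/m, currents uA; potentials are exchanged in mV.

#' Default pipeline configuration
#'
#' @return Nested list with `conductivities` (S/m), `R` (optional ratio
#'   override), `grounding` (`mode`, `radius_mm`, `pad`, `weights`),
#'   `stimulus` (`current_uA`), `grid` (`spacing_mm`, `ratio`), `electrode`
#'   (`model`), and `optimize` (`grid_min`, `grid_max`, `grid_n`).
#' @export
default_config <- function() {
  list(
    conductivities = as.list(unclass(conductivity_table())),
    R = NULL,
    grounding = list(mode = "sphere50", radius_mm = 50, pad = 3,
                     weights = NULL),
    stimulus = list(current_uA = 106.5),
    grid = list(spacing_mm = 0.3, ratio = 1.5),
    electrode = list(model = "CI24RE"),
    optimize = list(grid_min = 9.16, grid_max = 71.5, grid_n = 20)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()]; unknown keys are an error.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad) > 0) {
        stop("unknown config key(s): ", paste0(k, ".", bad, collapse = ", "))
      }
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

# conductivity_table from a config list
config_sigma <- function(cfg) {
  sig <- do.call(conductivity_table, cfg$conductivities)
  if (!is.null(cfg$R)) sig["bone"] <- sig["scala_tympani"] / cfg$R
  sig
}

# short hash of a configuration, stamped into output files
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %%
            .Machine$integer.max)
}

#' Build a labelled, electrode-bearing volume from a config
#'
#' Convenience wrapper chaining template, loft, voxelization and canonical
#' electrode placement for a given cochlea spec.
#'
#' @param spec A `cochlea_spec`.
#' @param cfg Configuration list (see [default_config()]).
#' @param array Optional `electrode_array`; defaults to the canonical
#'   lateral-wall positions for the spec geometry.
#' @return A `labeled_volume` ready for [solve_potential()].
#' @export
build_patient_volume <- function(spec, cfg = default_config(), array = NULL) {
  cmodel <- loft_cochlea(build_template(), spec)
  g <- grounding_config(mode = cfg$grounding$mode,
                        radius = cfg$grounding$radius_mm,
                        pad = cfg$grounding$pad)
  vol <- voxelize(cmodel, spacing = cfg$grid$spacing_mm, grounding = g,
                  ratio = cfg$grid$ratio)
  array <- array %||% canonical_electrode_positions(
    cmodel, electrode_array_spec(cfg$electrode$model))
  add_electrode_array(vol, array)
}
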