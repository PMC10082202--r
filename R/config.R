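# YAML run configuration -> constructor arguments; used by the command-line
# wrappers under inst/cli and available for scripted runs.

#' Read a YAML run configuration
#'
#' Recognised top-level sections: `surface`, `scene`, `optics`, `plan`
#' (axial scan plan), `detector`, `scan` (grid / tile geometry). Each
#' section is passed as arguments to the matching constructor; missing
#' sections fall back to defaults.
#'
#' @param path YAML file.
#' @return list with elements `surface` (`height_field` args), `scene`
#'   (`populate_scene` args), `optics` (`optics_model`), `plan`
#'   (`scan_plan`), `detector` (`detector_params`), `scan` (list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(fn, args) do.call(fn, as.list(args))
  list(
    surface = cfg$surface,
    scene = cfg$scene,
    optics = build(optics_model, cfg$optics),
    plan = build(scan_plan, cfg$plan),
    detector = build(detector_params, cfg$detector),
    scan = cfg$scan
  )
}
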