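# Facility configuration: chemistry constants, plate geometry, validation
# limits. Everything numeric is policy, shipped in a YAML file, never a code
# constant.

#' Load a facility configuration
#'
#' Reads the YAML configuration that holds the chemistry constants
#' (reaction volume, reaction-mix volume, fixed/variable dosing targets),
#' plate geometry and control counts, robot/manual sheet settings,
#' submission validation limits, the sequencing-type catalogue and the
#' facility-stock primer list. `default_config()` returns the
#' configuration shipped with the package.
#'
#' @param path Path to a YAML configuration file.
#' @return A `seqfab_config` list.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$chemistry$total_reaction_volume
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  class(cfg) <- c("seqfab_config", "list")
  cfg
}

#' @rdname load_config
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_config.yaml", package = "seqfab"))
}

validate_config <- function(cfg) {
  ch <- cfg$chemistry
  if (is.null(ch$total_reaction_volume) || ch$total_reaction_volume <= 0)
    stop_seqfab("total_reaction_volume must be > 0", "seqfab_config_error")
  fixed_sum <- ch$fixed_template_volume + ch$fixed_primer_volume + ch$mix_volume
  if (fixed_sum >= ch$total_reaction_volume + 1e-9)
    stop_seqfab("fixed volumes + mix_volume must be < total_reaction_volume",
                "seqfab_config_error")
  n_controls <- controls_per_plate(cfg)
  if (n_controls >= cfg$plate$rows * cfg$plate$cols)
    stop_seqfab("control count must be smaller than the plate",
                "seqfab_config_error")
  lim <- cfg$limits
  for (fld in c("template_concentration", "primer_concentration")) {
    if (lim[[fld]]$min > lim[[fld]]$max)
      stop_seqfab(sprintf("limits$%s: min > max", fld), "seqfab_config_error")
  }
  invisible(cfg)
}

controls_per_plate <- function(config) {
  (config$plate$reaction_controls %||% 0L) +
    (config$plate$instrument_controls %||% 0L)
}

plate_size <- function(config) {
  config$plate$rows * config$plate$cols
}

# Usable sample wells per plate once control wells are reserved.
usable_wells <- function(config) {
  plate_size(config) - controls_per_plate(config)
}

target_template_mass <- function(config, sequencing_type) {
  m <- config$chemistry$target_template_mass[[sequencing_type]]
  if (is.null(m))
    stop_seqfab(sprintf("no target template mass configured for type '%s'",
                        sequencing_type), "seqfab_config_error")
  m
}

is_facility_primer <- function(config, primer_name) {
  primer_name %in% (config$facility_primers %||% character())
}
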