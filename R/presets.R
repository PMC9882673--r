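#' Named generating-parameter presets
#'
#' Returns the per-condition `nuca_params` presets shipped with the package,
#' built from the published per-condition distribution statistics: the
#' mononucleosome at 5 mM Na+ (alpha mixture 39/14 deg at 54%/46%, beta
#' -9 deg, unwrapping -5/-11 bp), the di-/tri-/tetranucleosome low-salt
#' conditions, the tetranucleosome at 50 mM Na+, and the tetranucleosome
#' with linker histone H1. Dispersions not reported per condition default to
#' the mononucleosome values and the preset is flagged
#' `partially_specified`.
#'
#' @param name optional preset name; with no argument, all presets are
#'   returned as a named list.
#' @param noise_sd coordinate noise passed to each preset (Angstrom).
#' @return a `nuca_params`, or a named list of them.
#' @examples
#' preset_table("mono_5mM")$alpha
#' names(preset_table())
#' @export
preset_table <- function(name = NULL, noise_sd = 2) {
  path <- system.file("extdata", "presets.yaml", package = "nucarray")
  raw <- yaml::read_yaml(path)
  mk <- function(nm) {
    p <- raw[[nm]]
    sp <- synthetic_params(
      template = build_template(p$n_ncp),
      alpha = list(weights = as.numeric(p$alpha$weights),
                   means = as.numeric(p$alpha$means),
                   sds = as.numeric(p$alpha$sds)),
      beta = p$beta,
      delta_entry = p$delta_entry,
      delta_exit = p$delta_exit,
      noise_sd = noise_sd,
      name = nm,
      partially_specified = isTRUE(p$partially_specified))
    sp$spacing_A <- p$spacing_A
    sp
  }
  if (is.null(name)) {
    out <- lapply(names(raw), mk)
    names(out) <- names(raw)
    return(out)
  }
  if (!name %in% names(raw))
    stop(sprintf("unknown preset '%s' (known: %s)", name,
                 paste(names(raw), collapse = ", ")))
  mk(name)
}

preset_spacing <- function(name) {
  path <- system.file("extdata", "presets.yaml", package = "nucarray")
  raw <- yaml::read_yaml(path)
  if (!name %in% names(raw)) stop(sprintf("unknown preset '%s'", name))
  raw[[name]]$spacing_A
}
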