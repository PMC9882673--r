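# JSON schema I/O for array models, plus pseudo-atom PDB export.
#
# Schema (all coordinates Angstrom, full precision):
#   {
#     "template":  {n_ncp, entry_arm_bp, exit_arm_bp, linker_bp},
#     "trace":     {"coords": [[x,y,z], ...]},
#     "placements": [{absent, wrap_interval, delta_entry_bp, delta_exit_bp,
#                     frame: {origin, x_axis, y_axis, z_axis}}, ...],
#     "label":      string,
#     "provenance": "synthetic" | "fitted",
#     "ground_truth": optional opaque block (generator parameters/samples)
#   }

schema_stop <- function(field, why) {
  stop(sprintf("array-model schema error in field '%s': %s", field, why),
       call. = FALSE)
}

need_field <- function(obj, field, where = field) {
  if (is.null(obj[[field]])) schema_stop(where, "missing")
  obj[[field]]
}

#' Write an array model to a JSON file
#'
#' @param model a `nuca_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_array_model()]
#' @export
write_array_model <- function(model, path) {
  validate_model(model)
  tpl <- model$template
  pl <- lapply(model$placements, function(p) {
    if (p$absent) return(list(absent = TRUE))
    list(absent = FALSE,
         wrap_interval = p$wrap_interval,
         delta_entry_bp = p$delta_entry_bp,
         delta_exit_bp = p$delta_exit_bp,
         frame = if (is.null(p$frame)) NULL else
           list(origin = p$frame$origin, x_axis = p$frame$x_axis,
                y_axis = p$frame$y_axis, z_axis = p$frame$z_axis))
  })
  obj <- list(
    template = list(n_ncp = tpl$n_ncp, entry_arm_bp = tpl$entry_arm_bp,
                    exit_arm_bp = tpl$exit_arm_bp, linker_bp = tpl$linker_bp),
    trace = list(coords = unname(model$trace)),
    placements = pl,
    label = model$label,
    provenance = model$provenance
  )
  if (!is.null(model$ground_truth)) obj$ground_truth <- model$ground_truth
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read an array model from a JSON file
#'
#' Validates the schema and every model invariant (trace length against the
#' template, spacing sanity bounds, placement ordering); malformed input
#' raises an error naming the offending field.
#'
#' @param path path to a model JSON written by [write_array_model()].
#' @return a `nuca_model`.
#' @export
read_array_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) schema_stop("<root>", conditionMessage(e)))
  if (!is.list(obj) || length(obj) == 0) schema_stop("<root>", "empty document")
  tj <- need_field(obj, "template")
  for (f in c("n_ncp", "entry_arm_bp", "exit_arm_bp", "linker_bp"))
    need_field(tj, f, paste0("template.", f))
  tpl <- build_template(tj$n_ncp, tj$entry_arm_bp, tj$exit_arm_bp, tj$linker_bp)

  trj <- need_field(obj, "trace")
  coords <- need_field(trj, "coords", "trace.coords")
  if (!length(coords)) schema_stop("trace.coords", "empty")
  trace <- do.call(rbind, lapply(coords, function(p) {
    if (length(p) != 3) schema_stop("trace.coords", "point is not length 3")
    as.numeric(p)
  }))
  if (nrow(trace) != tpl$total_bp)
    schema_stop("trace.coords",
                sprintf("length %d != template total_bp %d",
                        nrow(trace), tpl$total_bp))

  plj <- need_field(obj, "placements")
  placements <- lapply(plj, function(p) {
    if (isTRUE(p$absent)) return(ncp_placement(NULL, NULL, NA, NA, absent = TRUE))
    wi <- need_field(p, "wrap_interval", "placements.wrap_interval")
    fr <- NULL
    if (!is.null(p$frame)) {
      fj <- p$frame
      for (f in c("origin", "x_axis", "y_axis", "z_axis"))
        need_field(fj, f, paste0("placements.frame.", f))
      fr <- ncp_frame(as.numeric(fj$origin), as.numeric(fj$x_axis),
                      as.numeric(fj$y_axis), as.numeric(fj$z_axis))
    }
    ncp_placement(fr, as.integer(unlist(wi)),
                  need_field(p, "delta_entry_bp", "placements.delta_entry_bp"),
                  need_field(p, "delta_exit_bp", "placements.delta_exit_bp"))
  })
  array_model(tpl, trace, placements,
              label = obj$label %||% "",
              provenance = need_field(obj, "provenance"),
              ground_truth = obj$ground_truth)
}

#' Export a model as a pseudo-atom PDB file
#'
#' Writes one phosphorus pseudo-atom per base pair (residue number =
#' bp index + 1) and one HETATM record per placed NCP center, parseable by
#' standard PDB readers. Intended as a visualization aid.
#'
#' @param model a `nuca_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_pseudo_pdb <- function(model, path) {
  validate_model(model)
  n_bp <- nrow(model$trace)
  centers <- Filter(Negate(is.null),
                    lapply(model$placements,
                           function(p) if (p$absent || is.null(p$frame)) NULL
                           else p$frame$origin))
  if (n_bp + length(centers) > 99999L)
    stop("model exceeds the 99,999-atom PDB field width")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   nucarray pseudo-atom export: %s", model$label), con)
  fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  serial <- 0L
  for (i in seq_len(n_bp)) {
    serial <- serial + 1L
    writeLines(sprintf(fmt, "ATOM", serial, " P", "", " DN", "A",
                       i %% 10000L, "", model$trace[i, 1], model$trace[i, 2],
                       model$trace[i, 3], 1, 0, "P"), con)
  }
  for (k in seq_along(centers)) {
    serial <- serial + 1L
    writeLines(sprintf(fmt, "HETATM", serial, "NCP", "", "NCP", "B",
                       k, "", centers[[k]][1], centers[[k]][2],
                       centers[[k]][3], 1, 0, "C"), con)
  }
  writeLines("END", con)
  invisible(path)
}
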