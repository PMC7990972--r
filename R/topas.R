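# Plain-text parameter export in TOPAS key syntax (s:/d:/i:/u: prefixes),
# for cross-validating the generated geometry in external Monte-Carlo codes.
# Numeric values are written with full double precision so that radii
# round-trip exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Export a geometry as a TOPAS-style parameter file
#'
#' Emits the cell, membrane, nucleus, mitochondria and nanoparticle
#' dimensions and counts as `s:`/`d:`/`i:`/`u:` key lines. The file is an
#' export format only; the run configuration uses a flat key/value schema
#' (see [read_run_config()]).
#'
#' @param geom A `cell_geometry`.
#' @param spec Optional [placement_spec()] whose targeting parameters are
#'   recorded alongside the geometry.
#' @param path Optional file path; when given the lines are written there.
#' @return Character vector of parameter lines, invisibly when `path` is
#'   given.
#' @export
export_topas_parameters <- function(geom, spec = NULL, path = NULL) {
  sp <- geom$spheres
  nuc <- sp[sp$role == "nucleus", ]
  mito <- sp[sp$role == "mitochondrion", ]
  np <- sp[sp$role == "nanoparticle", ]
  lines <- c(
    "s:Ge/MyCell/Type = \"SphericalCell\"",
    sprintf("d:Ge/MyCell/CellRadius = %s nm", fmt_num(geom$cell_radius)),
    sprintf("d:Ge/MyCell/MembraneThickness = %s nm",
            fmt_num(geom$membrane_thickness))
  )
  if (nrow(nuc) > 0) {
    lines <- c(lines, sprintf("d:Ge/MyCell/Nucleus/NucleusRadius = %s nm",
                              fmt_num(nuc$radius[1])))
  }
  if (nrow(mito) > 0) {
    lines <- c(
      lines,
      sprintf("i:Ge/MyCell/Mitochondria/NumberOfMitochondria = %d",
              nrow(mito)),
      sprintf("d:Ge/MyCell/Mitochondria/Radius = %s nm",
              fmt_num(mito$radius[1]))
    )
  }
  if (nrow(np) > 0) {
    lines <- c(
      lines,
      sprintf("i:Ge/MyCell/Nanoparticle/NumberOfNanoparticles = %d",
              nrow(np)),
      sprintf("d:Ge/MyCell/Nanoparticle/Radius = %s nm",
              fmt_num(np$radius[1]))
    )
  }
  if (!is.null(spec)) {
    lines <- c(
      lines,
      sprintf("u:Ge/MyCell/Nanoparticle/FractionAttached = %s",
              fmt_num(spec$fraction_targeted)),
      sprintf("s:Ge/MyCell/Nanoparticle/Target = \"%s\"", spec$target)
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a TOPAS-style parameter file
#'
#' Reads the documented subset written by [export_topas_parameters()].
#'
#' @param x Character vector of lines, or a file path.
#' @return Named list of parameter values (numerics for `d:`/`u:`, integers
#'   for `i:`, strings for `s:`), keyed by the part of the name after the
#'   last slash-group (e.g. `"Nucleus/NucleusRadius"`).
#' @export
parse_topas_parameters <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[grepl("^[sdiu]:", lines)]
  out <- list()
  for (ln in lines) {
    type <- substr(ln, 1, 1)
    rest <- sub("^[sdiu]:", "", ln)
    key <- trimws(sub("=.*$", "", rest))
    key <- sub("^Ge/MyCell/", "", key)
    val <- trimws(sub("^[^=]*=", "", rest))
    out[[key]] <- switch(type,
      s = gsub("\"", "", val),
      d = as.numeric(sub("\\s*nm$", "", val)),
      u = as.numeric(val),
      i = as.integer(val))
  }
  out
}
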