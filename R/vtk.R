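#' Export a mesh (and solution) to legacy VTK
#'
#' Writes the annulus mesh as an ASCII legacy-VTK `UNSTRUCTURED_GRID` of
#' hexahedra, optionally attaching the point data of a solved stress field
#' (`von_mises_MPa` scalars and `displacement_mm` vectors) for inspection
#' in ParaView.
#'
#' @param mesh an [annulus_mesh()].
#' @param path output file path (conventionally `.vtk`).
#' @param field optional `"stress_field"` from [solve_stress()].
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, field = NULL) {
  stopifnot(inherits(mesh, "annulus_mesh"))
  n <- nrow(mesh$coords); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tavrisk annulus mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$coords, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  if (!is.null(field)) {
    stopifnot(inherits(field, "stress_field"))
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "SCALARS von_mises_MPa double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", field$von_mises), con)
    writeLines("VECTORS displacement_mm double", con)
    utils::write.table(format(field$displacement, digits = 9, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Export (remodelled) deposits as VTK points
#'
#' Deposit centres become a VTK `POLYDATA` point cloud with thickness and
#' volume scalars, for overlaying on the annulus mesh.
#'
#' @param deposits a deposits data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_deposits <- function(deposits, path) {
  xyz <- cyl_to_cart(deposits$r, deposits$phi, deposits$z)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tavrisk calcium deposits", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(xyz))), con)
  utils::write.table(format(xyz, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", nrow(xyz)),
               "SCALARS thickness_mm double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", deposits$thickness), con)
  writeLines(c("SCALARS volume_mm3 double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", deposits$volume), con)
  invisible(path)
}
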