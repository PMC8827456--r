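# Plain-text exports: legacy-ASCII VTK structured points for field
# inspection in ParaView, and CSV for metrics and platelet snapshots.

#' Write lattice fields to a legacy-ASCII VTK file
#'
#' Writes one or more scalar voxel fields (3D arrays on the domain lattice)
#' as a STRUCTURED_POINTS dataset with the voxel spacing in um.
#'
#' @param file output path (.vtk)
#' @param domain a `lattice_domain`
#' @param fields named list of 3D numeric/logical arrays on the lattice
#' @return the file path, invisibly
#' @export
write_vtk_fields <- function(file, domain, fields) {
  stopifnot(length(fields) > 0, !is.null(names(fields)))
  d <- domain$shape; h <- domain$h_lkmc
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "thrombosim lattice fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", h / 2, h / 2, h / 2),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    stopifnot(all(dim(v) == d))
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK expects x fastest, matching R array order
    writeLines(paste(formatC(as.numeric(v), format = "g", digits = 6),
                     collapse = "\n"), con)
  }
  invisible(file)
}

#' Write run metrics to CSV
#'
#' @param result a `thrombosim_result`
#' @param file output path
#' @return the file path, invisibly
#' @export
write_metrics_csv <- function(result, file) {
  write.csv(result$metrics, file, row.names = FALSE)
  invisible(file)
}

#' Write the final platelet snapshot (positions, mobility, activation) to CSV
#'
#' @param result a `thrombosim_result`
#' @param file output path
#' @return the file path, invisibly
#' @export
write_platelets_csv <- function(result, file) {
  write.csv(result$snapshot_final, file, row.names = FALSE)
  invisible(file)
}
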