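# Export helpers: VTU (XML unstructured grid, ASCII), Gmsh MSH 2.2,
# trajectory / ensemble CSV, and cut-line sampling.

write_vtu_mesh <- function(mesh, point_data, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                   mesh$tri[, 3] - 1L), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * 3L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(5L, m)), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <PointData>')
  for (nm in names(point_data)) {
    pd <- point_data[[nm]]
    if (is.null(dim(pd))) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(paste(pd), con)
    } else {
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
      writeLines(paste(pd[, 1], pd[, 2], 0), con)
    }
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Export the flow field as VTU
#'
#' Vertex velocity vectors (um/s) and pressure (Pa) on the triangulation.
#'
#' @param flow A [solve_stokes()] result.
#' @param path Output `.vtu` path.
#' @return `path`, invisibly.
#' @export
write_vtu_flow <- function(flow, path) {
  nv <- nrow(flow$mesh$nodes)
  write_vtu_mesh(flow$mesh,
                 list(velocity_um_s = cbind(flow$ux[seq_len(nv)],
                                            flow$uy[seq_len(nv)]),
                      pressure_Pa = flow$p),
                 path)
}

#' Export the potential solution as VTU
#'
#' Potential (V), recovered field magnitude |E| (V/um) and the DEP drive
#' grad|E|^2 (V^2/um^3).
#'
#' @param sol A [solve_potential()] result.
#' @param path Output `.vtu` path.
#' @return `path`, invisibly.
#' @export
write_vtu_potential <- function(sol, path) {
  nv <- nrow(sol$mesh$nodes)
  write_vtu_mesh(sol$mesh,
                 list(V = sol$V[seq_len(nv)],
                      E_mag_V_um = sqrt(pmax(sol$e2, 0)),
                      dep_drive_V2_um3 = cbind(sol$gx, sol$gy)),
                 path)
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#'
#' @param mesh A [generate_mesh()] result.
#' @param path Output `.msh` path.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tags <- sort(unique(mesh$boundary$tag))
  tag_id <- stats::setNames(seq_along(tags), tags)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", paste(length(tags) + 1)), con)
  writeLines(sprintf('1 %d "%s"', tag_id, tags), con)
  writeLines(sprintf('2 %d "%s"', length(tags) + 1L, "fluid"), con)
  writeLines("$EndPhysicalNames", con)
  writeLines(c("$Nodes", paste(nrow(mesh$nodes))), con)
  writeLines(paste(seq_len(nrow(mesh$nodes)), mesh$nodes[, 1],
                   mesh$nodes[, 2], 0), con)
  writeLines(c("$EndNodes", "$Elements",
               paste(nrow(mesh$boundary) + nrow(mesh$tri))), con)
  nb <- nrow(mesh$boundary)
  writeLines(paste(seq_len(nb), 1, 2, tag_id[mesh$boundary$tag],
                   tag_id[mesh$boundary$tag],
                   mesh$boundary$n1, mesh$boundary$n2), con)
  fid <- length(tags) + 1L
  writeLines(paste(nb + seq_len(nrow(mesh$tri)), 2, 2, fid, fid,
                   mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Export trajectories as CSV
#'
#' Long format: one row per recorded time point with `id`, `species`,
#' `t_s`, `x_um`, `y_um`, `F_N` (DEP force magnitude).
#'
#' @param trajectories An [advance_particles()] result.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    data.frame(id = tr$id, species = tr$species, tr$path,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export / import a particle ensemble as CSV
#'
#' @param ensemble A [generate_ensemble()] result.
#' @param path CSV path.
#' @return `path` (write) / the ensemble (read).
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "x", "y", "t_release_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ensemble CSV missing columns: ",
                         paste(miss, collapse = ", "))
  class(df) <- c("particle_ensemble", "data.frame")
  df
}

#' Sample a solved field along a cut line
#'
#' @param field A [solve_stokes()] or [solve_potential()] result.
#' @param p1,p2 Segment endpoints, um.
#' @param n Number of sample points.
#' @return data.frame with `s_um` (arc length) plus the sampled columns;
#'   write with [utils::write.csv()] for CSV export.
#' @export
sample_cut_line <- function(field, p1, p2, n = 101) {
  t <- seq(0, 1, length.out = n)
  pts <- cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]))
  s <- t * sqrt(sum((p2 - p1)^2))
  vals <- if (inherits(field, "flow_field")) sample_flow(field, pts)
          else sample_potential(field, pts)
  cbind(data.frame(s_um = s, x_um = pts[, 1], y_um = pts[, 2]), vals)
}
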