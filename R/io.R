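#' Write a mesh (and optional solution fields) as legacy VTK
#'
#' ASCII legacy VTK unstructured grid with quadratic tetrahedra (cell type
#' 24). Nodal displacement and reaction fields are appended as POINT_DATA
#' vectors when a solution is given; element regions as CELL_DATA. Node
#' sets are persisted as an integer-set sidecar file (`<file>.sets`, one
#' line per set: name followed by 1-based node indices).
#'
#' @param mesh an `fe_mesh`.
#' @param file output path (conventionally `.vtk`).
#' @param solution optional `fe_solution`.
#' @return The file path, invisibly.
#' @export
write_vtk <- function(mesh, file, solution = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "osteoload construct mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 12, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, m * 11), con)
  utils::write.table(cbind(10L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(24L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$region)), con)
  if (!is.null(solution)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines("VECTORS displacement double", con)
    utils::write.table(format(solution$U, digits = 12, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines("VECTORS reaction double", con)
    utils::write.table(format(solution$reactions, digits = 12, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  if (length(mesh$node_sets)) {
    sets <- vapply(names(mesh$node_sets), function(nm) {
      paste(nm, paste(mesh$node_sets[[nm]], collapse = " "))
    }, "")
    writeLines(sets, paste0(file, ".sets"))
  }
  invisible(file)
}

#' Read a legacy VTK unstructured grid written by [write_vtk()]
#'
#' Minimal reader for the subset this package writes (ASCII, tet10 cells);
#' restores the node-set sidecar when present.
#'
#' @param file path to the `.vtk` file.
#' @return An `fe_mesh` (without geometry/params provenance).
#' @export
read_vtk <- function(file) {
  lines <- readLines(file)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  coords <- scan(text = lines[(ip + 1):length(lines)], n = 3 * n, quiet = TRUE)
  nodes <- matrix(coords, n, 3, byrow = TRUE)
  # count lines consumed by points
  off <- ip
  got <- 0L
  while (got < 3 * n) {
    off <- off + 1L
    got <- got + length(scan(text = lines[off], quiet = TRUE))
  }
  ic <- grep("^CELLS", lines)
  ic <- ic[ic > ip][1]
  m <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cells <- scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE)
  cells <- matrix(cells, m, 11, byrow = TRUE)
  if (any(cells[, 1] != 10)) stop("only tet10 cells are supported")
  elems <- cells[, -1, drop = FALSE] + 1L
  region <- NULL
  ir <- grep("^SCALARS region", lines)
  if (length(ir)) {
    lv <- c("cortical", "trabecular", "plate", "screw")
    region <- factor(lv[as.integer(lines[(ir[1] + 2):(ir[1] + 1 + m)])], levels = lv)
  }
  node_sets <- list()
  side <- paste0(file, ".sets")
  if (file.exists(side)) {
    for (ln in readLines(side)) {
      tok <- strsplit(trimws(ln), " +")[[1]]
      node_sets[[tok[1]]] <- as.integer(tok[-1])
    }
  }
  structure(list(nodes = nodes, elems = elems,
                 region = if (is.null(region))
                   factor(rep("plate", m),
                          levels = c("cortical", "trabecular", "plate", "screw"))
                 else region,
                 part = rep(NA_character_, n),
                 node_sets = node_sets, geometry = NULL, params = NULL),
            class = "fe_mesh")
}

#' Append per-step section loads to a trial CSV
#'
#' Writes one row per loading step with trial identifiers, travel,
#' normalized distance and the six section loads.
#'
#' @param curve data.frame from [moment_curve()].
#' @param ids named list or one-row data.frame with `hand`, `digit`, `test`,
#'   `trial`.
#' @param file path; rows are appended when the file exists.
#' @export
write_loads_csv <- function(curve, ids, file) {
  df <- cbind(as.data.frame(ids)[rep(1, nrow(curve)), , drop = FALSE], curve,
              row.names = NULL)
  utils::write.table(df, file, sep = ",", row.names = FALSE,
                     col.names = !file.exists(file), append = file.exists(file))
  invisible(file)
}
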