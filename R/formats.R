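# Documented plain-text interchange formats: mesh, nodal field, tracking
# grid, and validated section-area CSV. Chosen over binary containers for
# diffability; every file self-describes its units.

.fmt_version <- "vascelast-v1"

#' Write / read a mesh in the package text format
#'
#' Header (format tag, units, counts) followed by whitespace-separated node,
#' element, region and boundary blocks. Round-trips losslessly.
#'
#' @param mesh a `ve_mesh`.
#' @param path file path.
#' @return `read_mesh()` returns a `ve_mesh`; `write_mesh()` the path,
#'   invisibly.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("# mesh", .fmt_version), "# units mm",
    paste("nodes", nrow(mesh$nodes)),
    paste("elements", nrow(mesh$elements)),
    paste("n_vertex", mesh$n_vertex),
    paste("radii", format(mesh$inner_radius, digits = 17),
          format(mesh$outer_radius, digits = 17)),
    paste("n_theta", mesh$n_theta),
    paste("edge_length", format(mesh$edge_length, digits = 17)),
    paste("r_grid", paste(format(mesh$r_grid, digits = 17), collapse = " "))
  ), con)
  utils::write.table(format(mesh$nodes, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(mesh$elements, mesh$region), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(mesh$inner_edges, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(mesh$outer_edges, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (!grepl(paste("^# mesh", .fmt_version), lines[1])) {
    stop("not a ", .fmt_version, " mesh file: ", path, call. = FALSE)
  }
  hdr <- function(key) {
    ln <- grep(paste0("^", key, " "), lines[1:9], value = TRUE)
    if (!length(ln)) stop("mesh header lacks '", key, "' (line <= 9)", call. = FALSE)
    strsplit(ln, " +")[[1]][-1]
  }
  n_nodes <- as.integer(hdr("nodes"))
  n_el <- as.integer(hdr("elements"))
  body <- lines[-(1:9)]
  nodes <- do.call(rbind, lapply(body[seq_len(n_nodes)], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  colnames(nodes) <- c("x", "y")
  el_lines <- body[n_nodes + seq_len(n_el)]
  el_tok <- strsplit(trimws(el_lines), " +")
  elements <- t(vapply(el_tok, function(t) as.integer(t[1:6]), integer(6)))
  region <- vapply(el_tok, function(t) t[7], character(1))
  n_theta <- as.integer(hdr("n_theta"))
  edges <- function(off) {
    do.call(rbind, lapply(body[off + seq_len(n_theta)], function(l)
      as.integer(strsplit(trimws(l), " +")[[1]])))
  }
  radii <- as.numeric(hdr("radii"))
  structure(list(
    nodes = nodes, elements = elements, region = region,
    inner_edges = edges(n_nodes + n_el),
    outer_edges = edges(n_nodes + n_el + n_theta),
    n_vertex = as.integer(hdr("n_vertex")),
    inner_radius = radii[1], outer_radius = radii[2],
    r_grid = as.numeric(hdr("r_grid")),
    n_theta = n_theta,
    edge_length = as.numeric(hdr("edge_length"))
  ), class = "ve_mesh")
}

#' Write / read a nodal displacement field
#'
#' @param field a `ve_field`.
#' @param path file path.
#' @param mesh optional mesh for cross-checking the node count on read.
#' @return `read_field()` returns a `ve_field`; `write_field()` the path,
#'   invisibly.
#' @export
write_field <- function(field, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("# field", .fmt_version), "# units mm",
               paste("nodes", nrow(field)),
               paste("provenance", attr(field, "provenance"))), con)
  utils::write.table(format(unclass(field)[, 1:2], digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path, mesh = NULL) {
  lines <- readLines(path)
  if (!grepl(paste("^# field", .fmt_version), lines[1])) {
    stop("not a ", .fmt_version, " field file: ", path, call. = FALSE)
  }
  n <- as.integer(strsplit(lines[3], " +")[[1]][2])
  prov <- strsplit(lines[4], " +")[[1]][2]
  vals <- do.call(rbind, lapply(lines[4 + seq_len(n)], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  if (!is.null(mesh) && n != nrow(mesh$nodes)) {
    stop("field has ", n, " nodes but mesh has ", nrow(mesh$nodes), call. = FALSE)
  }
  displacement_field(vals, prov)
}

#' Read and validate a section-area CSV
#'
#' Expects columns `station_um`, `lumen_um2`, `intima_um2`, `media_um2`,
#' `adventitia_um2` (missing intima allowed). Schema violations are reported
#' with row and column.
#'
#' @param path CSV path.
#' @return validated tibble.
#' @export
read_section_areas <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("station_um", "lumen_um2", "intima_um2", "media_um2",
            "adventitia_um2")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  for (cc in setdiff(need, "station_um")) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad)) {
      stop("negative area at row ", bad[1], ", column '", cc, "'", call. = FALSE)
    }
  }
  .check_section_areas(df)
}

#' Write a tracking grid as CSV
#' @param grid a `ve_grid`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_grid <- function(grid, path) {
  readr::write_csv(as_tibble(grid), path)
  invisible(path)
}
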