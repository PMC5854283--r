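#' Read / write labeled meshes as Gmsh MSH v2 ASCII
#'
#' The mesh exchange format: nodes, tetrahedral volume cells, and boundary
#' triangles carrying physical-group tags whose names must be `glottis`,
#' `wall` and `lips`. Only the v2.2 ASCII dialect is handled, which is what
#' mesh generators emit for simple acoustic cavities and suffices to ingest
#' externally produced volume meshes.
#'
#' @param mesh A `labeled_mesh`.
#' @param path File path.
#' @return `write_msh()`: `path` invisibly. `read_msh()`: a `labeled_mesh`.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("$MeshFormat"); wl("2.2 0 8"); wl("$EndMeshFormat")
  wl("$PhysicalNames"); wl("4")
  wl('2 1 "glottis"'); wl('2 2 "wall"'); wl('2 3 "lips"'); wl('3 4 "volume"')
  wl("$EndPhysicalNames")
  wl("$Nodes"); wl(nrow(mesh$nodes))
  writeLines(paste(seq_len(nrow(mesh$nodes)), mesh$nodes[, 1],
                   mesh$nodes[, 2], mesh$nodes[, 3]), con)
  wl("$EndNodes")
  lab_id <- c(glottis = 1L, wall = 2L, lips = 3L)
  nf <- nrow(mesh$facets); nt <- nrow(mesh$tets)
  wl("$Elements"); wl(nf + nt)
  writeLines(paste(seq_len(nf), 2, 2, lab_id[mesh$facet_label],
                   lab_id[mesh$facet_label],
                   mesh$facets[, 1], mesh$facets[, 2], mesh$facets[, 3]), con)
  writeLines(paste(nf + seq_len(nt), 4, 2, 4L, 4L,
                   mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                   mesh$tets[, 4]), con)
  wl("$EndElements")
  invisible(path)
}

#' @rdname write_msh
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  section <- function(name) {
    i0 <- which(lines == paste0("$", name))
    i1 <- which(lines == paste0("$End", name))
    if (length(i0) != 1L || length(i1) != 1L) {
      stop(sprintf("missing $%s section in '%s'", name, path))
    }
    lines[(i0 + 1):(i1 - 1)]
  }
  fmt <- strsplit(section("MeshFormat")[1], "\\s+")[[1]]
  if (!startsWith(fmt[1], "2")) {
    stop("only MSH v2 ASCII is supported; got version ", fmt[1])
  }

  phys <- section("PhysicalNames")
  phys_names <- character(0)
  for (ln in phys[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) >= 3) {
      phys_names[parts[2]] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
    }
  }

  node_lines <- section("Nodes")
  nn <- as.integer(node_lines[1])
  nd <- utils::read.table(text = node_lines[-1], col.names = c("id", "x", "y", "z"))
  nodes <- matrix(NA_real_, nn, 3)
  nodes[nd$id, ] <- as.matrix(nd[, c("x", "y", "z")])

  el_lines <- section("Elements")[-1]
  parts <- strsplit(el_lines, "\\s+")
  tets <- list(); tris <- list(); tri_phys <- integer(0)
  for (p in parts) {
    p <- as.integer(p)
    type <- p[2]; ntags <- p[3]
    conn <- p[(4 + ntags):length(p)]
    if (type == 4) {
      tets[[length(tets) + 1L]] <- conn
    } else if (type == 2) {
      tris[[length(tris) + 1L]] <- conn
      tri_phys <- c(tri_phys, p[4])
    }
  }
  if (length(tets) == 0) stop("no tetrahedra in mesh file")
  if (length(tris) == 0) stop("no labeled boundary triangles in mesh file")
  lab <- phys_names[as.character(tri_phys)]
  if (any(is.na(lab)) || !all(lab %in% c("glottis", "wall", "lips"))) {
    stop("boundary triangles must carry physical groups named glottis/wall/lips")
  }
  new_labeled_mesh(nodes, do.call(rbind, tets), do.call(rbind, tris),
                   unname(lab))
}
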