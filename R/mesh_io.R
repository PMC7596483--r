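## Mesh I/O: Gmsh MSH 4.1 (ASCII), VTU (ASCII XML) and XDMF 3.0 with inline
## data items. All three formats carry the tetrahedra with their region tags
## and the boundary triangles with their facet tags; coordinates are written
## with 17 significant digits so a round trip preserves them to 1e-10 relative.

.fmt_num <- function(x) formatC(x, format = "g", digits = 17)

.default_tag_names <- function(facet_tags, region_tags) {
  ft <- sort(unique(facet_tags))
  nm <- c(fixed_interface = 1L)
  extra <- setdiff(ft, 1L)
  if (length(extra)) nm[paste0("opening_", seq_along(extra))] <- extra
  c(nm, left_hemisphere = 1L, right_hemisphere = 2L)
}

#' Write a labeled mesh to a standard format
#'
#' Supported formats: Gmsh MSH 4.1 ASCII (`"gmsh_msh"`), VTK unstructured grid
#' XML (`"vtu"`, ASCII) and XDMF 3.0 with inline ASCII data (`"xdmf"`).
#' Tetrahedra carry the integer cell field `region_tag`; boundary triangles
#' carry `facet_tag`.
#'
#' @param mesh A `labeled_mesh`.
#' @param path Output file path.
#' @param format One of `"gmsh_msh"`, `"vtu"`, `"xdmf"`; default guessed from
#'   the file extension (`.msh`, `.vtu`, `.xdmf`/`.xmf`).
#' @return `invisible(path)`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  format <- format %||% .guess_format(path)
  switch(format,
         gmsh_msh = .write_msh(mesh, path),
         vtu = .write_vtu_mesh(mesh, path),
         xdmf = .write_xdmf(mesh, path),
         stop("unknown mesh format: ", format))
  invisible(path)
}

#' Read a labeled mesh from a standard format
#'
#' Accepts only tetrahedral volume cells (plus boundary triangles carrying
#' facet tags); any other volume cell type is rejected. Tag name mapping is
#' not part of the file formats, so names default to `fixed_interface` for
#' facet tag 1 and `opening_k` for the remaining tags unless supplied.
#'
#' @param path Input file path.
#' @param format One of `"gmsh_msh"`, `"vtu"`, `"xdmf"`; default guessed from
#'   the extension.
#' @param tag_names Optional named integer vector overriding the default tag
#'   naming.
#' @param h Characteristic element size to record (mm); estimated from the
#'   mean cell edge length when `NULL`.
#' @return A `labeled_mesh`.
#' @export
read_mesh <- function(path, format = NULL, tag_names = NULL, h = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% .guess_format(path)
  m <- switch(format,
              gmsh_msh = .read_msh(path),
              vtu = .read_vtu_mesh(path),
              xdmf = .read_xdmf(path),
              stop("unknown mesh format: ", format))
  if (is.null(m$facet_tags) || !length(m$facet_tags))
    stop("mesh file carries no facet tags; required tags: fixed_interface, opening_k")
  if (is.null(m$region_tags) || !length(m$region_tags))
    stop("mesh file carries no region tags; required tags: left_hemisphere, right_hemisphere")
  if (is.null(h)) {
    e <- m$nodes[m$cells[, 2], ] - m$nodes[m$cells[, 1], ]
    h <- mean(sqrt(rowSums(e^2)))
  }
  tn <- tag_names %||% .default_tag_names(m$facet_tags, m$region_tags)
  .new_labeled_mesh(m$nodes, m$cells, m$facets, m$facet_tags, m$region_tags,
                    tn, h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, msh = "gmsh_msh", vtu = "vtu", xdmf = "xdmf", xmf = "xdmf",
         stop("cannot guess mesh format from extension '.", ext, "'"))
}

## ---------------------------------------------------------------- Gmsh MSH 4.1

.write_msh <- function(mesh, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$cells); nf <- nrow(mesh$facets)
  ftags <- sort(unique(mesh$facet_tags))
  rtags <- sort(unique(mesh$region_tags))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  # minimal entity blocks: one surface per facet tag, one volume per region tag
  bb <- apply(mesh$nodes, 2, range)
  bbs <- paste(.fmt_num(c(bb[1, ], bb[2, ])), collapse = " ")
  w("$Entities", paste(0, 0, length(ftags), length(rtags)))
  for (t in ftags) w(paste(t, bbs, 0, 0))
  for (t in rtags) w(paste(t, bbs, 0))
  w("$EndEntities")
  w("$Nodes")
  w(paste(1, n, 1, n))
  w(paste(3, rtags[1], 0, n))
  w(format(seq_len(n)))
  w(paste(.fmt_num(mesh$nodes[, 1]), .fmt_num(mesh$nodes[, 2]),
          .fmt_num(mesh$nodes[, 3])))
  w("$EndNodes")
  w("$Elements")
  nblocks <- length(ftags) + length(rtags)
  w(paste(nblocks, nf + m, 1, nf + m))
  # element ids encode the original facet/cell row so readers can restore order
  for (t in ftags) {
    sel <- which(mesh$facet_tags == t)
    w(paste(2, t, 2, length(sel)))
    w(paste(sel, mesh$facets[sel, 1], mesh$facets[sel, 2], mesh$facets[sel, 3]))
  }
  for (t in rtags) {
    sel <- which(mesh$region_tags == t)
    w(paste(3, t, 4, length(sel)))
    w(paste(nf + sel, mesh$cells[sel, 1], mesh$cells[sel, 2], mesh$cells[sel, 3],
            mesh$cells[sel, 4]))
  }
  w("$EndElements")
}

.read_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("MSH file lacks $", name, " section")
    lines[(i0 + 1):(i1 - 1)]
  }
  fmt <- strsplit(sect("MeshFormat")[1], "\\s+")[[1]]
  if (fmt[2] != "0") stop("only ASCII MSH files are supported")
  nl <- sect("Nodes")
  hdr <- as.numeric(strsplit(nl[1], "\\s+")[[1]])
  n_nodes <- hdr[2]
  i <- 2L
  ids <- integer(0); coords <- list()
  while (length(ids) < n_nodes) {
    bh <- as.numeric(strsplit(nl[i], "\\s+")[[1]])
    nb <- bh[4]
    bid <- as.integer(nl[i + seq_len(nb)])
    bco <- do.call(rbind, lapply(nl[i + nb + seq_len(nb)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])[1:3]))
    ids <- c(ids, bid)
    coords[[length(coords) + 1L]] <- bco
    i <- i + 2L * nb + 1L
  }
  nodes <- do.call(rbind, coords)
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  el <- sect("Elements")
  hdr <- as.numeric(strsplit(el[1], "\\s+")[[1]])
  i <- 2L
  facets <- list(); ftags <- list(); fids <- list()
  cells <- list(); rtags <- list(); cids <- list()
  for (b in seq_len(hdr[1])) {
    bh <- as.numeric(strsplit(el[i], "\\s+")[[1]])
    dim <- bh[1]; etag <- bh[2]; etype <- bh[3]; nb <- bh[4]
    rows <- do.call(rbind, lapply(el[i + seq_len(nb)], function(s)
      as.integer(strsplit(trimws(s), "\\s+")[[1]])))
    if (etype == 2) {
      facets[[length(facets) + 1L]] <- rows[, 2:4, drop = FALSE]
      ftags[[length(ftags) + 1L]] <- rep(as.integer(etag), nb)
      fids[[length(fids) + 1L]] <- rows[, 1]
    } else if (etype == 4) {
      cells[[length(cells) + 1L]] <- rows[, 2:5, drop = FALSE]
      rtags[[length(rtags) + 1L]] <- rep(as.integer(etag), nb)
      cids[[length(cids) + 1L]] <- rows[, 1]
    } else if (dim == 3) {
      stop("non-tetrahedral volume cells (gmsh element type ", etype,
           ") are not supported")
    }
    i <- i + nb + 1L
  }
  if (!length(cells)) stop("MSH file contains no tetrahedra")
  co <- order(unlist(cids))
  cells <- do.call(rbind, cells)[co, , drop = FALSE]
  rtags <- unlist(rtags)[co]
  cells[] <- remap[cells]
  if (length(facets)) {
    fo <- order(unlist(fids))
    facets <- do.call(rbind, facets)[fo, , drop = FALSE]
    ftags <- unlist(ftags)[fo]
    facets[] <- remap[facets]
  } else {
    facets <- matrix(0L, 0, 3); ftags <- integer(0)
  }
  list(nodes = nodes, cells = cells, facets = facets,
       facet_tags = ftags, region_tags = rtags)
}

## ------------------------------------------------------------------------ VTU

## generic ASCII VTU writer; cells = list of (connectivity matrix, vtk type)
.write_vtu <- function(nodes, cell_blocks, path, cell_data = list(),
                       point_data = list()) {
  conn <- unlist(lapply(cell_blocks, function(b) t(b$cells - 1L)))
  sizes <- unlist(lapply(cell_blocks, function(b)
    rep(ncol(b$cells), nrow(b$cells))))
  types <- unlist(lapply(cell_blocks, function(b) rep(b$type, nrow(b$cells))))
  offs <- cumsum(sizes)
  da <- function(name, x, type = "Float64", ncomp = NULL) {
    attrs <- sprintf(' Name="%s"', name)
    if (!is.null(ncomp)) attrs <- paste0(attrs,
                                         sprintf(' NumberOfComponents="%d"', ncomp))
    vals <- if (type == "Float64") .fmt_num(x) else format(x, scientific = FALSE)
    c(sprintf('<DataArray type="%s"%s format="ascii">', type, attrs),
      paste(vals, collapse = " "), "</DataArray>")
  }
  out <- c('<?xml version="1.0"?>',
           '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
           "<UnstructuredGrid>",
           sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">',
                   nrow(nodes), length(types)),
           "<Points>",
           da("Points", as.vector(t(nodes)), "Float64", 3L),
           "</Points>",
           "<Cells>",
           da("connectivity", conn, "Int64"),
           da("offsets", offs, "Int64"),
           da("types", types, "UInt8"),
           "</Cells>")
  if (length(cell_data)) {
    out <- c(out, "<CellData>")
    for (nm in names(cell_data)) {
      x <- cell_data[[nm]]
      if (is.integer(x)) out <- c(out, da(nm, x, "Int64"))
      else if (is.matrix(x)) out <- c(out, da(nm, as.vector(t(x)), "Float64",
                                              ncol(x)))
      else out <- c(out, da(nm, x, "Float64"))
    }
    out <- c(out, "</CellData>")
  }
  if (length(point_data)) {
    out <- c(out, "<PointData>")
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      if (is.matrix(x)) out <- c(out, da(nm, as.vector(t(x)), "Float64", ncol(x)))
      else out <- c(out, da(nm, x, "Float64"))
    }
    out <- c(out, "</PointData>")
  }
  writeLines(c(out, "</Piece>", "</UnstructuredGrid>", "</VTKFile>"), path)
}

.write_vtu_mesh <- function(mesh, path) {
  blocks <- list(list(cells = mesh$cells, type = 10L),
                 list(cells = mesh$facets, type = 5L))
  cell_data <- list(
    region_tag = c(as.integer(mesh$region_tags),
                   rep(0L, nrow(mesh$facets))),
    facet_tag = c(rep(0L, nrow(mesh$cells)), as.integer(mesh$facet_tags)))
  .write_vtu(mesh$nodes, blocks, path, cell_data = cell_data)
}

.read_vtu_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_da <- function(xpath) {
    node <- xml2::xml_find_first(piece, xpath)
    if (inherits(node, "xml_missing")) return(NULL)
    txt <- xml2::xml_text(node)
    scan(text = txt, quiet = TRUE)
  }
  pts <- get_da("./Points/DataArray")
  conn <- get_da('./Cells/DataArray[@Name="connectivity"]')
  offs <- get_da('./Cells/DataArray[@Name="offsets"]')
  types <- get_da('./Cells/DataArray[@Name="types"]')
  cd <- list()
  for (node in xml2::xml_find_all(piece, "./CellData/DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    cd[[nm]] <- scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pd <- list()
  for (node in xml2::xml_find_all(piece, "./PointData/DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    nc <- xml2::xml_attr(node, "NumberOfComponents")
    x <- scan(text = xml2::xml_text(node), quiet = TRUE)
    if (!is.na(nc) && as.integer(nc) > 1)
      x <- matrix(x, ncol = as.integer(nc), byrow = TRUE)
    pd[[nm]] <- x
  }
  list(nodes = matrix(pts, ncol = 3, byrow = TRUE),
       conn = conn, offsets = offs, types = types,
       cell_data = cd, point_data = pd)
}

.read_vtu_mesh <- function(path) {
  a <- .read_vtu_arrays(path)
  starts <- c(0, a$offsets[-length(a$offsets)])
  bad <- setdiff(unique(a$types), c(5, 10))
  if (length(bad))
    stop("non-tetrahedral volume cells (VTK type ",
         paste(bad, collapse = ", "), ") are not supported")
  take <- function(type, width) {
    sel <- which(a$types == type)
    if (!length(sel)) return(NULL)
    idx <- unlist(lapply(sel, function(i) starts[i] + seq_len(width)))
    matrix(a$conn[idx] + 1L, ncol = width, byrow = TRUE)
  }
  cells <- take(10, 4L)
  facets <- take(5, 3L)
  if (is.null(cells)) stop("VTU file contains no tetrahedra")
  rt <- a$cell_data$region_tag; ft <- a$cell_data$facet_tag
  list(nodes = a$nodes, cells = cells, facets = facets %||% matrix(0L, 0, 3),
       facet_tags = if (!is.null(ft)) as.integer(ft[a$types == 5]) else integer(0),
       region_tags = if (!is.null(rt)) as.integer(rt[a$types == 10]) else integer(0))
}

## ----------------------------------------------------------------------- XDMF

.write_xdmf <- function(mesh, path) {
  n <- nrow(mesh$nodes)
  di <- function(x, dims, type, indent = "      ") {
    c(sprintf('%s<DataItem Dimensions="%s" NumberType="%s" Format="XML">',
              indent, dims, type),
      paste(indent, paste(x, collapse = " ")),
      sprintf("%s</DataItem>", indent))
  }
  geo <- di(.fmt_num(as.vector(t(mesh$nodes))), sprintf("%d 3", n), "Float")
  out <- c('<?xml version="1.0"?>',
           '<Xdmf Version="3.0">', " <Domain>",
           '  <Grid Name="cells" GridType="Uniform">',
           sprintf('   <Topology TopologyType="Tetrahedron" NumberOfElements="%d">',
                   nrow(mesh$cells)),
           di(t(mesh$cells - 1L), sprintf("%d 4", nrow(mesh$cells)), "Int"),
           "   </Topology>",
           '   <Geometry GeometryType="XYZ">', geo, "   </Geometry>",
           '   <Attribute Name="region_tag" AttributeType="Scalar" Center="Cell">',
           di(as.integer(mesh$region_tags), nrow(mesh$cells), "Int"),
           "   </Attribute>",
           "  </Grid>",
           '  <Grid Name="facets" GridType="Uniform">',
           sprintf('   <Topology TopologyType="Triangle" NumberOfElements="%d">',
                   nrow(mesh$facets)),
           di(t(mesh$facets - 1L), sprintf("%d 3", nrow(mesh$facets)), "Int"),
           "   </Topology>",
           '   <Geometry GeometryType="XYZ">', geo, "   </Geometry>",
           '   <Attribute Name="facet_tag" AttributeType="Scalar" Center="Cell">',
           di(as.integer(mesh$facet_tags), nrow(mesh$facets), "Int"),
           "   </Attribute>",
           "  </Grid>",
           " </Domain>", "</Xdmf>")
  writeLines(out, path)
}

.read_xdmf <- function(path) {
  doc <- xml2::read_xml(path)
  grids <- xml2::xml_find_all(doc, ".//Grid")
  nodes <- NULL; cells <- NULL; facets <- NULL
  ftags <- integer(0); rtags <- integer(0)
  for (g in grids) {
    topo <- xml2::xml_find_first(g, "./Topology")
    ttype <- xml2::xml_attr(topo, "TopologyType")
    conn <- scan(text = xml2::xml_text(xml2::xml_find_first(topo, "./DataItem")),
                 quiet = TRUE)
    geo <- scan(text = xml2::xml_text(
      xml2::xml_find_first(g, "./Geometry/DataItem")), quiet = TRUE)
    nodes <- matrix(geo, ncol = 3, byrow = TRUE)
    attr_nodes <- xml2::xml_find_all(g, "./Attribute")
    attrs <- list()
    for (an in attr_nodes)
      attrs[[xml2::xml_attr(an, "Name")]] <-
        scan(text = xml2::xml_text(xml2::xml_find_first(an, "./DataItem")),
             quiet = TRUE)
    if (identical(ttype, "Tetrahedron")) {
      cells <- matrix(as.integer(conn) + 1L, ncol = 4, byrow = TRUE)
      if (!is.null(attrs$region_tag)) rtags <- as.integer(attrs$region_tag)
    } else if (identical(ttype, "Triangle")) {
      facets <- matrix(as.integer(conn) + 1L, ncol = 3, byrow = TRUE)
      if (!is.null(attrs$facet_tag)) ftags <- as.integer(attrs$facet_tag)
    } else {
      stop("non-tetrahedral topology '", ttype, "' is not supported")
    }
  }
  if (is.null(cells)) stop("XDMF file contains no tetrahedra")
  list(nodes = nodes, cells = cells, facets = facets %||% matrix(0L, 0, 3),
       facet_tags = ftags, region_tags = rtags)
}
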