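## Tetrahedral meshing of the idealized head: an icosphere surface is swept
## radially into layered prisms, each split into three tetrahedra with a
## diagonal rule that is consistent across neighbouring prisms, then the unit
## ball is scaled onto the ellipsoid semi-axes.

## icosphere with `s` subdivision levels (vertices on the unit sphere)
.icosphere <- function(s) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(s)) {
    midcache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- midcache[[key]]
      if (!is.null(id)) return(id)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      midcache[[key]] <- id
      id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c_, ca, bc)
      nf[4 * i, ]     <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  # orient faces outward (CCW seen from outside)
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  flip <- rowSums(nrm * cent) < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  list(vertices = v, faces = f)
}

## signed volumes of tetrahedra (nodes: N x 3, cells: M x 4)
tet_signed_volumes <- function(nodes, cells) {
  a <- nodes[cells[, 1], , drop = FALSE]
  b <- nodes[cells[, 2], , drop = FALSE] - a
  c_ <- nodes[cells[, 3], , drop = FALSE] - a
  d <- nodes[cells[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) +
   b[, 2] * (c_[, 3] * d[, 1] - c_[, 1] * d[, 3]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

## unit-ball tet mesh: icosphere subdivision `s`, `L` radial layers
.ball_mesh <- function(s, L) {
  ico <- .icosphere(s)
  nsurf <- nrow(ico$vertices)
  radii <- seq_len(L) / L
  nodes <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(radii, function(r) r * ico$vertices)))
  layer_id <- function(l) 1L + (l - 1L) * nsurf # offset: node = offset + surf id
  f <- ico$faces
  cells <- matrix(0L, 0, 3) # filled below
  # innermost shell: tets from the centre to layer-1 triangles
  inner <- cbind(1L, layer_id(1) + f[, 1], layer_id(1) + f[, 2],
                 layer_id(1) + f[, 3])
  # prism layers, split consistently: sort each surface triangle's vertex ids,
  # then the quad over surface edge (p, q), p < q, always gets diagonal
  # p_upper - q_lower
  prisms <- list()
  if (L > 1) {
    fs <- t(apply(f, 1, sort))
    for (l in seq_len(L - 1)) {
      lo <- layer_id(l); hi <- layer_id(l + 1)
      i1 <- fs[, 1]; i2 <- fs[, 2]; i3 <- fs[, 3]
      prisms[[l]] <- rbind(
        cbind(lo + i1, lo + i2, lo + i3, hi + i1),
        cbind(lo + i2, lo + i3, hi + i1, hi + i2),
        cbind(lo + i3, hi + i1, hi + i2, hi + i3))
    }
  }
  cells <- rbind(inner, do.call(rbind, prisms))
  vol <- tet_signed_volumes(nodes, cells)
  neg <- vol < 0
  cells[neg, c(3, 4)] <- cells[neg, c(4, 3)]
  vol <- abs(vol)
  if (any(vol <= 0)) stop("degenerate tetrahedra produced by the ball mesher")
  surface_faces <- layer_id(L) + f # outer boundary triangles, outward CCW
  list(nodes = nodes, cells = cells, surface_faces = surface_faces)
}

## boundary facets of a tet mesh (faces appearing exactly once), outward oriented
boundary_facets <- function(nodes, cells) {
  faces <- rbind(cells[, c(2, 3, 4)], cells[, c(1, 4, 3)],
                 cells[, c(1, 2, 4)], cells[, c(1, 3, 2)])
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  sel <- match(bkey, key)
  fb <- faces[sel, , drop = FALSE]
  # orient outward: normal should point away from the owning cell's centroid
  owner <- ((sel - 1L) %% nrow(cells)) + 1L
  cc <- (nodes[cells[owner, 1], ] + nodes[cells[owner, 2], ] +
         nodes[cells[owner, 3], ] + nodes[cells[owner, 4], ]) / 4
  fc <- (nodes[fb[, 1], ] + nodes[fb[, 2], ] + nodes[fb[, 3], ]) / 3
  e1 <- nodes[fb[, 2], ] - nodes[fb[, 1], ]
  e2 <- nodes[fb[, 3], ] - nodes[fb[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  flip <- rowSums(nrm * (fc - cc)) < 0
  fb[flip, c(2, 3)] <- fb[flip, c(3, 2)]
  fb
}

## areas of triangular facets
facet_areas <- function(nodes, facets) {
  e1 <- nodes[facets[, 2], , drop = FALSE] - nodes[facets[, 1], , drop = FALSE]
  e2 <- nodes[facets[, 3], , drop = FALSE] - nodes[facets[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cr^2)) / 2
}

.new_labeled_mesh <- function(nodes, cells, facets, facet_tags, region_tags,
                              tag_names, h, geom = NULL) {
  storage.mode(cells) <- "integer"
  storage.mode(facets) <- "integer"
  facet_tags <- as.integer(facet_tags)
  region_tags <- as.integer(region_tags)
  structure(list(nodes = nodes, cells = cells, facets = facets,
                 facet_tags = facet_tags, region_tags = region_tags,
                 tag_names = tag_names, characteristic_h_mm = h, geom = geom),
            class = "labeled_mesh")
}

#' Mesh an idealized head geometry with tetrahedra
#'
#' Builds a layered tetrahedral mesh of the ellipsoidal cavity (icosphere
#' surface swept radially, prisms split into tetrahedra with a conforming
#' diagonal rule). Boundary facets on opening patches are tagged `opening_k`
#' (a bifrontal opening with a midline bar yields two tags, one per lobe);
#' all remaining boundary facets are the rigid skull interface
#' `fixed_interface`. Cells are tagged `left_hemisphere` / `right_hemisphere`
#' by the sign of their centroid's sagittal coordinate.
#'
#' @param geom A [build_idealized_head()] geometry.
#' @param h Target element size in mm; must be positive and smaller than the
#'   smallest opening radius so patches are resolved.
#' @param angular_subdiv,radial_layers Optional overrides of the icosphere
#'   subdivision level and the number of radial layers (normally both derived
#'   from `h`); useful for radially resolved verification meshes.
#' @return A `labeled_mesh` with nodes in mm.
#' @export
mesh_head <- function(geom, h = 8, angular_subdiv = NULL,
                      radial_layers = NULL) {
  stopifnot(inherits(geom, "head_geometry"), h > 0)
  radii <- vapply(geom$openings, function(op)
    if (!is.null(op$radius_mm)) op$radius_mm else Inf, 0)
  if (length(radii) && h >= min(radii))
    stop("element size h must be smaller than the smallest opening radius")
  abar <- mean(geom$semi_axes)
  s <- angular_subdiv %||%
    max(1L, min(5L, as.integer(round(log2(1.05 * abar / h)))))
  L <- radial_layers %||% max(2L, as.integer(round(abar / h)))
  ball <- .ball_mesh(s, L)
  nodes <- ball$nodes * matrix(geom$semi_axes, nrow(ball$nodes), 3, byrow = TRUE)
  cells <- ball$cells
  vol <- tet_signed_volumes(nodes, cells)
  neg <- vol < 0
  cells[neg, c(3, 4)] <- cells[neg, c(4, 3)]
  if (any(abs(vol) <= 0))
    stop("degenerate tetrahedra after scaling to the ellipsoid")
  facets <- ball$surface_faces
  # tag boundary facets by the parameter-domain direction of their centroid
  fc <- (nodes[facets[, 1], ] + nodes[facets[, 2], ] + nodes[facets[, 3], ]) / 3
  U <- fc / matrix(geom$semi_axes, nrow(fc), 3, byrow = TRUE)
  U <- U / sqrt(rowSums(U^2))
  facet_tags <- rep(1L, nrow(facets))
  tag_names <- c(fixed_interface = 1L)
  next_tag <- 2L
  for (i in seq_along(geom$openings)) {
    op <- geom$openings[[i]]
    par <- .opening_param(op, geom$semi_axes)
    if (op$kind != "unilateral_circular") par$ext <- op$angular_extents
    mem <- .opening_member(U, op, par, geom$semi_axes)
    if (!any(mem))
      stop("opening ", i, " captured no boundary facets; refine the mesh")
    if (op$kind == "bifrontal_midline_bar") {
      left <- mem & fc[, 1] < 0
      right <- mem & fc[, 1] >= 0
      facet_tags[left] <- next_tag
      facet_tags[right] <- next_tag + 1L
      tag_names[paste0("opening_", i, c("_left", "_right"))] <-
        c(next_tag, next_tag + 1L)
      next_tag <- next_tag + 2L
    } else {
      facet_tags[mem] <- next_tag
      tag_names[paste0("opening_", i)] <- next_tag
      next_tag <- next_tag + 1L
    }
  }
  cc1 <- (nodes[cells[, 1], 1] + nodes[cells[, 2], 1] +
          nodes[cells[, 3], 1] + nodes[cells[, 4], 1]) / 4
  region_tags <- ifelse(cc1 < 0, 1L, 2L)
  tag_names <- c(tag_names, left_hemisphere = 1L, right_hemisphere = 2L)
  .new_labeled_mesh(nodes, cells, facets, facet_tags, region_tags,
                    tag_names, h, geom)
}

#' Total mesh volume
#'
#' @param mesh A `labeled_mesh`.
#' @return Volume in the cube of the node units (mm^3 for generated meshes).
#' @export
mesh_volume <- function(mesh) {
  sum(abs(tet_signed_volumes(mesh$nodes, mesh$cells)))
}

#' Validity checks for a labeled mesh
#'
#' Verifies positive tetrahedron volumes, a watertight (closed, exactly
#' once-shared) boundary that matches the stored facets, and complete
#' facet/region tagging.
#'
#' @param mesh A `labeled_mesh`.
#' @return `TRUE` invisibly; stops with a diagnostic otherwise.
#' @export
check_mesh <- function(mesh) {
  vol <- tet_signed_volumes(mesh$nodes, mesh$cells)
  if (any(vol <= 0))
    stop("non-positive tetrahedron volume in cell(s) ",
         paste(utils::head(which(vol <= 0)), collapse = ", "))
  bf <- boundary_facets(mesh$nodes, mesh$cells)
  key <- function(f) apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  if (!setequal(key(bf), key(mesh$facets)))
    stop("stored boundary facets do not match the mesh boundary")
  if (length(mesh$facet_tags) != nrow(mesh$facets))
    stop("facet_tags must cover every boundary facet")
  if (length(mesh$region_tags) != nrow(mesh$cells))
    stop("region_tags must cover every cell")
  invisible(TRUE)
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("Labeled tetrahedral mesh: %d nodes, %d cells, %d boundary facets\n",
              nrow(x$nodes), nrow(x$cells), nrow(x$facets)))
  cat(sprintf("  target h = %g mm, volume = %.1f ml\n",
              x$characteristic_h_mm, mesh_volume(x) / 1000))
  tn <- x$tag_names[!names(x$tag_names) %in%
                      c("left_hemisphere", "right_hemisphere")]
  for (nm in names(tn))
    cat(sprintf("  facet tag %-18s %d facets\n", nm,
                sum(x$facet_tags == tn[[nm]])))
  invisible(x)
}
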