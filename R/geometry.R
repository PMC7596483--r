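## Geometry layer: idealized ellipsoidal cavity with parametric craniectomy
## openings. Lengths in mm throughout; the solver converts to SI internally.
## Coordinate convention: origin at the cavity centroid, x = left-right axis
## (sagittal-plane normal, +x = right hemisphere), y = posterior-anterior
## (+y = anterior/frontal), z = inferior-superior.

#' Craniectomy opening specification
#'
#' Describes a skull opening as the intersection of the cavity surface with a
#' cone (unilateral circular) or an elliptical angular sector (bifrontal,
#' optionally split by a midline bone bar). Patch areas are computed on the
#' curved cavity surface by [build_idealized_head()]; for circular openings
#' the planar cross-sectional area `pi * r^2` is reported alongside.
#'
#' @param kind One of `"unilateral_circular"`, `"bifrontal"`,
#'   `"bifrontal_midline_bar"`.
#' @param axis Direction from the cavity centroid to the opening center
#'   (normalized internally). Defaults: lateral `(1, 0, 0.35)` for unilateral
#'   (a fronto-parietal opening on the right), anterior-superior
#'   `(0, 1, 0.45)` for bifrontal kinds.
#' @param radius_mm Opening radius in mm (unilateral only).
#' @param angular_extents Pair of angular half-widths in radians (toward the
#'   left-right and inferior-superior directions; bifrontal kinds). Ignored
#'   when `area_mm2` is requested.
#' @param area_mm2 For bifrontal kinds, the requested total patch area in mm^2;
#'   the angular extents are then found by a 1-D root search (to within 1%).
#' @param bar_width_mm Width of the retained midline bone bar in mm
#'   (`bifrontal_midline_bar` only; default 25).
#' @return An object of class `opening_spec`.
#' @export
opening_spec <- function(kind = c("unilateral_circular", "bifrontal",
                                  "bifrontal_midline_bar"),
                         axis = NULL, radius_mm = NULL, angular_extents = NULL,
                         area_mm2 = NULL, bar_width_mm = NULL) {
  kind <- match.arg(kind)
  if (is.null(axis))
    axis <- if (kind == "unilateral_circular") c(1, 0, 0.35) else c(0, 1, 0.45)
  stopifnot(length(axis) == 3L, is.numeric(axis))
  nr <- sqrt(sum(axis^2))
  if (nr == 0) stop("opening axis must be a non-zero direction")
  axis <- axis / nr
  if (kind == "unilateral_circular") {
    if (is.null(radius_mm) || radius_mm <= 0)
      stop("unilateral_circular openings need radius_mm > 0")
    angular_extents <- NULL
  } else {
    if (is.null(angular_extents) && is.null(area_mm2))
      stop(kind, " openings need angular_extents or a requested area_mm2")
    if (!is.null(angular_extents)) {
      stopifnot(length(angular_extents) == 2L, all(angular_extents > 0),
                all(angular_extents < pi / 2))
    }
    radius_mm <- NULL
    if (kind == "bifrontal_midline_bar") {
      if (is.null(bar_width_mm)) bar_width_mm <- 25
      stopifnot(bar_width_mm > 0)
    } else bar_width_mm <- NULL
  }
  structure(list(kind = kind, axis = axis, radius_mm = radius_mm,
                 angular_extents = angular_extents,
                 requested_area_mm2 = if (!is.null(area_mm2)) area_mm2 else NULL,
                 bar_width_mm = bar_width_mm,
                 area_mm2 = NULL, area_planar_mm2 = NULL),
            class = "opening_spec")
}

## tangent frame of the unit-sphere parameter domain at direction u_c
.patch_frame <- function(u_c) {
  ref <- if (abs(u_c[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  t1 <- ref - sum(ref * u_c) * u_c
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u_c[2] * t1[3] - u_c[3] * t1[2],
          u_c[3] * t1[1] - u_c[1] * t1[3],
          u_c[1] * t1[2] - u_c[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

## parameter-domain data for one opening on an ellipsoid with given semi-axes:
## center direction, frame, cone half-angles
.opening_param <- function(op, semi_axes) {
  a <- op$axis
  r_loc <- 1 / sqrt(sum((a / semi_axes)^2)) # centroid->surface distance along axis
  centre <- a * r_loc
  u_c <- centre / semi_axes                 # unit by construction
  fr <- .patch_frame(u_c)
  nrm <- centre / semi_axes^2               # outward surface normal at the centre
  nrm <- nrm / sqrt(sum(nrm^2))
  list(u_c = u_c, t1 = fr$t1, t2 = fr$t2, r_loc = r_loc, centre = centre,
       normal = nrm, ext = op$angular_extents)
}

## membership of unit directions (rows of U) in the opening patch.
## A circular opening is the surface patch cut by a cylinder of radius
## radius_mm about the surface normal through the opening centre (a circular
## bone cut); bifrontal openings are elliptical sectors in the angular
## parameter domain.
.opening_member <- function(U, op, par, semi_axes) {
  if (op$kind == "unilateral_circular") {
    X <- U * matrix(semi_axes, nrow(U), 3, byrow = TRUE)
    D <- X - matrix(par$centre, nrow(U), 3, byrow = TRUE)
    along <- D %*% par$normal
    Dp <- D - along %*% t(par$normal)
    inside <- rowSums(Dp^2) <= op$radius_mm^2 & as.vector(U %*% par$u_c) > 0
  } else {
    ca <- pmin(1, pmax(-1, U %*% par$u_c))
    psi <- acos(ca)
    a1 <- U %*% par$t1
    a2 <- U %*% par$t2
    phi <- atan2(a2, a1)
    inside <- (psi * cos(phi) / par$ext[1])^2 +
              (psi * sin(phi) / par$ext[2])^2 <= 1
    if (op$kind == "bifrontal_midline_bar") {
      x1 <- U[, 1] * semi_axes[1] # sagittal coordinate of the surface point
      inside <- inside & (abs(x1) > op$bar_width_mm / 2)
    }
  }
  as.vector(inside)
}

## curved patch area by midpoint quadrature in polar coordinates about the
## opening axis (parameter-domain polar angle psi, azimuth phi)
.patch_area <- function(op, par, semi_axes, n_psi = 400, n_phi = 400) {
  psi_max <- if (op$kind == "unilateral_circular")
    pi / 2 * 0.999 else min(pi / 2 * 0.999, max(par$ext) * 1.05)
  dpsi <- psi_max / n_psi
  dphi <- 2 * pi / n_phi
  psi <- (seq_len(n_psi) - 0.5) * dpsi
  phi <- (seq_len(n_phi) - 0.5) * dphi
  g <- expand.grid(psi = psi, phi = phi)
  cpsi <- cos(g$psi); spsi <- sin(g$psi); cphi <- cos(g$phi); sphi <- sin(g$phi)
  # unit direction and its partials
  U  <- cpsi %o% par$u_c + (spsi * cphi) %o% par$t1 + (spsi * sphi) %o% par$t2
  Up <- (-spsi) %o% par$u_c + (cpsi * cphi) %o% par$t1 + (cpsi * sphi) %o% par$t2
  Uf <- (-spsi * sphi) %o% par$t1 + (spsi * cphi) %o% par$t2
  # surface point X = semi_axes * U; cross product of partials
  S <- matrix(semi_axes, nrow(U), 3, byrow = TRUE)
  Xp <- S * Up; Xf <- S * Uf
  cr <- cbind(Xp[, 2] * Xf[, 3] - Xp[, 3] * Xf[, 2],
              Xp[, 3] * Xf[, 1] - Xp[, 1] * Xf[, 3],
              Xp[, 1] * Xf[, 2] - Xp[, 2] * Xf[, 1])
  dA <- sqrt(rowSums(cr^2))
  member <- .opening_member(U, op, par, semi_axes)
  sum(dA[member]) * dpsi * dphi
}

## resolve a bifrontal opening's angular extents from a requested area
.resolve_extents <- function(op, semi_axes, base_ratio = 0.6) {
  target <- op$requested_area_mm2
  area_of <- function(t) {
    par <- .opening_param(op, semi_axes)
    par$ext <- c(t, base_ratio * t)
    .patch_area(op, par, semi_axes, n_psi = 200, n_phi = 200)
  }
  f <- function(t) area_of(t) - target
  upper <- 1.55
  if (f(upper) < 0)
    stop("requested bifrontal area ", target, " mm^2 exceeds the reachable patch size")
  t <- stats::uniroot(f, c(0.02, upper), tol = 1e-4)$root
  c(t, base_ratio * t)
}

#' Build an idealized skull/brain geometry
#'
#' The cavity is a triaxial ellipsoid (a rigid-skull stand-in at adult-brain
#' scale) with craniectomy openings cut on its surface. For every opening the
#' true curved patch area is computed by surface quadrature and stored in
#' `area_mm2`; circular openings additionally carry the planar
#' cross-sectional area `pi * r^2` in `area_planar_mm2`, the value quoted for
#' such openings in the clinical literature. Bifrontal openings given a
#' requested area have their angular extents resolved by a root search to
#' within 1%.
#'
#' @param semi_axes Ellipsoid semi-axes `(a, b, c)` in mm along the
#'   left-right, posterior-anterior and inferior-superior axes. The default
#'   `c(80, 66, 59)` gives a cavity of about 1.3 l.
#' @param openings List of [opening_spec()] objects (possibly empty).
#' @return An object of class `head_geometry` with fields `semi_axes`,
#'   `openings` (areas filled in), `sagittal_normal`, `cavity_volume_ml`.
#' @export
build_idealized_head <- function(semi_axes = c(80, 66, 59), openings = list()) {
  stopifnot(is.numeric(semi_axes), length(semi_axes) == 3L, all(semi_axes > 0))
  if (inherits(openings, "opening_spec")) openings <- list(openings)
  stopifnot(all(vapply(openings, inherits, TRUE, "opening_spec")))
  pars <- vector("list", length(openings))
  for (i in seq_along(openings)) {
    op <- openings[[i]]
    if (op$kind != "unilateral_circular" && is.null(op$angular_extents))
      op$angular_extents <- .resolve_extents(op, semi_axes)
    par <- .opening_param(op, semi_axes)
    op$area_mm2 <- .patch_area(op, par, semi_axes)
    op$area_planar_mm2 <- if (op$kind == "unilateral_circular")
      pi * op$radius_mm^2 else op$area_mm2
    if (op$kind == "unilateral_circular") {
      # a unilateral opening must stay clear of the mid-sagittal plane
      samp <- .sphere_samples()
      mem <- .opening_member(samp, op, par, semi_axes)
      x1 <- samp[mem, 1] * semi_axes[1]
      if (length(x1) && min(x1) * max(x1) < 0)
        stop("unilateral opening ", i, " intersects the mid-sagittal plane")
    }
    openings[[i]] <- op
    pars[[i]] <- par
  }
  # pairwise overlap check on a dense direction sample
  if (length(openings) > 1) {
    samp <- .sphere_samples()
    mem <- vapply(seq_along(openings), function(i)
      .opening_member(samp, openings[[i]], pars[[i]], semi_axes),
      logical(nrow(samp)))
    for (i in seq_len(length(openings) - 1)) for (j in (i + 1):length(openings))
      if (any(mem[, i] & mem[, j]))
        stop("openings ", i, " and ", j, " overlap")
  }
  structure(list(semi_axes = semi_axes, openings = openings,
                 sagittal_normal = c(1, 0, 0),
                 cavity_volume_ml = 4 / 3 * pi * prod(semi_axes) / 1000),
            class = "head_geometry")
}

## quasi-uniform direction sample (icosphere vertices, 2 subdivisions + centroids)
.sphere_samples <- function() {
  ico <- .icosphere(3)
  cent <- (ico$vertices[ico$faces[, 1], ] + ico$vertices[ico$faces[, 2], ] +
           ico$vertices[ico$faces[, 3], ]) / 3
  rbind(ico$vertices, cent / sqrt(rowSums(cent^2)))
}

#' @export
print.head_geometry <- function(x, ...) {
  cat("Idealized head geometry\n")
  cat(sprintf("  semi-axes: %g x %g x %g mm, cavity volume %.0f ml\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$cavity_volume_ml))
  if (!length(x$openings)) cat("  closed skull (no openings)\n")
  for (i in seq_along(x$openings)) {
    op <- x$openings[[i]]
    cat(sprintf("  opening %d: %s, curved area %.0f mm^2", i, op$kind, op$area_mm2))
    if (!is.null(op$radius_mm))
      cat(sprintf(" (r = %g mm, planar area %.0f mm^2)", op$radius_mm,
                  op$area_planar_mm2))
    cat("\n")
  }
  invisible(x)
}
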