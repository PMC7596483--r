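## Mixed P2/P1 finite-element core. Displacements use quadratic Lagrange
## basis functions on tetrahedra, the interstitial pressure linear ones.
## Assembly is total-Lagrangian on the reference configuration; the heavy
## per-element work lives in src/assembly.cpp.

## Gauss-Jacobi rule on [0,1] with weight (1 - x)^alpha (Golub-Welsch)
.gauss_jacobi01 <- function(n, alpha) {
  k <- seq_len(n - 1)
  a <- c(-alpha / (alpha + 2),
         -alpha^2 / ((2 * k + alpha) * (2 * k + alpha + 2)))
  b <- 4 * k^2 * (k + alpha)^2 /
    ((2 * k + alpha)^2 * (2 * k + alpha + 1) * (2 * k + alpha - 1))
  Jm <- diag(a[seq_len(n)], n)
  if (n > 1) {
    sb <- sqrt(b)
    Jm[cbind(seq_len(n - 1), 2:n)] <- sb
    Jm[cbind(2:n, seq_len(n - 1))] <- sb
  }
  e <- eigen(Jm, symmetric = TRUE)
  mu0 <- 2^(alpha + 1) / (alpha + 1)
  ord <- order(e$values)
  x <- e$values[ord]
  w <- mu0 * e$vectors[1, ord]^2
  list(x = (x + 1) / 2, w = w * 0.5^(alpha + 1))
}

## conical-product quadrature on the reference tetrahedron
## {x,y,z >= 0, x+y+z <= 1}; 27 points, exact for total degree 5
.tet_quadrature <- function() {
  qu <- .gauss_jacobi01(3, 2)
  qv <- .gauss_jacobi01(3, 1)
  qw <- .gauss_jacobi01(3, 0)
  g <- expand.grid(iu = 1:3, iv = 1:3, iw = 1:3)
  u <- qu$x[g$iu]; v <- qv$x[g$iv]; w <- qw$x[g$iw]
  pts <- cbind(x = u, y = v * (1 - u), z = w * (1 - u) * (1 - v))
  wt <- qu$w[g$iu] * qv$w[g$iv] * qw$w[g$iw]
  list(points = pts, weights = wt)
}

## P2 shape values and reference gradients at reference points (n x 3);
## node order: 4 vertices, then edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
.p2_shapes <- function(pts) {
  n <- nrow(pts)
  L <- cbind(1 - rowSums(pts), pts)
  gL <- rbind(c(-1, -1, -1), diag(3)) # gradient of each barycentric coord
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  N <- matrix(0, n, 10)
  dN <- matrix(0, 10 * n, 3)
  for (i in 1:4) {
    N[, i] <- L[, i] * (2 * L[, i] - 1)
    dN[(seq_len(n) - 1) * 10 + i, ] <- (4 * L[, i] - 1) %o% gL[i, ]
  }
  for (k in 1:6) {
    a <- edges[k, 1]; b <- edges[k, 2]
    N[, 4 + k] <- 4 * L[, a] * L[, b]
    dN[(seq_len(n) - 1) * 10 + 4 + k, ] <-
      4 * (L[, a] %o% gL[b, ] + L[, b] %o% gL[a, ])
  }
  list(N = N, dN = dN)
}

## P1 values at reference points
.p1_shapes <- function(pts) cbind(1 - rowSums(pts), pts)

#' Finite-element setup for a labeled mesh
#'
#' Builds the mixed discretization: quadratic displacement nodes (vertices
#' plus edge midpoints), linear pressure nodes (vertices), the quadrature
#' rule, and the constrained degree-of-freedom sets implied by the boundary
#' tags (see [apply_boundary_conditions()]). Node coordinates are converted
#' to meters.
#'
#' @param mesh A `labeled_mesh` (coordinates in mm).
#' @param fix_displacement Fix the displacement field everywhere (pressure-only
#'   solves, used by verification problems).
#' @param p_dirichlet_all_boundary Impose `p = 0` on the whole boundary
#'   instead of only on opening patches (verification problems).
#' @param seal_openings Treat all opening facets as fixed interface (the
#'   closed-skull step of the two-step DCC procedure).
#' @return An opaque `fe_model` list used by the assembly and solve routines.
#' @export
fe_setup <- function(mesh, fix_displacement = FALSE,
                     p_dirichlet_all_boundary = FALSE,
                     seal_openings = FALSE) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  cells <- mesh$cells
  nv <- max(cells)
  m <- nrow(cells)
  ep <- rbind(cells[, c(1, 2)], cells[, c(1, 3)], cells[, c(1, 4)],
              cells[, c(2, 3)], cells[, c(2, 4)], cells[, c(3, 4)])
  ek <- pmin(ep[, 1], ep[, 2]) * (nv + 1) + pmax(ep[, 1], ep[, 2])
  uk <- unique(ek)
  eid <- match(ek, uk)
  a <- uk %/% (nv + 1); b <- uk %% (nv + 1)
  nodes_p2 <- rbind(mesh$nodes[seq_len(nv), , drop = FALSE],
                    (mesh$nodes[a, , drop = FALSE] +
                     mesh$nodes[b, , drop = FALSE]) / 2) / 1000 # mm -> m
  cells10 <- cbind(cells, nv + matrix(eid, m, 6))
  storage.mode(cells10) <- "integer"
  np2 <- nrow(nodes_p2)
  ndof <- 3L * np2 + nv

  quad <- .tet_quadrature()
  sh <- .p2_shapes(quad$points)
  Np <- .p1_shapes(quad$points)

  bc <- apply_boundary_conditions(mesh,
                                  fix_displacement = fix_displacement,
                                  p_dirichlet_all_boundary = p_dirichlet_all_boundary,
                                  seal_openings = seal_openings)
  edge_key_of <- function(v1, v2) pmin(v1, v2) * (nv + 1) + pmax(v1, v2)
  u_nodes <- bc$u_fixed_vertices
  if (length(bc$u_fixed_edges_v1)) {
    bek <- edge_key_of(bc$u_fixed_edges_v1, bc$u_fixed_edges_v2)
    u_nodes <- c(u_nodes, nv + match(bek, uk))
  }
  if (fix_displacement) u_nodes <- seq_len(np2)
  u_nodes <- sort(unique(u_nodes))
  u_dofs <- as.integer(rep(3 * (u_nodes - 1), each = 3) + 1:3)
  p_dofs <- as.integer(3 * np2 + bc$p_fixed_vertices)
  fixed <- c(u_dofs, p_dofs)
  free <- setdiff(seq_len(ndof), fixed)
  dofmap <- rep(-1L, ndof)
  dofmap[free] <- seq_along(free) - 1L

  list(mesh = mesh, nodes = nodes_p2, cells10 = cells10, nv = nv, np2 = np2,
       ndof = ndof, quad = quad, Nu = sh$N, dNu = sh$dN, Np = Np,
       free = free, dofmap = dofmap, n_free_u = sum(free <= 3L * np2),
       u_fixed_nodes = u_nodes,
       p_fixed_vertices = bc$p_fixed_vertices,
       edge_keys = uk)
}

#' Boundary-condition bookkeeping for a labeled mesh
#'
#' Realizes the model's boundary conditions from facet tags: displacement is
#' Dirichlet-fixed (`u = 0`) on the rigid skull interface and traction-free
#' on openings; pressure is Dirichlet-zero (`p_i = 0`) on openings and
#' natural zero-flux on the fixed interface.
#'
#' @param mesh A `labeled_mesh`.
#' @param fix_displacement,p_dirichlet_all_boundary,seal_openings See
#'   [fe_setup()].
#' @return A list with the constrained vertex ids (`u_fixed_vertices`,
#'   `p_fixed_vertices`) and the edge endpoints of constrained midside nodes.
#' @export
apply_boundary_conditions <- function(mesh, fix_displacement = FALSE,
                                      p_dirichlet_all_boundary = FALSE,
                                      seal_openings = FALSE) {
  fixed_tag <- mesh$tag_names[["fixed_interface"]]
  opening_tags <- setdiff(unique(mesh$facet_tags), fixed_tag)
  if (seal_openings) opening_tags <- integer(0)
  fixed_facets <- mesh$facets[!(mesh$facet_tags %in% opening_tags), ,
                              drop = FALSE]
  open_facets <- mesh$facets[mesh$facet_tags %in% opening_tags, , drop = FALSE]
  if (nrow(fixed_facets) == 0 && !fix_displacement)
    stop("mesh has no fixed_interface facets: rigid-body motion is unconstrained")
  fe1 <- rbind(fixed_facets[, c(1, 2)], fixed_facets[, c(2, 3)],
               fixed_facets[, c(1, 3)])
  p_fixed <- if (p_dirichlet_all_boundary)
    sort(unique(as.vector(mesh$facets))) else sort(unique(as.vector(open_facets)))
  list(u_fixed_vertices = sort(unique(as.vector(fixed_facets))),
       u_fixed_edges_v1 = fe1[, 1], u_fixed_edges_v2 = fe1[, 2],
       p_fixed_vertices = p_fixed,
       n_p_dirichlet = length(p_fixed))
}

#' Solver options
#'
#' @param newton_rtol Relative residual-norm reduction for Newton convergence.
#' @param newton_atol Absolute residual-norm floor.
#' @param max_newton_iters Maximum Newton iterations per load step.
#' @param n_load_steps Number of uniform growth increments from
#'   `lambda_g = 1` to the target (used when the growth field carries no
#'   explicit schedule).
#' @param mode `"stationary"` (equilibrium; solid velocity zero — the regime
#'   DCC planning targets, and the default) or `"quasistatic"` (backward-Euler
#'   solid velocity coupling with time step `dt`, provided for transient
#'   studies).
#' @param dt Time step in seconds (quasistatic mode only).
#' @param linear_solver `"direct"` (sparse LU; deterministic) is the only
#'   implemented backend.
#' @param seed Integer seed recorded for reproducibility (no randomized
#'   component is active with the direct solver).
#' @param fix_displacement,p_dirichlet_all_boundary Verification hooks, see
#'   [fe_setup()].
#' @return A `solver_options` object.
#' @export
solver_options <- function(newton_rtol = 1e-8, newton_atol = 1e-10,
                           max_newton_iters = 25, n_load_steps = 10,
                           mode = c("stationary", "quasistatic"), dt = NULL,
                           linear_solver = c("direct"), seed = 0,
                           fix_displacement = FALSE,
                           p_dirichlet_all_boundary = FALSE) {
  mode <- match.arg(mode)
  linear_solver <- match.arg(linear_solver)
  stopifnot(newton_rtol > 0, newton_atol > 0, max_newton_iters >= 1,
            n_load_steps >= 1)
  if (mode == "quasistatic" && (is.null(dt) || dt <= 0))
    stop("quasistatic mode requires a positive time step dt")
  structure(list(newton_rtol = newton_rtol, newton_atol = newton_atol,
                 max_newton_iters = max_newton_iters,
                 n_load_steps = n_load_steps, mode = mode, dt = dt,
                 linear_solver = linear_solver, seed = as.integer(seed),
                 fix_displacement = fix_displacement,
                 p_dirichlet_all_boundary = p_dirichlet_all_boundary),
            class = "solver_options")
}

## per-element linear growth stretch at one schedule level
.lambda_elements <- function(fe, growth, level_frac) {
  lam <- growth$lambda_g
  lam <- vapply(lam, growth_linear_stretch, 0,
                interpretation = growth$interpretation)
  m <- nrow(fe$cells10)
  tgt <- rep(1, m)
  for (nm in names(lam)) {
    sel <- switch(nm,
                  whole_brain = rep(TRUE, m),
                  left_hemisphere = fe$mesh$region_tags ==
                    fe$mesh$tag_names[["left_hemisphere"]],
                  right_hemisphere = fe$mesh$region_tags ==
                    fe$mesh$tag_names[["right_hemisphere"]])
    tgt[sel] <- pmax(tgt[sel], lam[[nm]])
  }
  1 + level_frac * (tgt - 1)
}

## growth schedule as fractions of the target increment, plus lambda levels
.growth_schedule <- function(growth, n_load_steps) {
  lam <- vapply(growth$lambda_g, growth_linear_stretch, 0,
                interpretation = growth$interpretation)
  target <- max(lam)
  if (target <= 1) return(data.frame(lambda = 1, frac = 1))
  if (!is.null(growth$schedule)) {
    sched <- vapply(growth$schedule, growth_linear_stretch, 0,
                    interpretation = growth$interpretation)
    data.frame(lambda = sched, frac = (sched - 1) / (target - 1))
  } else {
    lv <- 1 + (target - 1) * seq_len(n_load_steps) / n_load_steps
    data.frame(lambda = lv, frac = seq_len(n_load_steps) / n_load_steps)
  }
}

## residual (and optionally Jacobian on the free dofs) for a given state
.assemble <- function(fe, u, p, lambda_el, mat, vasc, jac_mode = 0L,
                      quasistatic = FALSE, dt = 1, u_old = NULL) {
  a_star <- vasc$Lp * vasc$SV * vasc$pv + vasc$Lpl * vasc$SlVl * vasc$pl
  b_star <- vasc$Lp * vasc$SV + vasc$Lpl * vasc$SlVl
  if (is.null(u_old)) u_old <- numeric(length(u))
  out <- .cpp_assemble(fe$nodes, fe$cells10, fe$quad$weights, fe$dNu, fe$Np,
                       u, p, lambda_el, mat$mu, mat$Kbulk, mat$k_hyd,
                       a_star, b_star, as.integer(jac_mode), fe$dofmap,
                       length(fe$free), fe$n_free_u, quasistatic, dt, u_old)
  if (jac_mode == 1L)
    out$J <- Matrix::sparseMatrix(i = out$i, j = out$j, x = out$x,
                                  dims = c(length(fe$free), length(fe$free)))
  if (jac_mode == 2L) {
    nfu <- fe$n_free_u
    nfp <- length(fe$free) - nfu
    out$Juu <- Matrix::sparseMatrix(i = out$iu, j = out$ju, x = out$xu,
                                    dims = c(nfu, nfu))
    out$Jpp <- Matrix::sparseMatrix(i = out$ip, j = out$jp, x = out$xp,
                                    dims = c(nfp, nfp))
  }
  out
}

## factor the (symmetric) momentum tangent; on indefiniteness fall back to a
## Levenberg-style diagonal shift so the line search still gets a usable
## descent direction
.solve_sym_block <- function(A, b) {
  if (length(b) == 0) return(numeric(0))
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  sh <- 0
  dscale <- max(abs(Matrix::diag(A)))
  for (k in 0:3) {
    ch <- tryCatch(Matrix::Cholesky(A + Matrix::Diagonal(nrow(A), sh),
                                    LDL = FALSE, super = TRUE),
                   error = function(e) NULL)
    if (!is.null(ch)) return(as.numeric(Matrix::solve(ch, b)))
    sh <- if (sh == 0) 1e-8 * dscale else 100 * sh
  }
  stop("momentum tangent factorization failed (strongly indefinite state)")
}

#' Assemble the discrete residual (and Jacobian) of the coupled problem
#'
#' Evaluates the mixed momentum/pressure residual for given displacement and
#' pressure fields at a fixed growth level; optionally also the consistent
#' Jacobian restricted to the unconstrained degrees of freedom. Mainly a
#' verification surface; [solve_equilibrium()] drives it internally.
#'
#' @param mesh A `labeled_mesh`, or an `fe_model` from [fe_setup()].
#' @param u Displacement matrix (`n_p2 x 3`, meters) or flat vector.
#' @param p Pressure vector at vertices, Pa.
#' @param growth A [growth_field()] (applied at full target level).
#' @param mat,vasc Parameter objects.
#' @param want_jacobian Also return the sparse Jacobian on free dofs.
#' @return List with `residual` (full vector, momentum rows N, pressure rows
#'   m^3/s), `free` (free dof indices) and optionally `J`.
#' @export
assemble_residual <- function(mesh, u, p, growth, mat, vasc,
                              want_jacobian = FALSE) {
  fe <- if (inherits(mesh, "labeled_mesh")) fe_setup(mesh) else mesh
  u <- as.numeric(t(u)) # node-major (x,y,z) triplets if given as matrix
  if (length(u) != 3 * fe$np2) stop("u has wrong length for this mesh")
  if (length(p) != fe$nv) stop("p has wrong length for this mesh")
  lam <- .lambda_elements(fe, growth, 1)
  out <- .assemble(fe, u, p, lam, mat, vasc,
                   jac_mode = if (want_jacobian) 1L else 0L)
  res <- list(residual = out$R, free = fe$free)
  if (want_jacobian) res$J <- out$J
  res
}

#' Solve the coupled equilibrium problem under growth loading
#'
#' Incremental Newton solution of the biphasic finite-strain problem: the
#' growth stretch is ramped from 1 to its target over the load schedule and
#' each level is solved by Newton iteration with backtracking line search
#' (halving, at most 8 halvings) and a sparse direct linear solver.
#' Identical inputs and options produce identical iterates.
#'
#' @param mesh A `labeled_mesh`.
#' @param growth A [growth_field()].
#' @param mat A [material_params()].
#' @param vasc A [vascular_params()].
#' @param opts A [solver_options()].
#' @param seal_openings Solve with all openings sealed (closed-skull step).
#' @param store_states Keep the converged state of every load level (used to
#'   build planning curves in one sweep); returned as attribute `"states"`.
#' @return A `solution_state`: `u` (n_p2 x 3, meters), `p` (vertices, Pa),
#'   `lambda_g_achieved`, `v_s` (quasistatic mode), `convergence_log`.
#' @export
solve_equilibrium <- function(mesh, growth, mat, vasc = vascular_params(),
                              opts = solver_options(), seal_openings = FALSE,
                              store_states = FALSE) {
  stopifnot(inherits(growth, "growth_field"), inherits(mat, "material_params"),
            inherits(vasc, "vascular_params"), inherits(opts, "solver_options"))
  fe <- fe_setup(mesh, fix_displacement = opts$fix_displacement,
                 p_dirichlet_all_boundary = opts$p_dirichlet_all_boundary,
                 seal_openings = seal_openings)
  .solve_on_fe(fe, growth, mat, vasc, opts, store_states)
}

.solve_on_fe <- function(fe, growth, mat, vasc, opts, store_states = FALSE) {
  quasistatic <- opts$mode == "quasistatic"
  dt <- if (quasistatic) opts$dt else 1
  u <- numeric(3 * fe$np2)
  p <- rep(starling_equilibrium_pressure(vasc), fe$nv)
  p[fe$p_fixed_vertices] <- 0
  # free-dof index maps: global indices and their positions in the reduced system
  gu <- which(fe$dofmap[seq_len(3 * fe$np2)] >= 0L)
  ru <- fe$dofmap[gu] + 1L
  gp <- which(fe$dofmap[3 * fe$np2 + seq_len(fe$nv)] >= 0L)
  rp <- fe$dofmap[3 * fe$np2 + gp] + 1L
  sched <- .growth_schedule(growth, opts$n_load_steps)
  log <- list()
  states <- if (store_states) vector("list", nrow(sched)) else NULL
  u_old <- numeric(length(u))
  for (s in seq_len(nrow(sched))) {
    lam_el <- .lambda_elements(fe, growth, sched$frac[s])
    rn0 <- NA
    converged <- FALSE
    res <- .assemble(fe, u, p, lam_el, mat, vasc, FALSE, quasistatic, dt, u_old)
    rn <- sqrt(sum(res$R[fe$free]^2))
    rn0 <- rn
    for (it in seq_len(opts$max_newton_iters)) {
      log[[length(log) + 1L]] <- data.frame(step = s,
                                            lambda = sched$lambda[s],
                                            iter = it - 1L, residual = rn)
      if (rn <= max(opts$newton_atol, opts$newton_rtol * rn0)) {
        converged <- TRUE
        break
      }
      # block Gauss-Seidel Newton step: the exact uu and pp tangent blocks
      # are factored (the weak Darcy/Starling coupling enters through the
      # residual, on which convergence is always measured)
      asj <- .assemble(fe, u, p, lam_el, mat, vasc, 2L, quasistatic, dt, u_old)
      rfree <- asj$R[fe$free]
      nfu <- fe$n_free_u
      du <- .solve_sym_block(asj$Juu, -rfree[seq_len(nfu)])
      dp <- .solve_sym_block(asj$Jpp, -rfree[setdiff(seq_along(rfree),
                                                     seq_len(nfu))])
      dx <- c(du, dp)
      t_ls <- 1
      for (bt in 0:8) {
        u_try <- u; p_try <- p
        u_try[gu] <- u[gu] + t_ls * dx[ru]
        p_try[gp] <- p[gp] + t_ls * dx[rp]
        rn_try <- {
          r2 <- tryCatch(.assemble(fe, u_try, p_try, lam_el, mat, vasc, FALSE,
                                   quasistatic, dt, u_old),
                         error = function(e) NULL)
          if (is.null(r2)) Inf else sqrt(sum(r2$R[fe$free]^2))
        }
        if (rn_try < (1 - 1e-4 * t_ls) * rn || rn_try <= opts$newton_atol) {
          u <- u_try; p <- p_try; rn <- rn_try
          break
        }
        t_ls <- t_ls / 2
        if (bt == 8) stop("line search failed at lambda_g = ",
                          signif(sched$lambda[s], 6),
                          "; consider more load steps")
      }
    }
    if (!converged && rn > max(opts$newton_atol, opts$newton_rtol * rn0))
      stop("Newton did not converge at lambda_g = ", signif(sched$lambda[s], 6),
           " after ", opts$max_newton_iters, " iterations (residual ",
           signif(rn, 4), ")")
    if (store_states)
      states[[s]] <- .pack_state(fe, u, p, sched$lambda[s],
                                 if (quasistatic) (u - u_old) / dt else NULL,
                                 do.call(rbind, log), lam_el, mat)
    if (quasistatic) u_old <- u
  }
  st <- .pack_state(fe, u, p, sched$lambda[nrow(sched)],
                    if (quasistatic) (u - u_old) / dt else NULL,
                    do.call(rbind, log),
                    .lambda_elements(fe, growth, sched$frac[nrow(sched)]), mat)
  if (store_states) attr(st, "states") <- states
  st
}

.pack_state <- function(fe, u, p, lambda, v_s, log, lam_el, mat) {
  structure(list(u = matrix(u, ncol = 3, byrow = TRUE), p = p,
                 lambda_g_achieved = lambda, lambda_elements = lam_el,
                 mu = mat$mu, Kbulk = mat$Kbulk,
                 v_s = if (!is.null(v_s)) matrix(v_s, ncol = 3, byrow = TRUE),
                 convergence_log = log, fe = fe),
            class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf("Converged biphasic state at lambda_g = %.4f\n",
              x$lambda_g_achieved))
  cat(sprintf("  max |u| = %.3f mm, p range [%.3g, %.3g] Pa\n",
              1000 * max(sqrt(rowSums(x$u^2))), min(x$p), max(x$p)))
  cat(sprintf("  %d Newton iterations over %d load steps\n",
              nrow(x$convergence_log), max(x$convergence_log$step)))
  invisible(x)
}
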