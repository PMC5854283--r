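#' Labeled tetrahedral mesh
#'
#' Internal-volume mesh of a resonator with every boundary facet labeled
#' exactly one of `glottis`, `wall`, `lips`. Constructed by
#' [cylinder_mesh()] or read from a Gmsh v2 ASCII file ([read_msh()]).
#'
#' @name labeled_mesh
#' @keywords internal
NULL

new_labeled_mesh <- function(nodes, tets, facets, facet_label) {
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4, ncol(facets) == 3,
            nrow(facets) == length(facet_label),
            all(facet_label %in% c("glottis", "wall", "lips")))
  structure(list(nodes = nodes, tets = tets, facets = facets,
                 facet_label = facet_label),
            class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("<labeled_mesh>", nrow(x$nodes), "nodes,", nrow(x$tets), "tets,",
      nrow(x$facets), "boundary facets\n")
  a <- boundary_areas(x)
  cat(sprintf("  areas: glottis %.4g, lips %.4g, wall %.4g m^2; volume %.4g m^3\n",
              a[["glottis"]], a[["lips"]], a[["wall"]], mesh_volume(x)))
  invisible(x)
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  det3 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  abs(det3) / 6
}

tri_areas <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  e1 <- nodes[tris[, 2], , drop = FALSE] - a
  e2 <- nodes[tris[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total mesh volume and labeled boundary areas
#' @param mesh A labeled mesh.
#' @return `mesh_volume()`: volume in m^3. `boundary_areas()`: named vector
#'   of areas (m^2) for `glottis`, `wall`, `lips`.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh$nodes, mesh$tets))

#' @rdname mesh_volume
#' @export
boundary_areas <- function(mesh) {
  ar <- tri_areas(mesh$nodes, mesh$facets)
  vapply(c(glottis = "glottis", wall = "wall", lips = "lips"),
         function(l) sum(ar[mesh$facet_label == l]), numeric(1))
}

# --- structured cylinder meshing -------------------------------------------

# triangulated unit disk scaled to `radius`: center node + nr concentric
# rings, ring i carrying 6i nodes; 6 nr^2 triangles in total
disk_triangulation <- function(radius, nr) {
  pts <- matrix(0, nrow = 1, ncol = 2)
  ring_start <- integer(nr)  # index of first node of each ring
  for (i in seq_len(nr)) {
    ring_start[i] <- nrow(pts) + 1L
    th <- 2 * pi * (0:(6 * i - 1)) / (6 * i)
    r <- radius * i / nr
    pts <- rbind(pts, cbind(r * cos(th), r * sin(th)))
  }
  ring_node <- function(i, j) {
    # node j (0-based, wraps) of ring i; ring 0 is the center
    if (i == 0) return(1L)
    ring_start[i] + (j %% (6L * i))
  }
  tris <- matrix(0L, nrow = 6 * nr^2, ncol = 3)
  t_i <- 0L
  for (i in seq_len(nr)) {
    for (s in 0:5) {
      for (j in 0:(i - 1)) {
        o1 <- ring_node(i, s * i + j); o2 <- ring_node(i, s * i + j + 1)
        n1 <- ring_node(i - 1L, s * (i - 1L) + j)
        t_i <- t_i + 1L; tris[t_i, ] <- c(o1, o2, n1)
        if (j < i - 1) {
          n2 <- ring_node(i - 1L, s * (i - 1L) + j + 1)
          t_i <- t_i + 1L; tris[t_i, ] <- c(o2, n2, n1)
        }
      }
    }
  }
  list(points = pts, triangles = tris[seq_len(t_i), , drop = FALSE])
}

# split one prism (bottom v1 v2 v3, top v4 v5 v6, v_{i+3} above v_i) into
# three tets with diagonals chosen from global indices, so that adjacent
# prisms agree on shared quad faces (Dompierre et al. subdivision)
split_prism <- function(v) {
  rots <- list(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
               c(4, 6, 5, 1, 3, 2), c(5, 4, 6, 2, 1, 3), c(6, 5, 4, 3, 2, 1))
  best <- which.min(vapply(rots, function(r) v[r[1]], numeric(1)))
  p <- v[rots[[best]]]
  if (min(p[2], p[6]) < min(p[3], p[5])) {
    rbind(p[c(1, 2, 3, 6)], p[c(1, 2, 6, 5)], p[c(1, 5, 6, 4)])
  } else {
    rbind(p[c(1, 2, 3, 5)], p[c(1, 5, 3, 6)], p[c(1, 5, 6, 4)])
  }
}

#' Structured tetrahedral mesh of a cylinder
#'
#' Meshes the cylinder `0 <= z <= length`, `x^2 + y^2 <= radius^2` with a
#' structured disk triangulation extruded into prisms, each split into
#' three tetrahedra with globally consistent diagonals. Boundary facets are
#' labeled by z-coordinate: the `z = 0` disk is the `glottis`, the
#' `z = length` disk the `lips`, the lateral surface the `wall`.
#'
#' The polygonal approximation of the circular cross-section under-covers
#' the disk area by `(2 pi / (6 nr))^2 / 6`; the default edge target keeps
#' this below 1%.
#'
#' @param radius Cylinder radius in m.
#' @param length Cylinder length in m.
#' @param target_edge Target edge length in m (default 3 mm, the resolution
#'   appropriate for speech-band acoustics of a ~170 mm resonator).
#' @return A `labeled_mesh`.
#' @examples
#' m <- cylinder_mesh(0.0138, 0.170, target_edge = 6e-3)
#' @export
cylinder_mesh <- function(radius, length, target_edge = 3e-3) {
  stopifnot(radius > 0, length > 0, target_edge > 0)
  if (target_edge >= radius) stop("target_edge must be smaller than the radius")
  nr <- max(2L, ceiling(radius / target_edge))
  nz <- max(2L, ceiling(length / target_edge))
  disk <- disk_triangulation(radius, nr)
  nd <- nrow(disk$points)
  zs <- seq(0, length, length.out = nz + 1)
  nodes <- cbind(
    rep(disk$points[, 1], nz + 1),
    rep(disk$points[, 2], nz + 1),
    rep(zs, each = nd)
  )
  ntri <- nrow(disk$triangles)
  tets <- matrix(0L, nrow = 3 * ntri * nz, ncol = 4)
  t_i <- 0L
  for (l in seq_len(nz) - 1L) {
    off_b <- l * nd
    off_t <- (l + 1L) * nd
    for (t in seq_len(ntri)) {
      tri <- disk$triangles[t, ]
      split <- split_prism(c(tri + off_b, tri + off_t))
      tets[t_i + 1:3, ] <- split
      t_i <- t_i + 3L
    }
  }
  vol <- tet_volumes(nodes, tets)
  degen <- sum(vol <= 0 | !is.finite(vol))
  if (degen > 0) stop(sprintf("mesh has %d degenerate cells", degen))

  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "_"))
  once <- names(which(table(key) == 1))
  boundary <- faces[match(once, key), , drop = FALSE]
  z <- nodes[, 3]
  tol <- length * 1e-9
  lab <- apply(boundary, 1, function(f) {
    if (all(z[f] < tol)) "glottis"
    else if (all(z[f] > length - tol)) "lips"
    else "wall"
  })
  new_labeled_mesh(nodes, tets, boundary, lab)
}

# --- assembly ---------------------------------------------------------------

# Linear (P1) tetrahedral assembly of the stiffness and mass matrices, the
# boundary mass matrices for the wall and lips regions, and the glottal load
# vector (integral of each basis function over the glottis facets).
fem_assemble <- function(mesh) {
  nodes <- mesh$nodes; tets <- mesh$tets
  nn <- nrow(nodes); nt <- nrow(tets)

  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  det3 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  vol <- abs(det3) / 6
  # rows of inv(J)^T = gradients of barycentric coords 2..4; grad 1 = -sum
  cross_rows <- function(u, v) cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- cross_rows(e2, e3) / det3
  g3 <- cross_rows(e3, e1) / det3
  g4 <- cross_rows(e1, e2) / det3
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)

  ii <- matrix(0L, nt, 16); jj <- matrix(0L, nt, 16)
  kk <- matrix(0, nt, 16); mm <- matrix(0, nt, 16)
  col <- 0L
  for (p in 1:4) {
    for (q in 1:4) {
      col <- col + 1L
      ii[, col] <- tets[, p]
      jj[, col] <- tets[, q]
      kk[, col] <- vol * rowSums(grads[[p]] * grads[[q]])
      mm[, col] <- vol / 20 * (1 + (p == q))
    }
  }
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(kk), dims = c(nn, nn))
  M <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(mm), dims = c(nn, nn))

  surf_mass <- function(tris) {
    if (nrow(tris) == 0) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                                     dims = c(nn, nn)))
    ar <- tri_areas(nodes, tris)
    si <- integer(0); sj <- integer(0); sx <- numeric(0)
    for (p in 1:3) {
      for (q in 1:3) {
        si <- c(si, tris[, p]); sj <- c(sj, tris[, q])
        sx <- c(sx, ar / 12 * (1 + (p == q)))
      }
    }
    Matrix::sparseMatrix(i = si, j = sj, x = sx, dims = c(nn, nn))
  }
  wall_tris <- mesh$facets[mesh$facet_label == "wall", , drop = FALSE]
  lips_tris <- mesh$facets[mesh$facet_label == "lips", , drop = FALSE]
  glot_tris <- mesh$facets[mesh$facet_label == "glottis", , drop = FALSE]

  g_load <- numeric(nn)
  g_ar <- tri_areas(nodes, glot_tris)
  for (p in 1:3) {
    g_load <- g_load + as.numeric(
      tapply(c(g_ar / 3), factor(glot_tris[, p], levels = seq_len(nn)),
             sum, default = 0))
  }
  # lips averaging weights: integral of basis functions over lips facets
  l_load <- numeric(nn)
  if (nrow(lips_tris) > 0) {
    l_ar <- tri_areas(nodes, lips_tris)
    for (p in 1:3) {
      l_load <- l_load + as.numeric(
        tapply(c(l_ar / 3), factor(lips_tris[, p], levels = seq_len(nn)),
               sum, default = 0))
    }
  }
  ar <- boundary_areas(mesh)
  B_wall <- surf_mass(wall_tris)
  B_lips <- surf_mass(lips_tris)
  out <- list(K = K, M = M, B_wall = B_wall, B_lips = B_lips,
              g_load = g_load, lips_weights = l_load, areas = ar)
  out$band <- band_layout(K, M, B_wall, B_lips, nn)
  out
}

# Precompute the LAPACK band-storage layout of the per-frequency system
# K - kap^2 M + cw B_wall + cl B_lips. All four matrices share (a subset
# of) one sparsity pattern; with the layered node ordering of the
# structured cylinder mesh the bandwidth is small and a banded complex LU
# (zgbsv) factors several times faster than a sparse LU on the equivalent
# real 2n system. Meshes with wide orderings fall back to the sparse path.
band_layout <- function(K, M, B_wall, B_lips, nn) {
  U <- abs(K) + abs(M) + abs(B_wall) + abs(B_lips)
  Ut <- methods::as(U, "TsparseMatrix")
  i <- Ut@i + 1L; j <- Ut@j + 1L
  kl <- max(abs(i - j))
  ldab <- 3L * kl + 1L
  if (as.double(ldab) * nn > 6e7) return(NULL)  # band too wide to pay off
  aligned <- function(X) {
    Xt <- methods::as(X, "TsparseMatrix")
    v <- numeric(length(i))
    v[match((Xt@j) * nn + Xt@i, (j - 1L) * nn + (i - 1L))] <- Xt@x
    v
  }
  list(kl = kl, ku = kl, ldab = ldab, n = nn,
       fill_idx = (j - 1L) * ldab + (2L * kl + 1L + i - j),
       kx = aligned(K), mx = aligned(M),
       bwx = aligned(B_wall), blx = aligned(B_lips))
}

band_solve <- function(band, kap, cw, cl, b) {
  vals <- band$kx - kap^2 * band$mx + cw * band$bwx + cl * band$blx
  ab <- matrix(0i, nrow = band$ldab, ncol = band$n)
  ab[band$fill_idx] <- vals
  banded_solve_cpp(ab, as.complex(b), band$kl, band$ku)
}

# solve the complex sparse system (Ar + i Ai) x = br + i bi through the
# equivalent real 2n x 2n block system
solve_complex_sparse <- function(Ar, Ai, br, bi) {
  big <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  rhs <- c(br, bi)
  x <- Matrix::solve(big, rhs)
  n <- length(br)
  complex(real = x[seq_len(n)], imaginary = x[n + seq_len(n)])
}

#' Solve the interior Helmholtz problem at one frequency
#'
#' Solves `-(kappa^2 + Laplacian) P = 0` with first-order tetrahedral
#' elements and the boundary conditions of an externally hard-driven
#' resonator (time convention `e^{+j omega t}`):
#' * glottis: prescribed normal velocity `V0` into the tract
#'   (`grad P . n = j omega rho V0` with the outward normal),
#' * wall: impedance condition `grad P . n = -(j kappa rho c / Zwall) P`,
#' * lips: radiation condition with the piston specific impedance `Zr`.
#'
#' Passing `Inf` for `zwall` or `zr` makes that surface rigid.
#'
#' @param mesh A `labeled_mesh`.
#' @param frequency_hz Single frequency in Hz, > 0.
#' @param constants An [acoustic_constants()] object.
#' @param zwall Specific wall impedance (Pa s/m), possibly complex or `Inf`.
#' @param zr Specific radiation impedance at this frequency (Pa s/m),
#'   possibly complex or `Inf`; defaults to the piston-in-baffle value for
#'   the lips area.
#' @param v0 Glottal normal velocity amplitude in m/s (cancels in transfer
#'   functions).
#' @param assembly Optional precomputed result of the internal assembly
#'   (reused across frequencies by [fem_transfer_function()]).
#' @return A list of class `fem_solution`: `p` (complex nodal pressure),
#'   `p_lips` (area-averaged lips pressure), `u_glottis`, `u_lips`, `h`
#'   (their ratio), `frequency_hz`, plus the glottal input impedance
#'   `z_in_glottis` (acoustic).
#' @export
solve_helmholtz <- function(mesh, frequency_hz,
                            constants = acoustic_constants(),
                            zwall = default_wall_impedance(constants),
                            zr = NULL, v0 = 1, assembly = NULL) {
  stopifnot(length(frequency_hz) == 1L, frequency_hz > 0, v0 != 0)
  if (is.null(assembly)) assembly <- fem_assemble(mesh)
  a <- assembly
  rho <- constants$density; c0 <- constants$speed_of_sound
  w <- omega(frequency_hz); kap <- w / c0
  if (is.null(zr)) {
    zr <- piston_in_baffle(freq_grid(frequency_hz),
                           effective_radius(a$areas[["lips"]]), constants)$z
  }
  if (any(zwall == 0) || any(zr == 0)) stop("zwall and zr must be nonzero")

  cw <- if (is.infinite(Mod(zwall))) 0 + 0i else 1i * kap * rho * c0 / zwall
  cl <- if (is.infinite(Mod(zr))) 0 + 0i else 1i * kap * rho * c0 / zr
  # weak form: int grad P . grad v - kap^2 int P v + cw int_wall P v
  #            + cl int_lips P v = j omega rho V0 int_glottis v
  b <- 1i * w * rho * v0 * a$g_load
  p <- tryCatch({
    if (!is.null(a$band)) {
      band_solve(a$band, kap, cw, cl, b)
    } else {
      Ar <- a$K - kap^2 * a$M + Re(cw) * a$B_wall + Re(cl) * a$B_lips
      Ai <- Im(cw) * a$B_wall + Im(cl) * a$B_lips
      solve_complex_sparse(Ar, Ai, Re(b), Im(b))
    }
  }, error = function(e) stop(
    "Helmholtz system could not be solved (lossless configuration at an exact resonance?); shift the frequency: ",
    conditionMessage(e)))

  a_lips <- a$areas[["lips"]]; a_glot <- a$areas[["glottis"]]
  p_lips <- sum(a$lips_weights * p) / a_lips
  u_glottis <- a_glot * v0
  v_lips <- if (is.infinite(Mod(zr))) 0 + 0i else p_lips / zr
  u_lips <- a_lips * v_lips
  p_glottis <- sum(a$g_load * p) / a_glot
  structure(list(
    frequency_hz = frequency_hz, p = p,
    p_lips = p_lips, p_glottis = p_glottis,
    u_glottis = u_glottis, u_lips = u_lips,
    h = u_lips / u_glottis,
    z_in_glottis = p_glottis / u_glottis
  ), class = "fem_solution")
}

#' Volume-velocity transfer function from the FEM reference model
#'
#' Solves the Helmholtz problem at each grid frequency with the piston
#' radiation load recomputed per frequency from the lips area, and returns
#' `H_FEM = U_lips / U_glottis`. The glottal drive `V0` cancels.
#'
#' @param mesh A `labeled_mesh`.
#' @param frequencies_hz Frequency grid (Hz).
#' @param constants An [acoustic_constants()] object.
#' @param zwall Specific wall impedance (Pa s/m); `Inf` for rigid walls.
#' @return A [transfer_function()] with provenance `"fem"`.
#' @export
fem_transfer_function <- function(mesh, frequencies_hz,
                                  constants = acoustic_constants(),
                                  zwall = default_wall_impedance(constants)) {
  f <- freq_grid(frequencies_hz)
  assembly <- fem_assemble(mesh)
  r_lips <- effective_radius(assembly$areas[["lips"]])
  zr <- piston_in_baffle(f, r_lips, constants)
  h <- vapply(seq_along(f), function(i) {
    solve_helmholtz(mesh, f[i], constants, zwall = zwall, zr = zr$z[i],
                    assembly = assembly)$h
  }, complex(1))
  transfer_function(f, h, provenance = "fem")
}

#' Single-frequency FEM evaluator
#'
#' Returns a function `h(f)` evaluating the FEM transfer function at
#' arbitrary single frequencies, with the assembly done once. Used for
#' coarse-scan-plus-refinement formant extraction, which visits far fewer
#' frequencies than a dense grid.
#'
#' @inheritParams fem_transfer_function
#' @return A function mapping a frequency (Hz) to a complex `H` value.
#' @export
fem_solver_function <- function(mesh, constants = acoustic_constants(),
                                zwall = default_wall_impedance(constants)) {
  assembly <- fem_assemble(mesh)
  r_lips <- effective_radius(assembly$areas[["lips"]])
  function(f) {
    zr <- piston_in_baffle(freq_grid(f), r_lips, constants)$z
    solve_helmholtz(mesh, f, constants, zwall = zwall, zr = zr,
                    assembly = assembly)$h
  }
}
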