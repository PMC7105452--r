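#' Finite element spaces on simplicial meshes
#'
#' Scalar Lagrange spaces of degree 1 or 2 (continuous), used for
#' displacement components, pressure and the electrophysiology fields; the
#' Kirchhoff stress lives in the discontinuous cell-wise space of degree
#' l = degree - 1 and is condensed out inside the assembly kernels.
#'
#' @param mesh a `cem_mesh`
#' @param degree polynomial degree (1 or 2)
#' @return list of class `cem_space` with the cell dof map, total dof count
#'   and dof coordinates
#' @export
build_space <- function(mesh, degree) {
  stopifnot(degree %in% c(1, 2))
  d <- mesh$d
  if (degree == 1) {
    sp <- list(mesh = mesh, degree = 1, dof = mesh$cells, ndof = mesh$np,
               node_coords = mesh$coords)
  } else {
    epairs <- if (d == 2) list(c(1, 2), c(2, 3), c(1, 3))
              else list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    ne <- length(epairs)
    a <- do.call(cbind, lapply(epairs, function(pp)
      pmin(mesh$cells[, pp[1]], mesh$cells[, pp[2]])))
    b <- do.call(cbind, lapply(epairs, function(pp)
      pmax(mesh$cells[, pp[1]], mesh$cells[, pp[2]])))
    key <- as.vector(a) * (mesh$np + 1) + as.vector(b)
    uk <- unique(key)
    eid <- match(key, uk)
    edof <- matrix(eid, mesh$nc, ne) + mesh$np
    ia <- as.vector(a)[match(uk, key)]
    ib <- as.vector(b)[match(uk, key)]
    mid <- (mesh$coords[ia, , drop = FALSE] +
            mesh$coords[ib, , drop = FALSE]) / 2
    sp <- list(mesh = mesh, degree = 2,
               dof = cbind(mesh$cells, edof),
               ndof = mesh$np + length(uk),
               node_coords = rbind(mesh$coords, mid))
  }
  storage.mode(sp$dof) <- "integer"
  sp$nb <- ncol(sp$dof)
  sp$geom <- mesh_geom(mesh)
  class(sp) <- "cem_space"
  sp
}

# per-cell affine geometry: detJ (vector) and Jginv (nc x d x d array)
mesh_geom <- function(mesh) {
  d <- mesh$d
  nc <- mesh$nc
  Jg <- array(0, c(nc, d, d))
  v0 <- mesh$coords[mesh$cells[, 1], , drop = FALSE]
  for (j in seq_len(d))
    Jg[, , j] <- mesh$coords[mesh$cells[, j + 1], , drop = FALSE] - v0
  if (d == 2) {
    det <- Jg[, 1, 1] * Jg[, 2, 2] - Jg[, 2, 1] * Jg[, 1, 2]
    inv <- array(0, c(nc, d, d))
    inv[, 1, 1] <- Jg[, 2, 2] / det
    inv[, 1, 2] <- -Jg[, 1, 2] / det
    inv[, 2, 1] <- -Jg[, 2, 1] / det
    inv[, 2, 2] <- Jg[, 1, 1] / det
  } else {
    a <- Jg[, , 1]; b <- Jg[, , 2]; ccol <- Jg[, , 3]
    cx <- cbind(b[, 2] * ccol[, 3] - b[, 3] * ccol[, 2],
                b[, 3] * ccol[, 1] - b[, 1] * ccol[, 3],
                b[, 1] * ccol[, 2] - b[, 2] * ccol[, 1])
    det <- rowSums(a * cx)
    inv <- array(0, c(nc, d, d))
    # rows of the inverse are cross products of columns / det
    r1 <- cx
    r2 <- cbind(ccol[, 2] * a[, 3] - ccol[, 3] * a[, 2],
                ccol[, 3] * a[, 1] - ccol[, 1] * a[, 3],
                ccol[, 1] * a[, 2] - ccol[, 2] * a[, 1])
    r3 <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    inv[, 1, ] <- r1 / det
    inv[, 2, ] <- r2 / det
    inv[, 3, ] <- r3 / det
  }
  list(detJ = det, Jginv = inv, v0 = v0)
}

# --- quadrature -------------------------------------------------------------

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch)
gauss01 <- function(n) {
  if (n == 1) return(list(x = 0.5, w = 1))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  x <- (rev(e$values) + 1) / 2
  w <- 2 * (e$vectors[1, ncol(e$vectors):1])^2 / 2
  list(x = x, w = w)
}

#' Quadrature rule on the reference simplex
#'
#' Conical-product (Duffy-mapped Gauss) rule exact for polynomials of at
#' least the requested degree.
#'
#' @param d dimension (2 or 3)
#' @param degree polynomial degree to integrate exactly
#' @return list with points (nq x d, barycentric-free reference coords) and
#'   weights summing to the reference simplex volume
#' @export
simplex_quadrature <- function(d, degree) {
  if (d == 2 && degree <= 6) return(triangle_rule(degree))
  if (d == 3 && degree <= 4) return(tet_rule(degree))
  ng <- ceiling((degree + d) / 2) + 1
  g <- gauss01(ng)
  if (d == 2) {
    u <- rep(g$x, each = ng); vv <- rep(g$x, times = ng)
    wu <- rep(g$w, each = ng); wv <- rep(g$w, times = ng)
    x <- u
    y <- vv * (1 - u)
    w <- wu * wv * (1 - u)
    list(points = cbind(x, y), weights = w)
  } else {
    u <- rep(g$x, each = ng * ng)
    vv <- rep(rep(g$x, each = ng), times = ng)
    ww <- rep(g$x, times = ng * ng)
    wu <- rep(g$w, each = ng * ng)
    wv <- rep(rep(g$w, each = ng), times = ng)
    wz <- rep(g$w, times = ng * ng)
    x <- u
    y <- vv * (1 - u)
    z <- ww * (1 - u) * (1 - vv)
    w <- wu * wv * wz * (1 - u)^2 * (1 - vv)
    list(points = cbind(x, y, z), weights = w)
  }
}

# symmetric Gauss rules on the reference triangle (weights sum to 1/2)
triangle_rule <- function(degree) {
  if (degree <= 1) {
    pts <- matrix(c(1/3, 1/3), 1)
    w <- 0.5
  } else if (degree <= 2) {
    pts <- rbind(c(1/6, 1/6), c(2/3, 1/6), c(1/6, 2/3))
    w <- rep(1/6, 3)
  } else if (degree <= 4) {
    a <- 0.445948490915965; b <- 0.091576213509771
    pts <- rbind(c(a, a), c(1 - 2*a, a), c(a, 1 - 2*a),
                 c(b, b), c(1 - 2*b, b), c(b, 1 - 2*b))
    w <- 0.5 * c(rep(0.223381589678011, 3), rep(0.109951743655322, 3))
  } else {
    a1 <- 0.249286745170910; a2 <- 0.063089014491502
    b1 <- 0.310352451033785; b2 <- 0.053145049844816
    pts <- rbind(c(a1, a1), c(1 - 2*a1, a1), c(a1, 1 - 2*a1),
                 c(a2, a2), c(1 - 2*a2, a2), c(a2, 1 - 2*a2),
                 c(b1, b2), c(b2, b1), c(1 - b1 - b2, b1),
                 c(b1, 1 - b1 - b2), c(b2, 1 - b1 - b2),
                 c(1 - b1 - b2, b2))
    w <- 0.5 * c(rep(0.116786275726379, 3), rep(0.050844906370207, 3),
                 rep(0.082851075618374, 6))
  }
  list(points = pts, weights = w)
}

# symmetric rules on the reference tetrahedron (weights sum to 1/6)
tet_rule <- function(degree) {
  if (degree <= 1) {
    pts <- matrix(1/4, 1, 3)
    w <- 1/6
  } else if (degree <= 2) {
    a <- (5 + 3 * sqrt(5)) / 20
    b <- (5 - sqrt(5)) / 20
    pts <- rbind(c(a, b, b), c(b, a, b), c(b, b, a), c(b, b, b))
    w <- rep(1/24, 4)
  } else {
    # 11-point degree-4 rule (one negative centroid weight)
    a <- 0.0714285714285714; b <- 0.785714285714286
    c1 <- 0.399403576166799; c2 <- 0.100596423833201
    pts <- rbind(
      c(1/4, 1/4, 1/4),
      c(a, a, a), c(b, a, a), c(a, b, a), c(a, a, b),
      c(c1, c1, c2), c(c1, c2, c1), c(c2, c1, c1),
      c(c2, c2, c1), c(c2, c1, c2), c(c1, c2, c2))
    w <- c(-0.0131555555555556, rep(0.00762222222222222, 4),
           rep(0.0248888888888889, 6))
  }
  list(points = pts, weights = w)
}

#' Reference basis functions
#'
#' Values and reference gradients of the P1/P2 Lagrange basis at given
#' reference points.
#'
#' @param d dimension; @param degree 1 or 2
#' @param pts reference coordinates (nq x d)
#' @return list `phi` (nq x nb), `dphi` (nq x nb x d array)
#' @export
basis_eval <- function(d, degree, pts) {
  nq <- nrow(pts)
  if (d == 2) {
    x <- pts[, 1]; y <- pts[, 2]
    lam <- cbind(1 - x - y, x, y)
    dlam <- rbind(c(-1, -1), c(1, 0), c(0, 1))
  } else {
    x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
    lam <- cbind(1 - x - y - z, x, y, z)
    dlam <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  }
  nv <- d + 1
  if (degree == 1) {
    phi <- lam
    dphi <- array(0, c(nq, nv, d))
    for (a in seq_len(nv)) for (k in seq_len(d)) dphi[, a, k] <- dlam[a, k]
    return(list(phi = phi, dphi = dphi))
  }
  epairs <- if (d == 2) list(c(1, 2), c(2, 3), c(1, 3))
            else list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  nb <- nv + length(epairs)
  phi <- matrix(0, nq, nb)
  dphi <- array(0, c(nq, nb, d))
  for (a in seq_len(nv)) {
    phi[, a] <- lam[, a] * (2 * lam[, a] - 1)
    for (k in seq_len(d))
      dphi[, a, k] <- (4 * lam[, a] - 1) * dlam[a, k]
  }
  for (e in seq_along(epairs)) {
    i <- epairs[[e]][1]; j <- epairs[[e]][2]
    phi[, nv + e] <- 4 * lam[, i] * lam[, j]
    for (k in seq_len(d))
      dphi[, nv + e, k] <- 4 * (lam[, j] * dlam[i, k] + lam[, i] * dlam[j, k])
  }
  list(phi = phi, dphi = dphi)
}

# basis tables bundle passed to the C++ kernels
basis_tables <- function(d, degree, quad) {
  be <- basis_eval(d, degree, quad$points)
  list(phi = be$phi, dphi = be$dphi, qw = quad$weights)
}

# P_l basis (for the condensed Kirchhoff stress space) at quadrature points
pi_phi <- function(d, l, quad) {
  if (l == 0) matrix(1, nrow(quad$points), 1)
  else basis_eval(d, 1, quad$points)$phi
}

# --- generic scalar-space assembly (vectorised over cells) ------------------

# physical coordinates of all cell quadrature points, stacked cell-major
cell_qpoints <- function(space, quad) {
  m <- space$mesh
  d <- m$d
  nq <- nrow(quad$points)
  out <- matrix(0, m$nc * nq, d)
  g <- space$geom
  for (q in seq_len(nq)) {
    xq <- g$v0
    for (j in seq_len(d))
      xq <- xq + quad$points[q, j] *
        (m$coords[m$cells[, j + 1], , drop = FALSE] - g$v0)
    out[(seq_len(m$nc) - 1) * nq + q, ] <- xq
  }
  out
}

# interpolate nodal field x to cell quadrature points -> nc x nq matrix
field_at_qp <- function(space, tables, x) {
  nq <- nrow(tables$phi)
  out <- matrix(0, space$mesh$nc, nq)
  for (q in seq_len(nq)) {
    acc <- 0
    for (a in seq_len(space$nb))
      acc <- acc + tables$phi[q, a] * x[space$dof[, a]]
    out[, q] <- acc
  }
  out
}

# consistent mass, stiffness and h^2-weighted stiffness for a scalar space
scalar_matrices <- function(space, quad = NULL) {
  m <- space$mesh
  d <- m$d
  if (is.null(quad)) quad <- simplex_quadrature(d, 2 * space$degree)
  tb <- basis_tables(d, space$degree, quad)
  nq <- length(tb$qw)
  nb <- space$nb
  g <- space$geom
  h2 <- cell_h(m)^2
  iM <- jM <- xM <- xK <- xS <- NULL
  ii <- matrix(0L, m$nc, 0)
  # physical gradients per qp: list over q of list over a of nc x d
  for (q in seq_len(nq)) {
    gphys <- vector("list", nb)
    for (a in seq_len(nb)) {
      ga <- matrix(0, m$nc, d)
      for (k in seq_len(d)) for (mm in seq_len(d))
        ga[, k] <- ga[, k] + tb$dphi[q, a, mm] * g$Jginv[, mm, k]
      gphys[[a]] <- ga
    }
    for (a in seq_len(nb)) for (b in seq_len(nb)) {
      mval <- tb$qw[q] * tb$phi[q, a] * tb$phi[q, b] * g$detJ
      kval <- tb$qw[q] * rowSums(gphys[[a]] * gphys[[b]]) * g$detJ
      iM <- c(iM, space$dof[, a]); jM <- c(jM, space$dof[, b])
      xM <- c(xM, mval); xK <- c(xK, kval); xS <- c(xS, kval * h2)
    }
  }
  M <- Matrix::sparseMatrix(i = iM, j = jM, x = xM,
                            dims = c(space$ndof, space$ndof))
  K <- Matrix::sparseMatrix(i = iM, j = jM, x = xK,
                            dims = c(space$ndof, space$ndof))
  S <- Matrix::sparseMatrix(i = iM, j = jM, x = xS,
                            dims = c(space$ndof, space$ndof))
  list(M = M, K = K, Kh2 = S, ML = Matrix::rowSums(M))
}

# load vector int c(x) phi_a with c given at cell quadrature points
# (cvals: nc x nq)
load_vector <- function(space, tables, cvals) {
  g <- space$geom
  nq <- length(tables$qw)
  out <- numeric(space$ndof)
  for (a in seq_len(space$nb)) {
    contrib <- as.vector(cvals %*% (tables$qw * tables$phi[, a])) * g$detJ
    out <- out + unname(
      rowsum_vec(contrib, space$dof[, a], space$ndof))
  }
  out
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

# evaluate a nodal field and its gradient at cell quadrature points
field_grad_at_qp <- function(space, tables, x) {
  m <- space$mesh
  d <- m$d
  nq <- length(tables$qw)
  g <- space$geom
  val <- matrix(0, m$nc, nq)
  grad <- array(0, c(m$nc, nq, d))
  for (q in seq_len(nq)) {
    acc <- 0
    gacc <- matrix(0, m$nc, d)
    for (a in seq_len(space$nb)) {
      xa <- x[space$dof[, a]]
      acc <- acc + tables$phi[q, a] * xa
      for (k in seq_len(d)) {
        gref <- 0
        for (mm in seq_len(d))
          gref <- gref + tables$dphi[q, a, mm] * g$Jginv[, mm, k]
        gacc[, k] <- gacc[, k] + gref * xa
      }
    }
    val[, q] <- acc
    grad[, q, ] <- gacc
  }
  list(val = val, grad = grad)
}
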