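#' Structured simplicial meshes
#'
#' Triangulations of rectangles (all diagonals in the same direction, so the
#' mesh size h is the diagonal length), the Cook membrane quadrilateral, and
#' Kuhn tetrahedralisations of boxes. Coordinates in mm.
#'
#' @param nx,ny,nz subdivisions per direction
#' @param Lx,Ly,Lz side lengths (mm)
#' @param x0,y0 origin offset
#' @return list of class `cem_mesh` with `coords`, `cells`, `d`, boundary
#'   facet table (`bfacets`, `bparent`, `bnormal`, `blabel`)
#' @export
rect_mesh <- function(nx, ny = nx, Lx = 1, Ly = Lx, x0 = 0, y0 = 0) {
  stopifnot(nx >= 1, ny >= 1)
  xs <- seq(x0, x0 + Lx, length.out = nx + 1)
  ys <- seq(y0, y0 + Ly, length.out = ny + 1)
  coords <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  vid <- function(i, j) (j - 1) * (nx + 1) + i
  cells <- matrix(0L, 2 * nx * ny, 3)
  k <- 1
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    v00 <- vid(i, j); v10 <- vid(i + 1, j)
    v01 <- vid(i, j + 1); v11 <- vid(i + 1, j + 1)
    cells[k, ] <- c(v00, v10, v11)
    cells[k + 1, ] <- c(v00, v11, v01)
    k <- k + 2
  }
  new_mesh(coords, cells)
}

#' @rdname rect_mesh
#' @param n subdivisions of the unit square per direction
#' @export
unit_square_mesh <- function(n) rect_mesh(n, n, 1, 1)

#' @rdname rect_mesh
#' @export
box_mesh <- function(nx, ny, nz, Lx, Ly, Lz) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  zs <- seq(0, Lz, length.out = nz + 1)
  coords <- cbind(rep(xs, times = (ny + 1) * (nz + 1)),
                  rep(rep(ys, each = nx + 1), times = nz + 1),
                  rep(zs, each = (nx + 1) * (ny + 1)))
  vid <- function(i, j, k)
    (k - 1) * (nx + 1) * (ny + 1) + (j - 1) * (nx + 1) + i
  # Kuhn decomposition: six tetrahedra per cube along vertex-ordered paths
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- matrix(0L, 6 * nx * ny * nz, 4)
  row <- 1
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    base <- c(i, j, k)
    for (pm in perms) {
      idx <- matrix(base, 4, 3, byrow = TRUE)
      for (s in 1:3) idx[(s + 1):4, pm[s]] <- idx[(s + 1):4, pm[s]] + 1
      cells[row, ] <- c(vid(idx[1, 1], idx[1, 2], idx[1, 3]),
                        vid(idx[2, 1], idx[2, 2], idx[2, 3]),
                        vid(idx[3, 1], idx[3, 2], idx[3, 3]),
                        vid(idx[4, 1], idx[4, 2], idx[4, 3]))
      row <- row + 1
    }
  }
  new_mesh(coords, cells)
}

#' @rdname rect_mesh
#' @param n subdivisions per direction of the Cook membrane (convex hull of
#'   (0,0), (48,44), (48,60), (0,44), mm)
#' @export
cook_mesh <- function(n) {
  m <- unit_square_mesh(n)
  xi <- m$coords[, 1]; eta <- m$coords[, 2]
  # bilinear map of the unit square onto the tapered panel
  x <- 48 * xi
  y <- (1 - eta) * (44 * xi) + eta * (44 + 16 * xi)
  m$coords <- cbind(x, y)
  new_mesh(m$coords, m$cells)
}

# construct mesh object: orient cells positively, extract boundary facets
new_mesh <- function(coords, cells) {
  d <- ncol(coords)
  storage.mode(cells) <- "integer"
  # positive orientation
  for (pass in 1) {
    v0 <- coords[cells[, 1], , drop = FALSE]
    if (d == 2) {
      e1 <- coords[cells[, 2], ] - v0
      e2 <- coords[cells[, 3], ] - v0
      det <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    } else {
      e1 <- coords[cells[, 2], ] - v0
      e2 <- coords[cells[, 3], ] - v0
      e3 <- coords[cells[, 4], ] - v0
      det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
             e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
             e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
    }
    flip <- det < 0
    if (any(flip)) {
      tmp <- cells[flip, 2]
      cells[flip, 2] <- cells[flip, 3]
      cells[flip, 3] <- tmp
    }
  }
  m <- list(coords = coords, cells = cells, d = d,
            np = nrow(coords), nc = nrow(cells))
  bf <- find_boundary_facets(m)
  m$bfacets <- bf$facets
  m$bparent <- bf$parent
  m$bnormal <- bf$normal
  m$blabel <- rep("N", nrow(bf$facets))
  class(m) <- "cem_mesh"
  m
}

# facets appearing in exactly one cell, with outward reference normals
find_boundary_facets <- function(m) {
  d <- m$d
  nc <- m$nc
  loc <- if (d == 2) list(c(1, 2), c(2, 3), c(3, 1))
         else list(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  nf <- length(loc)
  allf <- do.call(rbind, lapply(loc, function(ix) m$cells[, ix, drop = FALSE]))
  parent <- rep(seq_len(nc), times = nf)
  key <- apply(allf, 1, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  keep <- key %in% names(tab)[tab == 1]
  facets <- allf[keep, , drop = FALSE]
  parent <- parent[keep]
  # outward unit normal: perpendicular to the facet, pointing away from the
  # cell centroid
  nrm <- matrix(0, nrow(facets), d)
  for (i in seq_len(nrow(facets))) {
    pts <- m$coords[facets[i, ], , drop = FALSE]
    if (d == 2) {
      tangent <- pts[2, ] - pts[1, ]
      nvec <- c(tangent[2], -tangent[1])
    } else {
      nvec <- pracma_cross(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
    }
    nvec <- nvec / sqrt(sum(nvec^2))
    centroid <- colMeans(m$coords[m$cells[parent[i], ], , drop = FALSE])
    if (sum(nvec * (colMeans(pts) - centroid)) < 0) nvec <- -nvec
    nrm[i, ] <- nvec
  }
  list(facets = facets, parent = parent, normal = nrm)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Label boundary facets
#'
#' Assigns labels ("D", "N", "R", or experiment-specific tags) to boundary
#' facets whose centroid satisfies a predicate.
#'
#' @param mesh a `cem_mesh`
#' @param label label string
#' @param where predicate on facet centroid coordinates (matrix rows)
#' @export
label_boundary <- function(mesh, label, where) {
  cen <- facet_centroids(mesh)
  sel <- where(cen)
  mesh$blabel[sel] <- label
  mesh
}

facet_centroids <- function(mesh) {
  t(vapply(seq_len(nrow(mesh$bfacets)), function(i)
    colMeans(mesh$coords[mesh$bfacets[i, ], , drop = FALSE]),
    numeric(mesh$d)))
}

#' Mesh size
#'
#' Longest edge over all cells (the convention used to report h).
#' @param mesh a `cem_mesh`
#' @export
mesh_h <- function(mesh) {
  d <- mesh$d
  hmax <- 0
  pairs <- utils::combn(d + 1, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- mesh$coords[mesh$cells[, pairs[1, k]], , drop = FALSE]
    b <- mesh$coords[mesh$cells[, pairs[2, k]], , drop = FALSE]
    hmax <- max(hmax, sqrt(max(rowSums((a - b)^2))))
  }
  hmax
}

# per-cell longest edge (for the stabilisation weights)
cell_h <- function(mesh) {
  d <- mesh$d
  pairs <- utils::combn(d + 1, 2)
  h2 <- 0
  for (k in seq_len(ncol(pairs))) {
    a <- mesh$coords[mesh$cells[, pairs[1, k]], , drop = FALSE]
    b <- mesh$coords[mesh$cells[, pairs[2, k]], , drop = FALSE]
    h2 <- pmax(h2, rowSums((a - b)^2))
  }
  sqrt(h2)
}

#' Uniform refinement (2D)
#'
#' @param mesh triangle mesh
#' @export
refine_mesh <- function(mesh) {
  stopifnot(mesh$d == 2)
  sp <- build_space(mesh, degree = 2)  # edge midpoints already built there
  mid <- sp$node_coords[-seq_len(mesh$np), , drop = FALSE]
  coords <- rbind(mesh$coords, mid)
  cells <- NULL
  em <- sp$dof[, 4:6, drop = FALSE]  # midpoint ids per cell (global)
  c1 <- mesh$cells
  cells <- rbind(cbind(c1[, 1], em[, 1], em[, 3]),
                 cbind(em[, 1], c1[, 2], em[, 2]),
                 cbind(em[, 3], em[, 2], c1[, 3]),
                 cbind(em[, 1], em[, 2], em[, 3]))
  new_mesh(coords, cells)
}
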