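## Linear (P1) triangle finite-element core shared by the fluid and solid
## solvers: per-cell geometry, vectorized sparse assembly, boundary-edge
## quadrature, Dirichlet handling, and region submeshes.  All assembly is in
## SI units (coordinates converted mm -> m here and nowhere else).

#' @import Matrix
#' @importFrom methods as new
NULL

## dense numeric solve against a cached sparse LU factor
solve_lu <- function(lu, b) as.numeric(Matrix::solve(lu, b))

## row equilibration: scale each row by 1/max|entry| so blocks of very
## different physical magnitude (elastic stress vs Darcy flux) factor
## cleanly; the rhs must be scaled by the same factors before solving
row_equilibrate <- function(A) {
  tr <- Matrix::summary(A)
  rmax <- rep(1, nrow(A))
  agg <- tapply(abs(tr$x), tr$i, max)
  rmax[as.integer(names(agg))] <- pmax(agg, 1e-300)
  D <- Matrix::Diagonal(x = 1 / rmax)
  list(A = D %*% A, scale = 1 / rmax)
}

## per-cell P1 geometry on SI coordinates
fem_geom <- function(vertices_m, cells) {
  x <- vertices_m[, 1]; y <- vertices_m[, 2]
  a <- cells[, 1]; b <- cells[, 2]; c3 <- cells[, 3]
  det2 <- (x[b] - x[a]) * (y[c3] - y[a]) - (x[c3] - x[a]) * (y[b] - y[a])
  area <- 0.5 * det2                       # cells oriented CCW upstream
  bx <- cbind(y[b] - y[c3], y[c3] - y[a], y[a] - y[b]) / det2
  by <- cbind(x[c3] - x[b], x[a] - x[c3], x[b] - x[a]) / det2
  list(area = area, bx = bx, by = by, cells = cells,
       n_nodes = nrow(vertices_m))
}

## sparse matrix from per-cell local blocks: loc[[i]][[j]] or function
## giving vectorized entries local(i, j) -> numeric(m)
assemble_cells <- function(geom, local, n = geom$n_nodes, nloc = 3,
                           rows = geom$cells, cols = geom$cells) {
  m <- nrow(rows)
  ii <- jj <- xx <- vector("list", nloc * nloc)
  k <- 0
  for (i in seq_len(nloc)) for (j in seq_len(nloc)) {
    k <- k + 1
    ii[[k]] <- rows[, i]; jj[[k]] <- cols[, j]
    xx[[k]] <- local(i, j)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

## scalar stiffness:  sum_c coef_c int grad(phi_i).grad(phi_j)
assemble_stiffness <- function(geom, coef = 1) {
  cf <- coef * geom$area
  assemble_cells(geom, function(i, j)
    cf * (geom$bx[, i] * geom$bx[, j] + geom$by[, i] * geom$by[, j]))
}

## scalar consistent mass:  sum_c coef_c int phi_i phi_j
assemble_mass <- function(geom, coef = 1) {
  cf <- coef * geom$area / 12
  assemble_cells(geom, function(i, j) cf * (1 + (i == j)))
}

## advection:  int phi_i (a . grad phi_j), a piecewise-constant per cell
assemble_advection <- function(geom, ax, ay) {
  cf <- geom$area / 3
  assemble_cells(geom, function(i, j)
    cf * (ax * geom$bx[, j] + ay * geom$by[, j]))
}

## pressure-velocity coupling: rows pressure nodes, cols velocity nodes,
## entries  int phi_i d(phi_j)/dx  (or /dy)
assemble_grad_coupling <- function(geom, which = c("x", "y")) {
  d <- if (match.arg(which) == "x") geom$bx else geom$by
  cf <- geom$area / 3
  assemble_cells(geom, function(i, j) cf * d[, j])
}

## load vector from per-cell constant source:  int f phi_i
assemble_source <- function(geom, f_cell) {
  v <- numeric(geom$n_nodes)
  for (i in 1:3) {
    contrib <- f_cell * geom$area / 3
    v <- v + tabulate_add(geom$cells[, i], contrib, geom$n_nodes)
  }
  v
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

## boundary edge geometry: lengths (m) and outward normals w.r.t. the
## adjacent cell of each facet row (facets: n1, n2, cell)
edge_geom <- function(vertices_m, facets, centroids_m) {
  p1 <- vertices_m[facets$n1, , drop = FALSE]
  p2 <- vertices_m[facets$n2, , drop = FALSE]
  tx <- p2[, 1] - p1[, 1]; ty <- p2[, 2] - p1[, 2]
  len <- sqrt(tx^2 + ty^2)
  nx <- ty / len; ny <- -tx / len
  mx <- 0.5 * (p1[, 1] + p2[, 1]); my <- 0.5 * (p1[, 2] + p2[, 2])
  cx <- centroids_m[facets$cell, 1]; cy <- centroids_m[facets$cell, 2]
  flip <- (mx - cx) * nx + (my - cy) * ny < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  list(len = len, nx = nx, ny = ny, mx = mx, my = my)
}

## distribute an edgewise-constant flux density g [unit/m] to nodes:
## node gets g * len / 2 from each adjacent tagged edge
edge_load <- function(facets, eg, g, n) {
  tabulate_add(c(facets$n1, facets$n2), rep(g * eg$len / 2, 2), n)
}

## apply Dirichlet conditions by row replacement (matrix keeps its sparsity
## pattern; columns retained, solved with sparse LU)
apply_dirichlet <- function(A, rhs, dofs, values) {
  if (length(dofs) == 0) return(list(A = A, rhs = rhs))
  A[dofs, ] <- 0
  A[cbind(dofs, dofs)] <- 1
  rhs[dofs] <- values
  list(A = A, rhs = rhs)
}

## extract the subproblem a solver works on: cells of the given regions,
## renumbered nodes, boundary facets of those cells plus the FSI interface
## facets presented as boundary facets of the subdomain
submesh <- function(mesh, regions) {
  keep <- mesh$region %in% regions
  cells_g <- mesh$cells[keep, , drop = FALSE]
  nodes_g <- sort(unique(as.vector(cells_g)))
  remap <- integer(nrow(mesh$vertices)); remap[nodes_g] <- seq_along(nodes_g)
  cells <- matrix(remap[cells_g], ncol = 3)
  cell_map <- which(keep)                       # local cell -> global cell
  cell_remap <- integer(nrow(mesh$cells)); cell_remap[cell_map] <-
    seq_along(cell_map)
  bnd <- mesh$boundary[mesh$boundary$cell %in% cell_map, , drop = FALSE]
  bnd <- bnd[, c("n1", "n2", "tag", "cell")]
  bnd$ifc_row <- rep(NA_integer_, nrow(bnd))
  is_fluid <- all(regions %in% FLUID_REGIONS)
  ifc <- mesh$interfaces
  if (nrow(ifc) > 0) {
    adj <- if (is_fluid) ifc$fluid_cell else ifc$solid_cell
    sel <- adj %in% cell_map
    extra <- data.frame(n1 = ifc$n1[sel], n2 = ifc$n2[sel],
                        tag = ifc$tag[sel], cell = adj[sel],
                        ifc_row = which(sel))
    bnd <- rbind(bnd, extra)
  }
  bnd$n1 <- remap[bnd$n1]; bnd$n2 <- remap[bnd$n2]
  bnd$cell <- cell_remap[bnd$cell]
  vertices <- mesh$vertices[nodes_g, , drop = FALSE]
  list(vertices = vertices, cells = cells, boundary = bnd,
       nodes_global = nodes_g, cell_map = cell_map,
       region = mesh$region[keep])
}

## cell centroids of a submesh (same units as its vertices)
sub_centroids <- function(sub) {
  v <- sub$vertices; cl <- sub$cells
  cbind((v[cl[, 1], 1] + v[cl[, 2], 1] + v[cl[, 3], 1]) / 3,
        (v[cl[, 1], 2] + v[cl[, 2], 2] + v[cl[, 3], 2]) / 3)
}

## nodes of a submesh lying on facets with the given tags
tagged_nodes <- function(sub, tags) {
  b <- sub$boundary[sub$boundary$tag %in% tags, , drop = FALSE]
  sort(unique(c(b$n1, b$n2)))
}
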