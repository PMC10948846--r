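## Structured triangle meshing of the idealized head cross-section, plus a
## rectangle mesher for benchmark problems (channel flow, consolidation
## columns).  Meshes carry per-cell region labels and tagged boundary /
## interface facets; coordinates are stored in mm.

REGION_TAGS <- c("ventricle_csf", "sas_csf", "brain")
FLUID_REGIONS <- c("ventricle_csf", "sas_csf")

REFINEMENT_LEVELS <- c("coarse", "medium", "fine", "very_fine")

refinement_factor <- function(refinement_level) {
  if (is.numeric(refinement_level)) {
    stopifnot(refinement_level >= 1)
    return(refinement_level)
  }
  lev <- match.arg(refinement_level, REFINEMENT_LEVELS)
  2^(match(lev, REFINEMENT_LEVELS) - 1)
}

## canonical undirected edge keys for a set of (n1, n2) pairs
edge_key <- function(n1, n2) {
  lo <- pmin(n1, n2); hi <- pmax(n1, n2)
  lo * 2^26 + hi   # node counts stay far below 2^26
}

## assemble the mesh object: orient cells CCW, extract boundary and
## region-interface facets.  tagger(mid_x, mid_y) -> character tags for
## boundary edges (mid = edge midpoint, mm).
build_mesh_object <- function(vertices, cells, region, tagger,
                              refinement_level = NA, geometry = NULL) {
  stopifnot(ncol(vertices) == 2, ncol(cells) == 3,
            length(region) == nrow(cells))
  x <- vertices[, 1]; y <- vertices[, 2]
  a <- cells[, 1]; b <- cells[, 2]; c3 <- cells[, 3]
  det2 <- (x[b] - x[a]) * (y[c3] - y[a]) - (x[c3] - x[a]) * (y[b] - y[a])
  flip <- det2 < 0
  if (any(flip)) {
    tmp <- cells[flip, 2]
    cells[flip, 2] <- cells[flip, 3]
    cells[flip, 3] <- tmp
  }
  if (any(abs(det2) < 1e-14)) stop("degenerate cell in mesh")
  ## edge table: 3 edges per cell
  e1 <- cells[, c(1, 2)]; e2 <- cells[, c(2, 3)]; e3 <- cells[, c(3, 1)]
  edges <- rbind(e1, e2, e3)
  ecell <- rep(seq_len(nrow(cells)), 3)
  key <- edge_key(edges[, 1], edges[, 2])
  ord <- order(key)
  key_s <- key[ord]; edges_s <- edges[ord, , drop = FALSE]
  ecell_s <- ecell[ord]
  n_e <- length(key_s)
  same_next <- c(key_s[-n_e] == key_s[-1], FALSE)
  same_prev <- c(FALSE, same_next[-n_e])
  is_boundary <- !(same_next | same_prev)
  ## boundary facets
  bnd <- edges_s[is_boundary, , drop = FALSE]
  bnd_cell <- ecell_s[is_boundary]
  mid_x <- 0.5 * (x[bnd[, 1]] + x[bnd[, 2]])
  mid_y <- 0.5 * (y[bnd[, 1]] + y[bnd[, 2]])
  btag <- tagger(mid_x, mid_y)
  boundary <- data.frame(n1 = bnd[, 1], n2 = bnd[, 2], tag = btag,
                         cell = bnd_cell, stringsAsFactors = FALSE)
  ## interior facets between different regions
  first_idx <- which(same_next)
  c_a <- ecell_s[first_idx]; c_b <- ecell_s[first_idx + 1]
  reg_a <- region[c_a]; reg_b <- region[c_b]
  diff_reg <- reg_a != reg_b
  interfaces <- NULL
  if (any(diff_reg)) {
    ia <- c_a[diff_reg]; ib <- c_b[diff_reg]
    ra <- reg_a[diff_reg]; rb <- reg_b[diff_reg]
    nn <- edges_s[first_idx[diff_reg], , drop = FALSE]
    fluid_cell <- ifelse(ra %in% FLUID_REGIONS, ia, ib)
    solid_cell <- ifelse(ra == "brain", ia, ib)
    fluid_reg <- ifelse(ra %in% FLUID_REGIONS, ra, rb)
    has_solid <- ra == "brain" | rb == "brain"
    tag <- ifelse(fluid_reg == "ventricle_csf", "fsi_inner", "fsi_outer")
    interfaces <- data.frame(n1 = nn[, 1], n2 = nn[, 2], tag = tag,
                             fluid_cell = fluid_cell, solid_cell = solid_cell,
                             stringsAsFactors = FALSE)[has_solid, ,
                                                       drop = FALSE]
  }
  if (is.null(interfaces))
    interfaces <- data.frame(n1 = integer(), n2 = integer(),
                             tag = character(), fluid_cell = integer(),
                             solid_cell = integer())
  structure(list(vertices = vertices, cells = cells, region = region,
                 boundary = boundary, interfaces = interfaces,
                 refinement_level = refinement_level, geometry = geometry),
            class = "icp_mesh")
}

#' @exportS3Method base::print
print.icp_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d cells (max diameter %.2f mm)\n",
              nrow(x$vertices), nrow(x$cells), max_cell_diameter(x)))
  cat("  regions: ",
      paste(sprintf("%s=%d", names(table(x$region)), table(x$region)),
            collapse = ", "), "\n", sep = "")
  cat("  boundary tags: ",
      paste(unique(x$boundary$tag), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate a structured triangle mesh of the idealized head
#'
#' Rings of nodes are placed between the analytic band radii and connected
#' into triangles; each refinement level doubles both the angular and radial
#' node counts, halving the maximum cell diameter.  Cells are labelled
#' \code{ventricle_csf}, \code{brain} or \code{sas_csf} (aqueduct channel
#' cells count as SAS CSF: no production there); boundary facets are tagged
#' \code{inlet} (central hole), \code{spinal_outlet}, \code{sinus_outlet}
#' and \code{dura} (outer circle); brain-CSF interface facets get
#' \code{fsi_inner} / \code{fsi_outer}.
#'
#' @param geometry a \code{\link{build_geometry}} result (or a
#'   \code{\link{head_geometry}}, built automatically).
#' @param refinement_level \code{"coarse"}, \code{"medium"}, \code{"fine"},
#'   \code{"very_fine"}, or a numeric factor (1 = coarse).
#' @param base_h target cell size in mm at the coarse level.
#' @return An \code{icp_mesh}.
#' @examples
#' m <- generate_mesh(build_geometry(head_geometry()), "coarse")
#' @export
generate_mesh <- function(geometry, refinement_level = "coarse",
                          base_h = 16) {
  if (inherits(geometry, "head_geometry")) geometry <- build_geometry(geometry)
  stopifnot(inherits(geometry, "head_region"))
  fac <- refinement_factor(refinement_level)
  r <- geometry$radii
  even_ceil <- function(v) { n <- ceiling(v); n + n %% 2 }
  ## the angular count grows slightly faster than the refinement factor:
  ## the widest cell sits at the outer rim, and its mid-radius moves
  ## outward as the radial spacing shrinks, so exact doubling of counts
  ## would shrink the max diameter by marginally less than half
  n_theta <- even_ceil(2 * pi * r[["dura"]] / base_h * fac^1.2)
  bands <- list(
    ventricle = c(r[["inlet"]], r[["ventricle"]]),
    brain     = c(r[["ventricle"]], r[["brain"]]),
    sas       = c(r[["brain"]], r[["dura"]]))
  band_region <- c(ventricle = "ventricle_csf", brain = "brain",
                   sas = "sas_csf")
  radii <- numeric(0); ring_band <- character(0)
  for (bn in names(bands)) {
    b <- bands[[bn]]
    n_r <- max(1, ceiling((b[2] - b[1]) / base_h)) * fac
    rr <- seq(b[1], b[2], length.out = n_r + 1)
    if (length(radii) > 0) rr <- rr[-1]
    radii <- c(radii, rr)
    ring_band <- c(ring_band, rep(bn, length(rr)))
  }
  n_ring <- length(radii)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  xx <- outer(radii, cos(theta)); yy <- outer(radii, sin(theta))
  node_id <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  vertices <- cbind(as.vector(t(xx)), as.vector(t(yy)))
  ## quads between ring i and i+1, columns j
  ii <- rep(seq_len(n_ring - 1), each = n_theta)
  jj <- rep(seq_len(n_theta), n_ring - 1)
  a <- node_id(ii, jj); b <- node_id(ii, jj + 1L)
  cc <- node_id(ii + 1L, jj + 1L); d <- node_id(ii + 1L, jj)
  cells <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  quad_band <- ring_band[ii + 1L]      # band of the outer ring of the quad
  quad_theta <- (theta[jj] + pi / n_theta)  # cell-column mid angle
  quad_region <- band_region[quad_band]
  ha <- geometry$aqueduct_half_angle
  if (ha > 0) {
    dtheta <- 2 * pi / n_theta
    wrap <- function(t) atan2(sin(t), cos(t))
    dang <- abs(wrap(quad_theta - geometry$aqueduct_center_angle))
    in_chan <- quad_band == "brain" & dang < max(ha, 0.51 * dtheta)
    quad_region[in_chan] <- "sas_csf"
  }
  region <- c(quad_region, quad_region)
  in_arc <- function(th, arc) th >= arc[1] & th <= arc[2]
  tagger <- function(mx, my) {
    ## boundary edges are chords of either the inlet hole or the dura
    ## circle; split by the midway radius (chord sagitta safe)
    rr <- sqrt(mx^2 + my^2)
    th <- atan2(my, mx)
    outer_b <- rr > 0.5 * (r[["inlet"]] + r[["dura"]])
    tag <- ifelse(outer_b, "dura", "inlet")
    tag[outer_b & in_arc(th, geometry$spinal_outlet_arc)] <- "spinal_outlet"
    tag[outer_b & in_arc(th, geometry$sinus_outlet_arc)] <- "sinus_outlet"
    tag[!outer_b & in_arc(th, geometry$shunt_arc)] <- "shunt"
    tag
  }
  build_mesh_object(vertices, cells, region, tagger,
                    refinement_level = refinement_level, geometry = geometry)
}

#' Generate a structured triangle mesh of a rectangle
#'
#' Benchmark helper (channel flow, consolidation columns).  Boundary facets
#' are tagged \code{left}, \code{right}, \code{bottom}, \code{top}.
#'
#' @param lx,ly side lengths in mm.
#' @param nx,ny cell counts per side.
#' @param region region label for all cells (\code{"ventricle_csf"},
#'   \code{"sas_csf"} or \code{"brain"}).
#' @return An \code{icp_mesh}.
#' @export
rectangle_mesh <- function(lx, ly, nx, ny, region = "sas_csf") {
  region <- match.arg(region, REGION_TAGS)
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  vertices <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  node <- function(i, j) (j - 1L) * (nx + 1L) + i
  ii <- rep(seq_len(nx), ny); jj <- rep(seq_len(ny), each = nx)
  a <- node(ii, jj); b <- node(ii + 1L, jj)
  cc <- node(ii + 1L, jj + 1L); d <- node(ii, jj + 1L)
  cells <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  tol <- 1e-9 * max(lx, ly)
  tagger <- function(mx, my) {
    tag <- rep("wall", length(mx))
    tag[mx < tol] <- "left"; tag[mx > lx - tol] <- "right"
    tag[my < tol] <- "bottom"; tag[my > ly - tol] <- "top"
    tag
  }
  build_mesh_object(vertices, cells, rep(region, nrow(cells)), tagger)
}

#' Maximum cell diameter of a mesh (mm)
#'
#' @param mesh an \code{icp_mesh}.
#' @return Longest cell edge in mm.
#' @export
max_cell_diameter <- function(mesh) {
  v <- mesh$vertices; cl <- mesh$cells
  len <- function(i, j) sqrt((v[cl[, i], 1] - v[cl[, j], 1])^2 +
                             (v[cl[, i], 2] - v[cl[, j], 2])^2)
  max(len(1, 2), len(2, 3), len(3, 1))
}

cell_areas <- function(mesh) {
  v <- mesh$vertices; cl <- mesh$cells
  x <- v[, 1]; y <- v[, 2]
  a <- cl[, 1]; b <- cl[, 2]; c3 <- cl[, 3]
  0.5 * abs((x[b] - x[a]) * (y[c3] - y[a]) - (x[c3] - x[a]) * (y[b] - y[a]))
}

cell_centroids <- function(mesh) {
  v <- mesh$vertices; cl <- mesh$cells
  cbind((v[cl[, 1], 1] + v[cl[, 2], 1] + v[cl[, 3], 1]) / 3,
        (v[cl[, 1], 2] + v[cl[, 2], 2] + v[cl[, 3], 2]) / 3)
}

#' Measure intracranial volume and brain surface area from a mesh
#'
#' Revolves the upper half (y > 0) of the cross-section about the x-axis
#' (Pappus): the volume integral \eqn{2\pi \int_{y>0} y\, dA} over all
#' regions inside the dura converges to the sphere volume for the concentric
#' idealization, and the brain surface area is the revolved length of the
#' \code{fsi_inner} and \code{fsi_outer} facets.
#'
#' @param mesh an \code{icp_mesh} with labelled FSI interfaces.
#' @return List with \code{volume_ml}, \code{area_cm2}, and per-region
#'   revolved volumes \code{region_volume_ml}.
#' @export
measure_volume_and_area <- function(mesh) {
  if (nrow(mesh$interfaces) == 0)
    stop("mesh has no labelled FSI interfaces; cannot measure brain area")
  A <- cell_areas(mesh)
  yc <- cell_centroids(mesh)[, 2]
  up <- yc > 0
  vol_mm3 <- 2 * pi * sum(yc[up] * A[up])
  reg <- vapply(split(2 * pi * yc[up] * A[up], mesh$region[up]), sum,
                numeric(1))
  v <- mesh$vertices
  ifc <- mesh$interfaces
  ymid <- 0.5 * (v[ifc$n1, 2] + v[ifc$n2, 2])
  elen <- sqrt((v[ifc$n1, 1] - v[ifc$n2, 1])^2 +
               (v[ifc$n1, 2] - v[ifc$n2, 2])^2)
  keep <- ymid > 0
  area_mm2 <- 2 * pi * sum(ymid[keep] * elen[keep])
  list(volume_ml = vol_mm3 / 1000,       # mm^3 -> ml
       area_cm2 = area_mm2 / 100,        # mm^2 -> cm^2
       region_volume_ml = reg / 1000)
}

facet_set <- function(mesh, tags, where = c("boundary", "interfaces")) {
  where <- match.arg(where)
  tab <- mesh[[where]]
  tab[tab$tag %in% tags, , drop = FALSE]
}

#' Export a mesh as legacy ASCII VTK
#'
#' @param mesh an \code{icp_mesh}.
#' @param path output file.
#' @param point_data optional named list of per-vertex numeric vectors.
#' @return \code{path}, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$vertices); m <- nrow(mesh$cells)
  writeLines(c("# vtk DataFile Version 3.0", "icpfsi mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(cbind(mesh$vertices, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  utils::write.table(cbind(3L, mesh$cells - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(5L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, REGION_TAGS)), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 12), con)
    }
  }
  invisible(path)
}

#' Export / import a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Triangles carry the region as a physical tag (1 = ventricle_csf, 2 =
#' sas_csf, 3 = brain); tagged boundary edges are written as line elements.
#' \code{read_mesh_msh} reads the subset written by \code{write_mesh_msh}
#' and rebuilds interface labels from the region labels.
#'
#' @param mesh an \code{icp_mesh}.
#' @param path file path.
#' @return \code{write_mesh_msh}: \code{path} invisibly;
#'   \code{read_mesh_msh}: an \code{icp_mesh}.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$vertices); m <- nrow(mesh$cells)
  btags <- sort(unique(mesh$boundary$tag))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", as.character(length(btags) + 3)), con)
  for (k in seq_along(REGION_TAGS))
    writeLines(sprintf('2 %d "%s"', k, REGION_TAGS[k]), con)
  for (k in seq_along(btags))
    writeLines(sprintf('1 %d "%s"', 100 + k, btags[k]), con)
  writeLines(c("$EndPhysicalNames", "$Nodes", as.character(n)), con)
  utils::write.table(cbind(seq_len(n), mesh$vertices, 0), con,
                     row.names = FALSE, col.names = FALSE)
  nb <- nrow(mesh$boundary)
  writeLines(c("$EndNodes", "$Elements", as.character(m + nb)), con)
  bt <- 100 + match(mesh$boundary$tag, btags)
  utils::write.table(cbind(seq_len(nb), 1L, 2L, bt, bt,
                           mesh$boundary$n1, mesh$boundary$n2),
                     con, row.names = FALSE, col.names = FALSE)
  rt <- match(mesh$region, REGION_TAGS)
  utils::write.table(cbind(nb + seq_len(m), 2L, 2L, rt, rt, mesh$cells),
                     con, row.names = FALSE, col.names = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_mesh_msh
#' @export
read_mesh_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- which(lines == paste0("$", name)) + 1L
    i1 <- which(lines == paste0("$End", name)) - 1L
    lines[i0:i1]
  }
  pn <- sec("PhysicalNames")[-1]
  pn_split <- strsplit(pn, " ")
  ptag <- as.integer(vapply(pn_split, `[`, "", 2))
  pname <- gsub('"', "", vapply(pn_split, `[`, "", 3))
  nodes <- utils::read.table(text = sec("Nodes")[-1])
  vertices <- as.matrix(nodes[order(nodes[[1]]), 2:3])
  el <- utils::read.table(text = sec("Elements")[-1], fill = TRUE,
                          col.names = paste0("V", 1:8))
  tris <- el[el[[2]] == 2, ]
  lines2 <- el[el[[2]] == 1, ]
  cells <- as.matrix(tris[, 6:8]); storage.mode(cells) <- "integer"
  region <- pname[match(tris[[4]], ptag)]
  bmap <- data.frame(n1 = lines2[[6]], n2 = lines2[[7]],
                     tag = pname[match(lines2[[4]], ptag)])
  key <- edge_key(bmap$n1, bmap$n2)
  tagger <- function(mx, my) rep("untagged", length(mx))
  mesh <- build_mesh_object(vertices, cells, region, tagger)
  bkey <- edge_key(mesh$boundary$n1, mesh$boundary$n2)
  hit <- match(bkey, key)
  mesh$boundary$tag[!is.na(hit)] <- bmap$tag[hit[!is.na(hit)]]
  mesh
}
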