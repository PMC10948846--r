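test_that("invalid geometries are rejected", {
  expect_error(head_geometry(ventricle_radius = 80), "invalid geometry")
  expect_error(head_geometry(sas_thickness = 0), "invalid geometry")
  expect_error(head_geometry(inlet_radius = 25), "invalid geometry")
  expect_error(head_geometry(aqueduct_radius = -1), "invalid geometry")
})

test_that("geometry builds three concentric regions with all facet roles", {
  g <- build_geometry(head_geometry(ventricle_radius = 20,
                                    brain_outer_radius = 70,
                                    sas_thickness = 3))
  expect_equal(unname(g$radii), c(2, 20, 70, 73))
  mesh <- generate_mesh(g, "coarse")
  expect_setequal(unique(mesh$region),
                  c("ventricle_csf", "brain", "sas_csf"))
  expect_true(all(c("inlet", "shunt", "dura", "spinal_outlet",
                    "sinus_outlet") %in% mesh$boundary$tag))
  expect_setequal(unique(mesh$interfaces$tag), c("fsi_inner", "fsi_outer"))
})

test_that("closed aqueduct isolates the ventricular CSF from the SAS", {
  connectivity_components <- function(mesh) {
    ## flood fill over fluid cells sharing an edge (independent of the
    ## mesher's labelling)
    fluid <- which(mesh$region %in% c("ventricle_csf", "sas_csf"))
    edges_of <- function(cl) {
      e <- rbind(cl[, 1:2], cl[, 2:3], cl[, c(3, 1)])
      paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    }
    keys <- edges_of(mesh$cells[fluid, , drop = FALSE])
    cell_of_edge <- split(rep(seq_along(fluid), 3), keys)
    adj <- lapply(seq_along(fluid), function(i) integer(0))
    for (cc in cell_of_edge) if (length(cc) == 2) {
      adj[[cc[1]]] <- c(adj[[cc[1]]], cc[2])
      adj[[cc[2]]] <- c(adj[[cc[2]]], cc[1])
    }
    comp <- rep(0L, length(fluid)); k <- 0L
    for (s in seq_along(fluid)) {
      if (comp[s] > 0) next
      k <- k + 1L; queue <- s
      while (length(queue)) {
        c0 <- queue[[1]]; queue <- queue[-1]
        if (comp[c0] > 0) next
        comp[c0] <- k
        queue <- c(queue, adj[[c0]][comp[adj[[c0]]] == 0])
      }
    }
    k
  }
  closed <- generate_mesh(head_geometry(aqueduct_radius = 0), "coarse")
  open <- generate_mesh(head_geometry(aqueduct_radius = 2), "coarse")
  expect_equal(connectivity_components(closed), 2L)
  expect_equal(connectivity_components(open), 1L)
})

test_that("refinement halves the max cell diameter and scales cell counts", {
  g <- build_geometry(head_geometry())
  meshes <- lapply(c("coarse", "medium", "fine", "very_fine"),
                   function(l) generate_mesh(g, l))
  h <- vapply(meshes, max_cell_diameter, numeric(1))
  expect_true(all(diff(h) < 0))
  expect_true(all(h[-1] <= h[-4] / 2 + 1e-9))
  n_cells <- vapply(meshes, function(m) nrow(m$cells), numeric(1))
  expect_gte(n_cells[3] / n_cells[1], 4)   # fine vs coarse in 2-D
  expect_gte(n_cells[2] / n_cells[1], 4)   # each doubling quadruples cells
})

test_that("revolved measures converge to sphere volume and area", {
  g <- build_geometry(head_geometry())
  r_dura <- 73; r_in <- 2
  v_exact <- 4 / 3 * pi * (r_dura^3 - r_in^3) / 1000          # ml
  a_exact <- (4 * pi * 20^2 + 4 * pi * 70^2) / 100            # cm^2
  errs <- vapply(c("coarse", "medium", "fine"), function(l) {
    m <- measure_volume_and_area(generate_mesh(g, l))
    abs(m$volume_ml - v_exact) / v_exact
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # refinement reduces error
  fine <- measure_volume_and_area(generate_mesh(g, "fine"))
  expect_lt(abs(fine$volume_ml - v_exact) / v_exact, 0.01)
  expect_lt(abs(fine$area_cm2 - a_exact) / a_exact, 0.01)
  ## region volumes stable between fine and very fine
  vf <- measure_volume_and_area(generate_mesh(g, "very_fine"))
  expect_lt(max(abs(fine$region_volume_ml - vf$region_volume_ml) /
                  vf$region_volume_ml), 0.01)
})

test_that("every boundary facet carries exactly one known role tag", {
  mesh <- coarse_head_mesh()
  expect_true(all(mesh$boundary$tag %in%
                    c("inlet", "shunt", "dura", "spinal_outlet",
                      "sinus_outlet")))
  expect_false(anyNA(mesh$boundary$tag))
  ## FSI facets separate the right regions
  ifc <- mesh$interfaces
  fluid_reg <- mesh$region[ifc$fluid_cell]
  expect_true(all(mesh$region[ifc$solid_cell] == "brain"))
  expect_true(all(fluid_reg[ifc$tag == "fsi_inner"] == "ventricle_csf"))
  expect_true(all(fluid_reg[ifc$tag == "fsi_outer"] == "sas_csf"))
})

test_that("meshes round-trip through Gmsh MSH and export to VTK", {
  mesh <- coarse_head_mesh()
  p <- tempfile(fileext = ".msh")
  write_mesh_msh(mesh, p)
  back <- read_mesh_msh(p)
  expect_equal(nrow(back$cells), nrow(mesh$cells))
  expect_equal(sort(table(back$region)), sort(table(mesh$region)))
  expect_setequal(unique(back$boundary$tag), unique(mesh$boundary$tag))
  pv <- tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, pv, point_data = list(r = sqrt(rowSums(
    mesh$vertices^2))))
  head_lines <- readLines(pv, n = 5)
  expect_match(head_lines[1], "vtk DataFile")
  expect_match(head_lines[4], "UNSTRUCTURED_GRID")
})
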