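test_that("regular tetrahedron attains the closed-form quality optima", {
  for (edge in c(0.5, 1, 2, 7.3)) {
    v <- regular_tet(edge)
    expect_equal(aspect_ratio(v), sqrt(3 / 2), tolerance = 1e-12)
    ang <- dihedral_angles(v)
    expect_equal(ang, rep(acos(1 / 3) * 180 / pi, 6), tolerance = 1e-9)
    expect_equal(sum(ang), 6 * acos(1 / 3) * 180 / pi, tolerance = 1e-9)
    expect_equal(scaled_jacobian(v), 1, tolerance = 1e-12)
  }
})

test_that("right-corner tetrahedron has three 90-degree dihedrals", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ang <- dihedral_angles(v)
  # edges 1-2, 1-3, 1-4 meet at the orthogonal corner
  expect_equal(ang[1:3], rep(90, 3), tolerance = 1e-9)
})

test_that("degenerate elements report +Inf aspect ratio and zero Jacobian", {
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_identical(aspect_ratio(flat), Inf)
  expect_identical(scaled_jacobian(flat), 0)
  expect_error(dihedral_angles(flat), "coplanar")
  expect_error(aspect_ratio(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               "duplicated")
})

test_that("vertex swap flips the scaled Jacobian sign", {
  v <- regular_tet(2)
  expect_equal(scaled_jacobian(v[c(2, 1, 3, 4), ]), -scaled_jacobian(v),
               tolerance = 1e-12)
})

test_that("quality metrics are rigid-motion and scale invariant", {
  set.seed(31)
  for (i in 1:10) {
    v <- regular_tet(1) + matrix(rnorm(12, sd = 0.15), 4)  # perturbed tet
    if (scaled_jacobian(v) == 0) next
    R <- random_rotation()
    shift <- rnorm(3, sd = 50)
    w <- sweep(v %*% t(R), 2, shift, "+")
    expect_equal(aspect_ratio(w), aspect_ratio(v), tolerance = 1e-9)
    expect_equal(sort(dihedral_angles(w)), sort(dihedral_angles(v)),
                 tolerance = 1e-7)
    expect_equal(scaled_jacobian(w), scaled_jacobian(v), tolerance = 1e-9)
    s <- runif(1, 0.1, 10)
    expect_equal(aspect_ratio(v * s), aspect_ratio(v), tolerance = 1e-9)
    expect_equal(scaled_jacobian(v * s), scaled_jacobian(v), tolerance = 1e-9)
    # the regular tet minimizes AR among these perturbations
    expect_gte(aspect_ratio(v), sqrt(3 / 2) - 1e-12)
  }
})

test_that("mesh audit applies the element-quality acceptance criteria", {
  # single 2 mm regular tet: passes everything
  m2 <- disjoint_tet_mesh(list(regular_tet(2)))
  rep2 <- audit_mesh(m2)
  expect_equal(rep2$pct_ar_gt_3, 0)
  expect_false(rep2$any_nonpositive_jacobian)
  expect_false(rep2$any_jacobian_below_0_2)
  expect_false(rep2$any_dihedral_outside_30_120)
  expect_false(rep2$any_edge_outside_1_3mm)
  expect_true(rep2$passes_criteria)

  # 5 mm regular tet: fails the edge-length criterion only
  rep5 <- audit_mesh(disjoint_tet_mesh(list(regular_tet(5))))
  expect_true(rep5$any_edge_outside_1_3mm)
  expect_false(rep5$any_dihedral_outside_30_120)
  expect_equal(rep5$pct_ar_gt_3, 0)
  expect_false(rep5$passes_criteria)

  # criteria overrides rescue it
  repo <- audit_mesh(disjoint_tet_mesh(list(regular_tet(5))),
                     criteria = list(edge_max_mm = 6))
  expect_true(repo$passes_criteria)
})

test_that("a 100-element mesh with 6 bad aspect ratios reports exactly 6.0%", {
  stretched <- regular_tet(2) %*% diag(c(6, 1, 1))  # AR well above 3
  expect_gt(aspect_ratio(stretched), 3)
  tets <- c(replicate(94, regular_tet(2), simplify = FALSE),
            replicate(6, stretched, simplify = FALSE))
  rep <- audit_mesh(disjoint_tet_mesh(tets))
  expect_identical(rep$n_elements, 100L)
  expect_identical(rep$pct_ar_gt_3, 6)  # exact rational count, no drift
  expect_false(rep$passes_criteria)
})

test_that("legacy VTK meshes round-trip and MSH tet meshes load", {
  m <- disjoint_tet_mesh(list(regular_tet(2), regular_tet(1.5)), spacing = 10)
  p <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_tets(m, p)
  back <- read_tet_mesh(p)
  expect_equal(back$nodes, m$nodes, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$tets, m$tets, ignore_attr = TRUE)

  # minimal Gmsh MSH 2.2 file with one tet
  msh <- withr::local_tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "4",
               "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
               "$EndNodes",
               "$Elements", "1",
               "1 4 2 0 1 1 2 3 4",
               "$EndElements"), msh)
  mm <- read_tet_mesh(msh)
  expect_identical(nrow(mm$tets), 1L)
  expect_equal(scaled_jacobian(mm$nodes[mm$tets[1, ], ]),
               scaled_jacobian(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))))

  # non-tet cells are rejected
  bad <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "x", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               "POINTS 3 double", "0 0 0", "1 0 0", "0 1 0",
               "CELLS 1 4", "3 0 1 2",
               "CELL_TYPES 1", "5"), bad)
  expect_error(read_tet_mesh(bad), "non-tetrahedral")
})

test_that("quality reports are written as JSON plus per-element CSV", {
  rep <- audit_mesh(disjoint_tet_mesh(list(regular_tet(2))))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_quality_report(rep, json_path = jp, csv_path = cp)
  agg <- jsonlite::fromJSON(jp)
  expect_true(agg$passes_criteria)
  el <- read.csv(cp)
  expect_identical(names(el),
                   c("element_id", "aspect_ratio", "min_dihedral_deg",
                     "max_dihedral_deg", "min_edge_mm", "max_edge_mm",
                     "scaled_jacobian"))
})
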