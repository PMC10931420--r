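# Parametric fruit solid: deterministic meshing, region tagging, volume
# convergence, symmetry, quality metrics, VTK export.

test_that("meshing is deterministic and matches the closed-form counts", {
  dims <- fruit_dimensions()
  m1 <- build_fruit_mesh(dims, 1)
  m2 <- build_fruit_mesh(dims, 1)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  for (r in 1:2) {
    m <- build_fruit_mesh(dims, r)
    n <- 2 * (r + 1); L <- ceiling(n / 3)
    expect_identical(nrow(m$nodes), as.integer((n + 1)^3 + (6 * n^2 + 2) * L))
    expect_identical(nrow(m$tets), as.integer(6 * (n^3 + 6 * n^2 * L)))
  }
})

test_that("outer boundary nodes lie exactly on the fruit ellipsoid", {
  dims <- fruit_dimensions()
  m <- fruit_mesh_default(3)
  on <- m$nodes[m$outer_node, ]
  r2 <- (on[, 1] / dims$a_axial)^2 + (on[, 2] / dims$a_long)^2 +
    (on[, 3] / dims$a_short)^2
  expect_lt(max(abs(r2 - 1)), 1e-9)
})

test_that("the outer surface triangulation is watertight", {
  m <- build_fruit_mesh(fruit_dimensions(), 1)
  st <- m$skin_tris
  ed <- rbind(st[, 1:2], st[, 2:3], st[, c(1, 3)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  # every skin triangle is the face of exactly one tet (boundary faces)
  expect_identical(nrow(kiwifem:::boundary_faces(m$tets, nrow(m$nodes))),
                   nrow(st))
})

test_that("region tagging follows the core-ellipsoid centroid rule", {
  dims <- fruit_dimensions()
  m <- build_fruit_mesh(dims, 2)
  cen <- (m$nodes[m$tets[, 1], ] + m$nodes[m$tets[, 2], ] +
          m$nodes[m$tets[, 3], ] + m$nodes[m$tets[, 4], ]) / 4
  inside <- (cen[, 1] / dims$c_axial)^2 + (cen[, 2] / dims$c_long)^2 +
    (cen[, 3] / dims$c_short)^2 <= 1
  expect_identical(m$region == "core", inside)
})

test_that("mesh volume converges to the analytic ellipsoid volume", {
  dims <- fruit_dimensions()
  vol_an <- ellipsoid_volume(dims$a_axial, dims$a_long, dims$a_short)
  errs <- vapply(2:4, function(r) {
    abs(sum(build_fruit_mesh(dims, r)$volumes) / vol_an - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.03)                 # pole-graded surface: ~2.5% at r3
  expect_lt(errs[3], 0.02)                 # within 2% from refinement 4
  expect_true(all(diff(errs) < 0))         # monotone convergence
  # at least first-order in the grid spacing
  h_ratio <- (2 * (3 + 1)) / (2 * (2 + 1))
  expect_gt(errs[1] / errs[2], h_ratio^0.9)
})

test_that("core volume fraction converges to the analytic ratio", {
  dims <- fruit_dimensions()
  frac_an <- (dims$c_axial * dims$c_long * dims$c_short) /
    (dims$a_axial * dims$a_long * dims$a_short)
  for (r in 3:4) {
    m <- if (r == 4) fruit_mesh_default() else fruit_mesh_default(3)
    frac <- sum(m$volumes[m$region == "core"]) / sum(m$volumes)
    expect_lt(abs(frac - frac_an), 0.01)
  }
})

test_that("symmetric dimensions give mirror-symmetric node multisets", {
  m <- build_fruit_mesh(fruit_dimensions(), 1)
  key <- function(nd) sort(paste(round(nd[, 1], 9), round(nd[, 2], 9),
                                 round(nd[, 3], 9)))
  k0 <- key(m$nodes)
  for (axm in 1:3) {
    nd <- m$nodes
    nd[, axm] <- -nd[, axm]
    expect_identical(key(nd), k0)
  }
})

test_that("mesh quality: regular tet scores 1, fruit meshes stay sound", {
  a <- 1
  reg <- list(nodes = rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
                            c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3))),
              tets = matrix(1:4, 1), region = NULL)
  q <- mesh_quality(reg)
  expect_equal(q$min_scaled_jacobian, 1, tolerance = 1e-9)
  expect_equal(q$max_aspect, 1, tolerance = 1e-9)
  qf <- mesh_quality(fruit_mesh_default())
  expect_gt(qf$min_scaled_jacobian, 0.05)
  expect_identical(qf$n_elements, nrow(fruit_mesh_default()$tets))
})

test_that("inverted elements are reported with their indices", {
  m <- build_fruit_mesh(fruit_dimensions(), 1)
  bad <- m
  # collapse one tet far past its opposite face
  n4 <- bad$tets[17, 4]
  others <- bad$tets[17, 1:3]
  bad$nodes[n4, ] <- 2 * colMeans(bad$nodes[others, ]) - bad$nodes[n4, ] -
    10 * (bad$nodes[n4, ] - colMeans(bad$nodes[others, ]))
  expect_error(mesh_quality(bad), "17")
})

test_that("dimension presets differ only in the inferred long axis", {
  mc <- dimension_preset("mean_cohort")
  si <- dimension_preset("scanned_inferred")
  expect_equal(mc$a_axial, si$a_axial)
  expect_equal(mc$a_short, si$a_short)
  expect_equal(si$a_long, 54.4 / 2)
  expect_error(fruit_dimensions(a_axial = 10, c_axial = 12), "smaller")
})

test_that("VTU export writes well-formed grids for solid and skin", {
  m <- build_fruit_mesh(fruit_dimensions(), 1)
  path <- tempfile(fileext = ".vtu")
  write_mesh_vtu(m, path, cell_data = list(von_mises = seq_len(nrow(m$tets))))
  txt <- readLines(path)
  expect_true(any(grepl(sprintf('NumberOfCells="%d"', nrow(m$tets)), txt)))
  expect_true(any(grepl("von_mises", txt)))
  skin_path <- sub("\\.vtu$", "_skin.vtu", path)
  expect_true(file.exists(skin_path))
  expect_true(any(grepl(sprintf('NumberOfCells="%d"', nrow(m$skin_tris)),
                        readLines(skin_path))))
  unlink(c(path, skin_path))
})
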