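# Shared fixtures: reference materials, specimen geometries, and cached
# solver runs (the whole-fruit strain-level sweeps are reused by several
# test files and by the acceptance checks).

.kiwi_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .kiwi_cache, inherits = FALSE))
    assign(key, force(expr), envir = .kiwi_cache)
  get(key, envir = .kiwi_cache, inherits = FALSE)
}

kiwi_materials <- function() cached("materials", default_materials())

fruit_materials <- function() {
  m <- kiwi_materials()
  list(flesh = m$flesh, core = m$core, skin = m$skin)
}

cyl_geom <- function() specimen_geometry("cylinder", diameter = 10, height = 12)

strip_geom <- function() {
  specimen_geometry("strip", width = 15, thickness = 0.5, gauge_length = 50)
}

fruit_mesh_default <- function(refinement = 4) {
  cached(paste0("mesh_r", refinement),
         build_fruit_mesh(fruit_dimensions(), refinement = refinement))
}

# full strain-level sweep for one direction at the default refinement
fruit_run <- function(direction) {
  cached(paste0("run_", direction), {
    run_strain_levels(fruit_mesh_default(), fruit_materials(),
                      direction = direction,
                      levels = c(0.025, 0.05, 0.10, 0.20))
  })
}

# elastic sphere for contact benchmarks
sphere_mesh <- function(refinement = 5, R = 25) {
  cached(paste0("sphere_r", refinement),
         build_fruit_mesh(fruit_dimensions(R, R, R, NA, NA, NA),
                          refinement = refinement))
}

sphere_material <- function(E = 2, nu = 0.3) {
  list(flesh = tissue_params("elastic", E = E, nu = nu))
}

hertz_force <- function(E, nu, R, delta) {
  4 / 3 * E / (1 - nu^2) * sqrt(R) * delta^1.5
}

# rectangular block with contact faces only on the x-normal boundary
block_contact_mesh <- function(n = 4, side = 10) {
  m <- kiwifem:::cube_block_mesh(n, side)
  bf <- kiwifem:::boundary_faces(m$tets, nrow(m$nodes))
  xc <- m$nodes[, 1]
  keep <- apply(bf, 1, function(f) all(abs(xc[f]) < 1e-9) ||
                  all(abs(xc[f] - side) < 1e-9))
  m$skin_tris <- bf[keep, , drop = FALSE]
  m
}

# affine nodal displacement as a dof vector (x1, y1, z1, x2, ...)
affine_dofs <- function(A, nodes) as.numeric(A %*% t(nodes))

# Mirror comparison of a per-element field, restricted to the parent hexes
# that possess an exact mirror partner (volume-weighted centroids equal to
# rounding).  Only planar-faced hexes pair exactly: the six-tet split of a
# curved-face hex and of its mirror image cover slightly different regions,
# so no discrete mirror map exists for them and an element-level comparison
# there would measure the pairing error, not the field.
hex_mirror_dev <- function(mesh, x, axm) {
  hid <- mesh$parent_hex
  hv <- as.numeric(tapply(mesh$volumes, hid, sum))
  hx <- as.numeric(tapply(x * mesh$volumes, hid, sum)) / hv
  cen <- matrix(0, length(hv), 3)
  for (cc in 1:3) {
    tc <- (mesh$nodes[mesh$tets[, 1], cc] + mesh$nodes[mesh$tets[, 2], cc] +
           mesh$nodes[mesh$tets[, 3], cc] + mesh$nodes[mesh$tets[, 4], cc]) / 4
    cen[, cc] <- as.numeric(tapply(tc * mesh$volumes, hid, sum)) / hv
  }
  key <- function(M) paste(round(M[, 1], 6), round(M[, 2], 6),
                           round(M[, 3], 6))
  M2 <- cen
  M2[, axm] <- -M2[, axm]
  idx <- match(key(M2), key(cen))
  ok <- !is.na(idx)
  stopifnot(mean(ok) > 0.3)
  max(abs(hx[ok] - hx[idx[ok]])) / max(hx)
}
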