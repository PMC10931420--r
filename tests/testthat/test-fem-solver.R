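# Nonlinear FEM: assembly oracles, patch tests, contact, energy and
# balance checks, and field properties of the whole-fruit solves.

single_tet_mesh <- function(nodes) {
  tets <- matrix(1:4, 1, 4)
  V <- kiwifem:::tet_volumes(nodes, tets)
  list(nodes = nodes, tets = tets,
       region = factor("flesh", levels = c("flesh", "core")),
       skin_tris = NULL, volumes = V,
       grads = kiwifem:::tet_gradients(nodes, tets, V),
       outer_node = rep(TRUE, 4), dims = NULL)
}

# independent single-tet stiffness from Vandermonde shape functions
reference_tet_K <- function(nodes, C) {
  coefs <- solve(cbind(1, nodes), diag(4))
  G <- t(coefs[2:4, ])
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    ia <- 3 * (a - 1)
    B[1, ia + 1] <- G[a, 1]; B[2, ia + 2] <- G[a, 2]; B[3, ia + 3] <- G[a, 3]
    B[4, ia + 2] <- G[a, 3]; B[4, ia + 3] <- G[a, 2]
    B[5, ia + 1] <- G[a, 3]; B[5, ia + 3] <- G[a, 1]
    B[6, ia + 1] <- G[a, 2]; B[6, ia + 2] <- G[a, 1]
  }
  V <- kiwifem:::tet_volumes(nodes, matrix(1:4, 1, 4))
  V[1] * t(B) %*% C %*% B
}

test_that("assembled single-tet stiffness matches the textbook closed form", {
  nodes <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(0.2, 1.1, -0.1),
                 c(0.1, 0.3, 0.9))
  mesh <- single_tet_mesh(nodes)
  for (mat in list(list(flesh = tissue_params("iso", E = 2, nu = 0.3)),
                   list(flesh = kiwi_materials()$flesh))) {
    K <- as.matrix(assemble_system(mesh, mat)$K)
    Kref <- reference_tet_K(nodes, elastic_stiffness(mat$flesh))
    expect_lt(max(abs(K - Kref)), 1e-12)
    # rigid translations lie in the kernel
    for (d in 1:3) {
      tv <- rep(0, 12); tv[seq(d, 12, 3)] <- 1
      expect_lt(max(abs(K %*% tv)), 1e-9 * max(abs(K)))
    }
  }
})

test_that("patch test: affine boundary displacement gives exact uniform stress", {
  cm <- kiwifem:::cube_block_mesh(3, 1)
  A <- matrix(c(0.010, 0.004, -0.002,
                0.003, -0.008, 0.001,
                0.002, 0.005, 0.006), 3, 3, byrow = TRUE)
  for (mat in list(list(flesh = tissue_params("iso", E = 2, nu = 0.3)),
                   list(flesh = kiwi_materials()$flesh))) {
    C <- elastic_stiffness(mat$flesh)
    sys <- assemble_system(cm, mat)
    ub <- affine_dofs(A, cm$nodes)
    bd <- which(cm$outer_node)
    fdof <- sort(unlist(lapply(bd, function(n) 3 * (n - 1) + 1:3)))
    freedof <- setdiff(seq_len(3 * nrow(cm$nodes)), fdof)
    ui <- Matrix::solve(sys$K[freedof, freedof],
                        -sys$K[freedof, fdof] %*% ub[fdof])
    ufull <- ub; ufull[freedof] <- as.numeric(ui)
    expect_lt(max(abs(ufull - ub)), 1e-10)
    out <- assemble_system(cm, mat, displacement = ufull)
    eps_ex <- c(A[1, 1], A[2, 2], A[3, 3], A[2, 3] + A[3, 2],
                A[1, 3] + A[3, 1], A[1, 2] + A[2, 1])
    sig_ex <- as.numeric(C %*% eps_ex)
    expect_lt(max(abs(out$stress - sig_ex)), 1e-10)
  }
})

test_that("internal forces of an affinely deformed patch are self-equilibrated", {
  cm <- kiwifem:::cube_block_mesh(2, 1)
  mat <- list(flesh = tissue_params("iso", E = 3, nu = 0.25))
  A <- matrix(c(0.01, 0, 0, 0, -0.004, 0, 0, 0, -0.004), 3, 3)
  u <- affine_dofs(A, cm$nodes)
  out <- assemble_system(cm, mat, displacement = u)
  f <- matrix(out$f_int, ncol = 3, byrow = TRUE)
  interior <- !cm$outer_node
  expect_lt(max(abs(f[interior, ])), 1e-12)   # uniform stress: no net force
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("a block between frictionless plates carries F = E A strain", {
  m <- block_contact_mesh(3, 10)
  mat <- list(flesh = tissue_params("iso", E = 2, nu = 0.3))
  cfg <- simulation_config("axial", target_strain = 0.02,
                           n_increments = 4, friction_mu = 0)
  sol <- solve_compression(m, mat, cfg)
  F_exp <- 2 * 100 * 0.02
  expect_equal(tail(sol$curve$force_N, 1), F_exp, tolerance = 0.01)
  expect_equal(tail(sol$log$force_lower, 1), tail(sol$curve$force_N, 1),
               tolerance = 1e-6)
})

test_that("external work balances stored energy in the elastic range", {
  m <- sphere_mesh(4)
  mat <- sphere_material()
  cfg <- simulation_config("axial", target_strain = 0.01,
                           n_increments = 20, friction_mu = 0,
                           record_at = 0.01)
  sol <- solve_compression(m, mat, cfg)
  crv <- sol$curve
  W <- sum(diff(crv$displacement_mm) *
           (head(crv$force_N, -1) + tail(crv$force_N, -1)) / 2)
  K <- assemble_system(m, mat)$K
  u <- sol$final_state$u
  E_stored <- 0.5 * sum(u * as.numeric(K %*% u)) +
    sol$snapshots[[length(sol$snapshots)]]$contact_energy
  expect_lt(abs(W - E_stored) / E_stored, 0.01)
})

test_that("upper and lower plate reactions balance", {
  sol <- fruit_run("axial")
  expect_lt(max(abs(sol$log$force_upper - sol$log$force_lower) /
                pmax(sol$log$force_upper, 1)), 1e-3)
})

test_that("friction has a marginal effect in the near-Hertzian regime", {
  m <- sphere_mesh(4)
  mat <- sphere_material()
  f0 <- tail(solve_compression(m, mat,
    simulation_config("axial", 0.01, n_increments = 5,
                      friction_mu = 0))$curve$force_N, 1)
  f1 <- tail(solve_compression(m, mat,
    simulation_config("axial", 0.01, n_increments = 5,
                      friction_mu = 0.428))$curve$force_N, 1)
  expect_lt(abs(f1 - f0) / f0, 0.03)
})

test_that("Hertz sphere force is of the right order at small strain", {
  # the contact patch spans only one or two surface elements at desk
  # resolution; the force converges toward the closed form from above
  m <- sphere_mesh(5)
  mat <- sphere_material()
  cfg <- simulation_config("axial", target_strain = 0.01,
                           n_increments = 5, friction_mu = 0)
  sol <- solve_compression(m, mat, cfg)
  F <- tail(sol$curve$force_N, 1)
  Fh <- hertz_force(2, 0.3, 25, 0.25)
  expect_gt(F / Fh, 0.85)
  expect_lt(F / Fh, 1.35)
})

test_that("Newton converges rapidly with a tight final residual", {
  sol <- fruit_run("axial")
  el <- sol$log[sol$log$travel / sol$dimension <= 0.05, ]
  expect_lte(max(el$iters), 6)
  expect_true(all(sol$log$residual <=
                  1e-6 * pmax(1, sol$log$force_upper + sol$log$force_lower)))
})

test_that("plastic strain is non-decreasing across strain levels", {
  for (dir_ in c("axial", "long_radial")) {
    sol <- fruit_run(dir_)
    eb <- sapply(sol$snapshots, `[[`, "ebar_p")
    expect_true(all(diff(t(eb)) > -1e-12))
  }
})

test_that("flesh stress grows with strain level and yields within the sweep", {
  sol <- fruit_run("axial")
  vm_max <- vapply(c(0.025, 0.05, 0.10, 0.20), function(lv) {
    f <- field_snapshot(sol, lv)
    max(f$fields$von_mises[f$fields$region == "flesh"])
  }, numeric(1))
  expect_true(all(diff(vm_max) > 0))
  # purely elastic at 2.5%: no plastic strain anywhere
  snap0 <- field_snapshot(sol, 0.025)
  expect_equal(max(snap0$fields$ebar_p), 0)
  # flesh has yielded by the 20% level (bio-yield exceeded in volume)
  snap4 <- field_snapshot(sol, 0.20)
  fl <- snap4$fields$region == "flesh"
  expect_gt(max(snap4$fields$ebar_p[fl]), 0)
  expect_gte(max(snap4$fields$von_mises[fl]), 0.491)
})

test_that("the Von Mises field respects the transverse mirror symmetries", {
  sol <- fruit_run("axial")
  mesh <- sol$mesh
  sn <- sol$snapshots[[which.min(abs(sapply(sol$snapshots, `[[`,
                                            "strain_level") - 0.05))]]
  for (axm in 2:3)
    expect_lt(hex_mirror_dev(mesh, sn$von_mises, axm), 0.05)
})

test_that("force at 2.5% axial strain is mesh-converged within 5%", {
  mats <- fruit_materials()
  f <- vapply(c(4, 5), function(r) {
    m <- if (r == 4) fruit_mesh_default() else
      build_fruit_mesh(fruit_dimensions(), r)
    sol <- solve_compression(m, mats,
      simulation_config("axial", 0.025, friction_mu = 0.428))
    tail(sol$curve$force_N, 1)
  }, numeric(1))
  expect_lt(abs(f[2] - f[1]) / f[2], 0.05)
})

test_that("directional peak forces follow the anatomical ordering", {
  f20 <- vapply(c("axial", "long_radial", "short_radial"), function(d) {
    max(fruit_run(d)$curve$force_N)
  }, numeric(1))
  expect_gt(f20[["axial"]], f20[["long_radial"]])
  expect_gt(f20[["axial"]], f20[["short_radial"]])
  expect_lt(abs(f20[["long_radial"]] - f20[["short_radial"]]) /
            pmax(f20[["long_radial"]], f20[["short_radial"]]), 0.25)
})

test_that("simulation config rejects invalid settings", {
  expect_error(simulation_config(target_strain = 0.7), "0.5")
  expect_error(simulation_config(friction_mu = -1), ">= 0")
  expect_error(simulation_config(contact_penalty = -5), "positive")
  expect_error(field_snapshot(fruit_run("axial"), 0.33), "no snapshot")
})
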