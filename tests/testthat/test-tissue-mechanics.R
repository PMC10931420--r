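# Constitutive layer: stiffness construction, hardening conversion,
# radial-return plasticity, Von Mises invariants.

test_that("isotropic stiffness reproduces the Lame closed form", {
  C <- elastic_stiffness(tissue_params("t", E = 2.305, nu = 0.40))
  expect_equal(C[1, 1], 2.305 * 0.6 / (1.4 * 0.2), tolerance = 1e-12)
  # numerical cross-check: invert the compliance assembled independently
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- -0.40 / 2.305
  diag(S)[1:3] <- 1 / 2.305
  diag(S)[4:6] <- 2 * (1 + 0.40) / 2.305
  expect_equal(C, solve(S), tolerance = 1e-10)
  # nu = 0 decouples the normal and shear blocks
  C0 <- elastic_stiffness(tissue_params("t", E = 1, nu = 0))
  expect_equal(C0, diag(c(1, 1, 1, 0.5, 0.5, 0.5)), tolerance = 1e-12)
})

test_that("every reference tissue has a symmetric positive-definite stiffness", {
  for (p in kiwi_materials()) {
    C <- elastic_stiffness(p)
    expect_equal(C, t(C), tolerance = 1e-12)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("transverse flesh is stiffer along the fruit axis than radially", {
  C <- elastic_stiffness(kiwi_materials()$flesh)
  s_ax <- (C %*% c(0.01, 0, 0, 0, 0, 0))[1]
  s_ra <- (C %*% c(0, 0.01, 0, 0, 0, 0))[2]
  expect_gt(s_ax, s_ra)
})

test_that("stiffness rotation preserves the spectrum and follows the axis", {
  fl <- kiwi_materials()$flesh
  C0 <- elastic_stiffness(fl)
  set.seed(7)
  ax <- c(0.3, -0.8, 0.52); ax <- ax / sqrt(sum(ax^2))
  C1 <- elastic_stiffness(fl, axis = ax)
  # rotation acts orthogonally in Kelvin normalization (engineering Voigt
  # eigenvalues are representation artefacts, not invariants)
  D <- diag(c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2)))
  kelvin_eigs <- function(C) sort(eigen(D %*% C %*% D, symmetric = TRUE,
                                        only.values = TRUE)$values)
  expect_equal(kelvin_eigs(C0), kelvin_eigs(C1), tolerance = 1e-9)
  # uniaxial strain along the rotated axis sees the axial modulus
  R <- kiwifem:::rotation_from_x(ax)
  eps_t <- R %*% diag(c(0.01, 0, 0)) %*% t(R)
  ev <- kiwifem:::tensor_to_voigt_strain(eps_t)
  sig <- kiwifem:::voigt_to_tensor(as.numeric(C1 %*% ev))
  s_ax <- as.numeric(t(ax) %*% sig %*% ax)
  expect_equal(s_ax, as.numeric(C0[1, 1] * 0.01), tolerance = 1e-9)
})

test_that("hardening modulus converts the total-strain tangent correctly", {
  expect_equal(hardening_modulus(2.305, 0.967),
               2.305 * 0.967 / (2.305 - 0.967), tolerance = 1e-12)
  expect_equal(hardening_modulus(4.499, 1.381),
               4.499 * 1.381 / (4.499 - 1.381), tolerance = 1e-12)
  expect_identical(hardening_modulus(5, 0), 0)   # perfect plasticity
  expect_error(hardening_modulus(2, 2), "unsupported")
  expect_error(hardening_modulus(2, 2.5), "unsupported")
})

test_that("von Mises satisfies its defining special cases", {
  expect_equal(von_mises(c(2, 0, 0, 0, 0, 0)), 2)
  expect_equal(von_mises(c(-3, 0, 0, 0, 0, 0)), 3)
  expect_equal(von_mises(c(1, 1, 1, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, 0, 0, 0.7)), sqrt(3) * 0.7)
  expect_equal(von_mises(diag(3) * 2.5), 0)     # hydrostatic tensor input
})

test_that("von Mises is invariant under rotations and hydrostatic shifts", {
  set.seed(11)
  for (k in 1:25) {
    s <- rnorm(6)
    q0 <- von_mises(s)
    expect_equal(von_mises(s + c(rep(rnorm(1), 3), 0, 0, 0)), q0,
                 tolerance = 1e-10)
    A <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(A))
    st <- kiwifem:::voigt_to_tensor(s)
    expect_equal(von_mises(R %*% st %*% t(R)), q0, tolerance = 1e-10)
  }
})

test_that("radial return: elastic branch is exact and leaves no plasticity", {
  fl <- kiwi_materials()$flesh_axial
  C <- elastic_stiffness(fl)
  st <- virgin_state()
  # lateral strains chosen for a uniaxial stress state below yield
  e <- 0.1
  up <- radial_return(st, c(e, -fl$nu * e, -fl$nu * e, 0, 0, 0), fl, C)
  expect_equal(up$state$stress[1], fl$E * e, tolerance = 1e-9)
  expect_equal(up$state$ebar_p, 0)
  expect_equal(up$tangent, C, tolerance = 1e-12)
})

test_that("strain-driven uniaxial loop reproduces the bilinear curve", {
  mats <- kiwi_materials()
  for (nm in c("flesh_axial", "flesh_radial", "core")) {
    p <- mats[[nm]]
    eps_y <- p$sigma_y / p$E
    path <- seq(0, 0.40, by = 0.02)
    r <- uniaxial_response(p, path)
    pre <- r$strain > 0 & r$strain <= eps_y
    expect_equal(r$stress[pre], p$E * r$strain[pre], tolerance = 1e-6)
    post <- r$strain > eps_y + 1e-9
    expect_equal(r$stress[post],
                 p$sigma_y + p$Et * (r$strain[post] - eps_y),
                 tolerance = 1e-6)
    expect_true(all(diff(r$ebar_p) >= -1e-15))
  }
  # closed form at 40% strain for the axial flesh
  fl <- mats$flesh_axial
  r <- uniaxial_response(fl, seq(0, 0.40, by = 0.01))
  expect_equal(tail(r$stress, 1),
               0.491 + 0.967 * (0.40 - 0.491 / 2.305), tolerance = 1e-6)
})

test_that("unloading after plastic flow follows the elastic slope", {
  fl <- kiwi_materials()$flesh_axial
  path <- c(seq(0, 0.30, by = 0.01), 0.295, 0.29)
  r <- uniaxial_response(fl, path)   # non-monotone tail: small unloading
  n <- nrow(r)
  slope <- (r$stress[n] - r$stress[n - 2]) / (r$strain[n] - r$strain[n - 2])
  expect_equal(slope, fl$E, tolerance = 1e-6)
  expect_equal(r$ebar_p[n], r$ebar_p[n - 2], tolerance = 1e-12)
})

test_that("yield consistency holds after arbitrary plastic steps", {
  mats <- kiwi_materials()
  set.seed(3)
  for (nm in c("flesh_axial", "core")) {
    p <- mats[[nm]]
    C <- elastic_stiffness(p)
    H <- hardening_modulus(p$E, p$Et)
    st <- virgin_state()
    for (k in 1:20) {
      dstr <- rnorm(6, sd = 0.05)
      up <- radial_return(st, dstr, p, C)
      st_new <- up$state
      q <- von_mises(st_new$stress)
      f <- q - p$sigma_y - H * st_new$ebar_p
      expect_lte(f, 1e-10 * p$sigma_y)
      expect_gte(st_new$ebar_p, st$ebar_p)
      st <- st_new
    }
  }
})

test_that("transverse flesh with anisotropic elasticity still returns to the yield surface", {
  fl <- kiwi_materials()$flesh
  C <- elastic_stiffness(fl)
  H <- hardening_modulus(fl$E_axial, fl$Et_axial)
  st <- virgin_state()
  up <- radial_return(st, c(0.4, -0.1, -0.1, 0.05, 0, 0), fl, C,
                      direction = "axial")
  q <- von_mises(up$state$stress)
  expect_gt(up$state$ebar_p, 0)
  expect_lt(abs(q - fl$sigma_y_axial - H * up$state$ebar_p),
            1e-10 * fl$sigma_y_axial)
})

test_that("invalid parameters are rejected with informative errors", {
  expect_error(tissue_params("bad", E = -1, nu = 0.3), "positive")
  expect_error(tissue_params("bad", E = 1, nu = 0.5), "Poisson")
  expect_error(tissue_params("bad", E = 1, Et = 1.5, nu = 0.3), "Et")
  expect_error(radial_return(virgin_state(), c(NA, 0, 0, 0, 0, 0),
                             kiwi_materials()$core), "finite")
})
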