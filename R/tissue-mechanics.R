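# Constitutive models for kiwifruit tissue: elastic stiffness construction
# (isotropic and transversely isotropic), bilinear J2 plasticity via a
# radial-return map with linear isotropic hardening, and the Von Mises
# equivalent stress used as the damage criterion.
#
# Voigt convention: order (11, 22, 33, 23, 13, 12); strain vectors carry
# engineering shear (gamma = 2 * tensor shear); stress vectors carry the
# shear stresses themselves.  Stiffness matrices map engineering strain to
# stress.

#' Tissue constitutive parameters
#'
#' Container for one tissue's constants: Young's modulus `E` (MPa), tangent
#' modulus `Et` (MPa, slope of the stress-strain curve on total strain in the
#' post-yield interval; `NULL` for tissues with no plastic branch, such as
#' skin), bio-yield stress `sigma_y` (MPa), Poisson ratio `nu` and density
#' (g/cm^3).  `symmetry = "transverse"` declares one distinguished material
#' axis (the fruit's stem-blossom axis) with isotropy in the perpendicular
#' plane; it requires per-direction constants `E_axial`, `E_radial`,
#' `Et_axial`, `Et_radial`, `sigma_y_axial`, `sigma_y_radial`.
#'
#' Missing transverse constants are closed in the most common way for
#' engineering-constant input: a single Poisson ratio `nu` for both the
#' axial-radial and in-plane couplings, and out-of-plane shear modulus
#' `G = E_radial / (2 (1 + nu))`.
#'
#' @param name label, e.g. `"flesh"`.
#' @param E,Et,sigma_y,nu,density scalar constants (see description);
#'   `Et`/`sigma_y` may be `NULL`.
#' @param symmetry `"isotropic"` or `"transverse"`.
#' @param E_axial,E_radial,Et_axial,Et_radial,sigma_y_axial,sigma_y_radial
#'   transverse-symmetry constants (MPa); ignored for isotropic tissues.
#' @param ... further fields stored verbatim (e.g. `density_alt`).
#' @return object of class `tissue_params`.
#' @seealso [elastic_stiffness()], [radial_return()], [default_materials()]
#' @export
#' @examples
#' flesh_ax <- tissue_params("flesh_axial", E = 2.305, Et = 0.967,
#'                           sigma_y = 0.491, nu = 0.40, density = 1.248)
#' flesh_ax
tissue_params <- function(name, E = NULL, Et = NULL, sigma_y = NULL,
                          nu, density = NULL,
                          symmetry = c("isotropic", "transverse"),
                          E_axial = NULL, E_radial = NULL,
                          Et_axial = NULL, Et_radial = NULL,
                          sigma_y_axial = NULL, sigma_y_radial = NULL, ...) {
  symmetry <- match.arg(symmetry)
  p <- list(name = as.character(name), E = E, Et = Et, sigma_y = sigma_y,
            nu = nu, density = density, symmetry = symmetry,
            E_axial = E_axial, E_radial = E_radial,
            Et_axial = Et_axial, Et_radial = Et_radial,
            sigma_y_axial = sigma_y_axial, sigma_y_radial = sigma_y_radial,
            ...)
  class(p) <- "tissue_params"
  validate_tissue_params(p)
  p
}

validate_tissue_params <- function(p) {
  if (!is_number(p$nu) || p$nu < 0 || p$nu >= 0.5)
    stopf("tissue '%s': Poisson ratio must satisfy 0 <= nu < 0.5", p$name)
  chk_E <- function(E, lbl) {
    if (!is_number(E) || E <= 0)
      stopf("tissue '%s': %s must be a positive number", p$name, lbl)
  }
  chk_pair <- function(E, Et, sy, lbl) {
    chk_E(E, paste0("E", lbl))
    if (!is.null(Et)) {
      if (!is_number(Et) || Et < 0 || Et >= E)
        stopf("tissue '%s': Et%s must satisfy 0 <= Et < E", p$name, lbl)
    }
    if (!is.null(sy) && (!is_number(sy) || sy <= 0))
      stopf("tissue '%s': sigma_y%s must be positive", p$name, lbl)
  }
  if (p$symmetry == "isotropic") {
    chk_pair(p$E, p$Et, p$sigma_y, "")
  } else {
    chk_pair(p$E_axial, p$Et_axial, p$sigma_y_axial, "_axial")
    chk_pair(p$E_radial, p$Et_radial, p$sigma_y_radial, "_radial")
    # positive definiteness of the assembled compliance is enforced at
    # stiffness construction (elastic_stiffness).
  }
  invisible(p)
}

#' @exportS3Method base::print
print.tissue_params <- function(x, ...) {
  cat("Tissue:", x$name, sprintf("(%s)\n", x$symmetry))
  fmt <- function(v) if (is.null(v)) "-" else format(v)
  if (x$symmetry == "isotropic") {
    cat(sprintf("  E = %s MPa, Et = %s MPa, sigma_y = %s MPa, nu = %s\n",
                fmt(x$E), fmt(x$Et), fmt(x$sigma_y), fmt(x$nu)))
  } else {
    cat(sprintf("  axial : E = %s, Et = %s, sigma_y = %s MPa\n",
                fmt(x$E_axial), fmt(x$Et_axial), fmt(x$sigma_y_axial)))
    cat(sprintf("  radial: E = %s, Et = %s, sigma_y = %s MPa, nu = %s\n",
                fmt(x$E_radial), fmt(x$Et_radial), fmt(x$sigma_y_radial),
                fmt(x$nu)))
  }
  invisible(x)
}

#' Reference material table
#'
#' Reads the tissue parameter table shipped with the package (measured
#' constants for "Xuxiang" kiwifruit skin, flesh and core; the flesh is
#' provided both as separate isotropic axial/radial specimen rows and as a
#' single transversely isotropic entry used by the fruit-scale model).
#'
#' @param path path to a JSON material table; defaults to the shipped one.
#'   The file is a JSON object keyed by tissue name whose entries hold the
#'   fields of [tissue_params()].
#' @return named list of `tissue_params`.
#' @export
#' @examples
#' mats <- default_materials()
#' names(mats)
default_materials <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kiwifruit_materials.json",
                        package = "kiwifem", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) {
    f <- raw[[nm]]
    f <- f[!vapply(f, is.null, logical(1))]
    do.call(tissue_params, c(list(name = nm), f))
  })
  names(out) <- names(raw)
  out
}

# ---------------------------------------------------------------------------
# Voigt / tensor helpers

voigt_index <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))

# 6-vector (stress-like) -> symmetric 3x3
voigt_to_tensor <- function(v) {
  matrix(c(v[1], v[6], v[5],
           v[6], v[2], v[4],
           v[5], v[4], v[3]), 3, 3)
}

tensor_to_voigt_stress <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[2, 3], m[1, 3], m[1, 2])
}

# strain tensor -> engineering Voigt (doubled shears)
tensor_to_voigt_strain <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], 2 * m[2, 3], 2 * m[1, 3], 2 * m[1, 2])
}

# 6x6 engineering stiffness -> full 3x3x3x3 tensor (minor symmetries hold
# because the engineering convention already absorbs the shear factor 2).
stiffness_to_tensor4 <- function(C) {
  A <- array(0, c(3, 3, 3, 3))
  for (I in 1:6) for (J in 1:6) {
    i <- voigt_index[I, 1]; j <- voigt_index[I, 2]
    k <- voigt_index[J, 1]; l <- voigt_index[J, 2]
    A[i, j, k, l] <- C[I, J]; A[j, i, k, l] <- C[I, J]
    A[i, j, l, k] <- C[I, J]; A[j, i, l, k] <- C[I, J]
  }
  A
}

tensor4_to_stiffness <- function(A) {
  C <- matrix(0, 6, 6)
  for (I in 1:6) for (J in 1:6)
    C[I, J] <- A[voigt_index[I, 1], voigt_index[I, 2],
                 voigt_index[J, 1], voigt_index[J, 2]]
  C
}

rotate_tensor4 <- function(A, R) {
  B <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3)
      s <- s + R[i, a] * R[j, b] * R[k, cc] * R[l, d] * A[a, b, cc, d]
    B[i, j, k, l] <- s
  }
  B
}

# Rotation taking the x-axis onto `axis` (Rodrigues; any unit axis).
rotation_from_x <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  x <- c(1, 0, 0)
  v <- c(x[2] * a[3] - x[3] * a[2],
         x[3] * a[1] - x[1] * a[3],
         x[1] * a[2] - x[2] * a[1])
  c_ <- sum(x * a)
  if (abs(c_ - 1) < 1e-14) return(diag(3))
  if (abs(c_ + 1) < 1e-14) return(diag(c(-1, -1, 1)))  # 180 deg about z
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# ---------------------------------------------------------------------------

#' Elastic stiffness matrix (Voigt form)
#'
#' Builds the 6x6 engineering stiffness for a tissue.  Isotropic tissues use
#' the Lame form; transversely isotropic tissues assemble the compliance
#' from engineering constants (`E_axial`, `E_radial`, shared `nu`,
#' out-of-plane shear `E_radial / (2 (1 + nu))`), invert it, and rotate the
#' result so that the material symmetry axis coincides with `axis`.
#'
#' @param params a [tissue_params()] object.
#' @param axis unit 3-vector: the material symmetry axis in the global
#'   frame (only used for transverse symmetry).  Default: the x-axis.
#' @return symmetric positive-definite 6x6 matrix (MPa), Voigt order
#'   (11, 22, 33, 23, 13, 12), engineering shear strain convention.
#' @export
#' @examples
#' C <- elastic_stiffness(tissue_params("t", E = 2.305, nu = 0.40))
#' C[1, 1]  # E (1 - nu) / ((1 + nu) (1 - 2 nu)) = 4.9393 MPa
elastic_stiffness <- function(params, axis = c(1, 0, 0)) {
  stopifnot(inherits(params, "tissue_params"))
  if (params$symmetry == "isotropic") {
    E <- params$E; nu <- params$nu
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    G <- E / (2 * (1 + nu))
    C <- diag(c(rep(2 * G, 3), rep(G, 3)))
    C[1:3, 1:3] <- C[1:3, 1:3] + lam
  } else {
    Ea <- params$E_axial; Er <- params$E_radial; nu <- params$nu
    Gar <- Er / (2 * (1 + nu))        # out-of-plane shear closure
    Grr <- Er / (2 * (1 + nu))        # in-plane shear (isotropy in plane)
    S <- matrix(0, 6, 6)
    S[1, 1] <- 1 / Ea
    S[2, 2] <- S[3, 3] <- 1 / Er
    S[1, 2] <- S[2, 1] <- S[1, 3] <- S[3, 1] <- -nu / Ea
    S[2, 3] <- S[3, 2] <- -nu / Er
    S[4, 4] <- 1 / Grr
    S[5, 5] <- S[6, 6] <- 1 / Gar
    ev <- eigen(S[1:3, 1:3], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stopf(paste("tissue '%s': transverse compliance is not positive",
                  "definite (min normal-block eigenvalue %.3g <= 0)"),
            params$name, min(ev))
    C <- solve(S)
    if (!isTRUE(all.equal(axis / sqrt(sum(axis^2)), c(1, 0, 0),
                          tolerance = 1e-12))) {
      R <- rotation_from_x(axis)
      C <- tensor4_to_stiffness(rotate_tensor4(stiffness_to_tensor4(C), R))
    }
  }
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stopf("tissue '%s': stiffness not positive definite (min eigenvalue %.3g)",
          params$name, min(ev))
  C
}

#' Plastic hardening modulus from the total-strain tangent modulus
#'
#' The tangent modulus `Et` tabulated from compression tests is the slope of
#' the stress-strain curve on *total* strain in the post-yield interval.
#' The radial-return map needs the hardening modulus on *plastic* strain,
#' `H = E Et / (E - Et)`, which makes the simulated uniaxial post-yield
#' slope equal `Et` exactly.
#'
#' @param E Young's modulus (MPa).
#' @param Et tangent modulus (MPa), `0 <= Et < E` (`Et = 0`: perfect
#'   plasticity).
#' @return hardening modulus H (MPa).
#' @export
#' @examples
#' hardening_modulus(2.305, 0.967)  # 1.6659 MPa
hardening_modulus <- function(E, Et) {
  if (!is_number(E) || E <= 0) stopf("E must be positive")
  if (!is_number(Et) || Et < 0) stopf("Et must be non-negative")
  if (Et >= E)
    stopf("Et (%.4g) must be smaller than E (%.4g): a post-yield slope at or
above the elastic slope is unsupported", Et, E)
  E * Et / (E - Et)
}

#' Von Mises equivalent stress
#'
#' `sqrt(3 J2)` of a stress state: zero for hydrostatic states, equal to
#' `|s|` for uniaxial stress `s`, and invariant under rotations.
#'
#' @param stress a length-6 Voigt vector (11, 22, 33, 23, 13, 12), a
#'   symmetric 3x3 matrix, or a 6 x M matrix of M stress states.
#' @return scalar (or length-M vector) equivalent stress, same units as the
#'   input.
#' @export
#' @examples
#' von_mises(c(2, 0, 0, 0, 0, 0))       # 2
#' von_mises(c(1, 1, 1, 0, 0, 0))       # 0 (hydrostatic)
#' von_mises(c(0, 0, 0, 0, 0, 1))       # sqrt(3)
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3))) {
    if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress))))
      stopf("stress tensor must be symmetric")
    stress <- tensor_to_voigt_stress(stress)
  }
  v <- if (is.matrix(stress)) stress else matrix(stress, nrow = 6)
  if (nrow(v) != 6) stopf("stress must have 6 Voigt components")
  q <- sqrt(0.5 * ((v[1, ] - v[2, ])^2 + (v[2, ] - v[3, ])^2 +
                   (v[3, ] - v[1, ])^2) +
            3 * (v[4, ]^2 + v[5, ]^2 + v[6, ]^2))
  if (length(q) == 1L) q[[1]] else q
}

# ---------------------------------------------------------------------------
# J2 return map, vectorized over columns of a 6 x M trial stress block.
#
# Semi-implicit return: the flow direction is frozen at the trial normal and
# the plastic multiplier is found by a scalar Newton iteration so that the
# yield residual vanishes to `tol * sigma_y` even for anisotropic elasticity
# (for isotropic elasticity this reduces to the classical one-step radial
# return with dgamma = (q_trial - sigma_y - H ebar) / (3 G + H)).
#
# Returns sig (6xM), dgamma (M), Nflow (6xM strain-like normal at trial
# state), plastic (logical M).
j2_return_map <- function(sig_trial, ebar, C, sigma_y, H, tol = 1e-12,
                          max_iter = 50L) {
  M <- ncol(sig_trial)
  q_tr <- von_mises(sig_trial)
  f_tr <- q_tr - sigma_y - H * ebar
  plastic <- is.finite(f_tr) & f_tr > 0 & q_tr > 0
  sig <- sig_trial
  dgamma <- numeric(M)
  Nflow <- matrix(0, 6, M)
  if (any(plastic)) {
    idx <- which(plastic)
    sp <- sig_trial[, idx, drop = FALSE]
    qp <- q_tr[idx]
    p <- colMeans(sp[1:3, , drop = FALSE])
    s_dev <- sp
    s_dev[1:3, ] <- sweep(sp[1:3, , drop = FALSE], 2, p, "-")
    # strain-like yield normal d q / d sigma (engineering pairing)
    Np <- s_dev * (3 / (2 * qp))[col(s_dev)]
    Np[4:6, ] <- 2 * Np[4:6, ]
    CN <- C %*% Np
    dg <- rep(0, length(idx))
    ebar_p <- ebar[idx]
    for (it in seq_len(max_iter)) {
      sc <- sp - CN * rep(dg, each = 6)
      qc <- von_mises(sc)
      fv <- qc - sigma_y - H * (ebar_p + dg)
      if (max(abs(fv)) <= tol * sigma_y) break
      # d q / d dgamma = - Ncur : CN
      pc <- colMeans(sc[1:3, , drop = FALSE])
      sdc <- sc
      sdc[1:3, ] <- sweep(sc[1:3, , drop = FALSE], 2, pc, "-")
      Nc <- sdc * (3 / (2 * pmax(qc, 1e-300)))[col(sdc)]
      Nc[4:6, ] <- 2 * Nc[4:6, ]
      dq <- -colSums(Nc * CN)
      dg <- dg - fv / (dq - H)
      dg <- pmax(dg, 0)
    }
    sig[, idx] <- sp - CN * rep(dg, each = 6)
    dgamma[idx] <- dg
    Nflow[, idx] <- Np
  }
  list(sig = sig, dgamma = dgamma, Nflow = Nflow, plastic = plastic)
}

# Elastoplastic (continuum) tangent for one state; C elastic 6x6.
j2_tangent <- function(C, sig, H) {
  q <- von_mises(sig)
  if (q <= 0) return(C)
  p <- mean(sig[1:3])
  s <- sig; s[1:3] <- s[1:3] - p
  N <- s * (3 / (2 * q)); N[4:6] <- 2 * N[4:6]
  CN <- C %*% N
  C - (CN %*% t(CN)) / (sum(N * CN) + H)
}

# Direction-resolved yield constants for a tissue (transverse flesh keeps
# separate axial/radial bio-yield and tangent moduli; the J2 surface for a
# given simulated loading direction uses the matching pair).
plastic_constants <- function(params, direction = c("axial", "radial")) {
  direction <- match.arg(direction)
  if (params$symmetry == "isotropic") {
    if (is.null(params$sigma_y) || is.null(params$Et)) return(NULL)
    list(sigma_y = params$sigma_y,
         H = hardening_modulus(params$E, params$Et))
  } else {
    sy <- if (direction == "axial") params$sigma_y_axial else
      params$sigma_y_radial
    E <- if (direction == "axial") params$E_axial else params$E_radial
    Et <- if (direction == "axial") params$Et_axial else params$Et_radial
    if (is.null(sy) || is.null(Et)) return(NULL)
    list(sigma_y = sy, H = hardening_modulus(E, Et))
  }
}

#' Radial-return stress update
#'
#' One strain-driven update of a single material point under bilinear J2
#' plasticity with linear isotropic hardening.  The trial stress
#' `C (strain - plastic strain)` is returned to the yield surface
#' `q = sigma_y + H ebar_p` along the trial flow normal; the plastic
#' multiplier is iterated until the yield residual is below
#' `1e-12 * sigma_y`.  Purely elastic steps leave the plastic state
#' untouched and return the elastic tangent.
#'
#' @param state list with `stress` (Voigt 6), `eps_p` (engineering Voigt 6)
#'   and `ebar_p` (scalar, non-decreasing); use [virgin_state()] to start.
#' @param dstrain engineering Voigt strain increment (length 6).
#' @param params [tissue_params()]; must carry a yield stress and tangent
#'   modulus (for transverse flesh, the pair matching `direction`).
#' @param stiffness optional precomputed 6x6 elastic stiffness.
#' @param direction `"axial"` or `"radial"`: which bio-yield/tangent pair a
#'   transversely isotropic tissue uses.
#' @return list with the updated `state` (also carrying `strain`) and the
#'   consistent `tangent` (6x6).
#' @export
#' @examples
#' fl <- tissue_params("flesh_axial", E = 2.305, Et = 0.967,
#'                     sigma_y = 0.491, nu = 0.40)
#' st <- virgin_state()
#' up <- radial_return(st, c(0.05, -0.02, -0.02, 0, 0, 0), fl)
#' up$state$ebar_p   # still elastic: 0
radial_return <- function(state, dstrain, params, stiffness = NULL,
                          direction = "axial") {
  if (!all(is.finite(dstrain)) || length(dstrain) != 6)
    stopf("dstrain must be a finite length-6 engineering Voigt vector")
  C <- stiffness %||% elastic_stiffness(params)
  pc <- plastic_constants(params, direction)
  strain <- (state$strain %||% numeric(6)) + dstrain
  eps_e <- strain - state$eps_p
  sig_tr <- as.numeric(C %*% eps_e)
  if (is.null(pc)) {  # elastic-only tissue (skin)
    new <- list(stress = sig_tr, strain = strain, eps_p = state$eps_p,
                ebar_p = state$ebar_p)
    return(list(state = new, tangent = C))
  }
  rm_ <- j2_return_map(matrix(sig_tr, 6, 1), state$ebar_p, C,
                       pc$sigma_y, pc$H)
  sig <- rm_$sig[, 1]
  dg <- rm_$dgamma[1]
  eps_p <- state$eps_p + dg * rm_$Nflow[, 1]
  tangent <- if (rm_$plastic[1]) j2_tangent(C, sig, pc$H) else C
  new <- list(stress = sig, strain = strain, eps_p = eps_p,
              ebar_p = state$ebar_p + dg)
  list(state = new, tangent = tangent)
}

#' Virgin material state
#'
#' @return zero-stress state for [radial_return()].
#' @export
virgin_state <- function() {
  list(stress = numeric(6), strain = numeric(6), eps_p = numeric(6),
       ebar_p = 0)
}

#' Uniaxial stress response of a tissue
#'
#' Drives the strain in one direction while iterating the two lateral
#' normal strains to keep the lateral stresses at zero (a strain-driven
#' simulation of an unconfined uniaxial specimen).  For a bilinear tissue
#' the result is the exact bilinear curve: slope `E` up to the bio-yield
#' point, slope `Et` beyond it.
#'
#' @param params [tissue_params()].
#' @param strain increasing vector of applied strains (first entry 0 is
#'   implied).
#' @param direction `"axial"` (load along the material axis) or `"radial"`.
#' @param tol lateral-stress tolerance (MPa).
#' @return data.frame with `strain`, `stress` (MPa) and `ebar_p`.
#' @export
#' @examples
#' fl <- tissue_params("flesh_axial", E = 2.305, Et = 0.967,
#'                     sigma_y = 0.491, nu = 0.40)
#' r <- uniaxial_response(fl, seq(0, 0.4, by = 0.01))
#' tail(r, 1)$stress   # 0.491 + 0.967 * (0.4 - 0.491/2.305) = 0.6718
uniaxial_response <- function(params, strain, direction = c("axial", "radial"),
                              tol = 1e-12) {
  direction <- match.arg(direction)
  C <- elastic_stiffness(params)
  d <- if (direction == "axial") 1L else 2L
  lat <- setdiff(1:3, d)
  state <- virgin_state()
  strain <- as.numeric(strain)
  if (strain[1] != 0) strain <- c(0, strain)
  out <- data.frame(strain = strain, stress = 0, ebar_p = 0)
  for (i in seq_along(strain)[-1]) {
    de_d <- strain[i] - strain[i - 1]
    x <- rep(-params$nu * de_d, 2)  # lateral strain increment guess
    trial <- function(x) {
      dstr <- numeric(6)
      dstr[d] <- de_d; dstr[lat] <- x
      radial_return(state, dstr, params, stiffness = C,
                    direction = direction)
    }
    for (it in 1:60) {
      up <- trial(x)
      r <- up$state$stress[lat]
      if (max(abs(r)) < tol * max(1, abs(up$state$stress[d]))) break
      h <- 1e-8 * max(1, abs(de_d))
      J <- matrix(0, 2, 2)
      for (k in 1:2) {
        xk <- x; xk[k] <- xk[k] + h
        J[, k] <- (trial(xk)$state$stress[lat] - r) / h
      }
      x <- x - solve(J, r)
    }
    state <- trial(x)$state
    out$stress[i] <- state$stress[d]
    out$ebar_p[i] <- state$ebar_p
  }
  out
}
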