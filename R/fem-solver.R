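# Quasi-static, displacement-controlled nonlinear FEM for whole-fruit plate
# compression: linear tetrahedra for flesh and core, constant-strain
# membrane triangles for the skin, bilinear J2 plasticity through the
# radial-return map, and mortar-style node-averaged penalty contact with
# elastic-Coulomb friction against two axis-aligned rigid plates (lower
# fixed, upper advancing).  The nonlinear system is solved by full Newton
# with the elastoplastic consistent tangent and adaptive step bisection;
# all element-level work is vectorized over elements.

#' Compression simulation configuration
#'
#' @param direction `"axial"`, `"long_radial"` or `"short_radial"` (the
#'   compression axis; the material symmetry axis stays the fruit axis).
#' @param target_strain plate travel as a fraction of the initial
#'   plate-to-plate dimension, in (0, 0.5).
#' @param n_increments number of equal displacement increments (default:
#'   one per 0.5% strain).
#' @param contact_penalty penalty pressure stiffness (N/mm^3: pressure per
#'   unit penetration, integrated over the contact surface); default: 100
#'   times the stiffest elastic modulus divided by the surface element
#'   size.
#' @param friction_mu Coulomb friction coefficient (default 0.428).
#' @param newton_tol relative residual tolerance (against the total
#'   contact force).
#' @param max_newton_iters Newton iteration cap per increment.
#' @param record_at strain levels at which full stress fields are kept
#'   (default: every 2.5% plus the final level).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(direction = "axial", target_strain = 0.05,
                              n_increments = NULL, contact_penalty = NULL,
                              friction_mu = 0.428, newton_tol = 1e-6,
                              max_newton_iters = 30L, record_at = NULL) {
  direction <- match.arg(direction, DIRECTIONS)
  if (!is_number(target_strain) || target_strain <= 0 ||
      target_strain >= 0.5)
    stopf("target_strain must lie in (0, 0.5)")
  n_increments <- as.integer(n_increments %||%
                               max(1, round(target_strain / 0.005)))
  if (n_increments < 1) stopf("n_increments must be >= 1")
  if (!is.null(contact_penalty) &&
      (!is_number(contact_penalty) || contact_penalty <= 0))
    stopf("contact_penalty must be positive")
  if (!is_number(friction_mu) || friction_mu < 0)
    stopf("friction_mu must be >= 0")
  record_at <- record_at %||%
    unique(c(if (target_strain >= 0.025)
      seq(0.025, target_strain, by = 0.025), target_strain))
  record_at <- sort(unique(record_at[record_at <= target_strain + 1e-12]))
  structure(list(direction = direction, target_strain = target_strain,
                 n_increments = n_increments,
                 contact_penalty = contact_penalty,
                 friction_mu = friction_mu, newton_tol = newton_tol,
                 max_newton_iters = as.integer(max_newton_iters),
                 record_at = record_at),
            class = "simulation_config")
}

# ---------------------------------------------------------------------------
# Model setup: per-region constitutive data, dof maps, cached elastic
# stiffness triplets, membrane stiffness, constraint and contact metadata.

fem_model <- function(mesh, materials, direction = "axial") {
  stopifnot(inherits(mesh, "fruit_mesh") || is.list(mesh))
  ax <- direction_axis(direction)
  M <- nrow(mesh$tets); N <- nrow(mesh$nodes)
  if (is.null(materials$flesh)) stopf("materials must contain a 'flesh' entry")
  has_core <- any(mesh$region == "core")
  if (has_core && is.null(materials$core))
    stopf("mesh has core elements but materials has no 'core' entry")
  dir_kind <- if (ax == 1L) "axial" else "radial"
  regions <- list()
  mk_region <- function(name, params, idx) {
    C <- elastic_stiffness(params, axis = c(1, 0, 0))
    pc <- plastic_constants(params, dir_kind)
    list(name = name, idx = idx, C = C,
         A4 = stiffness_to_tensor4(C), pc = pc)
  }
  regions$flesh <- mk_region("flesh", materials$flesh,
                             which(mesh$region == "flesh"))
  if (has_core)
    regions$core <- mk_region("core", materials$core,
                              which(mesh$region == "core"))
  # dof bookkeeping: local column p = (a - 1) * 3 + i
  D <- matrix(0L, M, 12L)
  for (a in 1:4) for (i in 1:3)
    D[, (a - 1L) * 3L + i] <- 3L * (mesh$tets[, a] - 1L) + i
  pq <- expand.grid(p = 1:12, q = 1:12)
  ii_mat <- D[, pq$p, drop = FALSE]
  jj_mat <- D[, pq$q, drop = FALSE]
  G <- list(mesh$grads$gx, mesh$grads$gy, mesh$grads$gz)
  V <- mesh$volumes
  # cached elastic element stiffness values (M x 144)
  vals_el <- matrix(0, M, 144L)
  for (rg in regions) {
    idx <- rg$idx
    A <- rg$A4
    for (col in seq_len(144L)) {
      p <- pq$p[col]; q <- pq$q[col]
      a <- (p - 1L) %/% 3L + 1L; i <- (p - 1L) %% 3L + 1L
      b <- (q - 1L) %/% 3L + 1L; j <- (q - 1L) %% 3L + 1L
      acc <- 0
      for (k in 1:3) for (l in 1:3) {
        Aik <- A[i, k, j, l]
        if (Aik != 0)
          acc <- acc + Aik * (G[[k]][idx, a] * G[[l]][idx, b])
      }
      vals_el[idx, col] <- V[idx] * acc
    }
  }
  mem <- if (!is.null(materials$skin) && !is.null(mesh$skin_tris) &&
             nrow(mesh$skin_tris) > 0)
    membrane_setup(mesh, materials$skin) else NULL
  list(mesh = mesh, materials = materials, direction = direction, ax = ax,
       N = N, M = M, regions = regions, D = D,
       ii = as.integer(ii_mat), jj = as.integer(jj_mat),
       vals_el = vals_el, G = G, V = V, mem = mem, dir_kind = dir_kind)
}

# Constant-strain membrane triangles on the outer surface (plane stress,
# thickness from dims; in-plane stiffness only).
membrane_setup <- function(mesh, skin) {
  tris <- mesh$skin_tris
  K <- nrow(tris)
  t_ <- mesh$dims$skin_thickness %||% 0.5
  E <- skin$E; nu <- skin$nu
  Dm <- E / (1 - nu^2) *
    matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  DBT <- matrix(0, K, 27L)   # per-tri 3x9 stress-recovery, row-major packed
  dofs <- matrix(0L, K, 9L)
  areas <- numeric(K)
  ii_l <- vector("list", K); jj_l <- vector("list", K); xx_l <- vector("list", K)
  for (e in seq_len(K)) {
    nd <- tris[e, ]
    X <- mesh$nodes[nd, ]
    e1 <- X[2, ] - X[1, ]
    nrm <- c(e1[2] * (X[3, 3] - X[1, 3]) - e1[3] * (X[3, 2] - X[1, 2]),
             e1[3] * (X[3, 1] - X[1, 1]) - e1[1] * (X[3, 3] - X[1, 3]),
             e1[1] * (X[3, 2] - X[1, 2]) - e1[2] * (X[3, 1] - X[1, 1]))
    A2 <- sqrt(sum(nrm^2))
    areas[e] <- A2 / 2
    e1 <- e1 / sqrt(sum(e1^2))
    nn <- nrm / A2
    e2 <- c(nn[2] * e1[3] - nn[3] * e1[2],
            nn[3] * e1[1] - nn[1] * e1[3],
            nn[1] * e1[2] - nn[2] * e1[1])
    # local 2D coordinates
    x <- c(0, sum((X[2, ] - X[1, ]) * e1), sum((X[3, ] - X[1, ]) * e1))
    y <- c(0, sum((X[2, ] - X[1, ]) * e2), sum((X[3, ] - X[1, ]) * e2))
    A <- areas[e]
    B <- matrix(0, 3, 6)
    yv <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
    xv <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
    for (a in 1:3) {
      B[1, 2 * a - 1] <- yv[a]
      B[2, 2 * a] <- xv[a]
      B[3, 2 * a - 1] <- xv[a]
      B[3, 2 * a] <- yv[a]
    }
    B <- B / (2 * A)
    Tm <- matrix(0, 6, 9)
    for (a in 1:3) {
      Tm[2 * a - 1, (3 * a - 2):(3 * a)] <- e1
      Tm[2 * a, (3 * a - 2):(3 * a)] <- e2
    }
    Kg <- t(Tm) %*% (t_ * A * t(B) %*% Dm %*% B) %*% Tm
    dof <- as.integer(rbind(3L * (nd - 1L) + 1L, 3L * (nd - 1L) + 2L,
                            3L * (nd - 1L) + 3L))
    dofs[e, ] <- dof
    DBT[e, ] <- as.numeric(t(Dm %*% B %*% Tm))  # rows of the 3x9 packed
    ii_l[[e]] <- rep(dof, times = 9L)
    jj_l[[e]] <- rep(dof, each = 9L)
    xx_l[[e]] <- as.numeric(Kg)
  }
  Kmem <- sparseMatrix(i = unlist(ii_l), j = unlist(jj_l), x = unlist(xx_l),
                       dims = c(3 * nrow(mesh$nodes), 3 * nrow(mesh$nodes)))
  list(K = Kmem, DBT = DBT, dofs = dofs, areas = areas, thickness = t_)
}

# Membrane in-plane stress (3 x K: sxx, syy, sxy in the local frame).
membrane_stress <- function(mem, u) {
  K <- nrow(mem$dofs)
  ue <- matrix(u[t(mem$dofs)], nrow = 9L)   # 9 x K
  s <- matrix(0, 3, K)
  for (r in 1:3) {
    Br <- mem$DBT[, (9 * (r - 1) + 1):(9 * r), drop = FALSE]  # K x 9
    s[r, ] <- rowSums(Br * t(ue))
  }
  s
}

membrane_von_mises <- function(s) {
  sqrt(s[1, ]^2 + s[2, ]^2 - s[1, ] * s[2, ] + 3 * s[3, ]^2)
}

# Small strain from nodal displacements: 6 x M engineering Voigt.
element_strain <- function(model, u) {
  mesh <- model$mesh
  ux <- u[seq(1, 3 * model$N, by = 3)]
  uy <- u[seq(2, 3 * model$N, by = 3)]
  uz <- u[seq(3, 3 * model$N, by = 3)]
  gx <- model$G[[1]]; gy <- model$G[[2]]; gz <- model$G[[3]]
  eps <- matrix(0, 6, model$M)
  for (a in 1:4) {
    na <- mesh$tets[, a]
    ax_ <- ux[na]; ay <- uy[na]; az <- uz[na]
    eps[1, ] <- eps[1, ] + gx[, a] * ax_
    eps[2, ] <- eps[2, ] + gy[, a] * ay
    eps[3, ] <- eps[3, ] + gz[, a] * az
    eps[4, ] <- eps[4, ] + gz[, a] * ay + gy[, a] * az
    eps[5, ] <- eps[5, ] + gz[, a] * ax_ + gx[, a] * az
    eps[6, ] <- eps[6, ] + gy[, a] * ax_ + gx[, a] * ay
  }
  eps
}

# Stress update from committed plastic state; returns per-element stress and
# the return-map byproducts needed for the tangent and for committing.
stress_update <- function(model, eps, eps_p, ebar) {
  M <- model$M
  sig <- matrix(0, 6, M)
  dgamma <- numeric(M)
  Nflow <- matrix(0, 6, M)
  plastic <- logical(M)
  for (rg in model$regions) {
    idx <- rg$idx
    ee <- eps[, idx, drop = FALSE] - eps_p[, idx, drop = FALSE]
    st <- rg$C %*% ee
    if (is.null(rg$pc)) {
      sig[, idx] <- st
    } else {
      rmp <- j2_return_map(st, ebar[idx], rg$C, rg$pc$sigma_y, rg$pc$H)
      sig[, idx] <- rmp$sig
      dgamma[idx] <- rmp$dgamma
      Nflow[, idx] <- rmp$Nflow
      plastic[idx] <- rmp$plastic
    }
  }
  list(sig = sig, dgamma = dgamma, Nflow = Nflow, plastic = plastic)
}

# Internal nodal force vector from element stresses (plus membrane).
internal_force <- function(model, sig, u) {
  mesh <- model$mesh
  gx <- model$G[[1]]; gy <- model$G[[2]]; gz <- model$G[[3]]
  V <- model$V
  Fc <- matrix(0, model$M, 12L)
  for (a in 1:4) {
    Fc[, (a - 1L) * 3L + 1L] <- V * (sig[1, ] * gx[, a] +
                                     sig[6, ] * gy[, a] + sig[5, ] * gz[, a])
    Fc[, (a - 1L) * 3L + 2L] <- V * (sig[6, ] * gx[, a] +
                                     sig[2, ] * gy[, a] + sig[4, ] * gz[, a])
    Fc[, (a - 1L) * 3L + 3L] <- V * (sig[5, ] * gx[, a] +
                                     sig[4, ] * gy[, a] + sig[3, ] * gz[, a])
  }
  f <- numeric(3L * model$N)
  acc <- rowsum(as.vector(Fc), as.vector(model$D))
  f[as.integer(rownames(acc))] <- acc
  if (!is.null(model$mem)) f <- f + as.numeric(model$mem$K %*% u)
  f
}

# Rank-one elastoplastic corrections to the cached elastic stiffness values;
# returns triplets (i, j, x) for the plastic elements only.
plastic_correction_triplets <- function(model, upd) {
  idx <- which(upd$plastic)
  if (length(idx) == 0) return(NULL)
  sig <- upd$sig[, idx, drop = FALSE]
  q <- von_mises(sig)
  ok <- q > 0
  idx <- idx[ok]
  if (length(idx) == 0) return(NULL)
  sig <- sig[, ok, drop = FALSE]; q <- q[ok]
  p <- colMeans(sig[1:3, , drop = FALSE])
  s <- sig
  s[1:3, ] <- sweep(sig[1:3, , drop = FALSE], 2, p, "-")
  Nf <- s * (3 / (2 * q))[col(s)]
  Nf[4:6, ] <- 2 * Nf[4:6, ]
  # per-element C N and denominator (region-wise constants)
  CN <- matrix(0, 6, length(idx))
  H <- numeric(length(idx))
  for (rg in model$regions) {
    if (is.null(rg$pc)) next
    sel <- idx %in% rg$idx
    if (!any(sel)) next
    CN[, sel] <- rg$C %*% Nf[, sel, drop = FALSE]
    H[sel] <- rg$pc$H
  }
  denom <- colSums(Nf * CN) + H
  beta <- 1 / denom
  # W[, p] with p = (a-1)*3 + i:  sum_k wt[i,k] g_a[k]; wt symmetric from CN
  gx <- model$G[[1]][idx, , drop = FALSE]
  gy <- model$G[[2]][idx, , drop = FALSE]
  gz <- model$G[[3]][idx, , drop = FALSE]
  w1 <- CN[1, ]; w2 <- CN[2, ]; w3 <- CN[3, ]
  w4 <- CN[4, ]; w5 <- CN[5, ]; w6 <- CN[6, ]
  W <- matrix(0, length(idx), 12L)
  for (a in 1:4) {
    W[, (a - 1L) * 3L + 1L] <- w1 * gx[, a] + w6 * gy[, a] + w5 * gz[, a]
    W[, (a - 1L) * 3L + 2L] <- w6 * gx[, a] + w2 * gy[, a] + w4 * gz[, a]
    W[, (a - 1L) * 3L + 3L] <- w5 * gx[, a] + w4 * gy[, a] + w3 * gz[, a]
  }
  Vb <- model$V[idx] * beta
  vals <- matrix(0, length(idx), 144L)
  col <- 0L
  for (qq in 1:12) for (pp in 1:12) {
    col <- col + 1L
    vals[, col] <- -Vb * W[, pp] * W[, qq]
  }
  D <- model$D
  pq <- expand.grid(p = 1:12, q = 1:12)
  ii <- as.integer(D[idx, pq$p, drop = FALSE])
  jj <- as.integer(D[idx, pq$q, drop = FALSE])
  list(i = ii, j = jj, x = as.numeric(vals))
}

#' Assemble the global tangent stiffness and internal force
#'
#' Standard displacement FEM assembly for a (possibly deformed) state:
#' linear-tet solid stiffness consistent with the radial-return update,
#' plus the skin membrane when `materials$skin` is present.  Boundary
#' conditions and contact are not included; the matrix is singular exactly
#' on the rigid-body modes.
#'
#' @param mesh a [build_fruit_mesh()] mesh (or compatible list).
#' @param materials named list of [tissue_params()]: `flesh`, optionally
#'   `core` and `skin`.
#' @param displacement nodal displacements, `3N` vector or `N x 3` matrix
#'   (default zero).
#' @param eps_p,ebar committed plastic state (default virgin).
#' @param direction loading direction (selects the flesh yield pair).
#' @return list with sparse symmetric `K` (3N x 3N), `f_int` (3N),
#'   per-element `stress` (6 x M) and `von_mises` (M).
#' @export
assemble_system <- function(mesh, materials, displacement = NULL,
                            eps_p = NULL, ebar = NULL,
                            direction = "axial") {
  model <- fem_model(mesh, materials, direction)
  u <- displacement %||% numeric(3 * model$N)
  if (is.matrix(u)) u <- as.numeric(t(u))
  eps_p <- eps_p %||% matrix(0, 6, model$M)
  ebar <- ebar %||% numeric(model$M)
  eps <- element_strain(model, u)
  upd <- stress_update(model, eps, eps_p, ebar)
  f <- internal_force(model, upd$sig, u)
  K <- build_tangent(model, upd)
  list(K = K, f_int = f, stress = upd$sig, von_mises = von_mises(upd$sig))
}

build_tangent <- function(model, upd, extra = NULL) {
  corr <- plastic_correction_triplets(model, upd)
  ii <- model$ii; jj <- model$jj; xx <- as.numeric(model$vals_el)
  if (!is.null(corr)) {
    ii <- c(ii, corr$i); jj <- c(jj, corr$j); xx <- c(xx, corr$x)
  }
  if (!is.null(extra)) {
    ii <- c(ii, extra$i); jj <- c(jj, extra$j); xx <- c(xx, extra$x)
  }
  K <- sparseMatrix(i = ii, j = jj, x = xx,
                    dims = c(3 * model$N, 3 * model$N))
  if (!is.null(model$mem)) K <- K + model$mem$K
  K
}

# ---------------------------------------------------------------------------

#' Solve displacement-controlled plate compression
#'
#' Compresses the fruit between two rigid axis-normal plates: the lower
#' plate is fixed, the upper advances by
#' `target_strain * initial dimension` in equal increments.  Contact is a
#' mortar-style penalty: the gap to each plate - measured against the
#' exact ellipsoid surface, with the unmeshed facet-to-surface sliver
#' acting as an elastic layer in series - is averaged per surface node
#' over its facet ring with area weights, giving one smooth constraint
#' per surface node.  Friction is elastic-Coulomb (stick stiffness =
#' normal penalty, slip at `|t| = mu p`); surface points exactly on a
#' plate at the start count as in contact.  Increments that fail to
#' converge are bisected adaptively.  Rigid-body drift is removed by pinning the
#' lateral components of the two contact-pole nodes and one tangential
#' component of an equatorial node.  Each increment is solved by Newton
#' iteration on the residual with the consistent elastoplastic tangent.
#'
#' @param mesh a [build_fruit_mesh()] mesh.
#' @param materials named list of [tissue_params()] (`flesh`, `core`,
#'   `skin` as applicable).
#' @param config a [simulation_config()].
#' @param verbose print per-increment Newton summaries.
#' @return object of class `compression_solution`: the reaction
#'   [fd_curve()] (`$curve`), snapshots of the stress state at the
#'   `record_at` strain levels (`$snapshots`), a convergence log, the
#'   final plastic state, and run metadata.
#' @export
solve_compression <- function(mesh, materials, config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  model <- fem_model(mesh, materials, config$direction)
  ax <- model$ax
  N <- model$N
  xs <- mesh$nodes[, ax]
  dimension <- max(xs) - min(xs)
  travel_total <- config$target_strain * dimension
  dtravel <- travel_total / config$n_increments
  lat <- setdiff(1:3, ax)
  if (is.null(mesh$skin_tris) || nrow(mesh$skin_tris) == 0)
    stopf("plate contact needs the outer-surface triangulation (skin_tris)")

  # Mortar-style penalty contact: the gap to each rigid plate is averaged
  # per surface node over its facet ring (area weighting by quadrature on
  # the outer triangles), giving one smooth constraint per surface node.
  # Per-facet quadrature constraints over-constrain the surface (about six
  # sample points per node) and lock it against the rigid-surface
  # curvature; node-averaged gaps do not.  Gaps are measured against the
  # exact ellipsoid surface at each point's lateral position, and the
  # unmeshed material between the inscribed facet and the exact surface
  # (height = local sagitta) acts as an elastic layer in series with the
  # penalty - neither absent nor rigid.
  tris <- mesh$skin_tris
  areas <- triangle_areas(mesh$nodes, tris)
  qp_bary <- rbind(c(2, 1, 1), c(1, 2, 1), c(1, 1, 2)) / 4
  nq <- 3L * nrow(tris)
  qp_node <- tris[rep(seq_len(nrow(tris)), each = 3L), , drop = FALSE]
  qp_w <- rep(areas / 3, each = 3L)
  qp_N <- qp_bary[rep(1:3, nrow(tris)), , drop = FALSE]
  h_surf <- sqrt(mean(areas))
  Cmax <- max(vapply(model$regions, function(r) max(diag(r$C)), numeric(1)))
  kp <- config$contact_penalty %||% (100 * Cmax / h_surf)
  mu <- config$friction_mu
  # quadrature-point geometry
  qp_coord <- function(col) {
    qp_N[, 1] * mesh$nodes[qp_node[, 1], col] +
      qp_N[, 2] * mesh$nodes[qp_node[, 2], col] +
      qp_N[, 3] * mesh$nodes[qp_node[, 3], col]
  }
  X_ax <- qp_coord(ax); X_t1 <- qp_coord(lat[1]); X_t2 <- qp_coord(lat[2])
  if (!is.null(mesh$dims)) {
    semi <- c(mesh$dims$a_axial, mesh$dims$a_long, mesh$dims$a_short)
    rad2 <- 1 - (X_t1 / semi[lat[1]])^2 - (X_t2 / semi[lat[2]])^2
    X_cap <- semi[ax] * sqrt(pmax(rad2, 0))
    X_ax_u <- ifelse(X_ax >= 0, X_cap, X_ax)
    X_ax_l <- ifelse(X_ax <= 0, -X_cap, X_ax)
  } else {
    X_ax_u <- X_ax
    X_ax_l <- X_ax
  }
  C_surf <- model$regions$flesh$C[ax, ax]
  sag_u <- pmax(X_ax_u - X_ax, 0)
  sag_l <- pmax(X_ax - X_ax_l, 0)
  # surface-node averaging operator
  snode <- sort(unique(as.integer(tris)))
  ns <- length(snode)
  sidx <- match(qp_node, snode)            # nq x 3 positions in snode
  Wm <- sparseMatrix(i = as.integer(sidx), j = rep(seq_len(nq), 3L),
                     x = as.numeric(qp_N) * rep(qp_w, 3L),
                     dims = c(ns, nq))
  Aa <- as.numeric(Wm %*% rep(1, nq))      # tributary areas
  Nq <- sparseMatrix(i = rep(seq_len(nq), 3L), j = as.integer(sidx),
                     x = as.numeric(qp_N), dims = c(nq, ns))
  Bn <- Diagonal(x = 1 / Aa) %*% Wm %*% Nq # averaged interpolation, ns x ns
  Bnt <- t(Bn)
  Xb_u <- as.numeric(Wm %*% X_ax_u) / Aa
  Xb_l <- as.numeric(Wm %*% X_ax_l) / Aa
  sagb_u <- as.numeric(Wm %*% sag_u) / Aa
  sagb_l <- as.numeric(Wm %*% sag_l) / Aa
  kq_u <- 1 / (1 / kp + sagb_u / C_surf)   # effective stiffness per node
  kq_l <- 1 / (1 / kp + sagb_l / C_surf)
  sdof_ax <- 3L * (snode - 1L) + ax
  sdof_l1 <- 3L * (snode - 1L) + lat[1]
  sdof_l2 <- 3L * (snode - 1L) + lat[2]

  # constraints against rigid-body drift
  top <- which.max(xs); bot <- which.min(xs)
  eq_node <- which.max(mesh$nodes[, lat[1]])
  fixed <- c(3L * (top - 1L) + lat, 3L * (bot - 1L) + lat,
             3L * (eq_node - 1L) + lat[2])
  free <- setdiff(seq_len(3L * N), fixed)

  P_u0 <- max(xs); P_l0 <- min(xs)
  u <- numeric(3 * N)
  eps_p <- matrix(0, 6, model$M)
  ebar <- numeric(model$M)
  anchors_u <- mesh$nodes[snode, lat, drop = FALSE]
  anchors_l <- mesh$nodes[snode, lat, drop = FALSE]

  contact_eval <- function(u, P_u, frozen = NULL) {
    ub_ax <- as.numeric(Bn %*% u[sdof_ax])   # averaged axial displacement
    x_t <- cbind(mesh$nodes[snode, lat[1]] + u[sdof_l1],
                 mesh$nodes[snode, lat[2]] + u[sdof_l2])
    g_u <- Xb_u + ub_ax - P_u     # > 0: penetration of the upper plate
    g_l <- P_l0 - (Xb_l + ub_ax)
    act_u <- g_u >= -1e-12
    act_l <- g_l >= -1e-12
    Nu <- kq_u * Aa * pmax(g_u, 0)   # normal force per surface node
    Nl <- kq_l * Aa * pmax(g_l, 0)
    fric <- function(active, Nn, anchors, kq, fz = NULL) {
      ft <- matrix(0, ns, 2)
      stick <- logical(ns)
      if (mu > 0 && any(active)) {
        spring <- -kq * Aa *
          (x_t - anchors)
        if (is.null(fz)) {
          ft[active, ] <- spring[active, , drop = FALSE]
          mag <- sqrt(rowSums(ft^2))
          lim <- mu * Nn
          slip <- active & mag > lim & mag > 0
          if (any(slip)) {
            sc <- lim[slip] / mag[slip]
            ft[slip, ] <- ft[slip, , drop = FALSE] * sc
          }
          stick <- active & !slip
        } else {
          # the stick/slip classification is frozen after a few Newton
          # iterations (switching is non-smooth and can cycle): sticking
          # points keep their consistent springs, slipping points keep
          # their frozen force vectors
          stick <- fz$stick & active
          ft[stick, ] <- spring[stick, , drop = FALSE]
          slip_frozen <- active & !stick
          ft[slip_frozen, ] <- fz$ft[slip_frozen, , drop = FALSE]
        }
      }
      list(ft = ft, stick = stick)
    }
    if (is.null(frozen)) {
      fu <- fric(act_u, Nu, anchors_u, kq_u)
      fl <- fric(act_l, Nl, anchors_l, kq_l)
    } else {
      fu <- fric(act_u, Nu, anchors_u, kq_u, frozen$u)
      fl <- fric(act_l, Nl, anchors_l, kq_l, frozen$l)
    }
    f_cont <- numeric(3 * N)
    f_cont[sdof_ax] <- as.numeric(Bnt %*% (-Nu + Nl))
    f_cont[sdof_l1] <- fu$ft[, 1] + fl$ft[, 1]
    f_cont[sdof_l2] <- fu$ft[, 2] + fl$ft[, 2]
    list(f = f_cont, act_u = act_u, act_l = act_l, Nu = Nu, Nl = Nl,
         stick_u = fu$stick, stick_l = fl$stick, x_t = x_t,
         ft_u = fu$ft, ft_l = fl$ft,
         energy = 0.5 * (sum(Nu * pmax(g_u, 0)) + sum(Nl * pmax(g_l, 0))))
  }

  residual <- function(u, P_u, frozen = NULL) {
    eps <- element_strain(model, u)
    upd <- stress_update(model, eps, eps_p, ebar)
    f_int <- internal_force(model, upd$sig, u)
    ct <- contact_eval(u, P_u, frozen)
    r <- f_int - ct$f
    r[fixed] <- 0
    scale <- max(1, sum(ct$Nu), sum(ct$Nl))
    list(r = r, norm = sqrt(sum(r^2)), scale = scale, upd = upd, ct = ct)
  }

  contact_triplets <- function(ct) {
    # normal: kp-weighted Gram matrix of the averaged interpolation rows
    dg <- kq_u * Aa * ct$act_u + kq_l * Aa * ct$act_l
    Kc <- Bnt %*% Diagonal(x = dg) %*% Bn
    Kc <- as(Kc, "TsparseMatrix")
    ii <- sdof_ax[Kc@i + 1L]; jj <- sdof_ax[Kc@j + 1L]; xx <- Kc@x
    if (mu > 0) {
      st_u <- ct$stick_u; st_l <- ct$stick_l
      dlat <- kq_u * Aa * st_u + kq_l * Aa * st_l
      sel <- dlat > 0
      ii <- c(ii, sdof_l1[sel], sdof_l2[sel])
      jj <- c(jj, sdof_l1[sel], sdof_l2[sel])
      xx <- c(xx, dlat[sel], dlat[sel])
    }
    list(i = ii, j = jj, x = xx)
  }

  curve_d <- 0; curve_f <- 0
  snapshots <- list()
  log <- NULL
  rec_incs <- unique(pmin(config$n_increments,
                          pmax(1L, round(config$record_at *
                                           dimension / dtravel))))
  travel <- 0
  for (inc in seq_len(config$n_increments)) {
    travel_target <- travel + dtravel
    # Newton solve to a given plate travel from the committed state; on
    # non-convergence the step is bisected (contact-set or stick/slip
    # changes occasionally make a full step non-smooth)
    attempt <- function(trv) {
      P_u <- P_u0 - trv
      frozen <- NULL
      u_try <- u
      res <- residual(u_try, P_u)
      it <- 0L
      while (it < config$max_newton_iters) {
        if (res$norm <= config$newton_tol * res$scale)
          return(list(ok = TRUE, u = u_try, res = res, it = it))
        it <- it + 1L
        if (mu > 0 && it == 4L) {
          frozen <- list(u = list(stick = res$ct$stick_u, ft = res$ct$ft_u),
                         l = list(stick = res$ct$stick_l, ft = res$ct$ft_l))
          res <- residual(u_try, P_u, frozen)
        }
        K <- build_tangent(model, res$upd, extra = contact_triplets(res$ct))
        Kff <- K[free, free]
        rhs <- res$r[free]
        Ks <- forceSymmetric(Kff)
        du_f <- tryCatch({
          ch <- Cholesky(Ks, LDL = FALSE, perm = TRUE, super = TRUE)
          as.numeric(solve(ch, rhs))
        }, error = function(e) {
          # indefinite tangent (transient contact/plastic state): shift
          sh <- 1e-8 * mean(abs(diag(Ks)))
          ch <- Cholesky(Ks + Diagonal(nrow(Ks), sh), LDL = FALSE,
                         perm = TRUE, super = TRUE)
          as.numeric(solve(ch, rhs))
        })
        du <- numeric(3 * N)
        du[free] <- -du_f
        alpha <- 1
        res_try <- residual(u_try + du, P_u, frozen)
        tries <- 0L
        while (res_try$norm > 4 * res$norm && tries < 4L) {
          alpha <- alpha / 2
          res_try <- residual(u_try + alpha * du, P_u, frozen)
          tries <- tries + 1L
        }
        u_try <- u_try + alpha * du
        res <- res_try
      }
      list(ok = res$norm <= config$newton_tol * res$scale, u = u_try,
           res = res, it = it)
    }
    commit <- function(sol_inc) {
      u <<- sol_inc$u
      res <- sol_inc$res
      dg <- res$upd$dgamma
      if (any(dg > 0)) {
        eps_p <<- eps_p + res$upd$Nflow * rep(dg, each = 6)
        ebar <<- ebar + dg
      }
      if (mu > 0) {
        upd_anchor <- function(anchors, ft, act, kq) {
          anchors[act, ] <- res$ct$x_t[act, , drop = FALSE] +
            ft[act, , drop = FALSE] / (kq[act] * Aa[act])
          anchors[!act, ] <- res$ct$x_t[!act, , drop = FALSE]
          anchors
        }
        anchors_u <<- upd_anchor(anchors_u, res$ct$ft_u, res$ct$act_u, kq_u)
        anchors_l <<- upd_anchor(anchors_l, res$ct$ft_l, res$ct$act_l, kq_l)
      }
    }
    advance <- function(trv, depth) {
      sol_inc <- attempt(trv)
      if (sol_inc$ok) {
        commit(sol_inc)
        return(sol_inc)
      }
      if (depth >= 4L)
        stopf(paste("Newton failed to converge in increment %d/%d",
                    "(travel %.3f mm, %d bisections): residual %.3g vs",
                    "tolerance %.3g"),
              inc, config$n_increments, trv, depth, sol_inc$res$norm,
              config$newton_tol * sol_inc$res$scale)
      mid <- (travel + trv) / 2
      advance(mid, depth + 1L)
      travel <<- mid
      advance(trv, depth + 1L)
    }
    sol_inc <- advance(travel_target, 0L)
    travel <- travel_target
    res <- sol_inc$res
    it <- sol_inc$it
    F_up <- sum(res$ct$Nu)
    F_low <- sum(res$ct$Nl)
    curve_d <- c(curve_d, travel)
    curve_f <- c(curve_f, F_up)
    log <- rbind(log, data.frame(increment = inc, travel = travel,
                                 iters = it, residual = res$norm,
                                 force_upper = F_up, force_lower = F_low,
                                 n_contact_upper = sum(res$ct$act_u),
                                 n_contact_lower = sum(res$ct$act_l)))
    if (verbose)
      message(sprintf(
        "inc %3d/%d  travel %7.3f mm  F = %9.3f N  %d iters  res %.2e",
        inc, config$n_increments, travel, F_up, it, res$norm))
    if (inc %in% rec_incs) {
      sk <- if (!is.null(model$mem)) {
        sm <- membrane_stress(model$mem, u)
        list(stress = sm, von_mises = membrane_von_mises(sm))
      } else NULL
      snapshots[[length(snapshots) + 1L]] <- list(
        strain_level = travel / dimension, travel = travel,
        force_upper = F_up, force_lower = F_low,
        u = matrix(u, ncol = 3, byrow = TRUE),
        stress = res$upd$sig, von_mises = von_mises(res$upd$sig),
        ebar_p = ebar, skin = sk, contact_energy = res$ct$energy)
    }
  }
  out <- list(curve = fd_curve(curve_d, curve_f), snapshots = snapshots,
              log = log, config = config, direction = config$direction,
              dimension = dimension, mesh = mesh,
              materials = materials,
              final_state = list(u = u, eps_p = eps_p, ebar_p = ebar),
              contact_penalty = kp)
  class(out) <- "compression_solution"
  out
}

#' @exportS3Method base::print
print.compression_solution <- function(x, ...) {
  cat(sprintf(
    "Compression solution: %s, %.1f%% strain (%.2f mm), peak force %.2f N\n",
    x$direction, 100 * x$config$target_strain,
    max(x$curve$displacement_mm), max(x$curve$force_N)))
  cat(sprintf("  %d increments, max Newton iters %d, %d snapshots\n",
              nrow(x$log), max(x$log$iters), length(x$snapshots)))
  invisible(x)
}

#' Per-element field snapshot
#'
#' Extracts the export-ready per-element fields (Von Mises stress,
#' equivalent plastic strain, region) at a recorded strain level, together
#' with the location of the stress maximum.
#'
#' @param solution a [solve_compression()] result.
#' @param level recorded strain level (matched within 1e-9) or snapshot
#'   index.
#' @return list with `fields` (data.frame: `von_mises`, `ebar_p`,
#'   `region`), `skin_von_mises`, `strain_level`, `force`, and
#'   `max_location` (coordinates of the centroid of the most stressed
#'   element).
#' @export
field_snapshot <- function(solution, level) {
  stopifnot(inherits(solution, "compression_solution"))
  levels <- vapply(solution$snapshots, `[[`, numeric(1), "strain_level")
  k <- if (is_number(level) && level >= 1 && level == round(level) &&
           level <= length(levels) && level > 0.5) {
    as.integer(level)
  } else {
    j <- which(abs(levels - level) < 1e-9)
    if (length(j) == 0)
      stopf("no snapshot at strain level %s (recorded: %s)", level,
            paste(signif(levels, 4), collapse = ", "))
    j[1]
  }
  sn <- solution$snapshots[[k]]
  mesh <- solution$mesh
  imax <- which.max(sn$von_mises)
  cen <- (mesh$nodes[mesh$tets[imax, 1], ] + mesh$nodes[mesh$tets[imax, 2], ] +
          mesh$nodes[mesh$tets[imax, 3], ] + mesh$nodes[mesh$tets[imax, 4], ]) / 4
  list(fields = data.frame(von_mises = sn$von_mises, ebar_p = sn$ebar_p,
                           region = solution$mesh$region),
       skin_von_mises = if (!is.null(sn$skin)) sn$skin$von_mises else NULL,
       strain_level = sn$strain_level, force = sn$force_upper,
       max_location = cen)
}

#' Run one compression direction through a set of strain levels
#'
#' Convenience wrapper: a single [solve_compression()] run to the largest
#' requested level with snapshots recorded at every level.
#'
#' @param mesh,materials as in [solve_compression()].
#' @param direction compression direction.
#' @param levels strain levels (default 2.5 / 5 / 10 / 20%).
#' @param ... further arguments to [simulation_config()].
#' @param verbose print progress.
#' @return a `compression_solution` with one snapshot per level.
#' @export
run_strain_levels <- function(mesh, materials, direction = "axial",
                              levels = c(0.025, 0.05, 0.10, 0.20), ...,
                              verbose = FALSE) {
  cfg <- simulation_config(direction = direction,
                           target_strain = max(levels),
                           record_at = levels, ...)
  solve_compression(mesh, materials, cfg, verbose = verbose)
}
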