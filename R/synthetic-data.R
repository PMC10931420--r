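# Synthetic inputs standing in for the physical study: seeded uniaxial
# specimen records per tissue (bilinear elastoplastic for flesh/core,
# linear-brittle for skin) and pseudo-experimental whole-fruit compression
# curves for the validation workflow.

#' Generate a synthetic specimen test record
#'
#' The noiseless record is the exact constitutive curve of the tissue
#' mapped to force-displacement through the specimen geometry: bilinear
#' (slope `E` to the bio-yield point, `Et` beyond) when the tissue has a
#' tangent modulus, linear to the rupture stress followed by a terminal
#' stress drop when it does not (skin).  I.i.d. Gaussian noise with
#' standard deviation `noise_rel * max(force)` is then added to the force
#' channel only (the first sample stays at the origin).
#'
#' @param tissue a [tissue_params()] with scalar constants (isotropic).
#' @param geometry a [specimen_geometry()].
#' @param mode `"compression"` or `"tension"`.
#' @param max_strain largest applied strain (< 0.5, the validity limit of
#'   the small-strain bilinear idealization); ignored for brittle tissues,
#'   which run to rupture.
#' @param n_points samples (>= 10).
#' @param noise_rel force noise as a fraction of the peak force.
#' @param seed RNG seed (restores the caller's RNG state).
#' @param toe_strain optional initial compliant toe: below `toe_strain` the
#'   stress follows a quadratic ramp whose slope reaches `E` at the toe
#'   end, shifting the subsequent curve by `toe_strain / 2`.
#' @return a [test_record()].
#' @export
#' @examples
#' mats <- default_materials()
#' g <- specimen_geometry("cylinder", diameter = 10, height = 12)
#' rec <- gen_specimen_record(mats$core, g, seed = 1, noise_rel = 0.01)
gen_specimen_record <- function(tissue, geometry,
                                mode = c("compression", "tension"),
                                max_strain = 0.4, n_points = 200L,
                                noise_rel = 0, seed = NULL, toe_strain = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(geometry, "specimen_geometry"))
  if (tissue$symmetry != "isotropic")
    stopf("specimen records are generated per loading direction: pass the
isotropic per-direction tissue entry (e.g. 'flesh_axial')")
  if (!is_number(max_strain) || max_strain >= 0.5 || max_strain <= 0)
    stopf("max_strain must lie in (0, 0.5): the bilinear small-strain model
is not valid beyond 50%% strain")
  if (n_points < 10) stopf("n_points must be >= 10")
  if (noise_rel < 0) stopf("noise_rel must be >= 0")
  E <- tissue$E
  brittle <- is.null(tissue$Et)
  if (brittle) {
    if (is.null(tissue$sigma_y))
      stopf("brittle tissue needs a rupture stress in sigma_y")
    eps_r <- tissue$sigma_y / E + toe_strain / 2
    eps <- seq(0, eps_r, length.out = n_points - 2L)
    # terminal drop: rupture is abrupt, stress collapses over two samples
    deps <- eps_r - eps[length(eps) - 1L]
    eps <- c(eps, eps_r + deps, eps_r + 2 * deps)
  } else {
    eps <- seq(0, max_strain, length.out = n_points)
  }
  base_sigma <- function(e) {
    # elastic branch with optional quadratic toe
    el <- ifelse(e < toe_strain & toe_strain > 0,
                 E * e^2 / (2 * toe_strain),
                 E * (e - toe_strain / 2))
    if (brittle) return(el)
    eps_y <- tissue$sigma_y / E + toe_strain / 2
    ifelse(e <= eps_y, el,
           tissue$sigma_y + tissue$Et * (e - eps_y))
  }
  sig <- base_sigma(eps)
  if (brittle) {
    n <- length(eps)
    sig[n - 1L] <- 0.6 * tissue$sigma_y
    sig[n] <- 0.2 * tissue$sigma_y
  }
  F <- sig * geometry$S
  d <- eps * geometry$L
  if (noise_rel > 0) {
    F <- with_seed(seed, {
      F + c(0, rnorm(length(F) - 1L, sd = noise_rel * max(abs(F))))
    })
  }
  rec <- test_record(d, F, mode = mode)
  attr(rec, "tissue") <- tissue$name
  rec
}

#' Generate a pseudo-experimental whole-fruit compression curve
#'
#' Surrogate for a physical plate-compression record of a whole fruit: a
#' Hertz-type power-law elastic segment `F = A d^{3/2}` in the total plate
#' travel `d`, switching at the knee displacement `d_knee` to a straight
#' post-yield segment, with multiplicative Gaussian noise.  Defaults are
#' derived from first principles for the requested direction: each of the
#' two plate contacts takes half the travel, so
#' `A = (4/3) E* sqrt(R_eff) / 2^{3/2}` with `E* = E_dir / (1 - nu^2)` the
#' flesh plane-strain modulus for that direction and `R_eff` the
#' geometric-mean surface curvature radius of the ellipsoid at the contact
#' pole; `d_knee` is the travel at 5% nominal strain; the post-knee slope
#' is the backbone tangent at the knee scaled by `Et_dir / E_dir`.
#'
#' @param direction `"axial"`, `"long_radial"` or `"short_radial"`.
#' @param dims a [fruit_dimensions()] (defaults to the cohort means).
#' @param materials material list as from [default_materials()] (uses the
#'   transverse `flesh` entry).
#' @param A,d_knee,post_slope override the derived backbone parameters
#'   (N/mm^1.5, mm, N/mm).
#' @param noise_rel multiplicative force noise level (default 0.02).
#' @param seed RNG seed.
#' @param n_points samples.
#' @param max_displacement end of the record (mm; default: travel at 10%
#'   strain).
#' @return an [fd_curve()].
#' @export
#' @examples
#' crv <- gen_experiment_curve("axial", seed = 0)
#' head(as.data.frame(crv))
gen_experiment_curve <- function(direction = c("axial", "long_radial",
                                               "short_radial"),
                                 dims = fruit_dimensions(),
                                 materials = default_materials(),
                                 A = NULL, d_knee = NULL, post_slope = NULL,
                                 noise_rel = 0.02, seed = NULL,
                                 n_points = 120L, max_displacement = NULL) {
  direction <- match.arg(direction)
  ax <- direction_axis(direction)
  semi <- c(dims$a_axial, dims$a_long, dims$a_short)
  D <- 2 * semi[ax]
  fl <- materials$flesh
  if (ax == 1L) {
    E_dir <- fl$E_axial; Et_dir <- fl$Et_axial
  } else {
    E_dir <- fl$E_radial; Et_dir <- fl$Et_radial
  }
  oth <- setdiff(1:3, ax)
  # principal curvature radii of the ellipsoid at the contact pole
  R1 <- semi[oth[1]]^2 / semi[ax]
  R2 <- semi[oth[2]]^2 / semi[ax]
  R_eff <- sqrt(R1 * R2)
  Estar <- E_dir / (1 - fl$nu^2)
  A <- A %||% (4 / 3 * Estar * sqrt(R_eff) / 2^1.5)
  d_knee <- d_knee %||% (0.05 * D)
  max_displacement <- max_displacement %||% (0.10 * D)
  post_slope <- post_slope %||%
    (Et_dir / E_dir * 1.5 * A * sqrt(d_knee))
  if (A <= 0 || d_knee <= 0 || post_slope <= 0 || noise_rel < 0)
    stopf("backbone parameters must be positive")
  d <- seq(0, max_displacement, length.out = n_points)
  Fk <- A * d_knee^1.5
  F <- ifelse(d <= d_knee, A * d^1.5, Fk + post_slope * (d - d_knee))
  if (noise_rel > 0) {
    F <- with_seed(seed, F * (1 + c(0, rnorm(length(F) - 1L,
                                             sd = noise_rel))))
    F <- pmax(F, 0)
  }
  crv <- fd_curve(d, F)
  attr(crv, "direction") <- direction
  attr(crv, "backbone") <- list(A = A, d_knee = d_knee,
                                post_slope = post_slope)
  crv
}

#' Force-displacement curve
#'
#' Plate reaction force versus plate travel for one compression direction.
#'
#' @param displacement upper-plate travel (mm), starting at 0.
#' @param force reaction force (N), same length, starting at 0.
#' @return object of class `fd_curve` (a data.frame).
#' @export
fd_curve <- function(displacement, force) {
  displacement <- as.numeric(displacement); force <- as.numeric(force)
  if (length(displacement) != length(force))
    stopf("displacement and force lengths differ")
  if (length(displacement) < 2 || displacement[1] != 0 || force[1] != 0)
    stopf("a force-displacement curve starts at (0, 0)")
  d <- data.frame(displacement_mm = displacement, force_N = force)
  class(d) <- c("fd_curve", "data.frame")
  d
}

#' @exportS3Method base::print
print.fd_curve <- function(x, ...) {
  cat(sprintf("Force-displacement curve: %d points, travel %.3f mm, peak %.3f N\n",
              nrow(x), max(x$displacement_mm), max(x$force_N)))
  invisible(x)
}

#' Read / write a force-displacement curve as CSV
#'
#' Columns `displacement_mm`, `force_N`.
#' @param path file path.
#' @param curve an [fd_curve()].
#' @export
read_fd_curve <- function(path) {
  d <- read.csv(path)
  fd_curve(d$displacement_mm, d$force_N)
}

#' @rdname read_fd_curve
#' @export
write_fd_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
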