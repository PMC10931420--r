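# Specimen-scale analysis: force-displacement records from uniaxial tissue
# tests are converted to stress-strain (sigma = F/S, eps = dL/L), the
# bio-yield point is located by a two-segment piecewise-linear fit, and the
# elastic (Tan alpha) and tangent (Tan beta) moduli are extracted as
# least-squares slopes of the elastic and plastic intervals.
# Compression-positive sign convention throughout.

#' Specimen geometry
#'
#' Cylindrical plugs (flesh, core compression) or rectangular strips (skin
#' tension).  The cross-section is `pi d^2 / 4` for cylinders and
#' `width x thickness` for strips; the gauge length is the cylinder height
#' or the strip gauge length.
#'
#' @param shape `"cylinder"` or `"strip"`.
#' @param diameter,height cylinder dimensions (mm).
#' @param width,thickness,gauge_length strip dimensions (mm).
#' @return object of class `specimen_geometry` with `$S` (mm^2) and `$L`
#'   (mm) precomputed.
#' @export
#' @examples
#' specimen_geometry("cylinder", diameter = 10, height = 12)$S  # 78.5398
#' specimen_geometry("strip", width = 15, thickness = 0.5,
#'                   gauge_length = 50)$S                       # 7.5
specimen_geometry <- function(shape = c("cylinder", "strip"),
                              diameter = NULL, height = NULL,
                              width = NULL, thickness = NULL,
                              gauge_length = NULL) {
  shape <- match.arg(shape)
  pos <- function(x, lbl) {
    if (!is_number(x) || x <= 0) stopf("%s must be a positive number", lbl)
    x
  }
  if (shape == "cylinder") {
    d <- pos(diameter, "diameter"); h <- pos(height, "height")
    g <- list(shape = shape, diameter = d, height = h,
              S = pi * d^2 / 4, L = h)
  } else {
    w <- pos(width, "width"); t <- pos(thickness, "thickness")
    l <- pos(gauge_length, "gauge_length")
    g <- list(shape = shape, width = w, thickness = t, gauge_length = l,
              S = w * t, L = l)
  }
  class(g) <- "specimen_geometry"
  g
}

#' Uniaxial test record
#'
#' @param displacement crosshead displacement (mm), strictly increasing
#'   from 0 (a brittle record may append post-rupture samples at continuing
#'   displacement).
#' @param force load (N), same length, first sample 0.
#' @param mode `"compression"` or `"tension"`; informational.
#' @return object of class `test_record` (a data.frame with attributes).
#' @export
test_record <- function(displacement, force,
                        mode = c("compression", "tension")) {
  mode <- match.arg(mode)
  displacement <- as.numeric(displacement); force <- as.numeric(force)
  if (length(displacement) != length(force) || length(force) < 3)
    stopf("displacement and force must have equal length >= 3")
  if (displacement[1] != 0 || force[1] != 0)
    stopf("a test record must start at (0, 0)")
  if (any(diff(displacement) <= 0))
    stopf("displacement must be strictly increasing")
  r <- data.frame(displacement_mm = displacement, force_N = force)
  attr(r, "mode") <- mode
  class(r) <- c("test_record", "data.frame")
  r
}

#' Read / write a test record as CSV
#'
#' Two columns, `displacement_mm` and `force_N`, one header line.
#'
#' @param path file path.
#' @param record a [test_record()].
#' @param mode stored on read (not represented in the CSV).
#' @return `read_test_record`: a `test_record`; `write_test_record`: the
#'   path, invisibly.
#' @export
read_test_record <- function(path, mode = "compression") {
  d <- read.csv(path)
  if (!all(c("displacement_mm", "force_N") %in% names(d)))
    stopf("'%s': expected columns displacement_mm, force_N", path)
  test_record(d$displacement_mm, d$force_N, mode = mode)
}

#' @rdname read_test_record
#' @export
write_test_record <- function(record, path) {
  write.csv(as.data.frame(record)[c("displacement_mm", "force_N")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a force-displacement record to stress-strain
#'
#' Elementwise `sigma = F / S` (MPa) and `eps = dL / L` (dimensionless).
#'
#' @param record a [test_record()].
#' @param geom a [specimen_geometry()].
#' @return data.frame with `strain` and `stress` columns.
#' @export
#' @examples
#' g <- specimen_geometry("cylinder", diameter = 10, height = 12)
#' r <- test_record(c(0, 0.6, 1.2), c(0, 5, 10))
#' to_stress_strain(r, g)
to_stress_strain <- function(record, geom) {
  stopifnot(inherits(record, "test_record"),
            inherits(geom, "specimen_geometry"))
  if (geom$S <= 0 || geom$L <= 0)
    stopf("cross-section and gauge length must be positive")
  data.frame(strain = record$displacement_mm / geom$L,
             stress = record$force_N / geom$S)
}

# Closed-form simple linear regression on a window; returns intercept,
# slope, SSE.  Used by the breakpoint search (small n: plain loops).
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
  a <- my - b * mx
  list(a = a, b = b, sse = sum((y - a - b * x)^2))
}

#' Detect the bio-yield point
#'
#' Two-segment piecewise-linear least squares: every admissible split of
#' the samples into a leading and a trailing segment (each with at least
#' `min_seg` points) is fitted with two independent lines; the split with
#' the smallest total squared error is kept.  The bio-yield point is the
#' intersection of the two fitted lines, and is reported only when the
#' post-break slope has dropped below `(1 - min_drop)` times the pre-break
#' slope - otherwise the curve is considered break-free and `NULL` is
#' returned.
#'
#' @param stress,strain numeric vectors (MPa, dimensionless), >= 10 samples.
#' @param min_drop minimum relative slope drop that qualifies as a yield
#'   (default 0.25).
#' @param min_seg minimum samples per segment (default 3).
#' @return `NULL` if no qualifying slope change, else a list with `eps_y`,
#'   `sigma_y`, the fitted segment slopes `slope_pre`, `slope_post`, and
#'   the split index `k`.
#' @export
#' @examples
#' eps <- seq(0, 0.4, length.out = 100)
#' sig <- ifelse(eps < 0.213, 2.305 * eps, 0.491 + 0.967 * (eps - 0.213))
#' detect_bioyield(sig, eps)[c("eps_y", "sigma_y")]
detect_bioyield <- function(stress, strain, min_drop = 0.25, min_seg = 3L) {
  n <- length(strain)
  if (length(stress) != n) stopf("stress and strain lengths differ")
  if (n < 10) stopf("bio-yield detection needs at least 10 samples, got %d", n)
  ks <- seq(min_seg, n - min_seg)
  best <- NULL; best_sse <- Inf
  for (k in ks) {
    f1 <- ols_line(strain[1:k], stress[1:k])
    f2 <- ols_line(strain[(k + 1):n], stress[(k + 1):n])
    sse <- f1$sse + f2$sse
    if (is.null(best) || sse < best_sse - 1e-15 * max(1, best_sse)) {
      best_sse <- sse; best <- list(k = k, f1 = f1, f2 = f2)
    }
  }
  b1 <- best$f1$b; b2 <- best$f2$b
  if (!(b1 > 0) || b2 >= (1 - min_drop) * b1) return(NULL)
  eps_y <- (best$f2$a - best$f1$a) / (b1 - b2)
  list(eps_y = eps_y,
       sigma_y = best$f1$a + b1 * eps_y,
       slope_pre = b1, slope_post = b2, k = best$k)
}

# Through-origin least-squares slope.
slope_through_origin <- function(x, y) sum(x * y) / sum(x * x)

#' Fit the elastic and tangent moduli
#'
#' With a yield point: `E` is the through-origin least-squares slope on the
#' elastic window `strain in [elastic_window[1], elastic_window[2]] * eps_y`,
#' and `Et` the least-squares slope of the post-yield samples up to the
#' stress peak.  Without one (brittle skin): `E` is fitted on
#' `[skin_min_strain, strain at peak stress]` and the peak stress is
#' reported as the rupture stress.
#'
#' @param stress,strain numeric vectors (MPa, dimensionless).
#' @param yield result of [detect_bioyield()], or `NULL` for the brittle
#'   case.
#' @param elastic_window fractions of `eps_y` bounding the elastic fit
#'   window (default `c(0.2, 0.9)`).
#' @param skin_min_strain lower strain bound of the brittle elastic window
#'   (default 0.001).
#' @return object of class `mechanical_summary`: list with `E`, `Et`,
#'   `sigma_y`, `eps_y`, `rupture_stress`, `r2_elastic`, `yield_type`
#'   (`"plastic"`, `"rupture"` or `"none"`).
#' @export
fit_moduli <- function(stress, strain, yield = NULL,
                       elastic_window = c(0.2, 0.9),
                       skin_min_strain = 0.001) {
  out <- list(E = NA_real_, Et = NA_real_, sigma_y = NA_real_,
              eps_y = NA_real_, rupture_stress = NA_real_,
              r2_elastic = NA_real_, yield_type = "none")
  if (!is.null(yield) && yield$slope_post >= 0) {
    # elastoplastic tissue
    w <- strain >= elastic_window[1] * yield$eps_y &
         strain <= elastic_window[2] * yield$eps_y
    if (sum(w) < 2) stopf("empty elastic fit window")
    E <- slope_through_origin(strain[w], stress[w])
    peak <- which.max(stress)
    pw <- which(strain > yield$eps_y & seq_along(strain) <= peak)
    if (length(pw) < 2) stopf("empty post-yield fit window")
    ft <- ols_line(strain[pw], stress[pw])
    ss_tot <- sum(stress[w]^2)
    out$E <- E; out$Et <- ft$b
    out$sigma_y <- yield$sigma_y; out$eps_y <- yield$eps_y
    out$r2_elastic <- 1 - sum((stress[w] - E * strain[w])^2) /
      max(ss_tot, .Machine$double.xmin)
    out$yield_type <- "plastic"
  } else {
    # brittle (skin) or break-free: fit E up to the stress peak
    peak <- which.max(stress)
    w <- strain >= skin_min_strain & seq_along(strain) <= peak
    if (sum(w) < 2) stopf("empty elastic fit window")
    E <- slope_through_origin(strain[w], stress[w])
    out$E <- E
    out$r2_elastic <- 1 - sum((stress[w] - E * strain[w])^2) /
      max(sum(stress[w]^2), .Machine$double.xmin)
    if (!is.null(yield) || peak < length(stress)) {
      out$rupture_stress <- stress[peak]
      out$yield_type <- "rupture"
    }
  }
  class(out) <- "mechanical_summary"
  out
}

#' @exportS3Method base::print
print.mechanical_summary <- function(x, ...) {
  cat("Mechanical summary:\n")
  cat(sprintf("  E  = %.4f MPa (elastic fit R^2 = %.6f)\n", x$E,
              x$r2_elastic))
  if (x$yield_type == "plastic") {
    cat(sprintf("  Et = %.4f MPa\n  sigma_y = %.4f MPa at eps_y = %.4f\n",
                x$Et, x$sigma_y, x$eps_y))
  } else if (x$yield_type == "rupture") {
    cat(sprintf("  brittle: rupture stress = %.4f MPa\n", x$rupture_stress))
  } else cat("  no yield point detected\n")
  invisible(x)
}

#' Full specimen analysis
#'
#' [to_stress_strain()] + [detect_bioyield()] + [fit_moduli()] in one call.
#'
#' @inheritParams to_stress_strain
#' @param min_drop,elastic_window,skin_min_strain passed through.
#' @param toe_strain initial strain skipped before any fitting (some
#'   records show a compliant toe before the linear rise; default 0).
#' @return a `mechanical_summary` (see [fit_moduli()]).
#' @export
#' @examples
#' mats <- default_materials()
#' g <- specimen_geometry("cylinder", diameter = 10, height = 12)
#' rec <- gen_specimen_record(mats$flesh_axial, g)
#' analyze_specimen(rec, g)
analyze_specimen <- function(record, geom, min_drop = 0.25,
                             elastic_window = c(0.2, 0.9),
                             skin_min_strain = 0.001, toe_strain = 0) {
  ss <- to_stress_strain(record, geom)
  keep <- ss$strain >= toe_strain
  ss <- ss[keep, , drop = FALSE]
  y <- detect_bioyield(ss$stress, ss$strain, min_drop = min_drop)
  fit_moduli(ss$stress, ss$strain, yield = y,
             elastic_window = elastic_window,
             skin_min_strain = skin_min_strain)
}

#' Displacement applied at a nominal strain level
#'
#' The loading protocol expresses plate travel as a fraction of the
#' initial plate-to-plate dimension: `displacement = strain * dimension`.
#'
#' @param strain strain level (e.g. 0.05).
#' @param dimension initial dimension in the loading direction (mm).
#' @return displacement (mm).
#' @export
#' @examples
#' strain_displacement(0.05, 65.83)  # 3.2915 mm
strain_displacement <- function(strain, dimension) {
  stopifnot(is.numeric(strain), is.numeric(dimension))
  strain * dimension
}
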