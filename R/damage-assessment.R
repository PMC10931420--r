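# Damage assessment: turn solver stress fields into damage statements -
# per-tissue damaged-volume fractions at each strain level (Von Mises at or
# above the tissue bio-yield stress), the damage onset strain, the
# damage-threshold force at the 5% level, safe stacking counts, and
# curve-versus-curve validation against (pseudo-)experimental records.

#' Classify compression damage
#'
#' An element counts as damaged when its Von Mises equivalent stress
#' reaches the bio-yield stress of its tissue (for the flesh, the value
#' matching the loading direction: axial bio-yield for axial compression,
#' radial for radial).  Fractions are volume-weighted (area-weighted for
#' the skin membrane).  The onset strain is the smallest tested level at
#' which the flesh fraction exceeds `onset_frac`; the damage-threshold
#' force is the plate force at the 5% strain level.
#'
#' @param solution a [solve_compression()] / [run_strain_levels()] result
#'   with snapshots at the requested levels.
#' @param strain_levels levels to tabulate (default: all recorded).
#' @param onset_frac flesh damage fraction counting as "noticeable damage"
#'   (default 0.005).
#' @return object of class `damage_report`: `$table` (one row per level
#'   and tissue: damaged fraction, max Von Mises), `$onset_strain`
#'   (`NA` if no level qualifies), `$threshold_force` (N at the 5% level,
#'   `NA` if 5% was not recorded), `$direction`.
#' @export
classify_damage <- function(solution, strain_levels = NULL,
                            onset_frac = 0.005) {
  stopifnot(inherits(solution, "compression_solution"))
  levels_rec <- vapply(solution$snapshots, `[[`, numeric(1), "strain_level")
  strain_levels <- strain_levels %||% levels_rec
  mesh <- solution$mesh
  materials <- solution$materials
  dir_kind <- if (direction_axis(solution$direction) == 1L) "axial" else
    "radial"
  thr <- list()
  fl <- materials$flesh
  thr$flesh <- if (fl$symmetry == "transverse") {
    if (dir_kind == "axial") fl$sigma_y_axial else fl$sigma_y_radial
  } else fl$sigma_y
  if (!is.null(materials$core)) thr$core <- materials$core$sigma_y
  if (!is.null(materials$skin)) thr$skin <- materials$skin$sigma_y
  V <- mesh$volumes
  rows <- list()
  for (lv in strain_levels) {
    k <- which(abs(levels_rec - lv) < 1e-9)
    if (length(k) == 0)
      stopf("no snapshot at strain level %s (recorded: %s)", lv,
            paste(signif(levels_rec, 4), collapse = ", "))
    sn <- solution$snapshots[[k[1]]]
    for (tis in names(thr)) {
      if (tis == "skin") {
        if (is.null(sn$skin)) next
        a <- triangle_areas(mesh$nodes, mesh$skin_tris)
        dmg <- sn$skin$von_mises >= thr$skin
        frac <- sum(a[dmg]) / sum(a)
        mx <- max(sn$skin$von_mises)
      } else {
        sel <- mesh$region == tis
        if (!any(sel)) next
        dmg <- sel & sn$von_mises >= thr[[tis]]
        frac <- sum(V[dmg]) / sum(V[sel])
        mx <- max(sn$von_mises[sel])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strain_level = sn$strain_level, tissue = tis,
        damaged_fraction = frac, max_von_mises = mx,
        threshold = thr[[tis]], force_N = sn$force_upper)
    }
  }
  tab <- do.call(rbind, rows)
  fl_tab <- tab[tab$tissue == "flesh", ]
  onset <- fl_tab$strain_level[fl_tab$damaged_fraction > onset_frac]
  onset <- if (length(onset)) min(onset) else NA_real_
  k5 <- which(abs(tab$strain_level - 0.05) < 1e-9)
  thr_force <- if (length(k5)) tab$force_N[k5[1]] else NA_real_
  rep_ <- list(table = tab, onset_strain = onset,
               threshold_force = thr_force,
               direction = solution$direction, onset_frac = onset_frac)
  class(rep_) <- "damage_report"
  rep_
}

#' @exportS3Method base::print
print.damage_report <- function(x, ...) {
  cat(sprintf("Damage report (%s compression):\n", x$direction))
  tab <- x$table
  for (lv in unique(tab$strain_level)) {
    sub <- tab[tab$strain_level == lv, ]
    cat(sprintf("  %5.1f%% strain (F = %8.2f N): %s\n", 100 * lv,
                sub$force_N[1],
                paste(sprintf("%s %.2f%% (max %.3f MPa)", sub$tissue,
                              100 * sub$damaged_fraction,
                              sub$max_von_mises), collapse = ", ")))
  }
  cat(sprintf("  onset strain: %s;  damage-threshold force (5%%): %s\n",
              if (is.na(x$onset_strain)) "none" else
                sprintf("%.1f%%", 100 * x$onset_strain),
              if (is.na(x$threshold_force)) "n/a" else
                sprintf("%.2f N", x$threshold_force)))
  invisible(x)
}

#' Safe stacking count
#'
#' Under ideal stacking (a vertical column of identical fruits), the
#' bottom fruit carries the weight of all fruits above it.  The largest
#' safe column on top of it is `floor(F / (m g))` fruit weights, with `F`
#' the damage-threshold force (the compressive force at the 5% strain
#' level).  Counts at exact multiples of one fruit weight are resolved
#' exactly.
#'
#' @param threshold_force damage-threshold force (N).
#' @param fruit_mass fruit mass (g; default: cohort mean 97.11).
#' @param g gravitational acceleration (m/s^2, default 9.81).
#' @return integer count (>= 0; 0 with a warning when the threshold is
#'   below one fruit weight).
#' @export
#' @examples
#' stacking_count(75.82)   # 79
#' stacking_count(47.512)  # 49
stacking_count <- function(threshold_force, fruit_mass = 97.11, g = 9.81) {
  if (!is_number(threshold_force) || threshold_force < 0)
    stopf("threshold_force must be a non-negative number")
  if (!is_number(fruit_mass) || fruit_mass <= 0 || !is_number(g) || g <= 0)
    stopf("fruit_mass and g must be positive")
  w <- fruit_mass / 1000 * g                 # one fruit weight, N
  n <- floor(threshold_force / w + 1e-9)     # exact at integer multiples
  if (n < 1) {
    warning("threshold force is below one fruit weight; stacking count 0",
            call. = FALSE)
    return(0L)
  }
  as.integer(n)
}

#' Compare a simulated and an experimental force-displacement curve
#'
#' Both curves are linearly interpolated onto a uniform grid over their
#' overlapping displacement range; the Pearson correlation of the forces
#' and the root-mean-square error (N) are reported.
#'
#' @param sim,exp [fd_curve()] objects (or data.frames with
#'   `displacement_mm`, `force_N`).
#' @param n_grid grid points (default 200).
#' @return list with `r` (correlation), `rmse` (N), and the comparison
#'   grid (`displacement`, `force_sim`, `force_exp`).
#' @export
#' @examples
#' a <- fd_curve(0:10, (0:10)^1.5)
#' validate_curves(a, a)$r   # 1
validate_curves <- function(sim, exp, n_grid = 200L) {
  rng <- c(max(min(sim$displacement_mm), min(exp$displacement_mm)),
           min(max(sim$displacement_mm), max(exp$displacement_mm)))
  if (rng[2] <= rng[1])
    stopf("curves have no overlapping displacement range")
  d <- seq(rng[1], rng[2], length.out = n_grid)
  fs <- approx(sim$displacement_mm, sim$force_N, d)$y
  fe <- approx(exp$displacement_mm, exp$force_N, d)$y
  list(r = cor(fs, fe), rmse = sqrt(mean((fs - fe)^2)),
       grid = data.frame(displacement = d, force_sim = fs, force_exp = fe))
}
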