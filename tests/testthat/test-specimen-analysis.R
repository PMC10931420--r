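# Specimen-scale analysis: stress-strain conversion, bio-yield detection,
# modulus fitting, and the generator round-trips.

test_that("cross-sections and gauge lengths follow the geometry", {
  expect_equal(cyl_geom()$S, pi * 100 / 4, tolerance = 1e-12)
  expect_equal(cyl_geom()$L, 12)
  expect_equal(strip_geom()$S, 7.5, tolerance = 1e-12)
  expect_equal(strip_geom()$L, 50)
  expect_error(specimen_geometry("cylinder", diameter = 0, height = 1),
               "positive")
})

test_that("stress-strain conversion is elementwise F/S and dL/L", {
  g <- specimen_geometry("cylinder",
                         diameter = sqrt(400 / pi),   # S = 100 mm^2
                         height = 10)
  r <- test_record(c(0, 0.5, 1), c(0, 5, 10))
  ss <- to_stress_strain(r, g)
  expect_equal(ss$stress, c(0, 0.05, 0.1), tolerance = 1e-12)
  expect_equal(ss$strain, c(0, 0.05, 0.1), tolerance = 1e-12)
  # implied modulus: sigma / eps = 1 MPa
  expect_equal(ss$stress[3] / ss$strain[3], 1, tolerance = 1e-12)
})

test_that("record invariants are enforced", {
  expect_error(test_record(c(0, 1, 0.5), c(0, 1, 2)), "increasing")
  expect_error(test_record(c(0.1, 1, 2), c(0, 1, 2)), "start")
  expect_error(test_record(c(0, 1), c(0, 1)), "length")
})

test_that("noiseless round-trip recovers the reference constants exactly", {
  mats <- kiwi_materials()
  for (nm in c("flesh_axial", "flesh_radial", "core")) {
    p <- mats[[nm]]
    rec <- gen_specimen_record(p, cyl_geom())
    s <- analyze_specimen(rec, cyl_geom())
    expect_equal(s$E, p$E, tolerance = 1e-6, label = paste(nm, "E"))
    expect_equal(s$Et, p$Et, tolerance = 1e-6, label = paste(nm, "Et"))
    expect_equal(s$sigma_y, p$sigma_y, tolerance = 1e-6,
                 label = paste(nm, "sigma_y"))
    expect_equal(s$eps_y, p$sigma_y / p$E, tolerance = 1e-6)
    expect_identical(s$yield_type, "plastic")
  }
  # brittle skin: linear rise, rupture, no tangent modulus
  sk <- mats$skin
  rec <- gen_specimen_record(sk, strip_geom(), mode = "tension")
  s <- analyze_specimen(rec, strip_geom())
  expect_equal(s$E, sk$E, tolerance = 1e-6)
  expect_equal(s$rupture_stress, sk$sigma_y, tolerance = 1e-6)
  expect_identical(s$yield_type, "rupture")
  expect_true(is.na(s$Et))
})

test_that("a purely linear curve yields no bio-yield point", {
  eps <- seq(0, 0.1, length.out = 60)
  expect_null(detect_bioyield(3 * eps, eps))
  expect_error(detect_bioyield(1:5, 1:5 / 10), "at least 10")
})

test_that("bio-yield detection tolerates measurement noise", {
  p <- kiwi_materials()$flesh_axial
  rec <- gen_specimen_record(p, cyl_geom(), noise_rel = 0.01, seed = 101)
  s <- analyze_specimen(rec, cyl_geom())
  expect_lt(abs(s$sigma_y - p$sigma_y) / p$sigma_y, 0.05)
})

test_that("E recovery at 1% noise is tight and unbiased over replicates", {
  p <- kiwi_materials()$flesh_axial
  Es <- vapply(1:100, function(sd_) {
    rec <- gen_specimen_record(p, cyl_geom(), noise_rel = 0.01, seed = sd_)
    analyze_specimen(rec, cyl_geom())$E
  }, numeric(1))
  expect_true(all(abs(Es - p$E) / p$E < 0.03))
  expect_lt(abs(mean(Es) - p$E) / p$E, 0.01)
})

test_that("scaling laws: force scales stress, consistent geometry leaves E", {
  p <- kiwi_materials()$core
  rec <- gen_specimen_record(p, cyl_geom())
  k <- 3.7
  rec2 <- test_record(rec$displacement_mm, k * rec$force_N)
  s1 <- analyze_specimen(rec, cyl_geom())
  s2 <- analyze_specimen(rec2, cyl_geom())
  expect_equal(s2$E, k * s1$E, tolerance = 1e-9)
  expect_equal(s2$sigma_y, k * s1$sigma_y, tolerance = 1e-9)
  # scale all lengths by s and forces by s^2: stress and strain unchanged
  s_ <- 2
  g2 <- specimen_geometry("cylinder", diameter = 10 * s_, height = 12 * s_)
  rec3 <- test_record(rec$displacement_mm * s_, rec$force_N * s_^2)
  s3 <- analyze_specimen(rec3, g2)
  expect_equal(s3$E, s1$E, tolerance = 1e-9)
})

test_that("records survive a CSV round-trip", {
  p <- kiwi_materials()$core
  rec <- gen_specimen_record(p, cyl_geom(), noise_rel = 0.005, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_test_record(rec, path)
  rec2 <- read_test_record(path)
  expect_equal(rec2$displacement_mm, rec$displacement_mm, tolerance = 1e-9)
  expect_equal(rec2$force_N, rec$force_N, tolerance = 1e-9)
  unlink(path)
})

test_that("loading-protocol displacements are strain times dimension", {
  expect_equal(strain_displacement(0.05, 65.83), 3.2915)
  expect_equal(strain_displacement(c(0.025, 0.2), 55.43),
               c(1.38575, 11.086))
})
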