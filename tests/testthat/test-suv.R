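test_that("SUV normalisation is definitional: matched concentration gives SUV 1", {
  ctx <- scan_context(injected_activity_mbq = 236, body_weight_kg = 75,
                      minutes_injection_to_scan = 0)
  conc <- 236 * 1000 / (75 * 1000)  # decayed activity per gram, t = 0
  vol <- uptake_volume(array(conc, c(4, 4, 2)), units = "kBq_per_ml")
  suv <- suv_normalize(vol, ctx)
  expect_equal(suv$units, "suv")
  expect_equal(unique(as.vector(suv$values)), 1.0)
})

test_that("one half-life of uptake time doubles the SUV", {
  vol <- uptake_volume(array(5, c(3, 3, 3)), units = "kBq_per_ml")
  ctx0 <- scan_context(236, 75, 0)
  ctx1 <- scan_context(236, 75, 109.77)
  expect_equal(suv_normalize(vol, ctx1)$values,
               2 * suv_normalize(vol, ctx0)$values)
})

test_that("SUV scaling matches an independent hand calculation", {
  # C = 5 kBq/mL, A = 236 MBq, w = 75 kg, t = 56 min, F-18
  hand <- 5 * 75 * 1000 / (236 * 1000 * 2^(-56 / 109.77))
  vol <- uptake_volume(array(5, c(2, 2, 2)), units = "kBq_per_ml")
  ctx <- scan_context(236, 75, 56)
  expect_equal(as.vector(suv_normalize(vol, ctx)$values), rep(hand, 8),
               tolerance = 1e-12)
  expect_error(suv_normalize(suv_normalize(vol, ctx), ctx), "kBq_per_ml")
})

test_that("suv_normalize is linear and inversely proportional to decayed activity", {
  set.seed(5)
  vals <- array(runif(60, 0, 10), c(5, 4, 3))
  vol <- uptake_volume(vals, units = "kBq_per_ml")
  ctx <- scan_context(230, 80, 50)
  base <- suv_normalize(vol, ctx)$values
  expect_equal(suv_normalize(uptake_volume(3 * vals, units = "kBq_per_ml"),
                             ctx)$values, 3 * base)
  ctx2 <- scan_context(2 * 230, 80, 50)
  expect_equal(suv_normalize(vol, ctx2)$values, base / 2)
})

test_that("voi_voxels selects exactly the voxels with centers inside the sphere", {
  # tiny sphere on a voxel center picks that single voxel
  vol <- make_phantom(c(10, 10, 6), spacing_mm = c(1.5, 1.5, 5), background = 1)
  voi <- sphere_voi(c(3 * 1.5, 4 * 1.5, 2 * 5), diameter_mm = 1)
  expect_equal(voi_voxels(vol, voi),
               matrix(c(4L, 5L, 3L), 1, dimnames = list(NULL, c("i", "j", "k"))))

  # an enclosing sphere takes the whole grid
  big <- sphere_voi(c(7, 7, 12.5), diameter_mm = 1000)
  expect_equal(nrow(voi_voxels(vol, big)), prod(dim(vol$values)))

  # empty intersection errors, naming the VOI
  far <- sphere_voi(c(500, 500, 500), diameter_mm = 2)
  expect_error(voi_voxels(vol, far), "no voxel center")
})

test_that("random spheres match the exhaustive membership oracle", {
  set.seed(17)
  vol <- make_phantom(c(20, 20, 10), spacing_mm = c(1.5, 1.5, 5),
                      background = 1, noise_sd = 0.3, seed = 17)
  for (rep in 1:8) {
    voi <- sphere_voi(c(runif(1, 5, 25), runif(1, 5, 25), runif(1, 10, 35)),
                      diameter_mm = runif(1, 6, 25))
    got <- voi_voxels(vol, voi)
    want <- oracle_voi_voxels(vol, voi)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("suv_max/mean/peak behave on uniform and hot-spot phantoms", {
  uni <- make_phantom(c(12, 12, 8), background = 2.5)
  voi <- sphere_voi(c(8, 8, 17), diameter_mm = 14)
  expect_equal(suv_max(uni, voi), 2.5)
  expect_equal(suv_mean(uni, voi), 2.5)
  expect_equal(suv_peak(uni, voi), 2.5)

  hot <- uni
  hot$values[6, 6, 4] <- 10
  all_voi <- sphere_voi(c(8, 8, 17), diameter_mm = 500)
  expect_equal(suv_max(hot, all_voi), 10)
  expect_lt(suv_peak(hot, all_voi), 10)
  expect_gt(suv_peak(hot, all_voi), suv_mean(hot, all_voi))
})

test_that("metrics on random phantoms equal exhaustive-loop references", {
  set.seed(31)
  for (rep in 1:4) {
    vol <- make_phantom(c(10, 10, 6), spacing_mm = c(2, 2, 4), background = 1,
                        noise_sd = 0.4, seed = 31 + rep)
    voi <- sphere_voi(c(runif(1, 4, 14), runif(1, 4, 14), runif(1, 4, 16)),
                      diameter_mm = runif(1, 6, 16))
    vals <- vol$values[oracle_voi_voxels(vol, voi)]
    expect_equal(suv_max(vol, voi), max(vals))
    expect_equal(suv_mean(vol, voi), mean(vals))
    expect_equal(suv_peak(vol, voi), oracle_suv_peak(vol, voi))
    expect_lte(suv_peak(vol, voi), suv_max(vol, voi))
  }
})

test_that("SUV metrics are invariant under axis permutation", {
  set.seed(9)
  vol <- make_phantom(c(8, 10, 6), spacing_mm = c(1.5, 2.5, 5), background = 1,
                      noise_sd = 0.3, seed = 9)
  voi <- sphere_voi(c(6, 9, 12), diameter_mm = 12)
  perm <- c(3, 1, 2)
  vol_p <- uptake_volume(aperm(vol$values, perm), vol$spacing_mm[perm],
                         units = "suv")
  voi_p <- sphere_voi(voi$center_mm[perm], voi$diameter_mm)
  expect_equal(suv_max(vol_p, voi_p), suv_max(vol, voi))
  expect_equal(suv_mean(vol_p, voi_p), suv_mean(vol, voi))
  expect_equal(suv_peak(vol_p, voi_p), suv_peak(vol, voi))
})

test_that("phantoms paint lesions and are seed-reproducible", {
  les <- list(list(voi = sphere_voi(c(10, 10, 15), 8), value = 8))
  ph <- make_phantom(c(15, 15, 8), background = 0.5, lesions = les)
  enclosing <- sphere_voi(c(10, 10, 15), diameter_mm = 200)
  expect_equal(suv_max(ph, enclosing), 8)
  expect_equal(min(ph$values), 0.5)

  n1 <- make_phantom(c(6, 6, 4), background = 1, noise_sd = 0.2, seed = 99)
  n2 <- make_phantom(c(6, 6, 4), background = 1, noise_sd = 0.2, seed = 99)
  expect_identical(n1$values, n2$values)

  outside <- list(list(voi = sphere_voi(c(100, 0, 0), 8), value = 3))
  expect_error(make_phantom(c(6, 6, 4), lesions = outside), "outside")
})

test_that("uptake volumes round-trip through NIfTI with spacing intact", {
  vol <- make_phantom(c(7, 6, 5), spacing_mm = c(1.5, 1.5, 5), background = 1,
                      noise_sd = 0.25, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_uptake_volume(vol, tmp)
  back <- read_uptake_volume(tmp, units = "suv")
  expect_equal(back$values, vol$values, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(back$spacing_mm, vol$spacing_mm)
})
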