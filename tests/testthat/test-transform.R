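# a hand-specified mapping: landmarks (0, 10, 30) onto scale (0, 4, 10)
hand_spec <- function() {
  lm <- landmark_set(i_min = 0, p_alpha = 0, p_m = 10, p_beta = 30,
                     i_max = 50, beta = 95)
  sc <- standard_scale(s_m = 4, s_max = 10, beta = 95, inv_scale = 1,
                       modality = "AC")
  mapping_spec(lm, sc)
}

test_that("eta maps landmarks to scale landmarks and extrapolates linearly", {
  spec <- hand_spec()
  lm <- spec$landmarks
  sc <- spec$scale
  expect_equal(eta(lm$p_alpha, spec), sc$s_min)
  expect_equal(eta(lm$p_m, spec), sc$s_m)
  expect_equal(eta(lm$p_beta, spec), sc$s_max)

  # hand-evaluated piecewise values, including extrapolation past s_max
  expect_equal(eta(c(5, 20, 40), spec), c(2, 7, 13))

  # contract completeness: x below p_alpha extrapolates via the first slope
  lm2 <- landmark_set(i_min = 0, p_alpha = 2, p_m = 10, p_beta = 30,
                      i_max = 50, beta = 95)
  spec2 <- mapping_spec(lm2, spec$scale)
  expect_equal(eta(1, spec2), 0 + (4 / 8) * (1 - 2))  # negative, by design
})

test_that("eta is continuous and strictly increasing", {
  spec <- hand_spec()
  x <- seq(-2, 60, by = 0.25)
  y <- eta(x, spec)
  expect_true(all(diff(y) > 0))
  # continuity at the knee
  expect_equal(eta(10 - 1e-9, spec), eta(10 + 1e-9, spec), tolerance = 1e-6)
})

test_that("standardization fixes landmarks, preserves rank order, and cancels gain", {
  cohort <- generate_cohort(test_config(), n = 6, seed = 70)
  vols <- cohort_volumes(cohort)
  sc <- calibrate(vols, cohort_masks(cohort, "liver"), std_config("AC"))

  v <- vols[[1]]
  lm <- extract_landmarks(v, beta = sc$beta)
  sv <- standardize(v, sc)
  expect_identical(sv$modality, "STD_AC")

  # psi maps the three landmarks to inv_scale * {s_min, s_m, s_max}
  spec <- mapping_spec(lm, sc)
  psi <- function(x) sc$inv_scale * eta(x, spec)
  expect_equal(psi(lm$p_alpha), sc$inv_scale * sc$s_min, tolerance = 1e-9)
  expect_equal(psi(lm$p_m), sc$inv_scale * sc$s_m, tolerance = 1e-9)
  expect_equal(psi(lm$p_beta), sc$inv_scale * sc$s_max, tolerance = 1e-9)

  # a voxel sitting exactly at p_m maps to inv_scale * s_m
  v2 <- v
  v2$voxels[1] <- lm$p_m
  sv2 <- standardize(v2, sc)
  expect_equal(sv2$voxels[1], sc$inv_scale * sc$s_m, tolerance = 1e-9)

  # rank order is preserved exactly
  expect_identical(order(sv$voxels), order(v$voxels))

  # gain invariance: standardize(c * I) == standardize(I)
  for (c_gain in c(0.43, 2, 3.7)) {
    scaled <- pet_volume(c_gain * v$voxels, modality = "AC")
    expect_equal(standardize(scaled, sc)$voxels, sv$voxels, tolerance = 1e-6)
  }

  # modality mismatch is refused
  suv <- ac_to_suv(v, scan_meta(500, 70000))
  expect_error(standardize(suv, sc), "mismatch")
})

test_that("standardization matches an independent two-segment loop", {
  cohort <- generate_cohort(phantom_config(grid_shape = c(16, 16, 16)),
                            n = 4, seed = 80)
  vols <- cohort_volumes(cohort)
  sc <- calibrate(vols, cohort_masks(cohort, "liver"), std_config("AC"))
  v <- vols[[2]]
  sv <- standardize(v, sc)

  # independent: oracle landmarks + plain elementwise loop
  vox <- v$voxels
  body_vals <- vox[vox > mean(vox)]
  p_a <- min(vox)
  p_m <- oracle_percentile(body_vals, 50)
  p_b <- oracle_percentile(body_vals, sc$beta)
  slope1 <- sc$s_m / (p_m - p_a)
  slope2 <- (sc$s_max - sc$s_m) / (p_b - p_m)
  expected <- array(0, dim = dim(vox))
  for (i in seq_along(vox)) {
    x <- vox[i]
    expected[i] <- sc$inv_scale *
      (if (x <= p_m) slope1 * (x - p_a) else sc$s_m + slope2 * (x - p_m))
  }
  expect_equal(sv$voxels, expected, tolerance = 1e-10)
})

test_that("strategy chains compose the elementary operations", {
  cohort <- generate_cohort(test_config(), n = 6, seed = 90)
  calib <- cohort_volumes(cohort)[1:4]
  calib_metas <- lapply(cohort[1:4], `[[`, "meta")
  livers <- cohort_masks(cohort, "liver")[1:4]
  test_vols <- cohort_volumes(cohort)[5:6]
  test_metas <- lapply(cohort[5:6], `[[`, "meta")

  # [s-AC] is standardization with the AC scale
  r <- run_strategy("s-AC", test_vols, calib = calib, organ_masks = livers)
  sc <- calibrate(calib, livers, std_config("AC"))
  expect_equal(r$images[[1]]$voxels, standardize(test_vols[[1]], sc)$voxels)
  expect_length(r$scales, 1)
  expect_equal(r$scales[[1]]$beta, sc$beta)

  # [s-AC, SUV] equals ac_to_suv(standardize(.))
  r2 <- run_strategy(c("s-AC", "SUV"), test_vols, metas = test_metas,
                     calib = calib, calib_metas = calib_metas,
                     organ_masks = livers)
  manual <- ac_to_suv(standardize(test_vols[[2]], sc), test_metas[[2]])
  expect_equal(r2$images[[2]]$voxels, manual$voxels)
  expect_identical(r2$images[[2]]$modality, "SUV")

  # [SUV] alone is plain conversion
  r3 <- run_strategy("SUV", test_vols, metas = test_metas,
                     calib = calib, calib_metas = calib_metas,
                     organ_masks = livers)
  expect_equal(r3$images[[1]]$voxels,
               ac_to_suv(test_vols[[1]], test_metas[[1]])$voxels)

  # ill-typed chains are refused
  suv_vols <- Map(ac_to_suv, test_vols, test_metas)
  expect_error(run_strategy("SUV", suv_vols, metas = test_metas,
                            calib = calib, calib_metas = calib_metas,
                            organ_masks = livers), "ill-typed")
  expect_error(run_strategy("s-SUV", test_vols, calib = calib,
                            organ_masks = livers), "ill-typed")
  expect_error(run_strategy("warp", test_vols, calib = calib,
                            organ_masks = livers), "steps")
})

test_that("repeated standardization re-calibrates on the standardized cohort", {
  cohort <- generate_cohort(test_config(), n = 8, seed = 60)
  suv_subj <- lapply(cohort, subject_to_suv)
  calib <- cohort_volumes(suv_subj)[1:5]
  livers5 <- cohort_masks(suv_subj, "liver")[1:5]
  tests <- cohort_volumes(suv_subj)[6:8]

  r1 <- run_strategy("s-SUV", tests, calib = calib, organ_masks = livers5)
  r2 <- run_strategy(c("s-SUV", "s-SUV"), tests, calib = calib,
                     organ_masks = livers5)
  expect_length(r2$scales, 2)
  expect_identical(r2$images[[1]]$modality, "STD_SUV")
  # the first pass removes nearly all non-standardness, so the second pass
  # is close to an identity on the organ means
  livers_t <- cohort_masks(suv_subj, "liver")[6:8]
  mu1 <- mapply(organ_mean, r1$images, livers_t)
  mu2 <- mapply(organ_mean, r2$images, livers_t)
  expect_lt(max(abs(mu2 - mu1) / mu1), 0.15)
})
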