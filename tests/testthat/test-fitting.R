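test_that("actual flip angle is the linear B1+ scaling", {
  expect_equal(actual_flip_angle(10, 1.0), 10)
  expect_equal(actual_flip_angle(10, 0.9), 9)
  expect_equal(actual_flip_angle(4, 1.2), 4.8)
  expect_error(actual_flip_angle(10, 0), "positive")
  expect_error(actual_flip_angle(10, -0.5), "positive")
})

test_that("B1+ smoothing preserves constants and impulse mass, reduces variance", {
  const <- array(0.93, c(8, 8, 4))
  expect_equal(smooth_b1_map(const, sigma = 1.5), const, tolerance = 1e-12)
  expect_identical(smooth_b1_map(const, sigma = 0), const)
  # impulse response away from borders sums to the impulse mass
  imp <- array(0, c(13, 13, 13)); imp[7, 7, 7] <- 1
  sm <- smooth_b1_map(imp, sigma = 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_true(sm[7, 7, 7] < 1 && sm[6, 7, 7] > 0)
  chk <- array((-1)^(outer(outer(1:10, 1:10, "+"), 1:4, "+")), c(10, 10, 4))
  v <- vapply(c(0.5, 1, 2), function(s) var(as.numeric(smooth_b1_map(chk, s))),
              numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[1], var(as.numeric(chk)))
})

test_that("noiseless voxel fits recover the generating parameters", {
  p <- protocol_preset("invivo_ispgr")
  y <- model_vector(tissue_params(800, 50, 1), p)
  f <- fit_voxel(y, p)
  expect_lt(abs(f$T1 - 800) / 800, 0.001)
  expect_lt(abs(f$T2 - 50) / 50, 0.001)
  expect_lt(abs(f$M0 - 1), 0.001)
  expect_true(f$converged)
  expect_false(f$at_bound)
})

test_that("noiseless identifiability holds over the T1 x T2 grid", {
  p <- protocol_preset("invivo_ispgr")
  for (T1 in c(300, 900, 1700, 2500)) for (T2 in c(25, 60, 120, 250)) {
    y <- model_vector(tissue_params(T1, T2, 1), p)
    f <- fit_voxel(y, p)
    expect_lt(abs(f$T1 - T1) / T1, 0.005)
    expect_lt(abs(f$T2 - T2) / T2, 0.005)
  }
})

test_that("fits are scale-equivariant in the signal amplitude", {
  p <- protocol_preset("invivo_ispgr")
  y <- model_vector(tissue_params(1200, 80, 1), p)
  f1 <- fit_voxel(y, p)
  f2 <- fit_voxel(100 * y, p)
  expect_equal(f2$T1, f1$T1, tolerance = 1e-6)
  expect_equal(f2$T2, f1$T2, tolerance = 1e-6)
  expect_equal(f2$M0, 100 * f1$M0, tolerance = 1e-6)
})

test_that("SPGR-model fits of prepared data underestimate T1", {
  p <- protocol_preset("invivo_ispgr")
  ph <- small_phantom()
  for (i in seq_len(nrow(ph$vials))) {
    y <- model_vector(tissue_params(ph$vials$T1[i], ph$vials$T2[i], 1), p)
    fs <- fit_voxel(y, p, model = "spgr")
    fi <- fit_voxel(y, p, t2_bounds = c(10, 400))
    expect_lt(fs$T1, ph$vials$T1[i])
    expect_lt(abs(fi$T1 - ph$vials$T1[i]), abs(fs$T1 - ph$vials$T1[i]))
    expect_true(is.na(fs$T2))
  }
})

test_that("degenerate inputs yield a non-converged flag", {
  p <- protocol_preset("invivo_ispgr")
  f <- fit_voxel(rep(0, 6), p)
  expect_false(f$converged)
  expect_true(is.na(f$T1))
  f2 <- fit_voxel(c(1, 2, NA, 4, 5, 6), p)
  expect_false(f2$converged)
  expect_error(fit_voxel(1:5, p), "measurements")
})

test_that("truth at a fitting bound is flagged converged-at-bound", {
  p <- protocol_preset("invivo_ispgr")
  y <- model_vector(tissue_params(800, 15, 1), p)  # T2 below the lower bound
  f <- fit_voxel(y, p)  # default bounds clip T2 at 20
  expect_true(f$at_bound)
})

test_that("fit_volume honors the mask and closes the loop voxel-wise", {
  p <- protocol_preset("invivo_ispgr")
  ph <- small_phantom()
  st <- simulate_stack(ph, p)
  # single-voxel mask: maps defined only there
  vox <- which(ph$label == 5)[1]
  mask1 <- array(0L, dim(ph$label)); mask1[vox] <- 1L
  st1 <- image_stack(st$volumes, st$b1_ratio, mask1)
  maps1 <- fit_volume(st1, p, t2_bounds = c(10, 400))
  expect_equal(sum(!is.na(maps1$T1)), 1)
  expect_lt(abs(maps1$T1[vox] - ph$vials$T1[5]) / ph$vials$T1[5], 0.001)
  expect_error(fit_volume(image_stack(st$volumes, st$b1_ratio,
                                      array(0L, dim(ph$label))), p),
               "mask is empty")
})

test_that("ignoring a true B1+ reduction biases the fitted T1", {
  p <- protocol_preset("invivo_ispgr")
  tis <- tissue_params(1000, 60, 1)
  y_low_b1 <- model_vector(tis, p, alpha_scale = 0.8)
  f_wrong <- fit_voxel(y_low_b1, p, alpha_scale = 1)
  f_right <- fit_voxel(y_low_b1, p, alpha_scale = 0.8)
  expect_gt(abs(f_wrong$T1 - 1000), 50)
  expect_lt(abs(f_right$T1 - 1000), 1)
})

test_that("region-averaged fitting agrees with truth on noiseless stacks", {
  p <- protocol_preset("invivo_ispgr")
  ph <- small_phantom()
  st <- simulate_stack(ph, p)
  reg <- fit_regions(st, p, t2_bounds = c(10, 400))
  expect_equal(nrow(reg), 8)
  expect_true(all(abs(reg$T1 - ph$vials$T1) / ph$vials$T1 < 0.001))
  expect_true(all(abs(reg$T2 - ph$vials$T2) / ph$vials$T2 < 0.001))
})
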