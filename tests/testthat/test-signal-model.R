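test_that("Ernst equation limits and validation", {
  # full saturation: TR >> T1 at 90 degrees recovers (almost) all of M0
  tis <- tissue_params(500, 50, 1)
  expect_equal(ernst_signal(tis, TR = 5000, alpha = 90), 1 - exp(-10),
               tolerance = 1e-12)
  # zero excitation gives zero signal
  expect_identical(ernst_signal(tis, TR = 5, alpha = 0), 0)
  expect_error(ernst_signal(tis, TR = -1, alpha = 10), "TR")
  expect_error(tissue_params(-500, 50), "T1")
  expect_warning(tissue_params(100, 200), "implausible")
})

test_that("signal is maximized at the Ernst angle (brute-force oracle)", {
  tis <- tissue_params(500, 50, 1)
  alphas <- seq(0.1, 40, by = 0.01)
  s <- ernst_signal(tis, TR = 5, alpha = alphas)
  ernst_angle <- acos(exp(-5 / 500)) * 180 / pi
  expect_lt(abs(alphas[which.max(s)] - ernst_angle), 0.01 + 1e-9)
})

test_that("collapse property: no preparation reduces the model to Ernst", {
  set.seed(42)
  for (i in 1:100) {
    tis <- random_tissue()
    sq <- random_spgr_seq()
    n <- sample(seq_len(sq$k), 1)
    expect_equal(ispgr_signal(tis, sq, n),
                 ernst_signal(tis, sq$TR, sq$alpha),
                 tolerance = 1e-13)
  }
})

test_that("ispgr_signal input contract and degenerate cases", {
  sq <- validation_seq()
  tis <- tissue_params(800, 50, 1)
  expect_error(ispgr_signal(tis, sq, n = 0), "\\[1, k\\]")
  expect_error(ispgr_signal(tis, sq, n = 21), "\\[1, k\\]")
  zero_alpha <- seq_params(TR = 5, alpha = 0, k = 20, T_FS = 50, T_BS = 12,
                           T_Sp = 6)
  expect_identical(ispgr_signal(tis, zero_alpha, n = 5), 0)
  no_m0 <- tissue_params(800, 50, 0)
  expect_identical(ispgr_signal(no_m0, sq, n = 1), 0)
})

test_that("within-shot gap to the Ernst signal shrinks monotonically", {
  sq <- validation_seq()
  for (tis in validation_tissues()) {
    gap <- abs(ispgr_signal(tis, sq, n = 1:20) -
                 ernst_signal(tis, sq$TR, sq$alpha))
    expect_true(all(diff(gap) < 0))
    # geometric decay ratio E1 * cos(alpha)
    ratio <- exp(-sq$TR / tis$T1) * cos(sq$alpha * pi / 180)
    expect_equal(gap[-1] / gap[-20], rep(ratio, 19), tolerance = 1e-9)
  }
})

test_that("S1 monotonicity: non-increasing in T_BS, linear in M0", {
  tis <- tissue_params(800, 50, 1)
  tbs <- seq(0, 80, by = 4)
  s1 <- vapply(tbs, function(b)
    ispgr_signal(tis, seq_params(5, 15, 20, T_FS = 50, T_BS = b, T_Sp = 6), 1),
    numeric(1))
  expect_true(all(diff(s1) < 0))
  sq <- validation_seq()
  expect_equal(ispgr_signal(tissue_params(800, 50, 3), sq, 1:20),
               3 * ispgr_signal(tis, sq, 1:20), tolerance = 1e-14)
})

test_that("end-of-preparation magnetization ties to S1 and decays with T_BS", {
  sq <- validation_seq()
  tis <- tissue_params(1500, 50, 1)
  expect_equal(ispgr_signal(tis, sq, 1),
               sin(sq$alpha * pi / 180) * end_prep_magnetization(tis, sq),
               tolerance = 1e-14)
  # collapse case: Ernst longitudinal steady state
  sq0 <- seq_params(5, 15, 20)
  E1 <- exp(-5 / 1500)
  expect_equal(end_prep_magnetization(tis, sq0),
               (1 - E1) / (1 - E1 * cos(15 * pi / 180)), tolerance = 1e-13)
  # strictly decreasing in T_BS
  mz <- vapply(seq(0, 100, by = 5), function(b)
    end_prep_magnetization(tis, seq_params(5, 15, 20, 50, b, 6)), numeric(1))
  expect_true(all(diff(mz) < 0))
})

test_that("model_vector matches per-measurement evaluation and is linear in M0", {
  p <- protocol_preset("invivo_ispgr")
  expect_equal(nrow(p$measurements), 6)
  tis <- tissue_params(800, 50, 1)
  mv <- model_vector(tis, p)
  expect_length(mv, 6)
  by_hand <- vapply(seq_len(6), function(j) {
    m <- p$measurements[j, ]
    ispgr_signal(tis, seq_params(p$TR, m$alpha, p$k, p$T_FS, m$T_BS, m$T_Sp),
                 n = 1)
  }, numeric(1))
  expect_equal(mv, by_hand, tolerance = 1e-14)
  expect_equal(model_vector(tissue_params(800, 50, 2), p), 2 * mv,
               tolerance = 1e-14)
  # B1+ scaling equals evaluating at scaled flip angles
  mv_scaled <- model_vector(tis, p, alpha_scale = 0.9)
  by_hand_scaled <- vapply(seq_len(6), function(j) {
    m <- p$measurements[j, ]
    ispgr_signal(tis, seq_params(p$TR, m$alpha * 0.9, p$k, p$T_FS, m$T_BS,
                                 m$T_Sp), n = 1)
  }, numeric(1))
  expect_equal(mv_scaled, by_hand_scaled, tolerance = 1e-14)
})

test_that("relaxation factors are the four interval exponentials", {
  tis <- tissue_params(1000, 40, 1)
  sq <- seq_params(TR = 4, alpha = 10, k = 30, T_FS = 202, T_BS = 13,
                   T_Sp = 10)
  f <- relaxation_factors(tis, sq)
  expect_equal(f$E1, exp(-4 / 1000))
  expect_equal(f$E_FS, exp(-202 / 1000))
  expect_equal(f$E_BS, exp(-13 / 40))
  expect_equal(f$E_Sp, exp(-10 / 1000))
  expect_true(all(unlist(f) > 0 & unlist(f) <= 1))
})
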