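test_that("wCV matches the hand-enumerated two-pair oracle", {
  # pairs (100, 102) and (200, 196): d = (-2, 4)
  # within-subject SD = sqrt(mean(d^2)/2) = sqrt((4 + 16)/2/2) = sqrt(5)
  # grand mean = (100 + 102 + 200 + 196)/4 = 149.5
  r <- repeatability(c(100, 200), c(102, 196))
  expect_equal(r$wcv, sqrt(5) / 149.5, tolerance = 1e-12)
  expect_equal(r$mean_difference, 1)
  # limits of agreement symmetric about the mean difference
  expect_equal(r$loa_upper - r$mean_difference,
               r$mean_difference - r$loa_lower)
  expect_equal(r$loa_upper, 1 + 1.96 * sqrt(18), tolerance = 1e-12)
})

test_that("wCV is zero on identical replicates and scale-invariant", {
  x <- c(120, 340, 990, 1500)
  expect_equal(repeatability(x, x)$wcv, 0)
  r1 <- repeatability(x, x + c(-5, 4, 12, -8))
  r2 <- repeatability(7 * x, 7 * (x + c(-5, 4, 12, -8)))
  expect_equal(r2$wcv, r1$wcv, tolerance = 1e-12)
  expect_error(repeatability(c(1, -1), c(-1, 1)), "grand mean")
  expect_error(repeatability(1, 1), "2 pairs")
})

test_that("ROI summary uses the linear-interpolation quantile convention", {
  maps <- list(T1 = array(1:100, c(10, 10, 1)),
               T2 = array(50, c(10, 10, 1)),
               M0 = array(1, c(10, 10, 1)),
               converged = array(TRUE, c(10, 10, 1)),
               mask = array(1L, c(10, 10, 1)))
  s <- roi_summary(maps)
  t1 <- s[s$parameter == "T1", ]
  expect_equal(t1$median, 50.5)
  expect_equal(t1$q25, 25.75)
  expect_equal(t1$q75, 75.25)
  t2 <- s[s$parameter == "T2", ]
  expect_equal(t2$median, 50)
  expect_equal(t2$q75 - t2$q25, 0)
  # masking to a subregion changes only that summary
  sub <- array(0L, c(10, 10, 1)); sub[1, 1, 1] <- 1L
  s2 <- roi_summary(maps, mask = sub)
  expect_equal(s2[s2$parameter == "T1", "median"], 1)
  # all non-converged is an error
  maps$converged[] <- FALSE
  expect_error(roi_summary(maps), "converged")
})

test_that("bias table: zero on equality, antisymmetry, single-voxel regions", {
  dims <- c(6, 6, 1)
  lab <- array(0L, dims); lab[1:3, 1, 1] <- 1L; lab[5, 5, 1] <- 2L
  mk <- function(t1, t2) list(T1 = array(t1, dims), T2 = array(t2, dims),
                              converged = array(TRUE, dims))
  ref <- data.frame(label = 1:2, T1 = c(500, 1000), T2 = c(40, 80))
  # maps equal to the reference by label lookup: all biases are exactly 0
  exact <- mk(array(c(NA, 500, 1000)[lab + 1L], dims),
              array(c(NA, 40, 80)[lab + 1L], dims))
  tab0 <- bias_table(list(m = exact), lab, ref)
  expect_true(all(tab0$error == 0))
  maps <- mk(600, 50)
  tab <- bias_table(list(m = maps), lab, ref)
  expect_equal(tab$error, tab$fitted - tab$reference)
  # swapping fitted and reference negates the error
  swapped <- bias_table(list(m = mk(500, 40)), lab,
                        data.frame(label = 1:2, T1 = c(600, 600),
                                   T2 = c(50, 50)))
  expect_equal(swapped$error[swapped$label == 1 & swapped$parameter == "T1"],
               -tab$error[tab$label == 1 & tab$parameter == "T1"])
  # single-voxel region: bias equals that voxel's error
  expect_equal(tab$error[tab$label == 2 & tab$parameter == "T1"], -400)
  smry <- bias_summary(tab)
  expect_equal(smry$mean_error[smry$parameter == "T1"], 600 - 750)
})

test_that("sensitivity maps are seed-reproducible and vanish without noise", {
  p <- protocol_preset("invivo_ispgr")
  g1 <- c(500, 1500); g2 <- c(30, 100)
  a <- sensitivity_analysis(p, g1, g2, snr = 30, n_reps = 5, seed = 9)
  b <- sensitivity_analysis(p, g1, g2, snr = 30, n_reps = 5, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  hi <- sensitivity_analysis(p, g1, g2, snr = 1e9, n_reps = 3, seed = 1)
  expect_true(all(hi$t1_err_pct < 0.1))
  expect_true(all(hi$t2_err_pct < 0.1))
})

test_that("halving the SNR never improves the grid-median T1 error", {
  p <- protocol_preset("invivo_ispgr")
  g1 <- c(700, 1500); g2 <- c(40, 100)
  lo <- sensitivity_analysis(p, g1, g2, snr = 15, n_reps = 30, seed = 2)
  hi <- sensitivity_analysis(p, g1, g2, snr = 30, n_reps = 30, seed = 2)
  expect_gte(median(lo$t1_err_pct), median(hi$t1_err_pct))
})

test_that("normality gate selects Pearson or Spearman as prescribed", {
  set.seed(4)
  x <- rnorm(30, 100, 10)
  lin <- 2 * x + 5
  r <- correlate_with_diameter(x, lin)
  expect_equal(r$method, "pearson")
  expect_equal(r$estimate, 1, tolerance = 1e-12)
  # monotone nonlinear transform of a heavy-tailed variable: Spearman, rho = 1
  y <- exp(rnorm(30, 0, 2))
  r2 <- correlate_with_diameter(y, y^3)
  expect_equal(r2$method, "spearman")
  expect_equal(r2$estimate, 1, tolerance = 1e-12)
  # shuffled pairing of independent draws decorrelates
  set.seed(8)
  cors <- replicate(50, correlate_with_diameter(rnorm(40), rnorm(40))$estimate)
  expect_lt(abs(mean(cors)), 0.1)
  expect_error(correlate_with_diameter(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate_with_diameter(rnorm(2)[c(1, 2)], rnorm(2)), "3 paired")
})
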