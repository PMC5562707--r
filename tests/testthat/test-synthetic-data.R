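test_that("the generator is deterministic in its seed and validates its config", {
  cfg <- SimPanelConfig(k = 20, seed = 123)
  a <- simulatePanel(cfg)
  b <- simulatePanel(cfg)
  expect_identical(snpData(a$panel), snpData(b$panel))
  expect_identical(a$truth, b$truth)
  c_ <- simulatePanel(SimPanelConfig(k = 20, seed = 124))
  expect_false(identical(snpData(a$panel), snpData(c_$panel)))

  expect_error(SimPanelConfig(k = 1), "at least 2")
  expect_error(SimPanelConfig(k = 10, mafRange = c(0.6, 0.7)))
  expect_error(SimPanelConfig(k = 10, invalidFraction = 0.15), "integer")
  expect_error(SimPanelConfig(k = 10, pleiotropyMode = "balanced",
                              alphaMean = 0.02), "alphaMean")
})

test_that("generated standard errors scale as the inverse square root of sample size", {
  a <- simulatePanel(SimPanelConfig(k = 40, nExposure = 10000,
                                    nOutcome = 10000, seed = 5))
  b <- simulatePanel(SimPanelConfig(k = 40, nExposure = 40000,
                                    nOutcome = 40000, seed = 5))
  expect_equal(snpData(a$panel)$sigma_x / snpData(b$panel)$sigma_x,
               rep(2, nSNPs(a$panel)), tolerance = 1e-12)
  expect_equal(snpData(a$panel)$sigma_y / snpData(b$panel)$sigma_y,
               rep(2, nSNPs(a$panel)), tolerance = 1e-12)
})

test_that("generated panels satisfy the orientation invariant and truth bookkeeping", {
  sim <- simulatePanel(SimPanelConfig(k = 30, pleiotropyMode = "directional",
                                      invalidFraction = 0.5, seed = 9))
  d <- snpData(sim$panel)
  expect_true(all(d$gamma > 0))
  expect_equal(length(sim$truth$invalid), 15L)
  expect_true(all(sim$truth$gamma > 0))
  expect_true(all(sim$truth$alpha[!sprintf("rs%05d", 1:30) %in%
                                    sim$truth$invalid] == 0))
  expect_true(all(d$rsid %in% sim$truth$retained))
})

test_that("balanced pleiotropy leaves the Egger intercept centred on zero while directional pleiotropy biases IVW but not Egger", {
  reps <- 400
  int_bal <- ivw_dir <- egger_dir <- numeric(reps)
  for (r in seq_len(reps)) {
    bal <- simulatePanel(SimPanelConfig(pleiotropyMode = "balanced",
                                        invalidFraction = 1, alphaMean = 0,
                                        seed = deriveSeed(70, r)))
    int_bal[r] <- mrEgger(bal$panel)@intercept
    dir <- simulatePanel(SimPanelConfig(pleiotropyMode = "directional",
                                        invalidFraction = 1,
                                        seed = deriveSeed(71, r)))
    ivw_dir[r] <- mrBeta(mrIVW(dir$panel))
    egger_dir[r] <- mrBeta(mrEgger(dir$panel))
  }
  mc <- function(x) sd(x) / sqrt(reps)
  expect_lt(abs(mean(int_bal)), 3 * mc(int_bal))
  # IVW absorbs the mean pleiotropic effect; Egger (InSIDE) does not
  expect_gt(abs(mean(ivw_dir) - 0.1), 5 * mc(ivw_dir))
  expect_lt(abs(mean(egger_dir) - 0.1), 3 * mc(egger_dir))
  # Egger intercept under directional pleiotropy recovers the mean alpha
  dir_int <- vapply(1:200, function(r) {
    sim <- simulatePanel(SimPanelConfig(pleiotropyMode = "directional",
                                        invalidFraction = 1,
                                        seed = deriveSeed(72, r)))
    mrEgger(sim$panel)@intercept
  }, numeric(1))
  expect_lt(abs(mean(dir_int) - 0.02), 3 * mc(dir_int))
})

test_that("the weighted median resists 30% invalid weight far better than IVW and breaks at 70%", {
  # One-sided contamination below half the weight leaves the weighted
  # median with only a small finite-sample quantile-shift bias (of order
  # half the weighted ratio noise), while IVW absorbs the pleiotropic
  # mean in full; above half the weight the median breaks down too.
  reps <- 300
  wm30 <- ivw30 <- wm70 <- numeric(reps)
  for (r in seq_len(reps)) {
    s30 <- simulatePanel(SimPanelConfig(pleiotropyMode = "directional",
                                        invalidFraction = 0.3,
                                        alphaMean = 0.05, alphaSD = 0.01,
                                        seed = deriveSeed(80, r)))
    d <- snpData(s30$panel)
    wm30[r] <- panelMR:::.weightedMedian(d$Gamma / d$gamma,
                                         (d$sigma_y / abs(d$gamma))^-2)
    ivw30[r] <- mrBeta(mrIVW(s30$panel))
    s70 <- simulatePanel(SimPanelConfig(pleiotropyMode = "directional",
                                        invalidFraction = 0.7,
                                        alphaMean = 0.05, alphaSD = 0.01,
                                        seed = deriveSeed(81, r)))
    d <- snpData(s70$panel)
    wm70[r] <- panelMR:::.weightedMedian(d$Gamma / d$gamma,
                                         (d$sigma_y / abs(d$gamma))^-2)
  }
  mc <- function(x) sd(x) / sqrt(reps)
  expect_lt(abs(mean(wm30) - 0.1), abs(mean(ivw30) - 0.1) / 3)
  expect_gt(abs(mean(wm70) - 0.1), 5 * mc(wm70))   # negative control
  expect_gt(abs(mean(wm70) - 0.1), 3 * abs(mean(wm30) - 0.1))
})

test_that("multi-exposure panels recover the causal vector and expose confounded univariable fits", {
  # independent exposures: coefficient vector recovered at the sample
  # size of the large lipid GWAS (n = 188,577)
  reps <- 150
  cfg <- function(r, ...) SimPanelConfig(k = 50, nExposure = 188577,
                                         nOutcome = 188577,
                                         seed = deriveSeed(90, r), ...)
  co_id <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    mv <- simulateMVPanel(cfg(r), 2, c(0.6, -0.2))
    co_id[r, 1] <- mrBeta(mrMVIVW(mv$exposureBetas, mv$Gamma, mv$sigmaY, "X1"))
    co_id[r, 2] <- mrBeta(mrMVIVW(mv$exposureBetas, mv$Gamma, mv$sigmaY, "X2"))
  }
  mc <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(co_id[, 1]) - 0.6), 3 * mc(co_id[, 1]))
  expect_lt(abs(mean(co_id[, 2]) + 0.2), 3 * mc(co_id[, 2]))

  # heavy cross-loading makes the exposures nearly collinear; the
  # conditional signal is then tiny, so isolating the adjustment
  # property needs a very precise exposure GWAS (partial measurement-
  # error attenuation otherwise dominates, see the methods vignette)
  reps2 <- 100
  co_mv <- co_uv <- numeric(reps2)
  L <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  for (r in seq_len(reps2)) {
    mv <- simulateMVPanel(SimPanelConfig(k = 50, nExposure = 5e6,
                                         nOutcome = 188577,
                                         seed = deriveSeed(91, r)),
                          2, c(0.6, -0.2), crossLoadings = L)
    co_mv[r] <- mrBeta(mrMVIVW(mv$exposureBetas, mv$Gamma, mv$sigmaY, "X1"))
    uv_panel <- makePanel(mv$rsid, abs(mv$exposureBetas[, 1]),
                          mv$sigmaX[, 1],
                          sign(mv$exposureBetas[, 1]) * mv$Gamma,
                          mv$sigmaY)
    co_uv[r] <- mrBeta(mrIVW(uv_panel))
  }
  expect_lt(abs(mean(co_mv) - 0.6), 3 * mc(co_mv))
  # univariable fit of exposure 1 is pulled away from 0.6 by the
  # cross-loaded second exposure
  expect_gt(abs(mean(co_uv) - 0.6), 10 * mc(co_uv))

  # identity loadings with a null second effect reduce to univariable
  reps2 <- 100
  diff_red <- vapply(seq_len(reps2), function(r) {
    mv <- simulateMVPanel(cfg(r), 2, c(0.6, 0))
    a <- mrBeta(mrMVIVW(mv$exposureBetas, mv$Gamma, mv$sigmaY, "X1"))
    p <- makePanel(mv$rsid, abs(mv$exposureBetas[, 1]), mv$sigmaX[, 1],
                   sign(mv$exposureBetas[, 1]) * mv$Gamma, mv$sigmaY)
    a - mrBeta(mrIVW(p))
  }, numeric(1))
  expect_lt(abs(mean(diff_red)), 3 * sd(diff_red) / sqrt(reps2))

  expect_error(simulateMVPanel(cfg(1), 2, c(0.6, -0.2),
                               crossLoadings = matrix(1, 2, 2)),
               "singular")
})

test_that("simulated panels round-trip through the table writer and reader", {
  sim <- simulatePanel(SimPanelConfig(k = 15, seed = 33))
  ep <- tempfile(fileext = ".tsv")
  op <- tempfile(fileext = ".tsv")
  writePanelTables(sim$panel, ep, op, nExposure = 50000, nOutcome = 50000)
  hp <- harmonizePanel(readAssociations(ep, trait = "sim_exposure"),
                       readAssociations(op, trait = "sim_outcome"))
  d0 <- snpData(sim$panel)
  d1 <- snpData(hp)
  expect_equal(d1$gamma, d0$gamma, tolerance = 1e-10)
  expect_equal(d1$Gamma, d0$Gamma, tolerance = 1e-10)
  expect_equal(d1$sigma_y, d0$sigma_y, tolerance = 1e-10)
})
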