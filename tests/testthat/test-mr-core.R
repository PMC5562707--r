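test_that("ratio estimates divide outcome by exposure betas with first-order SEs", {
  panel <- makePanel(c("a", "b", "c"), gamma = c(0.1, 0.2, 0.1),
                     sigma_x = 0.01, Gamma = c(0.02, 0, -0.03),
                     sigma_y = c(0.05, 0.01, 0.02))
  r <- ratioEstimates(panel)
  expect_equal(r$ratio, c(0.2, 0, -0.3))
  expect_equal(r$se, c(0.5, 0.05, 0.2))
})

test_that("IVW reduces to the single-SNP ratio and is exact-fit invariant", {
  one <- makePanel("a", gamma = 0.1, sigma_x = 0.01, Gamma = 0.02,
                   sigma_y = 0.05)
  est <- mrIVW(one)
  expect_equal(mrBeta(est), 0.2)
  expect_equal(mrSE(est), 0.5)

  exact <- homogeneousPanel(8, slope = 0.3)
  expect_equal(mrBeta(mrIVW(exact)), 0.3)

  three <- makePanel(c("a", "b", "c"), gamma = c(0.1, 0.2, 0.3),
                     sigma_x = 0.01, Gamma = c(0.03, 0.05, 0.08),
                     sigma_y = 0.01)
  expect_equal(mrBeta(mrIVW(three)), 0.037 / 0.14)  # closed-form check
  o <- oracleIVW(c(0.1, 0.2, 0.3), c(0.03, 0.05, 0.08), rep(0.01, 3))
  expect_equal(mrBeta(mrIVW(three)), o$beta, tolerance = 1e-12)
})

test_that("random-effects IVW inflates the SE only under overdispersion", {
  set.seed(3)
  k <- 20
  panel <- makePanel(sprintf("rs%02d", 1:k), runif(k, 0.05, 0.3), 0.01,
                     rnorm(k, 0, 0.1), rep(0.01, k))  # strong heterogeneity
  fe <- mrIVW(panel)
  re <- mrIVW(panel, randomEffects = TRUE)
  expect_equal(mrBeta(fe), mrBeta(re))
  expect_equal(mrSE(re), mrSE(fe) * max(1, sqrt(fe@Q / (k - 1))))
  expect_gt(mrSE(re), mrSE(fe))

  hom <- homogeneousPanel(6)
  expect_equal(mrSE(mrIVW(hom, randomEffects = TRUE)), mrSE(mrIVW(hom)))
})

test_that("MR-Egger recovers exact affine relationships and needs 3 SNPs", {
  gamma <- c(0.05, 0.1, 0.2, 0.3)
  panel <- makePanel(letters[1:4], gamma, 0.01, 0.05 + 0.2 * gamma, 0.02)
  est <- mrEgger(panel)
  expect_equal(mrBeta(est), 0.2)
  expect_equal(est@intercept, 0.05)
  expect_equal(est@Q, 0, tolerance = 1e-20)

  expect_error(mrEgger(makePanel(c("a", "b"), c(0.1, 0.2), 0.01,
                                 c(0.02, 0.04), 0.01)), "at least 3")
})

test_that("duplicating every SNP halves the squared Egger SE under fixed dispersion", {
  set.seed(4)
  k <- 8
  gamma <- runif(k, 0.05, 0.3)
  Gamma <- 0.02 + 0.15 * gamma + rnorm(k, 0, 0.002)
  sigma_y <- rep(0.05, k)   # large sigma_y: dispersion < 1, so max(1,.) binds
  p1 <- makePanel(sprintf("a%d", 1:k), gamma, 0.01, Gamma, sigma_y)
  p2 <- makePanel(sprintf("b%d", 1:(2 * k)), rep(gamma, 2), 0.01,
                  rep(Gamma, 2), rep(sigma_y, 2))
  e1 <- mrEgger(p1)
  e2 <- mrEgger(p2)
  expect_equal(mrBeta(e2), mrBeta(e1), tolerance = 1e-12)
  expect_equal(mrSE(e2), mrSE(e1) / sqrt(2), tolerance = 1e-12)
})

test_that("Egger intercept is well calibrated under balanced pleiotropy", {
  reps <- 300
  hits <- 0
  for (r in seq_len(reps)) {
    sim <- simulatePanel(SimPanelConfig(k = 30, betaCausal = 0.1,
                                        pleiotropyMode = "balanced",
                                        invalidFraction = 1, alphaMean = 0,
                                        alphaSD = 0.01,
                                        seed = deriveSeed(900, r)))
    est <- mrEgger(sim$panel)
    lo <- est@intercept - est@interceptSE * qt(0.975, nSNPs(est) - 2)
    hi <- est@intercept + est@interceptSE * qt(0.975, nSNPs(est) - 2)
    if (lo <= 0 && 0 <= hi) hits <- hits + 1
  }
  # intercept CI coverage of the true zero directional bias near nominal
  expect_gt(hits / reps, 0.90)
})

test_that("weighted median interpolates the cumulative-weight midpoint", {
  panel <- makePanel(c("a", "b", "c"), gamma = c(1, 1, 1), sigma_x = 0.01,
                     Gamma = c(0.1, 0.2, 0.3), sigma_y = 1)
  est <- mrMedian(panel, nBoot = 200, seed = 1)
  expect_equal(mrBeta(est), 0.2)  # equal weights: middle ratio

  const <- makePanel(letters[1:4], c(0.1, 0.2, 0.3, 0.4), 1e-6,
                     0.25 * c(0.1, 0.2, 0.3, 0.4), 1e-6)
  estc <- mrMedian(const, nBoot = 200, seed = 1)
  expect_equal(mrBeta(estc), 0.25, tolerance = 1e-4)
  expect_lt(mrSE(estc), 1e-3)

  expect_error(mrMedian(panel, nBoot = 200), "seed")
  expect_error(mrMedian(makePanel(c("a", "b"), c(1, 1), 0.01,
                                  c(0.1, 0.2), 1), nBoot = 200, seed = 1),
               "at least 3")
})

test_that("weighted median matches the grid-search oracle on unequal weights", {
  for (s in 1:20) {
    panel <- randomPanel(4 + s %% 5, seed = 100 + s)
    d <- snpData(panel)
    est <- mrMedian(panel, nBoot = 100, seed = s)
    oracle <- oracleWeightedMedian(d$Gamma / d$gamma,
                                   (d$sigma_y / abs(d$gamma))^-2)
    expect_lt(abs(mrBeta(est) - oracle), 1e-5)
    expect_gte(mrBeta(est), min(d$Gamma / d$gamma))
    expect_lte(mrBeta(est), max(d$Gamma / d$gamma))
  }
})

test_that("multivariable IVW reduces to univariable and fits exact models", {
  set.seed(5)
  k <- 12
  X <- cbind(X1 = runif(k, 0.05, 0.3), X2 = rep(0, k))
  sy <- runif(k, 0.01, 0.03)
  Gamma <- 0.4 * X[, 1] + rnorm(k, 0, 0.01)
  # degenerate second exposure: target coefficient equals univariable IVW
  est_mv <- mrMVIVW(X[, 1, drop = FALSE], Gamma, sy, "X1")
  est_uv <- mrIVW(makePanel(sprintf("rs%d", 1:k), X[, 1], 0.01, Gamma, sy))
  expect_equal(mrBeta(est_mv), mrBeta(est_uv), tolerance = 1e-12)

  # exact linear model reproduced with zero residual
  X2 <- cbind(X1 = runif(k, 0.05, 0.3), X2 = runif(k, 0.05, 0.3))
  G2 <- 0.6 * X2[, 1] - 0.2 * X2[, 2]
  expect_equal(mrBeta(mrMVIVW(X2, G2, sy, "X1")), 0.6, tolerance = 1e-10)
  expect_equal(mrBeta(mrMVIVW(X2, G2, sy, "X2")), -0.2, tolerance = 1e-10)

  # collinearity is a named error
  X3 <- cbind(X1 = X2[, 1], X2 = 2 * X2[, 1])
  expect_error(mrMVIVW(X3, G2, sy, "X1"), "collinear")
  expect_error(mrMVIVW(X2[1:2, ], G2[1:2], sy[1:2], "X1"), "at least")
})

test_that("all estimators are scale equivariant in the outcome", {
  panel <- randomPanel(8, seed = 77)
  d <- snpData(panel)
  c_ <- 3.7
  scaled <- makePanel(d$rsid, d$gamma, d$sigma_x, c_ * d$Gamma,
                      c_ * d$sigma_y, d$eaf)
  for (fit in list(function(p) mrIVW(p), function(p) mrEgger(p),
                   function(p) mrMedian(p, nBoot = 500, seed = 9))) {
    a <- fit(panel)
    b <- fit(scaled)
    expect_equal(mrBeta(b), c_ * mrBeta(a), tolerance = 1e-10)
    expect_equal(mrSE(b), c_ * mrSE(a), tolerance = 1e-10)
  }
})

test_that("IVW with equal outcome SEs equals OLS through the origin", {
  set.seed(6)
  k <- 10
  gamma <- runif(k, 0.05, 0.3)
  Gamma <- rnorm(k, 0.2 * gamma, 0.01)
  panel <- makePanel(sprintf("rs%d", 1:k), gamma, 0.01, Gamma, rep(0.02, k))
  ols <- unname(coef(lm(Gamma ~ 0 + gamma)))
  expect_equal(mrBeta(mrIVW(panel)), ols, tolerance = 1e-12)
})

test_that("estimate objects carry consistent confidence intervals", {
  panel <- randomPanel(6, seed = 12)
  for (est in list(mrIVW(panel), mrEgger(panel),
                   mrMedian(panel, nBoot = 200, seed = 2))) {
    ci <- mrCI(est)
    expect_lte(ci[1], mrBeta(est))
    expect_gte(ci[2], mrBeta(est))
    expect_gt(mrSE(est), 0)
    df <- as.data.frame(est)
    expect_equal(df$beta, mrBeta(est))
    expect_equal(df$n_snps, nSNPs(est))
  }
})
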