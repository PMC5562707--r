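# Independent oracles and fixture builders shared across the suite.

# fixed-effect IVW via R's lm (normal equations), SE rescaled back from
# lm's residual-dispersion convention
oracleIVW <- function(gamma, Gamma, sigma_y) {
  fit <- stats::lm(Gamma ~ 0 + gamma, weights = sigma_y^-2)
  s2 <- summary(fit)$sigma^2
  list(beta = unname(coef(fit)[1]),
       se = sqrt(stats::vcov(fit)[1, 1] / s2))
}

oracleEgger <- function(gamma, Gamma, sigma_y) {
  fit <- stats::lm(Gamma ~ gamma, weights = sigma_y^-2)
  s2 <- summary(fit)$sigma^2
  cov_fixed <- stats::vcov(fit) / s2
  disp <- max(1, s2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       se_slope = sqrt(cov_fixed[2, 2] * disp),
       se_intercept = sqrt(cov_fixed[1, 1] * disp))
}

oracleMV <- function(X, Gamma, sigma_y) {
  fit <- stats::lm(Gamma ~ 0 + X, weights = sigma_y^-2)
  s2 <- summary(fit)$sigma^2
  cov_fixed <- stats::vcov(fit) / s2
  disp <- max(1, s2)
  list(coef = unname(coef(fit)),
       se = unname(sqrt(diag(cov_fixed) * disp)))
}

# weighted median by scanning the piecewise-linear cumulative-weight
# function on a fine grid over the ratio axis (resolution 1e-6)
oracleWeightedMedian <- function(ratios, weights, res = 1e-6) {
  o <- order(ratios)
  v <- ratios[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  grid <- seq(v[1], v[length(v)], by = res)
  cw <- stats::approx(v, p, xout = grid, ties = "ordered")$y
  grid[which.min(abs(cw - 0.5))]
}

# random well-formed harmonized panel for oracle comparisons
randomPanel <- function(k, seed) {
  set.seed(seed)
  makePanel(sprintf("rs%03d", seq_len(k)),
            gamma = runif(k, 0.02, 0.4),
            sigma_x = runif(k, 0.005, 0.05),
            Gamma = rnorm(k, 0, 0.1),
            sigma_y = runif(k, 0.005, 0.05),
            eaf = runif(k, 0.05, 0.95))
}

# homogeneous panel: Gamma = slope * gamma exactly (Q = 0)
homogeneousPanel <- function(k, slope = 0.2) {
  gamma <- seq(0.05, 0.3, length.out = k)
  makePanel(sprintf("rs%03d", seq_len(k)), gamma = gamma,
            sigma_x = 0.01, Gamma = slope * gamma, sigma_y = 0.02)
}

assocTable <- function(rsid, ea, oa, eaf, beta, se, trait = "trait",
                       pvalue = NA_real_, n = NA_real_) {
  new("AssociationTable", trait = trait,
      data = data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
                        eaf = eaf, beta = beta, se = se, pvalue = pvalue,
                        n = n, stringsAsFactors = FALSE))
}

writeAssocTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
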