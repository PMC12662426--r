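test_that("Wald ratios follow the first-order delta formula", {
  h <- makeHarm(gamma = c(0.1, 0.2, 0.1), se_gamma = 0.01,
                Gamma = c(0.02, 0, 0.1), se_Gamma = c(0.005, 0.01, 0.01))
  wr <- waldRatios(h)
  expect_equal(wr$ratio, c(0.2, 0, 1))       # incl. zero and identity cases
  expect_equal(wr$ratio_se[1], 0.05)
  expect_equal(wr$weight, 1 / wr$ratio_se^2)
  # negative gamma: ratio keeps its sign, SE uses |gamma|
  h2 <- makeHarm(-0.1, 0.01, 0.02, 0.005)
  expect_equal(waldRatios(h2)$ratio, -0.2)
  expect_equal(waldRatios(h2)$ratio_se, 0.05)
  # zero exposure effect excluded with a warning
  h3 <- makeHarm(c(0.1, 0), 0.01, c(0.02, 0.01), 0.005)
  expect_warning(wr3 <- waldRatios(h3), "zero exposure")
  expect_equal(nrow(wr3), 1L)
})

test_that("IVW reduces to the Wald ratio for one SNP and to consensus for equal ratios", {
  h1 <- makeHarm(0.1, 0.01, 0.02, 0.005)
  fit <- mrIVW(h1)
  expect_equal(fit@beta, 0.2)
  expect_equal(fit@se, 0.05)  # no heterogeneity scaling possible at J = 1
  h2 <- makeHarm(c(0.1, 0.2, 0.3), 0.01, c(0.02, 0.04, 0.06),
                 c(0.01, 0.02, 0.01))
  expect_equal(mrIVW(h2)@beta, 0.2)
  expect_error(mrIVW(makeHarm(numeric(0), numeric(0), numeric(0),
                              numeric(0))), "no instruments")
})

test_that("IVW matches the weighted-regression value on the reference fixture", {
  h <- makeHarm(gamma = c(0.1, 0.2, 0.15), se_gamma = 0.01,
                Gamma = c(0.02, 0.05, 0.03), se_Gamma = c(0.01, 0.01, 0.02))
  fit <- mrIVW(h, "fixed")
  expect_equal(fit@beta, 0.2359551, tolerance = 1e-6)
  orc <- ivwOracle(harmonizedData(h))
  expect_equal(fit@beta, orc$beta, tolerance = 1e-12)
  expect_equal(fit@se, orc$se, tolerance = 1e-12)
})

test_that("random-effects IVW never reports a smaller SE than fixed", {
  for (seed in 1:20) {
    h <- randomHarm(10, seed)
    expect_gte(mrIVW(h, "random")@se, mrIVW(h, "fixed")@se)
    expect_equal(mrIVW(h, "random")@beta, mrIVW(h, "fixed")@beta)
  }
})

test_that("MR-Egger recovers an exact linear relationship", {
  g <- c(0.05, 0.1, 0.2, 0.3)
  h <- makeHarm(g, 0.01, 0.01 + 0.3 * g, runif(4, 0.005, 0.02))
  fit <- mrEgger(h)
  expect_equal(fit@beta, 0.3, tolerance = 1e-10)
  expect_equal(fit@intercept, 0.01, tolerance = 1e-10)
  expect_error(mrEgger(makeHarm(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)),
               "at least 3")
})

test_that("origin-constrained weighted regression equals fixed-effect IVW", {
  for (seed in 1:10) {
    h <- randomHarm(8, seed)
    d <- harmonizedData(h)
    orc <- ivwOracle(d)
    expect_equal(mrIVW(h, "fixed")@beta, orc$beta, tolerance = 1e-10)
  }
})

test_that("MR-Egger agrees with the weighted normal-equations oracle", {
  for (seed in 1:20) {
    h <- randomHarm(4 + seed %% 10, seed)
    d <- harmonizedData(h)
    fit <- mrEgger(h)
    orc <- eggerOracle(d)
    expect_equal(fit@beta, orc$slope, tolerance = 1e-10)
    expect_equal(fit@intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit@se, orc$se_slope, tolerance = 1e-10)
    expect_equal(fit@interceptSe, orc$se_intercept, tolerance = 1e-10)
  }
})

test_that("weighted median reduces to the sample median and interpolates exactly", {
  h <- makeHarm(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.4), 0.01)
  expect_equal(mrWeightedMedian(h, n_boot = 0)@beta, 0.2)
  # weights {0.25, 0.5, 0.25}: cumulative midpoints 0.125/0.5/0.875
  h2 <- makeHarm(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.4),
                 c(0.02, 0.01 * sqrt(2), 0.02))
  expect_equal(mrWeightedMedian(h2, n_boot = 0)@beta, 0.2)
  expect_error(mrWeightedMedian(makeHarm(0.1, 0.01, 0.02, 0.01), n_boot = 0),
               "at least 3")
  # bootstrap needs a seed and is reproducible with one
  expect_error(mrWeightedMedian(h, n_boot = 10), "seed")
  a <- mrWeightedMedian(h, n_boot = 50, seed = 5)
  b <- mrWeightedMedian(h, n_boot = 50, seed = 5)
  expect_identical(a@se, b@se)
})

test_that("weighted median resists 40% invalid instruments", {
  set.seed(42)
  j <- 25
  valid <- rep(c(TRUE, FALSE), c(15, 10))
  gamma <- runif(j, 0.1, 0.3)
  truth <- 0.25
  Gamma <- ifelse(valid, truth * gamma, truth * gamma + runif(j, 0.05, 0.15))
  h <- makeHarm(gamma, 0.005, Gamma + rnorm(j, 0, 0.002), 0.002)
  wm <- mrWeightedMedian(h, n_boot = 0)@beta
  ivw <- mrIVW(h)@beta
  expect_lt(abs(wm - truth), abs(ivw - truth))
  expect_lt(abs(wm - truth), 0.05)
})

test_that("mode estimators find the majority signal", {
  h <- makeHarm(c(1, 1, 1), 0.01, c(0.3, 0.3, 0.3), 0.01)
  expect_equal(mrMode(h, n_boot = 0)@beta, 0.3)  # point mass
  h2 <- makeHarm(rep(1, 4), 0.01, c(0.2, 0.2, 0.2, 0.9), 0.01)
  est <- mrMode(h2, weighted = FALSE, n_boot = 0)@beta
  # dense grid search over the same kernel density as an oracle
  r <- c(0.2, 0.2, 0.2, 0.9)
  s <- sqrt(mean((r - mean(r))^2))
  bw <- 1.06 * s * 4^(-1 / 5)
  grid <- seq(-0.5, 1.5, length.out = 20001)
  dens <- vapply(grid, function(x) sum(dnorm((x - r) / bw)), numeric(1))
  expect_equal(est, grid[which.max(dens)], tolerance = 5e-3)
  expect_lt(abs(est - 0.2), 0.05)
  # equal weights: weighted mode equals simple mode
  expect_equal(mrMode(h2, weighted = TRUE, n_boot = 0)@beta, est,
               tolerance = 1e-8)
})

test_that("estimators are order-invariant and sign-equivariant", {
  h <- randomHarm(12, 99)
  d <- harmonizedData(h)
  perm <- h[sample.int(12)]
  neg <- makeHarm(d$gamma, d$se_gamma, -d$Gamma, d$se_Gamma)
  ests <- function(x, seed = 7) c(
    ivw = mrIVW(x)@beta, egger = mrEgger(x)@beta,
    wm = mrWeightedMedian(x, n_boot = 0)@beta,
    wmode = mrMode(x, TRUE, n_boot = 0)@beta,
    smode = mrMode(x, FALSE, n_boot = 0)@beta)
  e0 <- ests(h)
  expect_equal(ests(perm), e0, tolerance = 1e-9)
  en <- ests(neg)
  expect_equal(en, -e0, tolerance = 1e-6)
  expect_equal(mrIVW(neg)@se, mrIVW(h)@se)
  expect_equal(mrEgger(neg)@se, mrEgger(h)@se)
})

test_that("all five estimators converge under strong valid instruments", {
  h <- simulateHarmonized(150, gamma_sd = 0.3, alpha = 0.25,
                          se_exposure = 0.01, se_outcome = 0.005, seed = 31)
  fits <- mrAllMethods(h, n_boot = 0)
  betas <- vapply(fits, function(f) f@beta, numeric(1))
  expect_true(all(abs(betas - 0.25) < 0.05))
})

test_that("odds-ratio reporting exponentiates the estimate and its CI", {
  h <- makeHarm(c(0.1, 0.2, 0.15), 0.01, c(0.02, 0.05, 0.03), 0.01)
  fit <- mrIVW(h)
  expect_equal(fit@orValue, exp(fit@beta))
  expect_equal(fit@orCiLow, exp(fit@ciLow))
  expect_lte(fit@ciLow, fit@beta)
  expect_lte(fit@beta, fit@ciHigh)
  expect_equal(fit@pval, 2 * pnorm(-abs(fit@beta / fit@se)))
})
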