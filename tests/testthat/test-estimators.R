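test_that("Wald ratios follow the first-order definition", {
  h <- makeHarmonized(bx = c(1, 2, -1), by = c(0.5, 0.5, 0.5),
                      sy = c(0.1, 0.1, 0.1))
  wr <- waldRatios(h)
  expect_equal(wr$ratio, c(0.5, 0.25, -0.5))
  expect_equal(wr$se, c(0.1, 0.05, 0.1))
  expect_equal(wr$w, 1 / wr$se^2)
  # zero exposure effect dropped with warning
  h0 <- makeHarmonized(bx = c(1, 0), by = c(0.5, 0.2))
  expect_warning(wr0 <- waldRatios(h0), "zero exposure")
  expect_identical(nrow(wr0), 1L)
})

test_that("IVW equals the weighted mean and the zero-intercept WLS slope", {
  h <- makeHarmonized(bx = c(1, 1), by = c(0.4, 0.4))
  expect_equal(mrBeta(mrIVW(h)), 0.4)

  h2 <- makeHarmonized(bx = c(1, 1), by = c(0.5, 0.3), sy = c(1, 1))
  est <- mrIVW(h2, model = "fixed")
  expect_equal(mrBeta(est), 0.4)
  expect_equal(mrSE(est), 1 / sqrt(2))

  # algebraic identity with zero-intercept WLS on a random instance
  set.seed(99)
  bx <- rnorm(12, 0.1, 0.03); by <- 0.3 * bx + rnorm(12, 0, 0.02)
  sy <- runif(12, 0.01, 0.05)
  h3 <- makeHarmonized(bx, by, sy = sy)
  wls <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(mrBeta(mrIVW(h3)), unname(coef(wls)), tolerance = 1e-12)
  expect_error(mrIVW(makeHarmonized(1, 0.4)), "at least 2")
})

test_that("random-effects IVW never reports less than the fixed-effect se", {
  for (seed in 1:5) {
    pair <- simulateGwasPair(simConfig(nSnps = 50, seed = 300 + seed))
    h <- leanHarmonize(pair)
    expect_gte(mrSE(mrIVW(h, "random")), mrSE(mrIVW(h, "fixed")))
  }
})

test_that("MR-Egger matches the with-intercept WLS oracle", {
  # exact line through 3 points: slope 0.5, intercept 0.5, zero residual
  h <- makeHarmonized(bx = c(1, 2, 3), by = c(1, 1.5, 2), sy = rep(1, 3))
  est <- mrEgger(h)
  expect_equal(mrBeta(est), 0.5, tolerance = 1e-10)
  expect_equal(est@intercept, 0.5, tolerance = 1e-10)

  # 2-point exact fit via lm oracle (test-only degenerate case)
  fit2 <- lm(c(1, 1.5) ~ c(1, 2))
  expect_equal(unname(coef(fit2)), c(0.5, 0.5))

  # proportional data: intercept 0, slope c
  hp <- makeHarmonized(bx = c(1, 2, 3, 4), by = 0.7 * c(1, 2, 3, 4),
                       sy = rep(0.1, 4))
  ep <- mrEgger(hp)
  expect_equal(mrBeta(ep), 0.7, tolerance = 1e-10)
  expect_equal(ep@intercept, 0, tolerance = 1e-10)

  # weighted oracle on a random instance, to 1e-10
  set.seed(7)
  bx <- abs(rnorm(10, 0.1, 0.05)); by <- 0.02 + 0.3 * bx + rnorm(10, 0, 0.01)
  sy <- runif(10, 0.005, 0.02)
  h2 <- makeHarmonized(bx, by, sy = sy)
  wls <- lm(by ~ bx, weights = 1 / sy^2)
  e2 <- mrEgger(h2)
  expect_equal(mrBeta(e2), unname(coef(wls)[2]), tolerance = 1e-10)
  expect_equal(e2@intercept, unname(coef(wls)[1]), tolerance = 1e-10)
  expect_error(mrEgger(makeHarmonized(c(1, 2), c(1, 1))), "at least 3")
})

test_that("MR-Egger orients to non-negative exposure effects", {
  set.seed(17)
  bx <- rnorm(15, 0, 0.1); by <- 0.01 + 0.4 * bx + rnorm(15, 0, 0.01)
  sy <- rep(0.01, 15)
  h <- makeHarmonized(bx, by, sy = sy)
  s <- sign(bx)
  wls <- lm(I(s * by) ~ I(s * bx), weights = 1 / sy^2)
  expect_equal(mrBeta(mrEgger(h)), unname(coef(wls)[2]), tolerance = 1e-10)
})

test_that("weighted median interpolates the mid-cumulative weights", {
  h <- makeHarmonized(bx = rep(1, 3), by = rep(0.2, 3))
  expect_equal(mrBeta(mrWeightedMedian(h, nBoot = 50, seed = 1)), 0.2)

  # equal weights on {0.1, 0.2, 0.9}: s hits 0.5 exactly at the middle ratio
  h2 <- makeHarmonized(bx = rep(1, 3), by = c(0.1, 0.2, 0.9), sy = rep(1, 3))
  expect_equal(mrBeta(mrWeightedMedian(h2, nBoot = 50, seed = 1)), 0.2)

  # bootstrap se is bit-reproducible under a fixed seed
  a <- mrWeightedMedian(h2, nBoot = 200, seed = 42)
  b <- mrWeightedMedian(h2, nBoot = 200, seed = 42)
  expect_identical(mrSE(a), mrSE(b))
  expect_error(mrWeightedMedian(makeHarmonized(c(1, 1), c(1, 1)),
                                nBoot = 10, seed = 1), "at least 3")
})

test_that("weighted mode finds the dominant ratio cluster", {
  h <- makeHarmonized(bx = rep(1, 3), by = rep(0.5, 3))
  expect_equal(mrBeta(mrWeightedMode(h, nBoot = 50, seed = 1)), 0.5)

  # majority cluster at 0.5 against a lone 3.0; dense-grid KDE oracle
  ratios <- c(0.5, 0.5, 3.0); w <- rep(1, 3)
  h2 <- makeHarmonized(bx = rep(1, 3), by = ratios, sy = rep(1, 3))
  est <- mrBeta(mrWeightedMode(h2, nBoot = 50, seed = 1))
  bw <- 0.9 * sd(ratios) * 3^(-1/5)  # mad is 0 here, so the rule uses sd
  oracle_grid <- seq(-2, 5, length.out = 200001)
  dens <- vapply(oracle_grid,
                 function(x) sum(w * dnorm((x - ratios) / bw)), numeric(1))
  oracle <- oracle_grid[which.max(dens)]
  expect_equal(est, oracle, tolerance = 1e-2)
  expect_lt(abs(est - 0.5), 0.15)  # near the majority cluster

  # kernel-flattening limit: large phi approaches the weighted mean
  set.seed(3)
  r3 <- rnorm(9, 0.3, 0.1)
  h3 <- makeHarmonized(bx = rep(1, 9), by = r3, sy = rep(1, 9))
  big <- mrBeta(mrWeightedMode(h3, phi = 50, nBoot = 50, seed = 1))
  expect_equal(big, mean(r3), tolerance = 0.02)
})

test_that("MR-RAPS reduces to fixed-effect IVW for tiny exposure errors", {
  set.seed(12)
  bx <- rnorm(20, 0.1, 0.02); by <- 0.25 * bx + rnorm(20, 0, 0.01)
  sy <- runif(20, 0.005, 0.02)
  h <- makeHarmonized(bx, by, sx = rep(1e-10, 20), sy = sy)
  expect_equal(mrBeta(mrRAPS(h)), mrBeta(mrIVW(h, model = "fixed")),
               tolerance = 1e-8)
})

test_that("robust loss shields MR-RAPS from a gross outlier", {
  set.seed(23)
  n <- 50
  bx <- rnorm(n, 0.1, 0.02)
  by <- 0.2 * bx + rnorm(n, 0, 0.01)
  by[1:3] <- by[1:3] + 0.15          # planted large pleiotropic effects
  h <- makeHarmonized(bx, by, sx = rep(0.002, n), sy = rep(0.01, n))
  b_l2 <- mrBeta(mrRAPS(h, loss = "l2"))
  b_tk <- mrBeta(mrRAPS(h, loss = "tukey"))
  expect_lt(abs(b_tk - 0.2), abs(b_l2 - 0.2))
  expect_lt(abs(b_tk - 0.2), 0.05)
})

test_that("overdispersed MR-RAPS absorbs balanced pleiotropy in tau2", {
  pair <- simulateGwasPair(simConfig(
    trueSlope = 0.2, seed = 31, invalidFraction = 1,
    pleiotropy = list(type = "balanced", sd = 0.02)))
  h <- leanHarmonize(pair)
  fit <- mrRAPS(h, overdispersion = TRUE)
  expect_gt(fit@details$tau2, 0)
  # tau2 tracks the planted pleiotropy variance (order of magnitude)
  expect_gt(fit@details$tau2, 0.02^2 / 5)
  expect_lt(fit@details$tau2, 0.02^2 * 5)
  expect_lt(abs(mrBeta(fit) - 0.2), 4 * mrSE(fit))
})

test_that("heterogeneity statistics match their arithmetic oracles", {
  h0 <- makeHarmonized(bx = rep(1, 4), by = rep(0.3, 4))
  het0 <- mrHeterogeneity(h0)
  expect_equal(het0$cochran$Q, 0)
  expect_equal(het0$cochran$p, 1)

  # two ratios {0.5, 0.3} with unit weights: Q = 2 * 0.1^2 = 0.02, df 1
  h1 <- makeHarmonized(bx = c(1, 1), by = c(0.5, 0.3), sy = c(1, 1))
  het1 <- mrHeterogeneity(h1)
  expect_equal(het1$cochran$Q, 0.02)
  expect_identical(het1$cochran$df, 1L)
  expect_equal(het1$cochran$p, pchisq(0.02, 1, lower.tail = FALSE))
  expect_equal(het1$cochran$p, 0.888, tolerance = 1e-3)

  # Ruecker's Q never exceeds Cochran's Q (intercept absorbs heterogeneity)
  for (seed in 1:8) {
    set.seed(seed)
    bx <- abs(rnorm(10, 0.1, 0.04)) + 0.01
    by <- 0.2 * bx + rnorm(10, 0.01, 0.02)
    h <- makeHarmonized(bx, by, sy = runif(10, 0.01, 0.05))
    het <- mrHeterogeneity(h)
    expect_lte(het$rucker$Q, het$cochran$Q + 1e-12)
  }
})

test_that("odds-ratio conversion matches the normal-quantile oracle", {
  expect_equal(toOddsRatio(0, 0.1)$or, 1)
  d <- toOddsRatio(log(2), 0)
  expect_equal(d$or, 2); expect_equal(d$ciLow, 2); expect_equal(d$ciHigh, 2)
  ci <- toOddsRatio(0.2, 0.1, 0.95)
  z <- qnorm(0.975)
  expect_equal(ci$ciLow, exp(0.2 - z * 0.1))
  expect_equal(ci$ciHigh, exp(0.2 + z * 0.1))
  expect_equal(ci$ciLow, exp(0.004), tolerance = 1e-4)
  expect_equal(ci$ciHigh, exp(0.396), tolerance = 1e-4)
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(55)
  bx <- rnorm(15, 0.1, 0.03); by <- 0.3 * bx + rnorm(15, 0, 0.01)
  sy <- runif(15, 0.005, 0.02)
  h <- makeHarmonized(bx, by, sy = sy)
  hneg <- makeHarmonized(bx, -by, sy = sy)
  c0 <- 2.5
  hscale <- makeHarmonized(c0 * bx, by, sx = rep(0.01, 15), sy = sy)

  fits <- function(hh, seed = 9) list(
    ivw = mrBeta(mrIVW(hh)),
    egger = mrBeta(mrEgger(hh)),
    med = mrBeta(mrWeightedMedian(hh, nBoot = 30, seed = seed)),
    raps = mrBeta(mrRAPS(hh)))
  f <- fits(h); fn <- fits(hneg); fs <- fits(hscale)
  for (nm in names(f)) {
    expect_equal(fn[[nm]], -f[[nm]], tolerance = 1e-6)
    expect_equal(fs[[nm]], f[[nm]] / c0, tolerance = 1e-3)
  }
})
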