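#' Per-variant Wald ratios
#'
#' The shared kernel of all summary-data MR estimators: per variant, the
#' ratio estimate `beta_out / beta_exp` with first-order standard error
#' `se_out / |beta_exp|` and inverse-variance weight. Variants with zero
#' exposure effect are dropped with a warning.
#'
#' @param data [MrHarmonized-class].
#' @param secondOrder use second-order ratio SEs
#'   (`sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`)
#'   instead of first-order; default FALSE.
#' @return data.frame (`snp_id`, `ratio`, `se`, `w`).
#' @export
waldRatios <- function(data, secondOrder = FALSE) {
  stopifnot(is(data, "MrHarmonized"))
  tab <- harmonizedTable(data)
  zero <- tab$beta_exp == 0
  if (any(zero)) {
    warning(sum(zero), " variant(s) with zero exposure effect dropped")
    tab <- tab[!zero, , drop = FALSE]
  }
  if (!nrow(tab))
    return(data.frame(snp_id = character(), ratio = numeric(),
                      se = numeric(), w = numeric()))
  ratio <- tab$beta_out / tab$beta_exp
  se <- if (secondOrder)
    sqrt(tab$se_out^2 / tab$beta_exp^2 +
           tab$beta_out^2 * tab$se_exp^2 / tab$beta_exp^4)
  else tab$se_out / abs(tab$beta_exp)
  data.frame(snp_id = tab$snp_id, ratio = ratio, se = se, w = 1 / se^2,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' The primary MR estimator: the inverse-variance-weighted mean of the
#' per-variant Wald ratios, algebraically identical to the zero-intercept
#' weighted least-squares slope of outcome on exposure effects with weights
#' `1/se_out^2`. The default multiplicative random-effects model inflates
#' the fixed-effect standard error by `sqrt(Q/(J-1))` when heterogeneity
#' exceeds its expectation (inflation floored at 1); `model = "fixed"`
#' reports the unscaled standard error.
#'
#' @param data [MrHarmonized-class] with >= 2 instruments.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @param level confidence level.
#' @return [MrEstimate-class].
#' @export
mrIVW <- function(data, model = c("random", "fixed"), level = 0.95) {
  model <- match.arg(model)
  wr <- waldRatios(data)
  J <- nrow(wr)
  if (J < 2) stop("estimation error: IVW requires at least 2 instruments")
  beta <- sum(wr$w * wr$ratio) / sum(wr$w)
  se <- 1 / sqrt(sum(wr$w))
  Q <- sum(wr$w * (wr$ratio - beta)^2)
  infl <- 1
  if (model == "random") infl <- max(1, sqrt(Q / (J - 1)))
  .MrEstimate("IVW", beta, se * infl, J, level,
              details = list(model = model, Q = Q, inflation = infl))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an intercept,
#' weights `1/se_out^2`, after orienting the data so all exposure effects
#' are non-negative (outcome signs flipped accordingly). The intercept
#' estimates the average directional pleiotropic effect; the slope is the
#' causal estimate under the InSIDE assumption. Standard errors use the
#' multiplicative random-effects convention (residual dispersion floored at
#' 1); p-values use the normal reference (configurable to Student t).
#'
#' @param data [MrHarmonized-class] with >= 3 instruments.
#' @param level confidence level.
#' @param dist `"normal"` (default) or `"t"` reference for p-values.
#' @return [MrEstimate-class] with intercept fields populated.
#' @export
mrEgger <- function(data, level = 0.95, dist = c("normal", "t")) {
  dist <- match.arg(dist)
  stopifnot(is(data, "MrHarmonized"))
  tab <- harmonizedTable(data)
  tab <- tab[tab$beta_exp != 0, , drop = FALSE]
  J <- nrow(tab)
  if (J < 3) stop("estimation error: MR-Egger requires at least 3 instruments")
  s <- ifelse(tab$beta_exp < 0, -1, 1)
  x <- s * tab$beta_exp; y <- s * tab$beta_out
  w <- 1 / tab$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  sm <- suppressWarnings(summary(fit))   # exact fits handled below
  sigma <- sm$sigma
  # floor the residual dispersion at 1: never report less than fixed-effect
  adj <- if (sigma > 1e-10) 1 / min(sigma, 1) else 1
  slope <- unname(stats::coef(fit)[2]); slope_se <- sm$coefficients[2, 2] * adj
  icpt <- unname(stats::coef(fit)[1]); icpt_se <- sm$coefficients[1, 2] * adj
  if (sigma <= 1e-10) {
    # exactly collinear data: estimates are exact, uncertainty degenerate
    scale_y <- max(abs(y), 1e-300)
    if (abs(icpt) < 1e-10 * scale_y) icpt <- 0
    slope_se <- 0; icpt_se <- 0
  }
  est <- .MrEstimate("MR-Egger", slope, slope_se, J, level,
                     intercept = icpt, interceptSE = icpt_se,
                     details = list(sigma = sigma, dist = dist))
  if (dist == "t" && J > 2) {
    est@pval <- max(2 * stats::pt(-abs(slope / slope_se), df = J - 2),
                    .Machine$double.xmin)
    est@interceptPval <- max(2 * stats::pt(-abs(icpt / icpt_se), df = J - 2),
                             .Machine$double.xmin)
  }
  est
}

# weighted median of ratios by mid-cumulative-weight interpolation
.weightedMedian <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; ww <- w[ord]
  s <- (cumsum(ww) - ww / 2) / sum(ww)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

.bootSE <- function(wr, stat, nBoot, seed) {
  withr::with_seed(seed, {
    reps <- vapply(seq_len(nBoot), function(b) {
      rb <- stats::rnorm(nrow(wr), wr$ratio, wr$se)
      stat(rb, wr$w)
    }, numeric(1))
  })
  stats::sd(reps)
}

#' Weighted-median estimator
#'
#' Orders the Wald ratios, forms standardized mid-cumulative weights
#' \eqn{s_j = (\sum_{k \le j} w_k - w_j/2) / \sum_k w_k}, and linearly
#' interpolates the ratios at s = 0.5. Consistent when at least half of the
#' total weight comes from valid instruments. The standard error is a
#' seeded parametric bootstrap: ratios are resampled from
#' `Normal(ratio_j, se_j)` and the weighted median recomputed.
#'
#' @param data [MrHarmonized-class] with >= 3 instruments.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (mandatory for reproducibility).
#' @param level confidence level.
#' @return [MrEstimate-class].
#' @export
mrWeightedMedian <- function(data, nBoot = 1000, seed, level = 0.95) {
  wr <- waldRatios(data)
  if (nrow(wr) < 3)
    stop("estimation error: weighted median requires at least 3 instruments")
  beta <- .weightedMedian(wr$ratio, wr$w)
  se <- .bootSE(wr, function(r, w) .weightedMedian(r, w), nBoot, seed)
  .MrEstimate("weighted-median", beta, se, nrow(wr), level,
              details = list(nBoot = nBoot, seed = seed))
}

# weighted KDE argmax over a dense grid; bandwidth = phi * modified Silverman
.weightedModePoint <- function(ratio, w, phi = 1, gridN = 10000) {
  sdev <- stats::sd(ratio)
  madv <- stats::mad(ratio)
  h <- 0.9 * min(sdev, if (madv > 0) madv else Inf) * length(ratio)^(-1/5)
  if (!is.finite(h) || h <= 0) return(ratio[which.max(w)])
  h <- h * phi
  wn <- w / sum(w)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = gridN)
  dens <- as.vector(wn %*% stats::dnorm(outer(ratio, grid, "-") / h))
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' Forms a weighted normal-kernel density over the Wald ratios (bandwidth =
#' `phi` times the modified Silverman rule, 0.9 min(sd, mad) J^(-1/5)) and
#' returns the density argmax, located by grid search over the ratio range
#' plus/minus 3 bandwidths at 10,000 points. Estimates the causal effect
#' from the largest cluster of agreeing instruments; unbiased when the
#' instruments in that cluster are valid. Bootstrap standard error as in
#' [mrWeightedMedian()].
#'
#' @param data [MrHarmonized-class] with >= 3 instruments.
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot bootstrap replicates; @param seed RNG seed.
#' @param level confidence level.
#' @return [MrEstimate-class].
#' @export
mrWeightedMode <- function(data, phi = 1, nBoot = 1000, seed, level = 0.95) {
  wr <- waldRatios(data)
  if (nrow(wr) < 3)
    stop("estimation error: weighted mode requires at least 3 instruments")
  beta <- .weightedModePoint(wr$ratio, wr$w, phi)
  se <- .bootSE(wr, function(r, w) .weightedModePoint(r, w, phi), nBoot, seed)
  .MrEstimate("weighted-mode", beta, se, nrow(wr), level,
              details = list(phi = phi, nBoot = nBoot, seed = seed))
}

## ---- robust adjusted profile score (MR-RAPS style) ----

.rapsPsi <- function(loss, k) {
  switch(loss,
    l2    = function(t) t,
    huber = function(t) pmin(pmax(t, -k), k),
    tukey = function(t) ifelse(abs(t) <= k, t * (1 - (t / k)^2)^2, 0))
}

# delta = E[psi(Z) Z] under a standard normal, for overdispersion calibration
.rapsDelta <- function(loss, k) {
  if (loss == "l2") return(1)
  psi <- .rapsPsi(loss, k)
  stats::integrate(function(t) psi(t) * t * stats::dnorm(t),
                   -Inf, Inf)$value
}

# profile-score contributions for the slope at (beta, tau2)
.rapsScore <- function(beta, tau2, bx, by, sx, sy, psi) {
  v <- sy^2 + beta^2 * sx^2 + tau2
  r <- by - beta * bx
  t <- r / sqrt(v)
  psi(t) * (bx * v + beta * sx^2 * r) / v^1.5
}

#' Robust adjusted profile-score estimator
#'
#' Profile-likelihood estimation of the causal slope that accounts for
#' uncertainty in both the exposure and outcome effects (suitable for many
#' weak instruments), with optional systematic-pleiotropy overdispersion
#' and robust (Huber or Tukey) loss against idiosyncratic pleiotropy. The
#' slope solves the estimating equation
#' \eqn{\sum_j \psi(t_j) \, \partial t_j / \partial \beta = 0} with
#' standardized residuals
#' \eqn{t_j = (\hat\Gamma_j - \beta \hat\gamma_j) /
#'            \sqrt{se_{out,j}^2 + \beta^2 se_{exp,j}^2 + \tau^2}};
#' the overdispersion \eqn{\tau^2}, when enabled, solves
#' \eqn{\sum_j \psi(t_j) t_j = J \, \delta} with \eqn{\delta = E[\psi(Z)Z]}
#' under a standard normal. The standard error is sandwich-type. With L2
#' loss, no overdispersion, and vanishing exposure standard errors the
#' estimate reduces exactly to fixed-effect IVW.
#'
#' @param data [MrHarmonized-class] with >= 3 instruments and both
#'   exposure and outcome standard errors.
#' @param loss `"l2"` (default), `"huber"` or `"tukey"`.
#' @param overdispersion estimate a systematic-pleiotropy variance
#'   component (default FALSE).
#' @param k robustness tuning constant (defaults: Huber 1.345, Tukey 4.685).
#' @param level confidence level.
#' @return [MrEstimate-class] (details carry `tau2` and iteration count).
#' @export
mrRAPS <- function(data, loss = c("l2", "huber", "tukey"),
                   overdispersion = FALSE, k = NULL, level = 0.95) {
  loss <- match.arg(loss)
  if (is.null(k)) k <- switch(loss, l2 = Inf, huber = 1.345, tukey = 4.685)
  stopifnot(is(data, "MrHarmonized"))
  tab <- harmonizedTable(data)
  J <- nrow(tab)
  if (J < 3) stop("estimation error: MR-RAPS requires at least 3 instruments")
  bx <- tab$beta_exp; by <- tab$beta_out
  sx <- tab$se_exp; sy <- tab$se_out
  psi <- .rapsPsi(loss, k)
  delta <- .rapsDelta(loss, k)

  ivw_w <- (bx / sy)^2
  beta <- sum(ivw_w * (by / bx)) / sum(ivw_w)       # IVW init
  se0 <- 1 / sqrt(sum(ivw_w))
  tau2 <- 0

  S <- function(b, t2) sum(.rapsScore(b, t2, bx, by, sx, sy, psi))
  rho <- switch(loss,
    l2    = function(t) t^2 / 2,
    huber = function(t) ifelse(abs(t) <= k, t^2 / 2,
                               k * abs(t) - k^2 / 2),
    tukey = function(t) ifelse(abs(t) <= k,
                               (k^2 / 6) * (1 - (1 - (t / k)^2)^3),
                               k^2 / 6))
  obj <- function(b, t2) {
    v <- sy^2 + b^2 * sx^2 + t2
    sum(rho((by - b * bx) / sqrt(v)))
  }
  solveBeta <- function(b0, t2) {
    wdt <- max(20 * se0, 0.5)
    cand <- stats::optimize(obj, c(b0 - wdt, b0 + wdt), t2 = t2,
                            tol = 1e-10)$minimum
    # local polish: refine to a root of the profile score when one brackets
    for (eps in se0 * c(0.01, 0.1, 1, 10)) {
      lo <- cand - eps; hi <- cand + eps
      if (is.finite(S(lo, t2)) && is.finite(S(hi, t2)) &&
          sign(S(lo, t2)) != sign(S(hi, t2)))
        return(stats::uniroot(S, c(lo, hi), t2 = t2, tol = 1e-13)$root)
    }
    cand
  }
  solveTau2 <- function(b) {
    g <- function(t2) {
      v <- sy^2 + b^2 * sx^2 + t2
      t <- (by - b * bx) / sqrt(v)
      sum(psi(t) * t) - J * delta
    }
    if (g(0) <= 0) return(0)
    hi <- stats::var(by - b * bx) + 1
    for (tries in 1:20) {
      if (g(hi) < 0) break
      hi <- hi * 4
    }
    if (g(hi) >= 0) stop("estimation error: overdispersion did not converge")
    stats::uniroot(g, c(0, hi), tol = 1e-12)$root
  }

  iters <- 0L
  repeat {
    iters <- iters + 1L
    beta_new <- solveBeta(beta, tau2)
    tau2_new <- if (overdispersion) solveTau2(beta_new) else 0
    done <- abs(beta_new - beta) < 1e-12 && abs(tau2_new - tau2) < 1e-12
    beta <- beta_new; tau2 <- tau2_new
    if (done || iters >= 100L) break
  }
  if (iters >= 100L)
    warning("MR-RAPS alternation hit the iteration cap; estimate may be rough")

  # sandwich SE from score contributions
  g <- .rapsScore(beta, tau2, bx, by, sx, sy, psi)
  eps <- 1e-6 * max(1, abs(beta))
  A <- (S(beta + eps, tau2) - S(beta - eps, tau2)) / (2 * eps)
  se <- sqrt(sum(g^2)) / abs(A)
  .MrEstimate("MR-RAPS", beta, se, J, level,
              details = list(loss = loss, k = k, tau2 = tau2,
                             overdispersion = overdispersion,
                             iterations = iters))
}

#' Heterogeneity statistics about the IVW and Egger fits
#'
#' Cochran's Q is the weighted squared deviation of the Wald ratios about
#' the IVW estimate (df = J - 1); Ruecker's Q is the weighted residual sum
#' of squares about the MR-Egger fit (df = J - 2). Ruecker's Q never
#' exceeds Cochran's Q, since the intercept absorbs heterogeneity. P-values
#' from the chi-squared reference.
#'
#' @param data [MrHarmonized-class] (Cochran needs >= 2, Ruecker >= 3
#'   instruments; insufficient counts are marked not-computable with NA).
#' @return list with elements `cochran` and `rucker`, each `(Q, df, p)`.
#' @export
mrHeterogeneity <- function(data) {
  wr <- waldRatios(data)
  J <- nrow(wr)
  coch <- list(Q = NA_real_, df = NA_integer_, p = NA_real_)
  ruck <- list(Q = NA_real_, df = NA_integer_, p = NA_real_)
  if (J >= 2) {
    beta <- sum(wr$w * wr$ratio) / sum(wr$w)
    Q <- sum(wr$w * (wr$ratio - beta)^2)
    coch <- list(Q = Q, df = J - 1L,
                 p = stats::pchisq(Q, J - 1, lower.tail = FALSE))
  }
  if (J >= 3) {
    tab <- harmonizedTable(data)
    tab <- tab[tab$beta_exp != 0, , drop = FALSE]
    s <- ifelse(tab$beta_exp < 0, -1, 1)
    x <- s * tab$beta_exp; y <- s * tab$beta_out
    w <- 1 / tab$se_out^2
    fit <- stats::lm(y ~ x, weights = w)
    Qr <- sum(w * stats::residuals(fit)^2)
    ruck <- list(Q = Qr, df = J - 2L,
                 p = stats::pchisq(Qr, J - 2, lower.tail = FALSE))
  }
  list(cochran = coch, rucker = ruck)
}

#' Exponentiate a log-scale estimate to an odds ratio with CI
#'
#' @param beta log-scale effect; @param se its standard error (>= 0);
#' @param level confidence level in (0, 1).
#' @return list `(or, ciLow, ciHigh)` with
#'   `ci = exp(beta +/- z_(1+level)/2 * se)`.
#' @export
toOddsRatio <- function(beta, se, level = 0.95) {
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  list(or = exp(beta), ciLow = exp(beta - z * se), ciHigh = exp(beta + z * se))
}
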