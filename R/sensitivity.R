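#' MR-Egger intercept test for directional pleiotropy
#'
#' Two-sided test of the MR-Egger intercept against zero: an intercept
#' deviating from zero is evidence of directional pleiotropic bias.
#'
#' @param eggerFit [MrEstimate-class] from [mrEgger()] (must carry the
#'   intercept fields).
#' @param alpha significance level for the verdict (default 0.05).
#' @return list `(intercept, se, p, verdict)`; verdict is
#'   `"directional pleiotropy"` when p < alpha, `"no evidence"` otherwise.
#' @export
eggerInterceptTest <- function(eggerFit, alpha = 0.05) {
  stopifnot(is(eggerFit, "MrEstimate"))
  if (is.na(eggerFit@intercept) || is.na(eggerFit@interceptSE))
    stop("contract error: estimate carries no intercept (not an MR-Egger fit?)")
  p <- eggerFit@interceptPval
  list(intercept = eggerFit@intercept, se = eggerFit@interceptSE, p = p,
       verdict = if (p < alpha) "directional pleiotropy" else "no evidence")
}

# leave-one-out IVW slopes (zero-intercept WLS, weights 1/se_out^2),
# vectorized: slope_{-j} = (Snum - x_j y_j w_j) / (Sden - x_j^2 w_j)
.looSlopes <- function(bx, by, w) {
  num <- bx * by * w; den <- bx^2 * w
  (sum(num) - num) / (sum(den) - den)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed statistic is the weighted residual sum of
#' squares \eqn{\sum_j w_j (\hat\Gamma_j - \hat\beta^{(-j)} \hat\gamma_j)^2}
#' with \eqn{\hat\beta^{(-j)}} the leave-one-out IVW slope and
#' `w = 1/se_out^2`; its null distribution comes from `nSim` parametric
#' simulations of the outcome effects under the fitted no-pleiotropy model
#' (`beta_out_j* ~ Normal(beta^(-j) beta_exp_j, se_out_j)`), with add-one
#' smoothing `p = (1 + #\{sim >= obs\}) / (nSim + 1)`. Per-variant outlier
#' p-values compare each variant's observed residual with its own simulated
#' distribution, Bonferroni-corrected across variants; outliers are only
#' reported when the global test is significant. The distortion test
#' compares the slope change after outlier removal against the null of
#' removing equally many variants at random.
#'
#' @param data [MrHarmonized-class] with >= 4 instruments.
#' @param nSim simulation count (>= 100; default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed (mandatory; result is bit-reproducible).
#' @return [MrPresso-class]; with too few instruments, a result marked
#'   not-computable (`globalP = NA`).
#' @export
mrPresso <- function(data, nSim = 1000, alpha = 0.05, seed) {
  stopifnot(is(data, "MrHarmonized"), nSim >= 100)
  tab <- harmonizedTable(data)
  tab <- tab[tab$beta_exp != 0, , drop = FALSE]
  J <- nrow(tab)
  if (J < 4) {
    warning("MR-PRESSO requires at least 4 instruments; marked not-computable")
    return(new("MrPresso", globalRSS = NA_real_, globalP = NA_real_,
               outliers = data.frame(snp_id = character(), pval = numeric(),
                                     pval_bonferroni = numeric()),
               distortionP = NA_real_, corrected = NULL,
               nSim = as.integer(nSim), seed = as.integer(seed),
               alpha = alpha))
  }
  bx <- tab$beta_exp; by <- tab$beta_out; sy <- tab$se_out
  w <- 1 / sy^2
  loo <- .looSlopes(bx, by, w)
  obs_res <- w * (by - loo * bx)^2
  obs_rss <- sum(obs_res)

  withr::with_seed(seed, {
    # nSim x J simulated outcome effects under the leave-one-out fits
    sim_by <- matrix(stats::rnorm(nSim * J, mean = rep(loo * bx, each = nSim),
                                  sd = rep(sy, each = nSim)), nSim, J)
    sim_res <- matrix(0, nSim, J)
    for (s in seq_len(nSim)) {
      loo_s <- .looSlopes(bx, sim_by[s, ], w)
      sim_res[s, ] <- w * (sim_by[s, ] - loo_s * bx)^2
    }
    sim_rss <- rowSums(sim_res)
    global_p <- (1 + sum(sim_rss >= obs_rss)) / (nSim + 1)

    p_snp <- (1 + colSums(sim_res >= rep(obs_res, each = nSim))) / (nSim + 1)
    p_adj <- pmin(1, p_snp * J)
    flag <- global_p < alpha & p_adj < alpha
    outliers <- data.frame(snp_id = tab$snp_id[flag], pval = p_snp[flag],
                           pval_bonferroni = p_adj[flag],
                           stringsAsFactors = FALSE)

    distortion_p <- NA_real_; corrected <- NULL
    if (nrow(outliers)) {
      ivw_all <- sum(w * bx * by) / sum(w * bx^2)
      keep <- !flag
      if (sum(keep) >= 2) {
        ivw_cor <- sum((w * bx * by)[keep]) / sum((w * bx^2)[keep])
        d_obs <- ivw_cor - ivw_all
        n_out <- sum(flag)
        d_null <- vapply(seq_len(nSim), function(s) {
          drop_s <- sample.int(J, n_out)
          ivw_s <- sum((w * bx * by)[-drop_s]) / sum((w * bx^2)[-drop_s])
          ivw_s - ivw_all
        }, numeric(1))
        distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (nSim + 1)
        corrected <- mrIVW(.MrHarmonized(data@exposureName, data@outcomeName,
                                         tab[keep, , drop = FALSE]))
      }
    }
  })
  new("MrPresso", globalRSS = obs_rss, globalP = global_p,
      outliers = outliers, distortionP = distortion_p, corrected = corrected,
      nSim = as.integer(nSim), seed = as.integer(seed), alpha = alpha)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator J times, each omitting one instrument, to check
#' whether a single variant drives or biases the estimate. A variant is
#' flagged influential when its omission moves the IVW p-value across the
#' study significance threshold (in either direction).
#'
#' @param data [MrHarmonized-class] with >= 3 instruments.
#' @param pThreshold study significance threshold (e.g. the family-wise
#'   Bonferroni threshold; default 0.05).
#' @param model IVW model passed to [mrIVW()].
#' @return data.frame, one row per left-out variant (`snp_id`, `beta`,
#'   `se`, `pval`, `influential`); the full-sample fit is attached as the
#'   `"full"` attribute.
#' @export
leaveOneOut <- function(data, pThreshold = 0.05, model = "random") {
  stopifnot(is(data, "MrHarmonized"))
  tab <- harmonizedTable(data)
  if (nrow(tab) < 3)
    stop("estimation error: leave-one-out requires at least 3 instruments")
  full <- mrIVW(data, model = model)
  sig_full <- mrPval(full) < pThreshold
  rows <- lapply(seq_len(nrow(tab)), function(j) {
    hj <- .MrHarmonized(data@exposureName, data@outcomeName,
                        tab[-j, , drop = FALSE])
    fit <- mrIVW(hj, model = model)
    data.frame(snp_id = tab$snp_id[j], beta = mrBeta(fit), se = mrSE(fit),
               pval = mrPval(fit),
               influential = (mrPval(fit) < pThreshold) != sig_full,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "full") <- full
  res
}

#' Exclude instruments associated with known confounders
#'
#' Removes any instrument showing association with a measured risk factor
#' below the Bonferroni-corrected threshold
#' `0.05 / (number of instruments x number of risk factors)`. Instruments
#' missing from the association table are treated as non-associated.
#'
#' @param ivIds character vector of instrument ids.
#' @param confounderAssoc data.frame (`snp_id`, `risk_factor`, `pval`) of
#'   per-instrument confounder associations; may be empty.
#' @param nRiskFactors number of risk factors screened (>= 1).
#' @param alpha family-wise level before correction (default 0.05).
#' @return character vector of retained ids; removed ids and the threshold
#'   are attached as attributes `"removed"` and `"threshold"`.
#' @export
confounderFilter <- function(ivIds, confounderAssoc, nRiskFactors,
                             alpha = 0.05) {
  if (nRiskFactors < 1) stop("domain error: nRiskFactors must be >= 1")
  thr <- alpha / (length(ivIds) * nRiskFactors)
  if (is.null(confounderAssoc) || nrow(confounderAssoc) == 0) {
    warning("empty confounder association table; instrument set unchanged")
    out <- ivIds
    attr(out, "removed") <- character(); attr(out, "threshold") <- thr
    return(out)
  }
  ca <- confounderAssoc[confounderAssoc$snp_id %in% ivIds, , drop = FALSE]
  miss <- setdiff(ivIds, unique(ca$snp_id))
  if (length(miss))
    message(length(miss), " instrument(s) missing from the association ",
            "table; treated as non-associated")
  hit <- unique(ca$snp_id[!is.na(ca$pval) & ca$pval < thr])
  out <- setdiff(ivIds, hit)
  attr(out, "removed") <- hit
  attr(out, "threshold") <- thr
  out
}
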