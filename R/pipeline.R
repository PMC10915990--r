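#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param nTests number of tests in the family (>= 1).
#' @return `alpha / nTests` (e.g. 0.05 / 13 = 3.85e-3 for a study family of
#'   13 MR tests).
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  if (nTests < 1) stop("domain error: nTests must be >= 1")
  alpha / nTests
}

#' Analysis configuration for the MR pipeline
#'
#' All stage thresholds with their conventional defaults, the family size
#' for multiple-testing control, and the master seed. Per-stage seeds are
#' derived deterministically from the master seed and a fixed stage index
#' (`(master + 104729 * index) mod (2^31 - 1)`), so adding a stage never
#' silently re-seeds earlier stages.
#'
#' @param pThreshold instrument significance threshold (default 5e-8).
#' @param clumpR2 LD clumping r-squared threshold (default 0.001).
#' @param clumpWindowKb clumping window in kb (default 10000).
#' @param proxyR2 minimum proxy r-squared (default 0.8).
#' @param radialAlpha radial outlier-removal level (default 0.05).
#' @param palindromeWindow ambiguity window for palindromic variants.
#' @param ivwModel `"random"` or `"fixed"`.
#' @param nBoot bootstrap replicates for median/mode (default 1000).
#' @param pressoNSim MR-PRESSO simulation count (default 1000).
#' @param sensitivityAlpha level for heterogeneity / intercept / PRESSO
#'   verdicts (default 0.05).
#' @param alpha family-wise level; @param nTests declared family size for
#'   the Bonferroni threshold (user declaration wins over auto-counting).
#' @param level confidence level for intervals.
#' @param seed master integer seed.
#' @return list of class `"MrConfig"`.
#' @export
mrConfig <- function(pThreshold = 5e-8, clumpR2 = 0.001,
                     clumpWindowKb = 10000, proxyR2 = 0.8,
                     radialAlpha = 0.05, palindromeWindow = c(0.42, 0.58),
                     ivwModel = "random", nBoot = 1000, pressoNSim = 1000,
                     sensitivityAlpha = 0.05, alpha = 0.05, nTests = 1,
                     level = 0.95, seed = 1) {
  structure(list(pThreshold = pThreshold, clumpR2 = clumpR2,
                 clumpWindowKb = clumpWindowKb, proxyR2 = proxyR2,
                 radialAlpha = radialAlpha,
                 palindromeWindow = palindromeWindow, ivwModel = ivwModel,
                 nBoot = nBoot, pressoNSim = pressoNSim,
                 sensitivityAlpha = sensitivityAlpha, alpha = alpha,
                 nTests = nTests, level = level, seed = as.integer(seed)),
            class = "MrConfig")
}

# fixed master-seed -> stage-seed derivation (stays inside 32-bit range)
.stageSeed <- function(master, stageIndex) {
  as.integer((as.numeric(master) %% 2147483647 + 104729 * stageIndex) %%
               2147483647)
}

.STAGE_SEEDS <- c(median = 1L, mode = 2L, presso = 3L)

#' Run the full MR stage chain for one exposure/outcome pair
#'
#' Executes: significance selection, LD clumping, proxy substitution (when
#' an LD matrix is supplied), allele harmonization, palindromic handling,
#' radial outlier removal, Steiger filtering; then the five estimators
#' (IVW, MR-Egger, weighted median, weighted mode, MR-RAPS), heterogeneity
#' statistics, the Egger intercept test, MR-PRESSO and leave-one-out. Every
#' stage records its retained-instrument count, and every dropped variant
#' carries a stage and reason, so initial candidates = retained + dropped
#' (conservation).
#'
#' @param exposure,outcome [GwasSumstats-class] datasets.
#' @param ld optional [LdMatrix-class].
#' @param config [mrConfig()].
#' @return list of class `"MrResult"`: `estimable`, `estimates` (named list
#'   of [MrEstimate-class]), `heterogeneity`, `interceptTest`, `presso`,
#'   `loo`, `harmonized`, `stageCounts`, `fStatistics`, trait names and the
#'   config.
#' @export
runMr <- function(exposure, outcome, ld = NULL, config = mrConfig()) {
  stopifnot(is(exposure, "GwasSumstats"), is(outcome, "GwasSumstats"),
            inherits(config, "MrConfig"))
  stages <- list()
  note <- ""

  cand <- suppressWarnings(selectInstruments(exposure, config$pThreshold))
  stages[["select"]] <- length(cand)
  kept <- if (length(cand))
    ldClump(cand, exposure, ld, config$clumpR2, config$clumpWindowKb)
  else character()
  stages[["clump"]] <- length(kept)

  out_ids <- sumstatsTable(outcome)$snp_id
  missing <- setdiff(kept, out_ids)
  proxies <- NULL
  if (length(missing) && !is.null(ld))
    proxies <- findProxies(missing, ld, config$proxyR2, outcome)

  h <- harmonizeSumstats(exposure, outcome, kept, proxies)
  stages[["harmonize"]] <- nInstruments(h)
  h <- dropPalindromic(h, config$palindromeWindow)
  stages[["palindromic"]] <- nInstruments(h)
  h <- suppressWarnings(radialFilter(h, config$radialAlpha))
  stages[["radial"]] <- nInstruments(h)
  h <- suppressWarnings(steigerFilter(h))
  stages[["steiger"]] <- nInstruments(h)

  stageCounts <- data.frame(stage = names(stages),
                            n_retained = unlist(stages, use.names = FALSE),
                            stringsAsFactors = FALSE)
  J <- nInstruments(h)
  famThr <- bonferroniThreshold(config$alpha, config$nTests)
  res <- list(exposure = traitName(exposure), outcome = traitName(outcome),
              config = config, harmonized = h, stageCounts = stageCounts,
              estimable = J >= 2, estimates = list(),
              heterogeneity = NULL, interceptTest = NULL, presso = NULL,
              loo = NULL, fStatistics = numeric(), note = note)
  class(res) <- "MrResult"
  if (J < 2) {
    res$note <- "fewer than 2 instruments survived filtering; not estimable"
    return(res)
  }

  tab <- harmonizedTable(h)
  if (all(!is.na(tab$n_exp)))
    res$fStatistics <- fStatistic(
      varianceExplained(tab$beta_exp, tab$se_exp, tab$n_exp), tab$n_exp)

  ests <- list(IVW = mrIVW(h, model = config$ivwModel, level = config$level))
  if (J >= 3) {
    ests[["MR-RAPS"]] <- tryCatch(
      mrRAPS(h, level = config$level),
      error = function(e) NULL)
    ests[["MR-Egger"]] <- mrEgger(h, level = config$level)
    ests[["weighted-median"]] <- mrWeightedMedian(
      h, nBoot = config$nBoot,
      seed = .stageSeed(config$seed, .STAGE_SEEDS[["median"]]),
      level = config$level)
    ests[["weighted-mode"]] <- mrWeightedMode(
      h, nBoot = config$nBoot,
      seed = .stageSeed(config$seed, .STAGE_SEEDS[["mode"]]),
      level = config$level)
  }
  res$estimates <- Filter(Negate(is.null), ests)
  res$heterogeneity <- mrHeterogeneity(h)
  if (!is.null(ests[["MR-Egger"]]))
    res$interceptTest <- eggerInterceptTest(ests[["MR-Egger"]],
                                            config$sensitivityAlpha)
  if (J >= 4)
    res$presso <- mrPresso(h, nSim = config$pressoNSim,
                           alpha = config$sensitivityAlpha,
                           seed = .stageSeed(config$seed,
                                             .STAGE_SEEDS[["presso"]]))
  if (J >= 3)
    res$loo <- leaveOneOut(h, pThreshold = famThr, model = config$ivwModel)
  res
}

#' @export
print.MrResult <- function(x, ...) {
  cat("MrResult:", x$exposure, "->", x$outcome, "\n")
  print(x$stageCounts, row.names = FALSE)
  if (!x$estimable) { cat(" ", x$note, "\n"); return(invisible(x)) }
  for (e in x$estimates) show(e)
  invisible(x)
}

#' Bidirectional MR for a trait pair
#'
#' Runs the full stage chain in both directions (A as exposure of B, and B
#' as exposure of A). A direction where fewer than 2 instruments survive is
#' marked not-estimable without affecting the other direction. A self-pair
#' (identical trait names) is rejected.
#'
#' @param traitA,traitB [GwasSumstats-class] datasets.
#' @param ld optional [LdMatrix-class]; @param config [mrConfig()].
#' @return list `(forward, reverse)` of `"MrResult"`.
#' @export
runBidirectionalMr <- function(traitA, traitB, ld = NULL,
                               config = mrConfig()) {
  if (identical(traitName(traitA), traitName(traitB)))
    stop("configuration error: bidirectional MR of a trait with itself")
  list(forward = runMr(traitA, traitB, ld, config),
       reverse = runMr(traitB, traitA, ld, config))
}

#' Two-step MR mediation analysis
#'
#' Estimates the total effect (exposure to outcome), step 1 (exposure to
#' mediator) and step 2 (mediator to outcome), each through the full stage
#' chain; mediation (product of coefficients, delta-method SE, mediated
#' proportion) is computed only when the exposure-outcome and
#' exposure-mediator IVW effects pass the significance gate (the
#' family-wise Bonferroni threshold by default, or nominal 0.05 with
#' `gate = "nominal"`). On gate failure the result is explicitly marked
#' "not assessed" rather than silently omitted.
#'
#' @param exposure,mediator,outcome [GwasSumstats-class] datasets.
#' @param ld optional [LdMatrix-class]; @param config [mrConfig()].
#' @param gate `"family"` (default) or `"nominal"`.
#' @return list `(mediation, total, step1, step2)` where `mediation` is an
#'   [MrMediation-class] and the rest are `"MrResult"`.
#' @export
runMediationAnalysis <- function(exposure, mediator, outcome, ld = NULL,
                                 config = mrConfig(),
                                 gate = c("family", "nominal")) {
  gate <- match.arg(gate)
  total <- runMr(exposure, outcome, ld, config)
  step1 <- runMr(exposure, mediator, ld, config)
  step2 <- runMr(mediator, outcome, ld, config)
  thr <- if (gate == "family")
    bonferroniThreshold(config$alpha, config$nTests) else config$alpha
  ok <- total$estimable && step1$estimable && step2$estimable
  gatePass <- ok &&
    mrPval(total$estimates$IVW) < thr && mrPval(step1$estimates$IVW) < thr
  med <- if (gatePass) {
    .buildMediation(
      total = list(beta = mrBeta(total$estimates$IVW),
                   se = mrSE(total$estimates$IVW)),
      step1 = list(beta = mrBeta(step1$estimates$IVW),
                   se = mrSE(step1$estimates$IVW)),
      step2 = list(beta = mrBeta(step2$estimates$IVW),
                   se = mrSE(step2$estimates$IVW)),
      level = config$level)
  } else {
    why <- if (!ok) "a step was not estimable" else
      sprintf("significance gate failed at threshold %.3g", thr)
    .buildMediation(NULL, NULL, NULL, assessed = FALSE,
                    note = paste("mediation not assessed:", why))
  }
  list(mediation = med, total = total, step1 = step1, step2 = step2)
}

# one tidy row per method per pair
.estimateRows <- function(res) {
  if (!res$estimable || !length(res$estimates))
    return(data.frame())
  do.call(rbind, lapply(res$estimates, function(e) data.frame(
    exposure = res$exposure, outcome = res$outcome, method = e@method,
    n_snp = e@nSnp, beta = e@beta, se = e@se, pval = e@pval,
    or_value = e@orValue, ci_low = e@ciLow, ci_high = e@ciHigh,
    intercept = e@intercept, intercept_se = e@interceptSE,
    intercept_pval = e@interceptPval, stringsAsFactors = FALSE)))
}

.resultJson <- function(res) {
  out <- list(exposure = res$exposure, outcome = res$outcome,
              estimable = res$estimable,
              stage_counts = res$stageCounts,
              dropped = droppedLedger(res$harmonized))
  if (res$estimable) {
    out$estimates <- lapply(res$estimates, function(e) list(
      method = e@method, n_snp = e@nSnp, beta = e@beta, se = e@se,
      pval = e@pval, or_value = e@orValue, ci_low = e@ciLow,
      ci_high = e@ciHigh))
    out$heterogeneity <- res$heterogeneity
    if (!is.null(res$interceptTest)) out$egger_intercept <- res$interceptTest
    if (!is.null(res$presso))
      out$mr_presso <- list(global_rss = res$presso@globalRSS,
                            global_p = res$presso@globalP,
                            outliers = res$presso@outliers$snp_id,
                            distortion_p = res$presso@distortionP,
                            n_sim = res$presso@nSim)
    if (length(res$fStatistics))
      out$f_statistics <- list(min = min(res$fStatistics),
                               median = stats::median(res$fStatistics))
  } else out$note <- res$note
  out
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Write the analysis report
#'
#' Emits, into `dir`: `estimates.tsv` (one tidy row per method per
#' exposure-outcome pair), `report.json` (config with seeds, per-pair stage
#' counts and dropped ledgers, estimates, sensitivity results, mediation),
#' and plot-data tables `scatter.tsv` (per-variant exposure/outcome effects
#' with per-method fit lines), `leave_one_out.tsv` and `funnel.tsv` (Wald
#' ratio against precision). No timestamps are written, so re-running on
#' the same inputs and seeds reproduces byte-identical files.
#'
#' @param results list of `"MrResult"` objects (as returned by [runMr()] /
#'   [runBidirectionalMr()]), optionally with a `mediation` element from
#'   [runMediationAnalysis()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(results, dir) {
  if (inherits(results, "MrResult")) results <- list(results)
  mediation <- NULL
  if (!is.null(results$mediation) && is(results$mediation, "MrMediation")) {
    mediation <- results$mediation
    results <- Filter(function(x) inherits(x, "MrResult"), results)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mrres <- Filter(function(x) inherits(x, "MrResult"), results)

  est <- do.call(rbind, c(lapply(mrres, .estimateRows),
                          list(data.frame())))
  if (is.null(est) || !nrow(est))
    est <- data.frame(exposure = character(), outcome = character(),
                      method = character(), n_snp = integer(),
                      beta = numeric(), se = numeric(), pval = numeric(),
                      or_value = numeric(), ci_low = numeric(),
                      ci_high = numeric(), intercept = numeric(),
                      intercept_se = numeric(), intercept_pval = numeric())
  estPath <- file.path(dir, "estimates.tsv")
  .writeTsv(est, estPath)

  scatter <- do.call(rbind, c(lapply(mrres, function(r) {
    if (!r$estimable) return(NULL)
    tab <- harmonizedTable(r$harmonized)
    data.frame(exposure = r$exposure, outcome = r$outcome,
               snp_id = tab$snp_id, beta_exp = tab$beta_exp,
               se_exp = tab$se_exp, beta_out = tab$beta_out,
               se_out = tab$se_out, stringsAsFactors = FALSE)
  }), list(NULL)))
  if (is.null(scatter))
    scatter <- data.frame(exposure = character(), outcome = character(),
                          snp_id = character(), beta_exp = numeric(),
                          se_exp = numeric(), beta_out = numeric(),
                          se_out = numeric())
  .writeTsv(scatter, file.path(dir, "scatter.tsv"))

  funnel <- do.call(rbind, c(lapply(mrres, function(r) {
    if (!r$estimable) return(NULL)
    wr <- suppressWarnings(waldRatios(r$harmonized))
    data.frame(exposure = r$exposure, outcome = r$outcome,
               snp_id = wr$snp_id, ratio = wr$ratio,
               precision = 1 / wr$se, stringsAsFactors = FALSE)
  }), list(NULL)))
  if (is.null(funnel))
    funnel <- data.frame(exposure = character(), outcome = character(),
                         snp_id = character(), ratio = numeric(),
                         precision = numeric())
  .writeTsv(funnel, file.path(dir, "funnel.tsv"))

  loo <- do.call(rbind, c(lapply(mrres, function(r) {
    if (is.null(r$loo)) return(NULL)
    cbind(data.frame(exposure = r$exposure, outcome = r$outcome,
                     stringsAsFactors = FALSE), r$loo)
  }), list(NULL)))
  if (is.null(loo))
    loo <- data.frame(exposure = character(), outcome = character(),
                      snp_id = character(), beta = numeric(), se = numeric(),
                      pval = numeric(), influential = logical())
  .writeTsv(loo, file.path(dir, "leave_one_out.tsv"))

  cfg <- if (length(mrres)) unclass(mrres[[1]]$config) else NULL
  report <- list(
    package_version = as.character(utils::packageVersion("mrpath")),
    config = cfg,
    pairs = lapply(mrres, .resultJson))
  if (!is.null(mediation) && mediation@assessed)
    report$mediation <- list(
      assessed = TRUE,
      acme = mediation@indirectBeta, acme_se = mediation@indirectSE,
      acme_p = mediation@indirectPval,
      acme_ci = c(mediation@indirectCiLow, mediation@indirectCiHigh),
      total = mediation@totalBeta, total_se = mediation@totalSE,
      direct = mediation@directBeta,
      proportion_mediated = mediation@proportion,
      proportion_ci = c(mediation@proportionCiLow,
                        mediation@proportionCiHigh),
      reliable = mediation@reliable)
  else if (!is.null(mediation))
    report$mediation <- list(assessed = FALSE, note = mediation@note)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(c(estPath, file.path(dir, c("scatter.tsv", "funnel.tsv",
                                        "leave_one_out.tsv", "report.json"))))
}
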