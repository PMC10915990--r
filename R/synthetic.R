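#' Configuration for the synthetic two-sample GWAS generator
#'
#' Bundles and validates the generative parameters for
#' [simulateGwasPair()], [simulateMediationTriplet()] and
#' [simulateLdMatrix()]. Defaults emulate the scale of well-powered
#' behavioural/psychiatric GWAS: an exposure GWAS of 300,000, an outcome
#' GWAS of 130,000, 100 independent instruments jointly explaining 1
#' percent of the exposure variance (per-instrument expected F around 30,
#' comfortably past the F > 10 weak-instrument screen), and allele
#' frequencies uniform on (0.05, 0.5).
#'
#' @param nSnps instruments per trait.
#' @param mafRange interval in (0, 1) from which allele frequencies are
#'   drawn uniformly.
#' @param nExp,nOut,nMed GWAS sample sizes (constant per trait).
#' @param trueSlope causal effect of exposure on outcome (log scale).
#' @param exposureH2 total exposure variance explained by the instruments.
#' @param mediatorH2 variance of the mediator explained by its own
#'   instrument set in the mediation chain (defaults to `exposureH2`).
#' @param pleiotropy list with `type` in `"none"`, `"balanced"` (field
#'   `sd`), `"directional"` (`mean`, `sd`) or `"inside_violating"`
#'   (`correlation`, `sd`): the direct (pleiotropic) variant effect regime.
#' @param invalidFraction proportion of instruments carrying pleiotropy.
#' @param mediation optional list `(a, b, cprime)`: exposure-to-mediator,
#'   mediator-to-outcome and direct exposure-to-outcome effects for the
#'   mediation chain.
#' @param ldBlocks optional list `(sizes, r2)` for block-diagonal LD.
#' @param seed mandatory integer RNG seed.
#' @return validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nSnps = 100, mafRange = c(0.05, 0.5),
                      nExp = 300000, nOut = 130000, nMed = 85000,
                      trueSlope = 0, exposureH2 = 0.01, mediatorH2 = NULL,
                      pleiotropy = list(type = "none"),
                      invalidFraction = 0, mediation = NULL,
                      ldBlocks = NULL, seed) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  stopifnot(nSnps >= 1, length(mafRange) == 2,
            mafRange[1] > 0, mafRange[2] < 1, mafRange[1] <= mafRange[2],
            nExp >= 1, nOut >= 1, nMed >= 1,
            exposureH2 > 0, exposureH2 < 1,
            is.null(mediatorH2) || (mediatorH2 > 0 && mediatorH2 < 1),
            invalidFraction >= 0, invalidFraction <= 1)
  stopifnot(pleiotropy$type %in%
              c("none", "balanced", "directional", "inside_violating"))
  if (!is.null(mediation))
    stopifnot(all(c("a", "b", "cprime") %in% names(mediation)))
  if (!is.null(ldBlocks))
    stopifnot(all(c("sizes", "r2") %in% names(ldBlocks)))
  structure(list(nSnps = as.integer(nSnps), mafRange = mafRange,
                 nExp = nExp, nOut = nOut, nMed = nMed,
                 trueSlope = trueSlope, exposureH2 = exposureH2,
                 mediatorH2 = if (is.null(mediatorH2)) exposureH2 else mediatorH2,
                 pleiotropy = pleiotropy, invalidFraction = invalidFraction,
                 mediation = mediation, ldBlocks = ldBlocks,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# non-palindromic allele pairs only, so harmonization is exercised without
# strand ambiguity unless a test constructs palindromic variants on purpose
.ALLELE_PAIRS <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                      c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))

.simPositions <- function(n, ldBlocks = NULL) {
  if (is.null(ldBlocks)) {
    chrom <- rep(as.character(1:22), length.out = n)
    pos <- unlist(lapply(table(factor(chrom, levels = as.character(1:22))),
                         function(k) if (k) seq_len(k) * 2e6 else numeric()))
    ord <- order(as.integer(chrom))
    return(list(chrom = chrom[ord], pos = unname(pos)[seq_len(n)]))
  }
  # blocks are contiguous runs on one chromosome, 100 kb apart within block
  sizes <- ldBlocks$sizes
  chrom <- character(); pos <- numeric()
  at <- 1e6
  for (bi in seq_along(sizes)) {
    chrom <- c(chrom, rep("1", sizes[bi]))
    pos <- c(pos, at + seq_len(sizes[bi]) * 1e5)
    at <- at + 5e7  # blocks far apart
  }
  extra <- n - length(pos)
  if (extra > 0) {
    chrom <- c(chrom, rep("2", extra))
    pos <- c(pos, seq_len(extra) * 2e6)
  }
  list(chrom = chrom[seq_len(n)], pos = pos[seq_len(n)])
}

.simPleiotropy <- function(config, beta_true) {
  n <- config$nSnps
  alpha <- numeric(n)
  n_inv <- round(config$invalidFraction * n)
  pl <- config$pleiotropy
  if (pl$type == "none" || n_inv == 0) {
    return(list(alpha = alpha, valid = rep(TRUE, n)))
  }
  inv <- seq_len(n_inv)  # deterministic positions; effects are random
  alpha[inv] <- switch(pl$type,
    balanced = stats::rnorm(n_inv, 0, pl$sd),
    directional = stats::rnorm(n_inv, pl$mean, pl$sd),
    inside_violating = pl$correlation * beta_true[inv] +
      stats::rnorm(n_inv, 0, pl$sd))
  list(alpha = alpha, valid = alpha == 0)
}

.mkDataset <- function(ids, chrom, pos, ea, oa, f, beta_true, se, n,
                       traitName, traitType) {
  beta_obs <- beta_true + stats::rnorm(length(ids), 0, se)
  GwasSumstats(data.frame(
    snp_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = f,
    beta = beta_obs, se = se, pval = .normP(beta_obs / se), n = n,
    stringsAsFactors = FALSE), traitName, traitType)
}

#' Simulate a two-sample exposure/outcome GWAS pair with known truth
#'
#' Generative model: allele frequencies `f_j ~ U(mafRange)`; true exposure
#' effects drawn standard normal and rescaled so
#' \eqn{\sum_j 2 f_j (1-f_j) \beta_j^2 = exposureH2}; true outcome effects
#' `trueSlope * beta_exp_j + pleiotropy_j` (directional pleiotropy is
#' applied relative to the exposure-increasing allele, the coding the
#' Egger intercept estimates); per-variant standard errors
#' `1/sqrt(2 f (1-f) n)` per the standardization model; observed effects =
#' truth plus `Normal(0, se)` noise, with p-values computed from the
#' observed Z so emitted statistics always satisfy the dataset validator.
#' The two samples are independent (no overlap modelling) and binary-trait
#' outcomes are emulated directly on the log-odds scale.
#'
#' @param config a [simConfig()] object (the seed makes the draw
#'   deterministic).
#' @return list `(exposure, outcome, truth)`: two [GwasSumstats-class]
#'   datasets and a truth data.frame (`snp_id`, `beta_exp_true`,
#'   `pleiotropy`, `valid`) with the scenario slope as attribute
#'   `"trueSlope"`.
#' @export
simulateGwasPair <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(config$seed, {
    n <- config$nSnps
    ids <- paste0("rs", seq_len(n))
    loc <- .simPositions(n, config$ldBlocks)
    pair_idx <- sample.int(length(.ALLELE_PAIRS), n, replace = TRUE)
    ea <- vapply(.ALLELE_PAIRS[pair_idx], `[`, character(1), 1)
    oa <- vapply(.ALLELE_PAIRS[pair_idx], `[`, character(1), 2)
    f <- stats::runif(n, config$mafRange[1], config$mafRange[2])
    raw <- stats::rnorm(n)
    het <- 2 * f * (1 - f)
    beta_true <- raw * sqrt(config$exposureH2 / sum(het * raw^2))
    pl <- .simPleiotropy(config, beta_true)
    # directional pleiotropy is directional with respect to the
    # exposure-increasing allele (the coding MR-Egger orients to)
    alpha_eff <- if (config$pleiotropy$type == "directional")
      sign(beta_true) * pl$alpha else pl$alpha
    out_true <- config$trueSlope * beta_true + alpha_eff
    se_exp <- 1 / sqrt(het * config$nExp)
    se_out <- 1 / sqrt(het * config$nOut)
    exposure <- .mkDataset(ids, loc$chrom, loc$pos, ea, oa, f, beta_true,
                           se_exp, config$nExp, "sim_exposure", "continuous")
    outcome <- .mkDataset(ids, loc$chrom, loc$pos, ea, oa, f, out_true,
                          se_out, config$nOut, "sim_outcome", "binary")
    truth <- data.frame(snp_id = ids, beta_exp_true = beta_true,
                        pleiotropy = pl$alpha, valid = pl$valid,
                        stringsAsFactors = FALSE)
    attr(truth, "trueSlope") <- config$trueSlope
  })
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate an exposure/mediator/outcome summary-statistics triplet
#'
#' Builds the chain X -> M -> Y at summary level with distinct instrument
#' sets for the exposure and the mediator: `nSnps` instruments act on X
#' (affecting M with slope `a` and Y with slope `cprime + a*b`), and
#' `nSnps` further instruments act on M (affecting Y with slope `b`, and X
#' not at all). All three emitted datasets contain all `2 * nSnps`
#' variants, so instrument selection happens exactly as on real data. The
#' true indirect effect `a*b` and total effect `cprime + a*b` are recorded
#' in the truth table's attributes.
#'
#' @param config a [simConfig()] with the `mediation` field set.
#' @return list `(exposure, mediator, outcome, truth)`.
#' @export
simulateMediationTriplet <- function(config) {
  stopifnot(inherits(config, "SimConfig"), !is.null(config$mediation))
  a <- config$mediation$a; b <- config$mediation$b
  cp <- config$mediation$cprime
  withr::with_seed(config$seed, {
    n <- config$nSnps
    n2 <- 2L * n
    ids <- paste0("rs", seq_len(n2))
    loc <- .simPositions(n2, NULL)
    pair_idx <- sample.int(length(.ALLELE_PAIRS), n2, replace = TRUE)
    ea <- vapply(.ALLELE_PAIRS[pair_idx], `[`, character(1), 1)
    oa <- vapply(.ALLELE_PAIRS[pair_idx], `[`, character(1), 2)
    f <- stats::runif(n2, config$mafRange[1], config$mafRange[2])
    het <- 2 * f * (1 - f)
    is_x <- seq_len(n2) <= n
    raw <- stats::rnorm(n2)
    beta <- numeric(n2)
    beta[is_x] <- raw[is_x] *
      sqrt(config$exposureH2 / sum(het[is_x] * raw[is_x]^2))
    beta[!is_x] <- raw[!is_x] *
      sqrt(config$mediatorH2 / sum(het[!is_x] * raw[!is_x]^2))
    x_eff <- ifelse(is_x, beta, 0)                      # effect on X
    m_eff <- ifelse(is_x, a * beta, beta)               # effect on M
    y_eff <- ifelse(is_x, (cp + a * b) * beta, b * beta)  # effect on Y
    se_x <- 1 / sqrt(het * config$nExp)
    se_m <- 1 / sqrt(het * config$nMed)
    se_y <- 1 / sqrt(het * config$nOut)
    exposure <- .mkDataset(ids, loc$chrom, loc$pos, ea, oa, f, x_eff, se_x,
                           config$nExp, "sim_exposure", "continuous")
    mediator <- .mkDataset(ids, loc$chrom, loc$pos, ea, oa, f, m_eff, se_m,
                           config$nMed, "sim_mediator", "binary")
    outcome <- .mkDataset(ids, loc$chrom, loc$pos, ea, oa, f, y_eff, se_y,
                          config$nOut, "sim_outcome", "binary")
    truth <- data.frame(snp_id = ids, instrument_for = ifelse(is_x, "X", "M"),
                        beta_x = x_eff, beta_m = m_eff, beta_y = y_eff,
                        stringsAsFactors = FALSE)
    attr(truth, "a") <- a; attr(truth, "b") <- b; attr(truth, "cprime") <- cp
    attr(truth, "indirect") <- a * b
    attr(truth, "total") <- cp + a * b
  })
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate a block-diagonal LD matrix
#'
#' Builds an [LdMatrix-class] whose leading variants (matching the ids
#' emitted by [simulateGwasPair()] under the same config) fall into blocks
#' with the configured within-block r-squared, zero between blocks, unit
#' diagonal, and an all-positive sign matrix.
#'
#' @param config a [simConfig()] with the `ldBlocks` field set.
#' @return [LdMatrix-class] covering `sum(ldBlocks$sizes)` variants.
#' @export
simulateLdMatrix <- function(config) {
  stopifnot(inherits(config, "SimConfig"), !is.null(config$ldBlocks))
  sizes <- config$ldBlocks$sizes
  r2v <- config$ldBlocks$r2
  if (length(r2v) == 1) r2v <- rep(r2v, length(sizes))
  m <- sum(sizes)
  ids <- paste0("rs", seq_len(m))
  r2 <- matrix(0, m, m, dimnames = list(ids, ids))
  at <- 0
  for (bi in seq_along(sizes)) {
    idx <- at + seq_len(sizes[bi])
    r2[idx, idx] <- r2v[bi]
    at <- at + sizes[bi]
  }
  diag(r2) <- 1
  sgn <- matrix(1, m, m, dimnames = list(ids, ids))
  LdMatrix(r2, sgn)
}
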