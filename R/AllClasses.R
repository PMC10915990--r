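#' @import methods
NULL

.SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

.HARMONIZED_COLS <- c("snp_id", "effect_allele", "other_allele",
                      "beta_exp", "se_exp", "beta_out", "se_out",
                      "eaf_exp", "eaf_out", "n_exp", "n_out",
                      "palindromic", "flipped", "proxy_of", "proxy_r2")

.emptyDropped <- function() {
  data.frame(snp_id = character(), stage = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' GwasSumstats: one trait's GWAS summary statistics
#'
#' Container for per-variant association summary statistics of a single
#' trait: variant identifier, position, alleles, effect-allele frequency,
#' effect size (log odds ratio for binary traits, trait SD units for
#' standardized continuous traits), its standard error, p-value and
#' per-variant sample size.
#'
#' @slot traitName character(1) trait label.
#' @slot traitType `"binary"` or `"continuous"`.
#' @slot ancestry free-text ancestry label (metadata only).
#' @slot records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'
#' @seealso [readSumstats()], [simulateGwasPair()]
#' @export
setClass("GwasSumstats",
         representation(traitName = "character",
                        traitType = "character",
                        ancestry  = "character",
                        records   = "data.frame"))

setValidity("GwasSumstats", function(object) {
  msg <- character()
  if (length(object@traitName) != 1L) msg <- c(msg, "traitName must be length 1")
  if (!object@traitType %in% c("binary", "continuous"))
    msg <- c(msg, "traitType must be 'binary' or 'continuous'")
  rec <- object@records
  miss <- setdiff(.SUMSTAT_COLS, names(rec))
  if (length(miss))
    msg <- c(msg, paste("records missing columns:", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(rec)) {
    if (anyDuplicated(rec$snp_id)) msg <- c(msg, "snp_id not unique")
    if (any(!is.na(rec$se) & rec$se <= 0)) msg <- c(msg, "se must be > 0")
    if (any(!is.na(rec$pval) & (rec$pval <= 0 | rec$pval > 1)))
      msg <- c(msg, "pval must lie in (0, 1]")
    if (any(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1)))
      msg <- c(msg, "eaf must lie strictly in (0, 1)")
    bad <- rec$effect_allele == rec$other_allele
    if (any(bad, na.rm = TRUE)) msg <- c(msg, "effect and other allele must differ")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GwasSumstats object
#'
#' Missing optional columns (`chrom`, `pos`, `eaf`, `n`) are filled with NA;
#' alleles are uppercased.
#'
#' @param records data.frame of per-variant statistics (see
#'   [GwasSumstats-class] for the column contract).
#' @param traitName trait label.
#' @param traitType `"binary"` or `"continuous"`.
#' @param ancestry ancestry label (metadata).
#' @return A [GwasSumstats-class] object.
#' @export
GwasSumstats <- function(records, traitName, traitType = "continuous",
                         ancestry = "EUR") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "eaf", "n"))
    if (is.null(records[[col]])) records[[col]] <- NA
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele  <- toupper(as.character(records$other_allele))
  records <- records[, .SUMSTAT_COLS, drop = FALSE]
  rownames(records) <- NULL
  new("GwasSumstats", traitName = traitName, traitType = traitType,
      ancestry = ancestry, records = records)
}

#' LdMatrix: pairwise linkage-disequilibrium matrix
#'
#' Symmetric matrix of squared correlations (r-squared) between variants,
#' with unit diagonal, optionally accompanied by a matrix of correlation
#' signs used to phase-align proxy alleles.
#'
#' @slot r2 symmetric numeric matrix in \[0, 1\], unit diagonal, dimnames =
#'   snp ids.
#' @slot sign numeric matrix of correlation signs (-1/+1, 0 = unknown); a
#'   0 x 0 matrix when no sign information is available.
#' @export
setClass("LdMatrix",
         representation(r2 = "matrix", sign = "matrix"))

setValidity("LdMatrix", function(object) {
  msg <- character()
  r2 <- object@r2
  if (nrow(r2) != ncol(r2)) msg <- c(msg, "r2 must be square")
  if (is.null(rownames(r2)) || !identical(rownames(r2), colnames(r2)))
    msg <- c(msg, "r2 must carry identical row/col snp-id dimnames")
  if (nrow(r2)) {
    if (max(abs(r2 - t(r2))) > 1e-8) msg <- c(msg, "r2 must be symmetric")
    if (max(abs(diag(r2) - 1)) > 1e-8) msg <- c(msg, "r2 diagonal must be 1")
    if (any(r2 < 0 | r2 > 1 + 1e-12)) msg <- c(msg, "r2 values must lie in [0, 1]")
  }
  if (nrow(object@sign) &&
      !identical(dim(object@sign), dim(r2)))
    msg <- c(msg, "sign matrix must match r2 dimensions")
  if (length(msg)) msg else TRUE
})

#' Construct an LdMatrix
#'
#' @param r2 square symmetric matrix of r-squared values with snp-id dimnames.
#' @param sign optional matrix of correlation signs for proxy allele
#'   alignment (same dimensions as `r2`).
#' @return An [LdMatrix-class] object.
#' @export
LdMatrix <- function(r2, sign = NULL) {
  r2 <- as.matrix(r2)
  if (is.null(sign)) sign <- matrix(numeric(), 0, 0)
  new("LdMatrix", r2 = r2, sign = as.matrix(sign))
}

#' MrHarmonized: allele-aligned exposure/outcome effect pairs
#'
#' The working unit of all MR estimation: one row per retained instrument
#' with exposure and outcome effects expressed for the same effect allele,
#' plus a dropped-variant ledger recording every variant removed at any
#' stage together with the stage and reason (conservation: every variant
#' entering harmonization appears either in the table or in the ledger).
#'
#' @slot exposureName,outcomeName trait labels.
#' @slot table data.frame, one row per retained instrument.
#' @slot dropped data.frame with columns `snp_id`, `stage`, `reason`.
#' @export
setClass("MrHarmonized",
         representation(exposureName = "character",
                        outcomeName  = "character",
                        table        = "data.frame",
                        dropped      = "data.frame"))

setValidity("MrHarmonized", function(object) {
  msg <- character()
  miss <- setdiff(.HARMONIZED_COLS, names(object@table))
  if (length(miss))
    msg <- c(msg, paste("table missing columns:", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(object@table)) {
    tab <- object@table
    if (any(tab$se_exp <= 0) || any(tab$se_out <= 0))
      msg <- c(msg, "standard errors must be > 0")
    if (anyDuplicated(tab$snp_id)) msg <- c(msg, "snp_id not unique")
  }
  if (!all(c("snp_id", "stage", "reason") %in% names(object@dropped)))
    msg <- c(msg, "dropped ledger needs snp_id/stage/reason columns")
  if (length(msg)) msg else TRUE
})

.MrHarmonized <- function(exposureName, outcomeName, table,
                          dropped = .emptyDropped()) {
  rownames(table) <- NULL
  rownames(dropped) <- NULL
  new("MrHarmonized", exposureName = exposureName, outcomeName = outcomeName,
      table = table, dropped = dropped)
}

#' MrEstimate: one method's causal estimate
#'
#' @slot method estimator tag (`"IVW"`, `"MR-Egger"`, `"weighted-median"`,
#'   `"weighted-mode"`, `"MR-RAPS"`).
#' @slot beta causal effect on the log scale; @slot se its standard error.
#' @slot pval two-sided p-value (normal reference).
#' @slot nSnp number of instruments used.
#' @slot orValue,ciLow,ciHigh exponentiated effect and confidence limits.
#' @slot level confidence level of the interval.
#' @slot intercept,interceptSE,interceptPval MR-Egger intercept terms
#'   (NA for other methods).
#' @slot details list of method-specific diagnostics (e.g. overdispersion).
#' @export
setClass("MrEstimate",
         representation(method = "character", beta = "numeric", se = "numeric",
                        pval = "numeric", nSnp = "integer",
                        orValue = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", level = "numeric",
                        intercept = "numeric", interceptSE = "numeric",
                        interceptPval = "numeric", details = "list"))

setValidity("MrEstimate", function(object) {
  msg <- character()
  if (!is.na(object@pval) && (object@pval <= 0 || object@pval > 1))
    msg <- c(msg, "pval must lie in (0, 1]")
  if (!is.na(object@orValue) &&
      abs(object@orValue - exp(object@beta)) > 1e-8 * max(1, object@orValue))
    msg <- c(msg, "orValue must equal exp(beta)")
  if (!is.na(object@se) && object@se > 0 &&
      !(object@ciLow <= object@orValue && object@orValue <= object@ciHigh))
    msg <- c(msg, "confidence interval must bracket the odds ratio")
  if (length(msg)) msg else TRUE
})

# two-sided normal p with a positive floor so p stays in (0, 1]
.normP <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

.MrEstimate <- function(method, beta, se, nSnp, level = 0.95,
                        intercept = NA_real_, interceptSE = NA_real_,
                        details = list()) {
  pv <- if (se > 0) .normP(beta / se) else as.numeric(beta == 0)
  if (pv == 0) pv <- .Machine$double.xmin
  ci <- toOddsRatio(beta, se, level)
  ipv <- if (is.na(intercept) || is.na(interceptSE)) NA_real_
  else if (interceptSE > 0) .normP(intercept / interceptSE)
  else if (intercept == 0) 1 else .Machine$double.xmin
  new("MrEstimate", method = method, beta = beta, se = se, pval = pv,
      nSnp = as.integer(nSnp), orValue = ci$or, ciLow = ci$ciLow,
      ciHigh = ci$ciHigh, level = level, intercept = intercept,
      interceptSE = interceptSE, interceptPval = ipv, details = details)
}

#' MrPresso: MR-PRESSO global, outlier and distortion test result
#'
#' @slot globalRSS observed weighted residual sum of squares.
#' @slot globalP simulation p-value of the global pleiotropy test.
#' @slot outliers data.frame (`snp_id`, `pval`, `pval_bonferroni`) of
#'   flagged variants (empty when the global test is not significant).
#' @slot distortionP p-value of the distortion test (NA when no outliers).
#' @slot corrected IVW estimate after outlier removal (NULL when none).
#' @slot nSim simulation count; @slot seed RNG seed; @slot alpha level.
#' @export
setClass("MrPresso",
         representation(globalRSS = "numeric", globalP = "numeric",
                        outliers = "data.frame", distortionP = "numeric",
                        corrected = "ANY", nSim = "integer", seed = "integer",
                        alpha = "numeric"))

setValidity("MrPresso", function(object) {
  msg <- character()
  if (is.na(object@globalP)) return(TRUE)  # marked not-computable
  lo <- 1 / (object@nSim + 1)
  if (object@globalP < lo - 1e-12 || object@globalP > 1)
    msg <- c(msg, "globalP must lie in [1/(nSim+1), 1]")
  if (object@globalP >= object@alpha && nrow(object@outliers))
    msg <- c(msg, "outlier set must be empty when the global test is not significant")
  if (length(msg)) msg else TRUE
})

#' MrMediation: two-step MR mediation result
#'
#' Product-of-coefficients indirect effect with first-order delta-method
#' standard error, the direct effect as total minus indirect, and the
#' mediated proportion on the log-effect scale.
#'
#' @slot totalBeta,totalSE total effect (exposure to outcome).
#' @slot step1Beta,step1SE exposure-to-mediator effect.
#' @slot step2Beta,step2SE mediator-to-outcome effect.
#' @slot indirectBeta,indirectSE,indirectPval,indirectCiLow,indirectCiHigh
#'   indirect (mediated) effect.
#' @slot directBeta total minus indirect.
#' @slot proportion,proportionSE,proportionCiLow,proportionCiHigh mediated
#'   proportion with delta-method interval.
#' @slot reliable FALSE when the total effect is too imprecise
#'   (|total/se| < 2) for the ratio to be trustworthy.
#' @slot assessed FALSE when the significance gate failed and mediation was
#'   not computed; @slot note human-readable gate explanation.
#' @export
setClass("MrMediation",
         representation(totalBeta = "numeric", totalSE = "numeric",
                        step1Beta = "numeric", step1SE = "numeric",
                        step2Beta = "numeric", step2SE = "numeric",
                        indirectBeta = "numeric", indirectSE = "numeric",
                        indirectPval = "numeric",
                        indirectCiLow = "numeric", indirectCiHigh = "numeric",
                        directBeta = "numeric",
                        proportion = "numeric", proportionSE = "numeric",
                        proportionCiLow = "numeric",
                        proportionCiHigh = "numeric",
                        reliable = "logical", assessed = "logical",
                        note = "character"))

setValidity("MrMediation", function(object) {
  msg <- character()
  if (object@assessed) {
    if (abs(object@indirectBeta - object@step1Beta * object@step2Beta) > 1e-12)
      msg <- c(msg, "indirect must equal step1 * step2 exactly")
    if (abs(object@directBeta + object@indirectBeta - object@totalBeta) > 1e-12)
      msg <- c(msg, "direct + indirect must equal total exactly")
  }
  if (length(msg)) msg else TRUE
})

## ---- accessor generics ----

#' @rdname GwasSumstats-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("traitName", function(object) standardGeneric("traitName"))
#' @rdname GwasSumstats-class
#' @export
setGeneric("traitType", function(object) standardGeneric("traitType"))
#' @rdname GwasSumstats-class
#' @export
setGeneric("sumstatsTable", function(object) standardGeneric("sumstatsTable"))
#' @rdname GwasSumstats-class
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))
#' @rdname MrHarmonized-class
#' @param object an object.
#' @export
setGeneric("harmonizedTable", function(object) standardGeneric("harmonizedTable"))
#' @rdname MrHarmonized-class
#' @export
setGeneric("droppedLedger", function(object) standardGeneric("droppedLedger"))
#' @rdname MrHarmonized-class
#' @export
setGeneric("nInstruments", function(object) standardGeneric("nInstruments"))
#' @rdname MrEstimate-class
#' @param object an object.
#' @export
setGeneric("mrMethod", function(object) standardGeneric("mrMethod"))
#' @rdname MrEstimate-class
#' @export
setGeneric("mrBeta", function(object) standardGeneric("mrBeta"))
#' @rdname MrEstimate-class
#' @export
setGeneric("mrSE", function(object) standardGeneric("mrSE"))
#' @rdname MrEstimate-class
#' @export
setGeneric("mrPval", function(object) standardGeneric("mrPval"))
#' @rdname MrEstimate-class
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))
#' @rdname LdMatrix-class
#' @param object an object.
#' @export
setGeneric("ldSnps", function(object) standardGeneric("ldSnps"))

#' @rdname GwasSumstats-class
#' @export
setMethod("traitName", "GwasSumstats", function(object) object@traitName)
#' @rdname GwasSumstats-class
#' @export
setMethod("traitType", "GwasSumstats", function(object) object@traitType)
#' @rdname GwasSumstats-class
#' @export
setMethod("sumstatsTable", "GwasSumstats", function(object) object@records)
#' @rdname GwasSumstats-class
#' @export
setMethod("nVariants", "GwasSumstats", function(object) nrow(object@records))
#' @rdname MrHarmonized-class
#' @export
setMethod("harmonizedTable", "MrHarmonized", function(object) object@table)
#' @rdname MrHarmonized-class
#' @export
setMethod("droppedLedger", "MrHarmonized", function(object) object@dropped)
#' @rdname MrHarmonized-class
#' @export
setMethod("nInstruments", "MrHarmonized", function(object) nrow(object@table))
#' @rdname MrEstimate-class
#' @export
setMethod("mrMethod", "MrEstimate", function(object) object@method)
#' @rdname MrEstimate-class
#' @export
setMethod("mrBeta", "MrEstimate", function(object) object@beta)
#' @rdname MrEstimate-class
#' @export
setMethod("mrSE", "MrEstimate", function(object) object@se)
#' @rdname MrEstimate-class
#' @export
setMethod("mrPval", "MrEstimate", function(object) object@pval)
#' @rdname MrEstimate-class
#' @export
setMethod("oddsRatio", "MrEstimate", function(object)
  c(or = object@orValue, ciLow = object@ciLow, ciHigh = object@ciHigh))
#' @rdname LdMatrix-class
#' @export
setMethod("ldSnps", "LdMatrix", function(object) rownames(object@r2))

## ---- show methods ----

setMethod("show", "GwasSumstats", function(object) {
  cat("GwasSumstats:", object@traitName,
      sprintf("(%s, %s)\n", object@traitType, object@ancestry))
  cat(" ", nrow(object@records), "variants\n")
})

setMethod("show", "LdMatrix", function(object) {
  cat("LdMatrix:", nrow(object@r2), "variants;",
      if (nrow(object@sign)) "with" else "without", "sign information\n")
})

setMethod("show", "MrHarmonized", function(object) {
  cat("MrHarmonized:", object@exposureName, "->", object@outcomeName, "\n")
  cat(" ", nrow(object@table), "instruments retained,",
      nrow(object@dropped), "dropped\n")
  if (nrow(object@dropped)) {
    tb <- table(object@dropped$stage)
    cat("  dropped by stage:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "), "\n")
  }
})

setMethod("show", "MrEstimate", function(object) {
  cat(sprintf("%s estimate (%d SNPs): beta = %.4g (se %.4g), p = %.3g\n",
              object@method, object@nSnp, object@beta, object@se, object@pval))
  cat(sprintf("  OR = %.4g, %g%% CI [%.4g, %.4g]\n", object@orValue,
              100 * object@level, object@ciLow, object@ciHigh))
  if (!is.na(object@intercept))
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n", object@intercept,
                object@interceptSE, object@interceptPval))
})

setMethod("show", "MrPresso", function(object) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, p = %.4g (%d simulations)\n",
              object@globalRSS, object@globalP, object@nSim))
  if (nrow(object@outliers)) {
    cat("  outliers:", paste(object@outliers$snp_id, collapse = ", "), "\n")
    cat(sprintf("  distortion p = %.4g\n", object@distortionP))
  } else cat("  no outliers flagged\n")
})

setMethod("show", "MrMediation", function(object) {
  if (!object@assessed) {
    cat("MrMediation: not assessed --", object@note, "\n")
    return(invisible(NULL))
  }
  cat("MrMediation (two-step MR, product of coefficients):\n")
  cat(sprintf("  total  = %.4g (se %.4g)\n", object@totalBeta, object@totalSE))
  cat(sprintf("  indirect (ACME) = %.4g (se %.4g), p = %.3g, CI [%.4g, %.4g]\n",
              object@indirectBeta, object@indirectSE, object@indirectPval,
              object@indirectCiLow, object@indirectCiHigh))
  cat(sprintf("  direct = %.4g; mediated proportion = %.4g [%.4g, %.4g]%s\n",
              object@directBeta, object@proportion, object@proportionCiLow,
              object@proportionCiHigh,
              if (object@reliable) "" else " (unreliable: weak total effect)"))
})
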