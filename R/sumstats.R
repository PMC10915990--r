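#' Standardize effect sizes from Z-score, allele frequency and sample size
#'
#' Recovers a standardized per-allele effect and its standard error from the
#' association Z-score, the allele frequency and the sample size:
#' \deqn{\beta = z / \sqrt{2 f (1-f) (n + z^2)}, \qquad
#'       se = 1 / \sqrt{2 f (1-f) (n + z^2)}}
#' so that `beta / se` equals `z` exactly. Because the frequency enters only
#' through the product `f (1 - f)`, folding to the minor allele frequency is
#' immaterial and either the effect-allele or the minor-allele frequency may
#' be supplied.
#'
#' @param zscore association Z statistic (beta / se in the original data).
#' @param eaf allele frequency, strictly in (0, 1).
#' @param n total sample size (>= 1).
#' @return list with vectors `beta` and `se`.
#' @examples
#' standardizeEffects(5, 0.3, 10000)
#' @export
standardizeEffects <- function(zscore, eaf, n) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1))
    stop("eaf must lie strictly in (0, 1)")
  if (any(!is.finite(n)) || any(n < 1))
    stop("n must be >= 1")
  denom <- sqrt(2 * eaf * (1 - eaf) * (n + zscore^2))
  list(beta = zscore / denom, se = 1 / denom)
}

#' Variance in the trait explained by one variant
#'
#' The full expression with explicit `2 MAF (1 - MAF)` factors in numerator
#' and denominator cancels algebraically to
#' \deqn{R^2 = \beta^2 / (\beta^2 + n \, se^2)}
#' which is the form computed here; it is invariant to the allele frequency.
#'
#' @param beta per-allele effect; @param se its standard error (> 0);
#' @param n sample size (>= 1).
#' @return R-squared in \[0, 1).
#' @export
varianceExplained <- function(beta, se, n) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(n < 1)) stop("n must be >= 1")
  beta^2 / (beta^2 + n * se^2)
}

#' Instrument-strength F statistic
#'
#' \deqn{F = R^2 (n - 2) / (1 - R^2)}
#' Values above 10 conventionally indicate a non-weak instrument.
#'
#' @param r2 per-variant variance explained, in \[0, 1).
#' @param n sample size of the exposure GWAS (> 2).
#' @return non-negative F statistic.
#' @export
fStatistic <- function(r2, n) {
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(n <= 2)) stop("n must be > 2")
  r2 * (n - 2) / (1 - r2)
}

# row-level validation; returns kept records plus a reason-tagged drop table.
.validateSumstatRows <- function(df) {
  al_ok <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  bad_allele <- !al_ok(df$effect_allele) | !al_ok(df$other_allele) |
    df$effect_allele == df$other_allele
  reason[bad_allele] <- "invalid_alleles"
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  reason[is.na(reason) & bad_eaf] <- "eaf_out_of_range"
  bad_se <- is.na(df$se) | df$se <= 0 | !is.finite(df$se)
  reason[is.na(reason) & bad_se] <- "invalid_se"
  bad_p <- is.na(df$pval) | df$pval <= 0 | df$pval > 1
  reason[is.na(reason) & bad_p] <- "invalid_pval"
  bad_n <- !is.na(df$n) & df$n < 1
  reason[is.na(reason) & bad_n] <- "invalid_n"
  bad_id <- is.na(df$snp_id) | df$snp_id == "" | duplicated(df$snp_id)
  reason[is.na(reason) & bad_id] <- "missing_or_duplicate_id"
  keep <- is.na(reason)
  list(records = df[keep, , drop = FALSE],
       dropped = data.frame(snp_id = as.character(df$snp_id[!keep]),
                            reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-bearing, tab-separated (gzip accepted) table and maps its
#' columns onto the canonical fields via `dialect`, a named list/vector of
#' `canonical = "file column"` entries. The mapping must cover at minimum
#' `snp_id`, `effect_allele`, `other_allele` and either (`beta`, `se`) or
#' (`zscore`, `eaf`, `n`); in the Z-score-only case beta and se are filled
#' in through [standardizeEffects()]. Rows violating the record invariants
#' are dropped with a logged count (permissive validation, so dialect noise
#' does not abort a run). A consistency check warns when reported p-values
#' disagree with `2 * pnorm(-|beta/se|)` by more than 10 percent (relative).
#'
#' @param path file path (plain or gzip-compressed TSV with header).
#' @param dialect named character vector/list mapping canonical field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`, `zscore`) to column names in the file;
#'   canonical names already present in the file need not be listed.
#' @param traitName,traitType,ancestry dataset metadata (see
#'   [GwasSumstats()]).
#' @param sep field separator, default tab.
#' @return A [GwasSumstats-class] object.
#' @export
readSumstats <- function(path, dialect = list(), traitName = basename(path),
                         traitType = "continuous", ancestry = "EUR",
                         sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L) stop("input error: summary-statistics table is empty")
  canon <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pval", "n", "zscore")
  dialect <- as.list(dialect)
  cols <- list()
  for (f in canon) {
    src <- if (!is.null(dialect[[f]])) dialect[[f]] else f
    if (src %in% names(raw)) cols[[f]] <- raw[[src]]
  }
  mand <- c("snp_id", "effect_allele", "other_allele")
  if (!all(mand %in% names(cols)))
    stop("configuration error: mapping must cover ",
         paste(setdiff(mand, names(cols)), collapse = ", "))
  has_beta <- all(c("beta", "se") %in% names(cols))
  has_z    <- all(c("zscore", "eaf", "n") %in% names(cols))
  if (!has_beta && !has_z)
    stop("configuration error: need (beta, se) or (zscore, eaf, n) columns")
  df <- data.frame(snp_id = as.character(cols$snp_id),
                   stringsAsFactors = FALSE)
  df$chrom <- if (!is.null(cols$chrom)) as.character(cols$chrom) else NA_character_
  df$pos   <- if (!is.null(cols$pos)) as.numeric(cols$pos) else NA_real_
  df$effect_allele <- toupper(as.character(cols$effect_allele))
  df$other_allele  <- toupper(as.character(cols$other_allele))
  df$eaf <- if (!is.null(cols$eaf)) as.numeric(cols$eaf) else NA_real_
  df$n   <- if (!is.null(cols$n)) as.numeric(cols$n) else NA_real_
  if (has_beta) {
    df$beta <- as.numeric(cols$beta)
    df$se   <- as.numeric(cols$se)
  } else {
    std <- standardizeEffects(as.numeric(cols$zscore), df$eaf, df$n)
    df$beta <- std$beta
    df$se   <- std$se
  }
  df$pval <- if (!is.null(cols$pval)) as.numeric(cols$pval) else
    .normP(df$beta / df$se)
  df <- df[, .SUMSTAT_COLS]

  val <- .validateSumstatRows(df)
  if (nrow(val$dropped))
    message(nrow(val$dropped), " of ", nrow(df),
            " rows dropped during validation (",
            paste(sprintf("%s=%d", names(table(val$dropped$reason)),
                          as.integer(table(val$dropped$reason))),
                  collapse = ", "), ")")
  kept <- val$records
  if (nrow(kept)) {
    pimp <- .normP(kept$beta / kept$se)
    incons <- abs(kept$pval - pimp) > 0.1 * pmax(pimp, kept$pval)
    # only meaningful away from the numerical floor
    incons <- incons & pmax(pimp, kept$pval) > 1e-300
    if (any(incons))
      warning(sum(incons), " record(s) have p-values inconsistent with ",
              "|beta/se| under the normal approximation (>10% relative)")
  }
  GwasSumstats(kept, traitName = traitName, traitType = traitType,
               ancestry = ancestry)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Inverse of [readSumstats()] with the canonical dialect: a round trip
#' reproduces the dataset field-for-field (up to numeric printing
#' precision, 15 significant digits).
#'
#' @param dataset a [GwasSumstats-class] object.
#' @param path output file path (`.gz` suffix writes gzip).
#' @return invisibly, the path.
#' @export
writeSumstats <- function(dataset, path) {
  stopifnot(is(dataset, "GwasSumstats"))
  rec <- sumstatsTable(dataset)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  num <- vapply(rec, is.numeric, logical(1))
  out <- rec
  out[num] <- lapply(rec[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
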