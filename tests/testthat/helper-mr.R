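# shared fixture builders (all fixtures are generated in code)

# direct MrHarmonized constructor for estimator-level tests
makeHarmonized <- function(bx, by, sx = rep(0.01, length(bx)),
                           sy = rep(1, length(bx)),
                           eaf = rep(0.3, length(bx)),
                           n_exp = rep(1e5, length(bx)),
                           n_out = rep(1e5, length(bx)),
                           ids = paste0("rs", seq_along(bx))) {
  tab <- data.frame(
    snp_id = ids, effect_allele = "A", other_allele = "G",
    beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy,
    eaf_exp = eaf, eaf_out = eaf, n_exp = n_exp, n_out = n_out,
    palindromic = FALSE, flipped = FALSE,
    proxy_of = NA_character_, proxy_r2 = NA_real_,
    stringsAsFactors = FALSE)
  mrpath:::.MrHarmonized("X", "Y", tab)
}

# small GwasSumstats from minimal fields
makeSumstats <- function(ids, beta, se, pval = NULL, eaf = 0.3, n = 1e5,
                         ea = "A", oa = "G", chrom = "1",
                         pos = seq_along(ids) * 2e6,
                         traitName = "trait", traitType = "continuous") {
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  GwasSumstats(data.frame(
    snp_id = ids, chrom = chrom, pos = pos, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval, n = n,
    stringsAsFactors = FALSE), traitName, traitType)
}

# significance selection + harmonization, the lean front of the pipeline
# used by simulation-heavy tests
leanHarmonize <- function(pair) {
  ids <- suppressWarnings(selectInstruments(pair$exposure))
  harmonizeSumstats(pair$exposure, pair$outcome, ids)
}
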