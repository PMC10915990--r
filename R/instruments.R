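#' Select candidate instruments by significance threshold
#'
#' Returns the identifiers of variants whose exposure p-value is strictly
#' below the threshold (genome-wide significance, p < 5e-8, by default).
#'
#' @param exposure [GwasSumstats-class] exposure dataset.
#' @param pThreshold significance threshold in (0, 1).
#' @return character vector of snp ids.
#' @export
selectInstruments <- function(exposure, pThreshold = 5e-8) {
  stopifnot(is(exposure, "GwasSumstats"),
            pThreshold > 0, pThreshold <= 1)
  rec <- sumstatsTable(exposure)
  ids <- rec$snp_id[!is.na(rec$pval) & rec$pval < pThreshold]
  if (!length(ids))
    warning("no variants pass the significance threshold ", pThreshold)
  ids
}

.ldLookup <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  sn <- rownames(ld@r2)
  if (!(a %in% sn) || !(b %in% sn)) return(0)
  ld@r2[a, b]
}

#' Greedy LD clumping of candidate instruments
#'
#' Standard greedy clumping: candidates are ranked by ascending p-value
#' (ties broken by genomic position, then lexicographic id, for
#' determinism); the best variant is kept and every variant with
#' `r2 > r2Threshold` to a kept variant within `windowKb` kilobases on the
#' same chromosome is discarded. Variant pairs on different chromosomes are
#' always treated as unlinked; variants absent from the LD matrix are
#' treated as unlinked (a message reports how many). Missing positions are
#' conservatively treated as within the window. The result does not depend
#' on the input order of `candidates`.
#'
#' @param candidates character vector of candidate snp ids.
#' @param exposure [GwasSumstats-class] providing p-values and positions.
#' @param ld [LdMatrix-class] or NULL (all pairs unlinked).
#' @param r2Threshold clumping r-squared threshold (default 0.001).
#' @param windowKb window in kb; the window is inclusive,
#'   |pos_i - pos_j| <= windowKb * 1000 (default 10000).
#' @return character vector of retained, mutually independent snp ids.
#' @export
ldClump <- function(candidates, exposure, ld = NULL, r2Threshold = 0.001,
                    windowKb = 10000) {
  stopifnot(is(exposure, "GwasSumstats"))
  rec <- sumstatsTable(exposure)
  miss <- setdiff(candidates, rec$snp_id)
  if (length(miss)) stop("candidates absent from exposure dataset: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  df <- rec[match(sort(unique(candidates)), rec$snp_id), , drop = FALSE]
  if (!is.null(ld)) {
    absent <- sum(!df$snp_id %in% rownames(ld@r2))
    if (absent) message(absent, " candidate(s) absent from the LD matrix; ",
                        "treated as unlinked")
  }
  ord <- order(df$pval, df$pos, df$snp_id)
  df <- df[ord, , drop = FALSE]
  kept <- character()
  kept_chrom <- character(); kept_pos <- numeric()
  for (i in seq_len(nrow(df))) {
    id <- df$snp_id[i]; ch <- df$chrom[i]; po <- df$pos[i]
    linked <- FALSE
    for (k in seq_along(kept)) {
      same_chr <- !is.na(ch) && !is.na(kept_chrom[k]) && ch == kept_chrom[k]
      if (is.na(ch) || is.na(kept_chrom[k])) same_chr <- TRUE  # conservative
      if (!same_chr) next
      in_window <- is.na(po) || is.na(kept_pos[k]) ||
        abs(po - kept_pos[k]) <= windowKb * 1000
      if (!in_window) next
      if (.ldLookup(ld, id, kept[k]) > r2Threshold) { linked <- TRUE; break }
    }
    if (!linked) {
      kept <- c(kept, id)
      kept_chrom <- c(kept_chrom, as.character(ch)); kept_pos <- c(kept_pos, po)
    }
  }
  kept
}

#' Find proxy variants for instruments missing from the outcome dataset
#'
#' For each missing instrument, the available outcome variant with the
#' highest r-squared above `r2Min` is proposed as a proxy. Aligning the
#' proxy's effect allele to the original instrument requires the LD sign
#' matrix; when no sign information is available the proxy is ambiguous and
#' the instrument is dropped with a recorded reason.
#'
#' @param missing snp ids absent from the outcome dataset.
#' @param ld [LdMatrix-class] with (optionally) a sign matrix.
#' @param r2Min minimum r-squared for a usable proxy (default 0.8).
#' @param outcome [GwasSumstats-class] outcome dataset.
#' @return data.frame (`snp_id`, `proxy_id`, `r2`, `sign`) of substitutions;
#'   instruments without a usable proxy appear in the `"dropped"` attribute
#'   with a reason.
#' @export
findProxies <- function(missing, ld, r2Min = 0.8, outcome) {
  stopifnot(is(ld, "LdMatrix"), r2Min > 0, r2Min < 1,
            is(outcome, "GwasSumstats"))
  out_ids <- sumstatsTable(outcome)$snp_id
  has_sign <- nrow(ld@sign) > 0
  sub <- data.frame(snp_id = character(), proxy_id = character(),
                    r2 = numeric(), sign = numeric(), stringsAsFactors = FALSE)
  dropped <- data.frame(snp_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  sn <- rownames(ld@r2)
  for (id in missing) {
    if (!(id %in% sn)) {
      dropped <- rbind(dropped, data.frame(snp_id = id,
                                           reason = "absent_from_ld_matrix"))
      next
    }
    cand <- setdiff(intersect(sn, out_ids), id)
    if (!length(cand)) {
      dropped <- rbind(dropped, data.frame(snp_id = id, reason = "no_proxy"))
      next
    }
    r2v <- ld@r2[id, cand]
    ok <- r2v > r2Min
    if (!any(ok)) {
      dropped <- rbind(dropped, data.frame(snp_id = id,
                                           reason = "no_proxy_above_r2_min"))
      next
    }
    cand <- cand[ok]; r2v <- r2v[ok]
    best <- cand[order(-r2v, cand)][1]
    sgn <- if (has_sign) ld@sign[id, best] else 0
    if (sgn == 0) {
      dropped <- rbind(dropped,
                       data.frame(snp_id = id, reason = "proxy_sign_unavailable"))
      next
    }
    sub <- rbind(sub, data.frame(snp_id = id, proxy_id = best,
                                 r2 = unname(ld@r2[id, best]), sign = sgn,
                                 stringsAsFactors = FALSE))
  }
  attr(sub, "dropped") <- dropped
  sub
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome effect alleles
#'
#' Aligns the outcome dataset to the exposure's effect allele, per
#' instrument. When the outcome's alleles are swapped relative to the
#' exposure, the outcome beta sign is flipped and its allele frequency
#' replaced by 1 - eaf; when the alleles match only as strand complements
#' they are complemented first and then aligned the same way. Incompatible
#' allele pairs are dropped with a recorded reason. Palindromic (A/T, C/G)
#' variants cannot be oriented from alleles alone and are only flagged here;
#' [dropPalindromic()] resolves or removes them by allele frequency.
#' Proxy substitutions (from [findProxies()]) use the proxy's outcome record
#' with the LD correlation sign applied to the outcome beta; their alleles
#' belong to a different variant, so allele comparison is skipped.
#'
#' @param exposure,outcome [GwasSumstats-class] datasets.
#' @param ivIds instrument ids (present in the exposure; present in the
#'   outcome directly or through `proxies`).
#' @param proxies optional substitution data.frame from [findProxies()].
#' @return An [MrHarmonized-class] object (retained table + dropped ledger).
#' @export
harmonizeSumstats <- function(exposure, outcome, ivIds, proxies = NULL) {
  stopifnot(is(exposure, "GwasSumstats"), is(outcome, "GwasSumstats"))
  erec <- sumstatsTable(exposure)
  orec <- sumstatsTable(outcome)
  if (!all(ivIds %in% erec$snp_id))
    stop("instruments absent from exposure dataset")
  rows <- list(); drops <- list()
  for (id in ivIds) {
    e <- erec[erec$snp_id == id, ]
    prox <- if (!is.null(proxies) && nrow(proxies)) proxies[proxies$snp_id == id, ] else NULL
    use_proxy <- !is.null(prox) && nrow(prox) == 1
    oid <- if (use_proxy) prox$proxy_id else id
    o <- orec[orec$snp_id == oid, ]
    if (nrow(o) != 1) {
      drops[[id]] <- data.frame(snp_id = id, stage = "harmonize",
                                reason = "absent_from_outcome")
      next
    }
    pal <- .isPalindromic(e$effect_allele, e$other_allele)
    if (use_proxy) {
      sgn <- prox$sign
      beta_out <- sgn * o$beta
      eaf_out <- if (sgn < 0 && !is.na(o$eaf)) 1 - o$eaf else o$eaf
      flipped <- sgn < 0
    } else {
      ea <- e$effect_allele; oa <- e$other_allele
      ea2 <- o$effect_allele; oa2 <- o$other_allele
      if (ea2 == ea && oa2 == oa) {
        beta_out <- o$beta; eaf_out <- o$eaf; flipped <- FALSE
      } else if (ea2 == oa && oa2 == ea) {
        beta_out <- -o$beta
        eaf_out <- if (is.na(o$eaf)) NA_real_ else 1 - o$eaf
        flipped <- TRUE
      } else if (!pal && ea2 == .COMPLEMENT[ea] && oa2 == .COMPLEMENT[oa]) {
        beta_out <- o$beta; eaf_out <- o$eaf; flipped <- FALSE
      } else if (!pal && ea2 == .COMPLEMENT[oa] && oa2 == .COMPLEMENT[ea]) {
        beta_out <- -o$beta
        eaf_out <- if (is.na(o$eaf)) NA_real_ else 1 - o$eaf
        flipped <- TRUE
      } else {
        drops[[id]] <- data.frame(snp_id = id, stage = "harmonize",
                                  reason = "incompatible_alleles")
        next
      }
    }
    rows[[id]] <- data.frame(
      snp_id = id, effect_allele = e$effect_allele,
      other_allele = e$other_allele,
      beta_exp = e$beta, se_exp = e$se, beta_out = beta_out, se_out = o$se,
      eaf_exp = e$eaf, eaf_out = eaf_out, n_exp = e$n, n_out = o$n,
      palindromic = pal, flipped = flipped,
      proxy_of = if (use_proxy) prox$proxy_id else NA_character_,
      proxy_r2 = if (use_proxy) prox$r2 else NA_real_,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(.HARMONIZED_COLS))),
                    .HARMONIZED_COLS)
  dr <- if (length(drops)) do.call(rbind, drops) else .emptyDropped()
  .MrHarmonized(traitName(exposure), traitName(outcome), tab, dr)
}

.appendDropped <- function(h, ids, stage, reason) {
  if (!length(ids)) return(h)
  add <- data.frame(snp_id = ids, stage = stage, reason = reason,
                    stringsAsFactors = FALSE)
  h@dropped <- rbind(h@dropped, add)
  h@table <- h@table[!h@table$snp_id %in% ids, , drop = FALSE]
  rownames(h@table) <- NULL
  validObject(h)
  h
}

#' Remove or align palindromic variants by allele frequency
#'
#' Palindromic (A/T or C/G) variants with exposure effect-allele frequency
#' inside the ambiguity window are removed: at intermediate frequency the
#' strand cannot be resolved. Palindromic variants with extreme frequency
#' are retained after frequency-based alignment: when the exposure and
#' outcome frequencies fall on opposite sides of 0.5 the two datasets are
#' reporting opposite strands/alleles, so the outcome beta sign is flipped
#' and its frequency replaced by 1 - eaf.
#'
#' @param data [MrHarmonized-class].
#' @param ambiguityWindow open interval of frequencies deemed ambiguous
#'   (default (0.42, 0.58)).
#' @return [MrHarmonized-class] with ambiguous palindromic variants moved to
#'   the dropped ledger.
#' @export
dropPalindromic <- function(data, ambiguityWindow = c(0.42, 0.58)) {
  stopifnot(is(data, "MrHarmonized"), length(ambiguityWindow) == 2)
  tab <- data@table
  if (!nrow(tab)) return(data)
  pal <- tab$palindromic
  amb <- pal & !is.na(tab$eaf_exp) &
    tab$eaf_exp > ambiguityWindow[1] & tab$eaf_exp < ambiguityWindow[2]
  # frequency-based alignment for retained palindromic variants
  fix <- pal & !amb & !is.na(tab$eaf_exp) & !is.na(tab$eaf_out) &
    (tab$eaf_exp - 0.5) * (tab$eaf_out - 0.5) < 0
  if (any(fix)) {
    tab$beta_out[fix] <- -tab$beta_out[fix]
    tab$eaf_out[fix] <- 1 - tab$eaf_out[fix]
    tab$flipped[fix] <- !tab$flipped[fix]
  }
  data@table <- tab
  .appendDropped(data, tab$snp_id[amb], "palindromic",
                 "palindromic_intermediate_eaf")
}

#' Steiger directionality filter
#'
#' Removes any instrument that explains more variance in the outcome than
#' in the exposure (computed per SNP via [varianceExplained()]), enforcing
#' the assumed exposure-to-outcome causal direction. The default decision is
#' the plain r-squared comparison; `method = "ztest"` additionally requires
#' the difference to be significant at `alpha` using the normal
#' approximation on Fisher-transformed correlations.
#'
#' @param data [MrHarmonized-class]; needs per-SNP `n_exp` and `n_out`
#'   (variants with missing sample size are retained with a warning).
#' @param method `"simple"` (default) or `"ztest"`.
#' @param alpha significance level for the z-test variant.
#' @return filtered [MrHarmonized-class].
#' @export
steigerFilter <- function(data, method = c("simple", "ztest"), alpha = 0.05) {
  stopifnot(is(data, "MrHarmonized"))
  method <- match.arg(method)
  tab <- data@table
  if (!nrow(tab)) return(data)
  has_n <- !is.na(tab$n_exp) & !is.na(tab$n_out)
  if (any(!has_n))
    warning(sum(!has_n), " variant(s) lack sample size; retained unfiltered")
  r2e <- rep(NA_real_, nrow(tab)); r2o <- rep(NA_real_, nrow(tab))
  r2e[has_n] <- varianceExplained(tab$beta_exp[has_n], tab$se_exp[has_n],
                                  tab$n_exp[has_n])
  r2o[has_n] <- varianceExplained(tab$beta_out[has_n], tab$se_out[has_n],
                                  tab$n_out[has_n])
  rm_flag <- has_n & (r2o > r2e)
  if (method == "ztest" && any(rm_flag)) {
    # Fisher z on |correlations| implied by r2; keep unless significantly larger
    idx <- which(rm_flag)
    zdiff <- (atanh(sqrt(r2o[idx])) - atanh(sqrt(r2e[idx]))) /
      sqrt(1 / (tab$n_out[idx] - 3) + 1 / (tab$n_exp[idx] - 3))
    rm_flag[idx] <- stats::pnorm(zdiff, lower.tail = FALSE) < alpha
  }
  .appendDropped(data, tab$snp_id[rm_flag], "steiger",
                 "explains_more_outcome_variance")
}

#' Radial (modified Q) outlier removal
#'
#' Fits the radial inverse-variance-weighted slope with first-order weights,
#' computes each variant's heterogeneity contribution
#' \eqn{Q_j = w_j (\hat\theta_j - \hat\beta)^2} referred to a chi-squared
#' distribution with 1 df, removes variants with p < alpha, and iterates
#' fit-and-remove until no new outlier is found or fewer than 3 variants
#' remain.
#'
#' @param data [MrHarmonized-class] with >= 2 instruments (fewer passes
#'   through with a warning).
#' @param alpha per-variant significance level (default 0.05; `alpha = 0`
#'   never removes anything).
#' @return filtered [MrHarmonized-class].
#' @export
radialFilter <- function(data, alpha = 0.05) {
  stopifnot(is(data, "MrHarmonized"), alpha >= 0, alpha <= 1)
  if (nrow(data@table) < 2) {
    warning("fewer than 2 instruments; radial filter skipped")
    return(data)
  }
  repeat {
    tab <- data@table
    if (nrow(tab) < 3) break
    ratio <- tab$beta_out / tab$beta_exp
    w <- (tab$beta_exp / tab$se_out)^2
    slope <- sum(w * ratio) / sum(w)
    qj <- w * (ratio - slope)^2
    pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
    out <- pj < alpha
    if (!any(out)) break
    # remove the single worst contributor, then refit: a gross outlier
    # inflates every other variant's Q against the distorted slope
    worst <- which.max(qj)
    data <- .appendDropped(data, tab$snp_id[worst], "radial",
                           "radial_q_outlier")
  }
  data
}
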