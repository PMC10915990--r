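test_that("instrument selection uses a strict significance threshold", {
  ds <- makeSumstats(c("rs1", "rs2"), beta = c(0.1, 0.05), se = 0.01,
                     pval = c(1e-9, 1e-7))
  expect_identical(selectInstruments(ds, 5e-8), "rs1")
  expect_setequal(selectInstruments(ds, 1.0), c("rs1", "rs2"))
  expect_warning(empty <- selectInstruments(ds, 1e-30), "no variants")
  expect_length(empty, 0)
})

test_that("selection recovers simulated true effects at large n", {
  pair <- simulateGwasPair(simConfig(nSnps = 100, exposureH2 = 0.05,
                                     nExp = 1e6, seed = 11))
  sel <- selectInstruments(pair$exposure)
  rec <- sumstatsTable(pair$exposure)
  # selection is exactly the strict-threshold set
  expect_setequal(sel, rec$snp_id[rec$pval < 5e-8])
  # and a good share of the (normally distributed) true effects make it
  expect_gte(length(sel), 50)
})

test_that("greedy clumping honours the r2 threshold and window", {
  ds <- makeSumstats(c("A", "B", "C"), beta = 0.1,
                     se = 0.01, pval = c(1e-20, 1e-10, 1e-9),
                     chrom = "1", pos = c(1e6, 1.05e6, 3e6))
  r2 <- diag(3); dimnames(r2) <- list(c("A", "B", "C"), c("A", "B", "C"))
  r2["A", "B"] <- r2["B", "A"] <- 0.5
  ld <- LdMatrix(r2)
  expect_setequal(ldClump(c("A", "B", "C"), ds, ld, 0.001, 10000),
                  c("A", "C"))
  # same pair but 20,000 kb apart: outside the 10,000 kb window, both kept
  ds2 <- makeSumstats(c("A", "B"), beta = 0.1, se = 0.01,
                      pval = c(1e-20, 1e-10), chrom = "1",
                      pos = c(1e6, 1e6 + 2e7))
  expect_setequal(ldClump(c("A", "B"), ds2, ld, 0.001, 10000), c("A", "B"))
  # mutually unlinked variants are all kept
  expect_setequal(ldClump(c("A", "B", "C"), ds, NULL), c("A", "B", "C"))
})

test_that("clumping is order-independent and leaves no linked pair", {
  set.seed(421)
  for (rep in 1:5) {
    m <- 8
    ids <- paste0("s", 1:m)
    ds <- makeSumstats(ids, beta = 0.1, se = 0.01,
                       pval = runif(m, 1e-20, 1e-8), chrom = "1",
                       pos = sort(runif(m, 1e6, 5e6)))
    r2 <- matrix(runif(m * m, 0, 0.9), m, m)
    r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    ld <- LdMatrix(r2)
    kept <- ldClump(ids, ds, ld, 0.1, 10000)
    perm <- sample(ids)
    expect_setequal(ldClump(perm, ds, ld, 0.1, 10000), kept)
    # brute force: no retained pair with r2 above threshold within window
    if (length(kept) > 1) {
      combs <- combn(kept, 2)
      for (k in seq_len(ncol(combs)))
        expect_lte(r2[combs[1, k], combs[2, k]], 0.1)
    }
  }
})

test_that("proxy search picks the best available proxy above the floor", {
  ids <- c("miss", "p1", "p2", "far")
  r2 <- diag(4); dimnames(r2) <- list(ids, ids)
  r2["miss", "p1"] <- r2["p1", "miss"] <- 0.85
  r2["miss", "p2"] <- r2["p2", "miss"] <- 0.92
  r2["miss", "far"] <- r2["far", "miss"] <- 0.6
  sgn <- matrix(1, 4, 4, dimnames = list(ids, ids))
  outcome <- makeSumstats(c("p1", "p2", "far"), beta = 0.05, se = 0.01)

  sub <- findProxies("miss", LdMatrix(r2, sgn), 0.8, outcome)
  expect_identical(sub$proxy_id, "p2")  # argmax r2
  expect_equal(sub$r2, 0.92)

  # nothing above the floor -> dropped with reason
  sub2 <- findProxies("miss", LdMatrix(r2, sgn), 0.95, outcome)
  expect_identical(nrow(sub2), 0L)
  expect_identical(attr(sub2, "dropped")$reason, "no_proxy_above_r2_min")

  # no sign matrix -> ambiguous, dropped
  sub3 <- findProxies("miss", LdMatrix(r2), 0.8, outcome)
  expect_identical(nrow(sub3), 0L)
  expect_identical(attr(sub3, "dropped")$reason, "proxy_sign_unavailable")
})

test_that("harmonization handles all allele-order and strand cases", {
  exp <- makeSumstats("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G")
  cases <- list(
    list(ea = "A", oa = "G", flip = FALSE),  # direct match
    list(ea = "G", oa = "A", flip = TRUE),   # swapped order
    list(ea = "T", oa = "C", flip = FALSE),  # strand complement
    list(ea = "C", oa = "T", flip = TRUE))   # complement + swapped
  for (cs in cases) {
    out <- makeSumstats("rs1", beta = -0.05, se = 0.02, ea = cs$ea,
                        oa = cs$oa, eaf = 0.25, traitName = "out")
    h <- harmonizeSumstats(exp, out, "rs1")
    tab <- harmonizedTable(h)
    expect_identical(nrow(tab), 1L)
    expect_equal(tab$beta_out, if (cs$flip) 0.05 else -0.05)
    expect_equal(tab$eaf_out, if (cs$flip) 0.75 else 0.25)
    expect_identical(tab$flipped, cs$flip)
  }
  # incompatible alleles are dropped with a reason
  out_bad <- makeSumstats("rs1", beta = 0.05, se = 0.02, ea = "A", oa = "C",
                          traitName = "out")
  h <- harmonizeSumstats(exp, out_bad, "rs1")
  expect_identical(nrow(harmonizedTable(h)), 0L)
  expect_identical(droppedLedger(h)$reason, "incompatible_alleles")
})

test_that("harmonization conserves variants and is involution-safe", {
  pair <- simulateGwasPair(simConfig(nSnps = 30, seed = 5))
  ids <- sumstatsTable(pair$exposure)$snp_id
  h <- harmonizeSumstats(pair$exposure, pair$outcome, ids)
  expect_setequal(c(harmonizedTable(h)$snp_id, droppedLedger(h)$snp_id), ids)

  # already-aligned data: harmonizing changes nothing
  h2 <- harmonizeSumstats(pair$exposure, pair$outcome,
                          harmonizedTable(h)$snp_id)
  expect_equal(harmonizedTable(h2), harmonizedTable(h))
  expect_false(any(harmonizedTable(h)$flipped))
})

test_that("palindromic variants are removed or frequency-aligned", {
  mk <- function(eaf_exp, eaf_out, ea = "A", oa = "T") {
    e <- makeSumstats("rs1", beta = 0.1, se = 0.01, ea = ea, oa = oa,
                      eaf = eaf_exp)
    o <- makeSumstats("rs1", beta = 0.05, se = 0.02, ea = ea, oa = oa,
                      eaf = eaf_out, traitName = "out")
    harmonizeSumstats(e, o, "rs1")
  }
  # intermediate frequency: removed
  h <- dropPalindromic(mk(0.50, 0.50))
  expect_identical(nrow(harmonizedTable(h)), 0L)
  expect_identical(droppedLedger(h)$reason, "palindromic_intermediate_eaf")
  # extreme, concordant frequencies: retained unchanged
  h2 <- dropPalindromic(mk(0.10, 0.12))
  expect_identical(nrow(harmonizedTable(h2)), 1L)
  expect_equal(harmonizedTable(h2)$beta_out, 0.05)
  # extreme but discordant (C/G, 0.10 vs 0.90): outcome sign flipped
  h3 <- dropPalindromic(mk(0.10, 0.90, ea = "C", oa = "G"))
  tab3 <- harmonizedTable(h3)
  expect_equal(tab3$beta_out, -0.05)
  expect_equal(tab3$eaf_out, 0.10)
})

test_that("Steiger filter removes variants explaining more outcome variance", {
  # r2 = beta^2/(beta^2 + n se^2); equal n and se, so r2 ordered by |beta|
  h <- makeHarmonized(bx = c(0.10, 0.05), by = c(0.05, 0.10),
                      sx = c(0.01, 0.01), sy = c(0.01, 0.01))
  hf <- steigerFilter(h)
  expect_identical(harmonizedTable(hf)$snp_id, "rs1")  # rs2 reversed
  expect_identical(droppedLedger(hf)$stage, "steiger")
  # idempotent on its own output
  expect_equal(harmonizedTable(steigerFilter(hf)), harmonizedTable(hf))
})

test_that("exposure-causal simulations rarely trip the Steiger filter", {
  removed <- total <- 0
  for (seed in 1:10) {
    pair <- simulateGwasPair(simConfig(trueSlope = 0.2, nOut = 3e5,
                                       seed = 800 + seed))
    h <- leanHarmonize(pair)
    hf <- steigerFilter(h)
    removed <- removed + nrow(droppedLedger(hf))
    total <- total + nInstruments(h)
  }
  expect_lt(removed / total, 0.05)
})

test_that("radial filter removes only genuine heterogeneity outliers", {
  # identical ratios: nothing removed
  h0 <- makeHarmonized(bx = rep(1, 5), by = rep(0.4, 5), sy = rep(0.1, 5))
  expect_identical(nrow(droppedLedger(radialFilter(h0))), 0L)

  # 10 concordant variants plus one gross outlier (tight SEs)
  h1 <- makeHarmonized(bx = rep(1, 11), by = c(rep(0.2, 10), 5.0),
                       sy = rep(0.05, 11))
  # direct computation: the outlier's Q against the IVW slope is enormous
  ratio <- c(rep(0.2, 10), 5.0); w <- rep(1 / 0.05^2, 11)
  slope <- sum(w * ratio) / sum(w)
  q_out <- w[11] * (5.0 - slope)^2
  expect_lt(pchisq(q_out, 1, lower.tail = FALSE), 1e-6)
  hf <- radialFilter(h1)
  expect_identical(droppedLedger(hf)$snp_id, "rs11")

  # alpha = 0 never removes; filter is idempotent at fixed alpha
  expect_identical(nrow(droppedLedger(radialFilter(h1, alpha = 0))), 0L)
  expect_equal(harmonizedTable(radialFilter(hf)), harmonizedTable(hf))
})
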