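test_that("standardization recovers beta and se from z, frequency and n", {
  # zero effect: beta 0, se = 1/sqrt(2 f (1-f) n)
  z0 <- standardizeEffects(0, 0.3, 10000)
  expect_equal(z0$beta, 0)
  expect_equal(z0$se, 1 / sqrt(0.42 * 10000))

  # arithmetic oracle: denominator 2*0.3*0.7*(10000 + 25)
  s <- standardizeEffects(5, 0.3, 10000)
  denom <- sqrt(2 * 0.3 * 0.7 * (10000 + 25))
  expect_equal(s$beta, 5 / denom)
  expect_equal(s$se, 1 / denom)
  expect_equal(s$beta, 0.07706, tolerance = 1e-4)
  expect_equal(s$se, 0.015412, tolerance = 1e-4)

  # beta/se returns z exactly; symmetry in f <-> 1-f
  expect_equal(s$beta / s$se, 5)
  expect_identical(standardizeEffects(5, 0.7, 10000), s)

  expect_error(standardizeEffects(1, 0, 1000))
  expect_error(standardizeEffects(1, 1, 1000))
  expect_error(standardizeEffects(1, 0.3, 0.5))
})

test_that("standardized se is monotone in n and f(1-f), minimal at f = 0.5", {
  f_grid <- seq(0.05, 0.95, by = 0.05)
  se_f <- vapply(f_grid, function(f) standardizeEffects(2, f, 1e4)$se,
                 numeric(1))
  expect_true(all(standardizeEffects(2, 0.5, 1e4)$se <= se_f))
  n_grid <- c(1e3, 1e4, 1e5, 1e6)
  se_n <- vapply(n_grid, function(n) standardizeEffects(2, 0.3, n)$se,
                 numeric(1))
  expect_true(all(diff(se_n) < 0))
})

test_that("standardization is idempotent on already-standardized records", {
  s1 <- standardizeEffects(3.2, 0.21, 54321)
  z <- s1$beta / s1$se
  s2 <- standardizeEffects(z, 0.21, 54321)
  expect_equal(s2$beta, s1$beta, tolerance = 1e-12)
  expect_equal(s2$se, s1$se, tolerance = 1e-12)
})

test_that("variance explained matches the simplified and full forms", {
  expect_equal(varianceExplained(0, 0.01, 1000), 0)
  expect_equal(varianceExplained(0.1, 0.01, 1000), 0.01 / 0.11)

  # full printed form with explicit 2 maf (1-maf) factors is identical
  full <- function(beta, se, n, maf) {
    h <- 2 * maf * (1 - maf)
    (h * beta^2) / (h * beta^2 + h * n * se^2)
  }
  for (maf in c(0.05, 0.25, 0.5)) {
    expect_equal(varianceExplained(0.1, 0.01, 1000),
                 full(0.1, 0.01, 1000, maf))
  }

  # equals z^2/(z^2 + n) when beta/se = z
  std <- standardizeEffects(4, 0.4, 20000)
  expect_equal(varianceExplained(std$beta, std$se, 20000),
               16 / (16 + 20000))
  expect_error(varianceExplained(0.1, 0, 1000))
})

test_that("F statistic follows R2 (n-2)/(1-R2) and the weak-instrument screen", {
  expect_equal(fStatistic(0, 1000), 0)
  f <- fStatistic(0.01, 1002)
  expect_equal(f, 0.01 * 1000 / 0.99)
  expect_gt(f, 10)  # passes the conventional F > 10 screen
  # monotone in r2 and n
  expect_true(all(diff(fStatistic(c(0.001, 0.01, 0.1), 1000)) > 0))
  expect_true(all(diff(fStatistic(0.01, c(100, 1000, 10000))) > 0))
  expect_error(fStatistic(1, 1000))
  expect_error(fStatistic(0.01, 2))
})

test_that("summary statistics survive a write/read round trip", {
  ds <- makeSumstats(paste0("rs", 1:3), beta = c(0.1, -0.2, 0.05),
                     se = c(0.01, 0.02, 0.03), eaf = c(0.1, 0.4, 0.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSumstats(ds, path)
  expect_identical(length(readLines(path)), 4L)  # header + 3 records
  back <- readSumstats(path, traitName = traitName(ds))
  expect_equal(sumstatsTable(back), sumstatsTable(ds), tolerance = 1e-12)

  # empty dataset -> header-only file
  empty <- GwasSumstats(sumstatsTable(ds)[0, ], "empty")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeSumstats(empty, p2)
  expect_identical(length(readLines(p2)), 1L)
})

test_that("round trip preserves randomly generated datasets", {
  for (seed in 1:5) {
    pair <- simulateGwasPair(simConfig(nSnps = 20, seed = seed))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSumstats(pair$exposure, path)
    back <- readSumstats(path)
    expect_equal(sumstatsTable(back), sumstatsTable(pair$exposure),
                 tolerance = 1e-12)
  }
})

test_that("reader drops invalid rows permissively and honours dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(marker = c("rs1", "rs2", "rs3"),
                   EA = c("A", "C", "G"), OA = c("G", "T", "A"),
                   freq = c(0.2, 1.2, 0.4),  # rs2 invalid
                   b = c(0.1, 0.1, -0.2), sd = c(0.01, 0.01, 0.02),
                   p = c(1e-20, 1e-20, 1e-20), N = 1e5)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dia <- c(snp_id = "marker", effect_allele = "EA", other_allele = "OA",
           eaf = "freq", beta = "b", se = "sd", pval = "p", n = "N")
  expect_message(ds <- suppressWarnings(readSumstats(path, dia)), "dropped")
  expect_identical(nVariants(ds), 2L)
  expect_false("rs2" %in% sumstatsTable(ds)$snp_id)

  # missing mandatory columns -> configuration error
  expect_error(readSumstats(path, dia[c("snp_id", "effect_allele")]),
               "configuration error")
  # empty table -> input error
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("snp_id\teffect_allele\tother_allele\tbeta\tse", p3)
  expect_error(readSumstats(p3), "input error")
})

test_that("Z-score-only input reproduces rowwise standardization", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(snp_id = paste0("rs", 1:4),
                   effect_allele = "A", other_allele = "G",
                   zscore = c(2, -3, 5.5, 0.4),
                   eaf = c(0.1, 0.3, 0.45, 0.2), n = c(1e4, 2e4, 5e4, 1e5))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- readSumstats(path)
  expected <- standardizeEffects(df$zscore, df$eaf, df$n)
  expect_equal(sumstatsTable(ds)$beta, expected$beta)
  expect_equal(sumstatsTable(ds)$se, expected$se)
  expect_equal(sumstatsTable(ds)$beta / sumstatsTable(ds)$se, df$zscore)
})

test_that("inconsistent p-values trigger a warning, not a drop", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(snp_id = c("rs1", "rs2"), effect_allele = "A",
                   other_allele = "G", eaf = 0.3,
                   beta = c(0.1, 0.1), se = c(0.05, 0.05),
                   pval = c(2 * pnorm(-2), 0.5), n = 1e4)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ds <- readSumstats(path), "inconsistent")
  expect_identical(nVariants(ds), 2L)
})
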