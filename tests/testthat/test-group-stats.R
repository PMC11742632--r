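test_that("exact Mann-Whitney p matches full enumeration on small samples", {
  gc <- compareGroups(c(1, 2), c(3, 4), "mann_whitney")
  expect_equal(gc@statistic, 0)
  expect_equal(gc@pValue, 1 / 3, tolerance = 1e-12)
  expect_equal(gc@pValue, mwExactOracle(c(1, 2), c(3, 4)), tolerance = 1e-12)
  set.seed(21)
  for (nA in 2:4) for (nB in 2:4) {
    a <- rnorm(nA); b <- rnorm(nB, 0.5)
    expect_equal(compareGroups(a, b, "mann_whitney")@pValue,
                 mwExactOracle(a, b), tolerance = 1e-12,
                 label = sprintf("nA=%d nB=%d", nA, nB))
  }
})

test_that("identical samples give zero effect size and conventional paired p", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(compareGroups(a, a, "mann_whitney")@effectSizeD, 0)
  paired <- compareGroups(a, a, "wilcoxon_paired")
  expect_equal(paired@pValue, 1)
  expect_equal(paired@statistic, 0)
  expect_equal(paired@effectSizeD, 0)
  expect_error(compareGroups(a, a[1:3], "wilcoxon_paired"), "equal-length")
  expect_error(compareGroups(numeric(0), a), "at least 2")
})

test_that("Cohen's d uses the pooled-SD definition", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 8)
  sp <- sqrt(((3) * var(a) + (3) * var(b)) / 6)
  expect_equal(compareGroups(a, b, "mann_whitney")@effectSizeD,
               (mean(a) - mean(b)) / sp)
  # Kruskal-Wallis route reports the same d
  expect_equal(compareGroups(a, b, "kruskal_wallis")@effectSizeD,
               (mean(a) - mean(b)) / sp)
})

test_that("BH step-up rejection and adjusted p match the brute-force rule", {
  r1 <- bhFdr(c(0.005, 0.01, 0.03, 0.04), 0.05)
  expect_true(all(r1$reject))
  r2 <- bhFdr(c(0.02, 0.5, 0.8), 0.05)
  expect_false(any(r2$reject))
  r3 <- bhFdr(0.04, 0.05)
  expect_true(r3$reject)
  expect_equal(r3$p_adjusted, 0.04)
  set.seed(22)
  for (i in 1:50) {
    m <- sample(1:124, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- bhFdr(p, 0.05)
    want <- bhOracle(p, 0.05)
    expect_equal(got$p_adjusted, want$p_adjusted, tolerance = 1e-12)
    expect_identical(as.logical(got$reject), want$reject)
  }
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is monotone: raising a p-value never enlarges the rejection set", {
  set.seed(23)
  for (i in 1:20) {
    p <- runif(10)^2
    base <- which(bhFdr(p, 0.05)$reject)
    j <- sample(10, 1)
    p2 <- p
    p2[j] <- min(1, p2[j] * 2)
    expect_true(all(which(bhFdr(p2, 0.05)$reject) %in% union(base, j)))
  }
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  tab <- matrix(c(8, 2, 2, 13), 2, byrow = TRUE)
  split <- medianSplit(c(1, 2, 3, 4))
  expect_identical(as.vector(table(split$grouping)), c(2L, 2L))
  got <- fisher.test(tab)$p.value
  expect_equal(got, fisherOracle(tab), tolerance = 1e-9)
  # balanced independent covariate: p = 1
  bal <- medianSplit(c(1, 2, 3, 4), data.frame(cov = c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(bal$tests$p, 1)
  expect_error(medianSplit(c(1, 2, 3, 4), data.frame(cov = rep(TRUE, 4))),
               "2 levels")
  expect_error(medianSplit(c(1, 2)), "at least 4")
})

test_that("median-split ties go to the low group deterministically", {
  split <- medianSplit(c(1, 2, 2, 5))
  expect_identical(as.character(split$grouping), c("low", "low", "low", "high"))
})

test_that("hemispheric asymmetry pairs homologous regions", {
  spec <- tinySpec()
  geom <- tinyGeom(spec)
  ids <- geom$atlas@table$region_id
  z <- setNames(rep(1.5, length(ids)), as.character(ids))
  sym <- hemisphericAsymmetry(z, geom$atlas)
  expect_equal(sym@pValue, 1)
  expect_equal(sym@effectSizeD, 0)
  # right = left + 1 for every pair: maximal effect favoring right
  zShift <- z
  right <- geom$atlas@table$hemisphere == "R"
  zShift[as.character(ids[right])] <- 2.5
  shift <- hemisphericAsymmetry(zShift, geom$atlas)
  expect_identical(shift@effectSizeD, -Inf)  # left - right < 0
  expect_lt(shift@pValue, 0.01)
})

test_that("a right-seeded cohort yields significant rightward asymmetry", {
  set.seed(24)
  spec <- tinySpec()
  geom <- tinyGeom(spec)
  ids <- geom$atlas@table$region_id
  right <- geom$atlas@table$hemisphere == "R"
  # 20 subjects with right-hemisphere elevated regional z
  meanZ <- colMeans(t(vapply(1:20, function(i) {
    rnorm(length(ids), ifelse(right, 1.2, 0.2), 0.5)
  }, numeric(length(ids)))))
  res <- hemisphericAsymmetry(setNames(meanZ, as.character(ids)), geom$atlas)
  expect_lt(res@pValue, 0.05)
  expect_lt(res@effectSizeD, 0)  # right exceeds left
})

test_that("severity PCA explains variance per the correlation-matrix eigenstructure", {
  set.seed(25)
  n <- 40
  f1 <- rnorm(n)
  # third feature residualized against f1 so its sample correlation is 0
  f3 <- residuals(lm(rnorm(n) ~ f1))
  feats <- data.frame(seizure_freq = f1, n_medications = 2 * f1 + 5,
                      years_epilepsy = f3)
  # correlation matrix has eigenvalues 2, 1, 0: PC1 explains 2/3
  res <- severityPca(feats, rnorm(n))
  expect_equal(res$explained_variance[1], 2 / 3, tolerance = 1e-10)
  # monotone function of PC1 has Spearman r = 1 with PC1 scores
  measure <- exp(res$pc_scores[, 1])
  res2 <- severityPca(feats, measure)
  expect_equal(abs(res2$correlation$r[1]), 1, tolerance = 1e-12)
  # permutation invariance of loadings and correlations
  perm <- sample(n)
  res3 <- severityPca(feats[perm, ], measure[perm])
  expect_equal(abs(res3$correlation$r), abs(res2$correlation$r),
               tolerance = 1e-9)
  expect_equal(abs(unname(res3$loadings)), abs(unname(res2$loadings)),
               tolerance = 1e-9)
  expect_warning(
    severityPca(data.frame(a = rnorm(10), b = rep(1, 10)), rnorm(10)),
    "constant")
})

test_that("false-positive rate of the group comparison is nominal under the null", {
  set.seed(26)
  rej <- replicate(200, {
    compareGroups(rnorm(20), rnorm(20), "mann_whitney")@pValue <= 0.05
  })
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})
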