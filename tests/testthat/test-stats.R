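test_that("Cohen's d matches hand arithmetic and guards degeneracy", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohensD(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_error(cohensD(c(0, 0), c(1, 1)), "pooled SD")
  expect_error(cohensD(1, c(1, 2)))
})

test_that("Cohen's f2 follows its closed form", {
  expect_equal(cohensF2(0.5, 0.5), 0)
  expect_equal(cohensF2(0.5, 0.25), 0.5)
  expect_equal(cohensF2(0.19, 0.10), 0.09 / 0.81)
  expect_error(cohensF2(1, 0.5), "undefined")
})

test_that("f2 of an OLS term matches the t-statistic identity", {
  # partial F for one added regressor equals t^2, so f2 = t^2 / df_resid
  set.seed(5)
  n <- 60
  x <- rnorm(n); z <- rnorm(n)
  y <- 0.4 * x + 0.3 * z + rnorm(n)
  full <- lm(y ~ x + z); red <- lm(y ~ z)
  f2 <- cohensF2(summary(full)$r.squared, summary(red)$r.squared)
  tval <- summary(full)$coefficients["x", "t value"]
  expect_equal(f2, tval^2 / full$df.residual, tolerance = 1e-10)
})

test_that("BH step-up matches hand examples and brute-force enumeration", {
  r1 <- bhFDR(0.04)
  expect_equal(r1$adjusted, 0.04)
  expect_true(r1$rejected)

  r4 <- bhFDR(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r4$adjusted, rep(0.04, 4))
  expect_true(all(r4$rejected))

  expect_false(any(bhFDR(rep(1, 5))$rejected))

  set.seed(8)
  for (i in 1:60) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- bhFDR(p, q)$rejected
    expect_identical(got, bruteBH(p, q), info = paste(p, collapse = ","))
  }
})

test_that("the GAM with a fixed 2-knot spline reproduces OLS", {
  tab <- simTable(150, beta = 0.02, seed = 3)
  m <- fitBurdenGAM(tab, "uf_burden", "severity_ordinal", splineK = 2,
                    splineFixed = TRUE)
  ols <- lm(uf_burden ~ severity + sex + total_brain_volume_mm3 + age,
            data = tab)
  sm <- summary(ols)$coefficients["severity", ]
  expect_equal(m$estimate, unname(sm["Estimate"]), tolerance = 1e-6)
  expect_equal(m$T, unname(sm["t value"]), tolerance = 1e-6)
  expect_equal(m$p, unname(sm["Pr(>|t|)"]), tolerance = 1e-6)
})

test_that("the penalized spline captures a strong nonlinear age signal", {
  set.seed(13)
  tab <- simTable(300, beta = 0, seed = 13)
  tab$uf_burden <- 0.05 + 0.04 * sin(tab$age / 8) + rnorm(300, 0, 0.01)
  m <- fitBurdenGAM(tab, "uf_burden", "severity_ordinal", splineK = 8)
  # age smooth soaks up the signal; severity term stays null
  expect_gt(summary(m$fit)$r.sq, 0.5)
  expect_gt(m$p, 0.001)
})

test_that("diagnosis contrast uses only the none and severe strata", {
  tab <- simTable(200, beta = 0.03, seed = 4)
  m <- fitBurdenGAM(tab, "uf_burden", "diagnosis_binary")
  expect_equal(m$n, sum(tab$anxiety %in% c("none", "severe")))
  expect_gt(m$estimate, 0)
  expect_error(fitBurdenGAM(tab[tab$anxiety == "none", ], "uf_burden",
                            "severity_ordinal"), "2 predictor groups")
})

test_that("bootstrap f2 interval is ordered and degenerate at B = 1", {
  tab <- simTable(100, beta = 0.03, seed = 6)
  prep <- tractburden:::prepareGamData(tab, "uf_burden", "severity_ordinal")
  ci1 <- bootstrapF2CI(prep$data, "uf_burden", "pred", B = 1, seed = 9)
  expect_equal(ci1[1], ci1[2])
  ci <- bootstrapF2CI(prep$data, "uf_burden", "pred", B = 30, seed = 9)
  expect_lte(ci[1], ci[2])
  # same seed reproduces the interval
  expect_identical(ci, bootstrapF2CI(prep$data, "uf_burden", "pred",
                                     B = 30, seed = 9))
})

test_that("demographic battery matches textbook formulas", {
  tab <- simTable(180, seed = 7)
  rep <- demographicBattery(tab)
  expect_setequal(unique(rep$contrast), c("severity", "diagnosis"))

  # two-group ANOVA F equals t^2
  two <- tab[tab$anxiety %in% c("none", "severe"), ]
  fval <- summary(aov(age ~ anxiety, data = two))[[1]][1, "F value"]
  trow <- rep[rep$variable == "age" & rep$contrast == "diagnosis", ]
  expect_equal(fval, trow$statistic^2, tolerance = 1e-10)

  # 2x2 chi-squared (with continuity correction) against the hand formula
  t22 <- table(two$anxiety != "none", two$sex)[, 1:2]
  a <- t22[1, 1]; b <- t22[1, 2]; cc <- t22[2, 1]; d <- t22[2, 2]
  nn <- sum(t22)
  hand <- nn * (abs(a * d - b * cc) - nn / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  chrow <- rep[rep$variable == "sex" & rep$contrast == "diagnosis", ]
  expect_equal(chrow$statistic, unname(hand), tolerance = 1e-10)
})

test_that("PROMIS comparisons run the Shapiro/t battery with FDR", {
  set.seed(10)
  tab <- simTable(200, seed = 10)
  tab$promis_physical <- rnorm(200, 50 - tab$severity, 6)
  tab$promis_emotional <- rnorm(200, 50 - 4 * tab$severity, 6)
  res <- promisComparisons(tab)
  expect_true(all(c("group", "measure", "W", "p") %in% names(res$shapiro)))
  expect_true(all(res$contrasts$p_fdr >= res$contrasts$p - 1e-12))

  # paired t equals the closed form on a 5-pair hand example
  e <- c(48, 52, 47, 50, 49); ph <- c(50, 51, 49, 53, 50)
  dd <- e - ph
  tHand <- mean(dd) / (sd(dd) / sqrt(5))
  small <- data.frame(anxiety = "mild", promis_emotional = e,
                      promis_physical = ph)
  res2 <- promisComparisons(small)
  prow <- res2$contrasts[res2$contrasts$type == "paired", ]
  expect_equal(prow$T, tHand, tolerance = 1e-10)

  # identical summaries give a zero paired statistic
  same <- data.frame(anxiety = "none", promis_emotional = ph,
                     promis_physical = ph)
  res3 <- promisComparisons(same)
  expect_equal(res3$contrasts$T[res3$contrasts$type == "paired"], 0)
})

test_that("sensitivity suite reports the full model family with FDR", {
  tab <- simTable(250, beta = 0.03, seed = 11)
  tab$total_lesion_volume <- 4000 + 1500 * tab$severity + rnorm(250, 0, 800)
  res <- sensitivitySuite(tab)
  expect_equal(nrow(res), 6)
  expect_setequal(unique(res$outcome),
                  c("fornix_burden", "uf_burden", "total_lesion_volume"))
  tlv <- res[res$outcome == "total_lesion_volume", ]
  expect_true(all(tlv$significant))
  # determinism: identical table, identical report
  expect_identical(res, sensitivitySuite(tab))
})
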