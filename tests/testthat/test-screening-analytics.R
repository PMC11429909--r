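test_that("percent of control is mean-based and validates its inputs", {
  expect_equal(percentOfControl(c(35, 35), c(50, 50)), 70)
  expect_equal(percentOfControl(c(10, 20), c(20, 40)), 50)
  expect_error(percentOfControl(numeric(0), c(1)), "at least one")
  expect_error(percentOfControl(c(1), c(0, 0)), "positive")
  t <- list(counts = c(30), cell_line = "M14", day = 8)
  c8 <- list(counts = c(60), cell_line = "M14", day = 8)
  c14 <- list(counts = c(60), cell_line = "M14", day = 14)
  expect_equal(percentOfControl(t, c8), 50)
  expect_error(percentOfControl(t, c14), "disagree on day")
  cOther <- list(counts = c(60), cell_line = "HT29", day = 8)
  expect_error(percentOfControl(t, cOther), "disagree on cell_line")
})

test_that("assay percent-of-control matches the generating curve at cv = 0", {
  truth <- list(bottom = 0, top = 100, ic50 = 0.05, hill = -1.2)
  fx <- makeColonyData(params = truth, cv = 0, replicates = 2, seed = 4)
  pct <- assayPercentOfControl(fx$assays)
  doses <- pct$concentration_uM
  expected <- fourPL(doses, truth$bottom, truth$top, log10(truth$ic50),
                     truth$hill)
  # integer rounding of counts bounds the error: control mean is 250
  expect_equal(pct$pct, expected, tolerance = 0.01)
  expect_error(assayPercentOfControl(fx$assays[fx$assays$concentration_uM > 0, ]),
               "control")
})

test_that("efficacy ratios divide percent-of-control values and validate", {
  expect_equal(efficacyRatio(70, 70), 1)
  expect_equal(efficacyRatio(2.1, 70), 0.03)
  expect_error(efficacyRatio(50, 0), "positive")
})

test_that("activity classification is strict and ignores missing entries", {
  r <- matrix(c(0.49, 0.5, NA, 0.2), 2,
              dimnames = list(c("L1", "L2"), c("X-1", "X-2")))
  tab <- efficacyTable(r, 40)
  act <- classifyActive(tab)
  expect_true(act["L1", "X-1"])
  expect_false(act["L2", "X-1"])   # exactly 0.5 is not active
  expect_true(is.na(act["L1", "X-2"]))
  expect_equal(relativeActivity(tab, "X-1"), 50L)
  expect_equal(relativeActivity(tab, "X-2"), 100L)  # NA excluded from denominator
  expect_error(relativeActivity(tab, "nope"), "not in table")
})

test_that("relative activity rounds half-up like the printed tables", {
  # 5 of 8 lines active = 62.5% -> 63, where banker's rounding would give 62
  r <- matrix(c(rep(0.1, 5), rep(0.9, 3)), ncol = 1,
              dimnames = list(paste0("L", 1:8), "Y-1"))
  expect_equal(relativeActivity(efficacyTable(r, 40), "Y-1"), 63L)
})

test_that("site summary pools sub-cutoff ratios of active compounds", {
  r <- matrix(c(0.1, 0.3, 0.9,   # S-1: active (2 ratios pooled)
                0.7, 0.8, 0.6),  # S-2: inactive
              nrow = 3, dimnames = list(c("L1", "L2", "L3"), c("S-1", "S-2")))
  siteOf <- c("S-1" = "S", "S-2" = "S", "S-3" = "S")  # S-3 tested, not listed
  tab <- efficacyTable(r, 40, siteOf = siteOf)
  s <- siteSummary(tab)
  expect_equal(s$tested, 3)
  expect_equal(s$pct_active_compounds, 33)   # 1 of 3, half-up
  expect_equal(s$pooled_mean, 0.2)
  expect_equal(s$pooled_sem, sd(c(0.1, 0.3)) / sqrt(2))
  expect_equal(s$pooled_n, 2)
  expect_equal(s$activity_min, 67L)          # 2/3 lines, half-up
  # single pooled ratio reports SEM 0; empty sites report NA
  r1 <- matrix(c(0.2, 0.9), 1, dimnames = list("L1", c("A-1", "B-1")))
  s1 <- siteSummary(efficacyTable(r1, 40))
  expect_equal(s1$pooled_sem[s1$site == "A"], 0)
  expect_true(is.na(s1$pooled_mean[s1$site == "B"]))
})

test_that("marrow toxicity flags use strict thresholds on inhibition", {
  day8 <- c(a = 90, b = 89.9, c = 70, d = 110, e = 69.9)
  fl <- marrowToxicityFlags(day8)
  expect_equal(unname(fl$counts), c(3L, 1L))
  expect_equal(fl$flagged$over_10, c("b", "c", "e"))  # a at exactly 10% is not flagged
  expect_equal(fl$flagged$over_30, "e")
  expect_error(marrowToxicityFlags(unname(day8)), "named")
})

test_that("4PL fit recovers exact parameters from noiseless data", {
  d <- c(0.0061, 0.018, 0.05, 0.16, 0.49, 1.48, 4.44, 13.33, 40)
  y <- fourPL(d, 5, 98, log10(0.12), -0.9)
  f <- fit4PL(c(0, d), c(100, y))   # zero dose excluded automatically
  expect_equal(ic50(f), 0.12, tolerance = 1e-6)
  expect_equal(hillSlope(f), -0.9, tolerance = 1e-6)
  expect_equal(f@bottom, 5, tolerance = 1e-5)
  expect_equal(f@top, 98, tolerance = 1e-5)
  expect_true(f@convergence$converged)
  expect_lte(f@bottom, f@top)
})

test_that("4PL fit validates its inputs", {
  expect_error(fit4PL(c(1, 2, 3), c(1, 2)), "equal length")
  expect_error(fit4PL(c(1, 2, 3), c(10, 20, 30)), "at least 4 distinct")
  d <- c(0.1, 1, 10, 100)
  expect_error(fit4PL(d, rep(50, 4)), "flat")
})

test_that("rising curves fit with positive slope and canonical asymptotes", {
  d <- c(0.1, 0.3, 1, 3, 10, 30)
  y <- fourPL(d, 2, 90, log10(2), 1.5)   # agonist-style increase
  f <- fit4PL(d, y)
  expect_gt(hillSlope(f), 0)
  expect_lte(f@bottom, f@top)
  expect_equal(ic50(f), 2, tolerance = 1e-5)
})
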