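test_that("drug-likeness window boundaries behave as documented", {
  recs <- data.frame(
    compound_id = c("mwLo", "mwEdgeLo", "mwEdgeHi", "mwHi", "tpsaEdge",
                    "hbdEdge", "hbaEdge", "ok", "missing"),
    mw = c(159.9, 160, 480, 480.1, 300, 300, 300, 300, NA),
    tpsa = c(50, 50, 50, 50, 140, 50, 50, 139.9, 50),
    hbd = c(1, 1, 1, 1, 1, 5, 1, 4, 1),
    hba = c(2, 2, 2, 2, 2, 2, 10, 9, 2),
    stringsAsFactors = FALSE)
  out <- druglikeFilter(recs)
  expect_setequal(out$kept$compound_id, c("mwEdgeLo", "mwEdgeHi", "ok"))
  rej <- setNames(out$rejected$reasons, out$rejected$compound_id)
  expect_equal(rej[["mwLo"]], "mw_out_of_range")
  expect_equal(rej[["tpsaEdge"]], "tpsa_too_high")
  expect_equal(rej[["hbdEdge"]], "too_many_hbd")
  expect_equal(rej[["hbaEdge"]], "too_many_hba")
  expect_equal(rej[["missing"]], "missing_property")
})

test_that("multiple violations are all reported", {
  recs <- data.frame(compound_id = "bad", mw = 900, tpsa = 200, hbd = 9,
                     hba = 14)
  out <- druglikeFilter(recs)
  expect_equal(out$rejected$reasons,
               "mw_out_of_range;tpsa_too_high;too_many_hbd;too_many_hba")
  expect_error(druglikeFilter(recs[0, ]), "non-empty")
  expect_error(druglikeFilter(data.frame(compound_id = "x")), "lack")
})

test_that("ranks are dense with ties sharing a rank", {
  r <- rankWithinStage(c(a = -9.1, b = -7.0, c = -9.1, d = -8))
  expect_equal(r, c(a = 1L, b = 3L, c = 1L, d = 2L))
  rHigh <- rankWithinStage(c(a = 5, b = 9), lowerIsBetter = FALSE)
  expect_equal(rHigh, c(a = 2L, b = 1L))
  expect_error(rankWithinStage(c(a = 1, a = 2)), "duplicate")
})

test_that("funnel equals the generator's exhaustive cut composition", {
  for (seed in c(2, 9, 17)) {
    fx <- makeScoreTables(80, stages = 3, seed = seed)
    final <- runFunnel(fx$stageTables, fx$spec)
    truth <- fx$manifest$ground_truth$survivors
    # survivors of the last stage, ordered by that stage's ranking
    expect_setequal(as.character(final), truth[[3]])
    # every final compound survived all previous stages
    expect_true(all(final %in% truth[[2]]))
    expect_true(all(final %in% truth[[1]]))
  }
})

test_that("keepFraction cuts by ceiling and finalK truncates", {
  scores <- setNames(seq_len(10), sprintf("c%02d", 1:10))
  spec <- funnelSpec(list(list(name = "s1", keepFraction = 0.25)), finalK = 2)
  out <- runFunnel(list(scores), spec)
  # ceiling(0.25 * 10) = 3 survive, finalK = 2 truncates
  expect_equal(as.character(out), c("c01", "c02"))
})

test_that("stage-one union of method tables and later-stage drops", {
  t1a <- c(a = 1, b = 2, c = 3, d = 4)
  t1b <- c(a = 4, b = 3, c = 2, d = 1)
  t2 <- c(a = 1, d = 2)  # b, c unscored -> dropped with a message
  spec <- funnelSpec(list(list(name = "dock", keepCount = 1),
                          list(name = "rescore", keepCount = 2)),
                     finalK = 10)
  out <- runFunnel(list(list(t1a, t1b), t2), spec)
  expect_setequal(as.character(out), c("a", "d"))
  # survivors of stage 1 are the union {a, d}; b and c were cut, not dropped
  expect_equal(attr(out, "dropped"), character(0))
  # a surviving compound missing a later-stage score is dropped with a message
  t2miss <- c(a = 1)
  expect_message(out2 <- runFunnel(list(list(t1a, t1b), t2miss), spec),
                 "dropped")
  expect_equal(attr(out2, "dropped"), "d")
})

test_that("funnel spec validation", {
  expect_error(funnelSpec(list(list(keepCount = 1))), "name")
  expect_error(funnelSpec(list(list(name = "x"))), "keepCount or keepFraction")
  expect_error(funnelSpec(list(list(name = "x", keepFraction = 1.2))),
               "keepFraction")
  expect_error(funnelSpec(list(list(name = "x", keepCount = 2)), finalK = 0),
               "finalK")
  spec <- funnelSpec(list(list(name = "a", keepCount = 2),
                          list(name = "b", keepCount = 1)))
  expect_error(runFunnel(list(c(x = 1)), spec), "expected 2 stages")
  expect_error(runFunnel(list(c(x = 1), list(c(x = 1), c(x = 2))), spec),
               "first stage")
})

test_that("compound tables read with sniffed delimiter", {
  df <- data.frame(compound_id = c("a", "b"), score = c(1.5, -2))
  p1 <- tempfile(fileext = ".csv"); write.csv(df, p1, row.names = FALSE)
  p2 <- tempfile(fileext = ".tsv")
  write.table(df, p2, sep = "\t", row.names = FALSE)
  expect_equal(readCompoundTable(p1), df)
  expect_equal(readCompoundTable(p2), df)
  expect_error(readCompoundTable(tempfile()), "not found")
})
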