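test_that("Shannon entropy closed forms", {
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_equal(shannonEntropy(c(0.5, 0.5)), log(2))
  expect_equal(shannonEntropy(rep(1 / 26, 26)), log(26))
  expect_error(shannonEntropy(c(0.7, 0.4)), "sum to 1")
  expect_error(shannonEntropy(c(1.2, -0.2)), "non-negative")
})

test_that("JSD limiting cases and agreement with direct formula evaluation", {
  u <- c(0.3, 0.2, 0.5)
  expect_equal(jsd(rbind(u, u, u), rep(1 / 3, 3)), 0)
  expect_equal(jsd(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5)), log(2))
  d <- list(c(0.5, 0.5), c(1, 0), c(0.5, 0.5))
  expect_equal(jsd(d, rep(1 / 3, 3)), oracleJsd(d, rep(1 / 3, 3)),
               tolerance = 1e-12)
  expect_gte(jsd(d, rep(1 / 3, 3)), 0)
  expect_error(jsd(list(c(0.5, 0.5), c(1, 0, 0))), "common support")
  expect_error(jsd(rbind(u, u), c(0.9, 0.2)), "sum to 1")
})

test_that("UC-JSD normalization, bounds and invariances", {
  # constant vectors (any constants): all three normalize to uniform -> 0
  expect_equal(ucJsd(rep(2, 7), rep(0.1, 7), rep(31, 7)), 0)
  # identical element-wise vectors -> 0
  v <- c(1, 2, 3, 4)
  expect_equal(ucJsd(v, v, v), 0)
  # positive for differing profiles, matches direct evaluation
  tr <- c(1, 1); va <- c(2, 1e-6); sa <- c(1, 1)
  got <- ucJsd(tr, va, sa)
  expect_gt(got, 0)
  expect_equal(got, oracleJsd(list(tr / sum(tr), va / sum(va), sa / sum(sa)),
                              rep(1 / 3, 3)), tolerance = 1e-12)
  # bounded by log(3); invariant under scaling ONE vector
  set.seed(5)
  for (i in 1:50) {
    a <- runif(20); b <- runif(20); c <- runif(20)
    x <- ucJsd(a, b, c)
    expect_gte(x, 0); expect_lte(x, log(3))
    expect_equal(ucJsd(7.3 * a, b, c), x, tolerance = 1e-12)
  }
  # NOT invariant under a common shift
  a <- c(1, 5); b <- c(2, 2); c <- c(4, 1)
  expect_false(isTRUE(all.equal(ucJsd(a + 10, b + 10, c + 10),
                                ucJsd(a, b, c))))
  expect_error(ucJsd(c(1, 2), c(1, 2, 3), c(1, 2)), "same length")
  expect_error(ucJsd(c(0, 0), c(1, 1), c(1, 1)), "positive sums")
})

test_that("phi closed form, edge cases and Monte-Carlo agreement", {
  expect_equal(phi(1, 10), 0.1)
  expect_equal(phi(0, 100), 0)
  expect_equal(phi(5, 1), 1)
  expect_equal(phi(4, 4), 175 / 256)
  ks <- c(10, 100, 1000, 1e4, 1e6)
  expect_true(all(diff(phi(ks, 1000)) > 0))
  # Monte-Carlo birthday-sampling oracle
  set.seed(17)
  for (k in c(100, 1000, 10000)) {
    fr <- replicate(200, length(unique(sample.int(1000, k,
                                                  replace = TRUE))) / 1000)
    expect_lt(abs(mean(fr) - phi(k, 1000)),
              3 * sd(fr) / sqrt(length(fr)) + 1e-12)
  }
})

test_that("sample evaluation reproduces hand arithmetic and count chains", {
  sp <- chemicalSpace(c("C", "CC", "CCC", "CCCC"))   # N = 4
  ev <- evaluateSample(c("C", "C", "CC", "C1CC"), sp)  # invalid 4th
  expect_equal(ev@ratioValid, 0.75)
  expect_equal(ev@closedness, 0.75)
  expect_equal(ev@ratioUnique, 0.5)
  expect_equal(ev@completeness, 0.5 / phi(4, 4), tolerance = 1e-12)
  expect_equal(ev@uniformity, 0.5 / phi(3, 4), tolerance = 1e-12)
  expect_equal(ev@ucc, ev@completeness * ev@uniformity * 0.75,
               tolerance = 1e-12)
  expect_equal(ucc(ev), ev@ucc)
  # degenerate model: one in-space molecule repeated k times
  ev2 <- evaluateSample(rep("CC", 40), sp)
  expect_equal(ev2@ratioUnique, 1 / 4)
  expect_equal(ev2@closedness, 1)
  expect_equal(ev2@completeness, (1 / 4) / phi(40, 4))
  # fuzzed count chain n_unique <= n_in <= n_valid <= k
  set.seed(23)
  pool <- c("C", "CC", "CCC", "CCCC", "CCCCC", "C#C", "zz", "C1CC", NA)
  for (i in 1:25) {
    s <- sample(pool, sample(3:30, 1), replace = TRUE)
    if (all(is.na(s))) next
    e <- evaluateSample(s, sp)
    expect_true(e@nUnique <= e@nIn && e@nIn <= e@nValid && e@nValid <= e@k)
    expect_equal(e@ratioIn, e@closedness)
  }
  # all-invalid sample
  e0 <- evaluateSample(c("xx", "yy"), sp)
  expect_equal(c(e0@nValid, e0@nIn, e0@nUnique, e0@ucc), c(0, 0, 0, 0))
})

test_that("UCC is the plain three-way product", {
  expect_equal(ucc(0.5, 0.5, 0.5), 0.125)
  expect_equal(ucc(0.9, 0, 0.9), 0)
})

test_that("evaluation report JSON carries the full schema", {
  sp <- chemicalSpace(c("C", "CC"))
  f <- tempfile(fileext = ".json")
  writeEvaluationReport(evaluateSample(c("C", "C", "CC"), sp), f)
  rep <- jsonlite::read_json(f)
  expect_setequal(names(rep),
                  c("k", "n_valid", "n_in", "n_unique", "ratio_valid",
                    "ratio_in", "ratio_unique", "completeness", "uniformity",
                    "closedness", "ucc", "space_size", "phi_k", "phi_in"))
})

test_that("molecule NLL aggregates string probabilities correctly", {
  vocab <- spaceVocabulary(spaceSmall())
  model <- smilesRNN(vocab, layers = 1, width = 12, seed = 6, maxLen = 30)
  # single-writing molecule: molecule NLL is the string NLL
  expect_equal(moleculeNll(model, "C", "randomized_restricted", "exact"),
               sequenceNll(model, "C"))
  expect_equal(moleculeNll(model, "OCC", "canonical"),
               sequenceNll(model, "CCO"))
  # exact <= estimate for any budget (more strings, more probability mass)
  ex <- moleculeNll(model, "OCC", "randomized_restricted", "exact")
  for (budget in c(1, 3, 50)) {
    expect_gte(moleculeNll(model, "OCC", "randomized_restricted", "estimate",
                           budget = budget, seed = 2) + 1e-12, ex)
  }
  expect_error(moleculeNll(model, "OCC", mode = "estimate", budget = 0),
               "budget")
  # brute-force oracle: per-string probabilities via repeated forwardStep
  strs <- enumerateRandomSmiles("OCC", "randomized_restricted")
  pTot <- 0
  for (s in strs) {
    enc <- encodeTokens(tokenizeSmiles(s), vocab)
    st <- NULL; p <- 1
    for (t in seq_len(length(enc) - 1L)) {
      fs <- forwardStep(model, enc[t], st)
      p <- p * fs$probs[1, enc[t + 1L]]
      st <- fs$state
    }
    pTot <- pTot + p
  }
  expect_equal(ex, -log(pTot), tolerance = 1e-6)
})
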