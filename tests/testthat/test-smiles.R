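aspirin <- "CC(=O)Oc1ccccc1C(=O)O"

test_that("canonicalization is idempotent and returns failure values for bad input", {
  expect_equal(canonicalizeSmiles("OCC"), "CCO")
  expect_equal(canonicalizeSmiles("C"), "C")
  expect_true(is.na(canonicalizeSmiles("C1CC")))    # unclosed ring
  expect_true(is.na(canonicalizeSmiles("C(C")))     # unclosed branch
  expect_true(is.na(canonicalizeSmiles("CC(C)(C)(C)C")))  # valence
  expect_true(is.na(canonicalizeSmiles("xyz")))
  for (s in c("OCC", aspirin, "c1ccccc1", "C/C=C/C", "[O-]C(=O)C")) {
    canon <- canonicalizeSmiles(s)
    expect_identical(canonicalizeSmiles(canon), canon)
  }
})

test_that("canonical strings are invariant under atom reordering", {
  mols <- c(aspirin, "c1ccoc1", "N#Cc1ccccc1", spaceMembers(spaceSmall()))
  for (m in mols) {
    canon <- canonicalizeSmiles(m)
    rand <- vapply(1:8, function(s)
      randomizeSmiles(canon, "randomized_restricted", s), character(1))
    expect_identical(unique(canonicalizeSmiles(rand)), canon)
  }
})

test_that("randomized strings preserve the molecular graph per an external toolkit", {
  skip_if_not_installed("ChemmineOB")
  set.seed(3)
  mols <- sample(spaceMembers(spaceMedium()), 25)
  for (m in c(mols, canonicalizeSmiles(aspirin))) {
    strs <- c(m,
              vapply(1:4, function(s)
                randomizeSmiles(m, "randomized_restricted", s), character(1)),
              vapply(1:4, function(s)
                randomizeSmiles(m, "randomized_unrestricted", s),
                character(1)))
    expect_length(unique(obCanonical(strs)), 1L)
  }
})

test_that("exhaustive enumeration matches sampled randomization and the n! bound", {
  # only one writing of a single atom
  expect_equal(enumerateRandomSmiles("C", "randomized_restricted"), "C")
  expect_equal(randomizeSmiles("C", "randomized_unrestricted", 99L), "C")
  # the distinct strings over many seeds equal the exhaustive permutation set
  ex <- enumerateRandomSmiles("CCO", "randomized_restricted")
  sampled <- unique(vapply(1:300, function(s)
    randomizeSmiles("CCO", "randomized_restricted", s), character(1)))
  expect_setequal(sampled, ex)
  # unrestricted CCO: all 6 orderings give distinct literal writings
  exU <- enumerateRandomSmiles("CCO", "randomized_unrestricted")
  expect_setequal(exU, c("CCO", "OCC", "C(C)O", "C(O)C", "CC(O)", "OC(C)"))
  expect_true(all(ex %in% exU))
  # n! bound
  for (m in sample(spaceMembers(spaceMedium()), 20)) {
    n <- heavyAtomCount(m)
    expect_lte(length(enumerateRandomSmiles(m, "randomized_unrestricted")),
               factorial(n))
  }
  expect_error(enumerateRandomSmiles("CCCCCCCCO", maxHeavyAtoms = 8),
               "countRandomSmiles")
})

test_that("sampled distinct-count estimates are deterministic lower bounds", {
  expect_equal(countRandomSmiles("C", nDraws = 100, seed = 1), 1L)
  ex <- length(enumerateRandomSmiles("CC=O", "randomized_restricted"))
  cnt <- countRandomSmiles("CC=O", "randomized_restricted",
                           nDraws = 50L * 6L, seed = 2)
  expect_equal(cnt, ex)   # coupon-collector regime: 50 n! draws
  expect_lte(countRandomSmiles("CC=O", "randomized_restricted",
                               nDraws = 3, seed = 5), ex)
  expect_identical(countRandomSmiles(aspirin, nDraws = 40, seed = 7),
                   countRandomSmiles(aspirin, nDraws = 40, seed = 7))
})

test_that("the unrestricted writer emits ring-into-branch forms the restricted one never does", {
  benz <- "c1ccccc1"
  er <- enumerateRandomSmiles(benz, "randomized_restricted", 6)
  eu <- enumerateRandomSmiles(benz, "randomized_unrestricted", 6)
  expect_true(all(er %in% eu))
  expect_gt(length(eu), length(er))
  # the redundant-branch family c1cc(c(cc1)) exists only unrestricted
  expect_false(any(grepl("(", er, fixed = TRUE)))
  expect_true("c1cc(c(cc1))" %in% eu)
  expect_identical(unique(canonicalizeSmiles(eu)), canonicalizeSmiles(benz))
})

test_that("parse-level validity screens valence and syntax", {
  expect_true(all(isValidSmiles(c("CCO", "c1ccccc1", "[nH]1cccc1",
                                  "[O-]C=O", "C#N"))))
  expect_false(any(isValidSmiles(c("C1CC", "C(((", "O=C=O=C", "CC(C)(C)(C)C",
                                   ""))))
  expect_equal(heavyAtomCount(c("CCO", aspirin, "bogus")), c(3L, 13L, NA))
})
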