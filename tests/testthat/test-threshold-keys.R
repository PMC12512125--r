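test_that("full additive committee reconstructs; partial sets do not", {
  t <- 97
  bk <- mockBackend(smallParams(t = t), seed = 1)
  keys <- dkg(bk, committeeConfig(4, 4), seed = 42)
  v <- c(7, 0, 3)
  ct <- heEncrypt(bk, v, keys$pk)
  partials <- lapply(keys$shares, function(s) partialDecrypt(bk, ct, s))
  expect_equal(combinePartials(partials, t = t)[1:3], v)
  # any 3 of 4: combine refuses, and the naive sum is not the plaintext
  for (drop in 1:4) {
    sub3 <- partials[-drop]
    expect_error(combinePartials(sub3, t = t), "quorum not met")
    naive <- Reduce(`+`, lapply(sub3, function(p) p@payload)) %% t
    expect_false(all(naive[1:3] == v))
  }
})

test_that("two additive partials sum mod t to the plaintext", {
  t <- 101
  bk <- mockBackend(smallParams(t = t), seed = 2)
  keys <- dkg(bk, committeeConfig(2, 2), seed = 5)
  v <- c(42, 0, 100)
  ct <- heEncrypt(bk, v, keys$pk)
  partials <- lapply(keys$shares, function(s) partialDecrypt(bk, ct, s))
  expect_equal((partials[[1]]@payload + partials[[2]]@payload)[1:3] %% t, v)
})

test_that("any quorum of Shamir shares reconstructs; fewer never do", {
  t <- 257
  bk <- mockBackend(smallParams(t = t), seed = 3)
  keys <- dkg(bk, committeeConfig(5, 3), seed = 9)
  v <- sample(0:(t - 1), 8)
  ct <- heEncrypt(bk, v, keys$pk)
  partials <- lapply(keys$shares, function(s) partialDecrypt(bk, ct, s))
  subsets <- utils::combn(5, 3)
  for (k in seq_len(ncol(subsets)))
    expect_equal(combinePartials(partials[subsets[, k]], t = t), v)
  # all five together also works (overdetermined interpolation)
  expect_equal(combinePartials(partials, t = t), v)
  expect_error(combinePartials(partials[1:2], t = t), "quorum not met")
})

test_that("a single share reveals nothing: residuals are ring-uniform", {
  t <- 101
  bk <- mockBackend(smallParams(t = t, slotCount = 64L), seed = 4)
  keys <- dkg(bk, committeeConfig(5, 3), seed = 7)
  set.seed(21)
  resid <- c()
  for (i in 1:200) {
    v <- sample(0:(t - 1), 64, replace = TRUE)
    ct <- heEncrypt(bk, v, keys$pk)
    p <- partialDecrypt(bk, ct, keys$shares[[1]])
    expect_false(all(p@payload == v))
    resid <- c(resid, (p@payload - v) %% t)
  }
  # blinding term share*h with h uniform over [1, t-1]: chi-square sanity
  obs <- tabulate(resid, nbins = t - 1)   # residual 0 impossible
  chi <- sum((obs - length(resid) / (t - 1))^2 / (length(resid) / (t - 1)))
  expect_lt(chi, qchisq(1 - 1e-6, df = t - 2))
})

test_that("distributed keygen is deterministic under a fixed seed", {
  bk <- mockBackend(smallParams(), seed = 5)
  k1 <- dkg(bk, committeeConfig(4, 4), seed = 77)
  k2 <- dkg(bk, committeeConfig(4, 4), seed = 77)
  expect_equal(lapply(k1$shares, function(s) s@value),
               lapply(k2$shares, function(s) s@value))
  expect_equal(k1$pk@keyId, k2$pk@keyId)
  k3 <- dkg(bk, committeeConfig(4, 4), seed = 78)
  expect_false(identical(lapply(k1$shares, function(s) s@value),
                         lapply(k3$shares, function(s) s@value)))
})

test_that("protocol errors: digest binding, duplicates, key mismatch", {
  t <- 97
  bk <- mockBackend(smallParams(t = t), seed = 6)
  keys <- dkg(bk, committeeConfig(3, 3), seed = 1)
  ct1 <- heEncrypt(bk, c(1, 2, 3), keys$pk)
  ct2 <- heEncrypt(bk, c(4, 5, 6), keys$pk)
  p1 <- lapply(keys$shares, function(s) partialDecrypt(bk, ct1, s))
  p2 <- partialDecrypt(bk, ct2, keys$shares[[3]])
  expect_error(combinePartials(c(p1[1:2], list(p2)), t = t),
               "different ciphertexts")
  expect_error(combinePartials(c(p1[1:2], p1[1]), t = t), "duplicate")
  other <- keygen(bk)
  ctO <- heEncrypt(bk, c(1), other$pk)
  expect_error(partialDecrypt(bk, ctO, keys$shares[[1]]), "protocol error")
})

test_that("committee decryption of a filtering circuit equals the single-key path", {
  params <- smallParams(t = 257, slotCount = 8L)
  roles <- trioRoles()
  spec <- simSpec(14, roles, "recessive", nImplanted = 2, seed = 31)
  cohort <- generateCohort(spec)
  # single-key route
  single <- runBothMethods(cohort$channels, recessiveQuery(roles), params)
  # committee route over the same circuit
  bk <- mockBackend(params, seed = 1)
  keys <- dkg(bk, committeeConfig(4, 4), seed = 2)
  enc <- encryptCohort(bk, packBlocks(cohort$channels, 8L), keys$pk)
  eq <- encryptQuery(bk, recessiveQuery(roles), keys$pk)
  out <- filterMulInRD(bk, enc, eq, keys$pk)
  partials <- lapply(keys$shares, function(s)
    partialDecrypt(bk, out@payload[[1]], s))
  expect_equal(decodeCountMulIn(combinePartials(partials, t = 257)),
               single$mulCount)
})

test_that("key shares round-trip through their serialized form", {
  bk <- mockBackend(smallParams(), seed = 7)
  keys <- dkg(bk, committeeConfig(3, 2, mode = "shamir"), seed = 3)
  path <- tempfile(fileext = ".json")
  writeKeyShare(keys$shares[[2]], path)
  back <- readKeyShare(path)
  expect_equal(back@value, keys$shares[[2]]@value)
  expect_equal(back@x, keys$shares[[2]]@x)
  expect_equal(back@mode, "shamir")
})
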