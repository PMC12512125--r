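test_that("the equality indicator is 1 iff variant equals query", {
  bk <- mockBackend(smallParams(slotCount = 8L), seed = 1)
  keys <- keygen(bk)
  one <- heEncrypt(bk, rep(1, 8), keys$pk)
  v <- heEncrypt(bk, c(1, 1, 0, 0), keys$pk)
  q <- heEncrypt(bk, c(1, 0, 1, 0), keys$pk)
  ind <- matchIndicator(bk, v, q, one)
  expect_equal(heDecrypt(bk, ind, keys$sk)[1:4], c(1, 0, 0, 1))
  # exact per-call cost: 1 multiplication, 2 subtractions + 1 addition
  resetOpCounts(bk)
  matchIndicator(bk, v, q, one)
  oc <- opCounts(bk)
  expect_equal(oc@ctMultiplications, 1)
  expect_equal(oc@ctAdditions, 3)
  # random bit vectors: indicator == elementwise equality
  set.seed(5)
  for (i in 1:100) {
    a <- sample(0:1, 8, replace = TRUE); b <- sample(0:1, 8, replace = TRUE)
    ind <- matchIndicator(bk, heEncrypt(bk, a, keys$pk),
                          heEncrypt(bk, b, keys$pk), one)
    expect_equal(heDecrypt(bk, ind, keys$sk), as.numeric(a == b))
  }
})

test_that("a trio with one matching variant yields count 1 by both methods", {
  params <- smallParams(t = 97, slotCount = 8L)
  # 6 variants: row 2 is the exact recessive pattern M=het F=het P=hom
  codes <- rbind(c(0, 0, 0), c(1, 1, 2), c(1, 1, 1),
                 c(2, 2, 2), c(0, 1, 2), c(1, 1, 0))
  colnames(codes) <- c("M", "F", "P")
  r <- runBothMethods(codesToChannels(codes), recessiveQuery(trioRoles()),
                      params)
  expect_equal(r$mulCount, 1L)
  expect_equal(r$addCount, 1L)
  # all-reference data matches nothing
  ref <- matrix(0, 6, 3, dimnames = list(NULL, c("M", "F", "P")))
  r0 <- runBothMethods(codesToChannels(ref), recessiveQuery(trioRoles()),
                       params)
  expect_equal(r0$mulCount, 0L)
  expect_equal(r0$addCount, 0L)
})

test_that("multi-block filtering with padding matches the plaintext oracle", {
  params <- smallParams(t = 257, slotCount = 8L)
  roles <- trioRoles(extraUnaffected = 1)
  set.seed(9)
  for (trial in 1:10) {
    n <- sample(c(5, 8, 19, 24), 1)     # exercises partial and exact blocks
    codes <- matrix(sample(0:2, n * 4, replace = TRUE, prob = c(.6, .3, .1)),
                    nrow = n, dimnames = list(NULL, roles$sampleId))
    ch <- codesToChannels(codes)
    q <- recessiveQuery(roles)
    truth <- sum(referenceFilter(ch, q))
    r <- runBothMethods(ch, q, params, seed = trial)
    expect_equal(r$mulCount, truth)
    expect_equal(r$addCount, truth)
    expect_equal(length(r$outAdd@payload), ceiling(n / 8))
  }
})

test_that("de novo circuits count variants shared by affected, absent in unaffected", {
  params <- smallParams(t = 257, slotCount = 8L)
  roles <- cohortRoles(c("A1", "A2", "U1"),
                       c("affected", "affected", "unaffected"))
  part <- deNovoPartition(roles)
  # row 1: both affected het, unaffected ref -> passes
  # row 2: mixed het/hom among affected -> fails (no shared class)
  # row 3: all three het -> fails (present in unaffected)
  # row 4: both affected hom, unaffected ref -> passes via first channel
  codes <- rbind(c(1, 1, 0), c(1, 2, 0), c(1, 1, 1), c(2, 2, 0))
  colnames(codes) <- roles$sampleId
  ch <- codesToChannels(codes)
  r <- runBothMethods(ch, part, params)
  expect_equal(r$mulCount, 2L)
  expect_equal(r$addCount, 2L)
  expect_equal(referenceFilter(ch, part), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("de novo passes first channel even when an unaffected sample is het", {
  # characterization of the circuit algebra: all affected homozygous and an
  # unaffected heterozygous still passes on the homozygous channel, because
  # each channel tests presence/absence of its own genotype class only
  params <- smallParams(t = 257, slotCount = 8L)
  roles <- cohortRoles(c("A1", "A2", "U1"),
                       c("affected", "affected", "unaffected"))
  codes <- matrix(c(2, 2, 1), 1, dimnames = list(NULL, roles$sampleId))
  r <- runBothMethods(codesToChannels(codes), deNovoPartition(roles), params)
  expect_equal(r$mulCount, 1L)
  expect_equal(r$addCount, 1L)
})

test_that("de novo supports u = 0 and a = 1 edge cohorts", {
  params <- smallParams(t = 257, slotCount = 8L)
  roles <- cohortRoles(c("A1", "A2"), c("affected", "affected"))
  codes <- rbind(c(1, 1), c(1, 0), c(2, 2))
  colnames(codes) <- roles$sampleId
  r <- runBothMethods(codesToChannels(codes), deNovoPartition(roles), params)
  expect_equal(r$mulCount, 2L)
  expect_equal(r$addCount, 2L)
  one <- cohortRoles("A1", "affected")
  codes1 <- matrix(c(1, 0, 2), 3, 1, dimnames = list(NULL, "A1"))
  r1 <- runBothMethods(codesToChannels(codes1), deNovoPartition(one), params)
  expect_equal(r1$mulCount, 2L)
})

test_that("MUL-IN and ADD-IN agree with the oracle on random cohorts", {
  params <- smallParams(t = 65537, slotCount = 16L)
  set.seed(17)
  for (trial in 1:15) {
    extra <- sample(0:2, 1)
    roles <- trioRoles(extraUnaffected = extra)
    n <- sample(10:60, 1)
    codes <- matrix(sample(0:2, n * nrow(roles), replace = TRUE,
                           prob = c(.7, .2, .1)),
                    nrow = n, dimnames = list(NULL, roles$sampleId))
    ch <- codesToChannels(codes)
    for (q in list(recessiveQuery(roles), dominantQuery(
           cohortRoles(roles$sampleId,
                       ifelse(roles$role == "proband", "affected",
                              "unaffected"))))) {
      truth <- sum(referenceFilter(ch, q))
      r <- runBothMethods(ch, q, params, seed = trial)
      expect_equal(r$mulCount, truth)
      expect_equal(r$addCount, truth)
    }
  }
})

test_that("masking and shuffling preserve zeros and their multiset", {
  params <- smallParams(t = 97, slotCount = 8L)
  bk <- mockBackend(params, seed = 3)
  keys <- keygen(bk)
  set.seed(23)
  resid <- lapply(1:4, function(i)
    heEncrypt(bk, sample(c(0, 0, 5, 9, 0, 1, 96, 3)), keys$pk))
  plainZeros <- sum(vapply(resid, function(ct)
    sum(heDecrypt(bk, ct, keys$sk) == 0), numeric(1)))
  out <- maskAndShuffle(bk, resid, keys$pk, maskSpec(7))
  dec <- lapply(out, function(ct) heDecrypt(bk, ct, keys$sk))
  expect_equal(sum(vapply(dec, function(p) sum(p == 0), numeric(1))),
               plainZeros)
  # every nonzero survives as nonzero (mask is never 0 mod a prime)
  expect_equal(sum(unlist(dec) != 0), 32 - plainZeros)
  expect_length(out, 4)
})

test_that("masked nonzero residuals are uniform over the nonzero ring", {
  t <- 97
  params <- smallParams(t = t, slotCount = 64L)
  bk <- mockBackend(params, seed = 4)
  keys <- keygen(bk)
  # constant nonzero residual blocks; the mask alone must spread them
  resid <- lapply(1:160, function(i) heEncrypt(bk, rep(5, 64), keys$pk))
  out <- maskAndShuffle(bk, resid, keys$pk, maskSpec(11))
  draws <- unlist(lapply(out, function(ct) heDecrypt(bk, ct, keys$sk)))
  expect_gte(length(draws), 1e4)
  expect_true(all(draws != 0))
  obs <- tabulate(draws, nbins = t - 1)
  expected <- length(draws) / (t - 1)
  chi <- sum((obs - expected)^2 / expected)
  expect_lt(chi, qchisq(1 - 1e-6, df = t - 2))
})

test_that("decode helpers enforce their integrity invariants", {
  expect_equal(decodeCountMulIn(rep(5, 4)), 5L)
  expect_equal(decodeCountMulIn(rep(0, 4)), 0L)
  expect_error(decodeCountMulIn(c(5, 4, 5, 5)), "integrity")
  expect_equal(decodeCountAddIn(list(c(0, 917, 0, 4411))), 2L)
  expect_equal(decodeCountAddIn(list(c(3, 1), c(9, 2))), 0L)
  expect_error(decodeCountAddIn(list(c(0, 0, 0)), validSlotTotal = 2),
               "integrity")
})

test_that("filter preconditions and depth budget are enforced", {
  roles <- trioRoles()
  codes <- matrix(0, 4, 3, dimnames = list(NULL, roles$sampleId))
  ch <- codesToChannels(codes)
  # ADD-IN needs depth 2: budget 1 must fail with a noise error
  params1 <- smallParams(t = 97, slotCount = 8L, depthBudget = 1L)
  vb <- packBlocks(ch, 8L)
  bk <- mockBackend(params1, seed = 1)
  keys <- keygen(bk)
  enc <- encryptCohort(bk, vb, keys$pk)
  eq <- encryptQuery(bk, recessiveQuery(roles), keys$pk)
  expect_error(filterAddInRD(bk, enc, eq, keys$pk), "noise budget")
  # modulus too small for the cohort
  roles17 <- cohortRoles(sprintf("A%d", 1:60), rep("affected", 60))
  expect_error({
    params <- smallParams(t = 97, slotCount = 8L)
    bk2 <- mockBackend(params, seed = 1)
    k2 <- keygen(bk2)
    codes60 <- matrix(0, 2, 60, dimnames = list(NULL, roles17$sampleId))
    enc2 <- encryptCohort(bk2, packBlocks(codesToChannels(codes60), 8L), k2$pk)
    eq2 <- encryptQuery(bk2, dominantQuery(roles17), k2$pk)
    filterAddInRD(bk2, enc2, eq2, k2$pk)
  }, "modulus")
})

test_that("query/cohort compatibility is checked", {
  params <- smallParams(t = 97, slotCount = 8L)
  bk <- mockBackend(params, seed = 1)
  keys <- keygen(bk)
  roles <- trioRoles()
  codes <- matrix(0, 2, 3, dimnames = list(NULL, roles$sampleId))
  enc <- encryptCohort(bk, packBlocks(codesToChannels(codes), 8L), keys$pk)
  other <- keygen(bk)
  eqOther <- encryptQuery(bk, recessiveQuery(roles), other$pk)
  expect_error(filterMulInRD(bk, enc, eqOther, other$pk), "different keys")
})
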