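test_that("encryption round-trips and keys are bound to ciphertexts", {
  bk <- mockBackend(smallParams(), seed = 3)
  keys <- keygen(bk)
  for (v in list(c(0, 1, 2), c(0, 96, 5), numeric(0))) {
    ct <- heEncrypt(bk, v, keys$pk)
    expect_equal(depthConsumed(ct), 0L)
    expect_equal(heDecrypt(bk, ct, keys$sk)[seq_along(v)], v %% 97)
  }
  k1 <- keygen(bk, seed = 10); k2 <- keygen(bk, seed = 20)
  expect_false(identical(k1$sk@material, k2$sk@material) &&
                 identical(k1$pk@keyId, k2$pk@keyId))
  ct <- heEncrypt(bk, c(1, 2), k1$pk)
  expect_error(heDecrypt(bk, ct, k2$sk), "does not match")
  expect_error(heEncrypt(bk, numeric(9), keys$pk), "packing error")
})

test_that("homomorphic arithmetic matches direct mod-t evaluation", {
  t <- 97
  bk <- mockBackend(smallParams(t = t), seed = 5)
  keys <- keygen(bk)
  set.seed(1)
  for (i in 1:100) {
    a <- sample(0:(t - 1), 8, replace = TRUE)
    b <- sample(0:(t - 1), 8, replace = TRUE)
    ea <- heEncrypt(bk, a, keys$pk); eb <- heEncrypt(bk, b, keys$pk)
    expect_equal(heDecrypt(bk, heAdd(bk, ea, eb), keys$sk), (a + b) %% t)
    expect_equal(heDecrypt(bk, heSub(bk, ea, eb), keys$sk), (a - b) %% t)
    expect_equal(heDecrypt(bk, heMul(bk, ea, eb), keys$sk), (a * b) %% t)
  }
  # subtraction wraps: 0 - 1 = t - 1
  e1 <- heEncrypt(bk, c(1, 0), keys$pk); e2 <- heEncrypt(bk, c(1, 1), keys$pk)
  expect_equal(heDecrypt(bk, heSub(bk, e1, e2), keys$sk)[1:2], c(0, t - 1))
  # repeated addition: x + x + x + x = 4x mod t
  x <- c(30, 60, 90); ex <- heEncrypt(bk, x, keys$pk)
  acc <- ex; for (i in 1:3) acc <- heAdd(bk, acc, ex)
  expect_equal(heDecrypt(bk, acc, keys$sk)[1:3], (4 * x) %% t)
  # zero is absorbing under multiplication
  z <- heEncrypt(bk, numeric(0), keys$pk)
  expect_equal(heDecrypt(bk, heMul(bk, ex, z), keys$sk), rep(0, 8))
})

test_that("plaintext-operand operations work and are tallied separately", {
  bk <- mockBackend(smallParams(), seed = 2)
  keys <- keygen(bk)
  ct <- heEncrypt(bk, c(3, 4), keys$pk)
  before <- opCounts(bk)
  masked <- heMulPlain(bk, ct, c(1, 0, rep(0, 6)))
  bumped <- heAddPlain(bk, heEncrypt(bk, 0, keys$pk), 5)
  after <- opCounts(bk)
  expect_equal(heDecrypt(bk, masked, keys$sk)[1:2], c(3, 0))
  expect_equal(heDecrypt(bk, bumped, keys$sk)[1], 5)
  expect_equal(after@ctMultiplications, before@ctMultiplications)
  expect_equal(after@ctAdditions, before@ctAdditions)
  expect_equal(after@plainMultiplications - before@plainMultiplications, 1)
  expect_equal(after@plainAdditions - before@plainAdditions, 1)
})

test_that("cumulative ops use k-1 operations and a balanced tree depth", {
  bk <- mockBackend(smallParams(), seed = 4)
  keys <- keygen(bk)
  ones <- lapply(1:8, function(i) heEncrypt(bk, rep(1, 8), keys$pk))
  resetOpCounts(bk)
  prod8 <- heMulMany(bk, ones)
  expect_equal(opCounts(bk)@ctMultiplications, 7)
  expect_equal(depthConsumed(prod8), 3L)           # ceil(log2 8)
  expect_equal(heDecrypt(bk, prod8, keys$sk), rep(1, 8))

  for (k in c(2, 3, 5, 6, 7)) {
    resetOpCounts(bk)
    p <- heMulMany(bk, ones[1:k])
    expect_equal(opCounts(bk)@ctMultiplications, k - 1)
    expect_equal(depthConsumed(p), as.integer(ceiling(log2(k))))
  }

  resetOpCounts(bk)
  single <- heMulMany(bk, ones[1])
  expect_equal(opCounts(bk)@ctMultiplications, 0)
  expect_identical(single, ones[[1]])

  k <- 13
  s <- heAddMany(bk, rep(list(heEncrypt(bk, 1, keys$pk)), k))
  expect_equal(heDecrypt(bk, s, keys$sk)[1], k %% 97)
  expect_error(heAddMany(bk, list()), "non-empty")
  expect_error(heMulMany(bk, list()), "non-empty")
})

test_that("depth bookkeeping follows the longest multiplication chain", {
  bk <- mockBackend(smallParams(depthBudget = 30L), seed = 6)
  keys <- keygen(bk)
  x <- heEncrypt(bk, c(2, 3), keys$pk)
  m <- heMul(bk, heMul(bk, x, x), heMul(bk, x, x))
  expect_equal(depthConsumed(m), 2L)

  # random straight-line circuits vs an independent DAG-depth computation
  set.seed(7)
  for (trial in 1:60) {
    cts <- lapply(1:3, function(i)
      heEncrypt(bk, sample(0:96, 8, replace = TRUE), keys$pk))
    depths <- c(0L, 0L, 0L)
    for (op in 1:25) {
      i <- sample(length(cts), 1); j <- sample(length(cts), 1)
      kind <- sample(c("add", "sub", "mul"), 1)
      cts[[length(cts) + 1]] <- switch(kind,
        add = heAdd(bk, cts[[i]], cts[[j]]),
        sub = heSub(bk, cts[[i]], cts[[j]]),
        mul = heMul(bk, cts[[i]], cts[[j]]))
      depths <- c(depths,
                  max(depths[i], depths[j]) + (kind == "mul"))
    }
    expect_equal(vapply(cts, depthConsumed, integer(1)), as.integer(depths))
  }
})

test_that("exceeding the depth budget raises a noise-exhaustion error", {
  bk <- mockBackend(smallParams(depthBudget = 2L), seed = 8)
  keys <- keygen(bk)
  x <- heEncrypt(bk, c(2, 2), keys$pk)
  y <- heMul(bk, heMul(bk, x, x), x)    # depth 2, at the budget
  expect_error(heMul(bk, y, x), "noise budget exhausted")
  expect_error(heMulPlain(bk, y, 2), "noise budget exhausted")
})

test_that("mock circuits agree with direct mod-t evaluation", {
  t <- 257
  bk <- mockBackend(smallParams(t = t), seed = 9)
  keys <- keygen(bk)
  set.seed(11)
  for (trial in 1:300) {
    nIn <- sample(2:4, 1)
    plain <- lapply(1:nIn, function(i) sample(0:(t - 1), 8, replace = TRUE))
    cts <- lapply(plain, function(v) heEncrypt(bk, v, keys$pk))
    for (op in 1:30) {
      i <- sample(length(cts), 1); j <- sample(length(cts), 1)
      kind <- sample(c("add", "sub", "mul"), 1)
      cts[[length(cts) + 1]] <- switch(kind,
        add = heAdd(bk, cts[[i]], cts[[j]]),
        sub = heSub(bk, cts[[i]], cts[[j]]),
        mul = heMul(bk, cts[[i]], cts[[j]]))
      plain[[length(plain) + 1]] <- switch(kind,
        add = (plain[[i]] + plain[[j]]) %% t,
        sub = (plain[[i]] - plain[[j]]) %% t,
        mul = (plain[[i]] * plain[[j]]) %% t)
    }
    last <- length(cts)
    expect_equal(heDecrypt(bk, cts[[last]], keys$sk), plain[[last]])
  }
})

test_that("operation tallies equal the number of calls made", {
  bk <- mockBackend(smallParams(), seed = 10)
  keys <- keygen(bk)
  a <- heEncrypt(bk, c(1, 2), keys$pk); b <- heEncrypt(bk, c(3, 4), keys$pk)
  resetOpCounts(bk)
  set.seed(13)
  nMul <- 0; nAdd <- 0
  for (i in 1:50) {
    kind <- sample(c("add", "sub", "mul"), 1)
    if (kind == "mul") { a <- heMul(bk, b, b); nMul <- nMul + 1 }
    else if (kind == "add") { a <- heAdd(bk, a, b); nAdd <- nAdd + 1 }
    else { a <- heSub(bk, a, b); nAdd <- nAdd + 1 }
  }
  oc <- opCounts(bk)
  expect_equal(oc@ctMultiplications, nMul)
  expect_equal(oc@ctAdditions, nAdd)
})

test_that("total-sum fills all slots and attributes v-1 slot additions", {
  bk <- mockBackend(smallParams(slotCount = 4L), seed = 12)
  keys <- keygen(bk)
  ct <- heEncrypt(bk, c(1, 0, 1, 0), keys$pk)
  resetOpCounts(bk)
  s <- heSumSlots(bk, ct, nValid = 4)
  expect_equal(heDecrypt(bk, s, keys$sk), rep(2, 4))
  expect_equal(opCounts(bk)@slotAdditions, 3)
  z <- heSumSlots(bk, heEncrypt(bk, numeric(0), keys$pk), nValid = 3)
  expect_equal(heDecrypt(bk, z, keys$sk), rep(0, 4))
  expect_equal(opCounts(bk)@slotAdditions, 5)
})

test_that("parameter validity is enforced", {
  expect_error(cryptoParams(t = 96), "prime")
  expect_error(cryptoParams(t = 2^26 + 15), "2\\^26|prime")
  expect_error(cryptoParams(slotCount = 12L), "power of two")
  expect_error(cryptoParams(depthBudget = 0L), "depthBudget")
  expect_error(committeeConfig(4, 5), "quorum")
  expect_error(committeeConfig(1, 1), "members|quorum")
})
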