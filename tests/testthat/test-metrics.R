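test_that("confusion counts partition pixels and swap symmetrically", {
  p <- mkMap(3, 3, rbind(c(1, 1), c(2, 2)))
  t <- mkMap(3, 3, rbind(c(2, 2), c(3, 3)))
  cc <- confusionCounts(p, t)
  expect_equal(cc, list(tp = 1L, fp = 1L, fn = 1L, tn = 6L))

  # identity and empty-prediction cases
  expect_equal(confusionCounts(t, t)[c("fp", "fn", "tp")],
               list(fp = 0L, fn = 0L, tp = 2L))
  expect_equal(confusionCounts(mkMap(3, 3), t)$fn, 2L)

  # swapping arguments swaps fp and fn, for random maps
  set.seed(1)
  for (i in 1:10) {
    a <- matrix(rbinom(36, 1, 0.3), 6, 6)
    b <- matrix(rbinom(36, 1, 0.3), 6, 6)
    f <- confusionCounts(a, b); r <- confusionCounts(b, a)
    expect_identical(f$fp, r$fn)
    expect_identical(f$fn, r$fp)
    expect_identical(f$tp + f$fp + f$fn + f$tn, 36L)
  }
  expect_error(confusionCounts(mkMap(3, 3), mkMap(4, 3)), "dimension")
})

test_that("precision, recall and F follow their definitions", {
  expect_equal(unname(precisionRecallF(list(tp = 1, fp = 1, fn = 1))),
               c(0.5, 0.5, 0.5))
  out <- precisionRecallF(list(tp = 8, fp = 2, fn = 4))
  expect_equal(unname(out), c(0.8, 2 / 3, 2 * 0.8 * (2/3) / (0.8 + 2/3)),
               tolerance = 1e-12)
  # P = R = p is a fixed point of the harmonic mean
  pr <- precisionRecallF(list(tp = 3, fp = 1, fn = 1))
  expect_equal(pr[["fScore"]], pr[["precision"]])
  # zero denominators degrade to 0 with a warning
  expect_warning(z <- precisionRecallF(list(tp = 0, fp = 0, fn = 2)),
                 "precision")
  expect_equal(z[["precision"]], 0)
})

test_that("pixel error is 1 - max F, with threshold sweep for graded input", {
  t <- mkMap(4, 4, rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(pixelError(t, t), 0)
  # binary prediction: exactly 1 - F of that binarisation
  set.seed(2)
  for (i in 1:10) {
    p <- matrix(rbinom(64, 1, 0.4), 8, 8)
    tt <- matrix(rbinom(64, 1, 0.4), 8, 8)
    f <- suppressWarnings(precisionRecallF(confusionCounts(p, tt)))[["fScore"]]
    expect_equal(pixelError(p, tt), 1 - f)
  }
  # graded prediction: threshold 0.6 attains F = 1
  pred <- matrix(c(0.9, 0.6, 0.2, 0.1), 1, 4)
  truth <- matrix(c(1, 1, 0, 0), 1, 4)
  expect_equal(pixelError(pred, truth), 0)
})

test_that("boundary maps induce 4-connected region labelings", {
  expect_equal(max(regionsFromBoundary(mkMap(5, 5))), 1L)
  line <- mkMap(5, 5); line[3, ] <- 1
  expect_equal(max(regionsFromBoundary(line)), 2L)
  ring <- mkRing(5, 2, 4)
  lab <- regionsFromBoundary(ring)
  expect_equal(max(lab), 2L)
  expect_equal(sum(lab == 0), 8L)                       # the ring itself
  sizes <- sort(tabulate(lab[lab > 0]))
  expect_equal(sizes, c(1L, 16L))                       # inside / outside
})

test_that("Rand index matches the exhaustive pair-enumeration oracle", {
  x <- matrix(1L, 2, 2); y <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  expect_equal(randIndex(x, x), 1)
  expect_equal(randIndex(x, y), 1 / 3)
  set.seed(3)
  for (i in 1:20) {
    a <- matrix(sample(0:3, 20, replace = TRUE), 4, 5)
    b <- matrix(sample(0:3, 20, replace = TRUE), 4, 5)
    if (sum(a != 0 & b != 0) < 2) next
    expect_equal(randIndex(a, b), bruteRandIndex(a, b))
    expect_equal(randIndex(a, b), randIndex(b, a))      # symmetry
    expect_equal(randError(a, b), 1 - randIndex(a, b))
  }
  expect_error(randIndex(matrix(0L, 2, 2), matrix(0L, 2, 2)), "fewer than 2")
})

test_that("macro metrics are plain arithmetic means", {
  r1 <- data.frame(precision = 1, recall = 1, fScore = 1, randError = 0.2)
  r2 <- data.frame(precision = 0, recall = 1, fScore = 0, randError = 0.4)
  single <- macroMetrics(r1)
  expect_equal(single[["randError"]], 0.2)
  both <- macroMetrics(rbind(r1, r2))
  expect_equal(both[["randError"]], 0.3)
  expect_equal(attr(both, "nImages"), 2L)
  # 30 randomized reports vs an independent summation order
  set.seed(4)
  df <- as.data.frame(matrix(runif(30 * 4), 30, 4))
  m <- macroMetrics(df)
  indep <- vapply(df, function(col) sum(rev(col)) / 30, numeric(1))
  expect_equal(unname(m), unname(indep), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(macroMetrics(df[0, ]), "no reports")
})

test_that("all metric values stay in [0, 1] on random binary maps", {
  set.seed(5)
  for (i in 1:10) {
    p <- mkBlobs(16, seed = i, frac = 0.7)
    t <- mkBlobs(16, seed = i + 100, frac = 0.7)
    rep <- suppressWarnings(evaluateBoundary(p, t))
    expect_true(all(unlist(rep) >= 0 & unlist(rep) <= 1))
  }
})
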