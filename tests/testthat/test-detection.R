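test_that("the Gaussian pyramid decimates by two and preserves range", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(gaussianPyramid(img, 1L), list(img))
  pyr <- gaussianPyramid(img, 3L)
  expect_equal(vapply(pyr, nrow, integer(1)), c(64L, 32L, 16L))
  expect_true(all(unlist(pyr) >= min(img) - 1e-12 &
                  unlist(pyr) <= max(img) + 1e-12))
  # a constant image stays constant at every level
  cpyr <- gaussianPyramid(matrix(0.4, 32, 32), 2L)
  expect_true(all(abs(unlist(cpyr) - 0.4) < 1e-12))
  expect_error(gaussianPyramid(matrix(0, 16, 16), 3L), "too small")
})

test_that("LoG response vanishes on constant and affine images", {
  expect_true(all(logResponse(matrix(0.7, 20, 20), 1) == 0))
  ramp <- outer(1:30, 1:30, function(r, c) 0.01 * r + 0.02 * c)
  resp <- logResponse(ramp, 1)
  expect_lt(max(abs(resp[8:23, 8:23])), 1e-10)  # interior only
  # a step edge gives opposite signs on the two sides
  step <- cbind(matrix(0, 20, 10), matrix(1, 20, 10))
  rs <- logResponse(step, 1)
  expect_true(all(rs[10, 8:9] > 0))
  expect_true(all(rs[10, 12:13] < 0))
})

test_that("zero-crossing extraction marks thin gated lines off the border", {
  expect_equal(sum(boundaryFromLog(matrix(0, 10, 10))), 0)
  step <- cbind(matrix(0, 20, 10), matrix(1, 20, 10))
  rs <- logResponse(step, 1)
  b <- boundaryFromLog(rs, 0)
  inner <- b[5:16, ]
  expect_true(all(rowSums(inner) == 1))          # a single 1-px line
  expect_true(all(which(inner == 1, arr.ind = TRUE)[, 2] %in% 10:11))
  expect_equal(sum(boundaryFromLog(rs, gradThresh = 10)), 0)
  expect_equal(sum(b[c(1, 20), ]) + sum(b[, c(1, 20)]), 0)  # frame clear
})

test_that("upsampling blocks and dilates coarse detections", {
  m <- mkMap(4, 4, rbind(c(2, 2)))
  expect_identical(upsampleBoundary(m, 1L), m)
  up <- upsampleBoundary(m, 2L)
  expect_equal(dim(up), c(8L, 8L))
  # the 2x2 block grown by one dilation: rows/cols 2..5
  expect_equal(which(up == 1, arr.ind = TRUE)[, 1], rep(2:5, 4),
               ignore_attr = TRUE)
  expect_true(all(up[2:5, 2:5] == 1))
  expect_equal(sum(upsampleBoundary(mkMap(4, 4), 2L)), 0)
})

test_that("fusion votes per pixel with weighted alpha and threshold", {
  maps <- list(mkMap(3, 3, rbind(c(2, 2))), mkMap(3, 3, rbind(c(2, 2))),
               mkMap(3, 3, rbind(c(2, 2))))
  cfg <- fusionConfig(3, alpha = 1, beta = 0, weight = c(0.5, 0.3, 0.2),
                      threshold = 0.6, sigma = rep(1, 3))
  expect_equal(fuseBoundaries(maps, cfg)[2, 2], 1)      # score 1.0 >= 0.6
  none <- list(mkMap(3, 3), mkMap(3, 3), mkMap(3, 3))
  expect_equal(sum(fuseBoundaries(none, cfg)), 0)
  # monotonicity: adding a vote can only add marked pixels
  set.seed(8)
  for (i in 1:10) {
    ms <- lapply(1:3, function(k) matrix(rbinom(25, 1, 0.4), 5, 5))
    f0 <- fuseBoundaries(ms, cfg)
    ms2 <- ms
    idx <- which(ms2[[2]] == 0)
    if (!length(idx)) next
    ms2[[2]][idx[1]] <- 1
    f1 <- fuseBoundaries(ms2, cfg)
    expect_true(all(f1 >= f0))
  }
  expect_error(fuseBoundaries(maps[1:2], cfg), "weights")
})

test_that("detection is deterministic, empty on constants, single-scale at l=1", {
  expect_equal(sum(detectBoundaries(matrix(0.5, 64, 64), fusionConfig(3))), 0)
  ph <- generatePhantom(phantomSpec(shape = c(64, 64), nCells = 2,
                                    noiseSigma = 0.05, seed = 11))
  d1 <- detectBoundaries(ph$image, fusionConfig(3))
  d2 <- detectBoundaries(ph$image, fusionConfig(3))
  expect_identical(d1, d2)
  # l = 1 degenerates to plain single-scale LoG detection
  cfg1 <- fusionConfig(1)
  dl1 <- detectBoundaries(ph$image, cfg1, 1L)
  ref <- boundaryFromLog(logResponse(ph$image, 1), 0)
  expect_equal(matrix(as.numeric(dl1), 64, 64), ref)
})

test_that("noise does not improve membrane recall (median over seeds)", {
  med <- vapply(c(0, 0.05, 0.15), function(sig) {
    median(vapply(1:10, function(s) {
      ph <- generatePhantom(phantomSpec(shape = c(128, 128), nCells = 4,
                                        noiseSigma = sig, clutterDensity = 0,
                                        seed = s))
      boundaryRecall(detectBoundaries(ph$image, fusionConfig(3)), ph$truth, 1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9))
})
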