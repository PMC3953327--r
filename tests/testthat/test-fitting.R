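test_that("tracing walks back from an endpoint and drops gap-near points", {
  m <- mkMap(9, 30)
  m[5, 3:22] <- 1                       # straight 20-px segment
  tr <- traceCurveSegment(m, c(5, 22))
  expect_equal(nrow(tr), 13L)           # 15 traced, 2 dropped near the gap
  expect_true(all(tr[, "row"] == 5))
  expect_equal(unname(tr[1, "col"]), 8L)   # ordered far -> near
  expect_equal(unname(tr[13, "col"]), 20L)

  # a branch stops the trace
  mb <- mkMap(11, 20)
  mb[6, 3:15] <- 1
  mb[5, 8] <- 1; mb[4, 8] <- 1; mb[3, 8] <- 1   # spur creating a branch
  trb <- traceCurveSegment(mb, c(6, 15))
  expect_lt(nrow(trb), 13L)
  expect_true(all(trb[, "col"] > 8))    # stopped at the branch pixel

  # too-short segments raise the insufficient-support condition
  ms <- mkMap(5, 10); ms[3, 2:5] <- 1
  expect_error(traceCurveSegment(ms, c(3, 5)), class = "insufficientSupport")
  expect_error(traceCurveSegment(mkRing(8, 2, 6), c(2, 2)),
               "exactly one marked")    # ring pixel is no endpoint
})

test_that("axis orientation makes segments function-like and is involutive", {
  horiz <- cbind(1:10, rep(3, 10))
  oh <- orientAxes(horiz)
  expect_false(oh$swapped)
  vert <- cbind(rep(3, 10), 1:10)
  ov <- orientAxes(vert)
  expect_true(ov$swapped)
  expect_equal(ov$points[, 1], 1:10)
  diag45 <- cbind(1:8, 1:8)
  expect_false(orientAxes(diag45)$swapped)
  # applying the recorded swap twice restores the original coordinates
  back <- ov$points[, c(2, 1)]
  expect_equal(back, vert, ignore_attr = TRUE)
})

test_that("polynomial evaluation and per-sample cost behave as defined", {
  expect_equal(polyEval(curveModel(c(7, 0, 0)), c(-3, 0, 12)), rep(7, 3))
  expect_equal(polyEval(curveModel(c(1, 2, 3)), 2), 17)
  expect_equal(polyEval(curveModel(c(0, 0, 0)), 5), 0)
  lin <- curveModel(c(0, 1, 0))         # y = x
  expect_equal(fitCost(lin, c(2, 5)), 3)
  expect_equal(fitCost(lin, c(4, 4)), 0)
  pts <- cbind(1:5, c(2, 1, 5, 4, 5))
  total <- sum(apply(pts, 1, function(p) fitCost(lin, p)))
  expect_equal(total, sum(abs(pts[, 2] - pts[, 1])))    # additivity
})

test_that("the gradient step reduces the sample residual", {
  th <- c(0.3, -0.2, 0.1)
  expect_equal(fitGradientStep(th, c(2, polyEval(th, 2))), th)  # residual 0
  expect_equal(fitGradientStep(c(0, 0, 0), c(1, 1), 0.1), rep(0.1, 3))
  # iterating one sample converges its residual to 0
  th <- c(0, 0, 0)
  for (i in 1:200) th <- fitGradientStep(th, c(0.5, 2), 0.1)
  expect_lt(abs(2 - polyEval(th, 0.5)), 1e-6)
})

test_that("fitCurve recovers the least-squares solution on clean data", {
  x <- 0:12
  y <- 0.5 * x^2 - x + 3
  m <- fitCurve(cbind(x, y))
  V <- cbind(1, x, x^2)
  ls <- solve(t(V) %*% V, t(V) %*% y)   # normal-equations oracle
  expect_lt(max(abs(m@theta - ls)), 1e-2)
  expect_false(m@axisSwapped)

  # constant data
  mc <- fitCurve(cbind(0:9, rep(2, 10)))
  expect_lt(abs(mc@theta[1] - 2), 1e-2)
  expect_lt(max(abs(mc@theta[-1])), 1e-2)

  # noisy data: fitted cost within 10% of the oracle's
  set.seed(9)
  yn <- y + rnorm(13, sd = 0.5)
  mn <- fitCurve(cbind(x, yn))
  lsn <- solve(t(V) %*% V, t(V) %*% yn)
  expect_lte(sum(abs(yn - polyEval(mn, x))),
             sum(abs(yn - V %*% lsn)) * 1.1)

  # determinism and the batch-updating variant
  expect_identical(fitCurve(cbind(x, y))@theta, m@theta)
  mb <- fitCurve(cbind(x, y), fitConfig(mode = "batch", episodes = 2000L))
  expect_lt(max(abs(mb@theta - ls)), 5e-2)
  expect_error(fitCurve(cbind(1:2, 1:2)), class = "insufficientSupport")
})

test_that("instant-mode fit cost is non-increasing across sweeps", {
  for (s in 1:20) {
    set.seed(s)
    th <- rnorm(3)
    x <- 0:12
    y <- th[1] + th[2] * x + th[3] * x^2
    ct <- attr(fitCurve(cbind(x, y)), "costTrace")
    expect_true(all(diff(ct) <= 1e-9), info = paste("seed", s))
  }
})

test_that("image pixels map into the model frame through the swap flag", {
  lin <- curveModel(c(0, 1, 0))                    # y = x
  expect_equal(modelDistance(lin, 5, 2), 3)        # x = col 2, y = row 5
  linS <- curveModel(c(0, 1, 0), axisSwapped = TRUE)
  expect_equal(modelDistance(linS, 2, 5), 3)       # swapped frame
  expect_equal(modelDistance(NULL, 10, 10), 0)
})
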