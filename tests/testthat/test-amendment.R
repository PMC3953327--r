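test_that("endpoints are degree-1 marked pixels away from the frame", {
  expect_equal(nrow(findEndpoints(mkRing(10, 3, 8))), 0L)   # closed curve
  seg <- mkMap(9, 20); seg[5, 4:15] <- 1
  ep <- findEndpoints(seg)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep[order(ep[, "col"]), "col"], c(4L, 15L), ignore_attr = TRUE)
  iso <- mkMap(9, 9, rbind(c(5, 5)))
  expect_equal(nrow(findEndpoints(iso)), 0L)                # isolated pixel
})

test_that("travel rewards compose gain, penalty and model distance", {
  cfg <- sarsaConfig()
  expect_equal(travelReward(TRUE, 0, cfg), 1)
  expect_equal(travelReward(FALSE, 0, cfg), -10)
  expect_equal(travelReward(FALSE, 2, cfg), -12)
  expect_equal(travelReward(TRUE, 0.5,
                            sarsaConfig(modelWeight = 2)), 0)
})

test_that("the SARSA(lambda) update follows the TD and trace equations", {
  cfg <- sarsaConfig()
  Q <- new.env(); e <- new.env()
  d <- sarsaUpdate(Q, e, c(3, 3), 1L, 1, c(2, 3), 2L, cfg)
  expect_equal(d, 1)
  expect_equal(Q[["3,3|1"]], 0.1)              # alpha * delta * e
  expect_equal(e[["3,3|1"]], 0.95 * 0.9)       # trace after decay

  # zero TD error leaves Q untouched but still decays traces
  Q2 <- new.env(); e2 <- new.env()
  Q2[["1,1|1"]] <- 2; Q2[["1,2|2"]] <- 2 / 0.95 * (2 - 0)  # contrived
  e2[["1,1|1"]] <- 0.5
  r0 <- 2 - 0.95 * Q2[["1,2|2"]]               # makes delta = 0 at Q(s,a)=2
  sarsaUpdate(Q2, e2, c(1, 1), 1L, r0, c(1, 2), 2L, cfg)
  expect_equal(Q2[["1,1|1"]], 2)
  expect_equal(e2[["1,1|1"]], 1.5 * 0.95 * 0.9)

  # traces stay non-negative and fall below 1e-6 within the decay bound
  steps <- ceiling(log(1e-6) / log(0.95 * 0.9))
  tr <- 1
  for (i in seq_len(steps)) tr <- tr * 0.95 * 0.9
  expect_lt(tr, 1e-6)
  expect_gte(tr, 0)
})

test_that("lambda = 0 reproduces one-step SARSA exactly", {
  cfg0 <- sarsaConfig(lambda = 0)
  traj <- list(
    list(s = c(1, 1), a = 1L, r = -10, s2 = c(2, 1), a2 = 2L),
    list(s = c(2, 1), a = 2L, r = -10, s2 = c(2, 2), a2 = 3L),
    list(s = c(2, 2), a = 3L, r = 1,   s2 = c(2, 3), a2 = 4L),
    list(s = c(2, 3), a = 4L, r = -10, s2 = c(2, 2), a2 = 3L),  # revisit
    list(s = c(2, 2), a = 3L, r = 1,   s2 = c(2, 3), a2 = 4L))
  Q <- new.env(); e <- new.env()
  for (tr in traj)
    sarsaUpdate(Q, e, tr$s, tr$a, tr$r, tr$s2, tr$a2, cfg0)
  ref <- oneStepSarsa(traj, alpha = cfg0@alphaLr, gamma = cfg0@gamma)
  for (k in names(ref))
    expect_equal(Q[[k]], ref[[k]], tolerance = 1e-15)
  expect_equal(sort(ls(Q)), sort(names(ref)))
})

test_that("closeGap crosses small gaps under model supervision", {
  # 1-px gap: the single blank neighbour touching the other arm
  m <- mkMap(9, 9); m[5, 1:3] <- 1; m[5, 5:9] <- 1
  res <- closeGap(m, c(5, 3), NULL, sarsaConfig(), seed = 1)
  expect_true(res$closed)
  expect_equal(nrow(res$added), 1L)
  expect_equal(res$map[5, 4], 1)

  # 5-px collinear gap with a fitted model: the filled pixels stay within
  # 1 px of the true line
  m2 <- mkMap(15, 40); m2[8, 2:15] <- 1; m2[8, 21:39] <- 1
  tr <- traceCurveSegment(m2, c(8, 15))
  mod <- fitCurve(tr[, c("col", "row")])
  res2 <- closeGap(m2, c(8, 15), mod, sarsaConfig(), seed = 1)
  expect_true(res2$closed)
  expect_true(all(abs(res2$added[, 1] - 8) <= 1))

  # a zero step cap forbids any movement
  res3 <- closeGap(m2, c(8, 15), mod, sarsaConfig(maximalStep = 0), seed = 1)
  expect_false(res3$closed)
  expect_identical(res3$map, m2)
})

test_that("amendment closes ring gaps, skips long ones, deletes nothing", {
  ring <- mkRing(24, 5, 20)
  ring[5, 10:15] <- 0                            # 6-px gap
  epBefore <- findEndpoints(ring)
  am <- amendBoundaries(ring, seed = 3)
  expect_equal(nrow(findEndpoints(am)), nrow(epBefore) - 2L)
  expect_true(all(am[ring == 1] == 1))           # no deletions

  # idempotence once no endpoints remain
  am2 <- amendBoundaries(am, seed = 4)
  expect_identical(matrix(as.numeric(am2), 24, 24),
                   matrix(as.numeric(am), 24, 24))

  # a gap beyond maxGapLen is skipped untouched
  far <- mkMap(15, 60); far[8, 2:20] <- 1; far[8, 45:59] <- 1
  amf <- amendBoundaries(far, sarsaCfg = sarsaConfig(maxGapLen = 15),
                         seed = 5)
  expect_identical(matrix(as.numeric(amf), 15, 60), far)
  expect_true(all(!attr(amf, "gapLog")$closed, na.rm = TRUE))
})

test_that("amendment is deterministic and input-preserving on phantoms", {
  ph <- generatePhantom(phantomSpec(shape = c(128, 128), nCells = 4,
                                    seed = 21))
  gi <- injectGaps(ph$truth, nGaps = 4, lengthRange = c(3, 8), seed = 21)
  a1 <- amendBoundaries(gi$map, seed = 7)
  a2 <- amendBoundaries(gi$map, seed = 7)
  expect_identical(a1, a2)
  expect_true(all(a1[gi$map == 1] == 1))
  expect_lt(nrow(findEndpoints(a1)), nrow(findEndpoints(gi$map)))
})
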