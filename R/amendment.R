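# SARSA(lambda)-based curve traveling and amendment: an agent starts at an
# open curve endpoint and walks the pixel grid under an epsilon-greedy
# policy over a tabular Q, with the local curve model steering both the
# reward and the tie-breaks, until it reaches a marked pixel of a
# different curve arm (gap closed) or gives up.

qKey <- function(r, c, a) paste0(r, ",", c, "|", a)

getQ <- function(Q, key) {
  v <- Q[[key]]
  if (is.null(v)) 0 else v
}

#' Open endpoints of a boundary map
#'
#' Marked pixels with exactly one marked 8-neighbour. Isolated marked
#' pixels (no neighbour) are not endpoints, and pixels on the outermost
#' 1-px frame are excluded: a curve clipped by the canvas is not a gap.
#' Results come in column-major raster order, for determinism.
#'
#' @param map binary boundary matrix.
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
findEndpoints <- function(map) {
  checkBinary(map)
  cnt <- neighborCount8(map)
  hit <- map == 1 & cnt == 1
  hit[c(1L, nrow(map)), ] <- FALSE
  hit[, c(1L, ncol(map))] <- FALSE
  idx <- which(hit)
  out <- cbind(row = ((idx - 1L) %% nrow(map)) + 1L,
               col = ((idx - 1L) %/% nrow(map)) + 1L)
  out
}

#' Reward of one traveling step
#'
#' Stepping onto a marked pixel earns `gain`; onto a blank pixel costs
#' `gapPenalty`; in both cases `modelWeight` times the model distance of
#' the target pixel is subtracted, so walking along the fitted curve is
#' always preferred.
#'
#' @param nextIsMarked whether the target pixel is marked.
#' @param modelDist non-negative distance of the target pixel from the
#'   local curve model (0 when no model is active).
#' @param cfg a [SarsaConfig-class].
#' @return the reward (a real number).
#' @examples
#' travelReward(TRUE, 0, sarsaConfig())    # +1
#' travelReward(FALSE, 0, sarsaConfig())   # -10
#' @export
travelReward <- function(nextIsMarked, modelDist = 0, cfg = sarsaConfig()) {
  stopifnot(modelDist >= 0)
  base <- if (nextIsMarked) cfg@gain else -cfg@gapPenalty
  base - cfg@modelWeight * modelDist
}

#' One SARSA(lambda) update with accumulating eligibility traces
#'
#' Computes the TD error `delta = r + gamma * Q(s', a') - Q(s, a)`,
#' increments the trace of `(s, a)` by one, then for every stored pair
#' applies `Q += alphaLr * delta * e` followed by the trace decay
#' `e *= gamma * lambda`. `Q` and `e` are environments keyed by
#' `"row,col|move"` and are modified in place; unseen pairs read as 0.
#'
#' @param Q,e environments holding the tables.
#' @param s,sNext integer `(row, col)` states.
#' @param a,aNext move indices in `1:8`.
#' @param r reward received for the transition.
#' @param cfg a [SarsaConfig-class].
#' @param qNext override for `Q(s', a')` (used at terminal transitions,
#'   where the successor value is 0 by definition).
#' @return the TD error, invisibly.
#' @export
sarsaUpdate <- function(Q, e, s, a, r, sNext, aNext, cfg = sarsaConfig(),
                        qNext = NULL) {
  kSA <- qKey(s[1L], s[2L], a)
  if (is.null(qNext))
    qNext <- getQ(Q, qKey(sNext[1L], sNext[2L], aNext))
  delta <- r + cfg@gamma * qNext - getQ(Q, kSA)
  prev <- e[[kSA]]
  e[[kSA]] <- if (is.null(prev)) 1 else prev + 1
  decay <- cfg@gamma * cfg@lambda
  for (k in ls(e)) {
    ek <- e[[k]]
    Q[[k]] <- getQ(Q, k) + cfg@alphaLr * delta * ek
    enew <- ek * decay
    if (enew < 1e-12) rm(list = k, envir = e) else e[[k]] <- enew
  }
  invisible(delta)
}

# Marked pixels within geodesic distance <= radius of `from`, walking
# along marked 8-neighbours: the endpoint's own curve arm.
geodesicArm <- function(map, from, radius) {
  nr <- nrow(map); nc <- ncol(map)
  arm <- matrix(FALSE, nr, nc)
  arm[from[1L], from[2L]] <- TRUE
  frontier <- matrix(from, 1L, 2L)
  for (d in seq_len(radius)) {
    if (nrow(frontier) == 0L) break
    nxt <- matrix(0L, 0L, 2L)
    for (i in seq_len(nrow(frontier))) {
      for (m in 1:8) {
        rr <- frontier[i, 1L] + MOVES[m, 1L]
        cc <- frontier[i, 2L] + MOVES[m, 2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            map[rr, cc] == 1 && !arm[rr, cc]) {
          arm[rr, cc] <- TRUE
          nxt <- rbind(nxt, c(rr, cc))
        }
      }
    }
    frontier <- nxt
  }
  arm
}

# Epsilon-greedy action choice at `pos`. Valid moves stay on canvas,
# avoid already-visited pixels and the endpoint's own arm. Ties among
# maximal-Q moves break toward marked (gap-closing) targets, then the
# smallest guide distance, then fixed move order. Returns NA when no move
# is valid. `guideFun(r, c)` is the model distance, or a straight-line
# fallback when no model could be fitted.
chooseAction <- function(Q, pos, visited, arm, map, guideFun, eps, cfg,
                         masking = FALSE) {
  nr <- nrow(visited); nc <- ncol(visited)
  valid <- integer(0); md <- numeric(0); marked <- logical(0)
  for (m in 1:8) {
    rr <- pos[1L] + MOVES[m, 1L]; cc <- pos[2L] + MOVES[m, 2L]
    if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
    if (visited[rr, cc] || arm[rr, cc]) next
    valid <- c(valid, m)
    md <- c(md, guideFun(rr, cc))
    marked <- c(marked, map[rr, cc] == 1)
  }
  if (length(valid) == 0L) return(NA_integer_)
  if (masking) {
    here <- guideFun(pos[1L], pos[2L])
    keep <- md <= here + 1e-9
    if (any(keep)) { valid <- valid[keep]; md <- md[keep]
                     marked <- marked[keep] }
  }
  if (eps > 0 && stats::runif(1) < eps)
    return(valid[sample.int(length(valid), 1L)])
  qv <- vapply(valid, function(m) getQ(Q, qKey(pos[1L], pos[2L], m)),
               numeric(1))
  top <- which(qv >= max(qv) - 1e-12)
  if (length(top) > 1L) top <- top[order(!marked[top], md[top])]
  valid[top[1L]]
}

#' Close one gap by SARSA(lambda) curve traveling
#'
#' The agent starts at `endpoint` and walks epsilon-greedily over Q, the
#' curve-model distance shaping every reward ([travelReward()]). An
#' episode ends in success when the walk reaches a marked pixel outside
#' the endpoint's own arm (the marked pixels within geodesic distance
#' `cfg@armRadius` of the start), and in failure when it returns to the
#' start, when the chosen Q drops below `cfg@qThreshold`, when the step
#' count exceeds `cfg@maximalStep`, or when no unvisited pixel remains.
#' Pixels may not be revisited within an episode. Only the blank pixels
#' of the final successful trajectory are committed to the returned map;
#' on failure the map is returned unchanged.
#'
#' @param map binary boundary matrix.
#' @param endpoint integer `(row, col)`, typically from [findEndpoints()].
#' @param model a [CurveModel-class] fitted to the endpoint's arm, or
#'   `NULL` when fitting failed (the walk is then unsupervised).
#' @param cfg a [SarsaConfig-class].
#' @param seed optional integer seed for the episode RNG.
#' @param arm optional logical matrix giving the endpoint's own arm
#'   (recomputed when `NULL`).
#' @return list with `map` (possibly amended), logical `closed`, `Q` (the
#'   final episode's table), `steps`, and `added` (n x 2 matrix of
#'   committed pixels).
#' @export
closeGap <- function(map, endpoint, model = NULL, cfg = sarsaConfig(),
                     seed = NULL, arm = NULL) {
  checkBinary(map)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(arm)) arm <- geodesicArm(map, endpoint, cfg@armRadius)
  nr <- nrow(map); nc <- ncol(map)
  if (!is.null(model)) {
    guideFun <- function(r, c) modelDistance(model, r, c)
  } else {
    # no curve model: guide ties by straight-line distance to the nearest
    # marked pixel outside the arm (the cheapest connection target)
    others <- which(map == 1 & !arm)
    if (length(others)) {
      orows <- ((others - 1L) %% nr) + 1L
      ocols <- ((others - 1L) %/% nr) + 1L
      d2 <- (orows - endpoint[1L])^2 + (ocols - endpoint[2L])^2
      tgt <- c(orows[which.min(d2)], ocols[which.min(d2)])
      guideFun <- function(r, c) sqrt((r - tgt[1L])^2 + (c - tgt[2L])^2)
    } else guideFun <- function(r, c) 0
  }
  eps <- cfg@epsilon
  bestPath <- NULL
  lastQ <- new.env(parent = emptyenv())
  lastSteps <- 0L
  for (episode in seq_len(cfg@episodes)) {
    Q <- new.env(parent = emptyenv())
    e <- new.env(parent = emptyenv())
    visited <- matrix(FALSE, nr, nc)
    visited[endpoint[1L], endpoint[2L]] <- TRUE
    pos <- endpoint
    path <- matrix(0L, 0L, 2L)
    steps <- 0L
    success <- FALSE
    a <- chooseAction(Q, pos, visited, arm, map, guideFun, eps, cfg,
                      masking = cfg@maskMoves && !is.null(model))
    while (!is.na(a)) {
      if (steps + 1L > cfg@maximalStep) break
      steps <- steps + 1L
      nxt <- c(pos[1L] + MOVES[a, 1L], pos[2L] + MOVES[a, 2L])
      md <- modelDistance(model, nxt[1L], nxt[2L])
      r <- travelReward(map[nxt[1L], nxt[2L]] == 1, md, cfg)
      if (all(nxt == endpoint)) {      # returned to start: failure
        sarsaUpdate(Q, e, pos, a, r, nxt, 1L, cfg, qNext = 0)
        break
      }
      if (map[nxt[1L], nxt[2L]] == 1 && !arm[nxt[1L], nxt[2L]]) {
        sarsaUpdate(Q, e, pos, a, r, nxt, 1L, cfg, qNext = 0)
        success <- TRUE
        break
      }
      aNext <- chooseAction(Q, nxt, visited, arm, map, guideFun, eps, cfg,
                            masking = cfg@maskMoves && !is.null(model))
      if (is.na(aNext)) {              # dead end
        sarsaUpdate(Q, e, pos, a, r, nxt, 1L, cfg, qNext = 0)
        break
      }
      sarsaUpdate(Q, e, pos, a, r, nxt, aNext, cfg)
      pos <- nxt
      visited[pos[1L], pos[2L]] <- TRUE
      if (map[pos[1L], pos[2L]] == 0) path <- rbind(path, pos)
      a <- aNext
      if (getQ(Q, qKey(pos[1L], pos[2L], a)) < cfg@qThreshold) break
    }
    if (success) bestPath <- path
    lastQ <- Q
    lastSteps <- steps
    eps <- eps * cfg@epsilonDecay
  }
  out <- map
  if (!is.null(bestPath) && nrow(bestPath) > 0L)
    out[bestPath] <- 1
  list(map = out, closed = !is.null(bestPath), Q = lastQ,
       steps = lastSteps,
       added = if (is.null(bestPath)) matrix(integer(), 0L, 2L) else bestPath)
}

#' Amend all gaps of a boundary map
#'
#' Iterates the open endpoints in raster order. For each endpoint still
#' open in the current map, the adjacent curve segment is traced
#' ([traceCurveSegment()]) and fitted ([fitCurve()]), the gap length is
#' estimated as the straight-line distance to the nearest marked pixel
#' outside the endpoint's own arm, gaps longer than `sarsaCfg@maxGapLen`
#' are skipped, and the remaining ones are closed with [closeGap()].
#' Endpoints consumed by an earlier closure are not revisited. Marked
#' pixels are never removed, and the result is deterministic for a fixed
#' seed.
#'
#' @param map binary boundary matrix.
#' @param fitCfg a [FitConfig-class].
#' @param sarsaCfg a [SarsaConfig-class].
#' @param seed integer seed driving the walker's exploration.
#' @return the amended binary matrix, with a `gapLog` attribute: one data
#'   frame row per visited endpoint (`row`, `col`, `gapLen`, `fitted`,
#'   `closed`, `steps`, `added`).
#' @export
amendBoundaries <- function(map, fitCfg = fitConfig(),
                            sarsaCfg = sarsaConfig(), seed = 1L) {
  checkBinary(map)
  set.seed(seed)
  eps <- findEndpoints(map)
  out <- map
  log <- list()
  for (i in seq_len(nrow(eps))) {
    ep <- eps[i, ]
    cnt <- 0L
    for (m in 1:8) {
      rr <- ep[1L] + MOVES[m, 1L]; cc <- ep[2L] + MOVES[m, 2L]
      if (rr >= 1L && rr <= nrow(out) && cc >= 1L && cc <= ncol(out))
        cnt <- cnt + (out[rr, cc] == 1)
    }
    if (cnt != 1L) {                   # consumed by an earlier closure
      log[[i]] <- data.frame(row = ep[1L], col = ep[2L], gapLen = NA_real_,
                             fitted = NA, closed = NA, steps = 0L, added = 0L)
      next
    }
    arm <- geodesicArm(out, ep, sarsaCfg@armRadius)
    others <- which(out == 1 & !arm)
    if (length(others) == 0L) {
      log[[i]] <- data.frame(row = ep[1L], col = ep[2L], gapLen = Inf,
                             fitted = NA, closed = FALSE, steps = 0L,
                             added = 0L)
      next
    }
    orows <- ((others - 1L) %% nrow(out)) + 1L
    ocols <- ((others - 1L) %/% nrow(out)) + 1L
    gapLen <- sqrt(min((orows - ep[1L])^2 + (ocols - ep[2L])^2))
    if (gapLen > sarsaCfg@maxGapLen) {
      log[[i]] <- data.frame(row = ep[1L], col = ep[2L], gapLen = gapLen,
                             fitted = NA, closed = FALSE, steps = 0L,
                             added = 0L)
      next
    }
    model <- tryCatch({
      traced <- traceCurveSegment(out, ep, fitCfg)
      fitCurve(traced[, c("col", "row")], fitCfg)
    }, insufficientSupport = function(cond) NULL)
    res <- closeGap(out, ep, model, sarsaCfg, arm = arm)
    if (res$closed) out <- res$map
    log[[i]] <- data.frame(row = ep[1L], col = ep[2L], gapLen = gapLen,
                           fitted = !is.null(model), closed = res$closed,
                           steps = res$steps, added = nrow(res$added))
  }
  attr(out, "gapLog") <- if (length(log)) do.call(rbind, log)
    else data.frame(row = integer(), col = integer(), gapLen = numeric(),
                    fitted = logical(), closed = logical(), steps = integer(),
                    added = integer())
  out
}
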