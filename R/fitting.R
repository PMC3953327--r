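# Reinforced gradient-descent curve shape fitting: a local polynomial
# model of the curve arm adjacent to a gap, trained by per-sample
# gradient descent over the traced pixels.

insufficientSupport <- function(msg) {
  structure(class = c("insufficientSupport", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Trace the curve segment behind a gap endpoint
#'
#' Walks backward from an endpoint (a marked pixel with exactly one marked
#' 8-neighbour) along marked 8-neighbours, up to `cfg@neighborhood` points
#' including the endpoint, stopping at a branch (two or more unvisited
#' marked neighbours) or a dead end. The `cfg@ignoreNearGap` points
#' closest to the endpoint are dropped: right at a break the detected
#' curve is least trustworthy.
#'
#' @param map binary boundary matrix.
#' @param endpoint integer (row, col) of the endpoint pixel.
#' @param cfg a [FitConfig-class].
#' @return matrix with columns `row`, `col`, ordered from the farthest
#'   traced point to the one nearest the gap.
#' @export
traceCurveSegment <- function(map, endpoint, cfg = fitConfig()) {
  checkBinary(map)
  r <- endpoint[1L]; c <- endpoint[2L]
  if (map[r, c] != 1) stop("endpoint is not a marked pixel")
  nr <- nrow(map); nc <- ncol(map)
  visited <- matrix(FALSE, nr, nc)
  pts <- matrix(0L, cfg@neighborhood, 2L)
  pts[1L, ] <- c(r, c)
  visited[r, c] <- TRUE
  n <- 1L
  while (n < cfg@neighborhood) {
    cur <- pts[n, ]
    nbr <- matrix(0L, 0L, 2L)
    for (i in 1:8) {
      rr <- cur[1L] + MOVES[i, 1L]; cc <- cur[2L] + MOVES[i, 2L]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
          map[rr, cc] == 1 && !visited[rr, cc])
        nbr <- rbind(nbr, c(rr, cc))
    }
    if (n == 1L && nrow(nbr) != 1L)
      stop("endpoint must have exactly one marked 8-neighbour")
    if (nrow(nbr) != 1L) break   # dead end or branch: stop the trace
    n <- n + 1L
    pts[n, ] <- nbr[1L, ]
    visited[nbr[1L, 1L], nbr[1L, 2L]] <- TRUE
  }
  keep <- n - cfg@ignoreNearGap
  if (keep < cfg@degree + 1L)
    stop(insufficientSupport(sprintf(
      "traced %d points, %d after dropping %d near the gap; need %d",
      n, keep, cfg@ignoreNearGap, cfg@degree + 1L)))
  out <- pts[seq(n, cfg@ignoreNearGap + 1L), , drop = FALSE]  # far -> near
  colnames(out) <- c("row", "col")
  out
}

#' Orient a point set so it is function-like
#'
#' The polynomial model assumes `y = F(x)`, which a near-vertical pixel
#' segment violates (one abscissa, many ordinates). The coordinates are
#' exchanged when the second axis carries more distinct values than the
#' first — the axis with more distinct coordinates is the one along which
#' the sample is closest to single-valued. Ties (for example a 45-degree
#' segment) keep the original orientation, and the swap is recorded so
#' predictions can be mapped back.
#'
#' @param points matrix with columns `(x, y)`.
#' @return list with `points` (possibly swapped) and logical `swapped`.
#' @export
orientAxes <- function(points) {
  stopifnot(nrow(points) >= 2L)
  nx <- length(unique(points[, 1L]))
  ny <- length(unique(points[, 2L]))
  if (ny > nx) list(points = points[, c(2L, 1L), drop = FALSE], swapped = TRUE)
  else list(points = points, swapped = FALSE)
}

#' Evaluate a polynomial curve model
#'
#' Horner evaluation of `theta[1] + theta[2] x + ... + theta[n+1] x^n`.
#'
#' @param model a [CurveModel-class] (or bare coefficient vector).
#' @param x abscissa value(s), in the model's oriented frame.
#' @return ordinate value(s).
#' @export
polyEval <- function(model, x) {
  theta <- if (is(model, "CurveModel")) model@theta else as.numeric(model)
  out <- rep(0, length(x))
  for (k in rev(seq_along(theta))) out <- out * x + theta[k]
  out
}

#' Distance of a point from the fitted curve
#'
#' Vertical (ordinate) distance `|y - F(x)|` in the model's oriented
#' frame; zero exactly when the point lies on the curve. With
#' `euclidean = TRUE` the shortest distance to the sampled curve is
#' computed instead (offered for inspection; the gradient update is linear
#' only in the vertical form, which therefore stays the default).
#'
#' @param model a [CurveModel-class].
#' @param point `(x, y)` in the oriented frame (use [modelDistance()] for
#'   image pixels).
#' @param euclidean use point-to-curve Euclidean distance.
#' @return non-negative distance.
#' @export
fitCost <- function(model, point, euclidean = FALSE) {
  x <- point[1L]; y <- point[2L]
  if (!euclidean) return(abs(y - polyEval(model, x)))
  xs <- seq(x - 5, x + 5, by = 0.25)
  min(sqrt((xs - x)^2 + (polyEval(model, xs) - y)^2))
}

#' Distance of an image pixel from a curve model
#'
#' Maps a `(row, col)` pixel into the model's oriented frame (x = col,
#' y = row, exchanged when the model was fitted with swapped axes) and
#' returns [fitCost()]. A `NULL` model yields 0, so an absent model simply
#' removes the supervision term.
#'
#' @param model a [CurveModel-class] or `NULL`.
#' @param row,col pixel coordinates.
#' @return non-negative distance.
#' @export
modelDistance <- function(model, row, col) {
  if (is.null(model)) return(0)
  if (model@axisSwapped) fitCost(model, c(row, col))
  else fitCost(model, c(col, row))
}

#' One per-sample gradient step of the polynomial fit
#'
#' `theta' = theta + alphaLr * (y - G theta) * G` with basis
#' `G = (1, x, x^2, ...)`: the stochastic gradient-descent update of the
#' squared vertical error for one sample.
#'
#' @param theta coefficient vector.
#' @param point `(x, y)` sample.
#' @param alphaLr learning rate.
#' @return updated coefficient vector.
#' @export
fitGradientStep <- function(theta, point, alphaLr = 0.1) {
  G <- point[1L]^(seq_along(theta) - 1L)
  theta + alphaLr * (point[2L] - sum(theta * G)) * G
}

# Map coefficients fitted in u = a + b*x back to the x frame by
# polynomial composition (Horner in polynomial arithmetic).
rescaleTheta <- function(theta, a, b) {
  lin <- c(a, b)
  res <- 0
  for (k in rev(seq_along(theta))) {
    # res <- res * lin + theta[k]
    if (length(res) == 1L && res[1L] == 0) res <- theta[k]
    else {
      conv <- rep(0, length(res) + 1L)
      for (i in seq_along(res)) {
        conv[i] <- conv[i] + res[i] * lin[1L]
        conv[i + 1L] <- conv[i + 1L] + res[i] * lin[2L]
      }
      conv[1L] <- conv[1L] + theta[k]
      res <- conv
    }
  }
  c(res, rep(0, length(theta) - length(res)))[seq_along(theta)]
}

#' Fit a polynomial curve model by per-sample gradient descent
#'
#' Orients the points ([orientAxes()]), rescales the abscissa to `[-1, 1]`
#' for conditioning, and sweeps the points in their traced order, updating
#' the coefficients per sample ([fitGradientStep()]; `"batch"` mode
#' accumulates `batchSize` residual gradients and applies their mean).
#' Sweeps repeat until the largest coefficient change over a full sweep
#' drops below `cfg@thetaTol`, capped at `cfg@episodes` sweeps. The
#' returned coefficients are mapped back to the original (oriented) pixel
#' frame. Deterministic: no randomness is involved.
#'
#' @param points matrix with columns `(x, y)` — typically a traced
#'   segment's `(col, row)`; see [traceCurveSegment()].
#' @param cfg a [FitConfig-class].
#' @return a [CurveModel-class], with a `costTrace` attribute holding the
#'   total absolute fit cost on the rescaled inputs after each sweep.
#' @examples
#' x <- 0:12
#' fitCurve(cbind(x, 0.5 * x^2 - x + 3))
#' @export
fitCurve <- function(points, cfg = fitConfig()) {
  points <- as.matrix(points)
  if (nrow(points) < cfg@degree + 1L)
    stop(insufficientSupport(sprintf(
      "%d points cannot support %d coefficients",
      nrow(points), cfg@degree + 1L)))
  ori <- orientAxes(points)
  x <- ori$points[, 1L]; y <- ori$points[, 2L]
  xmin <- min(x); xmax <- max(x)
  if (xmax == xmin)
    stop(insufficientSupport("degenerate segment: no abscissa extent"))
  b <- 2 / (xmax - xmin)
  a <- -1 - b * xmin           # u = a + b x  maps [xmin, xmax] -> [-1, 1]
  u <- a + b * x
  theta <- rep(0, cfg@degree + 1L)
  costTrace <- numeric(0)
  for (ep in seq_len(cfg@episodes)) {
    before <- theta
    if (cfg@mode == "instant") {
      for (i in seq_along(u))
        theta <- fitGradientStep(theta, c(u[i], y[i]), cfg@alphaLr)
    } else {
      acc <- rep(0, length(theta)); nAcc <- 0L
      for (i in seq_along(u)) {
        G <- u[i]^(seq_along(theta) - 1L)
        acc <- acc + (y[i] - sum(theta * G)) * G
        nAcc <- nAcc + 1L
        if (nAcc == cfg@batchSize) {
          theta <- theta + cfg@alphaLr * acc / nAcc
          acc[] <- 0; nAcc <- 0L
        }
      }
      if (nAcc > 0L) theta <- theta + cfg@alphaLr * acc / nAcc
    }
    costTrace <- c(costTrace, sum(abs(y - polyEval(theta, u))))
    if (max(abs(theta - before)) < cfg@thetaTol) break
  }
  model <- curveModel(rescaleTheta(theta, a, b), axisSwapped = ori$swapped)
  attr(model, "costTrace") <- costTrace
  model
}
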