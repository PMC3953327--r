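#' @import methods
NULL

#' Configuration for multi-scale fused boundary detection
#'
#' Holds the vote values, per-level weights, decision threshold and LoG
#' scales used by [detectBoundaries()]. A pixel detected at pyramid level
#' \eqn{i} contributes \eqn{\alpha \cdot weight_i} to its fusion account,
#' an undetected one contributes \eqn{\beta}; the pixel is declared a
#' boundary point when the account is at least `threshold`.
#'
#' @slot alpha positive vote value for a detected boundary point.
#' @slot beta non-positive vote value for a non-boundary point.
#' @slot weight per-level weights, one per pyramid level.
#' @slot threshold fusion decision level (mark when account >= threshold).
#' @slot sigma per-level LoG Gaussian scales (pixels at that level).
#' @slot gradThresh zero-crossing strength gate: a sign change is only
#'   accepted when the response difference across the crossing exceeds it.
#' @export
setClass("FusionConfig",
  representation(alpha = "numeric", beta = "numeric", weight = "numeric",
                 threshold = "numeric", sigma = "numeric",
                 gradThresh = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@alpha) != 1L || object@alpha <= 0)
      msg <- c(msg, "alpha must be a single positive value")
    if (length(object@beta) != 1L || object@beta > 0)
      msg <- c(msg, "beta must be a single non-positive value")
    if (length(object@weight) != length(object@sigma))
      msg <- c(msg, "weight and sigma must have one entry per level")
    if (any(object@weight <= 0)) msg <- c(msg, "weights must be positive")
    if (any(object@sigma <= 0)) msg <- c(msg, "sigmas must be positive")
    if (object@gradThresh < 0) msg <- c(msg, "gradThresh must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a FusionConfig
#'
#' Defaults: weights proportional to the linear resolution of each level
#' (finer levels weighted higher, normalised to sum 1), `alpha = 1`,
#' `beta = 0`, `threshold = 0.5 * alpha`, `sigma = 1` at every level, and
#' no gradient gate.
#'
#' @param levels number of pyramid levels the config is meant for.
#' @param alpha,beta,weight,threshold,sigma,gradThresh see
#'   [FusionConfig-class]; `NULL` selects the default.
#' @return a [FusionConfig-class] object.
#' @examples
#' fusionConfig(levels = 3)
#' @export
fusionConfig <- function(levels = 3L, alpha = 1, beta = 0, weight = NULL,
                         threshold = NULL, sigma = NULL, gradThresh = 0) {
  levels <- as.integer(levels)
  stopifnot(levels >= 1L)
  if (is.null(weight)) {
    weight <- 2^(-(seq_len(levels) - 1L))
    weight <- weight / sum(weight)
  }
  if (is.null(sigma)) sigma <- rep(1, levels)
  if (is.null(threshold)) threshold <- 0.5 * alpha
  new("FusionConfig", alpha = alpha, beta = beta, weight = weight,
      threshold = threshold, sigma = sigma, gradThresh = gradThresh)
}

setMethod("show", "FusionConfig", function(object) {
  cat("FusionConfig:", length(object@weight), "level(s)\n")
  cat("  alpha:", object@alpha, " beta:", object@beta,
      " threshold:", object@threshold, "\n")
  cat("  weight:", paste(signif(object@weight, 4), collapse = ", "), "\n")
  cat("  sigma:", paste(object@sigma, collapse = ", "),
      " gradThresh:", object@gradThresh, "\n")
})

#' Configuration for reinforced gradient-descent curve fitting
#'
#' Parameters of [fitCurve()] and [traceCurveSegment()]. The polynomial
#' model has `degree + 1` coefficients; the segment traced back from a gap
#' endpoint is at most `neighborhood` pixels long and its `ignoreNearGap`
#' pixels closest to the gap are dropped (they are the least reliable part
#' of a broken curve). Fitting sweeps the traced points repeatedly,
#' updating the coefficients per sample with step size `alphaLr`, and
#' stops once the largest coefficient change over a full sweep falls below
#' `thetaTol` (or after `episodes` sweeps, a safety cap).
#'
#' @slot degree polynomial degree (default 2: three coefficients).
#' @slot alphaLr per-sample learning rate.
#' @slot episodes hard cap on full sweeps over the traced points.
#' @slot neighborhood maximal number of points traced from the endpoint.
#' @slot ignoreNearGap traced points dropped nearest the gap.
#' @slot thetaTol coefficient-change tolerance terminating the sweeps.
#' @slot batchSize gradient accumulation length in `"batch"` mode.
#' @slot mode `"instant"` (update per sample) or `"batch"`.
#' @export
setClass("FitConfig",
  representation(degree = "integer", alphaLr = "numeric",
                 episodes = "integer", neighborhood = "integer",
                 ignoreNearGap = "integer", thetaTol = "numeric",
                 batchSize = "integer", mode = "character"),
  validity = function(object) {
    msg <- character()
    if (object@degree < 1L) msg <- c(msg, "degree must be >= 1")
    if (object@alphaLr <= 0) msg <- c(msg, "alphaLr must be positive")
    if (object@episodes < 1L) msg <- c(msg, "episodes must be >= 1")
    if (object@neighborhood < 1L) msg <- c(msg, "neighborhood must be >= 1")
    if (object@ignoreNearGap < 0L) msg <- c(msg, "ignoreNearGap must be >= 0")
    if (object@ignoreNearGap >= object@neighborhood)
      msg <- c(msg, "ignoreNearGap must be < neighborhood")
    if (object@thetaTol <= 0) msg <- c(msg, "thetaTol must be positive")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (!object@mode %in% c("instant", "batch"))
      msg <- c(msg, "mode must be 'instant' or 'batch'")
    if (length(msg)) msg else TRUE
  })

#' Construct a FitConfig
#'
#' @param degree,alphaLr,episodes,neighborhood,ignoreNearGap,thetaTol,batchSize,mode
#'   see [FitConfig-class].
#' @return a [FitConfig-class] object.
#' @export
fitConfig <- function(degree = 2L, alphaLr = 0.1, episodes = 500L,
                      neighborhood = 15L, ignoreNearGap = 2L,
                      thetaTol = 0.001, batchSize = 5L, mode = "instant") {
  new("FitConfig", degree = as.integer(degree), alphaLr = alphaLr,
      episodes = as.integer(episodes), neighborhood = as.integer(neighborhood),
      ignoreNearGap = as.integer(ignoreNearGap), thetaTol = thetaTol,
      batchSize = as.integer(batchSize), mode = mode)
}

setMethod("show", "FitConfig", function(object) {
  cat("FitConfig: degree", object@degree, "(", object@degree + 1L,
      "coefficients ),", object@mode, "updates\n")
  cat("  alphaLr:", object@alphaLr, " thetaTol:", object@thetaTol,
      " sweeps <=", object@episodes, "\n")
  cat("  neighborhood:", object@neighborhood,
      " ignoreNearGap:", object@ignoreNearGap, "\n")
})

#' Configuration for the SARSA(lambda) gap-closing walker
#'
#' Parameters of [closeGap()] and [amendBoundaries()]. Rewards follow the
#' marked/blank rule: stepping onto a marked pixel earns `gain`, onto a
#' blank pixel costs `gapPenalty`, and in both cases `modelWeight` times
#' the fitted-curve distance of the target pixel is subtracted, so the
#' walker is pushed along the local curve model.
#'
#' @slot alphaLr TD-update step size.
#' @slot gamma discount rate in `[0, 1)`.
#' @slot lambda eligibility-trace decay in `[0, 1]`.
#' @slot epsilon initial exploration rate of the epsilon-greedy policy.
#' @slot epsilonDecay multiplicative epsilon decay per episode.
#' @slot gapPenalty penalisation for stepping onto a blank pixel.
#' @slot gain reward for stepping onto a marked pixel.
#' @slot qThreshold episode aborts when the chosen Q drops below this.
#' @slot maximalStep per-episode step cap.
#' @slot maxGapLen gaps longer than this (straight-line px) are skipped.
#' @slot episodes walker episodes per gap.
#' @slot modelWeight coupling of the curve-model distance into the reward.
#' @slot maskMoves when `TRUE`, moves that increase the model distance are
#'   excluded from the action set (unless no move would remain).
#' @slot armRadius geodesic radius (px along the curve) defining the
#'   endpoint's own arm; reaching marked pixels outside it closes the gap.
#' @export
setClass("SarsaConfig",
  representation(alphaLr = "numeric", gamma = "numeric", lambda = "numeric",
                 epsilon = "numeric", epsilonDecay = "numeric",
                 gapPenalty = "numeric", gain = "numeric",
                 qThreshold = "numeric", maximalStep = "integer",
                 maxGapLen = "numeric", episodes = "integer",
                 modelWeight = "numeric", maskMoves = "logical",
                 armRadius = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@gamma < 0 || object@gamma >= 1)
      msg <- c(msg, "gamma must be in [0, 1)")
    if (object@lambda < 0 || object@lambda > 1)
      msg <- c(msg, "lambda must be in [0, 1]")
    if (object@epsilon < 0 || object@epsilon > 1)
      msg <- c(msg, "epsilon must be in [0, 1]")
    if (object@gapPenalty <= 0) msg <- c(msg, "gapPenalty must be positive")
    if (object@gain <= 0) msg <- c(msg, "gain must be positive")
    if (object@alphaLr <= 0) msg <- c(msg, "alphaLr must be positive")
    if (object@maximalStep < 0L) msg <- c(msg, "maximalStep must be >= 0")
    if (object@episodes < 1L) msg <- c(msg, "episodes must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a SarsaConfig
#'
#' Defaults: step size 0.1, discount 0.95, trace decay 0.9, epsilon 0.1
#' decayed by 0.95 per episode, gain 1, gap penalty 10, one episode per
#' gap, gap skip threshold 15 px, step cap `40 * maxGapLen`.
#'
#' @param alphaLr,gamma,lambda,epsilon,epsilonDecay,gapPenalty,gain,qThreshold,maximalStep,maxGapLen,episodes,modelWeight,maskMoves,armRadius
#'   see [SarsaConfig-class]; `maximalStep = NULL` selects `40 * maxGapLen`.
#' @return a [SarsaConfig-class] object.
#' @export
sarsaConfig <- function(alphaLr = 0.1, gamma = 0.95, lambda = 0.9,
                        epsilon = 0.1, epsilonDecay = 0.95, gapPenalty = 10,
                        gain = 1, qThreshold = -100, maximalStep = NULL,
                        maxGapLen = 15, episodes = 1L, modelWeight = 1,
                        maskMoves = FALSE, armRadius = 15L) {
  if (is.null(maximalStep)) maximalStep <- as.integer(40 * maxGapLen)
  new("SarsaConfig", alphaLr = alphaLr, gamma = gamma, lambda = lambda,
      epsilon = epsilon, epsilonDecay = epsilonDecay, gapPenalty = gapPenalty,
      gain = gain, qThreshold = qThreshold,
      maximalStep = as.integer(maximalStep), maxGapLen = maxGapLen,
      episodes = as.integer(episodes), modelWeight = modelWeight,
      maskMoves = maskMoves, armRadius = as.integer(armRadius))
}

setMethod("show", "SarsaConfig", function(object) {
  cat("SarsaConfig: alpha", object@alphaLr, " gamma", object@gamma,
      " lambda", object@lambda, "\n")
  cat("  reward: +", object@gain, " marked / -", object@gapPenalty,
      " blank, model weight ", object@modelWeight, "\n", sep = "")
  cat("  episodes:", object@episodes, " epsilon:", object@epsilon,
      " step cap:", object@maximalStep, " max gap:", object@maxGapLen, "\n")
})

#' Specification of a synthetic EM-like phantom
#'
#' Describes the phantom drawn by [generatePhantom()]: a Voronoi partition
#' of the canvas into cells bounded by dark membranes on a bright
#' background, with elliptical organelle-like clutter inside the cells and
#' additive Gaussian noise.
#'
#' @slot shape (height, width) in pixels.
#' @slot nCells number of cell regions.
#' @slot membraneWidth rendered membrane width in pixels.
#' @slot membraneDarkness intensity drop of the membrane, in `[0, 1]`.
#' @slot clutterDensity clutter blobs per 1000 square pixels.
#' @slot noiseSigma Gaussian noise standard deviation (intensity units).
#' @slot seed RNG seed; the phantom is fully determined by it.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", nCells = "integer",
                 membraneWidth = "numeric", membraneDarkness = "numeric",
                 clutterDensity = "numeric", noiseSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 2L || any(object@shape < 16L))
      msg <- c(msg, "shape must be (height, width), each >= 16")
    if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
    if (object@membraneWidth < 1) msg <- c(msg, "membraneWidth must be >= 1")
    if (object@membraneDarkness < 0 || object@membraneDarkness > 1)
      msg <- c(msg, "membraneDarkness must be in [0, 1]")
    if (object@clutterDensity < 0) msg <- c(msg, "clutterDensity must be >= 0")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a PhantomSpec
#'
#' @param shape,nCells,membraneWidth,membraneDarkness,clutterDensity,noiseSigma,seed
#'   see [PhantomSpec-class].
#' @return a [PhantomSpec-class] object.
#' @examples
#' phantomSpec(shape = c(128, 128), nCells = 6, seed = 7)
#' @export
phantomSpec <- function(shape = c(256L, 256L), nCells = 12L,
                        membraneWidth = 3, membraneDarkness = 0.6,
                        clutterDensity = 0.5, noiseSigma = 0.1, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), nCells = as.integer(nCells),
      membraneWidth = membraneWidth, membraneDarkness = membraneDarkness,
      clutterDensity = clutterDensity, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@shape, collapse = "x"), "canvas,",
      object@nCells, "cells\n")
  cat("  membrane: width", object@membraneWidth, "darkness",
      object@membraneDarkness, "\n")
  cat("  clutter:", object@clutterDensity, "/1000px^2  noise sigma:",
      object@noiseSigma, " seed:", object@seed, "\n")
})

#' Local polynomial model of a curve segment
#'
#' The fitted curve is \eqn{y = \theta_0 + \theta_1 x + \dots + \theta_n
#' x^n} in oriented coordinates: when `axisSwapped` is `TRUE` the roles of
#' row and column were exchanged during fitting (near-vertical segments),
#' and [fitCost()] maps candidate pixels accordingly.
#'
#' @slot theta coefficients, constant term first.
#' @slot degree polynomial degree (`length(theta) == degree + 1`).
#' @slot axisSwapped whether x/y were exchanged to make the segment
#'   function-like.
#' @export
setClass("CurveModel",
  representation(theta = "numeric", degree = "integer",
                 axisSwapped = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@theta) != object@degree + 1L)
      msg <- c(msg, "theta must have degree + 1 coefficients")
    if (any(!is.finite(object@theta)))
      msg <- c(msg, "theta must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a CurveModel
#'
#' @param theta coefficient vector, constant term first.
#' @param axisSwapped whether x and y were exchanged during fitting.
#' @return a [CurveModel-class] object.
#' @examples
#' curveModel(c(3, -1, 0.5))   # y = 3 - x + 0.5 x^2
#' @export
curveModel <- function(theta, axisSwapped = FALSE) {
  new("CurveModel", theta = as.numeric(theta),
      degree = length(theta) - 1L, axisSwapped = axisSwapped)
}

setMethod("show", "CurveModel", function(object) {
  terms <- paste0(signif(object@theta, 4),
                  c("", paste0("*x^", seq_len(object@degree))))
  cat("CurveModel: y =", paste(terms, collapse = " + "),
      if (object@axisSwapped) "(axes swapped)" else "", "\n")
})
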