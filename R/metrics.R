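# Evaluation measures for boundary maps and the segmentations they induce.

#' Pixel-wise confusion counts between two binary boundary maps
#'
#' @param pred,truth binary matrices of identical dimension (1 = boundary).
#' @return a named list with integer fields `tp`, `fp`, `fn`, `tn`
#'   partitioning all pixels.
#' @examples
#' p <- matrix(0, 3, 3); t <- matrix(0, 3, 3)
#' p[1, 1] <- 1; p[2, 2] <- 1; t[2, 2] <- 1; t[3, 3] <- 1
#' confusionCounts(p, t)   # tp 1, fp 1, fn 1, tn 6
#' @export
confusionCounts <- function(pred, truth) {
  checkSameDim(pred, truth)
  p <- pred != 0; t <- truth != 0
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' Precision, recall and F-score from confusion counts
#'
#' Precision is the probability that a detected boundary pixel is a true
#' one, recall the probability that a true boundary pixel is detected, and
#' the F-score their harmonic mean. A zero denominator yields 0 for the
#' affected quantity (with a warning) so that macro averages stay defined.
#'
#' @param counts list with `tp`, `fp`, `fn` as from [confusionCounts()].
#' @return named numeric vector `precision`, `recall`, `fScore`.
#' @examples
#' precisionRecallF(list(tp = 8, fp = 2, fn = 4))
#' @export
precisionRecallF <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp > 0) precision <- tp / (tp + fp) else {
    warning("no predicted positives; precision set to 0")
    precision <- 0
  }
  if (tp + fn > 0) recall <- tp / (tp + fn) else {
    warning("no true positives in reference; recall set to 0")
    recall <- 0
  }
  fScore <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, fScore = fScore)
}

#' Pixel error of a (possibly graded) boundary prediction
#'
#' Defined as 1 minus the maximal F-score of the pixel similarity. For a
#' binary prediction this is simply `1 - F` of that binarisation; for a
#' graded prediction the F-score is maximised over thresholds drawn from
#' the distinct predicted values together with 0 and 1 (binarising at
#' `pred >= t`).
#'
#' @param pred numeric matrix in `[0, 1]`.
#' @param truth binary matrix of the same dimension.
#' @return pixel error in `[0, 1]`.
#' @export
pixelError <- function(pred, truth) {
  checkSameDim(pred, truth)
  if (all(pred %in% c(0, 1))) {
    f <- suppressWarnings(precisionRecallF(confusionCounts(pred, truth)))
    return(1 - unname(f["fScore"]))
  }
  thresholds <- sort(unique(c(0, 1, as.vector(pred))))
  t <- truth != 0
  bestF <- 0
  for (th in thresholds) {
    p <- pred >= th
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (f > bestF) bestF <- f
  }
  1 - bestF
}

#' Region labelling induced by a boundary map
#'
#' Non-boundary pixels are labelled by 4-connected component labelling;
#' boundary pixels receive label 0 and are excluded from Rand pair
#' counting. An 8-connected boundary curve is a barrier to the 4-connected
#' flood, so closed curves separate regions.
#'
#' @param map binary boundary matrix.
#' @return integer matrix of region IDs (0 on the boundary).
#' @examples
#' m <- matrix(0, 5, 5); m[3, ] <- 1
#' max(regionsFromBoundary(m))   # 2 regions
#' @export
regionsFromBoundary <- function(map) {
  checkBinary(map)
  lab <- EBImage::bwlabel(1 - map)
  storage.mode(lab) <- "integer"
  matrix(lab, nrow(map), ncol(map))
}

#' Rand index of two region labelings
#'
#' The fraction of pixel pairs on which the two labelings agree (either
#' co-clustered in both or separated in both). Pixels labelled 0 in either
#' input are excluded from pair counting.
#'
#' @param x,y integer label matrices of identical dimension.
#' @return Rand index in `[0, 1]`; 1 for identical labelings.
#' @export
randIndex <- function(x, y) {
  checkSameDim(x, y)
  keep <- x != 0 & y != 0
  n <- sum(keep)
  if (n < 2) stop("fewer than 2 scored pixels; Rand index undefined")
  tab <- table(x[keep], y[keep])
  nij2 <- sum(choose(tab, 2))
  ni2 <- sum(choose(rowSums(tab), 2))
  nj2 <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  a <- nij2                      # co-clustered in both
  b <- tot - ni2 - nj2 + nij2    # separated in both
  (a + b) / tot
}

#' Rand error
#'
#' `1 - randIndex(x, y)`: the frequency with which the two segmentations
#' disagree over whether a pixel pair belongs to the same object.
#'
#' @inheritParams randIndex
#' @return Rand error in `[0, 1]`.
#' @export
randError <- function(x, y) 1 - randIndex(x, y)

#' Macro-averaged metrics over a set of per-image reports
#'
#' Each macro value is the unweighted arithmetic mean of the corresponding
#' per-image value.
#'
#' @param reports data frame with one row per image, as produced by
#'   [evaluateBoundary()] (or any data frame of numeric metric columns).
#' @return named numeric vector of column means, with an `nImages`
#'   attribute.
#' @export
macroMetrics <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) == 0L) stop("no reports to average")
  num <- vapply(reports, is.numeric, logical(1))
  out <- colMeans(reports[, num, drop = FALSE])
  attr(out, "nImages") <- nrow(reports)
  out
}

#' Boundary recall with a pixel tolerance
#'
#' Fraction of reference boundary pixels that have a predicted boundary
#' pixel within `tol` pixels (Chebyshev distance). This is the tolerant
#' recall used to judge detector coverage of thin reference centerlines.
#'
#' @param pred,truth binary boundary matrices.
#' @param tol matching tolerance in pixels.
#' @return recall in `[0, 1]`.
#' @export
boundaryRecall <- function(pred, truth, tol = 1L) {
  checkSameDim(pred, truth)
  grown <- pred
  for (i in seq_len(tol)) grown <- dilate3x3(grown)
  if (sum(truth) == 0) return(0)
  sum(truth == 1 & grown == 1) / sum(truth)
}

#' Full metric report for one prediction/reference pair
#'
#' Computes precision, recall, F-score, pixel error, Rand index/error on
#' the induced region labelings, and (optionally) the warping error.
#'
#' @param pred binary predicted boundary matrix.
#' @param truth binary reference boundary matrix.
#' @param metrics character vector choosing among `"pixel"`, `"rand"`,
#'   `"warping"`; precision/recall/F are always reported.
#' @return one-row data frame with columns `precision`, `recall`,
#'   `fScore`, and the selected `pixelError`, `randIndex`, `randError`,
#'   `warpingError`.
#' @export
evaluateBoundary <- function(pred, truth,
                             metrics = c("pixel", "rand", "warping")) {
  checkSameDim(pred, truth)
  metrics <- match.arg(metrics, several.ok = TRUE)
  prf <- suppressWarnings(precisionRecallF(confusionCounts(pred, truth)))
  out <- data.frame(precision = prf[["precision"]], recall = prf[["recall"]],
                    fScore = prf[["fScore"]])
  if ("pixel" %in% metrics) out$pixelError <- pixelError(pred, truth)
  if ("rand" %in% metrics) {
    ri <- randIndex(regionsFromBoundary(pred), regionsFromBoundary(truth))
    out$randIndex <- ri
    out$randError <- 1 - ri
  }
  if ("warping" %in% metrics) out$warpingError <- warpingError(pred, truth)
  out
}
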