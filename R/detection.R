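# Multi-scale fused structure boundary detection: a Gaussian pyramid,
# per-level Laplacian-of-Gaussian zero-crossing extraction, and a weighted
# per-pixel vote across levels.

# 5x5 binomial approximation of the Gaussian used between pyramid levels.
BINOMIAL5 <- c(1, 4, 6, 4, 1) / 16

#' Gaussian pyramid of a grayscale image
#'
#' Level 1 is the input; each further level is the previous one convolved
#' with a separable 5x5 binomial kernel (reflect padding) and decimated by
#' 2 (odd rows/columns kept), so level `i` has size `ceiling(size / 2^(i-1))`.
#'
#' @param img numeric matrix (intensities, any range).
#' @param l number of levels (`>= 1`); the coarsest level must keep at
#'   least 8 pixels along each side.
#' @return list of matrices, finest first.
#' @export
gaussianPyramid <- function(img, l = 3L) {
  l <- as.integer(l)
  stopifnot(l >= 1L)
  minSide <- min(dim(img))
  if (minSide / 2^(l - 1L) < 8)
    stop("image too small for ", l, " pyramid levels; need min side >= ",
         8 * 2^(l - 1L))
  levels <- vector("list", l)
  levels[[1L]] <- img
  for (i in seq_len(l - 1L)) {
    sm <- convSepReflect(levels[[i]], BINOMIAL5)
    levels[[i + 1L]] <- sm[seq(1L, nrow(sm), by = 2L),
                           seq(1L, ncol(sm), by = 2L), drop = FALSE]
  }
  levels
}

#' Laplacian-of-Gaussian response
#'
#' Gaussian blur at scale `sigma` (separable kernel truncated at 3 sigma,
#' reflect padding) followed by the 4-neighbour discrete Laplacian. The
#' response of a constant image is identically zero.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian scale in pixels (`> 0`).
#' @return numeric matrix of the same dimension.
#' @export
logResponse <- function(img, sigma = 1) {
  g <- convSepReflect(img, gaussKernel1D(sigma))
  p <- reflectPad(g, 1L)
  nr <- nrow(g); nc <- ncol(g)
  ctr <- p[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  p[1:nr, 2:(nc + 1L), drop = FALSE] + p[3:(nr + 2L), 2:(nc + 1L), drop = FALSE] +
    p[2:(nr + 1L), 1:nc, drop = FALSE] + p[2:(nr + 1L), 3:(nc + 2L), drop = FALSE] -
    4 * ctr
}

#' Boundary map from LoG zero crossings
#'
#' A pixel is marked when its response changes sign against a 4-neighbour
#' and the magnitude of the response difference across the crossing
#' exceeds `gradThresh`. Of each crossing pair, the pixel with the smaller
#' absolute response is marked (it sits closer to the true zero crossing,
#' hence to the boundary centre). The outermost 1-px frame is never
#' marked.
#'
#' @param response numeric matrix, e.g. from [logResponse()].
#' @param gradThresh non-negative crossing-strength gate.
#' @return binary matrix.
#' @export
boundaryFromLog <- function(response, gradThresh = 0) {
  nr <- nrow(response); nc <- ncol(response)
  out <- matrix(0, nr, nc)
  if (nc >= 2L) {
    a <- response[, -nc, drop = FALSE]; b <- response[, -1L, drop = FALSE]
    cross <- (a * b < 0) & (abs(a - b) > gradThresh)
    markA <- cross & (abs(a) <= abs(b))
    markB <- cross & !markA
    out[, -nc] <- out[, -nc] + markA
    out[, -1L] <- out[, -1L] + markB
  }
  if (nr >= 2L) {
    a <- response[-nr, , drop = FALSE]; b <- response[-1L, , drop = FALSE]
    cross <- (a * b < 0) & (abs(a - b) > gradThresh)
    markA <- cross & (abs(a) <= abs(b))
    markB <- cross & !markA
    out[-nr, ] <- out[-nr, ] + markA
    out[-1L, ] <- out[-1L, ] + markB
  }
  out <- (out > 0) * 1
  out[c(1L, nr), ] <- 0
  out[, c(1L, nc)] <- 0
  out
}

#' Upsample a coarse-level boundary map to base resolution
#'
#' Nearest-neighbour block upsampling by `factor`, cropped or zero-padded
#' to `outDim`, followed by one 3x3 dilation when `factor > 1` (tolerating
#' the ~1-px positional drift between adjacent scales).
#'
#' @param map binary matrix at a coarse level.
#' @param factor integer upsampling factor (`2^(level-1)`).
#' @param outDim target (rows, cols); defaults to `dim(map) * factor`.
#' @return binary matrix of dimension `outDim`.
#' @export
upsampleBoundary <- function(map, factor = 1L, outDim = NULL) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor > 1L)
    map <- map[rep(seq_len(nrow(map)), each = factor),
               rep(seq_len(ncol(map)), each = factor), drop = FALSE]
  if (is.null(outDim)) outDim <- dim(map)
  out <- matrix(0, outDim[1L], outDim[2L])
  rr <- seq_len(min(nrow(map), outDim[1L]))
  cc <- seq_len(min(ncol(map), outDim[2L]))
  out[rr, cc] <- map[rr, cc]
  if (factor > 1L) out <- dilate3x3(out)
  out
}

#' Fuse per-level boundary maps by weighted voting
#'
#' Per pixel, the fusion account is the sum over levels of
#' `alpha * weight[i]` where level `i` marks the pixel and `beta` where it
#' does not; the pixel is marked when the account is not below
#' `threshold`.
#'
#' @param maps list of binary matrices at base resolution, finest first.
#' @param cfg a [FusionConfig-class] with one weight per map.
#' @return binary matrix.
#' @export
fuseBoundaries <- function(maps, cfg = fusionConfig(length(maps))) {
  l <- length(maps)
  if (length(cfg@weight) != l)
    stop("config carries ", length(cfg@weight), " weights for ", l, " maps")
  for (m in maps) checkSameDim(m, maps[[1L]])
  account <- matrix(0, nrow(maps[[1L]]), ncol(maps[[1L]]))
  for (i in seq_len(l))
    account <- account +
      ifelse(maps[[i]] != 0, cfg@alpha * cfg@weight[i], cfg@beta)
  (account >= cfg@threshold) * 1
}

#' Multi-scale fused boundary detection
#'
#' The full detection pipeline: Gaussian pyramid, per-level LoG
#' zero-crossing boundary extraction, upsampling of every level to base
#' resolution, and the weighted fusion vote. Deterministic for fixed
#' inputs.
#'
#' @param img numeric matrix (grayscale intensities in `[0, 1]`).
#' @param cfg a [FusionConfig-class]; its weight/sigma length sets the
#'   default level count.
#' @param l number of pyramid levels; defaults to the config's.
#' @return binary boundary matrix at the input resolution, with a
#'   `levelCounts` attribute giving the per-level marked-pixel counts
#'   (after upsampling).
#' @examples
#' img <- matrix(1, 64, 64); img[, 30:33] <- 0.3
#' b <- detectBoundaries(img, fusionConfig(levels = 2), l = 2)
#' sum(b) > 0
#' @export
detectBoundaries <- function(img, cfg = fusionConfig(), l = length(cfg@weight)) {
  l <- as.integer(l)
  if (length(cfg@weight) != l)
    stop("config carries ", length(cfg@weight), " weights for ", l, " levels")
  pyr <- gaussianPyramid(img, l)
  base <- dim(img)
  maps <- vector("list", l)
  for (i in seq_len(l)) {
    resp <- logResponse(pyr[[i]], cfg@sigma[i])
    bnd <- boundaryFromLog(resp, cfg@gradThresh)
    maps[[i]] <- upsampleBoundary(bnd, 2L^(i - 1L), outDim = base)
  }
  fused <- fuseBoundaries(maps, cfg)
  attr(fused, "levelCounts") <- vapply(maps, sum, numeric(1))
  fused
}
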