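# Low-level raster helpers shared by every module. All rasters are plain
# base matrices indexed [row, col], 1-based, origin top-left. Binary maps
# use 1 = marked (boundary) and 0 = blank.

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shiftMat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# The 8 chessboard moves, fixed order: N, NE, E, SE, S, SW, W, NW.
MOVES <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                  1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                ncol = 2L, byrow = TRUE,
                dimnames = list(c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
                                c("dr", "dc")))

# Count of marked 8-neighbours for every pixel of a binary map.
neighborCount8 <- function(map) {
  out <- matrix(0, nrow(map), ncol(map))
  for (i in seq_len(8L))
    out <- out + shiftMat(map, MOVES[i, 1L], MOVES[i, 2L])
  out
}

# Reflect-pad a matrix by r rows/cols on every side (edge-mirrored).
reflectPad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(r, nr))), seq_len(nr),
          rev(seq_len(nr))[seq_len(min(r, nr))])
  ci <- c(rev(seq_len(min(r, nc))), seq_len(nc),
          rev(seq_len(nc))[seq_len(min(r, nc))])
  m[ri, ci, drop = FALSE]
}

# Separable convolution with an odd 1-D kernel applied along rows then
# columns, reflect padding. Kernel centre at (length+1)/2.
convSepReflect <- function(img, kernel) {
  stopifnot(length(kernel) %% 2L == 1L)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(img * kernel)
  nr <- nrow(img); nc <- ncol(img)
  p <- reflectPad(img, r)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(kernel))
    tmp <- tmp + kernel[i] * p[(i):(i + nr - 1L), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(kernel))
    out <- out + kernel[i] * tmp[, (i):(i + nc - 1L), drop = FALSE]
  out
}

# Normalised 1-D Gaussian kernel truncated at 3 sigma (radius >= 1).
gaussKernel1D <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# One binary dilation with a 3x3 (8-connected) structuring element.
dilate3x3 <- function(map) {
  out <- map
  for (i in seq_len(8L))
    out <- pmax(out, shiftMat(map, MOVES[i, 1L], MOVES[i, 2L]))
  out
}

checkSameDim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("rasters differ in dimension: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

checkBinary <- function(map) {
  if (!all(map %in% c(0, 1)))
    stop("binary boundary map expected (values 0/1)")
  invisible(TRUE)
}

#' Count connected components of a binary mask
#'
#' Components are counted by iterative minimum-label propagation, so the
#' result does not depend on the simple-point machinery used by
#' [warpingError()]; the two can therefore cross-check each other.
#'
#' @param mask binary matrix (nonzero = foreground).
#' @param connectivity 4 or 8.
#' @return integer component count.
#' @export
countComponents <- function(mask, connectivity = 8) {
  mask <- mask != 0
  if (!any(mask)) return(0L)
  lab <- matrix(as.numeric(seq_along(mask)), nrow(mask), ncol(mask))
  lab[!mask] <- Inf
  offs <- if (connectivity == 8) seq_len(8L) else c(1L, 3L, 5L, 7L)
  repeat {
    nb <- lab
    for (i in offs)
      nb <- pmin(nb, shiftMat(lab, MOVES[i, 1L], MOVES[i, 2L], fill = Inf))
    nb[!mask] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  length(unique(lab[is.finite(lab)]))
}

# 8-connected labelling of marked pixels: 4-connected labelling (EBImage)
# of the 3x3-dilated map, read back on the original marked set. Curves
# closer than 2 px may share a label; adequate as a curve identifier.
labelCurves8 <- function(map) {
  lab <- EBImage::bwlabel(dilate3x3(map))
  lab[map == 0] <- 0L
  lab
}
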