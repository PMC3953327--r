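# Morphological thinning (Zhang-Suen), used to reduce rendered membrane
# bands to 1-px, 8-connected centerline skeletons.

#' Thin a binary mask to a 1-px skeleton
#'
#' Zhang-Suen thinning: two alternating sub-iterations delete contour
#' pixels whose neighbourhood passes the connectivity and contour tests,
#' until the mask stops changing. The result is an 8-connected skeleton
#' that preserves the topology of the input; line ends are kept.
#'
#' @param mask binary matrix.
#' @return binary matrix of the thinned mask.
#' @export
thinBoundary <- function(mask) {
  m <- (mask != 0) * 1
  # neighbours P2..P9 clockwise from north
  offs <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                   1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                 ncol = 2L, byrow = TRUE)
  repeat {
    changedAny <- FALSE
    for (phase in 1:2) {
      P <- lapply(seq_len(8L), function(i)
        shiftMat(m, -offs[i, 1L], -offs[i, 2L]))
      B <- Reduce(`+`, P)
      A <- matrix(0, nrow(m), ncol(m))
      for (i in seq_len(8L)) {
        j <- if (i == 8L) 1L else i + 1L
        A <- A + (P[[i]] == 0 & P[[j]] == 1)
      }
      if (phase == 1L)
        cond <- P[[1L]] * P[[3L]] * P[[5L]] == 0 &
                P[[3L]] * P[[5L]] * P[[7L]] == 0
      else
        cond <- P[[1L]] * P[[3L]] * P[[7L]] == 0 &
                P[[1L]] * P[[5L]] * P[[7L]] == 0
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- 0
        changedAny <- TRUE
      }
    }
    if (!changedAny) break
  }
  m
}
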