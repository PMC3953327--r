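# Warping error: Hamming distance between a candidate map and the best
# topology-preserving deformation of the reference onto it. The admissible
# deformation steps are single-pixel flips of "simple points" in the
# standard 2-D digital-topology sense (foreground 8-connectivity,
# background 4-connectivity), so every accepted flip leaves the number of
# foreground and background components unchanged.

# Ring cell offsets around a pixel, fixed order (used for the pattern LUT).
RING <- matrix(c(-1L, -1L, -1L, 0L, -1L, 1L, 0L, 1L,
                 1L, 1L, 1L, 0L, 1L, -1L, 0L, -1L),
               ncol = 2L, byrow = TRUE)

# Component assignment for a subset of ring cells under an adjacency rule.
ringComponents <- function(cells, adjacent) {
  if (length(cells) == 0L) return(integer(0))
  comp <- seq_along(cells)
  repeat {
    changed <- FALSE
    for (i in seq_along(cells)) for (j in seq_along(cells)) {
      if (comp[i] != comp[j] && adjacent[cells[i], cells[j]]) {
        m <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# 256-entry lookup: for each 8-bit neighbourhood pattern (bit i-1 set when
# ring cell i is foreground), whether the centre pixel is a simple point.
# Simple iff the foreground ring cells form exactly one 8-connected
# component and the background ring cells form exactly one 4-connected
# component containing a 4-neighbour of the centre.
makeSimpleLUT <- function() {
  d <- as.matrix(stats::dist(RING, method = "maximum"))
  adj8 <- d <= 1 & d > 0
  dm <- as.matrix(stats::dist(RING, method = "manhattan"))
  adj4 <- dm == 1
  edgeCells <- which(abs(RING[, 1L]) + abs(RING[, 2L]) == 1L)
  lut <- logical(256L)
  for (pat in 0:255) {
    fg <- which(bitwAnd(pat, bitwShiftL(1L, 0:7)) != 0L)
    bg <- setdiff(1:8, fg)
    if (length(fg) == 0L || length(bg) == 0L) { lut[pat + 1L] <- FALSE; next }
    tfg <- length(unique(ringComponents(fg, adj8))) == 1L
    # topological number of the background: 4-components of the background
    # ring cells that contain a 4-neighbour of the centre
    bgComp <- ringComponents(bg, adj4)
    tbg <- length(unique(bgComp[bg %in% edgeCells])) == 1L
    lut[pat + 1L] <- tfg && tbg
  }
  lut
}

.simpleLUT <- NULL

simpleLUT <- function() {
  if (is.null(.simpleLUT))
    utils::assignInMyNamespace(".simpleLUT", makeSimpleLUT())
  .simpleLUT
}

# Neighbourhood bit pattern of pixel (r, c); out-of-canvas cells count as
# background.
neighborPattern <- function(map, r, c) {
  nr <- nrow(map); nc <- ncol(map)
  pat <- 0L
  for (i in 1:8) {
    rr <- r + RING[i, 1L]; cc <- c + RING[i, 2L]
    if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && map[rr, cc] != 0)
      pat <- pat + bitwShiftL(1L, i - 1L)
  }
  pat
}

# Whether flipping (r, c) preserves digital topology. The criterion does
# not depend on the pixel's current value, so it covers both additions and
# deletions.
isSimplePoint <- function(map, r, c) {
  simpleLUT()[neighborPattern(map, r, c) + 1L]
}

#' Warping error between a candidate and a reference boundary map
#'
#' Greedily deforms the reference onto the candidate by repeatedly
#' flipping, in raster order, any mismatched pixel that is a simple point
#' of the current warped reference (each such flip reduces the Hamming
#' distance by one and preserves the component counts of foreground and
#' background). The warping error is the normalised Hamming distance left
#' when no admissible flip reduces the disagreement further: boundary
#' displacements are forgiven, topological disagreements (splits, merges,
#' holes) are not.
#'
#' Because the descent is greedy, the scan order matters: a single order
#' can wedge the warped reference into a configuration where every
#' remaining mismatch is non-simple even though a different flip sequence
#' would have resolved it. The descent is therefore attempted under a
#' fixed family of deterministic scan orders (forward and reverse raster,
#' each plain, additions-first and deletions-first) and the best warping
#' found is reported; every accepted flip in every attempt is still a
#' simple-point flip.
#'
#' @param candidate,reference binary matrices of identical dimension.
#' @param details when `TRUE`, also return the flip sequence and the final
#'   warped reference (of the best attempt).
#' @return the warping error in `[0, 1]`; with `details = TRUE` a list
#'   with fields `error`, `flips` (n x 2 matrix of row/col, in flip
#'   order) and `warped`.
#' @export
warpingError <- function(candidate, reference, details = FALSE) {
  checkSameDim(candidate, reference)
  checkBinary(candidate); checkBinary(reference)
  lut <- simpleLUT()
  nr <- nrow(reference)
  descend <- function(reorder) {
    warped <- reference
    flips <- list()
    repeat {
      mis <- which(warped != candidate)
      if (length(mis) == 0L) break
      mis <- reorder(mis, warped)
      flipped <- FALSE
      for (idx in mis) {
        if (warped[idx] == candidate[idx]) next
        r <- ((idx - 1L) %% nr) + 1L
        c <- ((idx - 1L) %/% nr) + 1L
        if (lut[neighborPattern(warped, r, c) + 1L]) {
          warped[idx] <- candidate[idx]
          if (details) flips[[length(flips) + 1L]] <- c(r, c)
          flipped <- TRUE
        }
      }
      if (!flipped) break
    }
    list(warped = warped, flips = flips,
         ham = sum(warped != candidate))
  }
  orders <- list(
    function(m, w) m,
    function(m, w) rev(m),
    function(m, w) m[order(w[m] == 1)],          # additions first
    function(m, w) m[order(w[m] == 0)],          # deletions first
    function(m, w) rev(m[order(w[m] == 0)]),
    function(m, w) rev(m[order(w[m] == 1)]))
  best <- NULL
  for (o in orders) {
    res <- descend(o)
    if (is.null(best) || res$ham < best$ham) best <- res
    if (best$ham == 0L) break
  }
  err <- best$ham / length(candidate)
  if (!details) return(err)
  list(error = err,
       flips = if (length(best$flips)) do.call(rbind, best$flips)
               else matrix(integer(), 0L, 2L),
       warped = best$warped)
}
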