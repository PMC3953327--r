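# Synthetic EM-like phantoms: Voronoi cell partitions bounded by dark
# membranes, organelle-like clutter, additive noise, exact ground truth,
# and controlled gap injection. Every other module is testable on these
# with no external data.

#' Generate a synthetic EM-like phantom
#'
#' Seeds a Voronoi partition of the canvas into `nCells` regions (seed
#' points rejection-sampled to a minimum separation of
#' `0.5 * sqrt(area / nCells)`, giving cells of comparable size), renders
#' the region borders as dark membranes of the requested width on a bright
#' background, scatters dark elliptical clutter blobs strictly inside the
#' cells (emulating intracellular organelles), lightly blurs the render,
#' and adds clipped Gaussian noise. The ground-truth boundary map is the
#' 1-px, 8-connected skeleton of the rendered membrane ([thinBoundary()]);
#' the fields are computed on an internally padded canvas so membranes
#' meet the image border cleanly. Fully determined by `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `image` (grayscale matrix in `[0, 1]`), `truth`
#'   (binary centerline boundary map) and `labels` (integer Voronoi
#'   region IDs, every pixel labelled).
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(64, 64), nCells = 2,
#'                                   noiseSigma = 0, clutterDensity = 0,
#'                                   seed = 3))
#' max(regionsFromBoundary(ph$truth))   # 2 regions
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  H <- spec@shape[1L]; W <- spec@shape[2L]
  n <- spec@nCells
  if (H * W / n < 64)
    stop("canvas cannot fit ", n, " cells: mean cell area would be ",
         round(H * W / n, 1), " px^2 (need >= 64)")
  minSep <- 0.5 * sqrt(H * W / n)
  seeds <- matrix(0, 0L, 2L)
  tries <- 0L
  while (nrow(seeds) < n) {
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("cannot place ", n, " cell seeds with separation ", round(minSep),
           " on a ", H, "x", W, " canvas")
    cand <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    if (nrow(seeds) == 0L ||
        min((seeds[, 1L] - cand[1L])^2 + (seeds[, 2L] - cand[2L])^2) >=
          minSep^2)
      seeds <- rbind(seeds, cand)
  }
  pad <- 4L
  rows <- seq(1L - pad, H + pad)
  cols <- seq(1L - pad, W + pad)
  # nearest-seed (Voronoi) labelling on the padded canvas
  d1 <- matrix(Inf, length(rows), length(cols))
  lab <- matrix(0L, length(rows), length(cols))
  for (k in seq_len(n)) {
    dk <- outer((rows - seeds[k, 1L])^2, (cols - seeds[k, 2L])^2, `+`)
    closer <- dk < d1
    lab[closer] <- k
    d1 <- ifelse(closer, dk, d1)
  }
  # 1-px Voronoi edge set and Euclidean distance to it
  edge <- matrix(0, length(rows), length(cols))
  edge[, -ncol(lab)] <- edge[, -ncol(lab)] + (lab[, -ncol(lab)] != lab[, -1L])
  edge[-nrow(lab), ] <- edge[-nrow(lab), ] + (lab[-nrow(lab), ] != lab[-1L, ])
  edge <- (edge > 0) * 1
  D <- matrix(EBImage::distmap(1 - edge), length(rows), length(cols))
  # membrane: Gaussian absorption profile across the edge; membraneWidth
  # is the full visible width, so the profile sigma is width/4
  sigmaR <- spec@membraneWidth / 4
  membrane <- (D <= spec@membraneWidth / 2) * 1
  truthPad <- thinBoundary(membrane)
  crop <- function(m) m[pad + seq_len(H), pad + seq_len(W), drop = FALSE]
  truth <- crop(truthPad)
  # prune short dead-end spurs left by thinning at membrane junctions;
  # spurs never separate regions, and curves clipped by the canvas end on
  # the frame (or just inside it), which is left untouched
  for (it in seq_len(6L)) {
    ep <- findEndpoints(truth)
    if (nrow(ep) > 0L)
      ep <- ep[ep[, 1L] > 2L & ep[, 1L] < H - 1L &
               ep[, 2L] > 2L & ep[, 2L] < W - 1L, , drop = FALSE]
    if (nrow(ep) == 0L) break
    truth[ep] <- 0
  }
  labels <- crop(lab)
  img <- 0.85 - spec@membraneDarkness * exp(-D^2 / (2 * sigmaR^2))
  # organelle-like clutter, kept clear of membranes
  nBlobs <- round(spec@clutterDensity * H * W / 1000)
  if (nBlobs > 0) {
    interior <- which(D > 8)
    if (length(interior) > 0L) {
      centers <- sample(interior, min(nBlobs, length(interior)))
      for (ci in centers) {
        cr <- ((ci - 1L) %% nrow(img)) + 1L
        cc <- ((ci - 1L) %/% nrow(img)) + 1L
        ax <- stats::runif(1, 1.5, 3.5); bx <- stats::runif(1, 1.5, 3.5)
        ang <- stats::runif(1, 0, pi)
        drop <- stats::runif(1, 0.15, 0.4)
        rr <- max(1L, cr - 4L):min(nrow(img), cr + 4L)
        ccr <- max(1L, cc - 4L):min(ncol(img), cc + 4L)
        for (r in rr) for (c2 in ccr) {
          u <- (r - cr) * cos(ang) + (c2 - cc) * sin(ang)
          v <- -(r - cr) * sin(ang) + (c2 - cc) * cos(ang)
          if ((u / ax)^2 + (v / bx)^2 <= 1)
            img[r, c2] <- img[r, c2] - drop
        }
      }
    }
  }
  img <- convSepReflect(img, gaussKernel1D(0.5))   # slight optical blur
  img <- crop(img)
  if (spec@noiseSigma > 0)
    img <- img + matrix(stats::rnorm(H * W, sd = spec@noiseSigma), H, W)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, truth = truth, labels = labels)
}

#' Inject gaps into a boundary map
#'
#' Removes `nGaps` disjoint runs of consecutive curve pixels (runs traced
#' along interior degree-2 pixels), with lengths drawn uniformly from
#' `lengthRange`. A candidate removal is only accepted when it creates
#' exactly two new endpoints and lies at least 5 px (Chebyshev) from every
#' previously injected gap. Deterministic per seed.
#'
#' @param map binary boundary matrix.
#' @param nGaps number of gaps to inject.
#' @param lengthRange integer `(min, max)` gap length in pixels.
#' @param seed RNG seed.
#' @return list with `map` (degraded matrix) and `records`: one list
#'   entry per gap with fields `curveId`, `pixels` (n x 2), `length`,
#'   `endpoints` (2 x 2 matrix of the endpoints created).
#' @export
injectGaps <- function(map, nGaps = 8L, lengthRange = c(3L, 10L), seed = 1L) {
  checkBinary(map)
  set.seed(seed)
  if (nGaps == 0L) return(list(map = map, records = list()))
  nr <- nrow(map); nc <- ncol(map)
  curveLab <- labelCurves8(map)
  cnt <- neighborCount8(map)
  deg2 <- map == 1 & cnt == 2
  deg2[c(1L, 2L, nr - 1L, nr), ] <- FALSE
  deg2[, c(1L, 2L, nc - 1L, nc)] <- FALSE
  candidates <- which(deg2)
  epBefore <- findEndpoints(map)
  records <- list()
  out <- map
  removedAll <- matrix(0L, 0L, 2L)
  attempts <- 0L
  while (length(records) < nGaps) {
    attempts <- attempts + 1L
    if (attempts > 200L * nGaps)
      stop("could not place ", nGaps, " disjoint gaps (",
           length(records), " placed)")
    g <- sample(seq(lengthRange[1L], lengthRange[2L]), 1L)
    start <- candidates[sample.int(length(candidates), 1L)]
    sr <- ((start - 1L) %% nr) + 1L; sc <- ((start - 1L) %/% nr) + 1L
    run <- traceRun(out, c(sr, sc), g)
    if (is.null(run)) next
    if (nrow(removedAll) > 0L) {
      dmin <- min(pmax(abs(outer(run[, 1L], removedAll[, 1L], `-`)),
                       abs(outer(run[, 2L], removedAll[, 2L], `-`))))
      if (dmin < 5) next
    }
    trial <- out
    trial[run] <- 0
    epAfter <- findEndpoints(trial)
    if (nrow(epAfter) != nrow(findEndpoints(out)) + 2L) next
    newEp <- epAfter[!paste(epAfter[, 1L], epAfter[, 2L]) %in%
                       paste(findEndpoints(out)[, 1L], findEndpoints(out)[, 2L]), ,
                     drop = FALSE]
    if (nrow(newEp) != 2L) next
    out <- trial
    removedAll <- rbind(removedAll, run)
    records[[length(records) + 1L]] <-
      list(curveId = curveLab[sr, sc], pixels = run, length = nrow(run),
           endpoints = newEp)
  }
  list(map = out, records = records)
}

# Trace a run of `g` consecutive degree-2 interior curve pixels starting
# at `start` and following one direction; NULL when not possible.
traceRun <- function(map, start, g) {
  nr <- nrow(map); nc <- ncol(map)
  cnt <- neighborCount8(map)
  ok <- function(p) p[1L] > 2L && p[1L] < nr - 1L && p[2L] > 2L &&
    p[2L] < nc - 1L && map[p[1L], p[2L]] == 1 && cnt[p[1L], p[2L]] == 2
  if (!ok(start)) return(NULL)
  run <- matrix(start, 1L, 2L)
  while (nrow(run) < g) {
    cur <- run[nrow(run), ]
    cand <- matrix(0L, 0L, 2L)
    for (m in 1:8) {
      rr <- cur[1L] + MOVES[m, 1L]; cc <- cur[2L] + MOVES[m, 2L]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (map[rr, cc] != 1) next
      if (any(run[, 1L] == rr & run[, 2L] == cc)) next
      cand <- rbind(cand, c(rr, cc))
    }
    if (nrow(run) == 1L && nrow(cand) == 2L)
      cand <- cand[1L, , drop = FALSE]   # pick one direction at the seed
    if (nrow(cand) != 1L) return(NULL)
    nxt <- cand[1L, ]
    if (!ok(nxt)) return(NULL)
    run <- rbind(run, nxt)
  }
  run
}
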