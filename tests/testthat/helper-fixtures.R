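# Fixture builders shared across the suite. Everything is generated in
# code; no stored rasters.

# binary map from a list of (row, col) marked pixels
mkMap <- function(nr, nc, pts = NULL) {
  m <- matrix(0, nr, nc)
  if (!is.null(pts)) m[as.matrix(pts)] <- 1
  m
}

# square ring outline spanning rows/cols a..b
mkRing <- function(n, a, b) {
  m <- matrix(0, n, n)
  m[a:b, c(a, b)] <- 1
  m[c(a, b), a:b] <- 1
  m
}

# random smoothed-noise blob mask: structured binary maps resembling
# thresholded tissue, used for warping tests
mkBlobs <- function(n = 32, seed = 1, frac = 0.6, sigma = 2) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * n), n, n)
  s <- neuroseg:::convSepReflect(x, neuroseg:::gaussKernel1D(sigma))
  (s > stats::quantile(s, frac)) * 1
}

# independent component counters built on EBImage's 4-connected labeller;
# 8-connectivity merges diagonally adjacent labels. Used as the oracle
# against the warping module's simple-point machinery.
oracleCount4 <- function(m) max(EBImage::bwlabel(m))

oracleCount8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  k <- max(lab)
  if (k <= 1) return(k)
  par <- seq_len(k)
  find <- function(i) {
    while (par[i] != i) { par[i] <<- par[par[i]]; i <- par[i] }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in 1:2) {
    if (off == 1) { a <- lab[1:(nr - 1), 1:(nc - 1)]; b <- lab[2:nr, 2:nc] }
    else { a <- lab[1:(nr - 1), 2:nc]; b <- lab[2:nr, 1:(nc - 1)] }
    for (i in which(a > 0 & b > 0)) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) par[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

# foreground (8-conn) and background (4-conn, infinite-background
# convention: the complement is padded with background) component counts
topologyCounts <- function(m) {
  c(fg = oracleCount8(m),
    bg = oracleCount4(rbind(1, cbind(1, 1 - m, 1), 1)))
}

# brute-force Rand index by exhaustive pair enumeration (O(n^2) oracle)
bruteRandIndex <- function(x, y) {
  keep <- which(x != 0 & y != 0)
  n <- length(keep)
  stopifnot(n >= 2)
  agree <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    sameX <- x[keep[i]] == x[keep[j]]
    sameY <- y[keep[i]] == y[keep[j]]
    if (sameX == sameY) agree <- agree + 1
  }
  agree / tot
}

# one-step SARSA reference (no traces), list-backed
oneStepSarsa <- function(transitions, alpha = 0.1, gamma = 0.95) {
  Q <- list()
  g <- function(k) if (is.null(Q[[k]])) 0 else Q[[k]]
  for (tr in transitions) {
    k <- paste0(tr$s[1], ",", tr$s[2], "|", tr$a)
    k2 <- paste0(tr$s2[1], ",", tr$s2[2], "|", tr$a2)
    Q[[k]] <- g(k) + alpha * (tr$r + gamma * g(k2) - g(k))
  }
  Q
}
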