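# Brute-force oracles, written independently of the package's code paths:
# direct per-pixel loops and exhaustive searches at desk scale.

# Grayscale opening by direct double loop over pixels and element offsets.
oracle_opening <- function(img, radius, shape = "paraboloid") {
  r <- ceiling(radius)
  offs <- list()
  for (dr in -r:r) for (dc in -r:r) {
    d2 <- dr^2 + dc^2
    if (d2 <= radius^2 + 1e-9) {
      h <- if (shape == "paraboloid") -d2 / (2 * radius)
           else sqrt(max(radius^2 - d2, 0)) - radius
      offs[[length(offs) + 1]] <- c(dr, dc, h)
    }
  }
  nr <- nrow(img); nc <- ncol(img)
  ero <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    v <- Inf
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        v <- min(v, img[ii, jj] - o[3])
    }
    ero[i, j] <- v
  }
  dil <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    v <- -Inf
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        v <- max(v, ero[ii, jj] + o[3])
    }
    dil[i, j] <- v
  }
  dil
}

# Triangle threshold by exhaustive perpendicular-distance evaluation, using
# the same endpoint/mirroring convention as the geometric rule: line from
# the extended tail end to the peak on the longer-tail side.
oracle_triangle <- function(counts) {
  stopifnot(length(counts) == 256)
  nz <- which(counts > 0)
  lo <- max(nz[1] - 1, 1)          # 1-based extended ends
  hi <- min(nz[length(nz)] + 1, 256)
  peak <- which.max(counts)
  flipped <- FALSE
  if ((peak - lo) < (hi - peak)) {
    counts <- rev(counts)
    flipped <- TRUE
    lo <- 257 - hi
    peak <- 257 - peak
  }
  if (lo == peak) {
    t <- lo - 1
    return(if (flipped) 255 - t else t)
  }
  # perpendicular distance of (i, h_i) below the chord from (lo, h_lo) to
  # (peak, h_peak), via the vertical gap to the chord; the constant
  # positive normalizer (chord length over run) is dropped so the argmax
  # is computed in exact integer arithmetic
  x1 <- lo; y1 <- counts[lo]; x2 <- peak; y2 <- counts[peak]
  best <- lo; bestd <- 0
  for (i in (lo + 1):peak) {
    gap_x_run <- y1 * (x2 - x1) + (y2 - y1) * (i - x1) - counts[i] * (x2 - x1)
    if (gap_x_run > bestd) { best <- i; bestd <- gap_x_run }
  }
  t <- best - 1 - 1                 # back to 0-based, then the step below the split
  if (flipped) 255 - t else t
}

# Exhaustive maximizer of the two-class Renyi entropy criterion at one
# alpha, computed from the definition (log-sum form, direct loop).
oracle_renyi_candidate <- function(counts, alpha) {
  p <- counts / sum(counts)
  best <- -Inf; tb <- NA
  for (t in 0:254) {
    P1 <- sum(p[1:(t + 1)])
    if (P1 <= 0 || P1 >= 1) next
    pb <- p[1:(t + 1)]; pb <- pb[pb > 0] / P1
    po <- p[(t + 2):256]; po <- po[po > 0] / (1 - P1)
    tot <- if (alpha == 1) -sum(pb * log(pb)) - sum(po * log(po))
           else log(sum(pb^alpha)) / (1 - alpha) + log(sum(po^alpha)) / (1 - alpha)
    if (tot > best) { best <- tot; tb <- t }
  }
  tb
}

# Connected components by recursive flood fill over a frontier.
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  nbr <- if (connectivity == 8)
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  else cbind(c(-1,1,0,0), c(0,0,-1,1))
  for (i in 1:nr) for (j in 1:nc) {
    if (!mask[i, j] || seen[i, j]) next
    frontier <- matrix(c(i, j), 1, 2)
    seen[i, j] <- TRUE
    px <- frontier
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (k in seq_len(nrow(frontier))) {
        for (m in seq_len(nrow(nbr))) {
          ii <- frontier[k, 1] + nbr[m, 1]; jj <- frontier[k, 2] + nbr[m, 2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            nxt <- rbind(nxt, c(ii, jj))
          }
        }
      }
      if (!is.null(nxt)) px <- rbind(px, nxt)
      frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
    }
    comps[[length(comps) + 1]] <- px
  }
  comps
}

# Binary erosion by direct neighbor-count sweep (out-of-image = background).
oracle_erode <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in 1:nr) for (j in 1:nc) {
    if (!mask[i, j]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ii <- i + dr; jj <- j + dc
      bg <- ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]
      if (bg) { out[i, j] <- FALSE }
    }
  }
  out
}

# Direct 2-D Gaussian convolution with an explicitly built kernel and
# mirror padding, no separability shortcut.
oracle_gaussian <- function(img, sigma) {
  r <- max(1, ceiling(3.5 * sigma))
  k <- outer(-r:r, -r:r, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    acc <- 0
    for (a in -r:r) for (b in -r:r)
      acc <- acc + k[a + r + 1, b + r + 1] *
        img[refl(i + a, nr), refl(j + b, nc)]
    out[i, j] <- acc
  }
  out
}

# Random blob mask used by several component tests.
random_mask <- function(nr, nc, p = 0.3) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# A high-contrast spot image: peaked (diffraction-limited-like) Gaussian
# spots on a flat background -- large spots thresholding to >= 10 px and
# tiny specks thresholding to a few px.
blob_image <- function(nr = 128, nc = 128, centers_big, centers_small,
                       sigma_big = 2.2, sigma_small = 0.6,
                       level = 2000, bg = 100) {
  img <- matrix(bg, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  add <- function(ctr, s) {
    d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
    img <<- img + level * exp(-d2 / (2 * s^2))
  }
  for (k in seq_len(nrow(centers_big))) add(centers_big[k, ], sigma_big)
  for (k in seq_len(nrow(centers_small))) add(centers_small[k, ], sigma_small)
  strainsight::as_image(round(img), 16L)
}

# Dilation via the complement of erosion; used to define a generous
# "structure-free" region around ground-truth filaments.
dilate_mask <- function(mask, iterations = 1) {
  !strainsight::erode(!mask, iterations)
}
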