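## ---------------------------------------------------------------------------
## Image container helpers
##
## Images are plain numeric matrices (row, col), 0-based coordinates in the
## documentation, 1-based in R code as usual.  An optional "bits" attribute
## (8, 16 or NA for float) records the native bit depth; it only influences
## how the 256-bin histogram maps intensity to bins.
## ---------------------------------------------------------------------------

#' Validate and tag a pixel matrix as a 2-D image
#'
#' @param x numeric matrix of intensities (rows x cols).
#' @param bits native bit depth: 8, 16, or NA for floating point.
#' @return the matrix with a `bits` attribute set.
#' @export
as_image <- function(x, bits = NA_integer_) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("image must be a numeric matrix")
  if (any(!is.finite(x)))
    stop("image contains non-finite values")
  attr(x, "bits") <- as.integer(bits)
  x
}

image_bits <- function(x) {
  b <- attr(x, "bits")
  if (is.null(b)) NA_integer_ else as.integer(b)
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("degenerate_histogram", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## ---------------------------------------------------------------------------
## 256-bin histogram
## ---------------------------------------------------------------------------

#' Build the 256-bin intensity histogram used by the auto-threshold methods
#'
#' 8-bit images use their native 0..255 bins.  16-bit and floating-point
#' images are mapped to 256 bins by a min-max linear rescale (the convention
#' of histogram-based auto-thresholders, which operate on 256-bin
#' histograms regardless of depth).  The bin-to-intensity mapping is kept so
#' a chosen bin can be translated back to native intensity.
#'
#' @param img numeric matrix (see [as_image()]).
#' @return an object of class `histogram256`: list with `counts` (length
#'   256), `min`, `max`, and `native8` (logical, TRUE when bins are native
#'   8-bit values).
#' @export
histogram256 <- function(img) {
  v <- as.numeric(img)
  bits <- image_bits(img)
  native8 <- isTRUE(bits == 8L)
  if (native8) {
    idx <- pmin(pmax(floor(v), 0), 255)
    lo <- 0; hi <- 255
  } else {
    lo <- min(v); hi <- max(v)
    if (hi > lo) {
      idx <- floor((v - lo) / (hi - lo) * 256)
      idx[idx > 255] <- 255
    } else {
      idx <- rep(0, length(v))
    }
  }
  counts <- tabulate(idx + 1L, nbins = 256L)
  structure(list(counts = counts, min = lo, max = hi, native8 = native8),
            class = "histogram256")
}

#' Map image pixels to histogram bin indices (0..255)
#'
#' Uses the same mapping as [histogram256()] so that `bin_indices(img, h) > t`
#' reproduces exactly the foreground selected by thresholding bin `t`.
#'
#' @param img image matrix.
#' @param hist a `histogram256` built from a compatible image.
#' @return integer matrix of bin indices, same shape as `img`.
#' @export
bin_indices <- function(img, hist) {
  stopifnot(inherits(hist, "histogram256"))
  if (hist$native8) {
    idx <- pmin(pmax(floor(img), 0), 255)
  } else if (hist$max > hist$min) {
    idx <- floor((img - hist$min) / (hist$max - hist$min) * 256)
    idx[idx > 255] <- 255
  } else {
    idx <- array(0, dim(img))
  }
  storage.mode(idx) <- "integer"
  idx
}

#' Native intensity of a histogram bin's upper edge
#'
#' Reported in logs so a chosen bin threshold can be audited in native
#' intensity units; the pipelines themselves compare bin indices.
#'
#' @param hist a `histogram256`.
#' @param t bin index in 0..255.
#' @return native intensity at the upper edge of bin `t`.
#' @export
native_threshold <- function(hist, t) {
  stopifnot(inherits(hist, "histogram256"))
  if (hist$native8) return(t)
  hist$min + (t + 1) / 256 * (hist$max - hist$min)
}

n_nonzero_bins <- function(hist) sum(hist$counts > 0)

## ---------------------------------------------------------------------------
## Background subtraction (rolling ball / sliding paraboloid)
## ---------------------------------------------------------------------------

## Structuring-element offsets for a disc footprint of the given radius.
## Heights: ball = spherical cap (apex 0, edge -radius);
## paraboloid = -d^2/(2*radius), i.e. curvature radius `radius` at the apex.
se_offsets <- function(radius, shape = c("paraboloid", "ball")) {
  shape <- match.arg(shape)
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- g$dr^2 + g$dc^2
  keep <- d2 <= radius^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  h <- if (shape == "paraboloid") -d2 / (2 * radius)
       else sqrt(pmax(radius^2 - d2, 0)) - radius
  list(dr = g$dr, dc = g$dc, h = h, r = r)
}

## Grayscale erosion/dilation with a (possibly non-flat) structuring element.
## Out-of-image pixels act as +Inf (erosion) / -Inf (dilation), i.e. they do
## not constrain the result.
gray_morph <- function(img, off, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(img); nc <- ncol(img); r <- off$r
  fill <- if (op == "erode") Inf else -Inf
  pad <- matrix(fill, nr + 2 * r, nc + 2 * r)
  pad[(r + 1):(r + nr), (r + 1):(r + nc)] <- img
  acc <- matrix(fill, nr, nc)
  for (k in seq_along(off$dr)) {
    sub <- pad[(r + 1 + off$dr[k]):(r + nr + off$dr[k]),
               (r + 1 + off$dc[k]):(r + nc + off$dc[k]), drop = FALSE]
    acc <- if (op == "erode") pmin(acc, sub - off$h[k])
           else pmax(acc, sub + off$h[k])
  }
  acc
}

#' Grayscale opening: lower envelope of an image under a structuring element
#'
#' @param img image matrix.
#' @param radius element radius in pixels.
#' @param shape `"paraboloid"` or `"ball"`.
#' @return the morphological opening (erosion then dilation), everywhere
#'   less than or equal to `img`.
#' @export
gray_opening <- function(img, radius, shape = c("paraboloid", "ball")) {
  off <- se_offsets(radius, match.arg(shape))
  gray_morph(gray_morph(img, off, "erode"), off, "dilate")
}

#' Background subtraction by morphological opening
#'
#' Estimates the background as the grayscale opening of the image with a
#' paraboloid (default) or ball structuring element of the given radius --
#' the morphological core of the familiar rolling-ball / sliding-paraboloid
#' background filter -- and subtracts it.  The output is clamped at zero for
#' integer-typed images and is everywhere less than or equal to the input.
#'
#' @param img image matrix.
#' @param radius element radius in pixels (>= 1); default 3.
#' @param sliding_paraboloid use the paraboloid element (default TRUE);
#'   FALSE selects the ball.
#' @return background-subtracted image, same shape and `bits` attribute.
#' @export
subtract_background <- function(img, radius = 3, sliding_paraboloid = TRUE) {
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1)
    stop("radius must be a single number >= 1")
  bg <- gray_opening(img, radius, if (sliding_paraboloid) "paraboloid" else "ball")
  out <- img - bg
  bits <- image_bits(img)
  if (!is.na(bits)) out[out < 0] <- 0
  attr(out, "bits") <- bits
  out
}

## ---------------------------------------------------------------------------
## Gaussian blur
## ---------------------------------------------------------------------------

#' Gaussian blur with reflective boundary
#'
#' Separable convolution with a normalized discrete Gaussian kernel
#' truncated at `ceiling(3.5 * sigma)` taps per side; the boundary is
#' handled by mirror reflection (edge pixel duplicated).  Note: the
#' pipelines interpret the mask recipe's "radius = 1 pixel" as sigma = 1.
#'
#' @param img image matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return blurred image (floating point), same shape.
#' @export
gaussian_blur <- function(img, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single number > 0")
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- conv1d(img, k, r, rows = TRUE)
  out <- conv1d(out, k, r, rows = FALSE)
  attr(out, "bits") <- image_bits(img)
  out
}

## 1-D convolution along rows or columns with mirror padding.
conv1d <- function(m, k, r, rows = TRUE) {
  if (!rows) return(t(conv1d(t(m), k, r, rows = TRUE)))
  nr <- nrow(m)
  # mirror reflection with the edge pixel duplicated (..., 2, 1 | 1, 2, ...)
  i <- (1 - r):(nr + r)
  j <- ((i - 1) %% (2 * nr))
  j <- ifelse(j < 0, j + 2 * nr, j)
  idx <- ifelse(j < nr, j + 1, 2 * nr - j)
  pad <- m[idx, , drop = FALSE]
  acc <- matrix(0, nr, ncol(m))
  for (j in seq_along(k))
    acc <- acc + k[j] * pad[(j):(j + nr - 1), , drop = FALSE]
  acc
}

## ---------------------------------------------------------------------------
## Automatic thresholding
## ---------------------------------------------------------------------------

#' Triangle auto-threshold
#'
#' Geometric construction on the 256-bin histogram: a line is drawn from the
#' histogram peak to the far end of the longer tail, and the threshold is
#' the bin that maximizes the perpendicular distance between histogram and
#' line.  When the longer tail lies above the peak the histogram is mirrored
#' first and the result mirrored back, so the search always runs on the
#' long-tail side.  Foreground is pixels in bins strictly above the returned
#' bin.
#'
#' @param hist a `histogram256` (or a bare numeric vector of 256 counts).
#' @return threshold bin index in 0..255.
#' @export
threshold_triangle <- function(hist) {
  data <- if (inherits(hist, "histogram256")) hist$counts else as.numeric(hist)
  stopifnot(length(data) == 256)
  if (sum(data > 0) < 2)
    stop_degenerate("histogram has fewer than 2 nonzero bins; no threshold exists")
  first <- which(data > 0)[1] - 1L           # 0-based
  last <- rev(which(data > 0))[1] - 1L
  minb <- max(first - 1L, 0L)
  min2 <- min(last + 1L, 255L)
  peak <- which.max(data) - 1L
  inverted <- FALSE
  if ((peak - minb) < (min2 - peak)) {
    data <- rev(data)
    inverted <- TRUE
    minb <- 255L - min2
    peak <- 255L - peak
  }
  if (minb == peak) return(if (inverted) 255L - minb else minb)
  # signed distance below the line from (minb, data[minb]) to
  # (peak, data[peak]), scaled by the constant line length so the whole
  # criterion stays in exact integer arithmetic (ties break to the lower
  # bin deterministically instead of by floating-point rounding)
  rise <- data[peak + 1L] - data[minb + 1L]
  run <- peak - minb
  split <- minb
  split_dist <- 0
  for (i in (minb + 1L):peak) {
    nd <- rise * (i - minb) - run * (data[i + 1L] - data[minb + 1L])
    if (nd > split_dist) { split <- i; split_dist <- nd }
  }
  split <- split - 1L
  if (inverted) 255L - split else as.integer(split)
}

## Renyi entropy of order alpha for normalized class probabilities p / P.
## alpha == 1 is the Shannon (Kapur) limit.
renyi_class_entropy <- function(p, P, alpha) {
  q <- p[p > 0] / P
  if (alpha == 1) -sum(q * log(q))
  else log(sum(q^alpha)) / (1 - alpha)
}

## Exhaustive maximizer of the two-class Renyi entropy sum at one alpha.
## Candidate thresholds t keep both classes nonempty (0 < P1(t) < 1).
renyi_candidate <- function(counts, alpha) {
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  best_t <- NA_integer_
  best <- -Inf
  for (t in 0:254) {
    if (P1[t + 1] <= 0 || P1[t + 1] >= 1) next
    eb <- renyi_class_entropy(p[1:(t + 1)], P1[t + 1], alpha)
    eo <- renyi_class_entropy(p[(t + 2):256], 1 - P1[t + 1], alpha)
    tot <- eb + eo
    if (tot > best) { best <- tot; best_t <- t }
  }
  if (is.na(best_t))
    stop_degenerate("histogram has no valid two-class split")
  as.integer(best_t)
}

#' Renyi-entropy auto-threshold
#'
#' Three candidate thresholds maximize the sum of background and foreground
#' Renyi entropies at orders alpha -> 1 (the Shannon / maximum-entropy
#' limit), alpha = 0.5 and alpha = 2.  The candidates are sorted and
#' combined by the published weighted rule: weights (1,2,1) when all three
#' agree to within 5 bins or are mutually far apart, otherwise weight is
#' shifted toward the agreeing pair, and the final threshold blends the
#' sorted candidates through the cumulative histogram.
#'
#' @param hist a `histogram256` (or a bare numeric vector of 256 counts).
#' @param details if TRUE also return the three candidates.
#' @return threshold bin index in 0..255 (or a list when `details`).
#' @export
threshold_renyi_entropy <- function(hist, details = FALSE) {
  counts <- if (inherits(hist, "histogram256")) hist$counts else as.numeric(hist)
  stopifnot(length(counts) == 256)
  if (sum(counts > 0) < 2)
    stop_degenerate("histogram has fewer than 2 nonzero bins; no threshold exists")
  t_shannon <- renyi_candidate(counts, 1)
  t_half <- renyi_candidate(counts, 0.5)
  t_two <- renyi_candidate(counts, 2)
  ts <- sort(c(t_half, t_shannon, t_two))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) { b <- c(1, 2, 1) } else { b <- c(0, 1, 3) }
  } else {
    if (abs(t2 - t3) <= 5) { b <- c(3, 1, 0) } else { b <- c(1, 2, 1) }
  }
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  omega <- P1[t3 + 1] - P1[t1 + 1]
  opt <- t1 * (P1[t1 + 1] + 0.25 * omega * b[1]) +
    0.25 * t2 * omega * b[2] +
    t3 * (1 - P1[t3 + 1] + 0.25 * omega * b[3])
  thr <- as.integer(opt)
  if (details) list(threshold = thr, candidates = c(alpha_half = t_half,
                                                    alpha_1 = t_shannon,
                                                    alpha_2 = t_two))
  else thr
}

#' Threshold an image into a binary mask
#'
#' Foreground is strictly above the threshold.  When `hist` is supplied the
#' comparison runs on 256-bin indices (the auto-threshold convention and
#' what the pipelines use); otherwise on native intensities.
#'
#' @param img image matrix.
#' @param t threshold: a bin index in 0..255 when `hist` is given, a native
#'   intensity otherwise.
#' @param hist optional `histogram256` for the bin-index convention.
#' @return logical matrix, TRUE = foreground.
#' @export
binarize <- function(img, t, hist = NULL) {
  m <- if (is.null(hist)) unclass(img) > t else bin_indices(img, hist) > t
  attr(m, "bits") <- NULL
  m
}

## ---------------------------------------------------------------------------
## Binary erosion
## ---------------------------------------------------------------------------

#' Binary erosion (8-neighborhood)
#'
#' Each iteration removes every foreground pixel that touches at least one
#' background pixel in its 8-neighborhood; pixels beyond the image border
#' count as background, so masks erode at the frame edge.  The result is
#' always a subset of the input.
#'
#' @param mask logical matrix.
#' @param iterations number of erosion passes (>= 1).
#' @return eroded logical matrix.
#' @export
erode <- function(mask, iterations = 1L) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("mask must be a logical matrix")
  if (iterations < 1) stop("iterations must be >= 1")
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(iterations)) {
    pad <- matrix(FALSE, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- mask
    keep <- matrix(TRUE, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      keep <- keep & pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    }
    mask <- mask & keep
  }
  mask
}

## ---------------------------------------------------------------------------
## Connected components and particle filtering
## ---------------------------------------------------------------------------

#' Label connected components and remove small particles
#'
#' Two-pass union-find labeling under 4- or 8-connectivity, followed by
#' deletion of components with pixel area strictly below `min_area`
#' ("remove particles smaller than N pixels": area >= N survives).
#' Surviving labels are renumbered 1..K in first-pixel scan order.
#'
#' @param mask logical matrix.
#' @param min_area minimum surviving component area in pixels (>= 0).
#' @param connectivity 8 (default) or 4.
#' @return list of class `labeled_regions`: `labels` (integer matrix, 0 =
#'   background), `areas` (integer vector, one per surviving label),
#'   `n` (number of surviving components).
#' @export
label_and_filter <- function(mask, min_area = 0L, connectivity = 8L) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("mask must be a logical matrix")
  if (min_area < 0) stop("min_area must be >= 0")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)               # column-major order
  parent <- integer(0)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  next_label <- 0L
  # previously-scanned neighbors in column-major order: N (same col), and
  # the W column (for 8-conn also NW, SW)
  for (p in fg) {
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    nb <- integer(0)
    if (r > 1L && labels[p - 1L] > 0L) nb <- c(nb, labels[p - 1L])
    if (cc > 1L) {
      w <- p - nr
      if (labels[w] > 0L) nb <- c(nb, labels[w])
      if (connectivity == 8L) {
        if (r > 1L && labels[w - 1L] > 0L) nb <- c(nb, labels[w - 1L])
        if (r < nr && labels[w + 1L] > 0L) nb <- c(nb, labels[w + 1L])
      }
    }
    if (length(nb) == 0L) {
      next_label <- next_label + 1L
      parent[next_label] <- next_label
      labels[p] <- next_label
    } else {
      roots <- vapply(unique(nb), find_root, integer(1))
      m <- min(roots)
      labels[p] <- m
      for (rt in roots) parent[rt] <- m
    }
  }
  if (next_label > 0L) {
    roots <- vapply(seq_len(next_label), find_root, integer(1))
    labels[fg] <- roots[labels[fg]]
  }
  areas <- tabulate(labels[fg], nbins = max(next_label, 1L))
  keep <- which(areas >= min_area & areas > 0L)
  remap <- integer(max(next_label, 1L))
  # renumber survivors in order of first appearance in scan order
  first_seen <- unique(labels[fg])
  first_seen <- first_seen[first_seen %in% keep]
  remap[first_seen] <- seq_along(first_seen)
  out <- matrix(0L, nr, nc)
  out[fg] <- remap[labels[fg]]
  structure(list(labels = out,
                 areas = as.integer(areas[first_seen]),
                 n = length(first_seen)),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat("labeled_regions:", x$n, "component(s); areas:",
      paste(utils::head(x$areas, 10), collapse = ", "),
      if (x$n > 10) "..." else "", "\n")
  invisible(x)
}
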