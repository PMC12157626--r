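## ---------------------------------------------------------------------------
## Time-lapse bright-object counter (myosin-inhibition experiments).
##
## Per frame: subtract background (sliding paraboloid, r = 3) -> Renyi
## entropy threshold -> binary mask -> drop particles smaller than 10 px ->
## count surviving components.  The defaults are the verbatim recipe used on
## the reporter time-lapses.
## ---------------------------------------------------------------------------

#' Parameters of the object-counting pipeline
#'
#' Defaults reproduce the published recipe: background subtraction with a
#' sliding paraboloid of radius 3 px, Renyi-entropy auto-threshold, and
#' removal of particles smaller than 10 px.
#'
#' @param bg_radius background element radius, pixels.
#' @param use_paraboloid sliding paraboloid (TRUE) or rolling ball.
#' @param threshold_method `"RenyiEntropy"` or `"Triangle"`.
#' @param min_area minimum particle area in pixels; smaller particles are
#'   removed (area >= min_area survives).
#' @param connectivity component connectivity, 8 or 4.
#' @return object of class `counter_params`.
#' @export
counter_params <- function(bg_radius = 3, use_paraboloid = TRUE,
                           threshold_method = c("RenyiEntropy", "Triangle"),
                           min_area = 10, connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  if (bg_radius < 1) stop("bg_radius must be >= 1")
  if (min_area < 0) stop("min_area must be >= 0")
  structure(list(bg_radius = bg_radius, use_paraboloid = isTRUE(use_paraboloid),
                 threshold_method = threshold_method,
                 min_area = min_area, connectivity = as.integer(connectivity)),
            class = "counter_params")
}

apply_threshold_method <- function(hist, method) {
  switch(method,
         RenyiEntropy = threshold_renyi_entropy(hist),
         Triangle = threshold_triangle(hist),
         stop("unknown threshold method: ", method))
}

#' Count bright objects in one frame
#'
#' A constant (degenerate) frame has no distinguishable structures and
#' yields a count of 0 with a warning rather than an error, so time-lapses
#' that go fully dark terminate cleanly.
#'
#' @param img image matrix.
#' @param p a [counter_params()].
#' @param details if TRUE return the intermediate mask, threshold bin and
#'   component table as well.
#' @return integer count (or a list when `details`).
#' @export
count_frame <- function(img, p = counter_params(), details = FALSE) {
  stopifnot(inherits(p, "counter_params"))
  if (length(img) == 0) stop("img is empty")
  sub <- subtract_background(img, p$bg_radius, p$use_paraboloid)
  h <- histogram256(sub)
  if (n_nonzero_bins(h) < 2) {
    warning("constant frame: no structures distinguishable; count = 0")
    if (details) return(list(count = 0L, threshold = NA_integer_,
                             mask = matrix(FALSE, nrow(img), ncol(img)),
                             regions = NULL))
    return(0L)
  }
  t <- apply_threshold_method(h, p$threshold_method)
  mask <- binarize(sub, t, h)
  reg <- label_and_filter(mask, p$min_area, p$connectivity)
  if (details) list(count = reg$n, threshold = t, mask = mask, regions = reg)
  else reg$n
}

#' Count bright objects in every frame of a time-lapse
#'
#' The mask pipeline runs on every frame.  By default the threshold is
#' estimated once on frame 0 and its native-intensity cutoff reused for
#' the whole series (`fixed_threshold = TRUE`): entropy thresholds
#' re-estimated on frames that have lost all structure land in the noise
#' bulk and manufacture spurious objects, so a per-series anchor is needed
#' for the counts to report structures rather than noise.  Set
#' `fixed_threshold = FALSE` to re-estimate per frame (sensitivity
#' analysis).
#'
#' @param stack an `image_stack` (list of frames) or list of matrices.
#' @param p a [counter_params()].
#' @param frame_interval minutes between frames (used when the stack
#'   carries no `times` attribute).
#' @param replicate,condition labels copied into the output.
#' @param fixed_threshold reuse frame 1's threshold for all frames.
#' @return a `data.frame` (one row per frame): `condition`, `replicate`,
#'   `frame` (0-based), `time_min`, `count`, `threshold_bin`.
#' @export
count_stack <- function(stack, p = counter_params(), frame_interval = 1,
                        replicate = 1L, condition = "unlabeled",
                        fixed_threshold = TRUE) {
  frames <- if (is.list(stack)) stack else list(stack)
  if (length(frames) < 1) stop("stack must contain at least one frame")
  times <- attr(stack, "times")
  if (is.null(times)) times <- (seq_along(frames) - 1) * frame_interval
  counts <- integer(length(frames))
  thr <- integer(length(frames))
  cut_native <- NULL
  for (t in seq_along(frames)) {
    if (fixed_threshold && t > 1 && !is.null(cut_native)) {
      img <- frames[[t]]
      sub <- subtract_background(img, p$bg_radius, p$use_paraboloid)
      mask <- unclass(sub) > cut_native
      reg <- label_and_filter(mask, p$min_area, p$connectivity)
      counts[t] <- reg$n
      thr[t] <- thr[1]
      next
    }
    det <- count_frame(frames[[t]], p, details = TRUE)
    counts[t] <- det$count
    thr[t] <- if (is.na(det$threshold)) NA_integer_ else det$threshold
    if (fixed_threshold && t == 1 && !is.na(det$threshold)) {
      sub <- subtract_background(frames[[1]], p$bg_radius, p$use_paraboloid)
      cut_native <- native_threshold(histogram256(sub), det$threshold)
    }
  }
  data.frame(condition = condition, replicate = replicate,
             frame = seq_along(frames) - 1L, time_min = times,
             count = counts, threshold_bin = thr)
}

#' Summarize count series across replicates
#'
#' Per condition and timepoint: mean count, standard deviation and n (the
#' error bars of a myosin-inhibition response curve are the per-timepoint
#' standard deviation).  With `normalize = TRUE` each series is first
#' divided by its own frame-0 count; series starting at 0 are excluded with
#' a warning.
#'
#' @param series a `data.frame` as returned by [count_stack()] (rows from
#'   several replicates may be concatenated), or a list of such frames.
#' @param normalize divide each series by its frame-0 count first.
#' @return `data.frame` with `condition`, `frame`, `time_min`, `mean`,
#'   `sd`, `n`.
#' @export
summarize_series <- function(series, normalize = FALSE) {
  if (is.data.frame(series)) df <- series
  else if (is.list(series) && length(series) > 0) df <- do.call(rbind, series)
  else stop("series must be a nonempty data.frame or list of data.frames")
  if (nrow(df) == 0) stop("series must be nonempty")
  needed <- c("condition", "replicate", "frame", "time_min", "count")
  if (!all(needed %in% names(df)))
    stop("series must have columns: ", paste(needed, collapse = ", "))
  df$value <- as.numeric(df$count)
  if (normalize) {
    key <- interaction(df$condition, df$replicate, drop = TRUE)
    base0 <- tapply(df$value[df$frame == 0], key[df$frame == 0], `[`, 1)
    b <- base0[as.character(key)]
    bad <- !is.na(b) & b == 0
    if (any(bad)) {
      warning("excluding ", length(unique(key[bad])),
              " series with frame-0 count of 0 from normalization")
      df <- df[!bad, , drop = FALSE]
      b <- b[!bad]
    }
    df$value <- df$value / b
  }
  agg <- stats::aggregate(value ~ condition + frame + time_min, data = df,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(condition = agg$condition, frame = agg$frame,
                    time_min = agg$time_min,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]))
  out$sd[is.na(out$sd)] <- 0   # single replicate
  out[order(out$condition, out$frame), , drop = FALSE]
}
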