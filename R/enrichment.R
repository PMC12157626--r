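## ---------------------------------------------------------------------------
## Reference-mask enrichment pipeline.
##
## The reference (RFP, Zyxin-LCR) channel defines where stressed-actin sites
## are; the construct (GFP) channel is scored for recruitment to those sites
## by the enrichment statistic (GFP_i - GFP_o) / RFP_i, where _i/_o denote
## mean original-channel intensity inside/outside the reference mask.
## ---------------------------------------------------------------------------

#' Parameters of the reference-mask recipe
#'
#' Defaults reproduce the published mask recipe verbatim: background
#' subtraction (sliding paraboloid, radius 3 px), Gaussian blur (sigma 1
#' px), Triangle auto-threshold, one pass of 8-neighborhood erosion, and
#' removal of particles smaller than 30 px.
#'
#' @param bg_radius background element radius, pixels.
#' @param use_paraboloid sliding paraboloid (TRUE) or rolling ball.
#' @param blur_sigma Gaussian sigma in pixels.
#' @param threshold_method `"Triangle"` or `"RenyiEntropy"`.
#' @param erode_iterations erosion passes (0 disables the step).
#' @param min_area minimum particle area in pixels.
#' @param connectivity component connectivity, 8 or 4.
#' @return object of class `mask_params`.
#' @export
mask_params <- function(bg_radius = 3, use_paraboloid = TRUE, blur_sigma = 1,
                        threshold_method = c("Triangle", "RenyiEntropy"),
                        erode_iterations = 1, min_area = 30, connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  if (bg_radius < 1) stop("bg_radius must be >= 1")
  if (blur_sigma <= 0) stop("blur_sigma must be > 0")
  if (erode_iterations < 0) stop("erode_iterations must be >= 0")
  if (min_area < 0) stop("min_area must be >= 0")
  structure(list(bg_radius = bg_radius, use_paraboloid = isTRUE(use_paraboloid),
                 blur_sigma = blur_sigma, threshold_method = threshold_method,
                 erode_iterations = as.integer(erode_iterations),
                 min_area = min_area, connectivity = as.integer(connectivity)),
            class = "mask_params")
}

#' Build the stressed-actin reference mask from the RFP channel
#'
#' The processed image exists only to define the mask; all intensity
#' measurements are taken later on the original channels.  An image whose
#' processed histogram is degenerate (constant) or whose mask empties after
#' filtering yields an empty mask; [measure_enrichment()] then rejects it.
#'
#' @param rfp reference-channel image matrix.
#' @param p a [mask_params()].
#' @param details if TRUE also return the threshold bin and particle areas.
#' @return logical mask (or a list when `details`).
#' @export
build_reference_mask <- function(rfp, p = mask_params(), details = FALSE) {
  stopifnot(inherits(p, "mask_params"))
  if (length(rfp) == 0) stop("rfp is empty")
  proc <- subtract_background(rfp, p$bg_radius, p$use_paraboloid)
  proc <- gaussian_blur(proc, p$blur_sigma)
  h <- histogram256(proc)
  if (n_nonzero_bins(h) < 2) {
    empty <- matrix(FALSE, nrow(rfp), ncol(rfp))
    if (details) return(list(mask = empty, threshold = NA_integer_, areas = integer(0)))
    return(empty)
  }
  t <- apply_threshold_method(h, p$threshold_method)
  mask <- binarize(proc, t, h)
  if (p$erode_iterations > 0) mask <- erode(mask, p$erode_iterations)
  reg <- label_and_filter(mask, p$min_area, p$connectivity)
  out <- reg$labels > 0L
  if (details) list(mask = out, threshold = t, areas = reg$areas) else out
}

#' Measure the enrichment statistic for one image pair
#'
#' `RFP_i` and `GFP_i` are the mean original-channel intensities inside the
#' mask; `GFP_o` is the mean original GFP intensity outside it.  The score
#' is `(GFP_i - GFP_o) / RFP_i`: offset-invariant in GFP (a uniform added
#' background cancels), exactly linear in GFP scaling, and 0 for spatially
#' uniform GFP.
#'
#' @param gfp,rfp original (unprocessed) channel images.
#' @param mask reference mask from [build_reference_mask()].
#' @param stat `"mean"` (default) or `"integrated"` (summed intensity;
#'   provided as an option, the statistic is defined on means).
#' @param outside_region optional logical matrix restricting the
#'   outside-of-mask region (e.g. a cytosol ROI); default is the whole
#'   image complement of the mask.
#' @return list of class `enrichment_measurement`: `RFP_i`, `GFP_i`,
#'   `GFP_o`, `score`, `mask_area`.
#' @export
measure_enrichment <- function(gfp, rfp, mask, stat = c("mean", "integrated"),
                               outside_region = NULL) {
  stat <- match.arg(stat)
  if (!all(dim(gfp) == dim(rfp)) || !all(dim(gfp) == dim(mask)))
    stop("gfp, rfp and mask must have identical dimensions")
  area <- sum(mask)
  if (area == 0) stop("empty mask: no reference structures; image rejected")
  outside <- !mask
  if (!is.null(outside_region)) outside <- outside & outside_region
  if (sum(outside) == 0) stop("outside region is empty")
  f <- if (stat == "mean") mean else sum
  RFP_i <- f(rfp[mask])
  GFP_i <- f(gfp[mask])
  GFP_o <- f(gfp[outside])
  if (RFP_i <= 0) stop("RFP_i must be > 0: score undefined")
  structure(list(RFP_i = RFP_i, GFP_i = GFP_i, GFP_o = GFP_o,
                 score = (GFP_i - GFP_o) / RFP_i,
                 mask_area = as.integer(area), stat = stat),
            class = "enrichment_measurement")
}

#' @export
print.enrichment_measurement <- function(x, ...) {
  cat(sprintf("enrichment: RFP_i = %.4g, GFP_i = %.4g, GFP_o = %.4g, score = %.4g (mask %d px)\n",
              x$RFP_i, x$GFP_i, x$GFP_o, x$score, x$mask_area))
  invisible(x)
}

#' Normalize scores to the reference group, per trial
#'
#' Within each trial every raw score is divided by the mean raw score of
#' the reference-group rows of that same trial, so the reference group's
#' mean normalized score is 1 per trial by construction.
#'
#' @param table `data.frame` with columns `trial`, `group`, `score` (and
#'   usually `image`).
#' @param reference_group label of the reference construct group.
#' @return the table with a `score_norm` column added.
#' @export
normalize_scores <- function(table, reference_group) {
  stopifnot(is.data.frame(table))
  needed <- c("trial", "group", "score")
  if (!all(needed %in% names(table)))
    stop("table must have columns: ", paste(needed, collapse = ", "))
  table$score_norm <- NA_real_
  for (tr in unique(table$trial)) {
    in_trial <- table$trial == tr
    ref <- in_trial & table$group == reference_group
    if (!any(ref))
      stop("trial ", tr, " has no rows of reference group '", reference_group, "'")
    m <- mean(table$score[ref])
    if (!is.finite(m) || m == 0)
      stop("trial ", tr, ": reference-group mean score is 0; cannot normalize")
    table$score_norm[in_trial] <- table$score[in_trial] / m
  }
  table
}

#' One-way ANOVA across construct groups
#'
#' Classical fixed-effects one-way ANOVA on the normalized scores:
#' `F = MS_between / MS_within` on (k - 1, N - k) degrees of freedom, with
#' the p value from the F distribution.  A fully degenerate within-group
#' variance (all groups internally constant) is flagged and reported as
#' `F = Inf`, `p = 0`.
#'
#' @param table `data.frame` with `group` and a score column.
#' @param value which column to analyze: `"score_norm"` (default; falls
#'   back to `"score"` if absent) or `"score"`.
#' @return list of class `group_comparison`: `F`, `p`, `df`, `summary`
#'   (per-group mean, sd, n), `degenerate`.
#' @export
compare_groups <- function(table, value = c("score_norm", "score")) {
  stopifnot(is.data.frame(table))
  value <- match.arg(value)
  if (value == "score_norm" && !"score_norm" %in% names(table)) value <- "score"
  y <- table[[value]]
  g <- factor(table$group)
  if (nlevels(g) < 2) stop("ANOVA needs at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) stop("every group needs at least 2 values for ANOVA")
  smry <- data.frame(group = levels(g),
                     mean = as.numeric(tapply(y, g, mean)),
                     sd = as.numeric(tapply(y, g, stats::sd)),
                     n = as.integer(sizes))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  ms_within <- tab["Residuals", "Mean Sq"]
  if (!is.finite(ms_within) || ms_within <= .Machine$double.eps * mean(y)^2) {
    ms_between <- tab[1, "Mean Sq"]
    degenerate <- TRUE
    Fv <- if (ms_between > 0) Inf else NaN
    pv <- if (ms_between > 0) 0 else NaN
  } else {
    degenerate <- FALSE
    Fv <- tab[1, "F value"]
    pv <- tab[1, "Pr(>F)"]
  }
  structure(list(F = Fv, p = pv,
                 df = c(between = tab[1, "Df"], within = tab["Residuals", "Df"]),
                 summary = smry, degenerate = degenerate, value = value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA on %s: F(%d, %d) = %.4g, p = %.3g%s\n",
              x$value, x$df[1], x$df[2], x$F, x$p,
              if (x$degenerate) " [degenerate: zero within-group variance]" else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the full enrichment experiment over a cohort of image pairs
#'
#' Per image: reference mask -> enrichment measurement -> raw score; then
#' per-trial normalization to the reference group and one-way ANOVA across
#' groups (skipped with a message when only one group is present).  Images
#' failing a stage (empty mask, zero reference signal) are skipped and
#' logged, not fatal — unless the reference group ends empty.
#'
#' @param images list of entries, each a list with elements `gfp`, `rfp`
#'   (image matrices), `trial`, `group`, and optionally `image` (id).
#' @param params a [mask_params()].
#' @param reference_group label of the reference group.
#' @param stat passed to [measure_enrichment()].
#' @return list of class `enrichment_experiment`: `scores` (the score
#'   table with normalized scores), `stats` (a `group_comparison` or NULL),
#'   `skipped` (per-image failure messages), `params`.
#' @export
run_enrichment_experiment <- function(images, params = mask_params(),
                                      reference_group, stat = "mean") {
  stopifnot(is.list(images), length(images) > 0)
  rows <- list()
  skipped <- character(0)
  for (i in seq_along(images)) {
    e <- images[[i]]
    id <- if (!is.null(e$image)) e$image else paste0("image_", i)
    res <- tryCatch({
      det <- build_reference_mask(e$rfp, params, details = TRUE)
      m <- measure_enrichment(e$gfp, e$rfp, det$mask, stat = stat)
      data.frame(trial = e$trial, group = e$group, image = id,
                 score = m$score, RFP_i = m$RFP_i, GFP_i = m$GFP_i,
                 GFP_o = m$GFP_o, mask_area = m$mask_area,
                 threshold_bin = det$threshold)
    }, error = function(err) conditionMessage(err))
    if (is.character(res)) skipped[id] <- res else rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) stop("no image produced a valid measurement")
  scores <- do.call(rbind, rows)
  if (!any(scores$group == reference_group))
    stop("reference group '", reference_group, "' has no valid measurements")
  scores <- normalize_scores(scores, reference_group)
  stats <- NULL
  if (length(unique(scores$group)) >= 2 &&
      all(table(scores$group) >= 2)) {
    stats <- compare_groups(scores)
  } else {
    message("group comparison skipped: need >= 2 groups with >= 2 values each")
  }
  structure(list(scores = scores, stats = stats, skipped = skipped,
                 params = params, reference_group = reference_group),
            class = "enrichment_experiment")
}

#' @export
print.enrichment_experiment <- function(x, ...) {
  cat(sprintf("enrichment experiment: %d image(s), %d group(s), %d skipped\n",
              nrow(x$scores), length(unique(x$scores$group)), length(x$skipped)))
  agg <- stats::aggregate(score_norm ~ group, data = x$scores,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  print(data.frame(group = agg$group, mean_norm = agg$score_norm[, "mean"],
                   sd_norm = agg$score_norm[, "sd"]), row.names = FALSE)
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}
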