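## ---------------------------------------------------------------------------
## TIFF / CSV / config I/O.  Images travel as native-intensity matrices:
## 8/16-bit TIFFs round-trip bit-identically; float TIFFs are stored as
## 32-bit float scaled by `float_scale`.
## ---------------------------------------------------------------------------

FLOAT_SCALE <- 65535

#' Read a TIFF as an image or stack
#'
#' Single-page files return an image matrix with its native bit depth in
#' the `bits` attribute.  Multi-page files are ambiguous between a time
#' axis and a channel axis, so an explicit `axes` hint is required:
#' `"T"` returns an `image_stack` (list of frames), `"C"` a named list of
#' channel images (2 pages are named `gfp`, `rfp` in page order).
#'
#' @param path TIFF file path.
#' @param axes `"auto"` (single page only), `"T"` or `"C"`.
#' @param frame_interval minutes per frame for `"T"` stacks.
#' @return image matrix, `image_stack`, or named channel list.
#' @export
read_image <- function(path, axes = c("auto", "T", "C"), frame_interval = 1) {
  axes <- match.arg(axes)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  to_img <- function(pg) {
    if (length(dim(pg)) == 3) {
      if (axes == "auto")
        stop("multi-sample (RGB) TIFF without a channel hint: pass axes = \"C\"")
      return(lapply(seq_len(dim(pg)[3]), function(k) pg[, , k]))
    }
    pg
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  fmt <- attr(pages[[1]], "sample.format")
  is_float <- identical(fmt, "float") || isTRUE(bits >= 32)
  fix <- function(m) {
    m <- if (is_float) m * FLOAT_SCALE else m
    as_image(matrix(as.numeric(m), nrow(m), ncol(m)),
             if (is_float) NA_integer_ else as.integer(bits))
  }
  if (length(pages) == 1 && length(dim(pages[[1]])) == 2) {
    if (axes == "T")
      return(structure(list(fix(pages[[1]])), class = "image_stack", times = 0))
    return(fix(pages[[1]]))
  }
  if (axes == "auto")
    stop("multi-page or multi-sample TIFF is ambiguous between T and C axes: ",
         "pass axes = \"T\" or \"C\"")
  flat <- list()
  for (pg in pages) {
    img <- to_img(pg)
    if (is.list(img)) flat <- c(flat, img) else flat <- c(flat, list(img))
  }
  flat <- lapply(flat, fix)
  if (axes == "T") {
    structure(flat, class = "image_stack",
              times = (seq_along(flat) - 1) * frame_interval)
  } else {
    names(flat) <- if (length(flat) == 2) c("gfp", "rfp")
                   else paste0("ch", seq_along(flat))
    flat
  }
}

#' Write an image or stack to TIFF
#'
#' Integer depths (8/16 bit) round-trip bit-identically through
#' [read_image()]; floating-point images are written as 32-bit float TIFF
#' scaled into \[0, 1\] by a fixed factor of 65535 and rescaled on read.
#'
#' @param img image matrix, logical mask, or list of frames/channels.
#' @param path output path.
#' @param bits 8, 16, or NA (float); defaults to the image's `bits`
#'   attribute, else 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = NULL) {
  frames <- if (is.list(img)) img else list(img)
  if (is.null(bits)) {
    b <- image_bits(frames[[1]])
    bits <- if (is.logical(frames[[1]])) 8L else b
  }
  prep <- function(m) {
    m <- unclass(m)
    if (is.logical(m)) m <- m * 255
    if (is.na(bits)) pmax(pmin(m / FLOAT_SCALE, 1), 0)
    else pmax(pmin(round(m), 2^bits - 1), 0) / (2^bits - 1)
  }
  out <- lapply(frames, prep)
  if (length(out) == 1) out <- out[[1]]
  tiff::writeTIFF(out, path,
                  bits.per.sample = if (is.na(bits)) 32L else as.integer(bits))
  invisible(path)
}

#' Resolve a run configuration against the published defaults
#'
#' Reads an optional YAML key/value file; any field not given falls back
#' to the verbatim default of the corresponding recipe ([mask_params()],
#' [counter_params()], [scene_spec()]).
#'
#' @param path YAML file or NULL.
#' @param overrides named list applied on top of the file (CLI precedence).
#' @return list with `mask`, `counter`, `scene` parameter objects and
#'   `raw` (the fully resolved key/value list).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  cfg <- utils::modifyList(cfg, overrides)
  pick <- function(fun, keys) {
    args <- cfg[intersect(keys, names(cfg))]
    do.call(fun, args)
  }
  list(mask = pick(mask_params, names(formals(mask_params))),
       counter = pick(counter_params, names(formals(counter_params))),
       scene = pick(scene_spec, names(formals(scene_spec))),
       raw = cfg)
}

#' Write experiment outputs with a manifest
#'
#' CSV tables (stable column order), optional QC mask TIFFs, and the fully
#' resolved configuration are written under `out_dir`; re-running with the
#' same inputs overwrites the same files deterministically.  Returns a
#' manifest listing every artifact written.
#'
#' @param tables named list of `data.frame`s (written as `<name>.csv`).
#' @param masks named list of logical masks (written as `<name>_mask.tif`),
#'   or NULL.
#' @param config list written as `config.yaml`, or NULL.
#' @param out_dir output directory (created if needed).
#' @return `data.frame` manifest: `name`, `type`, `path`.
#' @export
write_results <- function(tables = list(), masks = NULL, config = NULL,
                          out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(name, type, path)
    manifest[[length(manifest) + 1]] <<- data.frame(name = name, type = type,
                                                    path = path)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    add(nm, "table", p)
  }
  for (nm in names(masks)) {
    p <- file.path(out_dir, paste0(nm, "_mask.tif"))
    write_image(masks[[nm]], p, bits = 8L)
    add(nm, "mask", p)
  }
  if (!is.null(config)) {
    p <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config, p)
    add("config", "config", p)
  }
  if (length(manifest) == 0) return(data.frame(name = character(0),
                                               type = character(0),
                                               path = character(0)))
  do.call(rbind, manifest)
}
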