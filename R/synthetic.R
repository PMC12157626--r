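## ---------------------------------------------------------------------------
## Synthetic two-channel scenes and time-lapse stacks with ground truth.
##
## Scenes emulate live dorsal-mesoderm fields: linear actin filaments carrying
## bright strain-site sub-segments (the structures the Zyxin-LCR reporter
## marks), round puncta, diffuse cytosolic signal, and photon + read noise.
## Everything is parameterized and seeded so each pipeline stage can be tested
## against exact ground truth.
## ---------------------------------------------------------------------------

#' Specify a synthetic two-channel scene
#'
#' Intensities are ideal photon counts per pixel before noise.  The RFP
#' (reference) channel is composed of diffuse background + dim filaments +
#' bright strain-site segments; the GFP (construct) channel is diffuse
#' cytosol + `enrichment_rho` times a strain-site component (+ optional
#' puncta).  `enrichment_rho` is the designed degree of construct
#' recruitment to strain sites: 0 = fully diffuse, 1 = full recruitment.
#'
#' @param width,height canvas size in pixels.
#' @param n_filaments number of filament segments.
#' @param filament_width_sigma Gaussian cross-section sigma, pixels.
#' @param strain_fraction fraction of each filament's length marked as a
#'   contiguous strain-site segment, in \[0, 1\].
#' @param n_puncta number of round GFP puncta.
#' @param puncta_sigma puncta Gaussian sigma, pixels.
#' @param enrichment_rho construct recruitment level, >= 0.
#' @param conserve_total if TRUE the strain-site GFP photons are taken out
#'   of the diffuse pool (redistribution at constant total) instead of
#'   being added on top.
#' @param intensity named list of ideal photon levels: `rfp_background`,
#'   `rfp_filament`, `rfp_strain`, `gfp_diffuse`, `gfp_strain`,
#'   `gfp_puncta`.
#' @param photon_noise apply per-pixel Poisson-law photon noise.
#' @param read_sigma additive Gaussian read-noise sigma (intensity units,
#'   >= 0).
#' @param bit_depth 8, 16, or "float".
#' @param seed integer RNG seed; (spec, seed) fully determines the output.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 512, height = 512,
                       n_filaments = 12, filament_width_sigma = 1.5,
                       strain_fraction = 0.25,
                       n_puncta = 0, puncta_sigma = 2,
                       enrichment_rho = 1, conserve_total = FALSE,
                       intensity = list(rfp_background = 100,
                                        rfp_filament = 150,
                                        rfp_strain = 1200,
                                        gfp_diffuse = 300,
                                        gfp_strain = 1200,
                                        gfp_puncta = 600),
                       photon_noise = TRUE, read_sigma = 5,
                       bit_depth = 16, seed = 1) {
  if (!is.numeric(width) || width < 1) stop("invalid scene field: width must be >= 1")
  if (!is.numeric(height) || height < 1) stop("invalid scene field: height must be >= 1")
  if (n_filaments < 0) stop("invalid scene field: n_filaments must be >= 0")
  if (filament_width_sigma <= 0) stop("invalid scene field: filament_width_sigma must be > 0")
  if (strain_fraction < 0 || strain_fraction > 1)
    stop("invalid scene field: strain_fraction must lie in [0, 1]")
  if (n_puncta < 0) stop("invalid scene field: n_puncta must be >= 0")
  if (enrichment_rho < 0) stop("invalid scene field: enrichment_rho must be >= 0")
  if (read_sigma < 0) stop("invalid scene field: read_sigma must be >= 0")
  if (!(identical(bit_depth, "float") || bit_depth %in% c(8, 16)))
    stop("invalid scene field: bit_depth must be 8, 16 or \"float\"")
  defaults <- eval(formals(scene_spec)$intensity)
  intensity <- utils::modifyList(defaults, as.list(intensity))
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_filaments = as.integer(n_filaments),
                 filament_width_sigma = filament_width_sigma,
                 strain_fraction = strain_fraction,
                 n_puncta = as.integer(n_puncta), puncta_sigma = puncta_sigma,
                 enrichment_rho = enrichment_rho,
                 conserve_total = isTRUE(conserve_total),
                 intensity = intensity,
                 photon_noise = isTRUE(photon_noise), read_sigma = read_sigma,
                 bit_depth = bit_depth, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Specify a synthetic single-channel time-lapse
#'
#' Frames share one scene geometry; the filament-associated (strain-site)
#' construct signal of frame t is scaled by `exp(-t * frame_interval /
#' decay_tau)` while the diffuse pool stays constant, emulating the loss of
#' reporter structures after myosin inhibition.  `decay_tau = Inf` is the
#' vehicle control (no decay).
#'
#' @param base a `scene_spec`; the GFP channel is the imaged channel.
#' @param n_frames number of frames (>= 1); 16 frames at 1 frame/min spans
#'   0-15 min inclusive.
#' @param frame_interval minutes between frames.
#' @param decay_tau exponential time constant in minutes, or `Inf`.
#' @param decay_target which compartment decays; `"strain"` (the
#'   filament-associated construct signal) is the modeled biology.
#' @return object of class `timelapse_spec`.
#' @export
timelapse_spec <- function(base = scene_spec(n_puncta = 0),
                           n_frames = 16, frame_interval = 1,
                           decay_tau = Inf, decay_target = "strain") {
  stopifnot(inherits(base, "scene_spec"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!(is.infinite(decay_tau) || decay_tau > 0)) stop("decay_tau must be > 0 or Inf")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  decay_target <- match.arg(decay_target, c("strain", "filament"))
  structure(list(base = base, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, decay_tau = decay_tau,
                 decay_target = decay_target),
            class = "timelapse_spec")
}

## Distance from every pixel to the segment p0-p1 (rows/cols in pixel units).
segment_distance <- function(nr, nc, p0, p1) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  vr <- p1[1] - p0[1]; vc <- p1[2] - p0[2]
  len2 <- vr^2 + vc^2
  if (len2 == 0) return(sqrt((r - p0[1])^2 + (c - p0[2])^2))
  t <- ((r - p0[1]) * vr + (c - p0[2]) * vc) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  sqrt((r - (p0[1] + t * vr))^2 + (c - (p0[2] + t * vc))^2)
}

## Noiseless scene components + ground-truth masks.  Mask half-width is one
## cross-section sigma: distance-to-axis <= sigma.
scene_geometry <- function(spec) {
  nr <- spec$height; nc <- spec$width
  set.seed(spec$seed)
  fil_profile <- matrix(0, nr, nc)
  strain_profile <- matrix(0, nr, nc)
  fil_mask <- matrix(FALSE, nr, nc)
  strain_mask <- matrix(FALSE, nr, nc)
  sw <- spec$filament_width_sigma
  for (i in seq_len(spec$n_filaments)) {
    len <- stats::runif(1, 0.3, 0.8) * min(nr, nc)
    theta <- stats::runif(1, 0, pi)
    mid <- c(stats::runif(1, 0.15 * nr, 0.85 * nr),
             stats::runif(1, 0.15 * nc, 0.85 * nc))
    d <- c(sin(theta), cos(theta)) * len / 2
    p0 <- mid - d; p1 <- mid + d
    df <- segment_distance(nr, nc, p0, p1)
    fil_profile <- fil_profile + exp(-df^2 / (2 * sw^2))
    fil_mask <- fil_mask | (df <= sw)
    if (spec$strain_fraction > 0) {
      a <- stats::runif(1, 0, 1 - spec$strain_fraction)
      b <- a + spec$strain_fraction
      q0 <- p0 + a * (p1 - p0); q1 <- p0 + b * (p1 - p0)
      ds <- segment_distance(nr, nc, q0, q1)
      strain_profile <- strain_profile + exp(-ds^2 / (2 * sw^2))
      strain_mask <- strain_mask | (ds <= sw)
    } else {
      stats::runif(1)   # keep the RNG stream aligned across strain fractions
    }
  }
  puncta_profile <- matrix(0, nr, nc)
  puncta_mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(spec$n_puncta)) {
    ctr <- c(stats::runif(1, 0.1 * nr, 0.9 * nr), stats::runif(1, 0.1 * nc, 0.9 * nc))
    dp <- segment_distance(nr, nc, ctr, ctr)
    puncta_profile <- puncta_profile + exp(-dp^2 / (2 * spec$puncta_sigma^2))
    puncta_mask <- puncta_mask | (dp <= spec$puncta_sigma)
  }
  list(fil_profile = fil_profile, strain_profile = strain_profile,
       puncta_profile = puncta_profile,
       fil_mask = fil_mask, strain_mask = strain_mask, puncta_mask = puncta_mask)
}

## Ideal (noiseless) channels from geometry.  The GFP strain-site component
## is returned separately so time-lapse decay can rescale it exactly; it is
## rendered strictly inside the ground-truth strain mask so that compartment
## statistics (mean inside vs outside) are exact, not blurred by Gaussian
## tails.
scene_ideal <- function(spec, geom) {
  I <- spec$intensity
  rfp <- I$rfp_background + I$rfp_filament * geom$fil_profile +
    I$rfp_strain * geom$strain_profile
  gfp_strain <- spec$enrichment_rho * I$gfp_strain * geom$strain_profile *
    geom$strain_mask
  diffuse <- I$gfp_diffuse
  if (spec$conserve_total) {
    # photon redistribution: what goes to strain sites leaves the cytosol
    diffuse <- diffuse - sum(gfp_strain) / (spec$width * spec$height)
    if (diffuse < 0)
      stop("conserve_total: strain-site photon demand exceeds the diffuse pool")
  }
  gfp <- diffuse + gfp_strain + I$gfp_puncta * geom$puncta_profile
  list(gfp = gfp, rfp = rfp, gfp_strain = gfp_strain, gfp_diffuse = diffuse)
}

#' Apply the photon + read noise model and quantize to a bit depth
#'
#' Photon noise is Poisson-law per pixel with mean equal to the ideal
#' image; read noise is additive zero-mean Gaussian with the stated sigma.
#' Integer depths round and clip to the representable range; `"float"`
#' clips at zero only.
#'
#' @param ideal nonnegative ideal image.
#' @param photon_noise logical.
#' @param read_sigma Gaussian read-noise sigma (>= 0).
#' @param bit_depth 8, 16, or "float".
#' @param seed optional integer; when given, the noise field is drawn from
#'   a stream seeded with it (reproducible).
#' @return noisy image with the matching `bits` attribute.
#' @export
render_noise <- function(ideal, photon_noise = TRUE, read_sigma = 0,
                         bit_depth = 16, seed = NULL) {
  if (any(ideal < 0)) stop("ideal image must be >= 0 everywhere")
  if (read_sigma < 0) stop("read_sigma must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- ideal
  if (photon_noise)
    out <- matrix(stats::rpois(length(ideal), as.numeric(ideal)),
                  nrow(ideal), ncol(ideal))
  if (read_sigma > 0)
    out <- out + matrix(stats::rnorm(length(ideal), 0, read_sigma),
                        nrow(ideal), ncol(ideal))
  if (identical(bit_depth, "float")) {
    out[out < 0] <- 0
    return(as_image(out, NA_integer_))
  }
  top <- 2^bit_depth - 1
  out <- round(out)
  out[out < 0] <- 0
  out[out > top] <- top
  as_image(out, as.integer(bit_depth))
}

#' Generate a two-channel scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with `gfp`, `rfp` (noisy images at the spec bit depth) and
#'   `truth`: ground-truth masks (`filament_mask`, `strain_mask`,
#'   `puncta_mask`), the noiseless channels (`gfp_ideal`, `rfp_ideal`), the
#'   noiseless strain-site GFP component (`gfp_strain_ideal`), and the spec.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  geom <- scene_geometry(spec)
  ideal <- scene_ideal(spec, geom)
  gfp <- render_noise(ideal$gfp, spec$photon_noise, spec$read_sigma,
                      spec$bit_depth, seed = spec$seed + 1L)
  rfp <- render_noise(ideal$rfp, spec$photon_noise, spec$read_sigma,
                      spec$bit_depth, seed = spec$seed + 2L)
  truth <- list(filament_mask = geom$fil_mask, strain_mask = geom$strain_mask,
                puncta_mask = geom$puncta_mask,
                gfp_ideal = ideal$gfp, rfp_ideal = ideal$rfp,
                gfp_strain_ideal = ideal$gfp_strain,
                gfp_diffuse_level = ideal$gfp_diffuse,
                spec = spec, seed = spec$seed)
  list(gfp = gfp, rfp = rfp, truth = truth)
}

#' Generate a single-channel time-lapse with per-frame ground truth
#'
#' The imaged channel is the construct (GFP) channel of the base scene; the
#' decay-target component of frame t (t = 0, 1, ...) is scaled by
#' `exp(-t * frame_interval / decay_tau)`.  Frame noise streams are derived
#' deterministically from the base seed.
#'
#' @param spec a [timelapse_spec()].
#' @return list with `stack` (list of frames, class `image_stack`, with
#'   `times` attribute in minutes) and `truth` (masks, per-frame decay
#'   factors, per-frame noiseless frames, spec).
#' @export
make_timelapse <- function(spec) {
  stopifnot(inherits(spec, "timelapse_spec"))
  base <- spec$base
  geom <- scene_geometry(base)
  ideal <- scene_ideal(base, geom)
  I <- base$intensity
  decaying <- if (spec$decay_target == "strain") ideal$gfp_strain
              else I$rfp_filament * geom$fil_profile
  constant <- ideal$gfp - decaying
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  factors <- if (is.infinite(spec$decay_tau)) rep(1, spec$n_frames)
             else exp(-times / spec$decay_tau)
  frames <- vector("list", spec$n_frames)
  ideal_frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    ideal_t <- constant + factors[t] * decaying
    ideal_frames[[t]] <- ideal_t
    frames[[t]] <- render_noise(ideal_t, base$photon_noise, base$read_sigma,
                                base$bit_depth, seed = base$seed + 100L + t)
  }
  stack <- structure(frames, class = "image_stack", times = times)
  truth <- list(filament_mask = geom$fil_mask, strain_mask = geom$strain_mask,
                decay_factors = factors, times = times,
                ideal_frames = ideal_frames,
                decaying_component = decaying,
                spec = spec, seed = base$seed)
  list(stack = stack, truth = truth)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec %dx%d: %d filaments (sigma %.2g px, strain fraction %.2g), %d puncta, rho = %.3g, seed %d\n",
              x$width, x$height, x$n_filaments, x$filament_width_sigma,
              x$strain_fraction, x$n_puncta, x$enrichment_rho, x$seed))
  invisible(x)
}

#' @export
print.timelapse_spec <- function(x, ...) {
  cat(sprintf("timelapse_spec: %d frames every %.3g min, tau = %s min (%s decays)\n",
              x$n_frames, x$frame_interval,
              if (is.infinite(x$decay_tau)) "Inf" else format(x$decay_tau),
              x$decay_target))
  invisible(x)
}
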