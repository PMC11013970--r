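# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sphere-phantom specification
#'
#' Geometry of a synthetic 3-D cell phantom: filled or shell spheres on a
#' constant background in a voxel volume. Every test of 3-D reconstruction
#' behaviour in the package runs on these phantoms, because they provide
#' exact ground truth.
#'
#' @param volume_shape integer `(x, y, m)` voxel dimensions.
#' @param spheres data.frame with columns `cx, cy, cz, radius, intensity`
#'   and optional `shell` (shell thickness in voxels; `NA` = filled).
#' @param background background intensity (>= 0).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape, spheres, background = 0) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1),
            background >= 0)
  spheres <- as.data.frame(spheres)
  need <- c("cx", "cy", "cz", "radius", "intensity")
  if (!all(need %in% names(spheres)))
    stop("`spheres` needs columns ", paste(need, collapse = ", "))
  if (!"shell" %in% names(spheres)) spheres$shell <- NA_real_
  if (any(spheres$radius <= 0)) stop("sphere radii must be positive")
  if (any(spheres$intensity < 0)) stop("sphere intensities must be >= 0")
  for (ax in 1:3) {
    c_ <- spheres[[c("cx", "cy", "cz")[ax]]]
    if (any(c_ - spheres$radius < 1 | c_ + spheres$radius > volume_shape[ax]))
      stop("sphere outside volume along axis ", ax)
  }
  structure(list(volume_shape = as.integer(volume_shape), spheres = spheres,
                 background = background),
            class = "phantom_spec")
}

#' Randomized default phantom
#'
#' Seed-controlled placement of filled spheres with radii 8-20 voxels in a
#' 128 x 128 x 100 volume (5 spheres by default) — a stand-in geometry for
#' sphere-based cell phantoms; smaller volumes are supported for fast
#' tests.
#'
#' @param seed integer seed controlling placement.
#' @param volume_shape voxel dimensions.
#' @param n_spheres number of spheres.
#' @param radius_range min/max radius in voxels.
#' @param intensity sphere interior intensity.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed = 1L, volume_shape = c(128, 128, 100),
                                n_spheres = 5L, radius_range = c(8, 20),
                                intensity = 100) {
  radius_range[2] <- min(radius_range[2], floor((min(volume_shape) - 2) / 2))
  with_seed(seed, {
    r <- stats::runif(n_spheres, radius_range[1], radius_range[2])
    ctr <- vapply(1:3, function(ax)
      stats::runif(n_spheres, 1 + r, volume_shape[ax] - r), numeric(n_spheres))
    phantom_spec(volume_shape,
                 data.frame(cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
                            radius = r, intensity = intensity))
  })
}

#' Voxelize a sphere phantom
#'
#' Renders the spheres of a [phantom_spec()] into an [image_stack]
#' (z axis). Deterministic given the spec. With background 0, frames
#' beyond the extent of every sphere are exactly zero — the sharp
#' intensity transitions that make the unconvolved phantom a worst case
#' for low-rank reconstruction.
#'
#' @param spec a [phantom_spec()].
#' @param step z spacing recorded on the output stack.
#' @return An [image_stack] with `axis_kind = "z"`.
#' @export
make_phantom <- function(spec, step = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$volume_shape
  arr <- array(spec$background, vs)
  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    ix <- max(1L, floor(s$cx - s$radius)):min(vs[1], ceiling(s$cx + s$radius))
    iy <- max(1L, floor(s$cy - s$radius)):min(vs[2], ceiling(s$cy + s$radius))
    iz <- max(1L, floor(s$cz - s$radius)):min(vs[3], ceiling(s$cz + s$radius))
    d2 <- outer(outer((ix - s$cx)^2, (iy - s$cy)^2, "+"), (iz - s$cz)^2, "+")
    mask <- if (is.na(s$shell)) d2 <= s$radius^2
            else d2 <= s$radius^2 & d2 >= (s$radius - s$shell)^2
    sub <- arr[ix, iy, iz, drop = FALSE]
    sub[mask] <- s$intensity
    arr[ix, iy, iz] <- sub
  }
  image_stack(arr, "z", step)
}

#' Widefield point-spread-function specification
#'
#' Parameters of a scalar-diffraction defocus PSF model for an
#' epifluorescence system. Defaults follow a high-NA oil objective with
#' green emission sampled at 25 nm laterally and 50 nm axially.
#'
#' @param na numerical aperture (0 < NA < `refractive_index`).
#' @param wavelength emission wavelength in nm.
#' @param refractive_index immersion refractive index.
#' @param pixel_size_xy lateral sampling in nm.
#' @param z_step axial sampling in nm.
#' @param shape integer `(x, y, m)` support.
#' @return A `psf_spec`.
#' @export
psf_spec <- function(na = 1.4, wavelength = 520, refractive_index = 1.515,
                     pixel_size_xy = 25, z_step = 50,
                     shape = c(33, 33, 21)) {
  if (na <= 0 || na >= refractive_index)
    stop("need 0 < NA < refractive index")
  stopifnot(wavelength > 0, pixel_size_xy > 0, z_step > 0,
            length(shape) == 3L, all(shape >= 1))
  structure(list(na = na, wavelength = wavelength,
                 refractive_index = refractive_index,
                 pixel_size_xy = pixel_size_xy, z_step = z_step,
                 shape = as.integer(shape)),
            class = "psf_spec")
}

#' Theoretical widefield PSF stack
#'
#' Scalar-diffraction defocus model: the in-focus amplitude is the Airy
#' pupil integral and defocus adds the quadratic phase
#' `exp(-i k rho^2 z NA^2 / (2 n))` across the pupil radius `rho`,
#' integrated numerically. The intensity stack is circularly symmetric in
#' xy, peaks at the central frame, and is normalized to unit total
#' intensity.
#'
#' @param spec a [psf_spec()].
#' @param n_quad quadrature points over the pupil radius.
#' @return An [image_stack] (`axis_kind = "z"`, step in micrometers).
#' @export
make_psf <- function(spec, n_quad = 200L) {
  stopifnot(inherits(spec, "psf_spec"))
  sh <- spec$shape
  k <- 2 * pi / spec$wavelength
  cx <- (sh[1] + 1) / 2; cy <- (sh[2] + 1) / 2; cz <- (sh[3] + 1) / 2
  rho <- (seq_len(n_quad) - 0.5) / n_quad
  drho <- 1 / n_quad
  # radial distances in nm for every xy pixel
  r <- sqrt(outer(((seq_len(sh[1]) - cx) * spec$pixel_size_xy)^2,
                  ((seq_len(sh[2]) - cy) * spec$pixel_size_xy)^2, "+"))
  ru <- sort(unique(as.vector(r)))
  J <- outer(ru, rho, function(rr, p) besselJ(k * spec$na * rr * p, 0))
  arr <- array(0, sh)
  for (iz in seq_len(sh[3])) {
    z <- (iz - cz) * spec$z_step
    defoc <- exp(-1i * k * rho^2 * z * spec$na^2 /
                   (2 * spec$refractive_index)) * rho * drho
    amp <- drop(J %*% defoc)
    inten <- Mod(amp)^2
    arr[, , iz] <- inten[match(r, ru)]
  }
  arr <- arr / sum(arr)
  image_stack(arr, "z", spec$z_step / 1000)
}

# Smallest 5-smooth integer >= n (keeps base fft fast on padded sizes).
next_fast_size <- function(n) {
  while (TRUE) {
    k <- n
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(as.integer(n))
    n <- n + 1
  }
}

#' Convolve a stack with a 3-D kernel
#'
#' Frequency-domain 3-D linear convolution with zero padding, cropped to
#' the input shape ("same" mode, aligned so that a centred delta kernel
#' reproduces the input). Zero-padding means structures within half a
#' kernel width of the border lose some intensity; total intensity of
#' interior structures is conserved.
#'
#' @param stack an [image_stack].
#' @param psf an [image_stack] (or 3-D array) kernel, support not larger
#'   than the stack.
#' @return An [image_stack] with the metadata of `stack`.
#' @export
convolve_stack <- function(stack, psf) {
  stopifnot(inherits(stack, "image_stack"))
  h <- if (inherits(psf, "image_stack")) psf$data else psf
  dx <- dim(stack$data); dh <- dim(h)
  if (any(dh > dx)) stop("PSF support exceeds the volume")
  pd <- vapply(dx + dh - 1L, next_fast_size, integer(1))
  a <- array(0, pd); a[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <-
    stack$data
  b <- array(0, pd); b[seq_len(dh[1]), seq_len(dh[2]), seq_len(dh[3])] <- h
  full <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) /
    prod(pd)
  off <- floor(dh / 2)
  out <- full[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2]),
              off[3] + seq_len(dx[3]), drop = FALSE]
  image_stack(out, stack$axis_kind, stack$step, stack$origin)
}

#' Poisson shot-noise corruption
#'
#' Each voxel is replaced by a draw from `Poisson(photon_scale * value) /
#' photon_scale`, emulating photon-counting detection: `photon_scale`
#' converts intensity units into expected photon counts, so it directly
#' sets the SNR (variance equals mean in photon units). Zero stays exactly
#' zero, and a given seed reproduces the draw bit-for-bit.
#'
#' @param stack an [image_stack] with non-negative intensities.
#' @param photon_scale photons per intensity unit (> 0).
#' @param seed integer seed.
#' @return A corrupted [image_stack].
#' @export
add_poisson <- function(stack, photon_scale = 1, seed = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (photon_scale <= 0) stop("`photon_scale` must be positive")
  if (any(stack$data < 0)) stop("negative intensities cannot be Poisson-",
                                "corrupted")
  lam <- stack$data * photon_scale
  noisy <- with_seed(seed,
    array(stats::rpois(length(lam), lam), dim(lam))) / photon_scale
  image_stack(noisy, stack$axis_kind, stack$step, stack$origin)
}

# Smooth blob pattern: sum of seed-placed 2-D Gaussians, scaled to `peak`.
make_blob_pattern <- function(frame_shape, peak = 20, n_blobs = 3L,
                              seed = 1L) {
  with_seed(seed, {
    cx <- stats::runif(n_blobs, 0.25, 0.75) * frame_shape[1]
    cy <- stats::runif(n_blobs, 0.25, 0.75) * frame_shape[2]
    sg <- stats::runif(n_blobs, 0.08, 0.2) * min(frame_shape)
    pat <- matrix(0, frame_shape[1], frame_shape[2])
    for (i in seq_len(n_blobs))
      pat <- pat + exp(-(outer((seq_len(frame_shape[1]) - cx[i])^2,
                               (seq_len(frame_shape[2]) - cy[i])^2, "+")) /
                         (2 * sg[i]^2))
    pat * peak / max(pat)
  })
}

#' Synthetic series specification
#'
#' Generative parameters for the 1-D-modulated test series that emulate
#' the experimental regimes the decomposition is used on:
#' \describe{
#'   \item{`bleach`}{a fixed spatial pattern under exponential
#'     photobleaching, `I_k = pattern * exp(-decay_rate (k-1))` —
#'     low-photon time-lapse imaging of a dim sterol probe.}
#'   \item{`polarimetry`}{angle sweep `I(theta_k) = background + pattern *
#'     exp(-decay_rate (k-1)) * (1 + modulation_depth cos 2(theta_k -
#'     theta0))` — two-photon polarimetry with superimposed bleaching and
#'     a static offset.}
#'   \item{`standing_wave`}{`background + amplitude * sin(spatial) *
#'     cos(omega (k-1))` — the classic control on which plain DMD fails;
#'     rank 1 at background 0, rank 2 otherwise.}
#'   \item{`axial_envelope`}{pattern weighted by a Gaussian axial profile
#'     centred mid-stack — a 3-D stack whose structure is confined to the
#'     central frames.}
#' }
#' Defaults are the package's reference study conditions (see the methods
#' vignette) and are deliberately not tuned per call site.
#'
#' @param kind one of the four series kinds.
#' @param frame_shape `(x, y)` pixels.
#' @param m number of frames.
#' @param decay_rate bleaching rate per frame (>= 0).
#' @param modulation_depth polarimetry modulation in [0, 1].
#' @param theta0 polarimetry peak angle in degrees.
#' @param background additive constant.
#' @param peak peak intensity of the spatial pattern
#'   (photon-count-like units).
#' @param photon_scale photons per intensity unit for the Poisson
#'   observation; `NA` or 0 returns a noise-free observation.
#' @param omega standing-wave temporal frequency (rad/frame).
#' @param envelope_sigma axial-envelope width in frames.
#' @param step,origin frame spacing and first-frame coordinate (degrees
#'   for polarimetry).
#' @param seed integer seed (pattern placement and Poisson draw).
#' @return A `series_spec`.
#' @export
series_spec <- function(kind = c("bleach", "polarimetry", "standing_wave",
                                 "axial_envelope"),
                        frame_shape = c(32, 32), m = NULL,
                        decay_rate = NULL, modulation_depth = 0.8,
                        theta0 = 100, background = NULL, peak = 20,
                        photon_scale = 1, omega = 0.3,
                        envelope_sigma = 4, step = NULL, origin = 0,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(m))
    m <- switch(kind, bleach = 50L, polarimetry = 36L,
                standing_wave = 30L, axial_envelope = 40L)
  if (is.null(decay_rate))
    decay_rate <- switch(kind, bleach = 0.02, polarimetry = 0.005, 0)
  if (is.null(background))
    background <- switch(kind, polarimetry = 2, 0)
  if (is.null(step))
    step <- switch(kind, polarimetry = 10, 1)
  if (kind == "standing_wave") frame_shape <- c(8, 8)
  stopifnot(decay_rate >= 0, modulation_depth >= 0, modulation_depth <= 1,
            m >= 2)
  structure(list(kind = kind, frame_shape = as.integer(frame_shape),
                 m = as.integer(m), decay_rate = decay_rate,
                 modulation_depth = modulation_depth, theta0 = theta0,
                 background = background, peak = peak,
                 photon_scale = photon_scale, omega = omega,
                 envelope_sigma = envelope_sigma, step = step,
                 origin = origin, seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a synthetic series with ground truth
#'
#' Renders the noise-free truth described by a [series_spec()] and a
#' Poisson-corrupted observation of it (for the standing wave, which takes
#' negative values, or when `photon_scale` is `NA`/0, the observation is
#' the truth itself).
#'
#' @param spec a [series_spec()].
#' @return list with `truth` and `observed`, both [image_stack]s.
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  fs <- spec$frame_shape; m <- spec$m
  axis <- if (spec$kind == "polarimetry") "angle"
          else if (spec$kind %in% c("axial_envelope")) "z" else "time"
  k <- seq_len(m)
  arr <- array(0, c(fs, m))
  if (spec$kind == "standing_wave") {
    spatial <- matrix(rep(sin(2 * pi * (seq_len(fs[1]) - 1) / fs[1]), fs[2]),
                      fs[1], fs[2])
    for (j in k)
      arr[, , j] <- spec$background +
        spec$peak * spatial * cos(spec$omega * (j - 1))
  } else {
    pat <- make_blob_pattern(fs, spec$peak, seed = spec$seed)
    weights <- switch(spec$kind,
      bleach = exp(-spec$decay_rate * (k - 1)),
      axial_envelope = exp(-(k - (m + 1) / 2)^2 /
                             (2 * spec$envelope_sigma^2)),
      polarimetry = exp(-spec$decay_rate * (k - 1)))
    for (j in k) {
      fr <- pat * weights[j]
      if (spec$kind == "polarimetry") {
        theta <- spec$origin + (j - 1) * spec$step
        fr <- fr * (1 + spec$modulation_depth *
                      cos(2 * (theta - spec$theta0) * pi / 180))
      }
      arr[, , j] <- spec$background + fr
    }
  }
  truth <- image_stack(arr, axis, spec$step, spec$origin)
  observed <- if (!is.na(spec$photon_scale) && spec$photon_scale > 0 &&
                  all(arr >= 0))
    add_poisson(truth, spec$photon_scale, spec$seed)
  else truth
  list(truth = truth, observed = observed)
}

#' Write a series/phantom with a provenance sidecar
#'
#' Writes the stack as 32-bit float TIFF and a YAML sidecar recording the
#' full generative spec, so any synthetic dataset can be regenerated
#' exactly.
#'
#' @param stack an [image_stack].
#' @param spec the generating spec object (any list-like).
#' @param prefix output path prefix.
#' @return TIFF path, invisibly.
#' @export
write_synthetic <- function(stack, spec, prefix) {
  path <- paste0(prefix, ".tif")
  write_stack(stack, path)
  side <- lapply(unclass(spec), function(x)
    if (is.data.frame(x)) as.list(x) else x)
  side$class <- class(spec)[1]
  yaml::write_yaml(side, paste0(prefix, "_spec.yaml"))
  invisible(path)
}
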