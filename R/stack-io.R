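#' Image stacks with axis semantics
#'
#' An `image_stack` is a 3-D intensity array with dimensions
#' `(x, y, frame)` plus the meaning of the stack axis: `"time"` for
#' time-lapse series, `"z"` for 3-D stacks acquired along the optical axis,
#' or `"angle"` for two-photon polarimetry sweeps over the polarization
#' angle. `step` is the spacing between consecutive frames (seconds,
#' micrometers or degrees) and `origin` the coordinate of the first frame,
#' so frame `k` sits at `origin + (k - 1) * step`.
#'
#' Intensities are stored in double precision regardless of the bit depth
#' of the source file; values are photon-count-like and are never rescaled
#' on input.
#'
#' @param data numeric 3-D array `(x, y, m)`; a matrix is treated as a
#'   single-frame stack.
#' @param axis_kind one of `"time"`, `"z"`, `"angle"`.
#' @param step positive scalar spacing between frames.
#' @param origin coordinate of the first frame (same units as `step`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, axis_kind = c("time", "z", "angle"),
                        step = 1, origin = 0) {
  axis_kind <- match.arg(axis_kind)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (x, y, frames)")
  if (dim(data)[3] < 1L) stop("stack must contain at least one frame")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("stack intensities must all be finite")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be a positive scalar")
  structure(
    list(data = data, axis_kind = axis_kind,
         step = as.numeric(step), origin = as.numeric(origin)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  unit <- switch(x$axis_kind, time = "s", z = "um", angle = "deg")
  cat(sprintf("<image_stack> %d x %d pixels, %d frame(s) along %s axis\n",
              d[1], d[2], d[3], x$axis_kind))
  cat(sprintf("  step %g %s, origin %g, intensity range [%g, %g]\n",
              x$step, unit, x$origin, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Number of frames in a stack
#' @param stack an [image_stack].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Coordinates of frames along the stack axis
#'
#' Frame `k` sits at `origin + (k - 1) * step`.
#' @param stack an [image_stack].
#' @param k frame indices (default: all frames).
#' @return numeric coordinates in the stack's axis units.
#' @export
frame_coords <- function(stack, k = seq_len(n_frames(stack))) {
  stack$origin + (k - 1) * stack$step
}

#' Read a multi-page TIFF into an image stack
#'
#' Accepts single-channel grayscale TIFF with 8/16-bit unsigned or 32-bit
#' float samples. Values are converted to double precision without any
#' rescaling (a 16-bit file with maximum 65535 yields a stack with maximum
#' 65535). Multi-channel files are rejected; split channels upstream.
#'
#' @param path path to a single- or multi-page TIFF file.
#' @inheritParams image_stack
#' @return An [image_stack] with one frame per TIFF page.
#' @export
read_stack <- function(path, axis_kind = c("time", "z", "angle"), step = 1,
                       origin = 0) {
  axis_kind <- match.arg(axis_kind)
  if (!file.exists(path)) stop("cannot read TIFF file: ", path)
  # as.is = TRUE keeps integer samples unscaled; float samples are only
  # readable without it (they come back unscaled anyway)
  pages <- tryCatch(
    tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
             error = function(e) tiff::readTIFF(path, all = TRUE)),
    error = function(e)
      stop("failed to read TIFF '", path, "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) pages[[i]] <- p[, , 1]
      else stop("multi-channel TIFF not supported (file '", path,
                "', page ", i, " has ", dim(p)[3], " channels)")
    }
  }
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), d1))
      stop("inconsistent page dimensions in '", path, "' at page ", i)
  data <- array(0, c(d1, length(pages)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]]
  image_stack(data, axis_kind, step, origin)
}

#' Write an image stack as a 32-bit float multi-page TIFF
#'
#' Output is single-channel grayscale, one page per frame, IEEE float
#' samples. Values are stored as-is (no rescaling, no clipping), so
#' negative excursions of reconstructions survive a round trip; the only
#' loss is the double-to-float32 rounding. `read_stack(write_stack(s))`
#' reproduces `s` exactly whenever its values are representable in float32.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(seq_len(n_frames(stack)), function(k) stack$data[, , k])
  write_tiff_float32(frames, path)
  invisible(path)
}

# Minimal little-endian single-channel float32 multi-page TIFF writer.
# The installed tiff package reads float TIFF but cannot write it.
# Layout per page: [pixel strip][IFD]; IFDs chained in page order.
write_tiff_float32 <- function(frames, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write TIFF: ", path))
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, offset of first IFD (follows first page's data)
  writeBin(charToRaw("II"), con); w16(42L)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  strip_bytes <- 4L * h * w
  n_entries <- 10L
  ifd_bytes <- 2L + 12L * n_entries + 4L
  page_bytes <- strip_bytes + ifd_bytes
  first_ifd <- 8L + strip_bytes
  w32(first_ifd)
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L && count == 1L) { w16(value); w16(0L) } else w32(value)
  }
  for (p in seq_along(frames)) {
    fr <- frames[[p]]
    # TIFF samples run row-major, top row first
    writeBin(as.numeric(t(fr)), con, size = 4, endian = "little")
    offset0 <- 8L + (p - 1L) * page_bytes
    w16(n_entries)
    entry(256L, 4L, 1L, w)            # ImageWidth
    entry(257L, 4L, 1L, h)            # ImageLength
    entry(258L, 3L, 1L, 32L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)           # Compression: none
    entry(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
    entry(273L, 4L, 1L, offset0)      # StripOffsets
    entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
    entry(278L, 4L, 1L, h)            # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)  # StripByteCounts
    entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
    next_ifd <- if (p < length(frames)) 8L + p * page_bytes + strip_bytes
                else 0L
    w32(next_ifd)
  }
  invisible(path)
}

#' Reshape a stack into its snapshot matrix
#'
#' Each frame is flattened into one column (column-major over the image
#' axes, R's native `as.vector` order — the single fixed bijection used
#' throughout the package), giving an `n x m` matrix with `n = x * y`.
#' This is the representation all decompositions consume.
#'
#' @param stack an [image_stack].
#' @return A `snapshot_matrix`: list with `matrix`, `frame_shape`, and the
#'   axis metadata of the source.
#' @export
to_snapshot_matrix <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  structure(
    list(matrix = matrix(stack$data, nrow = d[1] * d[2], ncol = d[3]),
         frame_shape = d[1:2], axis_kind = stack$axis_kind,
         step = stack$step, origin = stack$origin),
    class = "snapshot_matrix")
}

#' Reshape a snapshot matrix back into an image stack
#'
#' Exact inverse of [to_snapshot_matrix()]. Complex-valued matrices (e.g.
#' individual DMD modes) are refused unless `take_real = TRUE`, in which
#' case the real part is kept.
#'
#' @param snap a `snapshot_matrix`, or a plain matrix plus `frame_shape`.
#' @param frame_shape `(x, y)` when `snap` is a bare matrix.
#' @param take_real keep the real part of a complex matrix.
#' @inheritParams image_stack
#' @return An [image_stack].
#' @export
from_snapshot_matrix <- function(snap, frame_shape = NULL,
                                 axis_kind = "time", step = 1, origin = 0,
                                 take_real = FALSE) {
  if (inherits(snap, "snapshot_matrix")) {
    m <- snap$matrix; frame_shape <- snap$frame_shape
    axis_kind <- snap$axis_kind; step <- snap$step; origin <- snap$origin
  } else m <- snap
  if (is.null(frame_shape) || length(frame_shape) != 2L)
    stop("`frame_shape` (x, y) is required")
  if (is.complex(m)) {
    if (!take_real)
      stop("matrix is complex; pass take_real = TRUE to keep the real part")
    m <- Re(m)
  }
  if (nrow(m) != prod(frame_shape))
    stop("row count ", nrow(m), " does not match frame_shape ",
         frame_shape[1], " x ", frame_shape[2])
  image_stack(array(m, c(frame_shape, ncol(m))), axis_kind, step, origin)
}

#' Time-shifted snapshot pair
#'
#' Splits the snapshot matrix into the two shifted matrices whose linear
#' relation `X2 = A X1` defines the one-step propagator: `X1` holds frames
#' `1..m-1` and `X2` frames `2..m`.
#'
#' @param snap a `snapshot_matrix` (or bare matrix).
#' @return list with `X1` and `X2`.
#' @export
shift_matrices <- function(snap) {
  m <- if (inherits(snap, "snapshot_matrix")) snap$matrix else snap
  if (ncol(m) < 2L) stop("at least two snapshots required")
  list(X1 = m[, -ncol(m), drop = FALSE], X2 = m[, -1L, drop = FALSE])
}
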